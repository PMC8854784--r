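polar_pad <- function(n) paste(rep(c("D", "E", "Q", "N", "S"), length.out = n),
                               collapse = "")

test_that("a constructed tripartite signal peptide is found at its site", {
  # M + KK + 10xL + A S A | D...  -> cleavage at the -1 alanine (pos 16)
  s <- paste0("MKK", strrep("L", 10), "ASA", strrep("D", 20))
  res <- detect_spi(s)
  expect_true(res$present)
  expect_equal(res$cleavage_pos, 16L)
  expect_gt(res$confidence, 0.5)
  ann <- annotate_signals(s)
  expect_equal(ann$cleavage_window, "LASADDDD")
})

test_that("signal-peptide rules are each necessary", {
  expect_false(detect_spi(strrep("D", 40))$present)            # no h-region
  no_site <- paste0("MKK", strrep("L", 10), "ASW", strrep("D", 20))
  expect_false(detect_spi(no_site)$present)                    # -1 not small
  no_n <- paste0("MDD", strrep("L", 10), "ASA", strrep("D", 20))
  expect_false(detect_spi(no_n)$present)                       # no K/R in 1..5
})

test_that("a planted lipobox is found at its cysteine", {
  # h-region over 3..12, lipobox L-S-G-C at 12..15
  s <- paste0("MK", strrep("L", 9), "LSGC", polar_pad(40))
  res <- detect_lipobox(s)
  expect_true(res$present)
  expect_equal(res$cys_pos, 15L)
})

test_that("the printed lipoprotein window FVLSGCG is matched and rendered", {
  s <- paste0("MKR", "LLILLLILLLIL", "FVLSGCG", polar_pad(40))
  res <- detect_lipobox(s)
  expect_true(res$present)
  expect_equal(res$cys_pos, 21L)
  ann <- annotate_signals(s)
  expect_equal(ann$selected, "spii")
  expect_equal(ann$cleavage_window, "FVLSGCG")
})

test_that("no cysteine in the scan zone means no lipobox", {
  s <- paste0("MK", strrep("L", 16), polar_pad(30), "C", polar_pad(10))
  expect_false(detect_lipobox(s)$present)
})

test_that("a planted twin-arginine motif is found", {
  s <- paste0("MKA", "SRRGFL", polar_pad(30))
  res <- detect_tat(s)
  expect_true(res$present)
  expect_equal(res$rr_pos, 5L)
  no_rr <- paste0("MKA", "SRDGFL", polar_pad(30))
  expect_false(detect_tat(no_rr)$present)
})

test_that("detectors agree with independent pattern oracles on random sequences", {
  tat_oracle <- function(s) {
    zone <- substr(s, 1, 35)
    m <- regexpr("[ST]RR[A-Z][FGAVML][LITMVF]", zone)
    if (m > 0 && m <= 30) as.integer(m) + 1L else NA_integer_
  }
  lpxtg_pattern_oracle <- function(s) {
    L <- nchar(s)
    if (L < 50) return(NA_integer_)
    zone_start <- L - 39L
    m <- gregexpr("LP[A-Z]TG", s)[[1]]
    m <- m[m >= zone_start & m > 0]
    if (length(m)) max(m) else NA_integer_
  }
  withr::with_seed(5, {
    n_tat_hits <- 0L
    for (i in 1:1000) {
      s <- random_aa_seq(sample(50:120, 1))
      got <- detect_tat(s)
      want <- tat_oracle(s)
      expect_equal(got$present, !is.na(want))
      if (!is.na(want)) {
        expect_equal(got$rr_pos, want)
        n_tat_hits <- n_tat_hits + 1L
      }
      # LPXTG: the motif position must agree whenever the detector fires,
      # and the detector must never fire when the pattern oracle finds
      # nothing.
      lp <- scan_lpxtg(s)
      pat <- lpxtg_pattern_oracle(s)
      if (lp$present) expect_true(lp$motif_start %in% pat)
      if (is.na(pat)) expect_false(lp$present)
    }
    expect_gt(n_tat_hits, 0L)  # the oracle comparison actually exercised hits
  })
})

test_that("canonical sortase tails are recognised and rules are necessary", {
  body <- polar_pad(60)
  good <- paste0(body, "LPETG", strrep("L", 15), "KRKK")
  res <- scan_lpxtg(good)
  expect_true(res$present)
  expect_equal(res$motif_start, 61L)
  at_start <- paste0("LPETG", polar_pad(60))
  expect_false(scan_lpxtg(at_start)$present)
  no_charge <- paste0(body, "LPETG", strrep("L", 15), "AAAA")
  expect_false(scan_lpxtg(no_charge)$present)
  no_tm <- paste0(body, "LPETG", polar_pad(15), "KRKK")
  expect_false(scan_lpxtg(no_tm)$present)
})

test_that("cleavage windows have the printed widths and sentinel", {
  s <- paste0("MKK", strrep("L", 10), "ASA", strrep("D", 20))
  ann <- annotate_signals(s)
  expect_equal(nchar(ann$cleavage_window), 8L)  # SPI window is an 8-mer
  s2 <- paste0("MK", strrep("L", 9), "LSGC", polar_pad(40))
  ann2 <- annotate_signals(s2)
  expect_equal(nchar(ann2$cleavage_window), 7L)  # SPII window is a 7-mer
  expect_equal(substr(ann2$cleavage_window, 7, 7),
               substr(s2, ann2$cys_pos + 1L, ann2$cys_pos + 1L))
  ann3 <- annotate_signals(polar_pad(60))
  expect_equal(ann3$cleavage_window, "No cleavage site")
})

test_that("windows reaching past a terminus are truncated with a log note", {
  s <- paste0("AGC", polar_pad(20))
  fake <- list(selected = "spii", cys_pos = 3L)
  expect_message(w <- cleavage_window(s, fake), "truncated")
  expect_equal(w, substr(s, 1, 4))
})

test_that("planted signals are recovered at the correct positions", {
  specs <- list(
    spi = list(class = "@Secretory (released) (with CS)",
               pos = function(tr) tr$cleavage_pos,
               got = function(ann) ann$spi_pos),
    spii = list(class = "@Lipid-anchored",
                pos = function(tr) tr$cys_pos,
                got = function(ann) ann$cys_pos),
    tat = list(class = "@Lipid-anchored",
               pos = function(tr) tr$rr_pos,
               got = function(ann) ann$rr_pos),
    lpxtg = list(class = "@LPXTG cell-wall anchored",
                 pos = function(tr) tr$lpxtg_start,
                 got = function(ann) ann$lpxtg_start)
  )
  withr::with_seed(1, seeds <- sample.int(1e6, 50))
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    hits <- vapply(seeds, function(sd) {
      g <- generate_protein(sp$class, seed = sd,
                            options = list(tat = nm == "tat"))
      ann <- annotate_signals(g$record$sequence)
      got <- sp$got(ann)
      want <- sp$pos(g$truth)
      !is.na(got) && abs(got - want) <= 1L
    }, logical(1))
    expect_gte(mean(hits), 0.9)
  }
})

test_that("annotation is deterministic", {
  g <- generate_protein("@Lipid-anchored", seed = 5)
  a1 <- annotate_signals(g$record$sequence)
  a2 <- annotate_signals(g$record$sequence)
  expect_identical(a1, a2)
})
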