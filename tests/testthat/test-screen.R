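pred_row <- function(scl_class, intracellular, signal = 1, n_anchored = 1) {
  tibble::tibble(scl_class = scl_class,
                 intracellular_possibility = intracellular,
                 signal_possibility = signal,
                 n_anchored_possibility = n_anchored)
}

test_that("printed candidate fields pass the printed-field rules", {
  # lipoprotein candidate row: class admissible, intracellular -0.33
  res <- apply_rubric(pred_row("@Lipid-anchored", -0.33), NULL, NA)
  expect_true(res$pass)
  expect_length(res$fail_reasons, 0L)
  expect_equal(assign_anchor_site(pred_row("@Lipid-anchored", -0.33)),
               "N site")
})

test_that("a cytoplasmic porin fails on class and intracellular score", {
  res <- apply_rubric(pred_row("@Intracellular", 1), NULL, NA)
  expect_false(res$pass)
  expect_setequal(res$fail_reasons, c("h2_class", "h3_intracellular"))
})

test_that("oversized candidates fail only the length rule", {
  res <- apply_rubric(pred_row("@Lipid-anchored", -1), NULL, length = 700)
  expect_false(res$pass)
  expect_equal(res$fail_reasons, "h1_length")
  res2 <- apply_rubric(pred_row("@Lipid-anchored", -1), NULL, length = 599)
  expect_true(res2$pass)
})

test_that("anchoring-site assignment follows the class and window rules", {
  expect_equal(assign_anchor_site(
    pred_row("@C-terminally anchored (with CS)", 0)), "C site")
  expect_equal(assign_anchor_site(
    pred_row("@Secretory (released) (with CS)", 0)), "N site")
  expect_equal(assign_anchor_site(
    pred_row("@LPXTG cell-wall anchored", 0)), "C site")
  expect_true(is.na(assign_anchor_site(pred_row("@Intracellular", 1))))
  mt <- pred_row("@Multi-transmembrane", 0.17)
  expect_equal(assign_anchor_site(
    mt, make_summ(out_first_w = 0.2, out_last_w = 0.8)), "N site")
  expect_equal(assign_anchor_site(
    mt, make_summ(out_first_w = 0.8, out_last_w = 0.2)), "C site")
})

test_that("topology window rules gate candidates when strict", {
  cr <- screen_criteria()
  summ_good <- make_summ(helices = tibble::tibble(start = 10L, end = 29L),
                         prob_n_in = 0.95, out_first_w = 0.1,
                         out_last_w = 0.9)
  pred <- pred_row("@N-terminally anchored (no CS)", -1)
  expect_true(apply_rubric(pred, summ_good, 220, cr)$pass)

  summ_low_nin <- summ_good
  summ_low_nin$prob_n_in <- 0.5
  expect_equal(apply_rubric(pred, summ_low_nin, 220, cr)$fail_reasons,
               "h5_n_in")

  summ_in_tail <- summ_good
  summ_in_tail$out_last_w <- 0.3
  expect_true("h4_windows" %in%
                apply_rubric(pred, summ_in_tail, 220, cr)$fail_reasons)

  relaxed <- screen_criteria(strict_windows = FALSE)
  expect_true(apply_rubric(pred, summ_in_tail, 220, relaxed)$pass)
})

test_that("ranking is monotone in the soft criteria and ties go to ids", {
  base <- tibble::tibble(
    protein_id = c("b", "a"), signal_possibility = c(1, -1),
    n_anchored_possibility = c(1, 1), display_outside = c(0.8, 0.8),
    pass = TRUE)
  ranked <- rank_candidates(base)
  expect_equal(ranked$protein_id, c("b", "a"))
  expect_gt(ranked$rank_score[1], ranked$rank_score[2])

  tie <- base
  tie$signal_possibility <- c(1, 1)
  expect_equal(rank_candidates(tie)$protein_id, c("a", "b"))
})

test_that("ranking is invariant to input order", {
  rows <- withr::with_seed(9, tibble::tibble(
    protein_id = sprintf("p%02d", 1:20),
    signal_possibility = runif(20, -1, 1),
    n_anchored_possibility = sample(-2:7, 20, replace = TRUE),
    display_outside = runif(20),
    pass = runif(20) < 0.7))
  r1 <- rank_candidates(rows)
  r2 <- rank_candidates(rows[sample(20), ])
  expect_equal(r1, r2)
  # failing rows are appended, unranked
  expect_true(all(is.na(r1$rank_score[!r1$pass])))
  expect_true(all(!is.na(r1$rank_score[r1$pass])))
})

test_that("relaxing thresholds never shrinks the pass set", {
  withr::with_seed(23, {
    for (i in 1:100) {
      case <- random_case()
      cr <- screen_criteria()
      relaxed <- screen_criteria(
        max_length = cr$max_length + sample(0:400, 1),
        intracellular_max = min(1, cr$intracellular_max + runif(1, 0, 0.5)),
        n_in_min = max(0, cr$n_in_min - runif(1, 0, 0.5)),
        window_outside_min = max(0, cr$window_outside_min - runif(1, 0, 0.3)),
        opposite_window_outside_max =
          min(1, cr$opposite_window_outside_max + runif(1, 0, 0.3))
      )
      strict_pass <- apply_rubric(case$pred, case$summ, case$len, cr)$pass
      relaxed_pass <- apply_rubric(case$pred, case$summ, case$len, relaxed)$pass
      if (strict_pass) expect_true(relaxed_pass)
    }
  })
})

test_that("screening an empty proteome yields an empty table", {
  empty <- tibble::tibble(id = character(), sequence = character())
  sc <- screen_proteome(empty)
  expect_equal(nrow(sc), 0L)
  expect_s3_class(sc, "anchor_screen")
})

test_that("screen output keeps one row per input record, passes planted
           anchors and rejects most non-anchors", {
  pr <- generate_proteome(60, seed = 1)
  sc <- screen_proteome(pr$proteins)
  expect_equal(nrow(sc), 60L)
  expect_setequal(sc$protein_id, pr$proteins$id)
  j <- dplyr::left_join(tidy(sc), pr$truth, by = c(protein_id = "id"))
  expect_gte(mean(j$pass[j$is_anchor]), 0.9)
  expect_gte(mean(!j$pass[!j$is_anchor]), 0.9)
  expect_true(all(!is.na(j$anchored_site[j$pass])))
  # locus tags parsed from headers
  expect_true(all(grepl("^SYNg", sc$locus_tag)))
})

test_that("screening twice writes byte-identical candidate tables", {
  pr <- generate_proteome(12, seed = 4)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(pr$proteins, fa)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_candidate_table(screen_proteome(fa), p1)
  write_candidate_table(screen_proteome(fa), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("glance and autoplot summarise a screen", {
  pr <- generate_proteome(15, seed = 2)
  sc <- screen_proteome(pr$proteins)
  gl <- glance(sc)
  expect_equal(gl$n_proteins, 15L)
  expect_equal(gl$n_pass + gl$n_fail, 15L)
  expect_s3_class(autoplot(sc), "ggplot")
  post <- posterior_decode(default_topology_model(),
                           pr$proteins$sequence[[1]])
  expect_s3_class(autoplot(post), "ggplot")
})
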