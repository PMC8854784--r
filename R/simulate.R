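# Synthetic proteins and proteomes with planted, labelled export features.
# The generator defines the study conditions of the package's test suites:
# background residues follow a fixed approximate cytoplasmic composition;
# transmembrane helices are 18-22 strong hydrophobics with K/R on the
# cytoplasmic flank (positive-inside rule); planted signal-peptide
# h-regions are 15-18 residues so the topology model decodes the export
# event; classes without a signal peptide carry no K/R in residues 1-5.
# Intracellular sequences are rejection-sampled until they contain no
# accidental export feature, so ground-truth labels are guaranteed.

EXO_FREQ <- local({
  f <- BACKGROUND_FREQ
  polar <- c("D", "E", "N", "Q", "S", "T")
  f[polar] <- f[polar] * 1.6
  f / sum(f)
})

POLAR_SET <- c("D", "E", "N", "Q", "S", "T")

draw_bg <- function(n, flavor = c("cyto", "exo"), forbid_kr_first5 = FALSE,
                    forbid_c_first = 0L, max_hydro_run = 11L) {
  flavor <- match.arg(flavor)
  if (n <= 0L) return(character(0))
  p <- if (flavor == "cyto") BACKGROUND_FREQ else EXO_FREQ
  chars <- sample(AA20, n, replace = TRUE, prob = p)
  if (forbid_kr_first5 && n >= 1L) {
    k <- seq_len(min(5L, n))
    bad <- chars[k] %in% c("K", "R")
    if (any(bad)) {
      p2 <- p; p2[c("K", "R")] <- 0
      chars[k][bad] <- sample(AA20, sum(bad), replace = TRUE,
                              prob = p2 / sum(p2))
    }
  }
  if (forbid_c_first > 0L) {
    k <- seq_len(min(forbid_c_first, n))
    bad <- chars[k] == "C"
    if (any(bad)) {
      p2 <- p; p2["C"] <- 0
      chars[k][bad] <- sample(AA20, sum(bad), replace = TRUE,
                              prob = p2 / sum(p2))
    }
  }
  # Break accidental hydrophobic runs so background never mimics a helix.
  repeat {
    runs <- residue_runs(chars, HYDROPHOBIC_SET)
    runs <- runs[runs$len >= max_hydro_run, , drop = FALSE]
    if (!nrow(runs)) break
    mid <- runs$start[1] + runs$len[1] %/% 2L
    chars[mid] <- sample(POLAR_SET, 1L)
  }
  chars
}

helix_chars <- function(len) {
  sample(c("L", "I", "V", "F"), len, replace = TRUE,
         prob = c(0.40, 0.25, 0.20, 0.15))
}

h_region_chars <- function(len) {
  sample(c("L", "I", "F", "M"), len, replace = TRUE,
         prob = c(0.45, 0.25, 0.15, 0.15))
}

# Signal-peptide prefix (n-region + h-region); optionally with a planted
# twin-arginine motif in the n-region.
sp_prefix <- function(tat = FALSE) {
  n_chars <- if (tat) {
    c("M", "K", "T", "R", "R", "N", "F", "L")
  } else {
    c("M", sample(c("K", "R"), 1L), draw_bg(2L, "cyto"))
  }
  h_len <- sample(15:18, 1L)
  list(
    chars = c(n_chars, h_region_chars(h_len)),
    n_len = length(n_chars),
    h_start = length(n_chars) + 1L,
    h_end = length(n_chars) + h_len,
    rr_pos = if (tat) 4L else NA_integer_
  )
}

truth_tpl <- function() {
  list(sp_type = "none", cleavage_pos = NA_integer_, cys_pos = NA_integer_,
       rr_pos = NA_integer_, lpxtg_start = NA_integer_,
       helices = tibble::tibble(start = integer(), end = integer()),
       labels = character(0))
}

build_intracellular <- function(L) {
  # Effective hydropathy as a membrane propensity: Kyte-Doolittle with an
  # interface adjustment for W/Y, mirroring what helix propensities in
  # topology predictors respond to.
  kd_eff <- KD_SCALE
  kd_eff["W"] <- kd_eff["W"] + 2.8
  kd_eff["Y"] <- kd_eff["Y"] + 1.6
  clean <- FALSE
  model <- default_topology_model()
  for (i in 1:500) {
    chars <- draw_bg(L, "cyto")
    ann <- annotate_one(paste(chars, collapse = ""))
    # No detectable export feature and no helix-like hydrophobicity
    # window: the all-cytoplasmic truth label must be unambiguous.
    kd <- unname(kd_eff[chars])
    kd[is.na(kd)] <- 0
    win15 <- if (L >= 15L) {
      as.numeric(stats::filter(kd, rep(1 / 15, 15), sides = 1))
    } else kd
    clean <- !ann$spi && !ann$spii && !ann$tat && !ann$lpxtg &&
      is.null(find_h_region(chars)) && max(win15, na.rm = TRUE) < 1.6
    # Final arbiter: the shipped topology model must find no membrane
    # segment, so the all-inside truth labels cannot be contradicted by
    # an accidental helix-like stretch.
    if (clean) {
      segs <- viterbi_topology(model, paste(chars, collapse = ""))
      clean <- !any(segs$label == "membrane")
    }
    if (clean) break
  }
  if (!clean) {
    warn("Could not draw a feature-free cytoplasmic sequence; keeping last draw.")
  }
  tr <- truth_tpl()
  tr$labels <- rep("inside", L)
  list(chars = chars, truth = tr)
}

build_secretory <- function(L, tat = FALSE) {
  sp <- sp_prefix(tat)
  c_reg <- c(sample(c("A", "S", "T"), 1L), sample(c("Q", "E", "N"), 1L), "A")
  sp_len <- length(sp$chars) + 3L
  stopifnot(L > sp_len + 20L)
  mature <- draw_bg(L - sp_len, "exo", forbid_c_first = 25L)
  tr <- truth_tpl()
  tr$sp_type <- if (tat) "tat+spi" else "spi"
  tr$cleavage_pos <- sp_len
  tr$rr_pos <- sp$rr_pos
  tr$labels <- c(rep("inside", sp$n_len),
                 rep("membrane", sp$h_end - sp$n_len), rep("membrane", 3L),
                 rep("outside", L - sp_len))
  list(chars = c(sp$chars, c_reg, mature), truth = tr)
}

lipobox_chars <- function() {
  c(sample(c("L", "V", "I", "F"), 1L), sample(c("A", "S", "T", "G"), 1L),
    sample(c("G", "A", "S"), 1L), "C")
}

build_lipid <- function(L, tat = FALSE, extra_helices = 0L) {
  sp <- sp_prefix(tat)
  box <- lipobox_chars()
  cys <- length(sp$chars) + 4L
  stopifnot(L > cys + 30L * (extra_helices + 1L))
  tr <- truth_tpl()
  tr$sp_type <- if (tat) "tat+spii" else "spii"
  tr$cys_pos <- cys
  tr$cleavage_pos <- cys - 1L
  tr$rr_pos <- sp$rr_pos
  chars <- c(sp$chars, box)
  labels <- c(rep("inside", sp$n_len), rep("membrane", cys - sp$n_len))
  side <- "outside"
  if (extra_helices > 0L) {
    for (k in seq_len(extra_helices)) {
      loop_len <- if (side == "outside") sample(15:25, 1L) else sample(6:10, 1L)
      loop <- if (side == "outside") {
        draw_bg(loop_len, "exo")
      } else {
        c(sample(c("K", "R"), 2L, replace = TRUE), draw_bg(loop_len - 2L, "cyto"))
      }
      chars <- c(chars, loop)
      labels <- c(labels, rep(side, loop_len))
      hl <- sample(18:22, 1L)
      tr$helices <- dplyr::bind_rows(
        tr$helices,
        tibble::tibble(start = length(chars) + 1L,
                       end = length(chars) + hl))
      chars <- c(chars, helix_chars(hl))
      labels <- c(labels, rep("membrane", hl))
      side <- if (side == "outside") "inside" else "outside"
    }
  }
  tail_len <- L - length(chars)
  tail_chars <- if (side == "outside") {
    draw_bg(tail_len, "exo")
  } else {
    c(sample(c("K", "R"), 2L, replace = TRUE), draw_bg(tail_len - 2L, "cyto"))
  }
  tr$labels <- c(labels, rep(side, tail_len))
  list(chars = c(chars, tail_chars), truth = tr)
}

build_multi_tm <- function(L, n_helices = 3L) {
  stopifnot(n_helices >= 2L, L > 40L + 35L * n_helices)
  loop0 <- sample(8:12, 1L)  # flank K/R stay clear of the SPI n-region zone
  chars <- c(draw_bg(loop0 - 2L, "cyto", forbid_kr_first5 = TRUE),
             sample(c("K", "R"), 2L, replace = TRUE))
  labels <- rep("inside", loop0)
  tr <- truth_tpl()
  side <- "inside"
  for (k in seq_len(n_helices)) {
    hl <- sample(18:22, 1L)
    tr$helices <- dplyr::bind_rows(
      tr$helices,
      tibble::tibble(start = length(chars) + 1L, end = length(chars) + hl))
    chars <- c(chars, helix_chars(hl))
    labels <- c(labels, rep("membrane", hl))
    side <- if (side == "inside") "outside" else "inside"
    if (k < n_helices) {
      if (side == "outside") {
        ll <- sample(15:25, 1L)
        chars <- c(chars, draw_bg(ll, "exo"))
        labels <- c(labels, rep("outside", ll))
      } else {
        ll <- sample(6:10, 1L)
        chars <- c(chars, sample(c("K", "R"), 2L, replace = TRUE),
                   draw_bg(ll - 2L, "cyto"))
        labels <- c(labels, rep("inside", ll))
      }
    }
  }
  tail_len <- L - length(chars)
  stopifnot(tail_len >= 5L)
  tail_chars <- if (side == "outside") {
    draw_bg(tail_len, "exo")
  } else {
    c(sample(c("K", "R"), 2L, replace = TRUE), draw_bg(tail_len - 2L, "cyto"))
  }
  tr$labels <- c(labels, rep(side, tail_len))
  list(chars = c(chars, tail_chars), truth = tr)
}

build_n_anchored <- function(L) {
  loop0 <- sample(8:12, 1L)
  chars <- c(draw_bg(loop0 - 2L, "cyto", forbid_kr_first5 = TRUE),
             sample(c("K", "R"), 2L, replace = TRUE))
  hl <- sample(18:22, 1L)
  tr <- truth_tpl()
  tr$helices <- tibble::tibble(start = loop0 + 1L, end = loop0 + hl)
  tail_len <- L - loop0 - hl
  stopifnot(tail_len >= 30L)
  tr$labels <- c(rep("inside", loop0), rep("membrane", hl),
                 rep("outside", tail_len))
  list(chars = c(chars, helix_chars(hl), draw_bg(tail_len, "exo")),
       truth = tr)
}

build_c_anchored <- function(L) {
  sp <- sp_prefix(FALSE)
  c_reg <- c(sample(c("A", "S", "T"), 1L), sample(c("Q", "E", "N"), 1L), "A")
  sp_len <- length(sp$chars) + 3L
  hl <- sample(18:21, 1L)
  tail_len <- sample(4:6, 1L)
  dom_len <- L - sp_len - hl - tail_len
  stopifnot(dom_len >= 30L)
  dom <- draw_bg(dom_len, "exo", forbid_c_first = 25L)
  tail_chars <- c(sample(c("K", "R"), 2L, replace = TRUE),
                  draw_bg(tail_len - 2L, "cyto"))
  tr <- truth_tpl()
  tr$sp_type <- "spi"
  tr$cleavage_pos <- sp_len
  tr$helices <- tibble::tibble(start = sp_len + dom_len + 1L,
                               end = sp_len + dom_len + hl)
  tr$labels <- c(rep("inside", sp$n_len), rep("membrane", sp_len - sp$n_len),
                 rep("outside", dom_len), rep("membrane", hl),
                 rep("inside", tail_len))
  list(chars = c(sp$chars, c_reg, dom, helix_chars(hl), tail_chars),
       truth = tr)
}

build_lpxtg <- function(L) {
  sp <- sp_prefix(FALSE)
  c_reg <- c(sample(c("A", "S", "T"), 1L), sample(c("Q", "E", "N"), 1L), "A")
  sp_len <- length(sp$chars) + 3L
  m <- L - 28L  # motif start; within the last 40 residues
  dom_len <- m - 1L - sp_len
  stopifnot(dom_len >= 20L)
  dom <- draw_bg(dom_len, "exo", forbid_c_first = 25L)
  x <- sample(setdiff(AA20, "P"), 1L)
  motif <- c("L", "P", x, "T", "G")
  tmtail <- helix_chars(14L)
  final <- draw_bg(10L, "cyto")
  final[c(2L, 5L, 8L)] <- c("K", "R", "K")
  tr <- truth_tpl()
  tr$sp_type <- "spi"
  tr$cleavage_pos <- sp_len
  tr$lpxtg_start <- m
  tr$labels <- c(rep("inside", sp$n_len), rep("membrane", sp_len - sp$n_len),
                 rep("outside", dom_len + 5L), rep("membrane", 14L),
                 rep("inside", 10L))
  list(chars = c(sp$chars, c_reg, dom, motif, tmtail, final), truth = tr)
}

default_length <- function(target_class) {
  switch(target_class,
         "@Intracellular" = 300L,
         "@Lipid-anchored" = 250L,
         "@Multi-transmembrane" = 320L,
         "@Multi-transmembrane (lipid-modified N-termini)" = 340L,
         "@N-terminally anchored (no CS)" = 220L,
         "@C-terminally anchored (with CS)" = 260L,
         "@Secretory (released) (with CS)" = 240L,
         "@LPXTG cell-wall anchored" = 300L,
         abort(sprintf("Unknown target class: %s", target_class)))
}

#' Generate one synthetic protein with ground-truth labels
#'
#' Plants the export features implied by `target_class` at recorded
#' positions over a fixed cytoplasmic background composition. The same
#' specification (class, length, seed, options) always yields the same
#' sequence.
#'
#' @param target_class One of the seven SCL classes (see `SCL_CLASSES` in
#'   the package sources / [table_fixtures()] rows).
#' @param length Sequence length in residues (class-specific default);
#'   must be at least 50.
#' @param seed Integer seed.
#' @param options List: `n_helices` (multi-transmembrane classes; default
#'   3, or 2 extra helices for the lipid-modified class), `tat` (plant a
#'   twin-arginine motif in the signal peptide; default `FALSE`).
#' @return List with `record` (one-row protein tibble) and `truth`
#'   (planted positions, per-residue labels, helix table).
#' @examples
#' g <- generate_protein("@Lipid-anchored", seed = 2)
#' g$truth$cys_pos
#' @export
generate_protein <- function(target_class, length = NULL, seed = 1L,
                             options = list()) {
  if (!target_class %in% SCL_CLASSES) {
    abort(sprintf("Unknown target class: %s", target_class))
  }
  L <- as.integer(length %||% default_length(target_class))
  if (L < 50L) abort("`length` must be at least 50 residues.")
  tat <- isTRUE(options$tat)
  nh <- options$n_helices
  if (target_class == "@Intracellular" && !is.null(nh) && nh > 0L) {
    abort("@Intracellular conflicts with a non-zero helix count.")
  }
  built <- withr::with_seed(as.integer(seed), {
    switch(
      target_class,
      "@Intracellular" = build_intracellular(L),
      "@Secretory (released) (with CS)" = build_secretory(L, tat),
      "@Lipid-anchored" = build_lipid(L, tat, extra_helices = 0L),
      "@Multi-transmembrane (lipid-modified N-termini)" =
        build_lipid(L, tat, extra_helices = as.integer(nh %||% 2L)),
      "@Multi-transmembrane" = build_multi_tm(L, as.integer(nh %||% 3L)),
      "@N-terminally anchored (no CS)" = build_n_anchored(L),
      "@C-terminally anchored (with CS)" = build_c_anchored(L),
      "@LPXTG cell-wall anchored" = build_lpxtg(L)
    )
  })
  sequence <- paste(built$chars, collapse = "")
  stopifnot(nchar(sequence) == L, length(built$truth$labels) == L)
  truth <- built$truth
  truth$class <- target_class
  list(
    record = tibble::tibble(id = NA_character_, description = "",
                            sequence = sequence, length = L),
    truth = truth
  )
}

default_class_mix <- function() {
  c("@Intracellular" = 0.55,
    "@Lipid-anchored" = 0.08,
    "@Multi-transmembrane" = 0.08,
    "@Multi-transmembrane (lipid-modified N-termini)" = 0.04,
    "@N-terminally anchored (no CS)" = 0.08,
    "@C-terminally anchored (with CS)" = 0.04,
    "@Secretory (released) (with CS)" = 0.08,
    "@LPXTG cell-wall anchored" = 0.05)
}

#' Generate a synthetic proteome with a truth table
#'
#' Samples classes from `class_mix`, generates each protein with a
#' per-record seed derived from `seed`, and returns the protein table plus
#' a per-record truth table. Byte-identical output for identical
#' `(n, class_mix, seed)`.
#'
#' @param n Number of proteins (> 0).
#' @param class_mix Named numeric vector of class proportions summing to 1
#'   (default: 55% intracellular, 5% LPXTG, 40% across the six anchor
#'   classes).
#' @param seed Master integer seed.
#' @param out_dir Optional directory; when given, writes `proteome.fasta`
#'   and `truth.tsv` there.
#' @return List with `proteins` (tibble: id, description, sequence,
#'   length) and `truth` (tibble: id, class, is_anchor, planted positions).
#' @export
generate_proteome <- function(n, class_mix = default_class_mix(), seed = 1L,
                              out_dir = NULL) {
  if (!is.numeric(n) || n <= 0) abort("`n` must be a positive count.")
  n <- as.integer(n)
  if (abs(sum(class_mix) - 1) > 1e-6) {
    abort("`class_mix` proportions must sum to 1.")
  }
  unknown <- setdiff(names(class_mix), SCL_CLASSES)
  if (length(unknown)) {
    abort(sprintf("Unknown class in `class_mix`: %s",
                  paste(unknown, collapse = ", ")))
  }
  plan <- withr::with_seed(as.integer(seed), {
    classes <- sample(names(class_mix), n, replace = TRUE, prob = class_mix)
    tibble::tibble(
      class = classes,
      len = vapply(classes, default_length, integer(1)) +
        sample(-30:60, n, replace = TRUE),
      sub_seed = sample.int(2^31 - 2, n)
    )
  })
  gens <- purrr::pmap(plan, function(class, len, sub_seed) {
    generate_protein(class, length = len, seed = sub_seed)
  })
  ids <- sprintf("syn%04d", seq_len(n))
  proteins <- dplyr::bind_rows(purrr::map(gens, "record"))
  proteins$id <- ids
  proteins$description <- sprintf("locus_tag=SYNg%04d synthetic protein",
                                  seq_len(n))
  truth <- purrr::map2(gens, ids, function(g, id) {
    tr <- g$truth
    tibble::tibble(
      id = id, class = tr$class,
      is_anchor = tr$class %in% default_allowed_classes(),
      sp_type = tr$sp_type, cleavage_pos = tr$cleavage_pos,
      cys_pos = tr$cys_pos, rr_pos = tr$rr_pos,
      lpxtg_start = tr$lpxtg_start, n_helices_true = nrow(tr$helices)
    )
  })
  truth <- dplyr::bind_rows(truth)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_fasta(proteins, file.path(out_dir, "proteome.fasta"))
    readr::write_tsv(truth, file.path(out_dir, "truth.tsv"))
  }
  list(proteins = proteins, truth = truth)
}
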