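# Combine topology and signal evidence into one of seven subcellular
# localization classes, a secretion-pathway label, and the three
# possibility scores of the candidate tables.

# Helix segments that survive the selected cleavage event. A segment is
# retained unless it ends within 5 residues of (or before) the cleavage
# position -- a cleaved signal peptide decoded as a membrane segment is not
# part of the mature chain.
mature_helices <- function(segments, cleavage_pos) {
  helix <- segments[segments$label == "membrane", , drop = FALSE]
  if (is.na(cleavage_pos)) return(helix)
  helix[helix$end >= cleavage_pos + 5L, , drop = FALSE]
}

#' Classify a protein into one of seven SCL classes
#'
#' First-match decision tree over the combined evidence, with the more
#' specific evidence (LPXTG, lipobox) checked first:
#' LPXTG motif; lipobox with >= 2 mature-chain helices
#' (multi-transmembrane, lipid-modified); lipobox (lipid-anchored);
#' >= 2 mature helices (multi-transmembrane); a single uncleaved helix
#' overlapping the first 40 residues (N-terminally anchored, no cleavage
#' site); a single helix within the last 40 residues (C-terminally anchored
#' when an SPI site exists, otherwise treated as N-terminally anchored
#' without cleavage site); an SPI site with no mature helix (secretory,
#' released); otherwise intracellular. Helix counts refer to the mature
#' chain: membrane segments removed by the selected cleavage event are not
#' counted.
#'
#' @param annotation One-row signal annotation from [annotate_signals()].
#' @param summary One-row topology summary from [summarize_topology()].
#' @param record Optional protein record (unused beyond length checks).
#' @return One-row tibble: `scl_class`, `pathway`,
#'   `intracellular_possibility`, `signal_possibility`,
#'   `n_anchored_possibility`, `cleavage_window`.
#' @export
classify_scl <- function(annotation, summary, record = NULL) {
  segs <- summary$segments[[1]]
  L <- summary$len
  cleave <- annotation$cleavage_pos
  if (identical(annotation$selected, "none")) cleave <- NA_integer_
  mh <- mature_helices(segs, cleave)
  m <- nrow(mh)

  scl <- if (annotation$lpxtg) {
    "@LPXTG cell-wall anchored"
  } else if (annotation$spii && m >= 2L) {
    "@Multi-transmembrane (lipid-modified N-termini)"
  } else if (annotation$spii) {
    "@Lipid-anchored"
  } else if (m >= 2L) {
    "@Multi-transmembrane"
  } else if (m == 1L && mh$start[1] <= 40L &&
             identical(annotation$selected, "none")) {
    "@N-terminally anchored (no CS)"
  } else if (m == 1L && mh$end[1] >= L - 39L) {
    if (annotation$spi) "@C-terminally anchored (with CS)"
    else "@N-terminally anchored (no CS)"
  } else if (annotation$spi && m == 0L) {
    "@Secretory (released) (with CS)"
  } else {
    "@Intracellular"
  }

  pathway <- if (annotation$spii && annotation$tat) {
    "Possibly Tat/Sec-(SPII)"
  } else if (annotation$spii) {
    "Sec-(SPII)"
  } else if (annotation$tat && annotation$spi) {
    "Tat-(SPI)"
  } else if (annotation$spi || summary$n_helices >= 1L) {
    "Sec-(SPI)"
  } else {
    "No pathway"
  }

  window <- annotation$cleavage_window
  if (scl == "@Intracellular") {
    pathway <- "No pathway"
    window <- NO_CLEAVAGE
  }

  scores <- score_possibilities(annotation, summary)
  tibble::tibble(
    scl_class = scl,
    pathway = pathway,
    intracellular_possibility = scores$intracellular,
    signal_possibility = scores$signal,
    n_anchored_possibility = scores$n_anchored,
    cleavage_window = window
  )
}

#' Possibility scores from combined evidence
#'
#' Three scores with the ranges and thresholds of the reference tables:
#' \describe{
#' \item{intracellular}{`1 - 2 * E` with `E` the strongest export evidence
#'   (max of SPI confidence, SPII confidence, and `min(1, n_helices)`),
#'   clamped to `[0, 1]`. Exactly 1 when no export evidence exists; range
#'   `[-1, 1]`, screening threshold 0.5.}
#' \item{signal}{`2 * max(SPI, SPII confidence) - 1`; range `[-1, 1]`.}
#' \item{n_anchored}{`round(7 * r) - 2 * c` where `r` is the retention
#'   score (mean membrane posterior over the uncleaved N-terminal helix, 0
#'   if none is retained) and `c` indicates a selected cleavage event with
#'   no retained helix. Strong uncleaved N-anchors score up to 7; cleaved,
#'   fully released proteins score -2. Threshold 0.}
#' }
#' These formulas are this package's own; only the documented ranges,
#' thresholds and extremes are contractual.
#'
#' @inheritParams classify_scl
#' @return List with `intracellular`, `signal`, `n_anchored`.
#' @export
score_possibilities <- function(annotation, summary) {
  spi_conf <- if (isTRUE(annotation$spi)) annotation$spi_conf else 0
  spii_conf <- if (isTRUE(annotation$spii)) annotation$spii_conf else 0
  E <- clamp01(max(spi_conf, spii_conf, min(1, summary$n_helices)))
  intracellular <- 1 - 2 * E
  signal <- 2 * max(spi_conf, spii_conf) - 1

  cleave <- annotation$cleavage_pos
  if (identical(annotation$selected, "none")) cleave <- NA_integer_
  segs <- summary$segments[[1]]
  retained <- mature_helices(segs, cleave)
  nterm_retained <- !is.na(summary$nterm_helix_start) &&
    (is.na(cleave) || summary$nterm_helix_end >= cleave + 5L)
  r <- if (nterm_retained) summary$nterm_helix_mem else 0
  c_ind <- if (!is.na(cleave) && nrow(retained) == 0L) 1L else 0L
  n_anchored <- round(7 * r) - 2 * c_ind

  list(intracellular = intracellular, signal = signal,
       n_anchored = n_anchored)
}
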