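# Heuristic detectors for N-terminal export signals and the C-terminal
# LPXTG sortase motif. All positions are 1-based inclusive. The concrete
# thresholds (h-region length, hydropathy cut-off, motif alphabets) are this
# package's defaults, not values published for any external predictor.

SPI_MIN_LEN <- 15L
LIPOBOX_P1 <- c("L", "V", "I", "F")
LIPOBOX_P2 <- c("A", "S", "T", "V", "I", "G")
LIPOBOX_P3 <- c("G", "A", "S")
TAT_P1 <- c("S", "T")
TAT_P5 <- c("F", "G", "A", "V", "M", "L")
TAT_P6 <- c("L", "I", "T", "M", "V", "F")

# First hydrophobic run usable as a signal-peptide h-region: length >= 7,
# starting within `start_max`, mean hydropathy >= `kd_min`.
find_h_region <- function(chars, start_max = 25L, end_max = length(chars),
                          min_len = 7L, kd_min = 1.0) {
  zone <- chars[seq_len(min(length(chars), end_max))]
  runs <- residue_runs(zone, HYDROPHOBIC_SET)
  runs <- runs[runs$len >= min_len & runs$start <= start_max &
                 runs$start >= 3L, , drop = FALSE]
  if (!nrow(runs)) return(NULL)
  for (i in seq_len(nrow(runs))) {
    kd <- mean(kd_values(zone[runs$start[i]:runs$end[i]]))
    if (kd >= kd_min) {
      return(list(start = runs$start[i], end = runs$end[i], mean_kd = kd))
    }
  }
  NULL
}

#' Detect a Sec signal peptide with a signal-peptidase-I site
#'
#' Tripartite scan: an n-region with at least one K/R in positions 1-5, an
#' h-region (hydrophobic run of >= 7 residues starting within positions
#' 3-25 with mean Kyte-Doolittle hydropathy >= 1), and a c-region ending in
#' an A-X-A-type site (small residues at -3 and -1). The cleavage position
#' is the -1 residue, i.e. the last residue of the signal peptide.
#' Confidence is the product of three clamped sub-scores.
#'
#' @param x Sequence string or record with a `sequence` field.
#' @return List with `present`, `cleavage_pos`, `confidence`.
#' @export
detect_spi <- function(x) {
  s <- as_sequence(x)
  chars <- seq_chars(s)
  absent <- list(present = FALSE, cleavage_pos = NA_integer_, confidence = 0)
  if (length(chars) < SPI_MIN_LEN) return(absent)
  n_ok <- any(chars[1:5] %in% c("K", "R"))
  if (!n_ok) return(absent)
  h <- find_h_region(chars)
  if (is.null(h)) return(absent)
  # c-region: first valid -1 position after the h-region.
  p_max <- min(h$end + 8L, length(chars))
  cleave <- NA_integer_
  for (p in seq.int(h$end + 1L, p_max)) {
    if (p - 2L < 1L) next
    if (chars[p] %in% SMALL_SET && chars[p - 2L] %in% SMALL_SET) {
      cleave <- p
      break
    }
  }
  if (is.na(cleave)) return(absent)
  h_score <- clamp01(h$mean_kd / 4.5)
  conf <- clamp01(1 * h_score * 1)
  list(present = TRUE, cleavage_pos = cleave, confidence = conf)
}

#' Detect a lipoprotein signal peptide (SPII lipobox)
#'
#' Scans cysteines in positions 10-40 for the lipobox pattern
#' `[LVIF][ASTVIG][GAS]C` preceded by a hydrophobic h-region (as in
#' [detect_spi()], ending before the cysteine). The mature, lipid-modified
#' protein begins at the cysteine.
#'
#' @inheritParams detect_spi
#' @return List with `present`, `cys_pos`, `confidence`.
#' @export
detect_lipobox <- function(x) {
  s <- as_sequence(x)
  chars <- seq_chars(s)
  absent <- list(present = FALSE, cys_pos = NA_integer_, confidence = 0)
  if (length(chars) < SPI_MIN_LEN) return(absent)
  p_hi <- min(40L, length(chars))
  for (p in 10:p_hi) {
    if (chars[p] != "C") next
    if (!(chars[p - 3L] %in% LIPOBOX_P1 &&
          chars[p - 2L] %in% LIPOBOX_P2 &&
          chars[p - 1L] %in% LIPOBOX_P3)) next
    h <- find_h_region(chars, start_max = 25L, end_max = p - 1L)
    if (is.null(h)) next
    conf <- clamp01(h$mean_kd / 4.5)
    return(list(present = TRUE, cys_pos = p, confidence = conf))
  }
  absent
}

#' Detect a twin-arginine (Tat) export motif
#'
#' Matches the consensus `[ST]-R-R-x-[FGAVML]-[LITMVF]` within positions
#' 1-35 of the sequence; `rr_pos` is the position of the first arginine.
#'
#' @inheritParams detect_spi
#' @return List with `present`, `rr_pos`.
#' @export
detect_tat <- function(x) {
  s <- as_sequence(x)
  chars <- seq_chars(s)
  absent <- list(present = FALSE, rr_pos = NA_integer_)
  if (length(chars) < SPI_MIN_LEN) return(absent)
  i_max <- min(30L, length(chars) - 5L)
  if (i_max < 1L) return(absent)
  for (i in seq_len(i_max)) {
    if (chars[i] %in% TAT_P1 &&
        chars[i + 1L] == "R" && chars[i + 2L] == "R" &&
        chars[i + 4L] %in% TAT_P5 && chars[i + 5L] %in% TAT_P6 &&
        i + 1L <= 35L) {
      return(list(present = TRUE, rr_pos = i + 1L))
    }
  }
  absent
}

#' Scan for a C-terminal LPXTG sortase anchor
#'
#' Matches `L-P-x-T-G` within the last 40 residues, requires a downstream
#' hydrophobic run of >= 12 residues within the remaining tail and at least
#' two K/R in the final 10 residues (the canonical sortase-substrate tail
#' of Gram-positive cell-wall-anchored proteins).
#'
#' @inheritParams detect_spi
#' @return List with `present`, `motif_start`.
#' @export
scan_lpxtg <- function(x) {
  s <- as_sequence(x)
  chars <- seq_chars(s)
  L <- length(chars)
  absent <- list(present = FALSE, motif_start = NA_integer_)
  if (L < 50L) return(absent)
  lo <- max(1L, L - 39L)
  starts <- integer(0)
  for (m in lo:(L - 4L)) {
    if (chars[m] == "L" && chars[m + 1L] == "P" &&
        chars[m + 3L] == "T" && chars[m + 4L] == "G") {
      starts <- c(starts, m)
    }
  }
  for (m in rev(starts)) {  # prefer the most C-terminal motif
    tail_chars <- chars[(m + 5L):L]
    runs <- residue_runs(tail_chars, HYDROPHOBIC_SET)
    if (!nrow(runs) || max(runs$len) < 12L) next
    final10 <- chars[max(1L, L - 9L):L]
    if (sum(final10 %in% c("K", "R")) < 2L) next
    return(list(present = TRUE, motif_start = m))
  }
  absent
}

#' Cleavage-site window string
#'
#' The short residue string flanking the selected cleavage event, as printed
#' in anchor tables: an 8-mer for SPI sites (last 4 signal-peptide residues
#' and first 4 mature residues) and a 7-mer for SPII sites (five residues
#' before the lipobox cysteine through the residue after it). Windows
#' reaching past a terminus are truncated with a log note. With no selected
#' event the sentinel `"No cleavage site"` is returned.
#'
#' @param x Sequence string or record.
#' @param annotation One-row annotation as produced by [annotate_signals()],
#'   or a list with `selected` plus `cleavage_pos`/`cys_pos`.
#' @return Window string.
#' @export
cleavage_window <- function(x, annotation) {
  s <- as_sequence(x)
  L <- nchar(s)
  sel <- annotation$selected %||% "none"
  if (identical(sel, "spii")) {
    p <- annotation$cys_pos
    from <- p - 5L; to <- p + 1L
  } else if (identical(sel, "spi")) {
    p <- annotation$cleavage_pos
    from <- p - 3L; to <- p + 4L
  } else {
    return(NO_CLEAVAGE)
  }
  if (from < 1L || to > L) {
    as_log("INFO", sprintf("cleavage window truncated at a terminus (%d..%d, length %d)",
                           from, to, L))
    from <- max(1L, from); to <- min(L, to)
  }
  substr(s, from, to)
}

annotate_one <- function(sequence) {
  spi_res <- detect_spi(sequence)
  spii_res <- detect_lipobox(sequence)
  tat_res <- detect_tat(sequence)
  lpxtg_res <- scan_lpxtg(sequence)
  # At most one cleavage event is selected; the lipobox is the more
  # specific pattern and wins when both match.
  selected <- if (spii_res$present) "spii" else if (spi_res$present) "spi"
    else "none"
  cleavage_pos <- switch(selected,
                         spii = spii_res$cys_pos - 1L,  # mature starts at C
                         spi = spi_res$cleavage_pos,
                         none = NA_integer_)
  ann <- tibble::tibble(
    spi = spi_res$present, spi_pos = spi_res$cleavage_pos,
    spi_conf = spi_res$confidence,
    spii = spii_res$present, cys_pos = spii_res$cys_pos,
    spii_conf = spii_res$confidence,
    tat = tat_res$present, rr_pos = tat_res$rr_pos,
    lpxtg = lpxtg_res$present, lpxtg_start = lpxtg_res$motif_start,
    selected = selected, cleavage_pos = cleavage_pos
  )
  ann$cleavage_window <- cleavage_window(sequence, ann)
  ann
}

#' Annotate export signals for a protein table
#'
#' Runs all four detectors on every protein and records the selected
#' cleavage event and its window. Deterministic: identical sequences give
#' identical annotations.
#'
#' @param proteins Protein tibble from [read_fasta()] (needs `id`,
#'   `sequence`), or a single sequence string.
#' @return Tibble with one row per protein: detector flags, positions,
#'   confidences, `selected`, `cleavage_pos`, `cleavage_window`.
#' @export
annotate_signals <- function(proteins) {
  if (is.character(proteins)) {
    proteins <- tibble::tibble(id = sprintf("seq%d", seq_along(proteins)),
                               sequence = proteins)
  }
  res <- purrr::map(proteins$sequence, annotate_one)
  dplyr::bind_cols(tibble::tibble(id = proteins$id), dplyr::bind_rows(res))
}
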