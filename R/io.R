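#' Read an amino-acid FASTA file into a protein table
#'
#' Reads one record per FASTA entry, preserving order. Sequences are
#' uppercased and a single trailing `*` stop character is stripped. The `id`
#' is the first whitespace-delimited token of the header; the remainder is
#' kept as `description`.
#'
#' @param path Path to an amino-acid FASTA file.
#' @return A tibble with columns `id`, `description`, `sequence`, `length`.
#' @details Duplicated ids and empty sequences are hard errors. A file whose
#'   residues are >= 95% `A/C/G/T/U/N` looks like nucleotide data and only
#'   triggers a warning. Residues outside the 20 canonical amino acids plus
#'   `X/B/Z/U` are rejected.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo protein", "MKTAYIAKQR"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  seqs <- unname(toupper(as.character(aa)))
  seqs <- sub("\\*$", "", seqs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf("Duplicate FASTA id(s): %s", paste(dup, collapse = ", ")))
  }
  if (any(nchar(seqs) == 0L)) {
    abort(sprintf("Empty sequence for record(s): %s",
                  paste(ids[nchar(seqs) == 0L], collapse = ", ")))
  }
  bad <- vapply(seqs, function(s) {
    any(!seq_chars(s) %in% AA_ALPHABET)
  }, logical(1))
  if (any(bad)) {
    abort(sprintf("Sequence contains characters outside the amino-acid alphabet: %s",
                  paste(ids[bad], collapse = ", ")))
  }
  all_chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  if (length(all_chars) &&
      mean(all_chars %in% c("A", "C", "G", "T", "U", "N")) >= 0.95) {
    warn("Input looks like nucleotide data (>= 95% A/C/G/T/U/N residues).")
  }
  tibble::tibble(id = ids, description = unname(desc),
                 sequence = unname(seqs), length = nchar(seqs))
}

#' Write a protein table as FASTA
#'
#' @param proteins Tibble with `id`, `description`, `sequence` columns.
#' @param path Output file path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  desc <- if ("description" %in% names(proteins)) proteins$description
    else rep("", nrow(proteins))
  lines <- purrr::pmap(
    list(proteins$id, desc, proteins$sequence),
    function(id, d, s) {
      hdr <- if (nzchar(d)) paste0(">", id, " ", d) else paste0(">", id)
      body <- substring(s, seq(1, nchar(s), width),
                        pmin(seq(1, nchar(s), width) + width - 1L, nchar(s)))
      c(hdr, body)
    }
  )
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Screening criteria for anchor-protein candidates
#'
#' Builds the rubric thresholds applied by [apply_rubric()] and
#' [screen_proteome()]. Defaults encode the published screening table:
#' proteins shorter than 600 residues, intracellular possibility at most 0.5,
#' total N-in probability above 0.8 where required, and 20-residue terminal
#' windows whose outside probability must exceed 0.5 on the displayed
#' terminus and stay below 0.5 on the anchoring terminus.
#'
#' @param max_length Maximum candidate length in residues (exclusive bound).
#' @param intracellular_max Maximum intracellular possibility score.
#' @param n_in_min Minimum posterior probability that the N-terminus is
#'   inside, applied to N-terminally anchored and secretory classes.
#' @param terminal_window Terminal window width in residues.
#' @param window_outside_min Minimum mean outside probability over the
#'   display-terminus window.
#' @param opposite_window_outside_max Maximum mean outside probability over
#'   the anchoring-terminus window.
#' @param allowed_classes Character vector of admissible SCL classes.
#' @param soft_weights Named list of ranking weights: `signal`,
#'   `n_anchored`, `display_outside`.
#' @param strict_windows Apply the topology window and N-in rules as hard
#'   filters (`TRUE`, default) or leave them to ranking only.
#' @param window_stat Aggregate for terminal windows: `"mean"` (default) or
#'   `"max"`.
#' @return An object of class `screen_criteria` (a named list).
#' @export
screen_criteria <- function(max_length = 600,
                            intracellular_max = 0.5,
                            n_in_min = 0.8,
                            terminal_window = 20,
                            window_outside_min = 0.5,
                            opposite_window_outside_max = 0.5,
                            allowed_classes = default_allowed_classes(),
                            soft_weights = list(signal = 1, n_anchored = 1,
                                                display_outside = 1),
                            strict_windows = TRUE,
                            window_stat = c("mean", "max")) {
  assert_scalar_number(max_length, "max_length", lower = 1)
  assert_scalar_number(intracellular_max, "intracellular_max", 0, 1)
  assert_scalar_number(n_in_min, "n_in_min", 0, 1)
  assert_scalar_number(terminal_window, "terminal_window", lower = 1)
  assert_scalar_number(window_outside_min, "window_outside_min", 0, 1)
  assert_scalar_number(opposite_window_outside_max,
                       "opposite_window_outside_max", 0, 1)
  if (length(allowed_classes) == 0L) {
    abort("`allowed_classes` must be non-empty.")
  }
  unknown <- setdiff(allowed_classes, SCL_CLASSES)
  if (length(unknown)) {
    abort(sprintf("Unknown SCL class in `allowed_classes`: %s",
                  paste(unknown, collapse = ", ")))
  }
  stopifnot(is.list(soft_weights))
  sw <- list(signal = 1, n_anchored = 1, display_outside = 1)
  sw[names(soft_weights)] <- soft_weights
  structure(
    list(
      max_length = max_length,
      intracellular_max = intracellular_max,
      n_in_min = n_in_min,
      terminal_window = as.integer(terminal_window),
      window_outside_min = window_outside_min,
      opposite_window_outside_max = opposite_window_outside_max,
      allowed_classes = allowed_classes,
      soft_weights = sw,
      strict_windows = isTRUE(strict_windows),
      window_stat = match.arg(window_stat)
    ),
    class = "screen_criteria"
  )
}

#' Default admissible SCL classes for candidate anchors
#'
#' The six membrane- or export-associated classes of the screening table.
#' `@Intracellular` and `@LPXTG cell-wall anchored` are excluded by default
#' (the latter can be enabled through `allowed_classes`).
#' @return Character vector of class labels.
#' @export
default_allowed_classes <- function() {
  c(
    "@C-terminally anchored (with CS)",
    "@Multi-transmembrane (lipid-modified N-termini)",
    "@Lipid-anchored",
    "@Multi-transmembrane",
    "@N-terminally anchored (no CS)",
    "@Secretory (released) (with CS)"
  )
}

#' Load screening criteria from a YAML config file
#'
#' With `path = NULL` the defaults of [screen_criteria()] are returned.
#' Unknown keys are rejected; values are validated.
#'
#' @param path Path to a YAML key/value file, or `NULL`.
#' @return A `screen_criteria` object.
#' @export
load_criteria <- function(path = NULL) {
  if (is.null(path)) return(screen_criteria())
  if (!file.exists(path)) abort(sprintf("Criteria file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) return(screen_criteria())
  known <- names(formals(screen_criteria))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    abort(sprintf("Unknown criteria key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(screen_criteria, cfg)
}

candidate_table_columns <- function() {
  c("protein_id", "locus_tag", "product", "pathway", "scl_class",
    "intracellular_possibility", "signal_possibility",
    "n_anchored_possibility", "cleavage_window", "anchored_site",
    "rank_score", "pass", "fail_reasons")
}

#' Write a candidate table as TSV
#'
#' Writes the fixed candidate-table column layout with floats rendered to
#' two decimals and a deterministic row order: passing rows first by
#' descending rank score (ties by ascending id), then failing rows by
#' ascending id. Output bytes are identical across repeated runs on
#' identical input; provenance lives only in `#` comment lines.
#'
#' @param rows Candidate tibble as produced by [screen_proteome()] or
#'   [rank_candidates()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(rows, path) {
  cols <- candidate_table_columns()
  missing <- setdiff(cols, names(rows))
  if (length(missing)) {
    abort(sprintf("Candidate table is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  rows <- order_candidate_rows(rows)
  out <- rows[cols]
  num_cols <- c("intracellular_possibility", "signal_possibility",
                "n_anchored_possibility", "rank_score")
  for (nc in num_cols) {
    out[[nc]] <- ifelse(is.na(out[[nc]]), "NA", sprintf("%.2f", out[[nc]]))
  }
  out$pass <- ifelse(out$pass, "TRUE", "FALSE")
  out$anchored_site <- ifelse(is.na(out$anchored_site), "NA",
                              out$anchored_site)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# anchorscreen candidate table", con)
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(out)) {
    body <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

order_candidate_rows <- function(rows) {
  if (!nrow(rows)) return(rows)
  pass <- rows[rows$pass %in% TRUE, , drop = FALSE]
  fail <- rows[!rows$pass %in% TRUE, , drop = FALSE]
  pass <- pass[order(-pass$rank_score, pass$protein_id), , drop = FALSE]
  fail <- fail[order(fail$protein_id), , drop = FALSE]
  dplyr::bind_rows(pass, fail)
}

#' Read a candidate TSV back into a tibble
#'
#' Inverse of [write_candidate_table()]; `#` comment lines are skipped.
#' @param path TSV path.
#' @return Candidate tibble.
#' @export
read_candidate_table <- function(path) {
  readr::read_tsv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      protein_id = readr::col_character(),
      locus_tag = readr::col_character(),
      product = readr::col_character(),
      pathway = readr::col_character(),
      scl_class = readr::col_character(),
      intracellular_possibility = readr::col_double(),
      signal_possibility = readr::col_double(),
      n_anchored_possibility = readr::col_double(),
      cleavage_window = readr::col_character(),
      anchored_site = readr::col_character(),
      rank_score = readr::col_double(),
      pass = readr::col_logical(),
      fail_reasons = readr::col_character()
    ),
    na = "NA"
  )
}
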