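# The screening rubric, anchoring-site assignment, candidate ranking, and
# the top-level proteome screen.

#' Apply the hard screening rubric
#'
#' Hard rules (any failure fails the candidate):
#' \describe{
#' \item{h1_length}{protein shorter than `max_length` residues;}
#' \item{h2_class}{SCL class among `allowed_classes`;}
#' \item{h3_intracellular}{intracellular possibility at most
#'   `intracellular_max`;}
#' \item{h4_windows}{mean outside probability over the display-terminus
#'   window above `window_outside_min` and over the anchoring-terminus
#'   window below `opposite_window_outside_max` (the display terminus is
#'   the terminus opposite the anchoring site; its window starts at the
#'   mature N-terminus when the display terminus is N and a signal peptide
#'   was cleaved);}
#' \item{h5_n_in}{for N-terminally anchored and secretory classes, the
#'   posterior probability that the N-terminus is inside above `n_in_min`.}
#' }
#' Rules whose inputs are unavailable are not applied: `h1` is skipped when
#' `length` is `NA`, `h4`/`h5` when `summary` is `NULL` (or when
#' `strict_windows` is off). The "choose larger parameters" criteria
#' (signal and N-anchored possibility) are soft: they enter the rank score,
#' never the pass/fail decision.
#'
#' @param prediction One-row tibble or list with `scl_class`,
#'   `intracellular_possibility`.
#' @param summary One-row topology summary from [summarize_topology()], or
#'   `NULL` when only printed fields are available.
#' @param length Protein length in residues, or `NA`.
#' @param criteria A [screen_criteria()] object.
#' @return List with `pass` (flag) and `fail_reasons` (character vector,
#'   empty when passing).
#' @export
apply_rubric <- function(prediction, summary = NULL, length = NA,
                         criteria = screen_criteria()) {
  stopifnot(inherits(criteria, "screen_criteria"))
  reasons <- character(0)
  if (!is.na(length) && length >= criteria$max_length) {
    reasons <- c(reasons, "h1_length")
  }
  if (!prediction$scl_class %in% criteria$allowed_classes) {
    reasons <- c(reasons, "h2_class")
  }
  if (prediction$intracellular_possibility > criteria$intracellular_max) {
    reasons <- c(reasons, "h3_intracellular")
  }
  if (!is.null(summary) && criteria$strict_windows) {
    site <- assign_anchor_site(prediction, summary)
    if (!is.na(site)) {
      w <- terminal_windows(site, summary)
      if (!(w$display > criteria$window_outside_min &&
            w$anchor < criteria$opposite_window_outside_max)) {
        reasons <- c(reasons, "h4_windows")
      }
    }
    if (prediction$scl_class %in% c("@N-terminally anchored (no CS)",
                                    "@Secretory (released) (with CS)") &&
        summary$prob_n_in <= criteria$n_in_min) {
      reasons <- c(reasons, "h5_n_in")
    }
  }
  list(pass = length(reasons) == 0L, fail_reasons = reasons)
}

# Outside-probability windows for the display and anchoring termini.
# Anchoring windows are taken on the precursor; the display window uses the
# mature N-terminus when the display terminus is N.
terminal_windows <- function(site, summary) {
  if (site == "N site") {
    list(display = summary$out_last_w, anchor = summary$out_first_w)
  } else {
    list(display = summary$out_first_mature_w, anchor = summary$out_last_w)
  }
}

#' Assign the anchoring terminus
#'
#' `"N site"` / `"C site"` name the terminus through which the anchor is
#' riveted to the envelope; the passenger is fused at the opposite,
#' displayed terminus. C-terminally anchored and LPXTG proteins anchor at
#' C; lipid-anchored, lipid-modified multi-transmembrane, N-terminally
#' anchored and secretory proteins anchor at N. For plain
#' multi-transmembrane proteins the terminus with the lower mean outside
#' probability is the anchoring terminus: `"N site"` if
#' `out_last_w >= out_first_w`, else `"C site"`. Intracellular proteins
#' have no anchoring site (`NA`).
#'
#' @inheritParams apply_rubric
#' @return `"N site"`, `"C site"`, or `NA`.
#' @export
assign_anchor_site <- function(prediction, summary = NULL) {
  cls <- prediction$scl_class
  if (cls %in% c("@C-terminally anchored (with CS)",
                 "@LPXTG cell-wall anchored")) {
    return("C site")
  }
  if (cls %in% c("@Lipid-anchored",
                 "@Multi-transmembrane (lipid-modified N-termini)",
                 "@N-terminally anchored (no CS)",
                 "@Secretory (released) (with CS)")) {
    return("N site")
  }
  if (cls == "@Multi-transmembrane") {
    if (is.null(summary)) return(NA_character_)
    return(if (summary$out_last_w >= summary$out_first_w) "N site"
           else "C site")
  }
  NA_character_
}

#' Rank screened candidates
#'
#' `rank_score = w_sig * signal + w_anch * tanh(n_anchored / 7) +
#' w_out * display_outside` with the weights of
#' `criteria$soft_weights`. Passing rows are sorted by descending score
#' (ties by ascending id); failing rows follow, unranked (`NA` score), by
#' ascending id. Input order never affects output order.
#'
#' @param rows Candidate tibble (needs `protein_id`, `signal_possibility`,
#'   `n_anchored_possibility`, `pass`; `display_outside` when available).
#' @param criteria A [screen_criteria()] object.
#' @return The rows, ordered, with a `rank_score` column.
#' @export
rank_candidates <- function(rows, criteria = screen_criteria()) {
  w <- criteria$soft_weights
  disp <- if ("display_outside" %in% names(rows)) rows$display_outside
    else rep(0, nrow(rows))
  disp[is.na(disp)] <- 0
  score <- w$signal * rows$signal_possibility +
    w$n_anchored * tanh(rows$n_anchored_possibility / 7) +
    w$display_outside * disp
  rows$rank_score <- ifelse(rows$pass, score, NA_real_)
  order_candidate_rows(rows)
}

parse_locus_tag <- function(description) {
  vapply(description, function(d) {
    m <- stringr::str_match(d, "locus_tag=(\\S+)")[, 2]
    if (!is.na(m)) return(m)
    toks <- strsplit(d, "\\s+")[[1]]
    hit <- toks[grepl("^NCgl[0-9]{4}$", toks)]
    if (length(hit)) return(hit[1])
    "-"
  }, character(1), USE.NAMES = FALSE)
}

screen_one <- function(id, description, sequence, length, criteria, model) {
  ann <- annotate_one(sequence)
  post <- posterior_decode(model, sequence)
  segs <- viterbi_topology(model, sequence)
  mature_start <- if (!identical(ann$selected, "none")) {
    ann$cleavage_pos + 1L
  } else 1L
  summ <- summarize_topology(post, segs, window = criteria$terminal_window,
                             mature_start = mature_start,
                             stat = criteria$window_stat)
  pred <- classify_scl(ann, summ)
  site <- assign_anchor_site(pred, summ)
  rub <- apply_rubric(pred, summ, length, criteria)
  disp <- if (is.na(site)) NA_real_ else terminal_windows(site, summ)$display
  tibble::tibble(
    protein_id = id,
    locus_tag = parse_locus_tag(description),
    product = description,
    length = length,
    pathway = pred$pathway,
    scl_class = pred$scl_class,
    intracellular_possibility = pred$intracellular_possibility,
    signal_possibility = pred$signal_possibility,
    n_anchored_possibility = pred$n_anchored_possibility,
    cleavage_window = pred$cleavage_window,
    prob_n_in = summ$prob_n_in,
    out_first_w = summ$out_first_w,
    out_last_w = summ$out_last_w,
    out_first_mature_w = summ$out_first_mature_w,
    n_helices = summ$n_helices,
    anchored_site = site,
    display_outside = disp,
    pass = rub$pass,
    fail_reasons = paste(rub$fail_reasons, collapse = ",")
  )
}

empty_screen_tbl <- function() {
  tibble::tibble(
    protein_id = character(), locus_tag = character(), product = character(),
    length = integer(), pathway = character(), scl_class = character(),
    intracellular_possibility = numeric(), signal_possibility = numeric(),
    n_anchored_possibility = numeric(), cleavage_window = character(),
    prob_n_in = numeric(), out_first_w = numeric(), out_last_w = numeric(),
    out_first_mature_w = numeric(), n_helices = integer(),
    anchored_site = character(), display_outside = numeric(),
    pass = logical(), fail_reasons = character(), rank_score = numeric()
  )
}

#' Screen a proteome for candidate anchor proteins
#'
#' Top-level pipeline: for every protein, decode topology, annotate export
#' signals, classify the subcellular localization, apply the screening
#' rubric, assign the anchoring site, and rank. All rows (passing and
#' failing) are returned; the output row count always equals the input
#' record count. Deterministic: identical input gives identical output.
#'
#' @param x Path to an amino-acid FASTA file, or a protein tibble with
#'   `id`, `sequence` (and optionally `description`) columns.
#' @param criteria A [screen_criteria()] object.
#' @param model A `topology_model` (default [default_topology_model()]).
#' @return An `anchor_screen` tibble with prediction, rubric, site and rank
#'   columns; the criteria used are attached as an attribute.
#' @examples
#' prot <- generate_proteome(6, seed = 1)$proteins
#' screen_proteome(prot)
#' @export
screen_proteome <- function(x, criteria = screen_criteria(),
                            model = default_topology_model()) {
  proteins <- if (is.character(x)) read_fasta(x) else tibble::as_tibble(x)
  if (!all(c("id", "sequence") %in% names(proteins))) {
    abort("Protein table needs `id` and `sequence` columns.")
  }
  if (!"description" %in% names(proteins)) proteins$description <- ""
  if (!"length" %in% names(proteins)) {
    proteins$length <- nchar(proteins$sequence)
  }
  rows <- if (nrow(proteins) == 0L) {
    empty_screen_tbl()
  } else {
    res <- purrr::pmap(
      list(proteins$id, proteins$description, proteins$sequence,
           proteins$length),
      screen_one, criteria = criteria, model = model
    )
    rank_candidates(dplyr::bind_rows(res), criteria)
  }
  class(rows) <- c("anchor_screen", class(rows))
  attr(rows, "criteria") <- criteria
  rows
}

#' @export
print.anchor_screen <- function(x, ...) {
  cat(sprintf("<anchor_screen> %d proteins, %d candidates pass\n",
              nrow(x), sum(x$pass)))
  NextMethod()
}

#' Tidy an anchor screen result
#' @param x An `anchor_screen`.
#' @param ... Unused.
#' @return A plain tibble of the screen rows.
#' @export
tidy.anchor_screen <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "anchor_screen")
  attr(out, "criteria") <- NULL
  out
}

#' One-row summary of an anchor screen
#' @param x An `anchor_screen`.
#' @param ... Unused.
#' @export
glance.anchor_screen <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x),
    n_pass = sum(x$pass),
    n_fail = sum(!x$pass),
    n_site_n = sum(x$pass & x$anchored_site == "N site", na.rm = TRUE),
    n_site_c = sum(x$pass & x$anchored_site == "C site", na.rm = TRUE),
    top_rank_score = if (any(x$pass)) max(x$rank_score, na.rm = TRUE)
      else NA_real_
  )
}

#' Plot ranked anchor candidates
#'
#' Rank scores of passing candidates coloured by SCL class.
#' @param object An `anchor_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.anchor_screen <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$pass, , drop = FALSE]
  d$protein_id <- factor(d$protein_id, levels = rev(d$protein_id))
  ggplot2::ggplot(d, ggplot2::aes(.data$rank_score, .data$protein_id,
                                  fill = .data$scl_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "rank score", y = NULL, fill = "SCL class") +
    ggplot2::theme_minimal()
}
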