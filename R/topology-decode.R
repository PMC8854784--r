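# Forward/backward, posterior decoding and Viterbi for the topology HMM.
# Forward/backward use per-position scaling; Viterbi runs in log space, so
# underflow cannot reach callers for any realistic protein length.

# Sequence argument: a plain string, or anything with a `sequence` field.
as_sequence <- function(x) {
  if (is.character(x) && length(x) == 1L) return(x)
  if (!is.null(x$sequence)) {
    s <- x$sequence
    if (length(s) == 1L) return(s)
  }
  abort("Expected a single sequence string or a record with a `sequence` field.")
}

# Emission probabilities per position: states x L matrix. Residues outside
# the 20-letter alphabet (X/B/Z/U) emit the background average 1/20 in every
# state.
emission_matrix <- function(model, chars) {
  idx <- match(chars, AA20)
  E <- matrix(1 / 20, nrow = length(model$states), ncol = length(chars))
  known <- !is.na(idx)
  E[, known] <- model$emis[, idx[known], drop = FALSE]
  E
}

scaled_forward <- function(model, E) {
  L <- ncol(E)
  n <- nrow(E)
  alpha <- matrix(0, n, L)
  scale <- numeric(L)
  a <- model$init * E[, 1]
  scale[1] <- sum(a)
  alpha[, 1] <- a / scale[1]
  tTrans <- t(model$trans)
  for (t in seq_len(L)[-1]) {
    a <- as.vector(tTrans %*% alpha[, t - 1]) * E[, t]
    scale[t] <- sum(a)
    alpha[, t] <- a / scale[t]
  }
  loglik <- sum(log(scale)) + log(sum(alpha[, L] * model$final))
  list(alpha = alpha, scale = scale, loglik = loglik)
}

scaled_backward <- function(model, E, scale) {
  L <- ncol(E)
  n <- nrow(E)
  beta <- matrix(0, n, L)
  beta[, L] <- model$final / scale[L]
  for (t in rev(seq_len(L - 1))) {
    beta[, t] <- as.vector(model$trans %*% (E[, t + 1] * beta[, t + 1])) /
      scale[t]
  }
  beta
}

#' Log-likelihood of a sequence under a topology model
#'
#' Total probability of the sequence summed over all state paths, computed
#' with the scaled forward recursion (or backward, for cross-checking).
#'
#' @param model A `topology_model`.
#' @param x Sequence string or a record with a `sequence` field.
#' @param direction `"forward"` (default) or `"backward"`.
#' @return Finite log probability.
#' @export
sequence_likelihood <- function(model, x, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  chars <- seq_chars(as_sequence(x))
  if (!length(chars)) abort("Sequence must be non-empty.")
  E <- emission_matrix(model, chars)
  if (direction == "forward") {
    return(scaled_forward(model, E)$loglik)
  }
  # Backward recursion with its own ad-hoc rescaling, independent of the
  # forward pass, so the two directions genuinely cross-check each other.
  L <- ncol(E)
  b <- model$final
  log_acc <- 0
  if (L > 1L) {
    for (t in L:2) {
      b <- as.vector(model$trans %*% (E[, t] * b))
      s <- sum(b)
      b <- b / s
      log_acc <- log_acc + log(s)
    }
  }
  log_acc + log(sum(model$init * E[, 1] * b))
}

#' Posterior inside/membrane/outside probabilities per residue
#'
#' Forward-backward posteriors aggregated to the three topology labels (cap
#' and globular states fold into their side's label).
#'
#' @inheritParams sequence_likelihood
#' @return A `residue_posterior` tibble with columns `position`, `residue`,
#'   `p_in`, `p_mem`, `p_out`; each row sums to 1.
#' @export
posterior_decode <- function(model, x) {
  seqstr <- as_sequence(x)
  chars <- seq_chars(seqstr)
  if (!length(chars)) abort("Sequence must be non-empty.")
  E <- emission_matrix(model, chars)
  fwd <- scaled_forward(model, E)
  beta <- scaled_backward(model, E, fwd$scale)
  gamma <- fwd$alpha * beta
  gamma <- sweep(gamma, 2, colSums(gamma), "/")
  lab <- model$labels
  out <- tibble::tibble(
    position = seq_along(chars),
    residue = chars,
    p_in = colSums(gamma[lab == "inside", , drop = FALSE]),
    p_mem = colSums(gamma[lab == "membrane", , drop = FALSE]),
    p_out = colSums(gamma[lab == "outside", , drop = FALSE])
  )
  class(out) <- c("residue_posterior", class(out))
  attr(out, "loglik") <- fwd$loglik
  out
}

#' Maximum-probability topology segments
#'
#' Viterbi decoding under the model grammar. Ties are broken by fixed state
#' index order. Consecutive residues sharing a topology label are merged
#' into segments that tile the sequence.
#'
#' @inheritParams sequence_likelihood
#' @return Tibble with columns `label`, `start`, `end` (1-based, inclusive).
#' @export
viterbi_topology <- function(model, x) {
  chars <- seq_chars(as_sequence(x))
  if (!length(chars)) abort("Sequence must be non-empty.")
  E <- emission_matrix(model, chars)
  n <- nrow(E)
  L <- ncol(E)
  logtrans <- log(model$trans)
  delta <- log(model$init) + log(E[, 1])
  psi <- matrix(0L, n, L)
  for (t in seq_len(L)[-1]) {
    cand <- delta + logtrans  # cand[i, j]: best score ending in j via i
    best_prev <- max.col(t(cand), ties.method = "first")
    delta <- cand[cbind(best_prev, seq_len(n))] + log(E[, t])
    psi[, t] <- best_prev
  }
  path <- integer(L)
  path[L] <- which.max(delta + log(model$final))
  if (L > 1L) {
    for (t in rev(seq_len(L - 1))) path[t] <- psi[path[t + 1], t + 1]
  }
  labs <- unname(model$labels[path])
  r <- rle(labs)
  ends <- cumsum(r$lengths)
  tibble::tibble(label = r$values,
                 start = ends - r$lengths + 1L,
                 end = ends)
}

window_mean <- function(p, from, to, stat) {
  v <- p[from:to]
  if (stat == "max") max(v) else mean(v)
}

#' Window statistics consumed by the screening rubric
#'
#' Derives, from per-residue posteriors and Viterbi segments of the same
#' record: the helix count, the posterior probability that residue 1 is
#' inside (`prob_n_in`), and mean outside probabilities over the first and
#' last `window` residues. When the sequence is shorter than `window`, the
#' statistic is taken over all residues. `mature_start` shifts the
#' N-terminal window to the first residue of the mature chain (used by the
#' rubric when a signal peptide is cleaved); the precursor windows
#' `out_first_w`/`out_last_w` are always reported as well.
#'
#' @param posterior A `residue_posterior` from [posterior_decode()].
#' @param segments Segment tibble from [viterbi_topology()].
#' @param window Window width in residues (default 20).
#' @param mature_start 1-based first residue of the mature chain.
#' @param stat Window aggregate, `"mean"` (default) or `"max"`.
#' @return One-row tibble: `len`, `n_helices`, `prob_n_in`, `out_first_w`,
#'   `out_last_w`, `out_first_mature_w`, `window`, `mature_start`,
#'   N-terminal helix fields (`nterm_helix_start`, `nterm_helix_end`,
#'   `nterm_helix_mem`), and a `segments` list-column.
#' @export
summarize_topology <- function(posterior, segments, window = 20L,
                               mature_start = 1L,
                               stat = c("mean", "max")) {
  stat <- match.arg(stat)
  if (!is.numeric(window) || window < 1) abort("`window` must be >= 1.")
  window <- as.integer(window)
  L <- nrow(posterior)
  if (max(segments$end) != L || min(segments$start) != 1L) {
    abort("Posterior and segments disagree on sequence length.")
  }
  mature_start <- max(1L, min(as.integer(mature_start), L))
  p_out <- posterior$p_out
  first_to <- min(window, L)
  last_from <- max(1L, L - window + 1L)
  mat_to <- min(mature_start + window - 1L, L)
  helix <- segments[segments$label == "membrane", , drop = FALSE]
  nterm <- helix[helix$start <= 40L, , drop = FALSE]
  if (nrow(nterm)) {
    hs <- nterm$start[1]
    he <- nterm$end[1]
    hmem <- mean(posterior$p_mem[hs:he])
  } else {
    hs <- NA_integer_; he <- NA_integer_; hmem <- 0
  }
  tibble::tibble(
    len = L,
    n_helices = nrow(helix),
    prob_n_in = posterior$p_in[1],
    out_first_w = window_mean(p_out, 1L, first_to, stat),
    out_last_w = window_mean(p_out, last_from, L, stat),
    out_first_mature_w = window_mean(p_out, mature_start, mat_to, stat),
    window = window,
    mature_start = mature_start,
    nterm_helix_start = hs,
    nterm_helix_end = he,
    nterm_helix_mem = hmem,
    segments = list(segments)
  )
}

#' Plot per-residue topology posteriors
#'
#' Three posterior tracks (inside, membrane, outside) along the sequence.
#'
#' @param object A `residue_posterior`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.residue_posterior <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("position", "p_in", "p_mem", "p_out")],
    -"position", names_to = "track", values_to = "probability"
  )
  long$track <- factor(long$track, levels = c("p_in", "p_mem", "p_out"),
                       labels = c("inside", "membrane", "outside"))
  ggplot2::ggplot(long, ggplot2::aes(.data$position, .data$probability,
                                     colour = .data$track)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(inside = "#1b7837", membrane = "#762a83",
                 outside = "#2166ac"), name = NULL) +
    ggplot2::labs(x = "residue", y = "posterior probability") +
    ggplot2::theme_minimal()
}
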