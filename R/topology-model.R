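# Cyclic topology HMM: model construction and validation.
#
# State layout (cap and helix-core states carry the "membrane" label):
#   in -> cap-in(2) -> helix core io(min..max) -> cap-out(2) -> out
#   out -> cap-out(2) -> helix core oi(min..max) -> cap-in(2) -> in
#   out <-> outside-globular (long extracellular domains)
# Helix length is enforced by chained core states: `helix_min_len` mandatory
# plus up to `helix_max_len - helix_min_len` optional states, not by duration
# modelling. Membrane segments therefore span core + 4 cap residues.

#' Construct a topology HMM
#'
#' Low-level constructor used both for the shipped default model and for
#' small custom models in tests and experiments. Validates row-stochastic
#' transitions and emissions, the inside/membrane/outside grammar (no direct
#' inside-outside transition bypassing a membrane state), and helix length
#' bounds.
#'
#' @param states Character vector of state names.
#' @param labels Character vector (same length) over
#'   `c("inside", "membrane", "outside")`.
#' @param init Initial distribution over states (named or positional).
#' @param trans Row-stochastic transition matrix, states x states.
#' @param emis Row-stochastic emission matrix, states x 20 amino acids in
#'   the order `ACDEFGHIKLMNPQRSTVWY`.
#' @param helix_min_len,helix_max_len Helix core length bounds in residues.
#' @param final Non-negative end weights per state (default: no end
#'   constraint). The shipped default model forbids ending inside a
#'   membrane segment, so every decoded helix is complete.
#' @return An object of class `topology_model`.
#' @export
topology_model <- function(states, labels, init, trans, emis,
                           helix_min_len = 15L, helix_max_len = 25L,
                           final = NULL) {
  n <- length(states)
  if (is.null(final)) final <- rep(1, n)
  stopifnot(length(labels) == n, nrow(trans) == n, ncol(trans) == n,
            nrow(emis) == n, ncol(emis) == 20L, length(init) == n,
            length(final) == n)
  if (!all(labels %in% c("inside", "membrane", "outside"))) {
    abort("Labels must be one of inside/membrane/outside.")
  }
  dimnames(trans) <- list(states, states)
  dimnames(emis) <- list(states, AA20)
  names(init) <- states
  names(labels) <- states
  names(final) <- states
  model <- structure(
    list(states = states, labels = labels, init = init, trans = trans,
         emis = emis, final = final,
         helix_min_len = as.integer(helix_min_len),
         helix_max_len = as.integer(helix_max_len)),
    class = "topology_model"
  )
  validate_topology_model(model)
  model
}

#' Validate a topology model
#'
#' Checks stochasticity (1e-9), grammar, and helix length bounds; errors on
#' violation, returns the model invisibly otherwise.
#' @param model A `topology_model`.
#' @export
validate_topology_model <- function(model) {
  tol <- 1e-9
  if (any(abs(rowSums(model$trans) - 1) > tol)) {
    abort("Transition rows must sum to 1.")
  }
  if (any(abs(rowSums(model$emis) - 1) > tol)) {
    abort("Emission rows must sum to 1.")
  }
  if (abs(sum(model$init) - 1) > tol) abort("Initial distribution must sum to 1.")
  if (any(model$trans < 0) || any(model$emis < 0) || any(model$init < 0)) {
    abort("Probabilities must be non-negative.")
  }
  if (any(model$final < 0) || sum(model$final) == 0) {
    abort("End weights must be non-negative with at least one positive.")
  }
  ins <- model$labels == "inside"
  outs <- model$labels == "outside"
  if (any(model$trans[ins, outs, drop = FALSE] > 0) ||
      any(model$trans[outs, ins, drop = FALSE] > 0)) {
    abort("Grammar violation: direct inside-outside transition.")
  }
  if (model$helix_min_len < 5L) abort("helix_min_len must be >= 5.")
  if (model$helix_max_len < model$helix_min_len) {
    abort("helix_max_len must be >= helix_min_len.")
  }
  invisible(model)
}

# Normalise a non-negative vector to a distribution over AA20.
aa_dist <- function(w) {
  w <- w[AA20]
  w / sum(w)
}

#' The shipped default topology model
#'
#' Emissions are derived from the Kyte-Doolittle hydropathy scale: helix
#' cores favour I/L/V/F/M/A (with an interface adjustment for W and Y) and
#' disfavour charged and polar residues; inside loops up-weight K and R
#' (positive-inside rule); outside loops and the outside-globular state
#' up-weight polar residues, with the polar factor calibrated so that
#' neither loop side is favoured on average cytoplasmic composition. The
#' initial distribution places residue 1 inside with probability 0.9.
#'
#' Absolute posterior probabilities from this model are not those of any
#' externally trained predictor; the supported contract is the threshold
#' comparisons used by the screening rubric.
#'
#' @param helix_min_len,helix_max_len Helix core length bounds.
#' @param p_init_in Initial probability of starting in the inside loop.
#' @return A `topology_model`.
#' @export
default_topology_model <- function(helix_min_len = 15L, helix_max_len = 25L,
                                   p_init_in = 0.9) {
  helix_min_len <- as.integer(helix_min_len)
  helix_max_len <- as.integer(helix_max_len)
  ncore <- helix_max_len

  # Emission distributions -------------------------------------------------
  adj <- setNames(rep(0, 20), AA20)
  adj[c("W", "Y")] <- c(2.8, 1.6)  # interface aromatics sit in membranes
  adj["C"] <- -1.0
  helix_em <- aa_dist(exp((KD_SCALE[AA20] + adj[AA20]) / 2))

  background <- aa_dist(0.5 / 20 + 0.5 * BACKGROUND_FREQ)

  boost <- function(base, residues, factor) {
    w <- base
    w[residues] <- w[residues] * factor
    aa_dist(w)
  }
  inside_em <- boost(background, c("K", "R"), 2.5)

  # Calibrate the polar boost of the outside loop so the expected
  # log-emission difference between the loop sides is zero on the
  # background composition (residue 1's side is then decided by `init`
  # and by genuine compositional signals, not by a modelling artefact).
  polar <- c("D", "E", "N", "Q", "S", "T")
  target <- sum(BACKGROUND_FREQ * log(inside_em))
  f <- function(beta) {
    sum(BACKGROUND_FREQ * log(boost(background, polar, beta))) - target
  }
  beta <- stats::uniroot(f, c(1.01, 10))$root
  outside_em <- boost(background, polar, beta)

  cap_em <- aa_dist(0.5 * helix_em + 0.5 * background)

  # States ------------------------------------------------------------------
  core_io <- sprintf("hio%02d", seq_len(ncore))
  core_oi <- sprintf("hoi%02d", seq_len(ncore))
  states <- c("in", "ci_io1", "ci_io2", core_io, "co_io1", "co_io2",
              "out", "og", "co_oi1", "co_oi2", core_oi, "ci_oi1", "ci_oi2")
  labels <- setNames(rep("membrane", length(states)), states)
  labels["in"] <- "inside"
  labels[c("out", "og")] <- "outside"

  n <- length(states)
  trans <- matrix(0, n, n, dimnames = list(states, states))
  set <- function(from, to, p) trans[from, to] <<- p

  # Loop dwell probabilities are matched between the inside loop and the
  # outside-globular state so that neither side of the membrane is favoured
  # on signal-free background sequences (residue 1's side is then decided
  # by `init` and genuine compositional evidence).
  p_enter_in <- 0.04
  set("in", "in", 1 - p_enter_in)
  set("in", "ci_io1", p_enter_in)
  set("ci_io1", "ci_io2", 1)
  set("ci_io2", core_io[1], 1)
  p_cont <- 0.7
  for (k in seq_len(ncore)) {
    if (k < helix_min_len) {
      set(core_io[k], core_io[k + 1], 1)
    } else if (k < ncore) {
      set(core_io[k], core_io[k + 1], p_cont)
      set(core_io[k], "co_io1", 1 - p_cont)
    } else {
      set(core_io[k], "co_io1", 1)
    }
  }
  set("co_io1", "co_io2", 1)
  set("co_io2", "out", 1)

  set("out", "out", 0.90)
  set("out", "og", 0.04)
  set("out", "co_oi1", 0.06)
  set("og", "og", 0.96)
  set("og", "out", 0.04)

  set("co_oi1", "co_oi2", 1)
  set("co_oi2", core_oi[1], 1)
  for (k in seq_len(ncore)) {
    if (k < helix_min_len) {
      set(core_oi[k], core_oi[k + 1], 1)
    } else if (k < ncore) {
      set(core_oi[k], core_oi[k + 1], p_cont)
      set(core_oi[k], "ci_oi1", 1 - p_cont)
    } else {
      set(core_oi[k], "ci_oi1", 1)
    }
  }
  set("ci_oi1", "ci_oi2", 1)
  set("ci_oi2", "in", 1)

  emis <- matrix(0, n, 20, dimnames = list(states, AA20))
  for (s in states) {
    emis[s, ] <- switch(
      labels[[s]],
      inside = inside_em,
      outside = outside_em,
      membrane = if (grepl("^h", s)) helix_em else cap_em
    )
  }

  init <- setNames(rep(0, n), states)
  init["in"] <- p_init_in
  init["out"] <- 1 - p_init_in

  final <- as.numeric(labels != "membrane")
  topology_model(states, unname(labels), init, trans, emis,
                 helix_min_len, helix_max_len, final = final)
}

#' Re-estimate emissions from labelled residues
#'
#' Supervised re-estimation: pools residue counts per topology label
#' (`inside`/`membrane`/`outside`) across the training set, applies add-one
#' smoothing, and assigns the resulting distribution to every state carrying
#' that label. Transitions are unchanged. Labels absent from the training
#' data keep a smoothed (uniform-leaning) distribution.
#'
#' @param model A `topology_model`.
#' @param labelled Tibble with columns `sequence` (character) and `labels`
#'   (list of per-residue character vectors over the label alphabet).
#' @return A new `topology_model` passing all invariants.
#' @export
train_emissions <- function(model, labelled) {
  stopifnot(is.data.frame(labelled),
            all(c("sequence", "labels") %in% names(labelled)),
            nrow(labelled) >= 1L)
  alphabet <- unique(unname(model$labels))
  counts <- matrix(0, length(alphabet), 20,
                   dimnames = list(alphabet, AA20))
  for (i in seq_len(nrow(labelled))) {
    chars <- seq_chars(labelled$sequence[[i]])
    labs <- labelled$labels[[i]]
    if (length(labs) != length(chars)) {
      abort("Per-residue labels must match sequence length.")
    }
    bad <- setdiff(unique(labs), alphabet)
    if (length(bad)) {
      abort(sprintf("Label(s) not in model alphabet: %s",
                    paste(bad, collapse = ", ")))
    }
    keep <- chars %in% AA20  # ambiguity codes carry no emission information
    tab <- table(factor(labs[keep], levels = alphabet),
                 factor(chars[keep], levels = AA20))
    counts <- counts + as.matrix(tab)
  }
  probs <- (counts + 1) / (rowSums(counts) + 20)
  emis <- model$emis
  for (s in model$states) emis[s, ] <- probs[model$labels[[s]], ]
  topology_model(model$states, unname(model$labels), model$init,
                 model$trans, emis, model$helix_min_len,
                 model$helix_max_len, final = model$final)
}

#' @export
print.topology_model <- function(x, ...) {
  cat(sprintf(
    "<topology_model> %d states (%d inside, %d membrane, %d outside), helix core %d-%d\n",
    length(x$states), sum(x$labels == "inside"), sum(x$labels == "membrane"),
    sum(x$labels == "outside"), x$helix_min_len, x$helix_max_len))
  invisible(x)
}

#' Tidy a topology model's emissions
#'
#' @param x A `topology_model`.
#' @param ... Unused.
#' @return Tibble with one row per state/residue emission probability.
#' @export
tidy.topology_model <- function(x, ...) {
  tibble::tibble(
    state = rep(x$states, each = 20L),
    label = rep(unname(x$labels), each = 20L),
    residue = rep(AA20, times = length(x$states)),
    probability = as.vector(t(x$emis))
  )
}

#' One-row summary of a topology model
#'
#' @param x A `topology_model`.
#' @param ... Unused.
#' @export
glance.topology_model <- function(x, ...) {
  tibble::tibble(
    n_states = length(x$states),
    n_membrane_states = sum(x$labels == "membrane"),
    helix_min_len = x$helix_min_len,
    helix_max_len = x$helix_max_len,
    p_init_inside = sum(x$init[x$labels == "inside"])
  )
}
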