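# Toy models and brute-force oracles, independent of the package's
# forward/backward/Viterbi implementations.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Peaked but full-support emission row.
peaked_em <- function(peaks, w = 10) {
  v <- rep(1, 20)
  v[match(peaks, AA)] <- w
  v / sum(v)
}

# Two states (inside, membrane): minimal model for closed-form checks.
toy2_model <- function() {
  topology_model(
    states = c("a", "b"),
    labels = c("inside", "membrane"),
    init = c(0.7, 0.3),
    trans = matrix(c(0.8, 0.2,
                     0.4, 0.6), 2, byrow = TRUE),
    emis = rbind(peaked_em("K"), peaked_em("L")),
    helix_min_len = 5, helix_max_len = 5
  )
}

# Three states, one per label; grammar-respecting (no inside<->outside).
toy3_model <- function() {
  topology_model(
    states = c("i", "m", "o"),
    labels = c("inside", "membrane", "outside"),
    init = c(0.55, 0.25, 0.2),
    trans = matrix(c(0.6, 0.4, 0.0,
                     0.3, 0.4, 0.3,
                     0.0, 0.45, 0.55), 3, byrow = TRUE),
    emis = rbind(peaked_em(c("K", "R")), peaked_em(c("L", "I", "V")),
                 peaked_em(c("D", "E"))),
    helix_min_len = 5, helix_max_len = 5
  )
}

# All-outside degenerate model.
toy_all_outside <- function() {
  topology_model(
    states = c("o1", "o2"),
    labels = c("outside", "outside"),
    init = c(0.5, 0.5),
    trans = matrix(c(0.5, 0.5,
                     0.5, 0.5), 2, byrow = TRUE),
    emis = rbind(peaked_em("A"), peaked_em("G")),
    helix_min_len = 5, helix_max_len = 5
  )
}

# Random grammar-respecting model with n states.
random_toy_model <- function(n_states = 4) {
  labels <- c("inside", "membrane", "outside",
              sample(c("inside", "membrane", "outside"),
                     max(0, n_states - 3), replace = TRUE))[seq_len(n_states)]
  trans <- matrix(runif(n_states^2, 0.05, 1), n_states)
  ins <- labels == "inside"
  outs <- labels == "outside"
  trans[ins, outs] <- 0
  trans[outs, ins] <- 0
  trans <- trans / rowSums(trans)
  emis <- matrix(runif(n_states * 20, 0.2, 1), n_states)
  emis <- emis / rowSums(emis)
  init <- runif(n_states, 0.1, 1)
  topology_model(sprintf("s%d", seq_len(n_states)), labels,
                 init / sum(init), trans, emis,
                 helix_min_len = 5, helix_max_len = 5)
}

random_aa_seq <- function(len) paste(sample(AA, len, replace = TRUE),
                                     collapse = "")

# Brute force: joint probability of every state path for a sequence.
enum_joint <- function(model, sequence) {
  chars <- strsplit(sequence, "")[[1]]
  idx <- match(chars, AA)
  n <- length(model$states)
  L <- length(chars)
  P <- as.matrix(expand.grid(rep(list(seq_len(n)), L)))
  em <- function(state_col, t) {
    if (is.na(idx[t])) rep(1 / 20, length(state_col))
    else model$emis[cbind(state_col, idx[t])]
  }
  probs <- model$init[P[, 1]] * em(P[, 1], 1)
  if (L > 1) {
    for (t in 2:L) {
      probs <- probs * model$trans[cbind(P[, t - 1], P[, t])] * em(P[, t], t)
    }
  }
  probs <- probs * model$final[P[, L]]
  list(paths = P, probs = unname(probs))
}

enum_loglik <- function(model, sequence) log(sum(enum_joint(model, sequence)$probs))

enum_posterior <- function(model, sequence) {
  ej <- enum_joint(model, sequence)
  L <- ncol(ej$paths)
  lab <- unname(model$labels)
  tot <- sum(ej$probs)
  t(vapply(seq_len(L), function(t) {
    path_lab <- lab[ej$paths[, t]]
    c(p_in = sum(ej$probs[path_lab == "inside"]),
      p_mem = sum(ej$probs[path_lab == "membrane"]),
      p_out = sum(ej$probs[path_lab == "outside"])) / tot
  }, numeric(3)))
}

enum_viterbi_labels <- function(model, sequence) {
  ej <- enum_joint(model, sequence)
  best <- which.max(ej$probs)
  unname(model$labels[ej$paths[best, ]])
}

# Sample (sequence, per-residue labels) from a model, for supervised
# re-estimation tests.
sample_hmm <- function(model, len) {
  n <- length(model$states)
  states <- integer(len)
  states[1] <- sample.int(n, 1, prob = model$init)
  for (t in seq_len(len)[-1]) {
    states[t] <- sample.int(n, 1, prob = model$trans[states[t - 1], ])
  }
  chars <- vapply(states, function(s) sample(AA, 1, prob = model$emis[s, ]),
                  character(1))
  list(sequence = paste(chars, collapse = ""),
       labels = unname(model$labels[states]))
}
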