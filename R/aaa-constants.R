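# Shared constants and small helpers.

# Canonical residue order used for all emission tables.
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Ambiguity codes retained on input; they emit the background average (1/20).
AA_EXTRA <- c("X", "B", "Z", "U")
AA_ALPHABET <- c(AA20, AA_EXTRA)

# Kyte-Doolittle hydropathy.
KD_SCALE <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

# Residue sets used by the signal detectors.
HYDROPHOBIC_SET <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")
SMALL_SET <- c("A", "G", "S", "T", "V")

# Approximate average bacterial cytoplasmic amino-acid composition
# (normalised at load); fixed so synthetic data never needs external input.
BACKGROUND_FREQ <- local({
  f <- c(
    A = 0.089, C = 0.012, D = 0.054, E = 0.060, F = 0.037, G = 0.074,
    H = 0.022, I = 0.059, K = 0.058, L = 0.099, M = 0.024, N = 0.040,
    P = 0.044, Q = 0.039, R = 0.055, S = 0.058, T = 0.054, V = 0.072,
    W = 0.012, Y = 0.029
  )
  f[AA20] / sum(f)
})

SCL_CLASSES <- c(
  "@Intracellular",
  "@Multi-transmembrane",
  "@N-terminally anchored (no CS)",
  "@C-terminally anchored (with CS)",
  "@Lipid-anchored",
  "@Multi-transmembrane (lipid-modified N-termini)",
  "@LPXTG cell-wall anchored",
  "@Secretory (released) (with CS)"
)

PATHWAYS <- c(
  "Sec-(SPI)", "Sec-(SPII)", "Possibly Tat/Sec-(SPII)", "Tat-(SPI)",
  "No pathway"
)

NO_CLEAVAGE <- "No cleavage site"

clamp01 <- function(x) pmin(1, pmax(0, x))

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

kd_values <- function(chars) {
  v <- KD_SCALE[chars]
  v[is.na(v)] <- 0  # ambiguity codes count as neutral
  unname(v)
}

# Maximal runs of residues in `set`; returns tibble(start, end, len).
residue_runs <- function(chars, set) {
  inset <- chars %in% set
  r <- rle(inset)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep],
                 len = r$lengths[keep])
}

# Log lines go to stderr with a level tag; quiet by default in tests.
as_log <- function(level, msg) {
  message(sprintf("[%s] %s", level, msg))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}
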