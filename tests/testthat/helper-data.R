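# Builders for synthetic annotation and summary rows used by classifier
# and rubric tests (bypassing the decoding pipeline).

make_ann <- function(spi = FALSE, spi_pos = NA_integer_, spi_conf = 0,
                     spii = FALSE, cys_pos = NA_integer_, spii_conf = 0,
                     tat = FALSE, rr_pos = NA_integer_,
                     lpxtg = FALSE, lpxtg_start = NA_integer_,
                     cleavage_window = "No cleavage site") {
  selected <- if (spii) "spii" else if (spi) "spi" else "none"
  cleavage_pos <- if (spii) cys_pos - 1L else if (spi) spi_pos else NA_integer_
  tibble::tibble(spi = spi, spi_pos = spi_pos, spi_conf = spi_conf,
                 spii = spii, cys_pos = cys_pos, spii_conf = spii_conf,
                 tat = tat, rr_pos = rr_pos,
                 lpxtg = lpxtg, lpxtg_start = lpxtg_start,
                 selected = selected, cleavage_pos = cleavage_pos,
                 cleavage_window = cleavage_window)
}

# Summary with given helix segments over a protein of length `len`.
make_summ <- function(len = 200L, helices = NULL, prob_n_in = 0.9,
                      out_first_w = 0.1, out_last_w = 0.9,
                      out_first_mature_w = NULL, helix_mem = 0.95) {
  helices <- helices %||% tibble::tibble(start = integer(), end = integer())
  segs <- tibble::tibble(label = character(), start = integer(),
                         end = integer())
  pos <- 1L
  if (nrow(helices)) {
    for (k in seq_len(nrow(helices))) {
      if (helices$start[k] > pos) {
        segs <- rbind(segs, tibble::tibble(label = "inside", start = pos,
                                           end = helices$start[k] - 1L))
      }
      segs <- rbind(segs, tibble::tibble(label = "membrane",
                                         start = helices$start[k],
                                         end = helices$end[k]))
      pos <- helices$end[k] + 1L
    }
  }
  if (pos <= len) {
    segs <- rbind(segs, tibble::tibble(label = "outside", start = pos,
                                       end = len))
  }
  nterm <- helices[helices$start <= 40L, , drop = FALSE]
  tibble::tibble(
    len = len, n_helices = nrow(helices), prob_n_in = prob_n_in,
    out_first_w = out_first_w, out_last_w = out_last_w,
    out_first_mature_w = out_first_mature_w %||% out_last_w,
    window = 20L, mature_start = 1L,
    nterm_helix_start = if (nrow(nterm)) nterm$start[1] else NA_integer_,
    nterm_helix_end = if (nrow(nterm)) nterm$end[1] else NA_integer_,
    nterm_helix_mem = if (nrow(nterm)) helix_mem else 0,
    segments = list(segs)
  )
}

`%||%` <- rlang::`%||%`

# Random prediction/summary pair for property tests.
random_case <- function() {
  classes <- c("@Intracellular", "@Multi-transmembrane",
               "@N-terminally anchored (no CS)",
               "@C-terminally anchored (with CS)", "@Lipid-anchored",
               "@Multi-transmembrane (lipid-modified N-termini)",
               "@LPXTG cell-wall anchored", "@Secretory (released) (with CS)")
  len <- sample(160:800, 1)
  nh <- sample(0:3, 1)
  helices <- if (nh > 0) {
    starts <- sort(sample(seq(5, len - 30, by = 25), nh))
    tibble::tibble(start = starts, end = starts + 19L)
  } else NULL
  pred <- tibble::tibble(
    scl_class = sample(classes, 1),
    intracellular_possibility = runif(1, -1, 1),
    signal_possibility = runif(1, -1, 1),
    n_anchored_possibility = sample(-2:7, 1)
  )
  summ <- make_summ(len = len, helices = helices,
                    prob_n_in = runif(1), out_first_w = runif(1),
                    out_last_w = runif(1),
                    out_first_mature_w = runif(1))
  list(pred = pred, summ = summ, len = len)
}
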