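# anchorscreen

Genome-scale screening of candidate **surface-display anchor proteins** in
Gram-positive bacteria, modelled on the screen that identified new anchors
in *Corynebacterium glutamicum*.

Surface display fuses a passenger protein (EGFP, mCherry, an enzyme) to an
endogenous anchor protein that rivets it to the cell envelope. Good anchors
are rare: they need an export signal or transmembrane anchor, an admissible
subcellular localization (SCL), and a free, extracytoplasmic terminus for
the passenger. `anchorscreen` turns those requirements into a reproducible
per-protein pipeline:

1. **Topology** — a compact cyclic hidden Markov model over
   inside/membrane/outside labels (positive-inside emissions, 15–25-residue
   helix grammar, forward–backward posteriors and Viterbi segments) yields
   the N-in probability *P(N-in)*, terminal-window outside probabilities,
   and the helix count.
2. **Export signals** — deterministic detectors for Sec/SPI signal
   peptides (tripartite n/h/c scan, A-X-A cleavage site), SPII lipoboxes
   (`[LVIF][ASTVIG][GAS]C`), twin-arginine (Tat) motifs
   (`[ST]RRx[FGAVML][LITMVF]`), and C-terminal LPXTG sortase anchors.
3. **SCL classification** — a total decision tree assigns one of seven
   classes (intracellular, multi-transmembrane ± lipid-modified,
   N-/C-terminally anchored, lipid-anchored, LPXTG cell-wall anchored,
   secretory) plus a pathway label (Sec-(SPI), Sec-(SPII), Possibly
   Tat/Sec-(SPII), Tat-(SPI), No pathway) and three possibility scores:
   intracellular and signal possibilities in [−1, 1] (threshold 0.5) and an
   N-anchored possibility in [−2, 7] (threshold 0).
4. **Screening rubric** — hard rules (length < 600 AA; admissible class;
   intracellular possibility ≤ 0.5; displayed-terminus window outside
   probability > 0.5 with the anchoring terminus < 0.5; *P(N-in)* > 0.8
   where required), soft ranking criteria, and N/C anchoring-site
   assignment, written to a fixed-layout TSV.

A synthetic-proteome generator plants signal peptides, lipoboxes, Tat
motifs, TM helices and LPXTG tails with per-residue ground truth, so the
entire pipeline is testable offline. Embedded reference tables carry the
published feature rows of the five known *C. glutamicum* anchors and the 25
screened candidates.

## Worked example

```r
library(anchorscreen)

sim <- generate_proteome(60, seed = 1)   # 60 proteins, labelled ground truth
res <- screen_proteome(sim$proteins)     # topology -> signals -> class -> rubric
glance(res)
#> # A tibble: 1 x 6
#>   n_proteins n_pass n_fail n_site_n n_site_c top_rank_score
#> 1         60     26     34       24        2           1.58
```

26 of 60 proteins pass the rubric; 24 anchor at the N-terminus and 2 at the
C-terminus. The top candidates:

```r
dplyr::select(tidy(res)[res$pass, ], protein_id, scl_class,
              cleavage_window, anchored_site, rank_score) |> head(5)
#>   protein_id scl_class                                        cleavage_window anchored_site rank_score
#> 1 syn0007    @C-terminally anchored (with CS)                 IANATLMA        C site             1.58
#> 2 syn0021    @C-terminally anchored (with CS)                 ITQALLGG        C site             1.56
#> 3 syn0018    @Multi-transmembrane (lipid-modified N-termini)  MILSSCD         N site             1.50
#> 4 syn0036    @Lipid-anchored                                  IIVGACT         N site             1.43
#> 5 syn0029    @Secretory (released) (with CS)                  LAEALDID        N site             1.41
```

Each row reads like one line of a candidate-anchor table: the SCL class,
the predicted cleavage window (an 8-mer around SPI sites, a 7-mer ending
one residue past the lipobox cysteine, or `No cleavage site`), the
anchoring terminus — the passenger is fused at the opposite terminus — and
the rank score `signal + tanh(n_anchored/7) + display-window p_out`.
`write_candidate_table(res, "candidates.tsv")` writes the full table with a
fixed column order; `autoplot(res)` plots the ranked candidates and
`autoplot(posterior_decode(default_topology_model(), seq))` the per-residue
topology posteriors.

On a 200-protein synthetic proteome (seed 1) the screen recovers planted
anchor-class proteins with sensitivity 0.96 and specificity 1.00.

A thin CLI wraps the same functions
(`Rscript inst/cli/anchorscreen.R screen proteome.fasta --out candidates.tsv`,
plus `topology`, `signals`, `classify` and `simulate` subcommands).

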