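# Embedded reference tables: the five known endogenous anchor proteins of
# C. glutamicum and the 25 screened candidate anchors, with their printed
# prediction fields. Field values are transcribed verbatim (including the
# occasional capitalisation quirks of the printed cleavage-site sentinels).

table1_rows <- function() {
  tibble::tribble(
    ~anchor_protein, ~protein_id, ~product, ~pathway, ~cellular_destination,
    ~scl_class, ~intracellular_possibility, ~signal_possibility,
    ~n_anchored_possibility, ~cleavage_site,
    "NCgl1337", "WP_003858702.1", "SGNH/GDSL hydrolase family protein",
    "Sec-(SPI)", "Extracellular", "@Secretory (released) (with CS)",
    0.17, 1, -2, "PATAQSSG",
    "NCgl1221", "WP_011014245.1", "Mechanosensitive ion channel",
    "Sec-(SPI)", "Membrane", "@Multi-transmembrane",
    0.17, -1, 1, "No cleavage site",
    "NCgl0933", "WP_003856752.1", "PorB",
    "Sec-(SPI)", "Extracellular", "@Secretory (released) (with CS)",
    -0.17, 1, -1, "FAAPASAS",
    "NCgl0932", "WP_003856749.1", "PorC",
    "Sec-(SPI)", "Extracellular", "@Secretory (released) (with CS)",
    -0.17, 1, -1, "PSASAQDF",
    "PorH", "WP_011265995.1", "PorH",
    "No pathway", "Cytoplasmic", "@Intracellular",
    1, -1, -1, "No cleavage Site"
  )
}

table3_rows <- function() {
  tibble::tribble(
    ~rank, ~protein_id, ~product, ~locus_tag, ~pathway,
    ~cellular_destination, ~scl_class, ~intracellular_possibility,
    ~signal_possibility, ~n_anchored_possibility, ~cleavage_site,
    ~anchored_site,
    1L, "WP_011013799.1", "hypothetical protein", "NCgl0550",
    "Sec-(SPI)", "Membrane", "@C-terminally anchored (with CS)",
    0, 1, -2, "PTASAATL", "C site",
    2L, "WP_011013739.1",
    "type VII secretion-associated serine protease mycosin", "NCgl0633",
    "Sec-(SPI)", "Membrane", "@C-terminally anchored (with CS)",
    0, 1, -2, "TRAQEVEA", "C site",
    3L, "WP_011014951.1", "cytochrome c oxidase subunit II", "NCgl2115",
    "Sec-(SPII)", "Membrane",
    "@Multi-transmembrane (lipid-modified N-termini)",
    0, 1, 1, "LAMAGCE", "N site",
    4L, "WP_011265759.1",
    "gi| 62390400| ref| YP_225802.1| hypothetical protein cg1712",
    "NCgl1460", "Sec-(SPII)", "Extracellular", "@Lipid-anchored",
    0.17, 1, 1, "LLLSACT", "N site",
    5L, "WP_011014306.1", "hypothetical protein", "NCgl1307",
    "Sec-(SPII)", "Extracellular", "@Lipid-anchored",
    -0.33, 1, 1, "FVLSGCG", "N site",
    6L, "WP_011014779.1",
    "glutamate ABC transporter substrate-binding protein", "NCgl1876",
    "Sec-(SPII)", "Extracellular", "@Lipid-anchored",
    -0.33, 1, 1, "VTLTACG", "N site",
    7L, "WP_011265985.1",
    "twin-arginine translocation signal domain-containing protein",
    "NCgl2562", "Possibly Tat/Sec-(SPII)", "Extracellular",
    "@Lipid-anchored", -0.33, 1, 1, "ATLAACA", "N site",
    8L, "WP_011013364.1", "sensor histidine kinase", "NCgl0067",
    "Sec-(SPI)", "Membrane", "@Multi-transmembrane",
    0.17, -1, 2, "No Cleavage Site", "N site",
    9L, "WP_004567665.1", "MULTISPECIES: DUF4233 domain-containing protein",
    "NCgl2291", "Sec-(SPI)", "Membrane", "@Multi-transmembrane",
    0.17, -1, 1, "No cleavage site", "C site",
    10L, "WP_01101483.1", "family transporter", "NCgl1147",
    "Sec-(SPI)", "Membrane", "@Multi-transmembrane",
    0.17, -1, 1, "No cleavage site", "N site",
    11L, "WP_011014865.1", "ABC transporter ATP-binding protein", "NCgl1998",
    "Sec-(SPI)", "Membrane", "@Multi-transmembrane",
    0.17, -0.5, 1, "No cleavage site", "N site",
    12L, "WP_003859459.1", "MULTISPECIES: HlyC/CorC family transporter",
    "NCgl2206", "Sec-(SPI)", "Membrane", "@Multi-transmembrane",
    0.17, 0, 0, "No cleavage site", "N site",
    13L, "WP_003863539.1", "MULTISPECIES: potassium channel family protein",
    "NCgl0743", "Sec-(SPI)", "Membrane", "@Multi-transmembrane",
    0.17, -1, -1, "No cleavage site", "N site",
    14L, "WP_011013342.1", "penicillin-binding protein 2", "NCgl0042",
    "Sec-(SPI)", "Membrane", "@N-terminally anchored (no CS)",
    0.17, 1, 7, "No cleavage site", "N site",
    15L, "WP_011013540.1", "TlpA family protein disulfide reductase",
    "NCgl0289", "Sec-(SPI)", "Membrane", "@N-terminally anchored (no CS)",
    0.17, 1, 7, "No cleavage site", "N site",
    16L, "WP_011014270.1", "SRPBCC family protein", "NCgl1250",
    "Sec-(SPI)", "Membrane", "@N-terminally anchored (no CS)",
    0.17, 1, 7, "No cleavage site", "N site",
    17L, "WP_011015453.1", "cutinase family protein", "NCgl2775",
    "Sec-(SPI)", "Membrane", "@N-terminally anchored (no CS)",
    0.17, 1, 7, "No cleavage site", "N site",
    18L, "WP_003853779.1", "MULTISPECIES: DUF4247 domain-containing protein",
    "NCgl2610", "Sec-(SPI)", "Membrane", "@N-terminally anchored (no CS)",
    0.17, 1, 5, "No cleavage site", "N site",
    19L, "WP_011013420.1", "hypothetical protein", "NCgl0136",
    "Sec-(SPI)", "Extracellular", "@Secretory (released) (with CS)",
    0.17, 1, -1, "IAATPATA", "N site",
    20L, "WP_011013818.1", "CAP domain-containing protein", "NCgl0661",
    "Sec-(SPI)", "Extracellular", "@Secretory (released) (with CS)",
    0.17, 1, -1, "PSAHAFTA", "N site",
    21L, "WP_011013866.1", "hypothetical protein", "NCgl0717",
    "Sec-(SPI)", "Extracellular", "@Secretory (released) (with CS)",
    0.17, 1, -1, "DIATSTTT", "N site",
    22L, "WP_011014348.1", "copper transporter", "NCgl1361",
    "Sec-(SPI)", "Extracellular", "@Secretory (released) (with CS)",
    0.17, 1, -1, "GIAFGTYV", "N site",
    23L, "WP_011014599.1",
    "LysM peptidoglycan-binding domain-containing protein", "NCgl1682",
    "Sec-(SPI)", "Extracellular", "@Secretory (released) (with CS)",
    0.17, 1, -1, "GGSGVTFL", "N site",
    24L, "WP_042383306.1", "hypothetical protein", "NCgl2577",
    "Sec-(SPI)", "Extracellular", "@Secretory (released) (with CS)",
    0.17, 1, -1, "VVALRGGS", "N site",
    25L, "WP_003858490.1", "resuscitation-promoting factor", "NCgl0872",
    "Sec-(SPI)", "Extracellular", "@Secretory (released) (with CS)",
    0.17, 1, -2, "VTAAATKK", "N site"
  )
}

#' Embedded reference anchor tables
#'
#' Returns the prediction feature rows of the five known endogenous anchor
#' proteins of *C. glutamicum* (`table1`, 5 rows) and of the 25 screened
#' candidate anchors (`table3`, 25 rows): pathway, cellular destination,
#' SCL class, the three possibility scores, the cleavage-site window, and
#' (for the candidates) the anchoring site. No network or file access.
#'
#' @return List with tibbles `table1` and `table3`.
#' @examples
#' fx <- table_fixtures()
#' fx$table3[fx$table3$locus_tag == "NCgl1307", ]
#' @export
table_fixtures <- function() {
  list(table1 = table1_rows(), table3 = table3_rows())
}
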