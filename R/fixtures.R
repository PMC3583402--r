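#' Packaged genome geometries and experiment tables
#'
#' `mt_fixture()` returns one of the geometries the package ships with:
#'
#' * `"human"` — the 16,569-nt human mitochondrial genome (rCRS,
#'   NC_012920.1) with the standard gene annotation, the three promoters
#'   (HSP1 at 561, HSP2 at 646, LSP at 407) and the mTERF site at
#'   3230..3257 (1-based; immediately downstream of the 16S rRNA gene,
#'   inside tRNA-Leu, containing the MELAS position 3243). Passage
#'   probabilities default to the fitted values at 500 nt/s
#'   (p = 0.0164, q = 0.0056).
#' * `"rat"` — promoters of the rat mitochondrial genome (NC_001665.2):
#'   HSP1 at 16298, HSP2 at 66, LSP at 16193. Gene coordinates are not
#'   bundled; load them from GenBank/GFF3 annotation and merge with
#'   `merge_geometry()`.
#' * `"frog"` — the five promoters of the frog mitochondrial genome
#'   (NC_001573.1): HSP1 at 2102, HSP2 at 2049, LSP1 at 2103, LSP2A at
#'   2042, LSP2B at 2033. Genes as for rat.
#' * `"toy"` — a small fully synthetic 3-kb circle with two convergent
#'   promoters, four genes and one protein terminator, used throughout the
#'   tests and examples.
#'
#' The mTERF site coordinates for rat and frog are not printed in the
#' sources the package encodes and are left to the user (editable overlay).
#'
#' @param name fixture name.
#' @return an `mt_geometry`.
#' @export
mt_fixture <- function(name = c("human", "rat", "frog", "toy")) {
  name <- match.arg(name)
  switch(name,
         human = .fixture_human(),
         rat = .fixture_rat(),
         frog = .fixture_frog(),
         toy = .fixture_toy())
}

#' @rdname mt_fixture
#' @export
mt_fixture_names <- function() c("human", "rat", "frog", "toy")

# rCRS gene table (1-based inclusive); strands: H = heavy, L = light
.human_gene_table <- function() {
  tb <- c(
    "tRNA-Phe,577,647,H", "12S,648,1601,H", "tRNA-Val,1602,1670,H",
    "16S,1671,3229,H", "tRNA-Leu1,3230,3304,H", "ND1,3307,4262,H",
    "tRNA-Ile,4263,4331,H", "tRNA-Gln,4329,4400,L", "tRNA-Met,4402,4469,H",
    "ND2,4470,5511,H", "tRNA-Trp,5512,5579,H", "tRNA-Ala,5587,5655,L",
    "tRNA-Asn,5657,5729,L", "tRNA-Cys,5761,5826,L", "tRNA-Tyr,5826,5891,L",
    "COX1,5904,7445,H", "tRNA-Ser1,7446,7514,L", "tRNA-Asp,7518,7585,H",
    "COX2,7586,8269,H", "tRNA-Lys,8295,8364,H", "ATP8,8366,8572,H",
    "ATP6,8527,9207,H", "COX3,9207,9990,H", "tRNA-Gly,9991,10058,H",
    "ND3,10059,10404,H", "tRNA-Arg,10405,10469,H", "ND4L,10470,10766,H",
    "ND4,10760,12137,H", "tRNA-His,12138,12206,H", "tRNA-Ser2,12207,12265,H",
    "tRNA-Leu2,12266,12336,H", "ND5,12337,14148,H", "ND6,14149,14673,L",
    "tRNA-Glu,14674,14742,L", "CYTB,14747,15887,H", "tRNA-Thr,15888,15953,H",
    "tRNA-Pro,15956,16023,L")
  m <- do.call(rbind, strsplit(tb, ",", fixed = TRUE))
  data.frame(name = m[, 1], start = as.numeric(m[, 2]) - 1,
             end = as.numeric(m[, 3]), strand = m[, 4],
             stringsAsFactors = FALSE)
}

.fixture_human <- function() {
  mt_geometry(
    16569,
    genes = .human_gene_table(),
    promoters = data.frame(name = c("HSP1", "HSP2", "LSP"),
                           tss = c(561, 646, 407) - 1,
                           strand = c("heavy", "heavy", "light"),
                           stringsAsFactors = FALSE),
    factor_sites = data.frame(name = "mTERF", start = 3230 - 1, end = 3257,
                              pass_prob_heavy = 0.0164,
                              pass_prob_light = 0.0056,
                              binding_intensity = 0.6456,
                              stringsAsFactors = FALSE),
    name = "human_mtDNA")
}

.fixture_rat <- function() {
  mt_geometry(
    16313,
    promoters = data.frame(name = c("HSP1", "HSP2", "LSP"),
                           tss = c(16298, 66, 16193) - 1,
                           strand = c("heavy", "heavy", "light"),
                           stringsAsFactors = FALSE),
    name = "rat_mtDNA")
}

.fixture_frog <- function() {
  mt_geometry(
    17553,
    promoters = data.frame(
      name = c("HSP1", "HSP2", "LSP1", "LSP2A", "LSP2B"),
      tss = c(2102, 2049, 2103, 2042, 2033) - 1,
      strand = c("heavy", "heavy", "light", "light", "light"),
      stringsAsFactors = FALSE),
    name = "frog_mtDNA")
}

.fixture_toy <- function() {
  make_toy_genome(
    3000,
    promoter_specs = list(
      list(name = "PH", tss = 101, strand = "heavy"),
      list(name = "PL", tss = 2901, strand = "light")),
    gene_specs = list(
      list(name = "gH1", start = 201, end = 700, strand = "heavy"),
      list(name = "gH2", start = 901, end = 1400, strand = "heavy"),
      list(name = "gL1", start = 2301, end = 2800, strand = "light"),
      list(name = "gL2", start = 301, end = 600, strand = "light")),
    factor_specs = list(
      list(name = "TERM", start = 801, p = 0.3, q = 0.05, lambda = 0.5)),
    name = "toy")
}

#' Fitted model solutions reported for the study systems
#'
#' Parameter sets (binding-attempt intensities in attempts/s, passage
#' probabilities p and q) obtained by solving the inverse problem on the
#' full genomes, usable as forward-simulation inputs:
#'
#' * `"human_healthy"`, `"human_melas"` — LSP/HSP1/HSP2/mTERF intensities
#'   with shared p = 0.0164, q = 0.0056 (500 nt/s).
#' * `"rat_euthyroid"`, `"rat_hypothyroid"` — LSP/HSP/mTERF intensities
#'   (HSP is the pooled HSP1 + HSP2 intensity).
#' * `"passage_500"`, `"passage_200"` — the terminator passage
#'   probabilities fitted at elongation rates 500 and 200 nt/s.
#'
#' @param which solution name.
#' @return a named list with elements `promoter_intensities`,
#'   `factor_intensities`, `p`, `q`, `elongation_rate`.
#' @export
fitted_solution <- function(which = c("human_healthy", "human_melas",
                                      "rat_euthyroid", "rat_hypothyroid",
                                      "passage_500", "passage_200")) {
  which <- match.arg(which)
  sol <- switch(which,
    human_healthy = list(
      promoter_intensities = c(LSP = 0.0031, HSP1 = 0.0031, HSP2 = 0.0126),
      factor_intensities = c(mTERF = 0.6456)),
    human_melas = list(
      promoter_intensities = c(LSP = 0.0031, HSP1 = 0.0004, HSP2 = 0.0126),
      factor_intensities = c(mTERF = 0.5336)),
    rat_euthyroid = list(
      promoter_intensities = c(LSP = 0.1056, HSP = 0.0721),
      factor_intensities = c(mTERF = 0.9453)),
    rat_hypothyroid = list(
      promoter_intensities = c(LSP = 0.1056, HSP = 0.0336),
      factor_intensities = c(mTERF = 0.9453)),
    passage_500 = list(promoter_intensities = NULL,
                       factor_intensities = NULL),
    passage_200 = list(promoter_intensities = NULL,
                       factor_intensities = NULL))
  pq <- if (which == "passage_200") c(p = 0.2165, q = 0.0015) else
    c(p = 0.0164, q = 0.0056)
  rate <- if (which == "passage_200") 200 else 500
  c(sol, list(p = unname(pq["p"]), q = unname(pq["q"]),
              elongation_rate = rate))
}

#' Experimental mitochondrial transcript data in rat
#'
#' Normalized mRNA/16S-rRNA ratios (percent of the euthyroid ratio for the
#' hypothyroid column) and RNA half-lives (minutes) with absolute errors,
#' for euthyroid and hypothyroid animals. The 16S row carries half-lives
#' only (it is the normalization reference).
#'
#' @return data frame with columns `gene`, `u_eu`, `du_eu`, `t_eu`,
#'   `dt_eu`, `u_hypo`, `du_hypo`, `t_hypo`, `dt_hypo`.
#' @export
rat_experiment_table <- function() {
  data.frame(
    gene   = c("16S", "COX1", "ATP6/8", "COX3", "ND4", "ND5", "CYTB"),
    u_eu   = c(NA, 100, 100, 100, 100, 100, 100),
    du_eu  = c(NA, 16, 19, 19, 16, 25, 27),
    t_eu   = c(44.48, 84.41, 78.14, 78.14, 84.41, 46.00, 63.70),
    dt_eu  = c(6.34, 27.49, 21.05, 21.05, 27.49, 10.41, 7.82),
    u_hypo = c(NA, 86, 59, 59, 86, 52, 57),
    du_hypo = c(NA, 13, 9, 9, 13, 11, 7),
    t_hypo = c(87.50, 235.12, 277.52, 277.52, 235.12, 60.52, 204.30),
    dt_hypo = c(27.52, 48.68, 31.58, 31.58, 48.68, 5.92, 28.64),
    stringsAsFactors = FALSE)
}

#' Experimental relative transcription levels in healthy human
#'
#' Stationary-state transcription levels relative to ND1 (concentration
#' times the half-life ratio to the reference) with absolute errors under
#' the independence and dependence assumptions, and the corresponding model
#' levels of the published healthy-human solution.
#'
#' @return data frame with columns `gene`, `model`, `exp`, `d_indep`,
#'   `d_dep`.
#' @export
human_experiment_table <- function() {
  data.frame(
    gene = c("ND2", "COX1", "COX2", "ATP6/8", "ND3", "ND5", "CYTB"),
    model = c(1.00, 1.00, 1.00, 0.96, 0.96, 0.96, 0.96),
    exp = c(1.40, 1.04, 1.72, 0.91, 1.04, 1.86, 2.31),
    d_indep = c(0.23, 0.52, 0.61, 0.43, 0.12, 0.56, 0.56),
    d_dep = c(0.40, 0.82, 0.95, 0.71, 0.20, 0.99, 1.01),
    stringsAsFactors = FALSE)
}

#' Published hypothyroid/euthyroid model levels in rat
#'
#' Model transcription levels of the hypothyroid rat relative to the
#' euthyroid one at the published solution, by gene.
#'
#' @return named numeric vector.
#' @export
rat_model_levels <- function() {
  c("COX1" = 0.666, "ATP6/8" = 0.641, "COX3" = 0.646, "ND4" = 0.622,
    "ND5" = 0.614, "CYTB" = 0.613)
}

#' Fitted per-time-point intensities of the frog time courses
#'
#' mTERF and LSP1 binding intensities (attempts/s) fitted per developmental
#' time point for the three frog specimens; other promoters scale from LSP1
#' by the fixed relative intensities of `frog_promoter_intensities()`.
#'
#' @return data frame with columns `specimen`, `time_h`, `mTERF`, `LSP1`.
#' @export
frog_timecourse_solutions <- function() {
  rows <- list(
    # specimen, hours, mTERF, LSP1
    c(1, 0, 0.0157, 0.0034), c(1, 5, 0.0448, 0.0089),
    c(1, 10, 0.0872, 0.0157), c(1, 14, 0.0793, 0.0173),
    c(1, 16, 0.0960, 0.0209), c(1, 18, 0.0542, 0.0157),
    c(1, 20, 0.0655, 0.0157), c(1, 23, 0.0721, 0.0492),
    c(1, 48, 0.0542, 0.0872), c(1, 96, 0.0407, 0.0960),
    c(2, 0, 0.0089, 0.0041), c(2, 6, 0.0045, 0.0023),
    c(2, 9, 0.0073, 0.0045), c(2, 20, 0.0157, 0.0157),
    c(2, 30, 0.0157, 0.0230), c(2, 48, 0.0407, 0.1056),
    c(2, 168, 0.0041, 0.0073),
    c(3, 0, 0.0960, 0.0026), c(3, 5, 0.0407, 0.0050),
    c(3, 14, 0.0230, 0.0081), c(3, 20, 0.0038, 0.0028),
    c(3, 28, 0.0336, 0.1056), c(3, 48, 0.0143, 0.0306))
  m <- do.call(rbind, rows)
  data.frame(specimen = m[, 1], time_h = m[, 2], mTERF = m[, 3],
             LSP1 = m[, 4])
}
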