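# Independent Monte-Carlo oracle for the polysome decay model: ribosome
# passages at the cleavage site form a renewal process with headway
# d + Exp(lambda); the ribonuclease window is open for the part of each
# gap exceeding w, and cleavage accumulates exposure at rate mu until an
# Exp(mu) threshold is crossed. Returns the mean decay time over n
# replicates; the model's half-life is ln(2) times the long-run mean.
# The closed form is the stationary-hazard limit: it matches this
# renewal process only when cleavage is much slower than ribosome
# traffic (relative bias ~ mu/(lambda+mu)), which is the regime the
# model describes; oracle parameter sets must respect it.
polysome_mc_mean_decay_time <- function(lambda, mu, w, d, n = 1e4) {
  times <- vapply(seq_len(n), function(i) {
    need <- stats::rexp(1, mu)   # open-time exposure needed for cleavage
    t_total <- 0
    repeat {
      gap <- stats::rexp(1, lambda)
      open <- max(0, gap - w)
      if (open >= need) {
        # cleavage happens 'need' seconds into the open part of this gap
        return(t_total + d + (gap - open) + need)
      }
      need <- need - open
      t_total <- t_total + d + gap
    }
  }, 0)
  mean(times)
}

# toy circle large enough that no polymerase returns to its start within
# the horizon, making per-gene transcript counts a thinned Poisson count
long_circle_toy <- function(lambda = 0.01, gene = TRUE) {
  make_toy_genome(
    2e7,
    promoter_specs = list(list(name = "P", tss = 1001, strand = "heavy")),
    gene_specs = if (gene)
      list(list(name = "G", start = 1101, end = 1600, strand = "heavy")),
    name = "long_circle")
}

# small two-strand genome with one protein terminator, used by the engine
# comparison and recovery tests (identical to the packaged "toy" fixture
# but parameterized)
two_strand_toy <- function(p = 0.3, q = 0.05, lambda_term = 0.5) {
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
      list(name = "TERM", start = 801, p = p, q = q, lambda = lambda_term)))
}
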