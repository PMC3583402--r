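#' Relative time-course concentration
#'
#' Ratio of a gene's transcription level at a time point to its level at
#' the null time point; half-lives cancel, so the RNA-concentration ratio
#' equals the transcription-level ratio.
#'
#' @param z level at the time point.
#' @param z0 level at the null time point (> 0).
#' @return `z / z0`.
#' @export
relative_timecourse <- function(z, z0) {
  if (any(z0 <= 0)) stop("reference level must be positive")
  z / z0
}

#' Stationary-state expected level relative to a reference gene
#'
#' Converts a measured relative RNA concentration `u_j` (gene j over
#' reference) into the transcription-level ratio using the half-lives:
#' `u_j * t0 / t_j`.
#'
#' @param u_j relative RNA concentration.
#' @param t0 reference-gene half-life (> 0).
#' @param t_j gene half-life (> 0).
#' @return transcription-level ratio.
#' @export
steady_state_expected <- function(u_j, t0, t_j) {
  if (any(t0 <= 0) || any(t_j <= 0)) stop("half-lives must be positive")
  u_j * t0 / t_j
}

#' Hypothyroid/euthyroid transcription-level ratio
#'
#' The measured hypothyroid/euthyroid concentration ratio `u_j` (gene j
#' normalized to 16S, hypothyroid as a fraction of euthyroid) is converted
#' into the transcription-level ratio `z_jh * z_0e / (z_0h * z_je)` by
#' cancelling the half-lives: `u_j * (t0h * t_je) / (t_jh * t0e)`.
#'
#' @param u_j measured concentration ratio (hypothyroid / euthyroid).
#' @param t0h,t0e reference-gene (16S) half-life, hypothyroid / euthyroid.
#' @param t_je,t_jh gene half-life, euthyroid / hypothyroid.
#' @param digits decimal places for reporting; `NULL` for full precision.
#' @return transcription-level ratio, rounded to `digits`.
#' @export
hypo_eu_ratio <- function(u_j, t0h, t_je, t_jh, t0e, digits = 2) {
  if (any(c(t0h, t_je, t_jh, t0e) <= 0)) stop("half-lives must be positive")
  out <- u_j * (t0h * t_je) / (t_jh * t0e)
  if (!is.null(digits)) out <- round(out, digits) else out
}

#' Normalized L1 comparison functional
#'
#' `sum(|x - y| / pmax(x, y))` over paired relative levels. Symmetric,
#' non-negative, zero iff the vectors are equal, and bounded by the number
#' of terms.
#'
#' @param x,y positive vectors of equal length (model and experiment).
#' @return the functional value.
#' @export
l1n <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal lengths")
  if (any(x <= 0) || any(y <= 0)) stop("entries must be positive")
  sum(abs(x - y) / pmax(x, y))
}

#' Weighted combination of L1n scores over several datasets
#'
#' Each dataset k of dimension `n_k` contributes its L1n sum weighted by
#' `1 / (n_k * s)` with `s = sum(1 / n_k)`.
#'
#' @param datasets list of lists with elements `x`, `y` (paired levels) and
#'   `n` (dataset dimension); alternatively `sum` (a precomputed L1n sum)
#'   and `n`.
#' @return the combined score.
#' @export
l1n_total <- function(datasets) {
  if (!length(datasets)) stop("empty dataset list")
  n <- vapply(datasets, function(d) as.numeric(d$n), 0)
  if (any(n <= 0)) stop("dataset dimensions must be positive")
  sums <- vapply(datasets, function(d) {
    if (!is.null(d$sum)) as.numeric(d$sum) else l1n(d$x, d$y)
  }, 0)
  s <- sum(1 / n)
  sum(sums / (n * s))
}

#' Absolute-error propagation through products, ratios and sums
#'
#' For a product/ratio chain with member values `x_i` (absolute errors
#' `dx_i`) and result `value`, the propagated error is
#' `|value| * sqrt(sum((dx/x)^2))` when member errors are statistically
#' independent, and `|value| * sum(|dx/x|)` otherwise. For sums and
#' differences it is `sqrt(sum(dx^2))` / `sum(|dx|)` respectively.
#'
#' @param values member values (non-zero for `"ratio_product"`).
#' @param abs_errors absolute errors of the members (>= 0).
#' @param op `"ratio_product"` or `"sum"`.
#' @param independent logical: are member errors independent?
#' @param value result of the expression (required for `"ratio_product"`).
#' @return the propagated absolute error.
#' @export
propagate_error <- function(values, abs_errors, op = c("ratio_product", "sum"),
                            independent = TRUE, value = NULL) {
  op <- match.arg(op)
  if (length(values) != length(abs_errors))
    stop("'values' and 'abs_errors' must have equal lengths")
  if (any(abs_errors < 0)) stop("absolute errors must be >= 0")
  if (op == "sum") {
    return(if (independent) sqrt(sum(abs_errors^2)) else sum(abs(abs_errors)))
  }
  if (any(values == 0)) stop("ratio/product members must be non-zero")
  if (is.null(value)) stop("'value' (the expression result) is required")
  rel <- abs_errors / abs(values)
  abs(value) * if (independent) sqrt(sum(rel^2)) else sum(rel)
}

#' Error of the hypothyroid/euthyroid level ratio
#'
#' Propagates the printed absolute errors of the rat measurements through
#' the level-ratio expression, treating the measured concentration ratio as
#' the ratio of the two printed normalized values (each with its own
#' error).
#'
#' @param u_h,du_h hypothyroid normalized ratio and its error.
#' @param u_e,du_e euthyroid normalized ratio and its error.
#' @param t0h,dt0h,t_je,dt_je,t_jh,dt_jh,t0e,dt0e half-lives and errors.
#' @param independent independence assumption flag.
#' @param digits decimal places for reporting; `NULL` for full precision.
#' @return the propagated absolute error of the level ratio.
#' @export
hypo_eu_error <- function(u_h, du_h, u_e, du_e,
                          t0h, dt0h, t_je, dt_je, t_jh, dt_jh, t0e, dt0e,
                          independent = TRUE, digits = 2) {
  value <- (u_h / u_e) * (t0h * t_je) / (t_jh * t0e)
  err <- propagate_error(values = c(u_h, u_e, t0h, t_je, t_jh, t0e),
                         abs_errors = c(du_h, du_e, dt0h, dt_je, dt_jh, dt0e),
                         op = "ratio_product", independent = independent,
                         value = value)
  if (!is.null(digits)) round(err, digits) else err
}

#' Agreement of a model value with an experimental error interval
#'
#' Computes the multiple `c = |a - b| / delta` and whether the model value
#' lies within `b +- delta`.
#'
#' @param a model value.
#' @param b experimental value.
#' @param delta absolute error of `b` (> 0; `delta = 0` with `a != b` is
#'   reported as infinite and flagged).
#' @param digits decimal places for the reported multiple.
#' @return list with `multiple` (rounded), `within` (`c <= 1`), and
#'   `multiple_exact`.
#' @export
within_error <- function(a, b, delta, digits = 1) {
  if (delta < 0) stop("'delta' must be >= 0")
  if (delta == 0) {
    m <- if (a == b) 0 else Inf
    return(list(multiple = m, within = a == b, multiple_exact = m))
  }
  m <- abs(a - b) / delta
  list(multiple = round(m, digits), within = m <= 1, multiple_exact = m)
}

#' Percentage deviation of a model value from an experimental one
#'
#' `(a - b) * 100 / b`, reported to the nearest integer. Changes between
#' -50% (halving) and +100% (doubling) are conventionally considered
#' insignificant; the flag is returned alongside.
#'
#' @param a model value.
#' @param b experimental value (non-zero).
#' @param digits decimal places for reporting (default nearest integer).
#' @return list with `percent` (rounded), `insignificant`
#'   (-50 < deviation < 100), and `percent_exact`.
#' @export
deviation_percent <- function(a, b, digits = 0) {
  if (any(b == 0)) stop("'b' must be non-zero")
  p <- (a - b) * 100 / b
  list(percent = round(p, digits), insignificant = p > -50 & p < 100,
       percent_exact = p)
}

#' Lower bound on the phage-type polymerase elongation rate
#'
#' In systems with concurrent transcription and translation, transcription
#' of the first intron must finish before translation of the first exon
#' does, so the polymerase/ribosome rate ratio must exceed `(E + I) / E`.
#' With a ribosome rate of 15 codons/s (45 nt/s) this gives the lower
#' bound `((E + I) / E) * 45` nt/s.
#'
#' @param E first-exon length (nt, > 0), or `NULL` when `ratio` is given.
#' @param I first-intron length (nt, >= 0).
#' @param ratio the ratio `(E + I) / E` directly (overrides `E`, `I`).
#' @param ribosome_rate ribosome translation rate in nt/s (default 45).
#' @return lower bound on the elongation rate (nt/s), unrounded.
#' @export
nep_rate_lower_bound <- function(E = NULL, I = NULL, ratio = NULL,
                                 ribosome_rate = 45) {
  if (is.null(ratio)) {
    if (is.null(E) || is.null(I)) stop("give either 'ratio' or 'E' and 'I'")
    if (any(E <= 0)) stop("'E' must be positive")
    if (any(I < 0)) stop("'I' must be >= 0")
    ratio <- (E + I) / E
  }
  if (any(ratio < 1)) stop("'ratio' must be >= 1")
  ratio * ribosome_rate
}

#' Compare rat model levels to the experiment table
#'
#' Builds the full comparison report for the hypothyroid/euthyroid rat
#' levels: the experimental level ratio from the measured concentrations
#' and half-lives, its propagated error under both independence
#' assumptions, the error multiples of the model values, and the
#' percentage deviations.
#'
#' @param model_levels named vector of model hypothyroid/euthyroid level
#'   ratios per gene (defaults to the published solution's levels).
#' @param experiment the rat experiment table
#'   (default `rat_experiment_table()`).
#' @return data frame, one row per compared gene.
#' @export
rat_comparison_report <- function(model_levels = rat_model_levels(),
                                  experiment = rat_experiment_table()) {
  ref <- experiment[experiment$gene == "16S", ]
  ex <- experiment[experiment$gene != "16S", ]
  ex <- ex[ex$gene %in% names(model_levels), ]
  rows <- lapply(seq_len(nrow(ex)), function(i) {
    e <- ex[i, ]
    a <- unname(model_levels[[e$gene]])
    b <- hypo_eu_ratio(e$u_hypo / e$u_eu, ref$t_hypo, e$t_eu, e$t_hypo,
                       ref$t_eu, digits = NULL)
    err <- function(ind) hypo_eu_error(
      e$u_hypo, e$du_hypo, e$u_eu, e$du_eu,
      ref$t_hypo, ref$dt_hypo, e$t_eu, e$dt_eu, e$t_hypo, e$dt_hypo,
      ref$t_eu, ref$dt_eu, independent = ind, digits = NULL)
    di <- err(TRUE); dd <- err(FALSE)
    # agreement statistics are taken against the reported (2-decimal)
    # experimental value, with unrounded propagated errors
    b2 <- round(b, 2)
    data.frame(gene = e$gene, model = a, experiment = b2,
               d_indep = round(di, 2), d_dep = round(dd, 2),
               mult_indep = within_error(a, b2, di)$multiple,
               mult_dep = within_error(a, b2, dd)$multiple,
               deviation_pct = deviation_percent(a, b2)$percent,
               insignificant = deviation_percent(a, b2)$insignificant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare healthy-human model levels to the experiment
#'
#' Error multiples and percentage deviations of model transcription levels
#' (relative to ND1) against the experimental levels with their printed
#' absolute errors.
#'
#' @param table data frame as returned by `human_experiment_table()`.
#' @return data frame, one row per gene.
#' @export
human_comparison_report <- function(table = human_experiment_table()) {
  data.frame(
    gene = table$gene, model = table$model, experiment = table$exp,
    mult_indep = mapply(function(a, b, d) within_error(a, b, d)$multiple,
                        table$model, table$exp, table$d_indep),
    mult_dep = mapply(function(a, b, d) within_error(a, b, d)$multiple,
                      table$model, table$exp, table$d_dep),
    deviation_pct = mapply(function(a, b) deviation_percent(a, b)$percent,
                           table$model, table$exp),
    insignificant = mapply(function(a, b) deviation_percent(a, b)$insignificant,
                           table$model, table$exp),
    stringsAsFactors = FALSE)
}
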