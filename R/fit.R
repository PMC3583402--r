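#' Search configuration for the active-search fitter
#'
#' @param intensity_bounds lower/upper bounds for binding-attempt
#'   intensities (attempts/s), log-scale search.
#' @param prob_bounds lower/upper bounds for the passage probabilities p
#'   and q.
#' @param n_traj trajectories per objective evaluation (common random
#'   numbers: the same trajectory seeds are reused for every candidate).
#' @param restarts number of multi-start repetitions.
#' @param max_eval evaluation budget per restart.
#' @param step_factors decreasing sequence of multiplicative step sizes
#'   for the coordinate search.
#' @return a list of class `mt_search_config`.
#' @export
search_config <- function(intensity_bounds = c(1e-4, 1),
                          prob_bounds = c(1e-3, 1),
                          n_traj = 200, restarts = 3, max_eval = 60,
                          step_factors = c(3, 1.6, 1.25)) {
  stopifnot(intensity_bounds[1] > 0, intensity_bounds[2] > intensity_bounds[1],
            prob_bounds[1] > 0, prob_bounds[2] <= 1,
            n_traj >= 1, restarts >= 1, max_eval >= 1)
  structure(list(intensity_bounds = intensity_bounds,
                 prob_bounds = prob_bounds, n_traj = n_traj,
                 restarts = restarts, max_eval = max_eval,
                 step_factors = step_factors),
            class = "mt_search_config")
}

# build sim params with candidate values substituted into the template
.candidate_params <- function(template, theta, geometry) {
  if (is.null(names(theta))) names(theta) <- character(0)
  pi <- template$promoter_intensities
  for (nm in names(theta)) {
    if (nm %in% c("p", "q")) next
    if (startsWith(nm, "factor:")) next
    pi[nm] <- theta[[nm]]
  }
  fi <- template$factor_intensities
  fnm <- names(theta)[startsWith(names(theta), "factor:")]
  for (nm in fnm) fi[sub("^factor:", "", nm)] <- theta[[nm]]
  sim_params(promoter_intensities = pi, factor_intensities = fi,
             p = if ("p" %in% names(theta)) theta[["p"]] else template$p,
             q = if ("q" %in% names(theta)) theta[["q"]] else template$q,
             elongation_rate = template$elongation_rate,
             footprint = template$footprint,
             quadruplex_termination = template$quadruplex_termination,
             t_end = template$t_end, run_up = template$run_up)
}

#' Objective of the inverse problem
#'
#' Runs an ensemble at the candidate parameters and scores the model's
#' relative (or absolute) transcription levels against the experiment
#' with the normalized L1 functional. Genes whose model transcription is
#' zero contribute the maximal term 1 and are reported in `zero_genes`
#' (the signal used by the active-search boundary rule). Deterministic
#' given `crn_seed`.
#'
#' @param theta named vector of candidate values: promoter names,
#'   optionally `"factor:<site>"` entries, and `"p"`, `"q"`.
#' @param geometry an `mt_geometry`.
#' @param experiment data frame with columns `gene` and `level`.
#' @param template an `mt_sim_params` supplying every field not searched
#'   over (horizon, rate, intensities of fixed promoters/factors).
#' @param reference_gene gene whose mean normalizes model levels; `NULL`
#'   compares absolute mean transcript counts.
#' @param n_traj trajectories for the evaluation.
#' @param crn_seed master seed of the evaluation ensemble.
#' @return list with `value`, `model_levels`, `zero_genes`.
#' @export
fit_objective <- function(theta, geometry, experiment, template,
                          reference_gene = NULL, n_traj = 200,
                          crn_seed = 1L) {
  params <- .candidate_params(template, theta, geometry)
  ens <- ensemble(geometry, params, n_traj, master_seed = crn_seed)
  mu <- ens$per_gene_mean
  if (!all(experiment$gene %in% names(mu)))
    stop("experiment references genes absent from the geometry: ",
         paste(setdiff(experiment$gene, names(mu)), collapse = ", "))
  model <- mu[experiment$gene]
  if (!is.null(reference_gene)) {
    ref <- mu[[reference_gene]]
    model <- if (ref > 0) model / ref else rep(0, length(model))
  }
  y <- experiment$level
  # a gene silent in both model and data is a perfect match; silent in
  # only one of the two contributes the maximal term
  terms <- ifelse(model <= 0 & y <= 0, 0,
                  ifelse(model <= 0 | y <= 0, 1,
                         abs(model - y) / pmax(model, y)))
  list(value = sum(terms),
       model_levels = stats::setNames(as.numeric(model), experiment$gene),
       zero_genes = experiment$gene[model <= 0],
       ensemble = ens)
}

#' Fit binding intensities and terminator passage probabilities
#'
#' Solves the inverse problem: finds the promoter (and optionally factor)
#' binding-attempt intensities and the terminator passage probabilities
#' p/q that minimize the normalized L1 distance between simulated and
#' experimental transcription levels. The optimizer is a multiplicative
#' (log-grid) coordinate descent with multi-start, using common random
#' numbers across candidate evaluations, plus the "active search"
#' boundary rule: a proposal that raises a strand's promoter intensity is
#' rejected outright once any compared gene on the opposing strand loses
#' all transcription, since a silent strand signals that it is already
#' blocked by the opposing polymerase flow.
#'
#' @param geometry an `mt_geometry`.
#' @param experiment data frame with columns `gene` (present in the
#'   geometry) and `level` (target level).
#' @param template an `mt_sim_params` providing the horizon, elongation
#'   rate, and values of parameters not searched over.
#' @param fit_promoters promoter names to fit (default: all promoters in
#'   the geometry).
#' @param fit_factors factor-site names whose binding intensity to fit
#'   (default none).
#' @param fit_p,fit_q fit the passage probabilities?
#' @param reference_gene reference for relative levels; `NULL` compares
#'   absolute counts.
#' @param search an `mt_search_config`.
#' @param master_seed seed for start points and the common-random-number
#'   ensembles; fits with the same seed are identical.
#' @return an object of class `mt_fit`.
#' @export
fit_transcription <- function(geometry, experiment, template,
                              fit_promoters = NULL, fit_factors = character(0),
                              fit_p = TRUE, fit_q = TRUE,
                              reference_gene = NULL,
                              search = search_config(), master_seed = 1L) {
  stopifnot(inherits(geometry, "mt_geometry"),
            inherits(template, "mt_sim_params"),
            inherits(search, "mt_search_config"))
  experiment <- as.data.frame(experiment)
  if (!all(c("gene", "level") %in% names(experiment)))
    stop("'experiment' needs columns gene and level")
  if (is.null(fit_promoters)) fit_promoters <- geometry$promoters$name
  if (!all(fit_promoters %in% geometry$promoters$name))
    stop("unknown promoter in 'fit_promoters'")
  if (!all(fit_factors %in% geometry$factor_sites$name))
    stop("unknown factor site in 'fit_factors'")

  # strand of each fitted promoter, for the boundary rule
  pstrand <- geometry$promoters$strand[match(fit_promoters,
                                             geometry$promoters$name)]
  gstrand <- geometry$genes$strand[match(experiment$gene,
                                         geometry$genes$name)]

  # a promoter whose every compared same-strand gene is silent in the
  # data is unidentifiable from levels (the L1n term is flat in it);
  # such intensities are fixed at the grid floor and flagged as pinned
  floor_pinned <- character(0)
  for (k in seq_along(fit_promoters)) {
    same <- experiment$level[gstrand == pstrand[k]]
    if (length(same) && all(same <= 0))
      floor_pinned <- c(floor_pinned, fit_promoters[k])
  }
  if (length(floor_pinned)) {
    template$promoter_intensities[floor_pinned] <- search$intensity_bounds[1]
    fit_promoters <- setdiff(fit_promoters, floor_pinned)
    pstrand <- geometry$promoters$strand[match(fit_promoters,
                                               geometry$promoters$name)]
  }

  par_names <- c(fit_promoters,
                 if (length(fit_factors)) paste0("factor:", fit_factors),
                 if (fit_p) "p", if (fit_q) "q")
  if (!length(par_names) && !length(floor_pinned)) stop("nothing to fit")
  is_prob <- par_names %in% c("p", "q")
  lb <- ifelse(is_prob, search$prob_bounds[1], search$intensity_bounds[1])
  ub <- ifelse(is_prob, search$prob_bounds[2], search$intensity_bounds[2])

  set.seed(as.integer(master_seed) %% .Machine$integer.max)
  crn_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  starts <- matrix(exp(stats::runif(search$restarts * length(par_names),
                                    log(lb), log(ub))),
                   nrow = search$restarts, byrow = TRUE)
  # first start at the geometric center of the box
  starts[1, ] <- sqrt(lb * ub)
  colnames(starts) <- par_names

  audit <- list()
  n_eval_total <- 0L
  evaluate <- function(theta, restart) {
    res <- fit_objective(theta, geometry, experiment, template,
                         reference_gene = reference_gene,
                         n_traj = search$n_traj, crn_seed = crn_seed)
    n_eval_total <<- n_eval_total + 1L
    audit[[length(audit) + 1L]] <<- c(list(restart = restart,
                                           value = res$value,
                                           n_zero = length(res$zero_genes)),
                                      as.list(theta))
    res
  }

  # does raising promoter 'nm' violate the stop boundary? (an opposing-
  # strand compared gene fell silent)
  boundary_hit <- function(nm, res) {
    if (!nm %in% fit_promoters) return(FALSE)
    s <- pstrand[match(nm, fit_promoters)]
    opp <- if (s == "heavy") "light" else "heavy"
    any(res$zero_genes %in% experiment$gene[gstrand == opp])
  }

  # total log-intensity of a candidate; ties in the objective are broken
  # toward the smaller total binding flux (the minimal solution), which
  # also drives intensities of genes silent in the data down to the grid
  # floor where the L1n term is flat
  intensity_sum <- function(theta)
    sum(log(theta[!(par_names %in% c("p", "q"))]))
  better <- function(cand_val, cand_is, cur_val, cur_is)
    cand_val < cur_val - 1e-9 ||
    (cand_val < cur_val + 1e-9 && cand_is < cur_is - 1e-12)

  # steepest coordinate descent on the log grid: at each move, evaluate
  # both multiplicative steps for every parameter and take the best
  # admissible improvement; shrink the step factor when no move improves
  best <- NULL
  for (r in seq_len(search$restarts)) {
    theta <- starts[r, ]
    res <- evaluate(theta, r)
    n_eval <- 1L
    for (f in search$step_factors) {
      repeat {
        if (n_eval >= search$max_eval) break
        moves <- list()
        for (i in seq_along(theta)) for (d in c(f, 1 / f)) {
          v <- min(max(theta[i] * d, lb[i]), ub[i])
          if (v != theta[i])
            moves[[length(moves) + 1L]] <- list(i = i, v = v)
        }
        move_best <- NULL
        for (mv in moves) {
          if (n_eval >= search$max_eval) break
          cand <- theta; cand[mv$i] <- mv$v
          cres <- evaluate(cand, r)
          n_eval <- n_eval + 1L
          if (mv$v > theta[mv$i] && boundary_hit(par_names[mv$i], cres))
            next                       # active-search stop boundary
          if (better(cres$value, intensity_sum(cand), res$value,
                     intensity_sum(theta)) &&
              (is.null(move_best) ||
                 better(cres$value, intensity_sum(cand),
                        move_best$res$value, intensity_sum(move_best$theta))))
            move_best <- list(theta = cand, res = cres)
        }
        if (is.null(move_best)) break
        theta <- move_best$theta; res <- move_best$res
      }
    }
    if (is.null(best) ||
        better(res$value, intensity_sum(theta),
               best$res$value, intensity_sum(best$theta)))
      best <- list(theta = theta, res = res, restart = r)
  }

  audit <- do.call(rbind, lapply(audit, function(a)
    as.data.frame(a, stringsAsFactors = FALSE)))
  pinned <- union(floor_pinned, par_names[abs(best$theta - lb) < 1e-12])
  coefficients <- c(best$theta,
                    stats::setNames(rep(search$intensity_bounds[1],
                                        length(floor_pinned)), floor_pinned))

  structure(list(
    coefficients = coefficients,
    value = best$res$value,
    fitted_levels = best$res$model_levels,
    experiment = experiment,
    reference_gene = reference_gene,
    geometry = geometry,
    template = template,
    search = search,
    audit = audit,
    pinned = pinned,
    crn_seed = crn_seed,
    master_seed = as.integer(master_seed),
    n_eval = n_eval_total,
    best_restart = best$restart),
    class = "mt_fit")
}

#' @export
coef.mt_fit <- function(object, ...) object$coefficients

#' @export
deviance.mt_fit <- function(object, ...) object$value

#' @export
fitted.mt_fit <- function(object, ...) object$fitted_levels

#' @export
residuals.mt_fit <- function(object, ...)
  object$fitted_levels - stats::setNames(object$experiment$level,
                                         object$experiment$gene)

#' @export
print.mt_fit <- function(x, ...) {
  cat("Transcription-model fit (active search)\n")
  cat("coefficients:\n")
  print(signif(x$coefficients, 4))
  cat(sprintf("L1n value: %.4f over %d genes (%d evaluations, best restart %d)\n",
              x$value, nrow(x$experiment), x$n_eval, x$best_restart))
  if (length(x$pinned))
    cat("pinned at lower search bound:", paste(x$pinned, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mt_fit <- function(object, ...) {
  out <- list(coefficients = object$coefficients,
              value = object$value,
              comparison = data.frame(
                gene = object$experiment$gene,
                target = object$experiment$level,
                model = as.numeric(object$fitted_levels),
                residual = as.numeric(residuals(object))),
              pinned = object$pinned,
              n_eval = object$n_eval,
              restarts = object$search$restarts)
  class(out) <- "summary.mt_fit"
  out
}

#' @export
print.summary.mt_fit <- function(x, ...) {
  cat("Active-search fit:", x$n_eval, "evaluations over", x$restarts,
      "restarts\n\ncoefficients:\n")
  print(signif(x$coefficients, 4))
  cat(sprintf("\nL1n = %.4f\n\n", x$value))
  print(x$comparison, row.names = FALSE)
  if (length(x$pinned))
    cat("\npinned at lower search bound:", paste(x$pinned, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.mt_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted_levels)
  genes <- if (is.data.frame(newdata)) newdata$gene else as.character(newdata)
  params <- .candidate_params(object$template, object$coefficients,
                              object$geometry)
  ens <- ensemble(object$geometry, params, object$search$n_traj,
                  master_seed = object$crn_seed)
  mu <- ens$per_gene_mean
  lev <- mu[genes]
  if (!is.null(object$reference_gene))
    lev <- lev / mu[[object$reference_gene]]
  lev
}

#' @export
simulate.mt_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sim_seeds <- sample.int(.Machine$integer.max - 1L, nsim)
  params <- .candidate_params(object$template, object$coefficients,
                              object$geometry)
  out <- lapply(sim_seeds, function(s) {
    ens <- ensemble(object$geometry, params, object$search$n_traj,
                    master_seed = s)
    mu <- ens$per_gene_mean[object$experiment$gene]
    if (!is.null(object$reference_gene))
      mu <- mu / ens$per_gene_mean[[object$reference_gene]]
    mu
  })
  as.data.frame(do.call(rbind, out))
}

#' @export
plot.mt_fit <- function(x, ...) {
  m <- rbind(model = as.numeric(x$fitted_levels),
             experiment = x$experiment$level)
  colnames(m) <- x$experiment$gene
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m), las = 2,
                    ylab = if (is.null(x$reference_gene))
                      "transcripts per window" else
                        sprintf("level relative to %s", x$reference_gene),
                    ...)
  invisible(x)
}
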