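#' Ensemble of simulated trajectories
#'
#' Runs `n_traj` independent trajectories with seeds derived
#' deterministically from `master_seed` (so the result does not depend on
#' execution order, and a parallel or resumed run reproduces the
#' sequential one exactly) and averages the per-gene transcript counts.
#'
#' @param geometry an `mt_geometry`.
#' @param params an `mt_sim_params`.
#' @param n_traj number of trajectories (>= 1).
#' @param master_seed master RNG seed; per-trajectory seeds are drawn
#'   from it once, by trajectory index.
#' @param engine `"event"` (default) or `"fixed_step"` (the naive
#'   reference simulator).
#' @param checkpoint_file optional RDS path; completed trajectories are
#'   saved every `checkpoint_every` trajectories and a rerun resumes from
#'   the file, reproducing the uninterrupted result exactly.
#' @param checkpoint_every checkpoint interval in trajectories.
#' @return object of class `mt_ensemble`: per-gene mean and unbiased SD,
#'   terminator totals, circling/collision statistics, and the seeds
#'   used.
#' @export
ensemble <- function(geometry, params, n_traj, master_seed = 1L,
                     engine = c("event", "fixed_step"),
                     checkpoint_file = NULL, checkpoint_every = 100L) {
  stopifnot(n_traj >= 1)
  engine <- match.arg(engine)
  runner <- if (engine == "event") run_trajectory else run_trajectory_fixed_step

  set.seed(as.integer(master_seed) %% .Machine$integer.max)
  seeds <- sample.int(.Machine$integer.max - 1L, n_traj)

  trajs <- vector("list", n_traj)
  done <- 0L
  if (!is.null(checkpoint_file) && file.exists(checkpoint_file)) {
    ck <- readRDS(checkpoint_file)
    if (identical(ck$seeds, seeds)) {
      trajs[seq_along(ck$trajs)] <- ck$trajs
      done <- length(ck$trajs)
    }
  }
  for (i in seq_len(n_traj)) {
    if (i <= done) next
    trajs[[i]] <- runner(geometry, params, seed = seeds[i])
    if (!is.null(checkpoint_file) && (i %% checkpoint_every == 0L))
      saveRDS(list(seeds = seeds, trajs = trajs[seq_len(i)]), checkpoint_file)
  }
  if (!is.null(checkpoint_file) && file.exists(checkpoint_file))
    unlink(checkpoint_file)

  counts <- do.call(rbind, lapply(trajs, function(tr) tr$gene_counts))
  if (is.null(counts)) counts <- matrix(0, n_traj, 0)
  per_gene_mean <- colMeans(counts)
  per_gene_sd <- if (n_traj >= 2) apply(counts, 2, stats::sd) else
    stats::setNames(rep(NA_real_, ncol(counts)), colnames(counts))

  term <- trajs[[1]]$terminator
  if (nrow(term)) {
    term$stops <- Reduce(`+`, lapply(trajs, function(tr) tr$terminator$stops))
    term$passes <- Reduce(`+`, lapply(trajs, function(tr) tr$terminator$passes))
  }
  circ <- do.call(rbind, lapply(trajs, function(tr) tr$circling))

  structure(list(
    n_traj = n_traj,
    per_gene_mean = per_gene_mean,
    per_gene_sd = per_gene_sd,
    per_traj_counts = counts,
    terminator = term,
    circling_mean = colMeans(circ),
    circling_sd = if (n_traj >= 2) apply(circ, 2, stats::sd) else
      c(heavy = NA_real_, light = NA_real_),
    collisions_mean = mean(vapply(trajs, function(tr) as.numeric(tr$collisions), 0)),
    master_seed = as.integer(master_seed),
    seeds = seeds,
    engine = engine,
    t_end = params$t_end, run_up = params$run_up),
    class = "mt_ensemble")
}

#' @export
print.mt_ensemble <- function(x, ...) {
  cat(sprintf("ensemble of %d trajectories (%s engine, %g s window)\n",
              x$n_traj, x$engine, x$t_end - x$run_up))
  if (length(x$per_gene_mean)) {
    df <- data.frame(mean = round(x$per_gene_mean, 3),
                     sd = round(x$per_gene_sd, 3))
    print(df)
  }
  cat(sprintf("circling polymerases: heavy %.2f +- %.2f, light %.2f +- %.2f\n",
              x$circling_mean[["heavy"]], x$circling_sd[["heavy"]],
              x$circling_mean[["light"]], x$circling_sd[["light"]]))
  invisible(x)
}

#' @export
plot.mt_ensemble <- function(x, ...) {
  if (!length(x$per_gene_mean)) {
    warning("no genes to plot")
    return(invisible(x))
  }
  bp <- graphics::barplot(x$per_gene_mean, las = 2,
                          ylab = "transcripts per window",
                          main = sprintf("mean over %d trajectories", x$n_traj),
                          ...)
  graphics::arrows(bp, pmax(0, x$per_gene_mean - x$per_gene_sd),
                   bp, x$per_gene_mean + x$per_gene_sd,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Ratio R of two transcription levels
#'
#' The ratio of the mean transcription level of an rRNA gene (12S in the
#' study systems) to a reference mRNA gene (COX2).
#'
#' @param result an `mt_ensemble`.
#' @param rrna_gene,ref_gene gene names.
#' @return the ratio of ensemble means.
#' @export
ratio_R <- function(result, rrna_gene = "12S", ref_gene = "COX2") {
  stopifnot(inherits(result, "mt_ensemble"))
  if (!all(c(rrna_gene, ref_gene) %in% names(result$per_gene_mean)))
    stop("gene not present in the ensemble")
  num <- result$per_gene_mean[[rrna_gene]]
  den <- result$per_gene_mean[[ref_gene]]
  if (den == 0) stop("reference gene has zero mean transcription")
  num / den
}

#' Terminator polarization
#'
#' Fraction of polymerases terminated among encounters with the bound
#' site, in each direction. Encounters with an unbound (transparent) site
#' are not encounters in this sense.
#'
#' @param result an `mt_ensemble`.
#' @param site factor-site name.
#' @return named vector `c(heavy = ..., light = ...)`; a direction with
#'   no encounters is `NA` with attribute `no_encounters` listing it.
#' @export
polarization <- function(result, site) {
  stopifnot(inherits(result, "mt_ensemble"))
  term <- result$terminator[result$terminator$site == site, ]
  if (!nrow(term)) stop("no such factor site: ", site)
  enc <- term$stops + term$passes
  frac <- ifelse(enc > 0, term$stops / enc, NA_real_)
  out <- stats::setNames(frac, term$direction)[c("heavy", "light")]
  if (any(enc == 0))
    attr(out, "no_encounters") <- term$direction[enc == 0]
  out
}

#' Export an ensemble summary
#'
#' @param x an `mt_ensemble`.
#' @param file path of the JSON file to write; `NULL` returns the list.
#' @return the summary list, invisibly when written.
#' @export
ensemble_summary <- function(x, file = NULL) {
  stopifnot(inherits(x, "mt_ensemble"))
  s <- list(n_traj = x$n_traj,
            engine = x$engine,
            master_seed = x$master_seed,
            t_end = x$t_end, run_up = x$run_up,
            per_gene_mean = as.list(x$per_gene_mean),
            per_gene_sd = as.list(x$per_gene_sd),
            circling_mean = as.list(x$circling_mean),
            circling_sd = as.list(x$circling_sd),
            collisions_mean = x$collisions_mean,
            terminator = x$terminator)
  if (is.null(file)) return(s)
  jsonlite::write_json(s, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(s)
}
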