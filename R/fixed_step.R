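#' Naive fixed-step reference simulation
#'
#' Walks the chromosome one nucleotide per tick (tick length `1/v`
#' seconds) instead of jumping between events. Much slower than
#' `run_trajectory()` and statistically equivalent to it; kept as an
#' independent reference implementation for validating the event-driven
#' engine on small genomes. G-quadruplex sites are not implemented here.
#'
#' @inheritParams run_trajectory
#' @return a list shaped like the corresponding `mt_trajectory` fields:
#'   `gene_counts`, `terminator`, `circling`, `collisions`, `bindings`,
#'   `terminations`, `active_at_end`.
#' @export
run_trajectory_fixed_step <- function(geometry, params, seed = 1L) {
  stopifnot(inherits(geometry, "mt_geometry"), inherits(params, "mt_sim_params"))
  if (nrow(geometry$quadruplex_sites))
    stop("the fixed-step reference does not implement quadruplex sites")
  pr <- geometry$promoters
  pr_lambda <- rep(0, nrow(pr))
  m <- match(pr$name, names(params$promoter_intensities))
  pr_lambda[!is.na(m)] <- params$promoter_intensities[m[!is.na(m)]]

  fs <- geometry$factor_sites
  fs_lambda <- fs$binding_intensity
  if (nrow(fs) && !is.null(params$factor_intensities)) {
    m <- match(fs$name, names(params$factor_intensities))
    fs_lambda[!is.na(m)] <- params$factor_intensities[m[!is.na(m)]]
  }
  fs_p <- if (is.null(params$p)) fs$pass_prob_heavy else rep(params$p, nrow(fs))
  fs_q <- if (is.null(params$q)) fs$pass_prob_light else rep(params$q, nrow(fs))

  genes <- geometry$genes
  gene_dir <- ifelse(genes$strand == "heavy", 1L, -1L)
  gene_entry <- ifelse(gene_dir > 0, genes$start, genes$end %% geometry$length)

  set.seed(as.integer(seed) %% .Machine$integer.max)
  out <- .fixed_step_cpp(
    geometry$length, params$elongation_rate, params$t_end, params$run_up,
    as.integer(pr$tss), as.integer(ifelse(pr$strand == "heavy", 1L, -1L)),
    pr_lambda, as.integer(pr$fp_start),
    as.integer(pr$fp_end - pr$fp_start),
    as.integer(fs$start), as.integer(fs$end - fs$start),
    fs_p, fs_q, fs_lambda,
    as.integer(gene_entry), as.integer(genes$end - genes$start),
    gene_dir, as.integer(params$footprint))

  list(gene_counts = stats::setNames(out$gene_counts, genes$name),
       terminator = data.frame(
         site = rep(fs$name, 2L),
         direction = rep(c("heavy", "light"), each = nrow(fs)),
         stops = c(out$stops_heavy, out$stops_light),
         passes = c(out$passes_heavy, out$passes_light),
         stringsAsFactors = FALSE),
       circling = c(heavy = out$circling[["heavy"]],
                    light = out$circling[["light"]]),
       collisions = out$collisions,
       bindings = out$bindings,
       terminations = out$terminations,
       active_at_end = out$active_at_end)
}
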