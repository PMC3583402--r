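#' Simulation parameters
#'
#' Binding intensities and kinetic constants for the event-driven
#' transcription simulator.
#'
#' @param promoter_intensities named vector, binding-attempt intensity per
#'   promoter (attempts/s, Poisson). Promoters absent from the map attempt
#'   at intensity 0.
#' @param factor_intensities named vector of factor-site binding-attempt
#'   intensities (attempts/s); overrides the per-site defaults stored in
#'   the geometry. The intensity subsumes spontaneous dissociation of the
#'   factor-DNA complex, which is not modeled as a separate event.
#' @param p,q passage probabilities through a bound terminator for heavy-
#'   and light-strand polymerases; override the per-site values in the
#'   geometry when given.
#' @param elongation_rate polymerase elongation rate v, nt/s (default 500;
#'   200 is the usual control value).
#' @param footprint polymerase/promoter exclusion footprint in nt (default
#'   17: positions -15..+1 around the active site in transcription
#'   direction).
#' @param quadruplex_termination per-passage termination probability at
#'   G-quadruplex sites; overrides per-site values when given.
#' @param t_end modeled physical time horizon in seconds (default 32400 s,
#'   i.e. 9 h).
#' @param run_up initial interval discarded before counting (seconds,
#'   default 0).
#' @return object of class `mt_sim_params`.
#' @export
sim_params <- function(promoter_intensities, factor_intensities = NULL,
                       p = NULL, q = NULL, elongation_rate = 500,
                       footprint = 17, quadruplex_termination = NULL,
                       t_end = 32400, run_up = 0) {
  if (any(promoter_intensities < 0)) stop("promoter intensities must be >= 0")
  if (!is.null(factor_intensities) && any(factor_intensities < 0))
    stop("factor intensities must be >= 0")
  for (pr in list(p = p, q = q, g4 = quadruplex_termination))
    if (!is.null(pr) && (pr < 0 || pr > 1))
      stop("probabilities must lie in [0, 1]")
  if (elongation_rate <= 0) stop("elongation rate must be positive")
  if (t_end <= 0) stop("'t_end' must be positive")
  if (run_up < 0 || run_up >= t_end) stop("need t_end > run_up >= 0")
  structure(list(promoter_intensities = promoter_intensities,
                 factor_intensities = factor_intensities,
                 p = p, q = q, elongation_rate = elongation_rate,
                 footprint = footprint,
                 quadruplex_termination = quadruplex_termination,
                 t_end = t_end, run_up = run_up),
            class = "mt_sim_params")
}

#' First meeting time of two polymerases on a circle
#'
#' Polymerases move at equal speed `v`; converging (opposite-direction)
#' pairs meet after `gap / (2 v)` where `gap` is the arc from the first
#' polymerase, in its direction of motion, to the second (modulo the
#' circle length). Co-directional pairs never meet.
#'
#' @param pos_a,pos_b current positions (nt, modulo `length`).
#' @param dir_a,dir_b directions of motion, `+1` (heavy) or `-1` (light).
#' @param v elongation rate (nt/s).
#' @param length circle length (nt).
#' @return meeting time in seconds, or `NA` for co-directional pairs.
#' @export
next_meeting_time <- function(pos_a, dir_a, pos_b, dir_b, v, length) {
  if (dir_a == dir_b) return(NA_real_)
  gap <- ((pos_b - pos_a) * dir_a) %% length
  gap / (2 * v)
}

#' Passage decision at a bound protein terminator
#'
#' Bernoulli draw: a polymerase meeting a bound terminator passes with
#' probability `p` (heavy-strand direction) or `q` (light-strand); on a
#' pass the protein-DNA complex dissociates, on a stop the polymerase
#' terminates and the complex survives.
#'
#' @param direction `"heavy"` or `"light"`.
#' @param site one row of a geometry's `factor_sites` frame (or any list
#'   with `pass_prob_heavy`, `pass_prob_light`).
#' @param n number of independent draws.
#' @return character vector of `"pass"` / `"terminate"`.
#' @export
encounter_factor <- function(direction = c("heavy", "light"), site, n = 1) {
  direction <- match.arg(direction)
  pp <- if (direction == "heavy") site$pass_prob_heavy else site$pass_prob_light
  ifelse(stats::runif(n) < pp, "pass", "terminate")
}

# circular distance from 'from' to 'to' along direction 'dir'; an exact hit
# (distance ~ 0) means the obstacle was just handled, so the next encounter
# is one full circle away
.dist_ahead <- function(from, to, dir, L, tol = 1e-6) {
  d <- ((to - from) * dir) %% L
  d[d < tol] <- L
  d
}

# polymerase body interval [lo, lo + fp): fp-2 nt behind the active site,
# 1 nt ahead (the -15..+1 footprint for fp = 17)
.body_lo <- function(pos, dir, fp) ifelse(dir > 0, pos - (fp - 2), pos - 1)

#' Simulate one trajectory of the transcription model
#'
#' Event-driven realization over modeled time `[0, t_end]`: Poisson
#' binding attempts at promoters and factor sites, deterministic
#' elongation at rate `v` on the circular chromosome, head-on collisions
#' (both polymerases terminate at the meeting point), directional passage
#' of bound protein terminators, and optional Bernoulli termination at
#' G-quadruplex sites. A transcript counts for a gene each time the
#' polymerase traverses the gene's full span on the gene's strand;
#' additional full circles count again. Counting is restricted to
#' `(run_up, t_end]`.
#'
#' @param geometry an `mt_geometry`.
#' @param params an `mt_sim_params`.
#' @param seed RNG seed; identical (geometry, params, seed) triples give
#'   identical trajectories.
#' @return an object of class `mt_trajectory`: list with
#'   `gene_counts` (named integer vector of full-cover transcript counts),
#'   `terminator` (data frame site/direction/stops/passes for encounters
#'   with a bound site), `circling` (named vector: polymerases that
#'   completed at least one full circle, per strand), `collisions`,
#'   `quadruplex_stops`, and the conservation counters `bindings`,
#'   `terminations`, `active_at_end`.
#' @export
run_trajectory <- function(geometry, params, seed = 1L) {
  stopifnot(inherits(geometry, "mt_geometry"), inherits(params, "mt_sim_params"))
  L <- geometry$length
  if (L <= 0) stop("zero-length geometry")
  v <- params$elongation_rate
  fp <- params$footprint
  t_end <- params$t_end
  run_up <- params$run_up
  set.seed(as.integer(seed) %% .Machine$integer.max)

  # --- static tables -------------------------------------------------------
  pr <- geometry$promoters
  n_pr <- nrow(pr)
  pr_dir <- ifelse(pr$strand == "heavy", 1, -1)
  pr_lambda <- rep(0, n_pr)
  if (n_pr) {
    m <- match(pr$name, names(params$promoter_intensities))
    pr_lambda[!is.na(m)] <- params$promoter_intensities[m[!is.na(m)]]
  }

  fs <- geometry$factor_sites
  n_fs <- nrow(fs)
  fs_lambda <- fs$binding_intensity
  if (n_fs && !is.null(params$factor_intensities)) {
    m <- match(fs$name, names(params$factor_intensities))
    fs_lambda[!is.na(m)] <- params$factor_intensities[m[!is.na(m)]]
  }
  fs_p <- if (is.null(params$p)) fs$pass_prob_heavy else rep(params$p, n_fs)
  fs_q <- if (is.null(params$q)) fs$pass_prob_light else rep(params$q, n_fs)
  fs_bound <- rep(FALSE, n_fs)

  qs <- geometry$quadruplex_sites
  n_qs <- nrow(qs)
  qs_dir <- ifelse(qs$strand == "heavy", 1, -1)
  qs_prob <- if (is.null(params$quadruplex_termination))
    qs$termination_probability else rep(params$quadruplex_termination, n_qs)

  genes <- geometry$genes
  gene_dir <- ifelse(genes$strand == "heavy", 1, -1)
  gene_entry <- ifelse(gene_dir > 0, genes$start, genes$end %% L)
  gene_span <- genes$end - genes$start

  # --- mutable state -------------------------------------------------------
  cap <- 64L
  pol_pos0 <- pol_t0 <- pol_stop_t <- numeric(cap)
  pol_dir <- integer(cap)
  pol_stop_kind <- integer(cap)   # 0 none, 1 factor, 2 quadruplex
  pol_stop_site <- integer(cap)
  act <- integer(0)               # indices of active polymerases
  n_pol <- 0L

  draw_next <- function(now, lambda)
    if (lambda > 0) now + stats::rexp(1L, lambda) else Inf
  pr_next <- vapply(seq_len(n_pr), function(i) draw_next(0, pr_lambda[i]), 0)
  fs_next <- vapply(seq_len(n_fs), function(j) draw_next(0, fs_lambda[j]), 0)
  if (!n_pr) pr_next <- Inf
  if (!n_fs) fs_next <- Inf

  coll_t <- Inf; coll_a <- 0L; coll_b <- 0L

  gene_counts <- stats::setNames(integer(nrow(genes)), genes$name)
  stops <- passes <- matrix(0L, nrow = max(n_fs, 1L), ncol = 2,
                            dimnames = list(NULL, c("heavy", "light")))
  circling <- c(heavy = 0L, light = 0L)
  collisions <- 0L; quadruplex_stops <- 0L
  bindings <- 0L; terminations <- 0L

  in_window <- function(t) t > run_up && t <= t_end

  pos_at <- function(k, t) (pol_pos0[k] + pol_dir[k] * v * (t - pol_t0[k])) %% L

  # does any active polymerase body overlap circular interval [a1, a2)?
  any_body_overlap <- function(a1, a2, t) {
    if (!length(act)) return(FALSE)
    p <- pos_at(act, t)
    lo <- .body_lo(p, pol_dir[act], fp)
    off <- (lo - a1) %% L
    alen <- a2 - a1
    any(off < alen | (off + fp) > L)
  }

  # nearest obstacle ahead of polymerase k (bound factor edges, matching-
  # strand quadruplex edges); horizon handled globally
  schedule_stop <- function(k, t) {
    p <- pos_at(k, t)
    dmin <- Inf; kind <- 0L; site <- 0L
    if (n_fs && any(fs_bound)) {
      for (j in which(fs_bound)) {
        edge <- if (pol_dir[k] > 0) fs$start[j] else fs$end[j] %% L
        d <- .dist_ahead(p, edge, pol_dir[k], L)
        if (d < dmin) { dmin <- d; kind <- 1L; site <- j }
      }
    }
    if (n_qs) {
      for (j in seq_len(n_qs)) {
        if (qs_dir[j] != pol_dir[k] || qs_prob[j] <= 0) next
        edge <- if (pol_dir[k] > 0) qs$start[j] else qs$end[j] %% L
        d <- .dist_ahead(p, edge, pol_dir[k], L)
        if (d < dmin) { dmin <- d; kind <- 2L; site <- j }
      }
    }
    pol_stop_t[k] <<- if (is.finite(dmin)) t + dmin / v else Inf
    pol_stop_kind[k] <<- kind
    pol_stop_site[k] <<- site
  }

  reschedule_all <- function(t) for (k in act) schedule_stop(k, t)

  recompute_collisions <- function(t) {
    coll_t <<- Inf; coll_a <<- 0L; coll_b <<- 0L
    if (length(act) < 2L) return(invisible())
    hs <- act[pol_dir[act] > 0]; ls <- act[pol_dir[act] < 0]
    if (!length(hs) || !length(ls)) return(invisible())
    ph <- pos_at(hs, t); pl <- pos_at(ls, t)
    for (i in seq_along(hs)) {
      d <- (pl - ph[i]) %% L
      jmin <- which.min(d)
      tm <- t + d[jmin] / (2 * v)
      if (tm < coll_t) { coll_t <<- tm; coll_a <<- hs[i]; coll_b <<- ls[jmin] }
    }
    invisible()
  }

  # count full gene covers of polymerase k terminated at time t_stop
  finalize_pol <- function(k, t_stop) {
    dist <- v * (t_stop - pol_t0[k])
    tol <- 1e-6
    strand_match <- which(gene_dir == pol_dir[k])
    for (gi in strand_match) {
      d_entry <- ((gene_entry[gi] - pol_pos0[k]) * pol_dir[k]) %% L
      c0 <- d_entry + gene_span[gi]
      if (dist + tol < c0) next
      m_max <- floor((dist + tol - c0) / L)
      # the m-th cover completes at t0 + (c0 + m L) / v; count covers whose
      # completion falls in (run_up, t_end]
      lo_m <- max(0, floor(((run_up - pol_t0[k]) * v - c0) / L) + 1)
      hi_m <- min(m_max, floor(((t_end - pol_t0[k]) * v - c0) / L + 1e-9))
      if (hi_m >= lo_m)
        gene_counts[gi] <<- gene_counts[gi] + (hi_m - lo_m + 1L)
    }
    circ <- floor((dist + tol) / L)
    if (circ >= 1) {
      t_circ <- pol_t0[k] + L / v      # completion of the first circle
      if (t_circ > run_up && t_circ <= t_end) {
        s <- if (pol_dir[k] > 0) "heavy" else "light"
        circling[s] <<- circling[s] + 1L
      }
    }
    act <<- act[act != k]
  }

  new_pol <- function(tss, dir, t) {
    n_pol <<- n_pol + 1L
    if (n_pol > cap) {
      cap <<- cap * 2L
      for (nmv in c("pol_pos0", "pol_t0", "pol_stop_t"))
        assign(nmv, `length<-`(get(nmv), cap), inherits = TRUE)
      for (nmv in c("pol_dir", "pol_stop_kind", "pol_stop_site"))
        assign(nmv, `length<-`(get(nmv), cap), inherits = TRUE)
    }
    k <- n_pol
    pol_pos0[k] <<- tss; pol_t0[k] <<- t; pol_dir[k] <<- dir
    act <<- c(act, k)
    schedule_stop(k, t)
    recompute_collisions(t)
    k
  }

  # --- event loop ----------------------------------------------------------
  repeat {
    t_pr <- if (n_pr) min(pr_next) else Inf
    t_fs <- if (n_fs) min(fs_next) else Inf
    t_stop <- if (length(act)) min(pol_stop_t[act]) else Inf
    t_next <- min(t_pr, t_fs, t_stop, coll_t)
    if (t_next > t_end) break

    if (coll_t <= t_next && coll_t <= t_pr && coll_t <= t_fs && coll_t <= t_stop) {
      # head-on collision: both polymerases terminate at the meeting point
      t <- coll_t; a <- coll_a; b <- coll_b
      finalize_pol(a, t); finalize_pol(b, t)
      terminations <- terminations + 2L
      if (in_window(t)) collisions <- collisions + 1L
      reschedule_all(t)         # positions unchanged, but keep cache tidy
      recompute_collisions(t)
    } else if (t_stop <= t_pr && t_stop <= t_fs) {
      k <- act[which.min(pol_stop_t[act])]
      t <- pol_stop_t[k]
      kind <- pol_stop_kind[k]; j <- pol_stop_site[k]
      if (kind == 1L) {
        if (!fs_bound[j]) {     # stale; site was vacated since scheduling
          schedule_stop(k, t)
        } else {
          dircol <- if (pol_dir[k] > 0) "heavy" else "light"
          pp <- if (pol_dir[k] > 0) fs_p[j] else fs_q[j]
          if (stats::runif(1L) < pp) {
            if (in_window(t)) passes[j, dircol] <- passes[j, dircol] + 1L
            fs_bound[j] <- FALSE      # complex dissociates on pass-through
            reschedule_all(t)
          } else {
            if (in_window(t)) stops[j, dircol] <- stops[j, dircol] + 1L
            finalize_pol(k, t)
            terminations <- terminations + 1L
            recompute_collisions(t)
          }
        }
      } else if (kind == 2L) {
        if (stats::runif(1L) < qs_prob[j]) {
          if (in_window(t)) quadruplex_stops <- quadruplex_stops + 1L
          finalize_pol(k, t)
          terminations <- terminations + 1L
          recompute_collisions(t)
        } else {
          schedule_stop(k, t)   # passed; next obstacle beyond this site
        }
      } else {
        pol_stop_t[k] <- Inf    # nothing ahead
      }
    } else if (t_pr <= t_fs) {
      i <- which.min(pr_next)
      t <- pr_next[i]
      pr_next[i] <- draw_next(t, pr_lambda[i])
      free <- !any_body_overlap(pr$fp_start[i], pr$fp_end[i], t)
      if (free && n_fs && any(fs_bound)) {
        for (j in which(fs_bound))
          if (.circ_overlap(pr$fp_start[i], pr$fp_end[i],
                            fs$start[j], fs$end[j], L)) { free <- FALSE; break }
      }
      if (free) {
        bindings <- bindings + 1L
        new_pol(pr$tss[i], pr_dir[i], t)
      }
    } else {
      j <- which.min(fs_next)
      t <- fs_next[j]
      fs_next[j] <- draw_next(t, fs_lambda[j])
      if (!fs_bound[j] && !any_body_overlap(fs$start[j], fs$end[j], t)) {
        fs_bound[j] <- TRUE
        reschedule_all(t)       # a new obstacle appeared
      }
    }
  }

  # horizon: truncate everything still moving
  active_at_end <- length(act)
  for (k in rev(act)) finalize_pol(k, t_end)

  structure(list(
    gene_counts = gene_counts,
    terminator = if (n_fs) data.frame(
      site = rep(fs$name, 2L),
      direction = rep(c("heavy", "light"), each = n_fs),
      stops = c(stops[seq_len(n_fs), "heavy"], stops[seq_len(n_fs), "light"]),
      passes = c(passes[seq_len(n_fs), "heavy"], passes[seq_len(n_fs), "light"]),
      stringsAsFactors = FALSE) else
        data.frame(site = character(0), direction = character(0),
                   stops = integer(0), passes = integer(0)),
    circling = circling,
    collisions = collisions,
    quadruplex_stops = quadruplex_stops,
    bindings = bindings,
    terminations = terminations,
    active_at_end = active_at_end,
    seed = as.integer(seed),
    t_end = t_end, run_up = run_up),
    class = "mt_trajectory")
}

#' @export
print.mt_trajectory <- function(x, ...) {
  cat(sprintf("trajectory (seed %d): %d bindings, %d terminations, %d active at horizon\n",
              x$seed, x$bindings, x$terminations, x$active_at_end))
  cat(sprintf("  collisions %d, quadruplex stops %d, circling H/L %d/%d\n",
              x$collisions, x$quadruplex_stops,
              x$circling[["heavy"]], x$circling[["light"]]))
  if (length(x$gene_counts)) {
    cat("  transcripts per gene:\n")
    print(x$gene_counts)
  }
  invisible(x)
}

#' Is a promoter currently available for binding?
#'
#' A binding attempt succeeds only if neither a polymerase body nor a
#' bound factor overlaps the promoter footprint, even partially.
#'
#' @param geometry an `mt_geometry`.
#' @param promoter promoter name.
#' @param pol_pos,pol_dir positions and directions (+1/-1) of polymerases
#'   currently on the DNA.
#' @param bound_sites names of factor sites currently bound.
#' @param footprint polymerase footprint (nt).
#' @return `TRUE` if an attempt at this instant would succeed.
#' @export
promoter_available <- function(geometry, promoter, pol_pos = numeric(0),
                               pol_dir = integer(0), bound_sites = character(0),
                               footprint = 17) {
  L <- geometry$length
  i <- match(promoter, geometry$promoters$name)
  if (is.na(i)) stop("no such promoter: ", promoter)
  a1 <- geometry$promoters$fp_start[i]; a2 <- geometry$promoters$fp_end[i]
  if (length(pol_pos)) {
    lo <- .body_lo(pol_pos, pol_dir, footprint)
    for (k in seq_along(lo))
      if (.circ_overlap(a1 %% L, a1 %% L + (a2 - a1), lo[k] %% L,
                        lo[k] %% L + footprint, L)) return(FALSE)
  }
  for (s in bound_sites) {
    j <- match(s, geometry$factor_sites$name)
    if (is.na(j)) next
    if (.circ_overlap(a1 %% L, a1 %% L + (a2 - a1),
                      geometry$factor_sites$start[j],
                      geometry$factor_sites$end[j], L)) return(FALSE)
  }
  TRUE
}

#' Time to traverse the full circle once
#'
#' @param geometry an `mt_geometry`.
#' @param v elongation rate (nt/s).
#' @return seconds per complete circle.
#' @export
traversal_time <- function(geometry, v = 500) geometry$length / v
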