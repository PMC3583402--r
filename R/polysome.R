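#' Parameters of the polysome-ribonuclease decay model
#'
#' Closed-form model of how ribosome traffic on an mRNA protects it from
#' endonucleolytic cleavage: a ribonuclease of linear size `h = V * w`
#' codons can only attack its cleavage site through a ribosome-free window
#' of at least `h` codons. Ribosomes initiate as a Poisson stream of
#' intensity `lambda = nu * N / (1 + alpha * N)` (saturating at
#' `nu / alpha` for large `N`), keep a minimum headway of `h1` codons, and
#' translate at `V` codons/s.
#'
#' @param mu cleavage intensity at an exposed site (1/s, > 0).
#' @param nu specific ribosome-binding intensity at low ribosome numbers.
#' @param alpha saturation parameter of the binding intensity.
#' @param N ribosome count in the organelle (dimensionless, >= 0).
#' @param w ribonuclease size over ribosome rate, seconds. Cannot be below
#'   1/15 s and is likely below 4/3 s; values outside are allowed with a
#'   warning.
#' @param V ribosome elongation rate, codons/s (default 15).
#' @param h1 ribosome size on the mRNA, codons (default 10); the minimum
#'   headway time is `d = h1 / V` seconds.
#' @param k number of cleavage sites per RNA (default 1).
#' @return object of class `polysome_params`.
#' @export
polysome_params <- function(mu, nu = NULL, alpha = NULL, N = NULL, w,
                            V = 15, h1 = 10, k = 1) {
  stopifnot(mu >= 0, w >= 0, V > 0, h1 >= 0, k >= 0)
  if (w < 1 / 15 || w > 4 / 3)
    warning("'w' outside the plausible band [1/15, 4/3] s")
  structure(list(mu = mu, nu = nu, alpha = alpha, N = N, w = w, V = V,
                 h1 = h1, d = h1 / V, k = k),
            class = "polysome_params")
}

#' @export
print.polysome_params <- function(x, ...) {
  cat(sprintf("polysome model: mu=%g/s w=%g s (h=%g codons) d=%g s k=%g\n",
              x$mu, x$w, x$V * x$w, x$d, x$k))
  if (!is.null(x$nu))
    cat(sprintf("  ribosome binding: nu=%g alpha=%g N=%g -> lambda=%g/s\n",
                x$nu, x$alpha, x$N,
                binding_intensity(x$nu, x$alpha, x$N)))
  invisible(x)
}

#' Ribosome binding intensity
#'
#' `lambda = nu * N / (1 + alpha * N)`; saturates at `nu / alpha` as `N`
#' grows.
#'
#' @param nu specific binding intensity (>= 0).
#' @param alpha saturation parameter (>= 0).
#' @param N ribosome count (>= 0).
#' @return binding intensity (1/s).
#' @export
binding_intensity <- function(nu, alpha, N) {
  if (any(nu < 0) || any(alpha < 0) || any(N < 0))
    stop("'nu', 'alpha' and 'N' must be >= 0")
  nu * N / (1 + alpha * N)
}

.lambda_of <- function(params, lambda = NULL) {
  if (!is.null(lambda)) return(lambda)
  if (is.null(params$nu) || is.null(params$alpha) || is.null(params$N))
    stop("either 'lambda' or nu/alpha/N in the parameter set is required")
  binding_intensity(params$nu, params$alpha, params$N)
}

#' mRNA half-life under polysomal protection
#'
#' `tau = ln(2) * (1 + d * lambda) * exp(w * lambda) / mu`, divided by the
#' number of cleavage sites `k`. With no ribosomes (`lambda = 0`, `k = 1`)
#' this is the unprotected half-life `ln(2) / mu`.
#'
#' @param params a `polysome_params`.
#' @param lambda ribosome binding intensity; defaults to the one implied
#'   by `nu`, `alpha`, `N` in `params`.
#' @return half-life in seconds (`Inf` if `mu = 0`, with a warning).
#' @export
half_life <- function(params, lambda = NULL) {
  stopifnot(inherits(params, "polysome_params"))
  lam <- .lambda_of(params, lambda)
  if (params$mu == 0) {
    warning("mu = 0: half-life is infinite")
    return(Inf)
  }
  log(2) * (1 + params$d * lam) * exp(params$w * lam) /
    (params$mu * params$k)
}

#' Half-life ratio between two ribosome-loading states
#'
#' `tau / tau' = [(1 + d * lambda) / (1 + d * lambda')] *
#' exp(w * (lambda - lambda'))`; exceeds 1 whenever `lambda > lambda'`
#' (fewer ribosomes shorten the half-life).
#'
#' @param lambda_healthy,lambda_diseased binding intensities in the two
#'   states.
#' @param d ribosome headway time (s).
#' @param w ribonuclease window time (s).
#' @return the half-life ratio.
#' @export
half_life_ratio <- function(lambda_healthy, lambda_diseased, d, w) {
  (1 + d * lambda_healthy) / (1 + d * lambda_diseased) *
    exp(w * (lambda_healthy - lambda_diseased))
}

#' Ribonuclease decay intensity
#'
#' `kappa = mu * exp(-lambda * w) / (1 + d * lambda)`, multiplied by the
#' number of cleavage sites `k`. Identity: `half_life * decay_intensity =
#' ln(2)` exactly, for all parameters (the `k` factors cancel).
#'
#' @inheritParams half_life
#' @return decay intensity (1/s).
#' @export
decay_intensity <- function(params, lambda = NULL) {
  stopifnot(inherits(params, "polysome_params"))
  lam <- .lambda_of(params, lambda)
  params$k * params$mu * exp(-lam * params$w) / (1 + params$d * lam)
}

#' Invert the half-life formula for the specific binding intensity
#'
#' Given an observed half-life, solves `half_life(lambda) = tau_obs` for
#' `lambda` (unique root: the half-life is strictly increasing in
#' `lambda`), then returns `nu = lambda * (1 + alpha * N) / N`.
#'
#' @param tau_obs observed half-life (s); must be at least the unprotected
#'   half-life `ln(2) / (mu * k)`.
#' @param w,d,alpha,N,mu,k model parameters.
#' @return list with `nu` and `lambda`.
#' @export
solve_nu <- function(tau_obs, w, d, alpha, N, mu, k = 1) {
  stopifnot(mu > 0, N > 0, tau_obs > 0)
  tau0 <- log(2) / (mu * k)
  if (tau_obs < tau0 * (1 - 1e-12))
    stop("infeasible: observed half-life below the unprotected minimum ",
         format(tau0), " s")
  f <- function(lam) log(2) * (1 + d * lam) * exp(w * lam) / (mu * k) - tau_obs
  if (tau_obs <= tau0) {
    lam <- 0
  } else {
    hi <- 1
    while (f(hi) < 0) hi <- hi * 2
    lam <- stats::uniroot(f, c(0, hi), tol = 1e-14)$root
  }
  list(nu = lam * (1 + alpha * N) / N, lambda = lam)
}
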