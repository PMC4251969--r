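#' State-dependent emission distributions
#'
#' Accelerometer counts within one activity state are modelled by a
#' state-dependent distribution whose mean is the state's PA-level
#' (mean counts per epoch). Three families are supported:
#' \describe{
#'   \item{`"pois"`}{Poisson with rate `lambda` (variance = mean).}
#'   \item{`"genpois"`}{Generalized Poisson (Joe & Zhu parameterization)
#'     with rate `theta > 0` and dispersion `phi` in `[0, 0.95)`; its pmf is
#'     \deqn{P(x) = \theta(\theta + \phi x)^{x-1} e^{-\theta - \phi x} / x!}
#'     with mean \eqn{\theta/(1-\phi)} and variance \eqn{\theta/(1-\phi)^3},
#'     so `phi > 0` gives overdispersion relative to Poisson.}
#'   \item{`"gauss"`}{Gaussian with mean `mu` and standard deviation
#'     `sigma > 0`; the continuous density is evaluated directly at the
#'     integer counts (no discreteness correction), as is standard for
#'     Gaussian HMMs on counts.}
#' }
#'
#' @param family one of `"pois"`, `"genpois"`, `"gauss"`.
#' @param ... named parameters of the family: `lambda` (pois);
#'   `theta`, `phi` (genpois); `mu`, `sigma` (gauss).
#' @return an object of class `emission_params`.
#' @examples
#' p <- emission_params("genpois", theta = 2, phi = 0.5)
#' emission_mean(p)  # 2 / (1 - 0.5) = 4
#' @export
emission_params <- function(family = c("pois", "genpois", "gauss"), ...) {
  family <- match.arg(family)
  pars <- list(...)
  need <- switch(family,
    pois    = "lambda",
    genpois = c("theta", "phi"),
    gauss   = c("mu", "sigma"))
  missing <- setdiff(need, names(pars))
  if (length(missing))
    stop(sprintf("family '%s' requires parameter(s): %s",
                 family, paste(missing, collapse = ", ")), call. = FALSE)
  obj <- structure(c(list(family = family), pars[need]),
                   class = "emission_params")
  validate_emission_params(obj)
  obj
}

validate_emission_params <- function(p) {
  stopifnot(inherits(p, "emission_params"))
  switch(p$family,
    pois = {
      if (!is.finite(p$lambda) || p$lambda <= 0)
        stop("Poisson rate 'lambda' must be > 0", call. = FALSE)
    },
    genpois = {
      if (!is.finite(p$theta) || p$theta <= 0)
        stop("generalized Poisson rate 'theta' must be > 0", call. = FALSE)
      if (!is.finite(p$phi) || p$phi < 0 || p$phi >= GENPOIS_PHI_MAX + 1e-12)
        stop(sprintf("generalized Poisson dispersion 'phi' must lie in [0, %g]",
                     GENPOIS_PHI_MAX), call. = FALSE)
    },
    gauss = {
      if (!is.finite(p$sigma) || p$sigma <= 0)
        stop("Gaussian 'sigma' must be > 0", call. = FALSE)
      if (!is.finite(p$mu)) stop("Gaussian 'mu' must be finite", call. = FALSE)
    })
  invisible(p)
}

# Dispersion cap and EM sigma floor; the cap keeps (theta + phi*x) bounded
# away from degeneracy during optimization, the floor prevents a Gaussian
# state collapsing onto a single repeated count value.
GENPOIS_PHI_MAX <- 0.95
GAUSS_SIGMA_FLOOR <- 1.0

#' @export
print.emission_params <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat(sprintf("<emission_params %s: %s>\n", x$family,
              paste(sprintf("%s=%.4g", names(pars), unlist(pars)),
                    collapse = ", ")))
  invisible(x)
}

#' Generalized Poisson probability mass function
#'
#' @param x vector of nonnegative integers.
#' @param theta rate parameter, `> 0`.
#' @param phi dispersion parameter in `[0, 0.95]`; `phi = 0` recovers the
#'   Poisson distribution with rate `theta`.
#' @param log if `TRUE`, return log-probabilities.
#' @return vector of (log-)probabilities, same length as `x`.
#' @export
dgenpois <- function(x, theta, phi, log = FALSE) {
  if (theta <= 0) stop("'theta' must be > 0", call. = FALSE)
  if (phi < 0 || phi > GENPOIS_PHI_MAX)
    stop(sprintf("'phi' must lie in [0, %g]", GENPOIS_PHI_MAX), call. = FALSE)
  if (any(x < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(x != floor(x))) stop("counts must be integers", call. = FALSE)
  lp <- log(theta) + (x - 1) * log(theta + phi * x) - theta - phi * x -
    lgamma(x + 1)
  if (log) lp else exp(lp)
}

#' Log-density of an emission distribution at observed counts
#'
#' @param params an [emission_params()] object.
#' @param x numeric vector of observed counts (nonnegative; integer-valued
#'   for the count families, real-valued allowed for `"gauss"`).
#' @return vector of log-densities.
#' @export
emission_log_prob <- function(params, x) {
  validate_emission_params(params)
  if (any(!is.finite(x))) stop("counts must be finite", call. = FALSE)
  if (params$family != "gauss") {
    if (any(x < 0)) stop("counts must be nonnegative", call. = FALSE)
    if (any(x != floor(x)))
      stop("counts must be integers for count families", call. = FALSE)
  }
  switch(params$family,
    pois    = dpois(x, params$lambda, log = TRUE),
    genpois = dgenpois(x, params$theta, params$phi, log = TRUE),
    gauss   = dnorm(x, params$mu, params$sigma, log = TRUE))
}

#' Mean of an emission distribution (the state's PA-level)
#'
#' @param params an [emission_params()] object.
#' @return the distribution mean in counts per epoch.
#' @export
emission_mean <- function(params) {
  validate_emission_params(params)
  switch(params$family,
    pois    = params$lambda,
    genpois = params$theta / (1 - params$phi),
    gauss   = params$mu)
}

#' Weighted maximum-likelihood update of emission parameters
#'
#' The M-step of Baum-Welch: given observations and nonnegative weights
#' (state posteriors), return the parameters maximizing the weighted
#' log-likelihood. Poisson and Gaussian have closed forms (weighted mean;
#' weighted mean and sd with divisor `sum(w)`). The generalized Poisson has
#' none: it is maximized numerically over `(theta, phi)` from a
#' method-of-moments start, with a bounded grid refinement as fallback.
#'
#' @param family emission family identifier.
#' @param x observations (within the family domain).
#' @param w nonnegative weights, `sum(w) > 0`.
#' @param start optional `emission_params` used to warm-start the numeric
#'   genpois maximization.
#' @return an [emission_params()] object. If the weighted variance is
#'   degenerate the Gaussian sd is clamped to a floor of 1 count and the
#'   result carries attribute `clamped = TRUE`.
#' @export
weighted_mstep <- function(family, x, w, start = NULL) {
  if (length(x) != length(w)) stop("x and w must have equal length", call. = FALSE)
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  sw <- sum(w)
  if (!is.finite(sw) || sw <= 0) stop("sum of weights must be > 0", call. = FALSE)
  mu <- sum(w * x) / sw
  switch(family,
    pois = emission_params("pois", lambda = max(mu, 1e-8)),
    gauss = {
      v <- sum(w * (x - mu)^2) / sw
      clamped <- !is.finite(v) || v < GAUSS_SIGMA_FLOOR^2
      s <- if (clamped) GAUSS_SIGMA_FLOOR else sqrt(v)
      out <- emission_params("gauss", mu = mu, sigma = s)
      attr(out, "clamped") <- clamped
      out
    },
    genpois = genpois_mstep(x, w, mu, start),
    stop(sprintf("unknown family '%s'", family), call. = FALSE))
}

# Weighted genpois ML over (theta, phi). Observations are aggregated by
# unique value first: the weighted log-likelihood only depends on
# (value, total weight) pairs, which makes the inner optimization O(#unique).
genpois_mstep <- function(x, w, mu, start = NULL) {
  keep <- w > 0
  agg <- rowsum(w[keep], group = x[keep])
  xs <- as.numeric(rownames(agg))
  ws <- agg[, 1L]
  sw <- sum(ws)
  v <- sum(ws * (xs - mu)^2) / sw
  # method of moments: var/mean = (1-phi)^-2
  phi0 <- if (v > mu) 1 - sqrt(mu / v) else 0
  phi0 <- min(max(phi0, 0), GENPOIS_PHI_MAX)
  theta0 <- max(mu * (1 - phi0), 1e-6)
  if (!is.null(start) && identical(start$family, "genpois")) {
    theta0 <- start$theta
    phi0 <- start$phi
  }
  negll <- function(par) {
    th <- par[1]; ph <- par[2]
    -sum(ws * (log(th) + (xs - 1) * log(th + ph * xs) - th - ph * xs))
  }
  fit <- tryCatch(
    optim(c(theta0, phi0), negll, method = "L-BFGS-B",
          lower = c(1e-6, 0), upper = c(Inf, GENPOIS_PHI_MAX),
          control = list(maxit = 100)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) {
    # coarse grid refine around the moment estimate
    phis <- seq(0, GENPOIS_PHI_MAX, length.out = 40)
    thetas <- mu * (1 - phis)
    thetas[thetas <= 0] <- 1e-6
    vals <- vapply(seq_along(phis),
                   function(i) negll(c(thetas[i], phis[i])), numeric(1))
    i <- which.min(vals)
    return(emission_params("genpois", theta = thetas[i], phi = phis[i]))
  }
  emission_params("genpois", theta = fit$par[1], phi = fit$par[2])
}

#' Draw random counts from an emission distribution
#'
#' Generalized Poisson variates are drawn by the branching
#' (Galton-Watson/Borel) representation: the total progeny of a Poisson(theta)
#' founder generation with Poisson(phi) offspring has the GP(theta, phi) law.
#'
#' @param n number of draws.
#' @param params an [emission_params()] object.
#' @return numeric vector of counts.
#' @export
emission_rand <- function(n, params) {
  validate_emission_params(params)
  switch(params$family,
    pois  = rpois(n, params$lambda),
    gauss = rnorm(n, params$mu, params$sigma),
    genpois = {
      x <- rpois(n, params$theta)
      if (params$phi > 0) {
        gen <- x
        while (any(gen > 0)) {
          off <- vapply(gen, function(g)
            if (g > 0) sum(rpois(g, params$phi)) else 0L, numeric(1))
          x <- x + off
          gen <- off
        }
      }
      x
    })
}
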