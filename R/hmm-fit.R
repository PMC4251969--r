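#' Log-likelihood of a count series under an HMM
#'
#' Computed by the scaled forward recursion (per-epoch normalization with a
#' per-epoch log-shift), which is exact in log-likelihood and does not
#' underflow for series of typical day length.
#'
#' @param model an [hmm_model()].
#' @param x numeric count vector or a [count_series()].
#' @return the log-likelihood (sum over all `m^T` state paths).
#' @export
log_likelihood <- function(model, x) {
  x <- as_counts(x)
  res <- .hmm_forward_cpp(as_logmat(model, x), model$delta, model$gamma)
  if (!is.finite(res$loglik))
    stop(sprintf("zero emission likelihood at epoch %d (impossible observation)",
                 res$bad_t), call. = FALSE)
  res$loglik
}

#' AIC and BIC of a fitted HMM
#'
#' The free-parameter count is `p = (m-1) + m(m-1) + m*k`, i.e. the initial
#' probabilities, the transition matrix rows and `k` emission parameters per
#' state (`k = 1` for Poisson, `k = 2` for generalized Poisson and Gaussian).
#' Counting the `m - 1` initial probabilities as free parameters is a
#' documented convention of this package; it shifts AIC/BIC of all candidate
#' models by the same rule and so does not affect model ranking within a
#' family.
#'
#' @param logL maximized log-likelihood.
#' @param m number of states.
#' @param family emission family identifier.
#' @param T_len series length.
#' @return named vector `c(aic = ..., bic = ...)`.
#' @export
information_criteria <- function(logL, m, family, T_len) {
  stopifnot(T_len >= 1, m >= 1)
  k <- switch(family, pois = 1L, genpois = 2L, gauss = 2L,
              stop(sprintf("unknown family '%s'", family), call. = FALSE))
  p <- (m - 1L) + m * (m - 1L) + m * k
  c(aic = -2 * logL + 2 * p, bic = -2 * logL + p * log(T_len))
}

# Data-driven initialization: emission means at equally spaced quantiles,
# near-diagonal transitions, uniform start. `jitter_sd` (relative) perturbs
# the quantile means for EM restarts.
init_model <- function(x, m, family, jitter_sd = 0) {
  probs <- (seq_len(m) - 0.5) / m
  mu0 <- as.numeric(quantile(x, probs, names = FALSE))
  if (jitter_sd > 0)
    mu0 <- mu0 * exp(rnorm(m, 0, jitter_sd))
  mu0 <- sort(mu0)
  # hard-assign each epoch to its nearest initial mean
  grp <- max.col(-abs(outer(x, mu0, "-")), ties.method = "first")
  params <- vector("list", m)
  for (i in seq_len(m)) {
    xi <- x[grp == i]
    if (length(xi) < 2L) xi <- x[order(abs(x - mu0[i]))[1:2]]
    w <- rep(1, length(xi))
    params[[i]] <- switch(family,
      pois = emission_params("pois", lambda = max(mean(xi), 1e-8)),
      gauss = weighted_mstep("gauss", xi, w),
      genpois = weighted_mstep("genpois", xi, w))
  }
  gam <- matrix((1 - 0.9) / (m - 1 + (m == 1)), m, m)
  diag(gam) <- if (m == 1) 1 else 0.9
  hmm_model(delta = rep(1 / m, m), gamma = gam, params = params)
}

fit_result <- function(model, logL, T_len, n_iter, converged,
                       failure_reason = NULL, trace = NULL) {
  ic <- if (is.null(model) || !is.finite(logL)) c(aic = NA_real_, bic = NA_real_)
        else information_criteria(logL, model$m, model$family, T_len)
  structure(list(model = model, log_likelihood = logL,
                 aic = unname(ic["aic"]), bic = unname(ic["bic"]),
                 n_iter = n_iter, converged = converged,
                 failure_reason = failure_reason, trace = trace),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  if (is.null(x$model)) {
    cat(sprintf("<hmm_fit: FAILED (%s)>\n", x$failure_reason))
    return(invisible(x))
  }
  cat(sprintf("<hmm_fit: m=%d %s, logL=%.2f, AIC=%.1f, BIC=%.1f, %d iter%s>\n",
              x$model$m, x$model$family, x$log_likelihood, x$aic, x$bic,
              x$n_iter,
              if (x$converged) "" else sprintf(" [NOT CONVERGED: %s]",
                                              x$failure_reason)))
  invisible(x)
}

#' Fit an HMM by the Baum-Welch (EM) algorithm
#'
#' Alternates a scaled forward-backward E-step with weighted
#' maximum-likelihood M-steps until the log-likelihood changes by less than
#' `tol`. The log-likelihood is nondecreasing across iterations; numerical
#' failures (underflow, degenerate states) are trapped and returned as a
#' non-converged fit rather than an error, since instability is an expected
#' outcome for some series (notably under generalized Poisson emissions).
#'
#' @param x numeric count vector or [count_series()].
#' @param m number of hidden states.
#' @param family emission family: `"pois"`, `"genpois"` or `"gauss"`.
#' @param init an [hmm_model()] used as starting point, or `NULL` for the
#'   quantile-based automatic initialization.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter maximum EM iterations.
#' @param seed optional integer seed (only used by the jittered automatic
#'   initialization).
#' @param jitter_sd relative jitter applied to the automatic initial means
#'   (used for restarts).
#' @return an object of class `hmm_fit` with elements `model`,
#'   `log_likelihood`, `aic`, `bic`, `n_iter`, `converged`,
#'   `failure_reason` and the iteration `trace` of log-likelihoods. States
#'   of the returned model are sorted by emission mean.
#' @export
baum_welch <- function(x, m, family = c("pois", "genpois", "gauss"),
                       init = NULL, tol = 1e-4, max_iter = 500L,
                       seed = NULL, jitter_sd = 0) {
  family <- match.arg(family)
  x <- as_counts(x)
  T_len <- length(x)
  if (T_len <= m) stop("series length must exceed the number of states",
                       call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  model <- tryCatch(
    if (is.null(init)) init_model(x, m, family, jitter_sd) else init,
    error = function(e) e)
  if (inherits(model, "error"))
    return(fit_result(NULL, NA_real_, T_len, 0L, FALSE,
                      paste("initialization failed:",
                            conditionMessage(model))))
  ll_old <- -Inf
  trace <- numeric(0)
  out <- tryCatch({
    repeat_result <- NULL
    for (iter in seq_len(max_iter)) {
      es <- .hmm_estep_cpp(as_logmat(model, x), model$delta, model$gamma)
      if (!is.finite(es$loglik)) {
        repeat_result <- fit_result(NULL, NA_real_, T_len, iter, FALSE,
                                    "numerical instability", trace)
        break
      }
      trace <- c(trace, es$loglik)
      if (is.finite(ll_old) && abs(es$loglik - ll_old) < tol) {
        repeat_result <- fit_result(canonicalize_states(model), es$loglik,
                                    T_len, iter, TRUE, NULL, trace)
        break
      }
      ll_old <- es$loglik
      u <- es$posterior
      xi <- es$xi_sum
      delta <- pmax(u[1L, ], 0)
      delta <- delta / sum(delta)
      rs <- rowSums(xi)
      gam <- model$gamma
      for (i in seq_len(m))
        if (rs[i] > 0) gam[i, ] <- xi[i, ] / rs[i]
      params <- vector("list", m)
      for (i in seq_len(m)) {
        if (sum(u[, i]) <= T_len * 1e-12)
          stop("state posterior mass vanished", call. = FALSE)
        params[[i]] <- weighted_mstep(family, x, u[, i],
                                      start = model$params[[i]])
      }
      model <- hmm_model(delta, gam, params, canonical = FALSE)
    }
    if (is.null(repeat_result))
      repeat_result <- fit_result(canonicalize_states(model), ll_old, T_len,
                                  max_iter, FALSE,
                                  "maximum iterations reached", trace)
    repeat_result
  }, error = function(e)
    fit_result(NULL, NA_real_, T_len, length(trace), FALSE,
               paste("numerical instability:", conditionMessage(e)), trace))
  out
}

# --- direct numerical maximum likelihood -----------------------------------

# Pack an hmm_model into an unconstrained vector: multinomial logits for
# delta and each gamma row (first entry as reference), log/logit transforms
# for emission parameters.
pack_model <- function(model) {
  m <- model$m
  eps <- 1e-10
  logit_simplex <- function(p) {
    p <- pmax(p, eps); p <- p / sum(p)
    log(p[-1]) - log(p[1])
  }
  th <- c(logit_simplex(model$delta),
          unlist(lapply(seq_len(m),
                        function(i) logit_simplex(model$gamma[i, ]))))
  em <- unlist(lapply(model$params, function(p) switch(p$family,
    pois = log(p$lambda),
    gauss = c(p$mu, log(p$sigma)),
    genpois = c(log(p$theta),
                qlogis(min(max(p$phi / GENPOIS_PHI_MAX, eps), 1 - eps))))))
  c(th, em)
}

unpack_model <- function(par, m, family) {
  softmax <- function(a) {
    e <- exp(c(0, a) - max(0, a))
    e / sum(e)
  }
  i <- 0L
  take <- function(k) {
    out <- par[(i + 1L):(i + k)]
    i <<- i + k
    out
  }
  delta <- softmax(take(m - 1L + (m == 1L) * 0L))
  if (m == 1L) delta <- 1 # zero-length logit block
  gamma <- matrix(0, m, m)
  for (r in seq_len(m))
    gamma[r, ] <- if (m == 1L) 1 else softmax(take(m - 1L))
  params <- vector("list", m)
  for (s in seq_len(m)) {
    params[[s]] <- switch(family,
      pois = emission_params("pois", lambda = exp(take(1L))),
      gauss = {
        v <- take(2L)
        emission_params("gauss", mu = v[1], sigma = exp(v[2]))
      },
      genpois = {
        v <- take(2L)
        emission_params("genpois", theta = exp(v[1]),
                        phi = plogis(v[2]) * GENPOIS_PHI_MAX)
      })
  }
  hmm_model(delta, gamma, params, canonical = FALSE)
}

#' Fit an HMM by direct numerical maximization of the likelihood
#'
#' Maximizes the forward log-likelihood over logit/log-transformed
#' parameters with BFGS, as an alternative to [baum_welch()]. Both routes
#' reach the same optimum on well-behaved series; EM is more robust far from
#' the optimum, direct maximization converges faster near it.
#'
#' @inheritParams baum_welch
#' @return an `hmm_fit` object (see [baum_welch()]).
#' @export
direct_ml <- function(x, m, family = c("pois", "genpois", "gauss"),
                      init = NULL, seed = NULL, max_iter = 500L) {
  family <- match.arg(family)
  x <- as_counts(x)
  T_len <- length(x)
  if (T_len <= m) stop("series length must exceed the number of states",
                       call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  model0 <- if (is.null(init)) init_model(x, m, family) else init
  if (m == 1L) {
    # single state: transition structure is trivial, emissions are the
    # closed-form (or 1-D numeric) sample ML
    params <- list(weighted_mstep(family, x, rep(1, T_len)))
    model <- hmm_model(1, matrix(1, 1, 1), params)
    ll <- log_likelihood(model, x)
    return(fit_result(model, ll, T_len, 1L, TRUE))
  }
  negll <- function(par) {
    mod <- tryCatch(unpack_model(par, m, family), error = function(e) NULL)
    if (is.null(mod)) return(1e12)
    res <- .hmm_forward_cpp(as_logmat(mod, x), mod$delta, mod$gamma)
    if (!is.finite(res$loglik)) 1e12 else -res$loglik
  }
  opt <- tryCatch(
    optim(pack_model(model0), negll, method = "BFGS",
          control = list(maxit = max_iter, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e11)
    return(fit_result(NULL, NA_real_, T_len, 0L, FALSE,
                      "optimizer failure"))
  model <- canonicalize_states(unpack_model(opt$par, m, family))
  fit_result(model, -opt$value, T_len, opt$counts[["function"]],
             opt$convergence == 0,
             if (opt$convergence != 0) "optimizer did not converge")
}

# --- model-order selection --------------------------------------------------

# AIC/BIC disagreement rule: when the two criteria prefer different numbers
# of states, take the smaller model.
resolve_selection <- function(ms, aics, bics, criterion) {
  switch(criterion,
    aic = ms[which.min(aics)],
    bic = ms[which.min(bics)],
    parsimony = min(ms[which.min(aics)], ms[which.min(bics)]))
}

#' Select the number of hidden activities by AIC/BIC
#'
#' Fits one HMM per candidate number of states (best of `restarts` jittered
#' initializations each) and returns the fit preferred by the chosen
#' criterion. The default `"parsimony"` rule uses both criteria and opts for the
#' smaller number of states when AIC and BIC disagree, i.e. it prefers the
#' more parsimonious model. Non-converged fits are excluded from selection
#' but reported in the attached selection table.
#'
#' @inheritParams baum_welch
#' @param m_range candidate numbers of states (default `2:6`).
#' @param criterion `"parsimony"` (AIC/BIC with prefer-fewer on disagreement),
#'   `"aic"` or `"bic"`.
#' @param restarts number of jittered initializations per candidate `m`.
#' @param method `"baum_welch"` or `"direct_ml"`.
#' @param ... passed on to the fitting routine.
#' @return the selected `hmm_fit`, with attribute `selection`: a data frame
#'   of `m`, `logL`, `aic`, `bic`, `converged`, `failure_reason` for every
#'   candidate.
#' @export
select_model <- function(x, family = c("pois", "genpois", "gauss"),
                         m_range = 2:6, criterion = c("parsimony", "aic", "bic"),
                         restarts = 3L, seed = NULL,
                         method = c("baum_welch", "direct_ml"), ...) {
  family <- match.arg(family)
  criterion <- match.arg(criterion)
  method <- match.arg(method)
  x <- as_counts(x)
  if (!length(m_range)) stop("m_range must be non-empty", call. = FALSE)
  if (max(m_range) >= length(x))
    stop("largest candidate m must be below the series length", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fits <- vector("list", length(m_range))
  for (k in seq_along(m_range)) {
    m <- m_range[k]
    best <- NULL
    for (r in seq_len(max(restarts, 1L))) {
      f <- if (method == "baum_welch")
        baum_welch(x, m, family, jitter_sd = if (r == 1L) 0 else 0.15, ...)
      else
        direct_ml(x, m, family, ...)
      if (is.null(best) ||
          (f$converged && (!best$converged ||
                           f$log_likelihood > best$log_likelihood)))
        best <- f
      if (!f$converged && r == 1L) next
    }
    fits[[k]] <- best
  }
  tab <- data.frame(
    m = m_range,
    logL = vapply(fits, function(f) f$log_likelihood, numeric(1)),
    aic = vapply(fits, function(f) f$aic %||% NA_real_, numeric(1)),
    bic = vapply(fits, function(f) f$bic %||% NA_real_, numeric(1)),
    converged = vapply(fits, function(f) isTRUE(f$converged), logical(1)),
    failure_reason = vapply(fits, function(f)
      f$failure_reason %||% "", character(1)))
  ok <- tab$converged
  if (!any(ok))
    stop(paste0("no candidate model converged: ",
                paste(sprintf("m=%d (%s)", tab$m, tab$failure_reason),
                      collapse = "; ")), call. = FALSE)
  m_sel <- resolve_selection(tab$m[ok], tab$aic[ok], tab$bic[ok], criterion)
  out <- fits[[match(m_sel, m_range)]]
  attr(out, "selection") <- tab
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
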