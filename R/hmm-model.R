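#' Construct a hidden Markov model for count time series
#'
#' A homogeneous finite-state HMM is fully described by the initial state
#' probabilities `delta`, the transition matrix `gamma` and one
#' state-dependent emission distribution per state (all of the same family).
#' Each state represents one activity; its emission mean is the activity's
#' PA-level in counts per epoch.
#'
#' @param delta initial-probability vector of length `m` (nonnegative,
#'   sums to 1).
#' @param gamma `m x m` transition matrix, each row a probability vector.
#' @param params list of `m` [emission_params()] objects, one family for all
#'   states.
#' @param canonical if `TRUE` (default), states are relabelled so emission
#'   means are nondecreasing; this fixes the label-switching ambiguity.
#' @return an object of class `hmm_model`.
#' @examples
#' m <- hmm_model(delta = c(.5, .5),
#'                gamma = matrix(c(.9, .1, .2, .8), 2, byrow = TRUE),
#'                params = list(emission_params("gauss", mu = 100, sigma = 20),
#'                              emission_params("gauss", mu = 600, sigma = 50)))
#' @export
hmm_model <- function(delta, gamma, params, canonical = TRUE) {
  m <- length(delta)
  gamma <- as.matrix(gamma)
  if (!is.list(params) || length(params) != m || nrow(gamma) != m ||
      ncol(gamma) != m)
    stop("delta, gamma and params imply inconsistent numbers of states",
         call. = FALSE)
  if (any(delta < -1e-12) || abs(sum(delta) - 1) > 1e-8)
    stop("delta must be a probability vector", call. = FALSE)
  if (any(gamma < -1e-12) || any(abs(rowSums(gamma) - 1) > 1e-8))
    stop("each row of gamma must be a probability vector", call. = FALSE)
  fams <- vapply(params, function(p) p$family, character(1))
  if (length(unique(fams)) != 1L)
    stop("all states must share one emission family", call. = FALSE)
  lapply(params, validate_emission_params)
  obj <- structure(list(m = m, delta = as.numeric(delta), gamma = gamma,
                        params = params, family = fams[1L]),
                   class = "hmm_model")
  if (canonical) canonicalize_states(obj) else obj
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("<hmm_model: %d states, %s emissions>\n", x$m, x$family))
  cat("PA-levels (counts/epoch):",
      paste(sprintf("%.1f", state_means(x)), collapse = ", "), "\n")
  cat("transition diag:",
      paste(sprintf("%.3f", diag(x$gamma)), collapse = ", "), "\n")
  invisible(x)
}

#' State PA-levels of a model
#'
#' @param model an [hmm_model()].
#' @return numeric vector of the `m` emission means (counts/epoch).
#' @export
state_means <- function(model) {
  vapply(model$params, emission_mean, numeric(1))
}

# Relabel states so emission means are nondecreasing (canonical order).
canonicalize_states <- function(model) {
  ord <- order(state_means(model))
  if (identical(ord, seq_len(model$m))) return(model)
  model$delta <- model$delta[ord]
  model$gamma <- model$gamma[ord, ord, drop = FALSE]
  model$params <- model$params[ord]
  model
}

# T x m matrix of state-wise emission log-densities for a count series.
emission_logmat <- function(model, x) {
  vapply(model$params, function(p) emission_log_prob(p, x),
         numeric(length(x)))
}

as_logmat <- function(model, x) {
  lB <- emission_logmat(model, x)
  if (is.null(dim(lB))) lB <- matrix(lB, nrow = length(x))
  lB
}

#' Simulate a state path and counts from an HMM
#'
#' @param model an [hmm_model()].
#' @param T_len series length (epochs).
#' @return list with integer `states` and numeric `counts`, both length
#'   `T_len`.
#' @export
simulate_hmm <- function(model, T_len) {
  stopifnot(T_len >= 1)
  states <- integer(T_len)
  states[1] <- sample.int(model$m, 1L, prob = model$delta)
  for (t in seq_len(T_len - 1L))
    states[t + 1L] <- sample.int(model$m, 1L, prob = model$gamma[states[t], ])
  counts <- numeric(T_len)
  for (i in seq_len(model$m)) {
    idx <- which(states == i)
    if (length(idx))
      counts[idx] <- emission_rand(length(idx), model$params[[i]])
  }
  list(states = states, counts = counts)
}
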