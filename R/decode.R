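#' Decode the most likely activity sequence (global / Viterbi)
#'
#' Computes the single state path maximizing the joint probability of the
#' hidden states and the observed counts (global decoding). Ties are broken
#' toward the lower state index. Each decoded state is mapped to its
#' PA-level (the state's emission mean), which is the count-scale estimate
#' used downstream by the cutpoint assignment.
#'
#' @param model a trained [hmm_model()].
#' @param x numeric count vector or [count_series()].
#' @return an object of class `hmm_decoding`: list with integer `states`
#'   (in `1..m`), numeric `pa_levels` (counts/epoch) and `method`.
#' @export
viterbi <- function(model, x) {
  x <- as_counts(x)
  lB <- as_logmat(model, x)
  mx <- apply(lB, 1L, max)
  if (any(!is.finite(mx)))
    stop(sprintf("zero emission likelihood at epoch %d (impossible observation)",
                 which(!is.finite(mx))[1L]), call. = FALSE)
  states <- .hmm_viterbi_cpp(lB, model$delta, model$gamma)
  decoding(model, states, "global")
}

#' Decode activities locally from smoothed state posteriors
#'
#' For each epoch independently, picks the state maximizing the smoothed
#' posterior probability given the whole series (forward-backward). Unlike
#' [viterbi()], the resulting path may contain transitions of zero
#' probability.
#'
#' @inheritParams viterbi
#' @return an `hmm_decoding` (see [viterbi()]), `method = "local"`.
#' @export
local_decode <- function(model, x) {
  u <- state_posteriors(model, x)
  states <- max.col(u, ties.method = "first")
  decoding(model, states, "local")
}

#' Smoothed state posterior probabilities
#'
#' @inheritParams viterbi
#' @return a `T x m` matrix with rows summing to 1; entry `(t, i)` is
#'   `P(state_t = i | x_1..T)`.
#' @export
state_posteriors <- function(model, x) {
  x <- as_counts(x)
  es <- .hmm_estep_cpp(as_logmat(model, x), model$delta, model$gamma)
  if (!is.finite(es$loglik))
    stop(sprintf("zero emission likelihood at epoch %d (impossible observation)",
                 es$bad_t), call. = FALSE)
  es$posterior
}

decoding <- function(model, states, method) {
  structure(list(states = as.integer(states),
                 pa_levels = state_means(model)[states],
                 method = method),
            class = "hmm_decoding")
}

#' @export
print.hmm_decoding <- function(x, ...) {
  cat(sprintf("<hmm_decoding (%s): T=%d, states visited: %s>\n",
              x$method, length(x$states),
              paste(sort(unique(x$states)), collapse = ",")))
  invisible(x)
}
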