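# Brute-force HMM oracles by exhaustive path enumeration (feasible for
# m <= 3, T <= 8) and a random-instance generator for property tests.
# These are deliberately independent of the package's recursions.

all_paths <- function(m, T_len) {
  as.matrix(expand.grid(rep(list(seq_len(m)), T_len)))
}

bf_path_logjoint <- function(model, x) {
  paths <- all_paths(model$m, length(x))
  lB <- vapply(model$params, function(p) emission_log_prob(p, x),
               numeric(length(x)))
  apply(paths, 1L, function(s) {
    lp <- log(model$delta[s[1L]])
    if (length(s) > 1L)
      lp <- lp + sum(log(model$gamma[cbind(s[-length(s)], s[-1L])]))
    lp + sum(lB[cbind(seq_along(x), s)])
  })
}

bf_loglik <- function(model, x) {
  lj <- bf_path_logjoint(model, x)
  mx <- max(lj)
  mx + log(sum(exp(lj - mx)))
}

bf_viterbi <- function(model, x) {
  lj <- bf_path_logjoint(model, x)
  unname(all_paths(model$m, length(x))[which.max(lj), ])
}

bf_posterior <- function(model, x) {
  lj <- bf_path_logjoint(model, x)
  paths <- all_paths(model$m, length(x))
  w <- exp(lj - max(lj))
  w <- w / sum(w)
  T_len <- length(x)
  u <- matrix(0, T_len, model$m)
  for (t in seq_len(T_len))
    for (i in seq_len(model$m))
      u[t, i] <- sum(w[paths[, t] == i])
  u
}

random_simplex <- function(k) {
  p <- runif(k, 0.05, 1)
  p / sum(p)
}

random_model <- function(m, family = "gauss") {
  gamma <- t(vapply(seq_len(m), function(i) random_simplex(m), numeric(m)))
  params <- switch(family,
    gauss = lapply(seq_len(m), function(i)
      emission_params("gauss", mu = runif(1, 0, 20 * i), sigma = runif(1, 1, 6))),
    pois = lapply(seq_len(m), function(i)
      emission_params("pois", lambda = runif(1, 1, 10 * i))),
    genpois = lapply(seq_len(m), function(i)
      emission_params("genpois", theta = runif(1, 1, 5 * i),
                      phi = runif(1, 0, 0.6))))
  hmm_model(random_simplex(m), gamma, params, canonical = FALSE)
}

random_series <- function(model, T_len) {
  simulate_hmm(model, T_len)$counts
}

# small simulator config used by pipeline tests (shorter days, same
# structure as the default calibration)
test_sim_config <- function(seed = 1, epochs = 720L, n_days = 10L) {
  sim_config(n_days = n_days, epochs_per_day = epochs, seed = seed)
}
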