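test_that("forward likelihood, Viterbi and posteriors match exhaustive enumeration", {
  set.seed(101)
  for (rep in 1:40) {
    m <- sample(2:3, 1)
    T_len <- sample(2:8, 1)
    fam <- sample(c("gauss", "pois", "genpois"), 1)
    mod <- random_model(m, fam)
    x <- random_series(mod, T_len)
    expect_equal(log_likelihood(mod, x), bf_loglik(mod, x),
                 tolerance = 1e-9)
    expect_identical(viterbi(mod, x)$states, as.integer(bf_viterbi(mod, x)))
    expect_equal(state_posteriors(mod, x), bf_posterior(mod, x),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("single-state model reduces to iid emission likelihood", {
  p <- emission_params("gauss", mu = 5, sigma = 2)
  mod <- hmm_model(1, matrix(1, 1, 1), list(p))
  x <- c(4.2, 5.5, 6.1)
  expect_equal(log_likelihood(mod, x), sum(emission_log_prob(p, x)))
  expect_equal(viterbi(mod, x)$states, rep(1L, 3))
  expect_equal(local_decode(mod, x)$states, rep(1L, 3))
  expect_equal(viterbi(mod, x)$pa_levels, rep(5, 3))
})

test_that("likelihood is invariant to state relabelling", {
  set.seed(55)
  mod <- random_model(3, "gauss")
  x <- random_series(mod, 30)
  perm <- c(3, 1, 2)
  mod2 <- hmm_model(mod$delta[perm], mod$gamma[perm, perm],
                    mod$params[perm], canonical = FALSE)
  expect_equal(log_likelihood(mod, x), log_likelihood(mod2, x),
               tolerance = 1e-10)
  # decoded PA-level sequences agree even though labels differ
  expect_equal(viterbi(mod, x)$pa_levels, viterbi(mod2, x)$pa_levels)
})

test_that("posterior rows are probability vectors", {
  set.seed(77)
  mod <- random_model(3, "pois")
  x <- random_series(mod, 300)
  u <- state_posteriors(mod, x)
  expect_equal(rowSums(u), rep(1, 300), tolerance = 1e-10)
  expect_true(all(u >= 0))
})

test_that("Viterbi path dominates random alternative paths", {
  set.seed(31)
  mod <- random_model(3, "gauss")
  x <- random_series(mod, 50)
  lB <- sapply(mod$params, function(p) emission_log_prob(p, x))
  logjoint <- function(s)
    log(mod$delta[s[1]]) + sum(log(mod$gamma[cbind(s[-50], s[-1])])) +
      sum(lB[cbind(1:50, s)])
  best <- logjoint(viterbi(mod, x)$states)
  for (i in 1:1000)
    expect_gte(best, logjoint(sample(1:3, 50, replace = TRUE)))
})

test_that("well-separated states decode as nearest-mean assignment", {
  set.seed(13)
  mus <- c(100, 1000, 2000)
  mod <- hmm_model(rep(1 / 3, 3),
                   matrix(c(.9, .05, .05, .05, .9, .05, .05, .05, .9), 3,
                          byrow = TRUE),
                   lapply(mus, function(m)
                     emission_params("gauss", mu = m, sigma = 20)))
  x <- random_series(mod, 400)
  nearest <- apply(abs(outer(x, mus, "-")), 1, which.min)
  expect_identical(viterbi(mod, x)$states, as.integer(nearest))
})

test_that("Viterbi ties break toward the lower state index", {
  p <- emission_params("gauss", mu = 10, sigma = 3)
  mod <- hmm_model(c(.5, .5), matrix(.5, 2, 2), list(p, p),
                   canonical = FALSE)
  expect_equal(viterbi(mod, c(9, 11, 10))$states, rep(1L, 3))
})

test_that("impossible observations raise an epoch-indexed error", {
  mod <- hmm_model(c(.5, .5), matrix(c(.9, .1, .1, .9), 2, byrow = TRUE),
                   list(emission_params("pois", lambda = 2),
                        emission_params("pois", lambda = 4)))
  # dpois underflows to -Inf for astronomically large counts
  expect_error(log_likelihood(mod, c(2, 3, 1e308, 2)), "epoch 3")
})

test_that("information criteria use the documented parameter count", {
  ic <- information_criteria(0, 1, "pois", 10)
  expect_equal(unname(ic), c(2, log(10)))
  # m=4 Gaussian: 3 initial + 12 transition + 8 emission = 23 parameters
  ic4 <- information_criteria(-100, 4, "gauss", 1440)
  expect_equal(unname(ic4["aic"]), 200 + 2 * 23)
  expect_equal(unname(ic4["bic"]), 200 + 23 * log(1440))
  # both criteria strictly increase with model size at fixed logL
  aics <- sapply(1:6, function(m) information_criteria(-50, m, "genpois", 100)["aic"])
  bics <- sapply(1:6, function(m) information_criteria(-50, m, "genpois", 100)["bic"])
  expect_true(all(diff(aics) > 0))
  expect_true(all(diff(bics) > 0))
})
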