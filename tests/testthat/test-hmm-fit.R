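# 2-state Gaussian recovery fixture shared by several blocks
recovery_model <- function() {
  hmm_model(c(.5, .5),
            matrix(c(.95, .05, .05, .95), 2, byrow = TRUE),
            list(emission_params("gauss", mu = 100, sigma = 50),
                 emission_params("gauss", mu = 1000, sigma = 50)))
}

test_that("EM log-likelihood is nondecreasing for every family", {
  set.seed(21)
  for (fam in c("gauss", "pois", "genpois")) {
    mod <- random_model(2, fam)
    x <- random_series(mod, 300)
    f <- baum_welch(x, 2, fam)
    expect_true(f$converged, info = fam)
    expect_true(all(diff(f$trace) > -1e-8), info = fam)
    # canonical order: emission means sorted ascending
    expect_true(all(diff(state_means(f$model)) >= 0), info = fam)
  }
})

test_that("single-state EM equals the closed-form sample ML", {
  set.seed(22)
  x <- round(rnorm(400, 50, 8))
  f <- baum_welch(x, 1, "gauss")
  expect_equal(f$model$params[[1]]$mu, mean(x), tolerance = 1e-6)
  expect_equal(f$model$params[[1]]$sigma, sqrt(mean((x - mean(x))^2)),
               tolerance = 1e-6)
  expect_equal(f$log_likelihood,
               sum(dnorm(x, mean(x), sqrt(mean((x - mean(x))^2)), log = TRUE)),
               tolerance = 1e-6)
  xp <- rpois(300, 6)
  fp <- baum_welch(xp, 1, "pois")
  expect_equal(fp$model$params[[1]]$lambda, mean(xp), tolerance = 1e-6)
  expect_equal(fp$log_likelihood, sum(dpois(xp, mean(xp), log = TRUE)),
               tolerance = 1e-6)
})

test_that("Baum-Welch recovers a 2-state Gaussian HMM (20 seeds)", {
  rel_err_mu <- numeric(20)
  diag_err <- numeric(20)
  for (s in 1:20) {
    set.seed(1000 + s)
    x <- random_series(recovery_model(), 2000)
    f <- baum_welch(x, 2, "gauss")
    expect_true(f$converged)
    mus <- state_means(f$model)
    rel_err_mu[s] <- max(abs(mus - c(100, 1000)) / c(100, 1000))
    diag_err[s] <- max(abs(diag(f$model$gamma) - 0.95))
  }
  expect_lte(median(rel_err_mu), 0.10)
  expect_lte(median(diag_err), 0.05)
})

test_that("Baum-Welch recovers Poisson and generalized Poisson emissions", {
  for (fam in c("pois", "genpois")) {
    errs <- numeric(8)
    for (s in 1:8) {
      set.seed(2000 + s)
      params <- if (fam == "pois")
        list(emission_params("pois", lambda = 10),
             emission_params("pois", lambda = 60))
      else
        list(emission_params("genpois", theta = 6, phi = 0.3),
             emission_params("genpois", theta = 40, phi = 0.2))
      mod <- hmm_model(c(.5, .5), matrix(c(.95, .05, .05, .95), 2,
                                         byrow = TRUE), params)
      x <- random_series(mod, 2000)
      f <- baum_welch(x, 2, fam)
      expect_true(f$converged, info = fam)
      truth <- sapply(params, emission_mean)
      errs[s] <- max(abs(state_means(f$model) - truth) / truth)
    }
    expect_lte(median(errs), 0.10)
  }
})

test_that("direct ML agrees with Baum-Welch and improves on the truth", {
  set.seed(1234)
  truth <- recovery_model()
  x <- random_series(truth, 2000)
  f_em <- baum_welch(x, 2, "gauss")
  f_ml <- direct_ml(x, 2, "gauss")
  expect_true(f_ml$converged)
  expect_equal(f_ml$log_likelihood, f_em$log_likelihood, tolerance = 1e-2)
  # optimality: no worse than the generating parameters
  expect_gte(f_ml$log_likelihood, log_likelihood(truth, x) - 1e-6)
  # m = 1 reduces to closed-form ML
  f1 <- direct_ml(x, 1, "gauss")
  expect_equal(f1$model$params[[1]]$mu, mean(x), tolerance = 1e-8)
})

test_that("failed fits are reported, not raised", {
  set.seed(5)
  x <- rpois(50, 5)
  f <- baum_welch(x, 2, "pois", max_iter = 1)
  expect_false(f$converged)
  expect_match(f$failure_reason, "iterations")
  expect_s3_class(f, "hmm_fit")
})

test_that("model selection finds the true number of states", {
  # single-level data: BIC collapses to one state
  hits1 <- 0
  for (s in 1:10) {
    set.seed(300 + s)
    x <- round(rnorm(300, 500, 40))
    f <- select_model(x, "gauss", m_range = 1:4, criterion = "bic",
                      restarts = 1)
    hits1 <- hits1 + (f$model$m == 1)
  }
  expect_equal(hits1, 10)
  # four well-separated levels: selection recovers m = 4 in most runs
  mus <- c(100, 500, 1000, 1600)
  gen <- hmm_model(rep(.25, 4),
                   0.05 / 3 + diag(rep(0.95 - 0.05 / 3, 4)),
                   lapply(mus, function(m)
                     emission_params("gauss", mu = m, sigma = 40)))
  hits4 <- 0
  for (s in 1:10) {
    set.seed(400 + s)
    x <- random_series(gen, 600)
    f <- select_model(x, "gauss", m_range = 2:6, criterion = "parsimony",
                      restarts = 2)
    hits4 <- hits4 + (f$model$m == 4)
  }
  expect_gte(hits4, 8)
  # selection table is attached for every candidate
  tab <- attr(select_model(rnorm(200, 100, 10), "gauss", m_range = 2:3,
                           restarts = 1), "selection")
  expect_equal(tab$m, 2:3)
})

test_that("AIC/BIC disagreement resolves to the smaller model", {
  resolve <- actihmm:::resolve_selection
  ms <- 2:6
  aics <- c(10, 8, 6, 2, 4)   # AIC-best m = 5
  bics <- c(9, 5, 1, 3, 8)    # BIC-best m = 4
  expect_equal(resolve(ms, aics, bics, "parsimony"), 4)
  expect_equal(resolve(ms, aics, bics, "aic"), 5)
  expect_equal(resolve(ms, aics, bics, "bic"), 4)
  expect_equal(resolve(ms, bics, bics, "parsimony"), 4)
})
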