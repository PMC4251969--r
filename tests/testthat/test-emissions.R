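test_that("generalized Poisson pmf matches closed forms and reduces to Poisson", {
  # P(0) = exp(-theta) regardless of phi
  expect_equal(dgenpois(0, theta = 1, phi = 0.5, log = TRUE), -1)
  expect_equal(dgenpois(0, theta = 2.5, phi = 0.9, log = TRUE), -2.5)
  # phi = 0 is the Poisson pmf
  x <- 0:50
  expect_equal(dgenpois(x, theta = 3, phi = 0), dpois(x, 3),
               tolerance = 1e-12)
  expect_equal(dgenpois(2, theta = 3, phi = 0), 9 * exp(-3) / 2)
})

test_that("emission densities are normalized over their support", {
  expect_equal(sum(dgenpois(0:10000, theta = 2, phi = 0.3)), 1,
               tolerance = 1e-8)
  for (p in list(emission_params("pois", lambda = 7),
                 emission_params("genpois", theta = 5, phi = 0.5),
                 emission_params("genpois", theta = 1.2, phi = 0.05))) {
    tot <- sum(exp(emission_log_prob(p, 0:5000)))
    expect_equal(tot, 1, tolerance = 1e-6)
  }
  g <- emission_params("gauss", mu = 600, sigma = 80)
  expect_equal(
    integrate(function(v) exp(emission_log_prob(g, v)), -Inf, Inf)$value,
    1, tolerance = 1e-6)
})

test_that("emission means follow the family formulas", {
  expect_identical(emission_mean(emission_params("pois", lambda = 400)), 400)
  expect_equal(emission_mean(emission_params("genpois", theta = 2, phi = 0.5)), 4)
  expect_identical(emission_mean(emission_params("gauss", mu = 842, sigma = 50)),
                   842)
})

test_that("invalid parameters and domains are rejected", {
  expect_error(emission_params("gauss", mu = 0, sigma = 0), "sigma")
  expect_error(emission_params("genpois", theta = 0, phi = 0.2), "theta")
  expect_error(emission_params("genpois", theta = 1, phi = 1), "phi")
  expect_error(emission_params("pois", lambda = -1), "lambda")
  p <- emission_params("pois", lambda = 2)
  expect_error(emission_log_prob(p, -1), "nonnegative")
  expect_error(emission_log_prob(p, 1.5), "integer")
  expect_error(dgenpois(-1, 1, 0.1), "nonnegative")
  # Gaussian accepts real-valued observations
  expect_silent(emission_log_prob(emission_params("gauss", mu = 0, sigma = 1),
                                  c(-0.3, 2.7)))
})

test_that("generalized Poisson is overdispersed with the stated moments", {
  set.seed(42)
  th <- 4; ph <- 0.4
  x <- emission_rand(1e5, emission_params("genpois", theta = th, phi = ph))
  expect_equal(mean(x), th / (1 - ph), tolerance = 0.02)
  expect_equal(var(x), th / (1 - ph)^3, tolerance = 0.05)
  expect_gt(var(x), mean(x))
})

test_that("weighted M-step closed forms and equal-weight reduction", {
  expect_equal(weighted_mstep("pois", c(3, 5), c(1, 1))$lambda, 4)
  set.seed(7)
  x <- rnorm(200, 50, 9)
  w <- rep(1, 200)
  g <- weighted_mstep("gauss", x, w)
  expect_equal(g$mu, mean(x))
  expect_equal(g$sigma, sqrt(mean((x - mean(x))^2)))  # ML divisor n
  # equal weights equals unweighted ML regardless of the constant
  g2 <- weighted_mstep("gauss", x, rep(0.37, 200))
  expect_equal(g$mu, g2$mu)
  expect_equal(g$sigma, g2$sigma)
  # weighted means respond to the weights
  p <- weighted_mstep("pois", c(10, 20), c(3, 1))
  expect_equal(p$lambda, 12.5)
})

test_that("degenerate Gaussian variance is clamped to the sigma floor", {
  out <- weighted_mstep("gauss", rep(5, 10), rep(1, 10))
  expect_equal(out$sigma, 1)
  expect_true(attr(out, "clamped"))
})

test_that("genpois M-step recovers parameters and beats a grid-search oracle", {
  set.seed(11)
  truth <- emission_params("genpois", theta = 4, phi = 0.4)
  x <- emission_rand(500, truth)
  w <- rep(1, 500)
  est <- weighted_mstep("genpois", x, w)
  expect_equal(est$theta, 4, tolerance = 0.10)
  expect_equal(est$phi, 0.4, tolerance = 0.10)
  # independent coarse grid search over (theta, phi)
  ll <- function(th, ph) sum(dgenpois(x, th, ph, log = TRUE))
  grid <- expand.grid(theta = seq(2, 7, by = 0.05),
                      phi = seq(0, 0.9, by = 0.01))
  vals <- mapply(ll, grid$theta, grid$phi)
  expect_gte(ll(est$theta, est$phi), max(vals) - 1e-6)
})
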