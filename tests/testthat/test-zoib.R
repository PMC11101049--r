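test_that("zoib log-likelihood reproduces the mixture density pointwise", {
  # uniform beta: Beta(0.5; 1, 1) has density 1
  p <- list(gamma0 = NULL, gamma1 = NULL, beta = qlogis(0.5), delta = log(2))
  expect_equal(zoib_loglik(0.5, params = p, design = "null"), 0)
  # point mass at zero
  p0 <- list(gamma0 = qlogis(0.3), gamma1 = NULL, beta = 0, delta = 0)
  expect_equal(zoib_loglik(0, params = p0, design = "null"), log(0.3))
  # composed density oracle on random parameter and data draws
  set.seed(41)
  for (rep in 1:20) {
    y <- sample(c(0, 1, runif(5)), 1)
    g0 <- rnorm(2); g1 <- rnorm(2); b <- rnorm(2); d <- rnorm(1)
    x <- rnorm(1)
    ours <- zoib_loglik(y, x, list(gamma0 = g0, gamma1 = g1, beta = b, delta = d),
                        design = "linear")
    z <- c(1, x)
    expect_equal(ours, log(oracle_zoib_density(
      y, plogis(sum(z * g0)), plogis(sum(z * g1)),
      plogis(sum(z * b)), exp(d))), tolerance = 1e-12)
  }
  expect_error(zoib_loglik(1.2, params = p, design = "null"), "\\[0, 1\\]")
})

test_that("zoib density normalises to one by quadrature", {
  set.seed(43)
  for (rep in 1:5) {
    p0 <- runif(1, 0, 0.4); p1 <- runif(1, 0, 0.4)
    mu <- runif(1, 0.2, 0.8); phi <- runif(1, 1, 30)
    cont <- stats::integrate(function(v)
      (1 - p0) * (1 - p1) * dbeta(v, mu * phi, (1 - mu) * phi),
      0, 1, rel.tol = 1e-10)$value
    expect_equal(p0 + (1 - p0) * p1 + cont, 1, tolerance = 1e-8)
  }
})

test_that("interior-only data with constant covariate recover beta moments", {
  set.seed(47)
  y <- rbeta(400, 2, 5)                     # mu = 2/7
  f <- zoib_fit(y, design = "null")
  mu_hat <- plogis(f$par$beta[1])
  mu_mom <- mean(y)
  phi_mom <- mu_mom * (1 - mu_mom) / var(y) - 1
  expect_equal(mu_hat, mu_mom, tolerance = 1e-2)
  expect_equal(exp(f$par$delta), phi_mom, tolerance = 0.15)
  # ML solution is at least as good as the moment start
  expect_true(f$converged)
})

test_that("boundary values activate the point-mass parts and the fit succeeds", {
  set.seed(51)
  y <- c(rbeta(60, 5, 2), 1, 1, 0)          # relativised data contain an exact 1
  x <- rnorm(63)
  f <- zoib_fit(y, x, design = "linear")
  expect_true(f$has_one && f$has_zero)
  expect_true(is.finite(f$loglik))
  # likelihood at the solution beats the moment start by construction
  f0 <- zoib_fit(y, x, design = "null")
  expect_gte(f$loglik, f0$loglik - 1e-6)
})

test_that("delta-criterion selection follows the improvement rule", {
  apply_rule <- function(null, simple, quadratic, delta = 4) {
    crit <- c(simple = simple, quadratic = quadratic)
    best <- names(which.min(crit))
    if (crit[best] <= null - delta) best else "null"
  }
  expect_equal(apply_rule(100, 100, 100), "null")
  expect_equal(apply_rule(100, 90, 97), "simple")
  expect_equal(apply_rule(100, 97, 90), "quadratic")
  expect_equal(apply_rule(100, 96.5, 97), "null")

  # strong linear effect on the logit mean is detected
  set.seed(53)
  x <- runif(120, -1, 1)
  mu <- plogis(-0.3 + 2 * x)
  y <- rbeta(120, mu * 15, (1 - mu) * 15)
  ch <- select_zoib(y, x)
  expect_false(ch$chosen[ch$candidate == "null"])
  # and the same decision comes out of the DIC route
  chd <- select_zoib(y, x, criterion = "dic", seed = 5)
  expect_false(chd$chosen[chd$candidate == "null"])
})

test_that("parameter recovery at moderate size", {
  # single replicate sanity check; the full 200-replicate calibration runs
  # in the acceptance suite
  set.seed(57)
  n <- 500
  x <- runif(n, -2, 2)
  p0 <- 0.1
  mu <- plogis(0.5 + 1.0 * x)
  y <- ifelse(runif(n) < p0, 0, rbeta(n, mu * 20, (1 - mu) * 20))
  f <- zoib_fit(y, x, design = "linear")
  b <- f$par$beta
  # coefficients are on the internally scaled covariate
  slope <- b[2] / f$x_scale
  intercept <- b[1] - b[2] * f$x_center / f$x_scale
  expect_equal(intercept, 0.5, tolerance = 0.15)
  expect_equal(slope, 1.0, tolerance = 0.15)
  # zero-part likelihood factorises, so the fitted zero rate tracks the
  # empirical one, itself within binomial noise of the true 0.1
  expect_lt(abs(plogis(f$par$gamma0[1]) - 0.1), 0.045)
  expect_equal(exp(f$par$delta), 20, tolerance = 0.2)
})
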