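# Pure math of the survival models: predictor functions, survival and
# density functions, censored log-likelihood.

test_that("linear predictor is exp of the dot product", {
  expect_equal(linear_predictor(c(1, 3, -2), c(0, 0, 0)), 1.0)
  expect_equal(linear_predictor(1, log(2)), 2.0)
  expect_equal(linear_predictor(c(1, 0.5), c(0.1, -0.3)), exp(-0.05),
               tolerance = 1e-12)
  expect_error(linear_predictor(c(1, 2), c(1, 2, 3)), "lengths differ")
})

test_that("nn forward pass matches a layer-by-layer oracle", {
  # all-zero network: tanh(0) = 0, exp(0) = 1
  lay0 <- list(list(W = matrix(0, 4, 2), b = rep(0, 4)),
               list(W = matrix(0, 1, 4), b = 0))
  expect_equal(nn_forward(c(1.7, -0.3), lay0), 1.0)
  # zero final weights: output exp(b) regardless of input
  layb <- list(list(W = matrix(rnorm(8), 4, 2), b = rnorm(4)),
               list(W = matrix(0, 1, 4), b = 0.7))
  expect_equal(nn_forward(c(5, -5), layb), exp(0.7))
  expect_equal(nn_forward(c(0.1, 0.2), layb), exp(0.7))
  # random 2-4-1 network against explicit matrix arithmetic
  set.seed(42)
  W1 <- matrix(rnorm(8, sd = 0.5), 4, 2); b1 <- rnorm(4, sd = 0.5)
  W2 <- matrix(rnorm(4, sd = 0.5), 1, 4); b2 <- rnorm(1, sd = 0.5)
  x <- c(0.3, -1.2)
  a1 <- numeric(4)
  for (i in 1:4) {
    s <- b1[i]
    for (j in 1:2) s <- s + W1[i, j] * x[j]
    a1[i] <- tanh(s)
  }
  s2 <- b2[1]
  for (j in 1:4) s2 <- s2 + W2[1, j] * a1[j]
  oracle <- exp(s2)
  expect_equal(nn_forward(x, list(list(W = W1, b = b1),
                                  list(W = W2, b = b2))),
               oracle, tolerance = 1e-10)
  expect_error(nn_forward(c(1, 2, 3), lay0), "expects 2 inputs")
})

test_that("log survival follows the rate parameterization", {
  expect_equal(log_survival(0, lam = 2), 0.0)
  expect_equal(log_survival(0, lam = 2, kappa = 3,
                            distribution = "weibull"), 0.0)
  # at t = 1/lambda the Weibull exponent is 1 for any shape
  for (k in c(0.5, 1, 2, 5)) {
    expect_equal(log_survival(1 / 0.7, lam = 0.7, kappa = k,
                              distribution = "weibull"), -1.0,
                 tolerance = 1e-12)
  }
  expect_equal(log_survival(4, lam = 0.5, kappa = 2,
                            distribution = "weibull"), -4.0)
  expect_error(log_survival(-1, lam = 1), "non-negative")
})

test_that("survival probability is exp(log survival) and monotone", {
  expect_equal(survival_probability(0, lam = 3), 1.0)
  expect_equal(survival_probability(1, lam = 1), exp(-1), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:20) {
    lam <- runif(1, 0.1, 3); kap <- runif(1, 0.3, 4)
    tt <- sort(runif(50, 0, 10))
    s <- survival_probability(tt, lam, kap, "weibull")
    expect_true(all(diff(s) <= 1e-14))
    expect_equal(s, exp(log_survival(tt, lam, kap, "weibull")),
                 tolerance = 1e-12)
    expect_equal(event_probability(tt, lam, kap, "weibull") + s,
                 rep(1, 50), tolerance = 1e-12)
  }
})

test_that("event probability at t = 1/lambda is 63.2% for any shape", {
  for (k in c(0.5, 1, 1.8, 3)) {
    for (lam in c(0.2, 1, 5)) {
      expect_equal(
        event_probability(1 / lam, lam, k, "weibull"), 1 - exp(-1),
        tolerance = 1e-12)
    }
  }
  expect_equal(round(100 * (1 - exp(-1)), 1), 63.2)
})

test_that("censored log-likelihood sums density and survival terms", {
  set.seed(1)
  n <- 30
  tt <- rexp(n, 1); lam <- runif(n, 0.2, 2)
  all_cens <- survival_data(tt, rep(0, n), matrix(rnorm(n), n, 1))
  expect_equal(total_log_likelihood(all_cens, lam), sum(-lam * tt),
               tolerance = 1e-12)
  # Weibull with kappa = 1 is the exponential model
  ev <- rbinom(n, 1, 0.6)
  d <- survival_data(tt, ev, matrix(rnorm(n), n, 1))
  expect_equal(total_log_likelihood(d, lam, kappa = 1,
                                    distribution = "weibull"),
               total_log_likelihood(d, lam, distribution = "exponential"),
               tolerance = 1e-12)
  expect_error(total_log_likelihood(d, c(NaN, lam[-1])), "subject 1")
})

test_that("intercept-only exponential likelihood peaks at the censored MLE", {
  set.seed(3)
  n <- 80
  tt <- rexp(n, 0.7)
  ev <- rbinom(n, 1, 0.7)
  d <- survival_data(tt, ev, matrix(numeric(0), n, 0))
  mle <- sum(ev) / sum(tt)
  grid <- seq(0.05, 3, length.out = 2000)
  ll <- vapply(grid, function(l) total_log_likelihood(d, l), numeric(1))
  expect_equal(grid[which.max(ll)], mle, tolerance = 2e-3)
})

test_that("weibull median survival matches root-finding on S(t) = 1/2", {
  set.seed(11)
  for (i in 1:10) {
    lam <- runif(1, 0.2, 2); kap <- runif(1, 0.4, 3)
    m <- median_survival_time(lam, kap, "weibull")
    root <- uniroot(function(t)
      survival_probability(t, lam, kap, "weibull") - 0.5,
      c(1e-8, 1e4), tol = 1e-12)$root
    expect_equal(m, root, tolerance = 1e-7)
    expect_equal(m, log(2)^(1 / kap) / lam, tolerance = 1e-12)
  }
  expect_equal(median_survival_time(log(2)), 1.0)
})
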