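# Priors, sampling, diagnostics and posterior-predictive prediction.

test_that("default priors cover exactly the spec's parameters", {
  pr <- default_priors(bps_spec("exponential", "linear"), 3)
  expect_length(pr$mu, 4L)  # intercept + 3
  expect_true(all(pr$mu == 0) && all(pr$sd == 1))

  pr01 <- default_priors(bps_spec("exponential", "linear", prior_sd = 0.1),
                         3)
  expect_true(all(pr01$sd == 0.1))

  # weibull, intercept-only kappa, 2 features: 3 lambda + 1 kappa
  prw <- default_priors(bps_spec("weibull", "linear"), c("a", "b"))
  expect_length(prw$mu, 4L)
  expect_setequal(names(prw$mu),
                  c("lambda[(Intercept)]", "lambda[a]", "lambda[b]",
                    "kappa[(Intercept)]"))

  # covariate kappa doubles the coefficient blocks
  prc <- default_priors(bps_spec("weibull", "linear",
                                 kappa_mode = "covariate"), c("a", "b"))
  expect_length(prc$mu, 6L)
})

test_that("posterior_params_for delegates to the predictor functions", {
  spec <- bps_spec("exponential", "linear")
  fnames <- c("x1", "x2")
  draws <- rbind(c(0.2, -0.5, 0.9),
                 c(0, 0, 0),
                 c(1, 0.3, -0.2),
                 c(-0.4, 0.1, 0.6),
                 c(0.05, -1, 0.2))
  fit <- toy_fit(draws, spec, fnames)
  X <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, fnames))
  pars <- posterior_params_for(fit, X)
  # brute-force loop over (draw, subject) via the scalar primitive;
  # toy_fit duplicates draws over 2 chains
  for (s in 1:5) {
    for (j in 1:3) {
      expect_equal(pars$lam[s, j],
                   linear_predictor(c(1, X[j, ]), draws[s, ]),
                   tolerance = 1e-10)
    }
  }
  # all-zero coefficients give lambda = 1 everywhere
  expect_true(all(pars$lam[2, ] == 1))
  expect_error(posterior_params_for(fit, matrix(0, 2, 5)), "5 columns")
})

test_that("predict_survival summarizes draws exactly", {
  spec <- bps_spec("weibull", "linear")
  fnames <- "x1"
  set.seed(9)
  draws <- cbind(rnorm(100, 0, 0.3), rnorm(100, 0.5, 0.2),
                 rnorm(100, 0.2, 0.1))
  fit <- toy_fit(draws, spec, fnames)
  X <- matrix(c(-0.8, 1.2), 2, 1, dimnames = list(NULL, fnames))
  grid <- c(0, 0.5, 1, 2, 4)
  cur <- predict_survival(fit, X, grid)
  # t = 0: survival 1 with no uncertainty
  expect_equal(cur$mean[, 1], c(1, 1))
  expect_equal(cur$sd[, 1], c(0, 0))
  # independent double loop over draws and times (using duplicated chains)
  dd <- rbind(draws, draws)
  for (j in 1:2) {
    for (ti in seq_along(grid)) {
      vals <- numeric(nrow(dd))
      for (s in seq_len(nrow(dd))) {
        lam <- exp(dd[s, 1] + dd[s, 2] * X[j, 1])
        kap <- exp(dd[s, 3])
        vals[s] <- exp(-(lam * grid[ti])^kap)
      }
      expect_equal(cur$mean[j, ti], mean(vals), tolerance = 1e-12)
      expect_equal(cur$sd[j, ti], sd(vals), tolerance = 1e-12)
    }
  }
  # mean curves monotone non-increasing, bands clipped to [0, 1]
  expect_true(all(apply(cur$mean, 1, function(r) all(diff(r) <= 1e-12))))
  expect_true(all(cur$lower >= 0 & cur$upper <= 1))
  expect_error(predict_survival(fit, X, c(1, 0.5)), "sorted")

  # degenerate posterior: zero SD everywhere
  fit1 <- toy_fit(matrix(rep(c(0.1, 0.4, 0), 50), 50, 3, byrow = TRUE),
                  spec, fnames)
  cur1 <- predict_survival(fit1, X, grid)
  expect_true(all(cur1$sd == 0))
})

test_that("median survival draws follow the closed form", {
  spec <- bps_spec("exponential", "linear")
  fit <- toy_fit(matrix(log(log(2)), 10, 1), spec, character(0))
  med <- predict_median_survival(fit, matrix(numeric(0), 3, 0))
  expect_true(all(abs(med - 1) < 1e-12))
  specw <- bps_spec("weibull", "linear")
  fitw <- toy_fit(matrix(rep(c(log(0.5), log(2)), 10), 10, 2, byrow = TRUE),
                  specw, character(0))
  medw <- predict_median_survival(fitw, matrix(numeric(0), 1, 0))
  expect_equal(medw[1, 1], log(2)^(1 / 2) / 0.5, tolerance = 1e-12)
})

test_that("sampling is reproducible and tracks the censored MLE", {
  sim <- small_sim(300, seed = 21, coefficients = log(0.5))
  spec <- bps_spec("exponential", "linear", prior_sd = 10)
  f1 <- fit_fast(spec, sim$data, seed = 5)
  f2 <- fit_fast(spec, sim$data, seed = 5)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_fast(spec, sim$data, seed = 6)
  expect_false(identical(f1$draws, f3$draws))

  mle <- sum(sim$data$events) / sum(sim$data$times)
  post_lam <- mean(exp(bpsurv:::draw_matrix(f1)[, 1]))
  expect_lt(abs(post_lam / mle - 1), 0.05)
})

test_that("weibull shape concentrates near 1 on exponential data", {
  sim <- small_sim(400, seed = 33, coefficients = c(0, 0.6))
  fit <- fit_fast(bps_spec("weibull", "linear"), sim$data, seed = 2)
  kap_draws <- exp(bpsurv:::draw_matrix(fit)[, "kappa[(Intercept)]"])
  h <- hdi(kap_draws, 0.94)
  expect_true(h[1] <= 1 && 1 <= h[2])
})

test_that("with no informative data the posterior stays near the prior", {
  # a few heavily-censored subjects at tiny times carry almost no
  # information, so the posterior should essentially reproduce the prior
  d <- survival_data(rep(0.01, 5), rep(0, 5), matrix(numeric(0), 5, 0))
  fit <- suppressWarnings(bps_fit(bps_spec("exponential", "linear"), d,
                                  chains = 2, warmup = 400, draws = 600,
                                  seed = 4))
  post <- bpsurv:::draw_matrix(fit)[, 1]
  set.seed(1)
  prior_draws <- rnorm(length(post), 0, 1)
  expect_gte(overlap_index(post, prior_draws), 0.8)
})
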