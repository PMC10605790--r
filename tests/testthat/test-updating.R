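# Posterior-as-prior updating, partition streams, and the full-retrain vs
# update protocol.

test_that("posterior summaries become the next priors", {
  spec <- bps_spec("exponential", "linear")
  # exact mean 2, sd 0.5 by construction
  x <- scale(rnorm(400))[, 1] * 0.5 + 2
  fit <- toy_fit(cbind(x), spec, character(0))
  pr <- posterior_to_priors(fit)
  expect_equal(unname(pr$mu), 2, tolerance = 1e-12)
  expect_equal(unname(pr$sd), 0.5, tolerance = 1e-3)  # chain duplication
  pr2 <- posterior_to_priors(fit, widen = 2)
  expect_equal(unname(pr2$sd), 2 * unname(pr$sd), tolerance = 1e-12)
  expect_equal(pr2$mu, pr$mu)
  # degenerate posterior is refused
  fit0 <- toy_fit(matrix(1, 50, 1), spec, character(0))
  expect_error(posterior_to_priors(fit0), "degenerate")
})

test_that("updating refuses empty or mismatched new data", {
  sim <- small_sim(100, seed = 2)
  fit <- fit_fast(bps_spec("exponential", "linear"), sim$data)
  other <- survival_data(c(1, 2), c(1, 0),
                         cbind(z = c(0, 1)))
  expect_error(bps_update(fit, other), "do not match")
})

test_that("updating on the same data concentrates the posterior", {
  sim <- small_sim(200, seed = 8, coefficients = c(0.1, 0.7))
  spec <- bps_spec("exponential", "linear")
  fit1 <- fit_fast(spec, sim$data, seed = 1)
  fit2 <- suppressWarnings(bps_update(fit1, sim$data,
                                      chains = 2, warmup = 250,
                                      draws = 250, seed = 2))
  sd1 <- apply(bpsurv:::draw_matrix(fit1), 2, sd)
  sd2 <- apply(bpsurv:::draw_matrix(fit2), 2, sd)
  expect_true(all(sd2 < sd1))
  # roughly the sqrt(2) shrinkage expected from doubling the information
  expect_equal(unname(sd2 / sd1), rep(1 / sqrt(2), length(sd1)),
               tolerance = 0.25)
})

test_that("partition streams are disjoint, exhaustive and reproducible", {
  sim <- small_sim(100, seed = 3)
  p1 <- partition_stream(sim$data, 6, seed = 11)
  p2 <- partition_stream(sim$data, 6, seed = 11)
  expect_equal(sum(vapply(p1, n_subjects, integer(1))), 100L)
  expect_identical(lapply(p1, `[[`, "times"), lapply(p2, `[[`, "times"))
  all_times <- sort(unlist(lapply(p1, `[[`, "times")))
  expect_equal(all_times, sort(sim$data$times))
  expect_error(partition_stream(sim$data, 1), "between 2")
  tiny <- survival_data(1:5, rep(1, 5))
  expect_error(partition_stream(tiny, 6), "between 2")
})

test_that("year-based partitions are ordered by the year column", {
  n <- 60
  yr <- rep(2001:2003, each = 20)
  d <- survival_data(rexp(n) + 0.01, rbinom(n, 1, 0.7),
                     cbind(year = yr, x = rnorm(n)))
  parts <- partition_stream(d, 3, by = "year")
  expect_equal(vapply(parts, function(p) unique(p$covariates[, "year"]),
                      numeric(1)), c(2001, 2002, 2003))
  expect_error(partition_stream(d, 3, by = "enrollment"), "not found")
})

test_that("update protocol matches its definition and full mode grows data", {
  sim <- small_sim(240, seed = 5, coefficients = c(0, 0.8))
  spec <- bps_spec("exponential", "linear")
  full <- suppressWarnings(run_updating_experiment(
    sim$data, spec, 3, mode = "full_retrain", partition_seed = 7,
    chains = 2, warmup = 200, draws = 200, seed = 9))
  expect_equal(nrow(full), 2L)
  expect_equal(full$n_train, c(80L, 160L))
  upd <- suppressWarnings(run_updating_experiment(
    sim$data, spec, 3, mode = "update", partition_seed = 7,
    chains = 2, warmup = 200, draws = 200, seed = 9))
  expect_equal(upd$n_train, c(80L, 80L))
  # first step has no history: identical fits, identical C-index
  expect_equal(full$c_index[1], upd$c_index[1], tolerance = 1e-12)
  expect_true(all(full$c_index >= 0 & full$c_index <= 1))
})

test_that("update mode sees only the newest partition", {
  # privacy contract: the update path receives one partition's rows and
  # the previous model's summaries, nothing else
  sim <- small_sim(120, seed = 6)
  parts <- partition_stream(sim$data, 3, seed = 1)
  fit1 <- fit_fast(bps_spec("exponential", "linear"), parts[[1]], seed = 1)
  pr <- posterior_to_priors(fit1)
  # refit from the prior summaries alone reproduces bps_update exactly
  via_update <- suppressWarnings(bps_update(fit1, parts[[2]],
                                            chains = 2, warmup = 250,
                                            draws = 250, seed = 3))
  via_priors <- suppressWarnings(bps_fit(bps_spec("exponential", "linear"),
                                         parts[[2]], priors = pr,
                                         chains = 2, warmup = 250,
                                         draws = 250, seed = 3))
  expect_identical(via_update$draws, via_priors$draws)
})
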