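# Concordance index, normalization, feature ranking and CV tuning.

# quadratic-time reference implementation used as the independent oracle
cindex_brute <- function(times, events, risk) {
  conc <- 0; tot <- 0
  n <- length(times)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (events[i] == 1 && times[i] < times[j]) {
        tot <- tot + 1
        if (risk[i] > risk[j]) conc <- conc + 1
        else if (risk[i] == risk[j]) conc <- conc + 0.5
      }
    }
  }
  if (tot == 0) return(0.5)
  conc / tot
}

test_that("concordance index handles the canonical cases", {
  # perfectly anti-ordered risk, no censoring
  tt <- c(1, 2, 3, 4, 5)
  expect_equal(concordance_index(tt, rep(1, 5), rev(tt)), 1.0)
  expect_equal(concordance_index(tt, rep(1, 5), rep(0, 5)), 0.5)
  expect_equal(concordance_index(c(1, 2, 3, 4), c(1, 0, 1, 1),
                                 c(4, 1, 2, 3)), 0.75)
  expect_warning(ci <- concordance_index(tt, rep(0, 5), rev(tt)),
                 "no comparable")
  expect_equal(ci, 0.5)
})

test_that("concordance equals the brute-force oracle on random instances", {
  set.seed(10)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    tt <- sample(1:20, n, replace = TRUE)  # force tied times
    ev <- rbinom(n, 1, 0.7)
    rk <- sample(1:8, n, replace = TRUE)   # force tied risks
    if (sum(ev) == 0) ev[1] <- 1
    expect_equal(suppressWarnings(concordance_index(tt, ev, rk)),
                 suppressWarnings(cindex_brute(tt, ev, rk)),
                 tolerance = 1e-12)
  }
})

test_that("concordance agrees with the survival package on event-pairs", {
  set.seed(11)
  n <- 120
  tt <- rexp(n) + 0.01
  ev <- rbinom(n, 1, 0.6)
  rk <- rnorm(n)
  ours <- concordance_index(tt, ev, rk)
  ref <- survival::concordance(survival::Surv(tt, ev) ~ rk,
                               reverse = TRUE)$concordance
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("concordance is invariant under monotone transforms of risk", {
  set.seed(12)
  tt <- rexp(60) + 0.01; ev <- rbinom(60, 1, 0.7); rk <- rnorm(60)
  base <- concordance_index(tt, ev, rk)
  expect_equal(concordance_index(tt, ev, exp(rk)), base)
  expect_equal(concordance_index(tt, ev, 3 * rk - 10), base)
  expect_equal(concordance_index(tt, ev, rank(rk)), base)
})

test_that("random scores on random data score near one half", {
  set.seed(13)
  cis <- vapply(1:50, function(i) {
    tt <- rexp(200) + 0.01; ev <- rbinom(200, 1, 0.7)
    concordance_index(tt, ev, rnorm(200))
  }, numeric(1))
  expect_lt(abs(mean(cis) - 0.5), 0.05)
})

test_that("overfit gap is train minus test", {
  expect_equal(overfit_gap(0.80, 0.75), 0.05)
  expect_equal(overfit_gap(0.7, 0.7), 0)
  expect_lt(overfit_gap(0.6, 0.8), 0)
  expect_error(overfit_gap(1.2, 0.5))
})

test_that("normalizer uses training statistics only", {
  set.seed(14)
  Xtr <- cbind(age = rnorm(50, 60, 9), sex = rbinom(50, 1, 0.5))
  Xte <- cbind(age = rnorm(30, 40, 5), sex = rbinom(30, 1, 0.5))
  nm <- fit_normalizer(Xtr, c("continuous", "binary"))
  Ztr <- nm$apply(Xtr)
  expect_equal(mean(Ztr[, 1]), 0, tolerance = 1e-12)
  expect_equal(sd(Ztr[, 1]), 1, tolerance = 1e-12)
  expect_identical(Ztr[, 2], Xtr[, 2])  # binary untouched
  # test set transformed with train stats: its mean is NOT zero
  Zte <- nm$apply(Xte)
  expect_gt(abs(mean(Zte[, 1])), 0.5)
  # round trip
  expect_equal(nm$invert(Zte), Xte, tolerance = 1e-10)
  # mutating test rows cannot change the fitted transformer
  c0 <- nm$center
  Xte[, 1] <- Xte[, 1] * 100
  expect_identical(nm$center, c0)
  expect_warning(fit_normalizer(cbind(k = rep(2, 10)), "continuous"),
                 "zero-variance")
})

test_that("mutual-information ranking finds informative features", {
  set.seed(15)
  n <- 300
  tt <- rexp(n) + 0.01
  label_like <- as.numeric(tt > median(tt))
  X <- cbind(self = label_like, noise = rnorm(n), also_noise = rnorm(n))
  sel <- mi_kbest(X, tt, rep(1, n), k = 1)
  expect_identical(as.integer(sel[1]), 1L)
  sel_all <- mi_kbest(X, tt, rep(1, n), k = 3)
  expect_length(sel_all, 3L)
  expect_setequal(as.integer(sel_all), 1:3)
  expect_error(mi_kbest(X, tt, rep(1, n), k = 5), "in \\[1, 3\\]")
})

test_that("informative features outrank noise across simulations", {
  set.seed(16)
  wins <- 0L
  for (rep in 1:100) {
    n <- 200
    x_inf <- rnorm(n)
    tt <- rexp(n, rate = exp(0 + 1.2 * x_inf)) + 1e-6
    X <- cbind(inf = x_inf, noise = rnorm(n))
    sel <- mi_kbest(X, tt, rep(1, n), k = 1, seed = rep)
    if (sel[1] == 1L) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("train/test split is disjoint, sized and seeded", {
  sim <- small_sim(100, seed = 17)
  sp <- split_train_test(sim$data, 0.2, seed = 1)
  expect_equal(n_subjects(sp$train), 80L)
  expect_equal(n_subjects(sp$test), 20L)
  sp2 <- split_train_test(sim$data, 0.2, seed = 1)
  expect_identical(sp$test_idx, sp2$test_idx)
  sp3 <- split_train_test(sim$data, 0.2, seed = 2)
  expect_false(identical(sp$test_idx, sp3$test_idx))
  expect_error(split_train_test(survival_data(1:3, c(1, 1, 1))),
               "at least 5")
})

test_that("cv_tune scores configurations and picks the dominant one", {
  sim <- small_sim(150, seed = 18, coefficients = c(0, 1, 0),
                   distribution = "exponential")
  # scorer contract: k = 2 uses the informative covariate ranking, k = 1
  # is degraded to a constant scorer -> k = 2 must win
  scorer <- function(train, test_X, cfg) {
    if (cfg$k == 1) rep(0, nrow(test_X)) else test_X[, "x1"]
  }
  res <- cv_tune(sim$data, budget = 8, seed = 3, scorer = scorer,
                 k_bounds = c(1, 2))
  expect_true(all(c(1, 2) %in% res$trace$k))  # both arms explored
  expect_identical(res$best$k, 2L)
  expect_gt(res$best_score, 0.6)
  # a single-configuration space returns that configuration
  res1 <- cv_tune(sim$data, budget = 1, seed = 4, scorer = scorer,
                  k_bounds = c(2, 2), prior_sd_bounds = c(1, 1))
  expect_identical(res1$best$k, 2L)
  expect_equal(res1$best$prior_sd, 1)
  expect_equal(nrow(res1$trace), 1L)
})

test_that("cv_tune fits real models end to end on a small budget", {
  sim <- small_sim(120, seed = 19, coefficients = c(0, 1.2),
                   target_frac = 0.2)
  res <- suppressWarnings(
    cv_tune(sim$data, budget = 2, n_folds = 3, seed = 5,
            chains = 2, warmup = 150, draws = 150))
  expect_true(is.finite(res$best_score))
  expect_gt(res$best_score, 0.55)  # one strong covariate is detectable
})
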