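# Shared fixtures: small datasets built in code and reduced sampler
# settings so unit tests stay fast while exercising the full pipeline.

fast_sampler <- list(chains = 2L, warmup = 250L, draws = 250L)

fit_fast <- function(spec, data, seed = 1L, ...) {
  suppressWarnings(bps_fit(spec, data, chains = fast_sampler$chains,
                           warmup = fast_sampler$warmup,
                           draws = fast_sampler$draws, seed = seed, ...))
}

# deterministic toy posterior wrapped as a bps_fit, for tests of the
# prediction path that need exact control over the draws
toy_fit <- function(draw_mat, spec, feature_names) {
  lay <- bpsurv:::param_layout(spec, feature_names)
  stopifnot(ncol(draw_mat) == nrow(lay))
  n_draws <- nrow(draw_mat)
  arr <- array(NA_real_, dim = c(2L, n_draws, ncol(draw_mat)),
               dimnames = list(NULL, NULL, lay$name))
  arr[1, , ] <- draw_mat
  arr[2, , ] <- draw_mat
  structure(list(
    spec = spec, draws = arr,
    diagnostics = data.frame(parameter = lay$name, rhat = 1, ess = n_draws),
    priors = default_priors(spec, feature_names),
    feature_names = feature_names,
    feature_kinds = rep("continuous", length(feature_names)),
    n_subjects = 0L, n_events = 0L, seed = 0L,
    sampler = list(chains = 2L, warmup = 0L, draws = n_draws,
                   n_divergent = 0L),
    approximate_draws = FALSE
  ), class = "bps_fit")
}

small_sim <- function(n = 200, seed = 1, distribution = "exponential",
                      coefficients = c(0, 0.8), kappa = 1,
                      target_frac = 0.3) {
  simulate_survival(n, coefficients, distribution, kappa = kappa,
                    censoring = list(mode = "administrative",
                                     target_frac = target_frac),
                    seed = seed)
}
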