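#' Independent Normal priors for a model specification
#'
#' Builds the prior set used when training from scratch: Normal(0, prior_sd)
#' on every coefficient, weight and bias, with `prior_sd` taken from the
#' spec (default 1, a weakly-informative regularizing prior).
#'
#' @param spec A [bps_spec].
#' @param feature_names Character vector of covariate names (or an integer
#'   count, in which case names `x1..xp` are generated).
#' @return A `bps_priors` object: named vectors `mu` and `sd`, one entry per
#'   scalar parameter.
#' @examples
#' default_priors(bps_spec("exponential", "linear"), c("age", "sex"))
#' @export
default_priors <- function(spec, feature_names) {
  if (is.numeric(feature_names) && length(feature_names) == 1) {
    feature_names <- if (feature_names == 0) character(0) else
      paste0("x", seq_len(feature_names))
  }
  lay <- param_layout(spec, feature_names)
  mu <- stats::setNames(rep(0, nrow(lay)), lay$name)
  sd <- stats::setNames(rep(spec$prior_sd, nrow(lay)), lay$name)
  new_bps_priors(mu, sd)
}

new_bps_priors <- function(mu, sd) {
  stopifnot(length(mu) == length(sd), all(sd > 0),
            !is.null(names(mu)), identical(names(mu), names(sd)))
  structure(list(mu = mu, sd = sd), class = "bps_priors")
}

#' @export
print.bps_priors <- function(x, ...) {
  cat("<bps_priors> ", length(x$mu), " independent Normal priors\n", sep = "")
  df <- data.frame(parameter = names(x$mu), mu = unname(x$mu),
                   sd = unname(x$sd))
  print(utils::head(df, 10), row.names = FALSE)
  if (nrow(df) > 10) cat("... ", nrow(df) - 10, " more\n", sep = "")
  invisible(x)
}

#' Fit a Bayesian parametric survival model
#'
#' Samples the posterior of all coefficients with the package's No-U-Turn
#' sampler (dynamic Hamiltonian Monte Carlo with analytic gradients),
#' computes split-R-hat and effective-sample-size diagnostics, and returns
#' a `bps_fit` object carrying the draws, the spec and everything needed
#' for prediction and posterior-as-prior updating.
#'
#' @param spec A [bps_spec].
#' @param data A [survival_data] object.
#' @param priors A `bps_priors` object; defaults to
#'   `default_priors(spec, ...)`. Informative priors from a previous fit
#'   come from [posterior_to_priors()].
#' @param chains Number of independent chains (>= 2 for diagnostics).
#' @param warmup,draws Warmup (adaptation) and retained iterations per chain.
#' @param seed Integer seed; chain c uses `seed + c - 1`. Fixing it makes
#'   the draws bit-for-bit reproducible on the same platform.
#' @param target_accept Dual-averaging target acceptance statistic.
#' @param max_treedepth Doubling cap per iteration.
#'
#' @return A `bps_fit` object with elements `draws` (array
#'   chains x draws x parameters, named), `diagnostics` (per-parameter
#'   data frame with `rhat` and `ess`), `spec`, `priors`, `feature_names`,
#'   `seed`, `sampler` (config and divergence counts).
#' @export
bps_fit <- function(spec, data, priors = NULL, chains = 4L, warmup = 1000L,
                    draws = 1000L, seed = 1L, target_accept = 0.9,
                    max_treedepth = 10L) {
  stopifnot(inherits(spec, "bps_spec"), inherits(data, "survival_data"))
  if (length(data$times) == 0L) stop("no subjects to fit")
  if (chains < 2L) stop("at least 2 chains are required for diagnostics")
  if (sum(data$events) == 0L) {
    warning("no observed events: the likelihood only bounds survival ",
            "times from below; the posterior will track the prior")
  }
  if (is.null(priors)) priors <- default_priors(spec, data$feature_names)
  post_fn <- make_log_posterior(spec, data, priors)
  d <- post_fn$n_params

  chain_fits <- vector("list", chains)
  for (ch in seq_len(chains)) {
    ch_seed <- seed + ch - 1L
    set.seed(ch_seed)
    init <- post_fn$mu + 0.1 * post_fn$sigma * stats::rnorm(d)
    chain_fits[[ch]] <- nuts_chain(post_fn$lp_grad, init, warmup, draws,
                                   seed = ch_seed,
                                   target_accept = target_accept,
                                   max_treedepth = max_treedepth)
  }
  arr <- array(NA_real_, dim = c(chains, draws, d),
               dimnames = list(NULL, NULL, post_fn$layout$name))
  for (ch in seq_len(chains)) arr[ch, , ] <- chain_fits[[ch]]$draws

  diag_df <- data.frame(
    parameter = post_fn$layout$name,
    rhat = vapply(seq_len(d), function(j) split_rhat(t(arr[, , j])),
                  numeric(1)),
    ess = vapply(seq_len(d), function(j) ess_basic(t(arr[, , j])),
                 numeric(1)),
    stringsAsFactors = FALSE)
  n_div <- sum(vapply(chain_fits, function(f) f$n_divergent, integer(1)))
  bad <- diag_df$rhat > 1.01
  if (any(bad, na.rm = TRUE)) {
    warning("split R-hat > 1.01 for: ",
            paste(diag_df$parameter[which(bad)], collapse = ", "),
            " - consider more warmup/draws")
  }
  if (n_div > 0.01 * chains * draws) {
    warning(n_div, " divergent transitions after warmup adaptation")
  }

  structure(list(
    spec = spec, draws = arr, diagnostics = diag_df, priors = priors,
    feature_names = data$feature_names, feature_kinds = data$feature_kinds,
    n_subjects = length(data$times), n_events = sum(data$events),
    seed = as.integer(seed),
    sampler = list(chains = chains, warmup = warmup, draws = draws,
                   target_accept = target_accept,
                   max_treedepth = max_treedepth, n_divergent = n_div,
                   step_sizes = vapply(chain_fits, `[[`, numeric(1), "eps")),
    approximate_draws = FALSE
  ), class = "bps_fit")
}

#' @export
print.bps_fit <- function(x, ...) {
  cat("<bps_fit> ", x$spec$distribution, "/", x$spec$predictor,
      " model, ", dim(x$draws)[1], " chains x ", dim(x$draws)[2],
      " draws, ", dim(x$draws)[3], " parameters\n", sep = "")
  cat("  fitted on ", x$n_subjects, " subjects (", x$n_events,
      " events), seed ", x$seed, "\n", sep = "")
  cat("  max split R-hat ", round(max(x$diagnostics$rhat, na.rm = TRUE), 4),
      ", min ESS ", round(min(x$diagnostics$ess, na.rm = TRUE)),
      ", divergences ", x$sampler$n_divergent, "\n", sep = "")
  invisible(x)
}

#' Posterior summary of a fitted model
#'
#' @param object A `bps_fit`.
#' @param ... Unused.
#' @return Data frame with posterior mean, SD, 94% HDI bounds, split-R-hat
#'   and effective sample size per parameter.
#' @export
summary.bps_fit <- function(object, ...) {
  mat <- draw_matrix(object)
  df <- data.frame(
    parameter = colnames(mat),
    mean = colMeans(mat),
    sd = apply(mat, 2, stats::sd),
    stringsAsFactors = FALSE)
  h <- t(apply(mat, 2, function(x) hdi(x, 0.94)))
  df$hdi_3 <- h[, 1]; df$hdi_97 <- h[, 2]
  df$rhat <- object$diagnostics$rhat
  df$ess <- object$diagnostics$ess
  rownames(df) <- NULL
  df
}

# All chains stacked: (chains*draws) x parameters matrix.
draw_matrix <- function(fit) {
  dm <- dim(fit$draws)
  mat <- matrix(aperm(fit$draws, c(2, 1, 3)), nrow = dm[1] * dm[2],
                ncol = dm[3])
  colnames(mat) <- dimnames(fit$draws)[[3]]
  mat
}
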