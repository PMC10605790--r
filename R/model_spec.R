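#' Specify a Bayesian parametric survival model
#'
#' Chooses the survival-time distribution, the predictor function mapping
#' covariates to distribution parameters, and the prior scale. Three
#' canonical variants are used throughout: the Exponential model with linear
#' predictor, the Weibull model with linear predictor, and the Weibull model
#' with a feed-forward neural-network predictor.
#'
#' The Weibull is parameterized by a rate: S(t) = exp(-(lambda*t)^kappa),
#' i.e. lambda = 1/scale. `lambda` is always predicted from the covariates;
#' the shape `kappa` is by default modelled as an intercept only (one shared
#' positive shape, `kappa_mode = "intercept_only"`), or from the full
#' predictor with `kappa_mode = "covariate"`.
#'
#' @param distribution `"exponential"` or `"weibull"`.
#' @param predictor `"linear"` or `"nn"`.
#' @param prior_sd Standard deviation of the Normal(0, prior_sd) priors on
#'   every coefficient, weight and bias. Default 1 (weakly-informative
#'   regularizing prior).
#' @param kappa_mode `"intercept_only"` (default) or `"covariate"`; Weibull
#'   only.
#' @param n_hidden_layers Number of tanh hidden layers (nn predictor only).
#' @param n_hidden_units Units per hidden layer (nn only). Defaults to the
#'   number of input features at fit time (`NULL`).
#'
#' @return An object of class `bps_spec`.
#' @examples
#' bps_spec("weibull", "linear")
#' bps_spec("weibull", "nn", n_hidden_layers = 1, n_hidden_units = 4)
#' @export
bps_spec <- function(distribution = c("exponential", "weibull"),
                     predictor = c("linear", "nn"),
                     prior_sd = 1,
                     kappa_mode = c("intercept_only", "covariate"),
                     n_hidden_layers = 1L,
                     n_hidden_units = NULL) {
  distribution <- match.arg(distribution)
  predictor <- match.arg(predictor)
  kappa_mode <- match.arg(kappa_mode)
  stopifnot(is.numeric(prior_sd), length(prior_sd) == 1, prior_sd > 0)
  if (predictor == "nn") {
    stopifnot(n_hidden_layers >= 0, is.null(n_hidden_units) ||
                n_hidden_units >= 1)
  }
  structure(list(distribution = distribution, predictor = predictor,
                 prior_sd = prior_sd, kappa_mode = kappa_mode,
                 n_hidden_layers = as.integer(n_hidden_layers),
                 n_hidden_units = if (is.null(n_hidden_units)) NULL else
                   as.integer(n_hidden_units)),
            class = "bps_spec")
}

#' @export
print.bps_spec <- function(x, ...) {
  cat("<bps_spec> ", x$distribution, " / ", x$predictor, " predictor",
      if (x$distribution == "weibull") paste0(", kappa: ", x$kappa_mode),
      ", prior sd ", x$prior_sd, "\n", sep = "")
  invisible(x)
}

#' Number of distribution parameters for a spec
#' @param spec A [bps_spec].
#' @return 1 for Exponential (rate), 2 for Weibull (rate, shape).
#' @export
n_dist_params <- function(spec) {
  if (spec$distribution == "exponential") 1L else 2L
}

# Layout of the flat unconstrained parameter vector for a spec fitted to
# n_features covariates. Returns a data.frame (name, block, length-1 scalar
# entries) so every scalar parameter has a stable name, which is what the
# posterior container, the prior set, and posterior-as-prior updating key on.
param_layout <- function(spec, feature_names) {
  p <- length(feature_names)
  coef_names <- c("(Intercept)", feature_names)
  entries <- list()
  add <- function(names, block) {
    entries[[length(entries) + 1L]] <<- data.frame(
      name = names, block = block, stringsAsFactors = FALSE)
  }
  if (spec$predictor == "linear") {
    add(paste0("lambda[", coef_names, "]"), "lambda_coef")
    if (spec$distribution == "weibull") {
      if (spec$kappa_mode == "intercept_only") {
        add("kappa[(Intercept)]", "kappa_coef")
      } else {
        add(paste0("kappa[", coef_names, "]"), "kappa_coef")
      }
    }
  } else {
    units <- if (is.null(spec$n_hidden_units)) max(p, 1L) else
      spec$n_hidden_units
    dims_in <- p
    L <- spec$n_hidden_layers
    for (l in seq_len(L)) {
      add(paste0("W", l, "[", rep(seq_len(units), each = max(dims_in, 1L)),
                 ",", rep(seq_len(max(dims_in, 1L)), times = units), "]"),
          paste0("W", l))
      add(paste0("b", l, "[", seq_len(units), "]"), paste0("b", l))
      dims_in <- units
    }
    heads <- if (spec$distribution == "weibull" &&
                 spec$kappa_mode == "covariate") 2L else 1L
    add(paste0("Wout[", rep(seq_len(heads), each = max(dims_in, 1L)), ",",
               rep(seq_len(max(dims_in, 1L)), times = heads), "]"), "Wout")
    add(paste0("bout[", seq_len(heads), "]"), "bout")
    if (spec$distribution == "weibull" &&
        spec$kappa_mode == "intercept_only") {
      add("kappa[(Intercept)]", "kappa_coef")
    }
  }
  do.call(rbind, entries)
}

# Build a fast unpacker closure: the layout is computed once, subsequent
# calls only index into the flat vector (this sits on the sampler's hot
# path, one call per gradient evaluation for nn predictors).
make_unpacker <- function(spec, feature_names) {
  lay <- param_layout(spec, feature_names)
  p <- length(feature_names)
  blocks <- lapply(split(seq_len(nrow(lay)), lay$block), as.integer)
  if (spec$predictor == "linear") {
    il <- blocks$lambda_coef
    ik <- blocks$kappa_coef
    weib <- spec$distribution == "weibull"
    fn <- function(theta) {
      out <- list(theta_lambda = theta[il])
      if (weib) out$theta_kappa <- theta[ik]
      out
    }
  } else {
    units <- if (is.null(spec$n_hidden_units)) max(p, 1L) else
      spec$n_hidden_units
    L <- spec$n_hidden_layers
    dims <- c(max(p, 1L), rep(units, L))
    heads <- length(blocks$bout)
    specs <- vector("list", L + 1L)
    for (l in seq_len(L)) {
      specs[[l]] <- list(wi = blocks[[paste0("W", l)]],
                         bi = blocks[[paste0("b", l)]],
                         nrow = units, ncol = dims[l])
    }
    specs[[L + 1L]] <- list(wi = blocks$Wout, bi = blocks$bout,
                            nrow = heads, ncol = dims[L + 1L])
    ik <- blocks$kappa_coef
    int_kappa <- spec$distribution == "weibull" &&
      spec$kappa_mode == "intercept_only"
    fn <- function(theta) {
      layers <- lapply(specs, function(s) {
        list(W = matrix(theta[s$wi], nrow = s$nrow, ncol = s$ncol,
                        byrow = TRUE),
             b = theta[s$bi])
      })
      out <- list(layers = layers)
      if (int_kappa) out$theta_kappa <- theta[ik]
      out
    }
  }
  attr(fn, "layout") <- lay
  fn
}

# One-off convenience wrapper around make_unpacker (not for hot loops).
unpack_params <- function(theta, spec, feature_names) {
  up <- make_unpacker(spec, feature_names)
  stopifnot(length(theta) == nrow(attr(up, "layout")))
  up(unname(theta))
}
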