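#' Linear predictor on the positive scale
#'
#' Computes exp(theta . x) for one subject. The leading element of `x_row`
#' is the constant 1 so the first coefficient is the intercept; model-level
#' code prepends that column automatically, this primitive expects it
#' explicitly.
#'
#' @param x_row Numeric vector, leading 1 followed by the features.
#' @param theta Coefficient vector of the same length.
#' @return The strictly positive scalar exp(sum(theta * x_row)).
#' @examples
#' linear_predictor(c(1, 0.5), c(0.1, -0.3))  # exp(-0.05)
#' @export
linear_predictor <- function(x_row, theta) {
  if (length(x_row) != length(theta)) {
    stop("x_row (", length(x_row), ") and theta (", length(theta),
         ") lengths differ")
  }
  exp(sum(as.numeric(x_row) * as.numeric(theta)))
}

#' Feed-forward network predictor on the positive scale
#'
#' Applies tanh hidden layers followed by an exponentiated linear output
#' layer, so every output is a valid (positive) distribution parameter.
#' One output per distribution parameter.
#'
#' @param x_row Numeric feature vector (no leading 1; biases play that role).
#' @param layers List of `list(W = matrix, b = vector)`; all but the last
#'   are tanh hidden layers, the last is the exponentiated output layer.
#' @return Positive numeric vector, one entry per output unit.
#' @examples
#' lay <- list(list(W = matrix(0, 1, 2), b = 0))
#' nn_forward(c(1, 2), lay)  # exp(0) = 1
#' @export
nn_forward <- function(x_row, layers) {
  a <- as.numeric(x_row)
  L <- length(layers)
  for (l in seq_len(L)) {
    W <- layers[[l]]$W; b <- layers[[l]]$b
    if (ncol(W) != length(a)) {
      stop("layer ", l, ": weight matrix expects ", ncol(W),
           " inputs, got ", length(a))
    }
    z <- drop(W %*% a) + b
    a <- if (l < L) tanh(z) else exp(z)
  }
  a
}

# Vectorized forward pass over an n x p matrix; returns n x heads matrix of
# linear outputs (before exp) plus the activations needed for backprop.
nn_forward_matrix <- function(X, layers, keep_activations = FALSE) {
  A <- X
  L <- length(layers)
  acts <- if (keep_activations) vector("list", L) else NULL
  for (l in seq_len(L)) {
    W <- layers[[l]]$W; b <- layers[[l]]$b
    Z <- A %*% t(W)
    Z <- sweep(Z, 2, b, "+")
    if (l < L) {
      A2 <- tanh(Z)
    } else {
      A2 <- Z  # linear head; exp applied by caller
    }
    if (keep_activations) acts[[l]] <- list(input = A, output = A2)
    A <- A2
  }
  list(out = A, acts = acts)
}

#' Log survival function
#'
#' log S(t): `-lambda * t` for the Exponential model and `-(lambda*t)^kappa`
#' for the Weibull model in the rate parameterization. This is the censored
#' subject's contribution to the log-likelihood (the log complementary CDF).
#'
#' @param t Non-negative time(s).
#' @param lam Positive rate parameter(s).
#' @param kappa Positive shape (Weibull only); ignored for exponential.
#' @param distribution `"exponential"` or `"weibull"`.
#' @return Non-positive log survival probability, vectorized over inputs.
#' @examples
#' log_survival(4, lam = 0.5, kappa = 2, distribution = "weibull")  # -4
#' @export
log_survival <- function(t, lam, kappa = 1,
                         distribution = c("exponential", "weibull")) {
  distribution <- match.arg(distribution)
  if (any(t < 0)) stop("t must be non-negative")
  if (any(lam <= 0) || any(kappa <= 0)) stop("lam and kappa must be > 0")
  if (distribution == "exponential") -lam * t else -(lam * t)^kappa
}

#' Survival probability S(t)
#'
#' The complement of the CDF: probability the event has not occurred by
#' time t. Equals `exp(log_survival(...))`; 1 at t = 0, non-increasing in t.
#'
#' @inheritParams log_survival
#' @return Probability in [0, 1], vectorized.
#' @examples
#' survival_probability(1, lam = 1)           # exp(-1)
#' 1 - survival_probability(2, lam = 0.5, kappa = 3,
#'                          distribution = "weibull")  # 63.2% at t = 1/lam
#' @export
survival_probability <- function(t, lam, kappa = 1,
                                 distribution = c("exponential", "weibull")) {
  exp(log_survival(t, lam, kappa, distribution))
}

#' Event probability (CDF)
#'
#' `1 - survival_probability`. At t = 1/lambda the Weibull event
#' probability is 1 - exp(-1) = 63.2% for every shape kappa, which is the
#' interpretation of the rate parameter.
#'
#' @inheritParams log_survival
#' @return Probability in [0, 1].
#' @export
event_probability <- function(t, lam, kappa = 1,
                              distribution = c("exponential", "weibull")) {
  1 - survival_probability(t, lam, kappa, distribution)
}

#' Log density of the event time
#'
#' Contribution of an observed (uncensored) event at time t: log pdf =
#' log hazard + log survival. Exponential: log(lam) - lam*t. Weibull:
#' log(kappa) + kappa*log(lam) + (kappa-1)*log(t) - (lam*t)^kappa.
#'
#' @inheritParams log_survival
#' @return Log density, vectorized.
#' @export
log_event_density <- function(t, lam, kappa = 1,
                              distribution = c("exponential", "weibull")) {
  distribution <- match.arg(distribution)
  if (any(t <= 0)) stop("event times must be strictly positive")
  if (any(lam <= 0) || any(kappa <= 0)) stop("lam and kappa must be > 0")
  if (distribution == "exponential") {
    log(lam) - lam * t
  } else {
    log(kappa) + kappa * log(lam) + (kappa - 1) * log(t) - (lam * t)^kappa
  }
}

#' Total censored log-likelihood
#'
#' Sum over subjects: events contribute the log density at their time,
#' right-censored subjects the log survival (the probability the true time
#' exceeds the observation time).
#'
#' @param data A [survival_data] object.
#' @param lam Positive rate per subject (recycled if scalar).
#' @param kappa Positive shape per subject (Weibull; recycled if scalar).
#' @param distribution `"exponential"` or `"weibull"`.
#' @return Scalar log-likelihood.
#' @export
total_log_likelihood <- function(data, lam, kappa = 1,
                                 distribution = c("exponential", "weibull")) {
  distribution <- match.arg(distribution)
  n <- length(data$times)
  lam <- rep_len(lam, n); kappa <- rep_len(kappa, n)
  bad <- !is.finite(lam) | !is.finite(kappa)
  if (any(bad)) {
    stop("non-finite distribution parameter for subject ", which(bad)[1])
  }
  ev <- data$events == 1
  ll <- 0
  if (any(ev)) {
    ll <- ll + sum(log_event_density(data$times[ev], lam[ev], kappa[ev],
                                     distribution))
  }
  if (any(!ev)) {
    ll <- ll + sum(log_survival(data$times[!ev], lam[!ev], kappa[!ev],
                                distribution))
  }
  ll
}

#' Median survival time
#'
#' Solves S(t) = 1/2: `log(2)/lambda` for the Exponential model,
#' `log(2)^(1/kappa) / lambda` for the Weibull model.
#'
#' @inheritParams log_survival
#' @return Positive median time, vectorized over parameters.
#' @export
median_survival_time <- function(lam, kappa = 1,
                                 distribution = c("exponential", "weibull")) {
  distribution <- match.arg(distribution)
  if (any(lam <= 0) || any(kappa <= 0)) stop("lam and kappa must be > 0")
  if (distribution == "exponential") log(2) / lam else
    log(2)^(1 / kappa) / lam
}
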