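# Posterior-predictive machinery: per-draw distribution parameters for new
# subjects, survival curves with uncertainty bands, median survival, and the
# risk score that feeds the concordance index.

check_new_X <- function(fit, X_new) {
  if (is.data.frame(X_new)) X_new <- as.matrix(X_new)
  if (!is.matrix(X_new)) X_new <- matrix(X_new, ncol = length(fit$feature_names))
  storage.mode(X_new) <- "double"
  p <- length(fit$feature_names)
  if (ncol(X_new) != p) {
    have <- colnames(X_new)
    msg <- if (!is.null(have)) {
      extra <- setdiff(have, fit$feature_names)
      miss <- setdiff(fit$feature_names, have)
      paste0(" (missing: ", paste(miss, collapse = ", "),
             "; extra: ", paste(extra, collapse = ", "), ")")
    } else ""
    stop("X_new has ", ncol(X_new), " columns but the model was trained on ",
         p, " features", msg)
  }
  if (!is.null(colnames(X_new)) && p > 0 &&
      !identical(colnames(X_new), fit$feature_names)) {
    if (all(fit$feature_names %in% colnames(X_new))) {
      X_new <- X_new[, fit$feature_names, drop = FALSE]
    } else {
      stop("X_new column names do not match training features; missing: ",
           paste(setdiff(fit$feature_names, colnames(X_new)), collapse = ", "))
    }
  }
  X_new
}

# Draws from the posterior as a matrix, thinning evenly to at most max_draws
# rows; summaries-only fits are expanded to a Normal approximation (with a
# warning, once per call chain).
posterior_draw_matrix <- function(fit, max_draws = NULL) {
  if (isTRUE(fit$approximate_draws)) {
    warning("model file carried posterior summaries only: using a ",
            "Normal approximation of the posterior for prediction",
            call. = FALSE)
  }
  mat <- draw_matrix(fit)
  if (!is.null(max_draws) && nrow(mat) > max_draws) {
    keep <- unique(round(seq(1, nrow(mat), length.out = max_draws)))
    mat <- mat[keep, , drop = FALSE]
  }
  mat
}

#' Per-draw distribution parameters for new subjects
#'
#' Applies the fitted spec's predictor function to every retained posterior
#' draw, yielding the posterior distribution of the rate lambda (and shape
#' kappa for Weibull models) for each new subject.
#'
#' @param fit A `bps_fit`.
#' @param X_new Covariate matrix (subjects x features), columns matching the
#'   training features.
#' @param max_draws Optional cap on the number of posterior draws used
#'   (evenly thinned).
#' @return List with `lam` (draws x subjects matrix) and, for Weibull
#'   models, `kappa` (same shape).
#' @export
posterior_params_for <- function(fit, X_new, max_draws = NULL) {
  X_new <- check_new_X(fit, X_new)
  mat <- posterior_draw_matrix(fit, max_draws)
  S <- nrow(mat); n <- nrow(X_new)
  spec <- fit$spec
  weibull <- spec$distribution == "weibull"
  lam <- matrix(NA_real_, S, n)
  kap <- if (weibull) matrix(NA_real_, S, n) else NULL
  lay <- param_layout(spec, fit$feature_names)
  Xd <- cbind(1, X_new)
  if (spec$predictor == "linear") {
    Tl <- mat[, lay$name[lay$block == "lambda_coef"], drop = FALSE]
    lam <- exp(Tl %*% t(Xd))
    if (weibull) {
      if (spec$kappa_mode == "intercept_only") {
        kap <- matrix(exp(mat[, "kappa[(Intercept)]"]), S, n)
      } else {
        Tk <- mat[, lay$name[lay$block == "kappa_coef"], drop = FALSE]
        kap <- exp(Tk %*% t(Xd))
      }
    }
  } else {
    unpacker <- make_unpacker(spec, fit$feature_names)
    for (s in seq_len(S)) {
      parts <- unpacker(unname(mat[s, ]))
      H <- nn_forward_matrix(X_new, parts$layers)$out
      lam[s, ] <- exp(H[, 1])
      if (weibull) {
        kap[s, ] <- if (spec$kappa_mode == "covariate") exp(H[, 2]) else
          exp(parts$theta_kappa)
      }
    }
  }
  out <- list(lam = lam)
  if (weibull) out$kappa <- kap
  out
}

#' Posterior-predictive survival curves
#'
#' For each new subject and each time on the grid, evaluates the survival
#' function S(t) under every posterior draw and summarizes with the mean
#' and standard deviation; the default uncertainty band is mean +/- 1 SD
#' clipped to [0, 1], with central quantile bands as an option.
#'
#' @inheritParams posterior_params_for
#' @param time_grid Sorted non-negative times at which to evaluate S(t).
#' @param band `"sd"` (mean +/- SD, the default) or `"quantile"` (central
#'   interval at `level`).
#' @param level Probability mass for the quantile band.
#' @param max_draws Cap on posterior draws used (default 1000, evenly
#'   thinned).
#' @return A `bps_curves` object: `time_grid` plus matrices (subjects x
#'   times) `mean`, `sd`, `lower`, `upper`, and `n_posterior_samples`.
#' @export
predict_survival <- function(fit, X_new, time_grid,
                             band = c("sd", "quantile"), level = 0.94,
                             max_draws = 1000L) {
  band <- match.arg(band)
  if (is.unsorted(time_grid, strictly = FALSE)) {
    stop("time_grid must be sorted ascending")
  }
  if (any(time_grid < 0)) stop("time_grid must be non-negative")
  pars <- posterior_params_for(fit, X_new, max_draws = max_draws)
  S <- nrow(pars$lam); n <- ncol(pars$lam); Tn <- length(time_grid)
  weibull <- fit$spec$distribution == "weibull"
  mean_m <- matrix(NA_real_, n, Tn)
  sd_m <- matrix(NA_real_, n, Tn)
  lo_m <- matrix(NA_real_, n, Tn)
  up_m <- matrix(NA_real_, n, Tn)
  for (j in seq_len(n)) {
    lt <- outer(pars$lam[, j], time_grid)           # S x Tn
    surv <- if (weibull) exp(-(lt^pars$kappa[, j])) else exp(-lt)
    mu <- colMeans(surv)
    sdv <- apply(surv, 2, stats::sd)
    mean_m[j, ] <- mu
    sd_m[j, ] <- sdv
    if (band == "sd") {
      lo_m[j, ] <- pmax(mu - sdv, 0)
      up_m[j, ] <- pmin(mu + sdv, 1)
    } else {
      qs <- apply(surv, 2, stats::quantile,
                  probs = c((1 - level) / 2, 1 - (1 - level) / 2))
      lo_m[j, ] <- qs[1, ]
      up_m[j, ] <- qs[2, ]
    }
  }
  structure(list(time_grid = time_grid, mean = mean_m, sd = sd_m,
                 lower = lo_m, upper = up_m, n_posterior_samples = S,
                 band = band),
            class = "bps_curves")
}

#' @export
print.bps_curves <- function(x, ...) {
  cat("<bps_curves> ", nrow(x$mean), " subjects x ", length(x$time_grid),
      " time points, ", x$n_posterior_samples, " posterior draws, ",
      x$band, " band\n", sep = "")
  invisible(x)
}

#' Survival curves as a tidy data frame
#' @param x A `bps_curves` object.
#' @param ... Unused.
#' @return Data frame with columns subject, time, mean, sd, lower, upper.
#' @export
as.data.frame.bps_curves <- function(x, ...) {
  n <- nrow(x$mean); Tn <- length(x$time_grid)
  data.frame(subject = rep(seq_len(n), each = Tn),
             time = rep(x$time_grid, n),
             mean = as.vector(t(x$mean)),
             sd = as.vector(t(x$sd)),
             lower = as.vector(t(x$lower)),
             upper = as.vector(t(x$upper)))
}

#' Posterior draws of median survival time
#'
#' Per draw and subject: log(2)^(1/kappa)/lambda for Weibull models,
#' log(2)/lambda for Exponential models.
#'
#' @inheritParams posterior_params_for
#' @return Matrix (draws x subjects) of median survival times.
#' @export
predict_median_survival <- function(fit, X_new, max_draws = NULL) {
  pars <- posterior_params_for(fit, X_new, max_draws = max_draws)
  if (fit$spec$distribution == "weibull") {
    log(2)^(1 / pars$kappa) / pars$lam
  } else {
    log(2) / pars$lam
  }
}

#' Risk score for concordance evaluation
#'
#' Higher score means shorter predicted survival. For fitted models the
#' score is the negative posterior-mean median survival time (for the
#' Exponential model this ranks subjects identically to the rate lambda).
#' Any external model can be plugged into the evaluation harness as a plain
#' function `X -> scores`.
#'
#' @param model A `bps_fit`, or a function taking a covariate matrix and
#'   returning one numeric score per row.
#' @param X_new Covariate matrix.
#' @param max_draws Posterior draws used for `bps_fit` models (default 500).
#' @return Numeric vector of risk scores, one per subject.
#' @export
risk_score <- function(model, X_new, max_draws = 500L) {
  if (is.function(model)) return(as.numeric(model(X_new)))
  if (!inherits(model, "bps_fit")) {
    stop("model must be a bps_fit or a function(X) -> scores")
  }
  med <- predict_median_survival(model, X_new, max_draws = max_draws)
  -colMeans(med)
}

#' Plot posterior survival curves
#'
#' Mean curves with uncertainty ribbons, one colour per subject. Uses
#' ggplot2 when available, base graphics otherwise.
#'
#' @param curves A `bps_curves` object.
#' @param subjects Integer indices of subjects to draw (default: all, up to
#'   8).
#' @return A ggplot object (invisibly NULL for the base-graphics fallback).
#' @export
plot_survival_curves <- function(curves, subjects = NULL) {
  n <- nrow(curves$mean)
  if (is.null(subjects)) subjects <- seq_len(min(n, 8L))
  df <- as.data.frame(curves)
  df <- df[df$subject %in% subjects, ]
  df$subject <- factor(df$subject)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mean,
                                     colour = .data$subject,
                                     fill = .data$subject)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper),
                           alpha = 0.2, colour = NA) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time", y = "survival probability S(t)") +
      ggplot2::ylim(0, 1) +
      ggplot2::theme_minimal()
  } else {
    plot(NULL, xlim = range(df$time), ylim = c(0, 1), xlab = "time",
         ylab = "survival probability S(t)")
    for (s in levels(df$subject)) {
      d <- df[df$subject == s, ]
      graphics::lines(d$time, d$mean, col = as.integer(s))
      graphics::lines(d$time, d$lower, col = as.integer(s), lty = 3)
      graphics::lines(d$time, d$upper, col = as.integer(s), lty = 3)
    }
    invisible(NULL)
  }
}
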