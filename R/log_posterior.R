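# Log-posterior and analytic gradient for every model variant, on the flat
# unconstrained parameter vector defined by param_layout(). Both the rate
# lambda and the shape kappa are kept positive by exponentiation, so the
# sampler works on an unconstrained space and no Jacobian terms arise
# (coefficients, weights and biases are the parameters, not lambda itself).
#
# Likelihood pieces (rate parameterization, u = log(lambda) + log(t),
# z = (lambda*t)^kappa = exp(kappa*u)):
#   exponential: ll_i = delta_i*log(lambda_i) - lambda_i*t_i
#   weibull:     ll_i = delta_i*(log kappa_i + kappa_i*u_i - log t_i) - z_i
# Gradients w.r.t. the linear scales log(lambda) and log(kappa):
#   exponential: d ll / d log(lambda) = delta - lambda*t
#   weibull:     d ll / d log(lambda) = kappa*(delta - z)
#                d ll / d log(kappa)  = delta*(1 + kappa*u) - z*kappa*u
make_log_posterior <- function(spec, data, priors) {
  X <- data$covariates
  n <- nrow(X)
  p <- ncol(X)
  t_obs <- data$times
  delta <- data$events
  logt <- log(t_obs)
  lay <- param_layout(spec, data$feature_names)
  mu <- priors$mu[lay$name]
  sigma <- priors$sd[lay$name]
  if (anyNA(mu) || anyNA(sigma)) {
    stop("priors missing for parameters: ",
         paste(lay$name[is.na(mu) | is.na(sigma)], collapse = ", "))
  }
  d <- nrow(lay)
  Xd <- cbind(1, X)  # design with intercept for linear predictors
  weibull <- spec$distribution == "weibull"
  kappa_cov <- weibull && spec$kappa_mode == "covariate"
  linear <- spec$predictor == "linear"

  if (!linear && p == 0L) {
    stop("nn predictor requires at least one covariate")
  }

  # index bookkeeping for the flat vector
  idx <- split(seq_len(d), lay$block)
  unpacker <- if (!linear) make_unpacker(spec, data$feature_names)

  fail <- list(lp = -Inf, grad = rep(0, d))

  lp_grad <- function(theta) {
    if (any(!is.finite(theta))) return(fail)
    if (linear) {
      th_l <- theta[idx$lambda_coef]
      eta_l <- drop(Xd %*% th_l)               # log lambda
      if (!weibull) {
        lam_t <- exp(eta_l) * t_obs
        if (any(!is.finite(lam_t))) return(fail)
        ll <- sum(delta * eta_l) - sum(lam_t)
        dl <- delta - lam_t
        g <- numeric(d)
        g[idx$lambda_coef] <- drop(crossprod(Xd, dl))
      } else {
        th_k <- theta[idx$kappa_coef]
        eta_k <- if (kappa_cov) drop(Xd %*% th_k) else rep(th_k, n)
        kap <- exp(eta_k)
        u <- eta_l + logt
        z <- exp(kap * u)
        if (any(!is.finite(z)) || any(!is.finite(kap))) return(fail)
        ll <- sum(delta * (eta_k + kap * u - logt)) - sum(z)
        dl_l <- kap * (delta - z)
        dl_k <- delta * (1 + kap * u) - z * kap * u
        g <- numeric(d)
        g[idx$lambda_coef] <- drop(crossprod(Xd, dl_l))
        g[idx$kappa_coef] <- if (kappa_cov) drop(crossprod(Xd, dl_k)) else
          sum(dl_k)
      }
    } else {
      parts <- unpacker(theta)
      fwd <- nn_forward_matrix(X, parts$layers, keep_activations = TRUE)
      H <- fwd$out                              # n x heads, linear scale
      eta_l <- H[, 1]
      if (!weibull) {
        lam_t <- exp(eta_l) * t_obs
        if (any(!is.finite(lam_t))) return(fail)
        ll <- sum(delta * eta_l) - sum(lam_t)
        dH <- cbind(delta - lam_t)
        dkap_int <- NULL
      } else {
        if (kappa_cov) {
          eta_k <- H[, 2]
        } else {
          eta_k <- rep(theta[idx$kappa_coef], n)
        }
        kap <- exp(eta_k)
        u <- eta_l + logt
        z <- exp(kap * u)
        if (any(!is.finite(z)) || any(!is.finite(kap))) return(fail)
        ll <- sum(delta * (eta_k + kap * u - logt)) - sum(z)
        dl_l <- kap * (delta - z)
        dl_k <- delta * (1 + kap * u) - z * kap * u
        dH <- if (kappa_cov) cbind(dl_l, dl_k) else cbind(dl_l)
        dkap_int <- if (!kappa_cov) sum(dl_k) else NULL
      }
      # backprop through the layers
      L <- length(parts$layers)
      grads <- vector("list", L)
      dA <- dH
      for (l in rev(seq_len(L))) {
        act <- fwd$acts[[l]]
        dZ <- if (l == L) dA else dA * (1 - act$output^2)
        grads[[l]] <- list(W = crossprod(dZ, act$input),
                           b = colSums(dZ))
        if (l > 1L) dA <- dZ %*% parts$layers[[l]]$W
      }
      g <- numeric(d)
      for (l in seq_len(L)) {
        blk_w <- if (l < L) paste0("W", l) else "Wout"
        blk_b <- if (l < L) paste0("b", l) else "bout"
        g[idx[[blk_w]]] <- as.vector(t(grads[[l]]$W))  # row-major layout
        g[idx[[blk_b]]] <- grads[[l]]$b
      }
      if (!is.null(dkap_int)) g[idx$kappa_coef] <- dkap_int
    }
    if (!is.finite(ll)) return(fail)
    zc <- (theta - mu) / sigma
    lp <- ll - 0.5 * sum(zc^2)
    g <- g - zc / sigma
    if (any(!is.finite(g))) return(fail)
    list(lp = lp, grad = g)
  }

  list(lp_grad = lp_grad, layout = lay, mu = unname(mu),
       sigma = unname(sigma), n_params = d)
}
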