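# No-U-Turn sampler (dynamic Hamiltonian Monte Carlo) on an unconstrained
# parameter vector, with dual-averaging step-size adaptation toward a target
# acceptance statistic and a diagonal mass-matrix (metric) estimated during
# warmup. The recursion is the classic slice-variable doubling scheme with a
# depth cap and an energy-error divergence threshold.
#
# lp_grad: function(theta) -> list(lp, grad); metric = estimated posterior
# variances, so momentum ~ N(0, 1/metric) and the kinetic energy is
# 0.5 * sum(r^2 * metric).

nuts_chain <- function(lp_grad, init, n_warmup, n_draws, seed,
                       target_accept = 0.9, max_treedepth = 10L) {
  set.seed(seed)
  d <- length(init)
  metric <- rep(1, d)

  joint <- function(st, r) st$lp - 0.5 * sum(r^2 * metric)

  leapfrog <- function(st, r, eps) {
    r1 <- r + 0.5 * eps * st$grad
    th <- st$theta + eps * (r1 * metric)
    ev <- lp_grad(th)
    r2 <- r1 + 0.5 * eps * ev$grad
    list(st = list(theta = th, lp = ev$lp, grad = ev$grad), r = r2)
  }

  find_epsilon <- function(st) {
    eps <- 1
    r <- stats::rnorm(d, 0, sqrt(1 / metric))
    h0 <- joint(st, r)
    step <- leapfrog(st, r, eps)
    h1 <- joint(step$st, step$r)
    if (!is.finite(h1)) {
      while (!is.finite(h1) && eps > 1e-10) {
        eps <- eps / 2
        step <- leapfrog(st, r, eps)
        h1 <- joint(step$st, step$r)
      }
    }
    a <- if (h1 - h0 > log(0.5)) 1 else -1
    while (a * (h1 - h0) > a * log(0.5) && eps < 1e3 && eps > 1e-10) {
      eps <- eps * 2^a
      step <- leapfrog(st, r, eps)
      h1 <- joint(step$st, step$r)
      if (!is.finite(h1)) { h1 <- -Inf }
    }
    max(eps, 1e-8)
  }

  delta_max <- 1000
  n_divergent <- 0L

  build_tree <- function(st, r, logu, v, j, eps, h0) {
    if (j == 0L) {
      step <- leapfrog(st, r, v * eps)
      h <- joint(step$st, step$r)
      if (!is.finite(h)) h <- -Inf
      n_ok <- as.integer(logu <= h)
      s <- as.integer(h > logu - delta_max)
      if (s == 0L) n_divergent <<- n_divergent + 1L
      alpha <- min(1, exp(h - h0))
      list(minus = step, plus = step, prop = step$st, n = n_ok, s = s,
           alpha = alpha, n_alpha = 1L)
    } else {
      t1 <- build_tree(st, r, logu, v, j - 1L, eps, h0)
      if (t1$s == 1L) {
        if (v == -1L) {
          t2 <- build_tree(t1$minus$st, t1$minus$r, logu, v, j - 1L, eps, h0)
          t1$minus <- t2$minus
        } else {
          t2 <- build_tree(t1$plus$st, t1$plus$r, logu, v, j - 1L, eps, h0)
          t1$plus <- t2$plus
        }
        if (t2$n > 0L &&
            stats::runif(1) < t2$n / max(t1$n + t2$n, 1L)) {
          t1$prop <- t2$prop
        }
        dtheta <- t1$plus$st$theta - t1$minus$st$theta
        noturn <- (sum(dtheta * (t1$minus$r * metric)) >= 0) &&
                  (sum(dtheta * (t1$plus$r * metric)) >= 0)
        t1$s <- t2$s * as.integer(noturn)
        t1$n <- t1$n + t2$n
        t1$alpha <- t1$alpha + t2$alpha
        t1$n_alpha <- t1$n_alpha + t2$n_alpha
      }
      t1
    }
  }

  ev <- lp_grad(init)
  if (!is.finite(ev$lp)) stop("initial value has non-finite log posterior")
  st <- list(theta = init, lp = ev$lp, grad = ev$grad)

  # dual averaging state
  da_init <- function(eps0) {
    list(mu = log(10 * eps0), log_eps = log(eps0), log_eps_bar = 0,
         h_bar = 0, m = 0L, gamma = 0.05, t0 = 10, kappa = 0.75)
  }
  da_update <- function(da, alpha_stat) {
    da$m <- da$m + 1L
    eta <- 1 / (da$m + da$t0)
    da$h_bar <- (1 - eta) * da$h_bar + eta * (target_accept - alpha_stat)
    da$log_eps <- da$mu - sqrt(da$m) / da$gamma * da$h_bar
    w <- da$m^(-da$kappa)
    da$log_eps_bar <- w * da$log_eps + (1 - w) * da$log_eps_bar
    da
  }

  eps <- find_epsilon(st)
  da <- da_init(eps)

  total <- n_warmup + n_draws
  draws <- matrix(NA_real_, n_draws, d)
  lp_out <- numeric(n_draws)
  accept_stats <- numeric(total)
  treedepths <- integer(total)

  # one metric-adaptation window in the middle of warmup
  win_lo <- max(ceiling(0.25 * n_warmup), 2L)
  win_hi <- ceiling(0.75 * n_warmup)
  win_draws <- matrix(NA_real_, max(win_hi - win_lo + 1L, 1L), d)
  win_k <- 0L

  for (it in seq_len(total)) {
    r0 <- stats::rnorm(d, 0, sqrt(1 / metric))
    h0 <- joint(st, r0)
    logu <- h0 + log(stats::runif(1))  # slice variable
    minus <- list(st = st, r = r0); plus <- list(st = st, r = r0)
    prop <- st; n <- 1L; s <- 1L; j <- 0L
    alpha_sum <- 0; n_alpha <- 0L
    while (s == 1L && j < max_treedepth) {
      v <- if (stats::runif(1) < 0.5) -1L else 1L
      if (v == -1L) {
        tr <- build_tree(minus$st, minus$r, logu, v, j, eps, h0)
        minus <- tr$minus
      } else {
        tr <- build_tree(plus$st, plus$r, logu, v, j, eps, h0)
        plus <- tr$plus
      }
      if (tr$s == 1L && tr$n > 0L &&
          stats::runif(1) < min(1, tr$n / n)) {
        prop <- tr$prop
      }
      n <- n + tr$n
      alpha_sum <- alpha_sum + tr$alpha
      n_alpha <- n_alpha + tr$n_alpha
      dtheta <- plus$st$theta - minus$st$theta
      noturn <- (sum(dtheta * (minus$r * metric)) >= 0) &&
                (sum(dtheta * (plus$r * metric)) >= 0)
      s <- tr$s * as.integer(noturn)
      j <- j + 1L
    }
    st <- prop
    alpha_stat <- if (n_alpha > 0L) alpha_sum / n_alpha else 0
    accept_stats[it] <- alpha_stat
    treedepths[it] <- j

    if (it <= n_warmup) {
      da <- da_update(da, alpha_stat)
      eps <- exp(da$log_eps)
      if (it >= win_lo && it <= win_hi) {
        win_k <- win_k + 1L
        win_draws[win_k, ] <- st$theta
      }
      if (it == win_hi && win_k >= 10L) {
        v_est <- apply(win_draws[seq_len(win_k), , drop = FALSE], 2,
                       stats::var)
        # regularize toward unit metric as Stan does for short windows
        w <- win_k / (win_k + 5)
        metric <- pmax(w * v_est + (1 - w) * 1e-3, 1e-8)
        eps <- find_epsilon(st)
        da <- da_init(eps)
      }
      if (it == n_warmup) {
        eps <- exp(da$log_eps_bar)
        n_divergent <- 0L  # report post-warmup divergences only
      }
    } else {
      k <- it - n_warmup
      draws[k, ] <- st$theta
      lp_out[k] <- st$lp
    }
  }

  list(draws = draws, lp = lp_out, eps = eps, metric = metric,
       n_divergent = n_divergent,
       mean_accept = mean(accept_stats[(n_warmup + 1):total]),
       treedepth = treedepths)
}

# Split-chain potential scale reduction factor (split R-hat) for one
# parameter given a (draws x chains) matrix.
split_rhat <- function(mat) {
  n <- nrow(mat)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# Effective sample size from chain-averaged autocorrelations with Geyer's
# initial positive sequence truncation.
ess_basic <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  if (n < 4L) return(NA_real_)
  acov <- sapply(seq_len(m), function(j) {
    x <- mat[, j] - mean(mat[, j])
    a <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE,
                    type = "covariance", demean = FALSE)$acf[, 1, 1]
    a
  })
  acov <- matrix(acov, ncol = m)
  W <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- W  # within-chain estimate; B term folded into rhat, keep simple
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  rho[1] <- 1
  # sum consecutive pairs while positive
  tau <- 0; k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    tau <- tau + pair
    k <- k + 2
  }
  tau <- max(tau, 1e-3)
  min(n * m / max(2 * tau - 1, 1e-3), n * m)
}
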