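# Experiment-style ML pipeline pieces: concordance index, overfitting gap,
# training-statistics normalization, mutual-information feature ranking,
# train/test splitting and cross-validated hyperparameter search.

#' Harrell's concordance index for right-censored data
#'
#' Over all comparable pairs (t_i < t_j with event_i = 1), the fraction in
#' which the shorter-lived subject has the higher risk score; ties in risk
#' count 1/2. Pairs with tied event times are non-comparable. Returns 0.5
#' with a warning when no comparable pairs exist (e.g. everything
#' censored).
#'
#' @param times Observed times.
#' @param events 0/1 event indicators.
#' @param risk_scores Numeric scores; higher = shorter predicted survival.
#' @return C-index in [0, 1]; 0.5 = random ranking.
#' @export
concordance_index <- function(times, events, risk_scores) {
  n <- length(times)
  stopifnot(length(events) == n, length(risk_scores) == n)
  events <- as.numeric(events)
  # pair (i, j) comparable iff t_i < t_j and subject i had the event
  conc <- 0; total <- 0
  for (i in which(events == 1)) {
    later <- times > times[i]
    m <- sum(later)
    if (m == 0) next
    total <- total + m
    ri <- risk_scores[i]
    rj <- risk_scores[later]
    conc <- conc + sum(ri > rj) + 0.5 * sum(ri == rj)
  }
  if (total == 0) {
    warning("no comparable pairs; returning 0.5")
    return(0.5)
  }
  conc / total
}

#' Overfitting gap
#'
#' Training-set C-index minus test-set C-index; positive values indicate
#' overfitting, negative values are possible and allowed.
#'
#' @param train_ci,test_ci C-index values in [0, 1].
#' @return `train_ci - test_ci`.
#' @export
overfit_gap <- function(train_ci, test_ci) {
  stopifnot(train_ci >= 0, train_ci <= 1, test_ci >= 0, test_ci <= 1)
  train_ci - test_ci
}

#' Fit a training-statistics normalizer
#'
#' Z-scores continuous columns with the training mean and SD; binary and
#' one-hot columns pass through untouched. The returned transformer reuses
#' the training statistics on any new matrix, so no test-set value ever
#' leaks into the preprocessing.
#'
#' @param train_X Training covariate matrix.
#' @param feature_kinds Kind tag per column (`"continuous"`, `"binary"`,
#'   `"onehot"`).
#' @return A `bps_normalizer` with `$apply(X)` and `$invert(X)` closures
#'   plus the stored `center`/`scale`.
#' @export
fit_normalizer <- function(train_X, feature_kinds) {
  if (is.data.frame(train_X)) train_X <- as.matrix(train_X)
  p <- ncol(train_X)
  stopifnot(nrow(train_X) >= 1, length(feature_kinds) == p)
  cont <- feature_kinds == "continuous"
  center <- rep(0, p); scale <- rep(1, p)
  if (any(cont)) {
    center[cont] <- colMeans(train_X[, cont, drop = FALSE])
    s <- apply(train_X[, cont, drop = FALSE], 2, stats::sd)
    zero <- !is.finite(s) | s == 0
    if (any(zero)) {
      warning("zero-variance continuous column(s): ",
              paste(colnames(train_X)[cont][zero], collapse = ", "),
              "; scale set to 1")
      s[zero] <- 1
    }
    scale[cont] <- s
  }
  obj <- list(center = center, scale = scale, kinds = feature_kinds,
              names = colnames(train_X))
  obj$apply <- function(X) {
    if (is.data.frame(X)) X <- as.matrix(X)
    stopifnot(ncol(X) == p)
    sweep(sweep(X, 2, center), 2, scale, "/")
  }
  obj$invert <- function(X) {
    if (is.data.frame(X)) X <- as.matrix(X)
    sweep(sweep(X, 2, scale, "*"), 2, center, "+")
  }
  class(obj) <- "bps_normalizer"
  obj
}

# Plug-in mutual information (nats) between two discrete vectors.
mi_discrete <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  idx <- pxy > 0
  sum(pxy[idx] * log(pxy[idx] / outer(px, py)[idx]))
}

# Nearest-neighbour MI estimator between a continuous variable and a
# discrete label (Ross 2014), with a fixed neighbour count. The variable is
# 1-dimensional so neighbour searches reduce to sorted-order scans.
mi_ross <- function(x, y, k = 3L) {
  n <- length(x)
  mi_terms <- numeric(n)
  for (lvl in unique(y)) {
    idx <- which(y == lvl)
    if (length(idx) < 2L) next
    xi <- x[idx]
    oi <- order(xi)
    xis <- xi[oi]
    m_lvl <- length(xis)
    kk <- min(k, m_lvl - 1L)
    for (jj in seq_len(m_lvl)) {
      # distance to the kk-th nearest neighbour within the class
      lo <- max(1L, jj - kk); hi <- min(m_lvl, jj + kk)
      d <- sort(abs(xis[lo:hi] - xis[jj]))[kk + 1L]
      # count points in the full sample strictly within distance d
      subject <- idx[oi[jj]]
      xv <- x[subject]
      m_cnt <- sum(abs(x - xv) < d) - 1L
      mi_terms[subject] <- digamma(n) + digamma(kk) -
        digamma(m_lvl) - digamma(max(m_cnt, 1L))
    }
  }
  max(mean(mi_terms), 0)
}

#' Rank features by mutual information with median survival and keep k best
#'
#' Binarizes survival at the observed-time median (label: time > median),
#' estimates the mutual information of each feature with that label --
#' nearest-neighbour estimator (3 neighbours, seeded jitter) for continuous
#' features, plug-in contingency MI for binary/one-hot features -- and
#' returns the indices of the top k, ties broken by original column order.
#'
#' @param X Covariate matrix.
#' @param times,events Survival outcome (events currently unused by the
#'   default observed-time-median labelling; a Kaplan-Meier median label is
#'   available via `median_type`).
#' @param k Number of features to keep (1..ncol(X)).
#' @param feature_kinds Kind tag per column; guessed (0/1 = binary) when
#'   omitted.
#' @param median_type `"observed"` (default) or `"km"` (Kaplan-Meier-style
#'   median of the event-time distribution estimated from the data).
#' @param seed Seed for the jitter applied to continuous features before
#'   neighbour counting (breaks ties from discretized values).
#' @return Integer vector of selected column indices, in rank order, with
#'   the estimated MI per column as attribute `"mi"`.
#' @export
mi_kbest <- function(X, times, events, k, feature_kinds = NULL,
                     median_type = c("observed", "km"), seed = 1L) {
  if (is.data.frame(X)) X <- as.matrix(X)
  p <- ncol(X)
  if (k < 1 || k > p) stop("k must be in [1, ", p, "]")
  median_type <- match.arg(median_type)
  med <- if (median_type == "observed") stats::median(times) else
    km_median(times, events)
  label <- as.integer(times > med)
  if (is.null(feature_kinds)) {
    feature_kinds <- apply(X, 2, function(v)
      if (all(v %in% c(0, 1))) "binary" else "continuous")
  }
  set.seed(seed)
  mi <- vapply(seq_len(p), function(j) {
    v <- X[, j]
    if (feature_kinds[j] %in% c("binary", "onehot")) {
      mi_discrete(v, label)
    } else {
      jit <- v + stats::rnorm(length(v), 0, 1e-10 * max(stats::sd(v), 1))
      mi_ross(jit, label, k = 3L)
    }
  }, numeric(1))
  ord <- order(-mi, seq_len(p))  # ties keep original column order
  sel <- ord[seq_len(k)]
  attr(sel, "mi") <- mi
  sel
}

# Kaplan-Meier median: smallest time where the KM survival estimate drops
# to 0.5 or below (falls back to the observed median if it never does).
km_median <- function(times, events) {
  ord <- order(times)
  t_s <- times[ord]; d_s <- events[ord]
  n <- length(t_s)
  at_risk <- n:1
  surv <- cumprod(1 - d_s / at_risk)
  i <- which(surv <= 0.5)[1]
  if (is.na(i)) stats::median(times) else t_s[i]
}

#' Random train/test split
#'
#' @param data A [survival_data].
#' @param test_frac Fraction held out (default 0.2).
#' @param seed Integer seed; same seed gives the same membership.
#' @return List with `train` and `test` [survival_data] objects and the
#'   held-out row indices as `test_idx`.
#' @export
split_train_test <- function(data, test_frac = 0.2, seed = 1L) {
  n <- length(data$times)
  if (n < 5L) stop("need at least 5 subjects to split")
  set.seed(seed)
  n_test <- max(1L, round(test_frac * n))
  test_idx <- sort(sample.int(n, n_test))
  list(train = subset_survival_data(data, setdiff(seq_len(n), test_idx)),
       test = subset_survival_data(data, test_idx),
       test_idx = test_idx)
}

# Event-stratified fold assignment so every fold contains at least one
# event whenever the data allow it.
make_folds <- function(events, n_folds, seed) {
  set.seed(seed)
  n <- length(events)
  folds <- integer(n)
  ev <- which(events == 1); cs <- which(events == 0)
  folds[sample(ev)] <- rep_len(seq_len(n_folds), length(ev))
  folds[sample(cs)] <- rep_len(seq_len(n_folds), length(cs))
  if (length(ev) >= n_folds) {
    per_fold <- tabulate(folds[ev], n_folds)
    if (any(per_fold == 0)) warning("refolded: a fold had zero events")
  }
  folds
}

#' Cross-validated hyperparameter search for BPS models
#'
#' Seeded random search over the tuning space -- prior SD (log-uniform over
#' its bounds), number of selected features k, and for neural-network
#' predictors the number of hidden layers -- scored by mean C-index over
#' event-stratified cross-validation folds. Continuous features are
#' normalized with training-fold statistics and features are selected by
#' [mi_kbest()] on the training fold only, so no held-out information leaks
#' into the pipeline.
#'
#' @param data A [survival_data].
#' @param distribution,predictor Model family to tune (see [bps_spec()]).
#' @param prior_sd_bounds Bounds of the prior-SD search (default
#'   `c(0.1, 10)`).
#' @param k_bounds Bounds on the number of selected features (default
#'   `c(1, ncol)`).
#' @param n_hidden_layers_bounds Bounds for nn predictors (default
#'   `c(1, 2)`).
#' @param n_folds Cross-validation folds (default 5).
#' @param budget Number of configurations evaluated (default 10).
#' @param seed Seed controlling the search and fold assignment.
#' @param scorer Optional replacement model scorer
#'   `function(train_data, test_X, config) -> risk scores` (used for
#'   injecting baselines in tests); default fits the BPS model.
#' @param chains,warmup,draws Sampler effort per fold fit (kept small by
#'   default: tuning needs ranks, not tail quantiles).
#' @return List with `best` (the winning configuration), `best_score`, and
#'   `trace` (a data frame of every configuration with its mean CV
#'   C-index).
#' @export
cv_tune <- function(data, distribution = "exponential",
                    predictor = "linear",
                    prior_sd_bounds = c(0.1, 10),
                    k_bounds = NULL, n_hidden_layers_bounds = c(1, 2),
                    n_folds = 5L, budget = 10L, seed = 1L,
                    scorer = NULL,
                    chains = 2L, warmup = 250L, draws = 250L) {
  stopifnot(budget >= 1)
  p <- ncol(data$covariates)
  if (is.null(k_bounds)) k_bounds <- c(1L, max(p, 1L))
  if (k_bounds[1] < 1 || k_bounds[2] > p) stop("k bounds outside [1, ", p, "]")
  set.seed(seed)
  pick <- function(v) v[sample.int(length(v), 1L)]  # safe for length-1 v
  configs <- lapply(seq_len(budget), function(i) {
    cfg <- list(
      prior_sd = exp(stats::runif(1, log(prior_sd_bounds[1]),
                                  log(prior_sd_bounds[2]))),
      k = pick(seq.int(k_bounds[1], k_bounds[2])))
    if (predictor == "nn") {
      cfg$n_hidden_layers <- pick(seq.int(n_hidden_layers_bounds[1],
                                          n_hidden_layers_bounds[2]))
    }
    cfg
  })
  folds <- make_folds(data$events, n_folds, seed)
  trace <- data.frame(config = seq_len(budget),
                      prior_sd = vapply(configs, `[[`, numeric(1),
                                        "prior_sd"),
                      k = vapply(configs, `[[`, numeric(1), "k"),
                      cv_c_index = NA_real_)
  if (predictor == "nn") {
    trace$n_hidden_layers <- vapply(configs, `[[`, numeric(1),
                                    "n_hidden_layers")
  }

  eval_config <- function(cfg, cfg_i) {
    cis <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- subset_survival_data(data, which(folds != f))
      te <- subset_survival_data(data, which(folds == f))
      norm <- fit_normalizer(tr$covariates, tr$feature_kinds)
      Xtr <- norm$apply(tr$covariates)
      Xte <- norm$apply(te$covariates)
      sel <- mi_kbest(Xtr, tr$times, tr$events, k = cfg$k,
                      feature_kinds = tr$feature_kinds,
                      seed = seed + f)
      tr_sel <- survival_data(tr$times, tr$events,
                              Xtr[, sel, drop = FALSE],
                              feature_kinds = tr$feature_kinds[sel])
      Xte_sel <- Xte[, sel, drop = FALSE]
      scores <- if (!is.null(scorer)) {
        scorer(tr_sel, Xte_sel, cfg)
      } else {
        spec <- bps_spec(distribution, predictor, prior_sd = cfg$prior_sd,
                         n_hidden_layers = if (predictor == "nn")
                           cfg$n_hidden_layers else 1L)
        m <- suppressWarnings(
          bps_fit(spec, tr_sel, chains = chains, warmup = warmup,
                  draws = draws, seed = seed + 100 * cfg_i + f))
        risk_score(m, Xte_sel)
      }
      cis[f] <- suppressWarnings(
        concordance_index(te$times, te$events, scores))
    }
    mean(cis)
  }

  for (i in seq_len(budget)) {
    trace$cv_c_index[i] <- eval_config(configs[[i]], i)
  }
  best_i <- which.max(trace$cv_c_index)
  list(best = configs[[best_i]], best_score = trace$cv_c_index[best_i],
       trace = trace)
}
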