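# Bayes-rule model updating: the fitted posterior's per-parameter Normal
# summaries become the priors of the next fit, so a model can be handed to
# another institution and updated on new data alone. Correlations between
# parameters are deliberately discarded (only marginal mean/SD travel); the
# overlap-index diagnostic quantifies how much that costs.

#' Turn a fitted posterior into informative priors
#'
#' For every parameter, the prior of the next model is
#' Normal(posterior mean, widen * posterior SD). `widen > 1` deflates the
#' information carried over, which is useful when the old model was trained
#' on a very large sample and would otherwise dominate the new data.
#'
#' @param fit A `bps_fit`.
#' @param widen Positive multiplier on the posterior SDs (default 1).
#' @return A `bps_priors` object matching the fit's parameter layout.
#' @examples
#' # a parameter with posterior mean 2 and SD 0.5 yields prior Normal(2, 0.5)
#' @export
posterior_to_priors <- function(fit, widen = 1) {
  stopifnot(inherits(fit, "bps_fit"), widen > 0)
  mat <- draw_matrix(fit)
  if (nrow(mat) < 2L) stop("need at least 2 posterior draws per parameter")
  mu <- colMeans(mat)
  sd <- apply(mat, 2, stats::sd)
  if (any(sd == 0)) {
    stop("degenerate posterior (zero SD) for: ",
         paste(colnames(mat)[sd == 0], collapse = ", "))
  }
  new_bps_priors(mu, widen * sd)
}

#' Update a fitted model on new data only
#'
#' Refits the same spec on `new_data` with priors taken from the old
#' posterior ([posterior_to_priors()]). The old training data is never
#' touched; the sampling workflow is identical to the initial training.
#'
#' @param fit A `bps_fit` (the "old" model).
#' @param new_data A [survival_data] with the same features as the old fit.
#' @param widen Prior-widening factor passed to [posterior_to_priors()].
#' @param ... Sampler arguments forwarded to [bps_fit()] (chains, warmup,
#'   draws, seed, ...).
#' @return A new `bps_fit`.
#' @export
bps_update <- function(fit, new_data, widen = 1, ...) {
  stopifnot(inherits(fit, "bps_fit"), inherits(new_data, "survival_data"))
  if (length(new_data$times) < 1L) stop("updating requires >= 1 new subject")
  if (!identical(new_data$feature_names, fit$feature_names)) {
    stop("new data features do not match the fitted model; missing: ",
         paste(setdiff(fit$feature_names, new_data$feature_names),
               collapse = ", "),
         "; extra: ",
         paste(setdiff(new_data$feature_names, fit$feature_names),
               collapse = ", "))
  }
  priors <- posterior_to_priors(fit, widen = widen)
  bps_fit(fit$spec, new_data, priors = priors, ...)
}

#' Split a dataset into an ordered stream of partitions
#'
#' Emulates data arriving over time: either a seeded random split into
#' near-equal parts, or a split on a (year-like) covariate column, with
#' partitions ordered by ascending column value and input order preserved
#' within a partition.
#'
#' @param data A [survival_data].
#' @param n_partitions Number of partitions (>= 2, <= number of subjects).
#' @param by `"random"` or the name of a covariate column to group/order by.
#' @param seed Seed for the random mode.
#' @return List of [survival_data] partitions (disjoint, union = data).
#' @export
partition_stream <- function(data, n_partitions, by = "random", seed = 1L) {
  n <- length(data$times)
  if (n_partitions < 2L || n_partitions > n) {
    stop("n_partitions must be between 2 and the number of subjects (", n,
         ")")
  }
  if (identical(by, "random")) {
    set.seed(seed)
    ord <- sample.int(n)
    grp <- sort(rep_len(seq_len(n_partitions), n))
    idx_list <- split(ord, grp)
  } else {
    if (!by %in% data$feature_names) {
      stop("column '", by, "' not found among features")
    }
    v <- data$covariates[, by]
    vals <- sort(unique(v))
    if (length(vals) == n_partitions) {
      idx_list <- lapply(vals, function(y) which(v == y))
    } else {
      # order by the column, then cut into near-equal contiguous chunks
      ord <- order(v, seq_len(n))
      grp <- sort(rep_len(seq_len(n_partitions), n))
      idx_list <- split(ord, grp)
      idx_list <- lapply(idx_list, sort)
    }
  }
  lapply(unname(idx_list), function(idx) subset_survival_data(data, idx))
}

#' Run the full-retrain vs update protocol over a partition stream
#'
#' At step k the test set is partition k+1. In `"update"` mode the training
#' set is partition k only, with priors carried over from step k-1's model
#' (step 1 starts from the default priors). In `"full_retrain"` mode the
#' training set is partitions 1..k and every model starts from the default
#' priors. Test performance is the concordance index of the model's risk
#' scores.
#'
#' @param data A [survival_data].
#' @param spec A [bps_spec].
#' @param n_partitions Number of stream partitions (>= 3).
#' @param mode `"full_retrain"` or `"update"`.
#' @param by,partition_seed Passed to [partition_stream()].
#' @param widen Prior widening for update mode.
#' @param ... Sampler arguments forwarded to [bps_fit()] / [bps_update()].
#' @return Data frame with one row per step: `step`, `n_train`, `c_index`,
#'   plus the final model as attribute `"final_model"` and all per-step
#'   models as attribute `"models"`.
#' @export
run_updating_experiment <- function(data, spec, n_partitions,
                                    mode = c("full_retrain", "update"),
                                    by = "random", partition_seed = 1L,
                                    widen = 1, ...) {
  mode <- match.arg(mode)
  if (n_partitions < 3L) stop("n_partitions must be >= 3")
  parts <- partition_stream(data, n_partitions, by = by,
                            seed = partition_seed)
  steps <- n_partitions - 1L
  res <- data.frame(step = seq_len(steps), n_train = NA_integer_,
                    c_index = NA_real_)
  models <- vector("list", steps)
  prev <- NULL
  for (k in seq_len(steps)) {
    test <- parts[[k + 1L]]
    if (mode == "full_retrain") {
      train <- Reduce(bind_survival_data, parts[seq_len(k)])
      m <- bps_fit(spec, train, ...)
    } else {
      train <- parts[[k]]
      m <- if (k == 1L) bps_fit(spec, train, ...) else
        bps_update(prev, train, widen = widen, ...)
    }
    scores <- risk_score(m, test$covariates)
    res$n_train[k] <- length(train$times)
    res$c_index[k] <- concordance_index(test$times, test$events, scores)
    models[[k]] <- m
    prev <- m
  }
  attr(res, "models") <- models
  attr(res, "final_model") <- prev
  res
}
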