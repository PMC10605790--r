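# Posterior-comparison and decision statistics: highest-density intervals,
# the KDE overlap index, ROPE equivalence decisions, and the superiority
# sample-size computation with its Bonferroni arithmetic.

#' Highest-density interval
#'
#' The narrowest interval containing `level` of the empirical mass of a
#' sample: sort the draws and slide a window of ceiling(level * n) draws,
#' keeping the shortest.
#'
#' @param samples Numeric draws (>= 100 unless `min_n` is lowered).
#' @param level Probability mass in (0, 1). Default 0.94.
#' @param min_n Minimum sample size accepted.
#' @return Numeric `c(lower, upper)`.
#' @examples
#' hdi(rnorm(10000), 0.95)
#' @export
hdi <- function(samples, level = 0.94, min_n = 100L) {
  samples <- as.numeric(samples)
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < min_n) stop("hdi needs at least ", min_n, " samples, got ", n)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  xs <- sort(samples)
  n_incl <- max(ceiling(level * n), 1L)
  n_start <- n - n_incl + 1L
  if (n_start < 1L) return(c(xs[1], xs[n]))
  widths <- xs[n_incl:n] - xs[1:n_start]
  i <- which.min(widths)
  c(lower = xs[i], upper = xs[i + n_incl - 1L])
}

#' Overlap index of two sampled distributions
#'
#' Estimates each density by Gaussian KDE (Silverman's rule-of-thumb
#' bandwidth per sample) on a shared 512-point grid spanning the pooled
#' range extended by three bandwidths, then integrates the pointwise
#' minimum of the two densities. 1 = identical distributions, 0 = disjoint.
#'
#' @param samples_a,samples_b Numeric draws (>= 100 each).
#' @param n_grid Number of grid points (default 512).
#' @return Overlap index in [0, 1]; symmetric in its arguments.
#' @examples
#' overlap_index(rnorm(5000), rnorm(5000, 1))  # about 0.62
#' @export
overlap_index <- function(samples_a, samples_b, n_grid = 512L) {
  a <- as.numeric(samples_a); b <- as.numeric(samples_b)
  if (length(a) < 100L || length(b) < 100L) {
    stop("overlap_index needs at least 100 draws per sample")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("degenerate (zero-variance) sample")
  }
  bw_a <- stats::bw.nrd0(a)
  bw_b <- stats::bw.nrd0(b)
  pad <- 3 * max(bw_a, bw_b)
  lo <- min(a, b) - pad
  hi <- max(a, b) + pad
  da <- stats::density(a, bw = bw_a, from = lo, to = hi, n = n_grid)
  db <- stats::density(b, bw = bw_b, from = lo, to = hi, n = n_grid)
  dx <- da$x[2] - da$x[1]
  ov <- sum(pmin(da$y, db$y)) * dx
  min(max(ov, 0), 1)
}

#' ROPE equivalence decision
#'
#' Computes the HDI of a sample of differences and decides equivalence
#' against a region of practical equivalence (ROPE): accepted if the HDI
#' lies entirely inside the ROPE, rejected if entirely outside, undecided
#' otherwise. `pct_in_rope` is the percentage of the HDI's length inside
#' the ROPE.
#'
#' @param diff_samples Draws of the performance difference.
#' @param rope Length-2 interval, default `c(-0.01, 0.01)`.
#' @param hdi_level HDI mass; default 0.9833 (a 98.33% credible interval,
#'   i.e. 1 - 0.05/3 after a Bonferroni correction for 3 comparisons).
#' @param min_n Minimum number of draws.
#' @return List with `decision` (`"accepted"`, `"rejected"`,
#'   `"undecided"`), `pct_in_rope`, and `hdi`.
#' @export
rope_equivalence <- function(diff_samples, rope = c(-0.01, 0.01),
                             hdi_level = 0.9833, min_n = 1L) {
  if (length(rope) != 2 || rope[1] >= rope[2]) {
    stop("rope must be an interval c(lower, upper) with lower < upper")
  }
  if (length(diff_samples) == 0L) stop("diff_samples is empty")
  h <- if (length(unique(diff_samples)) == 1L) {
    rep(diff_samples[1], 2)
  } else {
    hdi(diff_samples, hdi_level, min_n = min_n)
  }
  w <- h[2] - h[1]
  if (w == 0) {
    inside <- h[1] >= rope[1] && h[1] <= rope[2]
    pct <- if (inside) 100 else 0
  } else {
    overlap <- max(0, min(h[2], rope[2]) - max(h[1], rope[1]))
    pct <- 100 * overlap / w
  }
  decision <- if (pct >= 100) "accepted" else if (pct <= 0) "rejected" else
    "undecided"
  list(decision = decision, pct_in_rope = unname(pct),
       hdi = unname(h))
}

#' Sample size for a two-sample superiority comparison
#'
#' Smallest n per group so a two-sided two-sample t-test detects a mean
#' difference `delta` (SD `sd`) with the requested power at significance
#' level `alpha`, by exact noncentral-t power inversion; rounded up.
#'
#' @param delta Positive mean difference to detect.
#' @param sd Common standard deviation.
#' @param alpha Two-sided significance level.
#' @param power Target power in (0, 1).
#' @return Integer n per group.
#' @examples
#' superiority_sample_size(0.02, 0.025, alpha = 0.05 / 15, power = 0.8) # 47
#' @export
superiority_sample_size <- function(delta, sd, alpha = 0.05, power = 0.8) {
  if (delta <= 0) stop("delta must be positive (no finite n otherwise)")
  if (sd <= 0 || alpha <= 0 || alpha >= 1) stop("invalid sd or alpha")
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  res <- stats::power.t.test(delta = delta, sd = sd, sig.level = alpha,
                             power = power, type = "two.sample",
                             alternative = "two.sided")
  as.integer(ceiling(res$n))
}

#' Bonferroni-corrected per-test significance level
#' @param alpha_family Family-wise error rate.
#' @param n_comparisons Number of tests (>= 1).
#' @return `alpha_family / n_comparisons`.
#' @export
bonferroni_alpha <- function(alpha_family, n_comparisons) {
  if (n_comparisons < 1) stop("n_comparisons must be >= 1")
  alpha_family / n_comparisons
}

#' Number of pairwise comparisons among models
#' @param n_models Number of models compared (>= 1).
#' @return `n_models * (n_models - 1) / 2`.
#' @export
pairwise_count <- function(n_models) {
  if (n_models < 1) stop("n_models must be >= 1")
  as.integer(n_models * (n_models - 1) / 2)
}

#' Per-parameter overlap index between two fitted models
#'
#' Convenience wrapper computing [overlap_index()] for every parameter the
#' two fits share (they must have the same layout).
#'
#' @param fit_a,fit_b `bps_fit` objects with identical parameter layouts.
#' @return Data frame with columns `parameter` and `ovi`.
#' @export
ovi_table <- function(fit_a, fit_b) {
  ma <- draw_matrix(fit_a); mb <- draw_matrix(fit_b)
  if (!identical(colnames(ma), colnames(mb))) {
    stop("models have different parameter layouts")
  }
  data.frame(
    parameter = colnames(ma),
    ovi = vapply(seq_len(ncol(ma)), function(j)
      overlap_index(ma[, j], mb[, j]), numeric(1)),
    stringsAsFactors = FALSE)
}
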