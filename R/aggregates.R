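#' Cluster-size counts
#'
#' The empirical aggregate-size distribution of a suspension culture: for
#' each integer cluster size n >= 1, the number of clusters of that size
#' observed.
#'
#' @param size Integer cluster sizes (>= 1).
#' @param count Non-negative counts per size, at least one nonzero.
#' @return An object of class `"cluster_counts"`: a data frame with columns
#'   `size` and `count` (sorted, deduplicated) and attributes `total_cells`
#'   (sum of size * count) and `total_clusters` (sum of count).
#' @export
cluster_counts <- function(size, count) {
  size <- as.integer(size); count <- as.numeric(count)
  if (length(size) != length(count)) stop("size and count differ in length")
  if (!length(size)) stop("empty cluster counts")
  if (any(size < 1L)) stop("cluster sizes must be integers >= 1")
  if (any(count < 0) || any(!is.finite(count)))
    stop("counts must be finite and non-negative")
  if (all(count == 0)) stop("at least one count must be nonzero")
  agg <- tapply(count, size, sum)
  out <- data.frame(size = as.integer(names(agg)), count = as.numeric(agg))
  out <- out[order(out$size), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cluster_counts", "data.frame"),
            total_cells = sum(out$size * out$count),
            total_clusters = sum(out$count))
}

total_cells <- function(x) attr(x, "total_cells")
total_clusters <- function(x) attr(x, "total_clusters")

#' Geometric cluster-size probability mass function
#'
#' \eqn{f(n) = (1-p)^{n-1} p} for integer cluster size n >= 1. The
#' parameter p is the probability that a cell is not part of an aggregate;
#' the pmf sums to 1 over all n >= 1.
#'
#' @param n Cluster sizes (integers >= 1).
#' @param p Success parameter in (0, 1].
#' @return Probabilities.
#' @examples
#' geometric_pmf(1:5, 0.655)
#' @export
geometric_pmf <- function(n, p) {
  if (any(n < 1) || any(n != floor(n))) stop("n must be integers >= 1")
  if (!is.numeric(p) || any(p <= 0) || any(p > 1))
    stop("p must lie in (0, 1]")
  stats::dgeom(n - 1, prob = p)
}

#' Fraction-of-singles estimator of the geometric parameter
#'
#' Two moment estimators of p from observed cluster counts: the fraction of
#' cells that are present as single cells (`per_cell`, the default: it
#' matches the interpretation of p as the fraction of non-aggregated cells)
#' and the fraction of clusters of size 1 (`per_cluster`, the size-1
#' probability of the cluster-size distribution). The two differ unless the
#' sample is exactly geometric.
#'
#' @param counts A [cluster_counts()].
#' @param weighting `"per_cell"` (default) or `"per_cluster"`.
#' @return The p estimate in (0, 1].
#' @export
singles_fraction <- function(counts, weighting = c("per_cell", "per_cluster")) {
  stopifnot(inherits(counts, "cluster_counts"))
  weighting <- match.arg(weighting)
  ones <- counts$count[counts$size == 1L]
  ones <- if (length(ones)) ones else 0
  if (weighting == "per_cell") ones / total_cells(counts)
  else ones / total_clusters(counts)
}

#' Maximum-likelihood estimator of the geometric parameter
#'
#' For the geometric distribution on cluster sizes the MLE is the inverse
#' mean cluster size, \eqn{\hat p = N_{clusters} / N_{cells}}.
#'
#' @param counts A [cluster_counts()].
#' @return The estimate \eqn{\hat p}.
#' @export
mle_p <- function(counts) {
  stopifnot(inherits(counts, "cluster_counts"))
  total_clusters(counts) / total_cells(counts)
}

# expected cluster counts under the geometric model, with the tail pooled so
# every expected count >= min_expected; the last bin is P(size >= cutoff)
pooled_expected <- function(counts, p, min_expected = 5) {
  N <- total_clusters(counts)
  max_obs <- max(counts$size)
  # start from bins 1..max_obs with an open tail, then pool from the right
  probs <- c(geometric_pmf(seq_len(max_obs), p),
             stats::pgeom(max_obs - 1, p, lower.tail = FALSE))
  obs <- numeric(max_obs + 1L)
  obs[counts$size] <- counts$count
  exp_cnt <- N * probs
  # pool the tail until the last bin's expectation reaches the floor
  while (length(exp_cnt) > 2L &&
         exp_cnt[length(exp_cnt)] < min_expected) {
    k <- length(exp_cnt)
    exp_cnt[k - 1L] <- exp_cnt[k - 1L] + exp_cnt[k]
    obs[k - 1L] <- obs[k - 1L] + obs[k]
    exp_cnt <- exp_cnt[-k]; obs <- obs[-k]
  }
  # pool any interior bin below the floor into its left neighbour
  i <- 2L
  while (i <= length(exp_cnt)) {
    if (exp_cnt[i] < min_expected && length(exp_cnt) > 2L) {
      exp_cnt[i - 1L] <- exp_cnt[i - 1L] + exp_cnt[i]
      obs[i - 1L] <- obs[i - 1L] + obs[i]
      exp_cnt <- exp_cnt[-i]; obs <- obs[-i]
    } else i <- i + 1L
  }
  list(observed = obs, expected = exp_cnt)
}

#' Chi-squared goodness-of-fit against the geometric model
#'
#' Pearson chi-squared test of observed cluster counts against the geometric
#' expectations, with tail bins pooled so that every expected count is at
#' least `min_expected` (default 5, standard practice). Degrees of freedom
#' are `bins - 1 - 1` when p was estimated from the same data, `bins - 1`
#' otherwise.
#'
#' @param counts A [cluster_counts()].
#' @param p The geometric parameter of the null hypothesis.
#' @param p_estimated Was p estimated from `counts` (default TRUE)?
#' @param min_expected Pooling floor for expected counts.
#' @return List with `statistic`, `df`, `p_value`, `pooled_bins`.
#' @export
gof_chi2 <- function(counts, p, p_estimated = TRUE, min_expected = 5) {
  stopifnot(inherits(counts, "cluster_counts"))
  if (total_clusters(counts) < 10)
    stop("goodness-of-fit needs at least 10 clusters")
  pe <- pooled_expected(counts, p, min_expected)
  if (length(pe$expected) < 2L)
    stop("fewer than 2 bins remain after pooling")
  stat <- sum((pe$observed - pe$expected)^2 / pe$expected)
  df <- length(pe$expected) - 1L - as.integer(p_estimated)
  if (df < 1L) stop("non-positive degrees of freedom after pooling")
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       pooled_bins = length(pe$expected))
}

#' G-test (log-likelihood ratio) goodness-of-fit against the geometric model
#'
#' \eqn{G = 2\sum O \ln(O/E)} over the same pooled bins as [gof_chi2()];
#' asymptotically equivalent to the Pearson statistic.
#'
#' @inheritParams gof_chi2
#' @return List with `statistic`, `df`, `p_value`, `pooled_bins`.
#' @export
gof_g_test <- function(counts, p, p_estimated = TRUE, min_expected = 5) {
  stopifnot(inherits(counts, "cluster_counts"))
  if (total_clusters(counts) < 10)
    stop("goodness-of-fit needs at least 10 clusters")
  pe <- pooled_expected(counts, p, min_expected)
  if (length(pe$expected) < 2L)
    stop("fewer than 2 bins remain after pooling")
  nz <- pe$observed > 0
  stat <- 2 * sum(pe$observed[nz] * log(pe$observed[nz] / pe$expected[nz]))
  df <- length(pe$expected) - 1L - as.integer(p_estimated)
  if (df < 1L) stop("non-positive degrees of freedom after pooling")
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       pooled_bins = length(pe$expected))
}

#' Fit the geometric cluster-size model
#'
#' Fits the geometric aggregate-size distribution
#' \eqn{f(n) = (1-p)^{n-1}p} to observed cluster counts. All three
#' estimators of p are computed (per-cell singles fraction, per-cluster
#' singles fraction, maximum likelihood); the one selected by `estimator`
#' drives the goodness-of-fit tests and the methods.
#'
#' @param counts A [cluster_counts()], or a data frame with columns
#'   `size` and `count`.
#' @param estimator Which estimate of p the fitted model uses:
#'   `"per_cell"` (default; p as the fraction of non-aggregated cells),
#'   `"per_cluster"`, or `"mle"`.
#' @param min_expected Pooling floor for the goodness-of-fit bins.
#' @return An object of class `"geomfit"` with components `p`, `estimator`,
#'   `estimates` (all three), `counts`, `gof_chi2`, `gof_g`, `logLik`.
#' @seealso [predict.geomfit()], [simulate.geomfit()], [lambda_link()]
#' @examples
#' cc <- cluster_counts(1:5, c(120, 45, 18, 7, 3))
#' fit <- geom_cluster_fit(cc)
#' fit
#' predict(fit, n_max = 8)
#' @export
geom_cluster_fit <- function(counts,
                             estimator = c("per_cell", "per_cluster", "mle"),
                             min_expected = 5) {
  if (!inherits(counts, "cluster_counts"))
    counts <- cluster_counts(counts$size, counts$count)
  estimator <- match.arg(estimator)
  est <- c(per_cell = singles_fraction(counts, "per_cell"),
           per_cluster = singles_fraction(counts, "per_cluster"),
           mle = mle_p(counts))
  p <- unname(est[[estimator]])
  if (p <= 0 || p > 1) stop("estimated p outside (0, 1]")
  chi2 <- tryCatch(gof_chi2(counts, p, TRUE, min_expected),
                   error = function(e) NULL)
  g <- tryCatch(gof_g_test(counts, p, TRUE, min_expected),
                error = function(e) NULL)
  ll <- sum(counts$count * log(geometric_pmf(counts$size, p)))
  structure(list(p = p, estimator = estimator, estimates = est,
                 counts = counts, gof_chi2 = chi2, gof_g = g,
                 logLik = ll),
            class = "geomfit")
}

#' @export
print.geomfit <- function(x, digits = 4, ...) {
  cat("Geometric cluster-size distribution fit\n")
  cat(sprintf("  clusters: %d   cells: %d\n",
              as.integer(total_clusters(x$counts)),
              as.integer(total_cells(x$counts))))
  cat(sprintf("  p (%s) = %.*g\n", x$estimator, digits, x$p))
  cat(sprintf("  estimates: per-cell %.*g, per-cluster %.*g, MLE %.*g\n",
              digits, x$estimates[["per_cell"]],
              digits, x$estimates[["per_cluster"]],
              digits, x$estimates[["mle"]]))
  invisible(x)
}

#' @export
summary.geomfit <- function(object, ...) {
  structure(list(fit = object), class = "summary.geomfit")
}

#' @export
print.summary.geomfit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat(sprintf("  mean cluster size: %.*g cells\n", digits, 1 / f$estimates[["mle"]]))
  if (!is.null(f$gof_chi2))
    cat(sprintf("  chi-squared GOF: X2 = %.*g, df = %d, p = %.3g (%d pooled bins)\n",
                digits, f$gof_chi2$statistic, f$gof_chi2$df,
                f$gof_chi2$p_value, f$gof_chi2$pooled_bins))
  if (!is.null(f$gof_g))
    cat(sprintf("  G-test GOF:      G  = %.*g, df = %d, p = %.3g\n",
                digits, f$gof_g$statistic, f$gof_g$df, f$gof_g$p_value))
  cat(sprintf("  log-likelihood: %.*g\n", digits, f$logLik))
  invisible(x)
}

#' @export
coef.geomfit <- function(object, ...) c(p = object$p)

#' @export
logLik.geomfit <- function(object, ...) {
  structure(object$logLik, df = 1L, nobs = total_clusters(object$counts),
            class = "logLik")
}

#' Predicted cluster-size probabilities
#'
#' @param object A [geom_cluster_fit()] model.
#' @param n_max Largest cluster size to evaluate (default: largest observed).
#' @param ... Unused.
#' @return Data frame with `size` and `probability`; the probabilities sum
#'   to `1 - (1-p)^n_max`.
#' @export
predict.geomfit <- function(object, n_max = NULL, ...) {
  if (is.null(n_max)) n_max <- max(object$counts$size)
  data.frame(size = seq_len(n_max),
             probability = geometric_pmf(seq_len(n_max), object$p))
}

#' Simulate cluster samples from a fitted geometric model
#'
#' @param object A [geom_cluster_fit()] model.
#' @param nsim Number of clusters to draw per replicate.
#' @param seed Optional seed (restores the RNG state afterwards).
#' @param ... Unused.
#' @return A [cluster_counts()] object.
#' @export
simulate.geomfit <- function(object, nsim = total_clusters(object$counts),
                             seed = NULL, ...) {
  gen_clusters(nsim, object$p, seed = seed)
}

#' Pearson residuals of a geometric cluster fit
#'
#' \eqn{(O - E)/\sqrt{E}} over the pooled goodness-of-fit bins.
#'
#' @param object A [geom_cluster_fit()] model.
#' @param min_expected Pooling floor, as in [gof_chi2()].
#' @param ... Unused.
#' @return Numeric vector of Pearson residuals, one per pooled bin.
#' @export
residuals.geomfit <- function(object, min_expected = 5, ...) {
  pe <- pooled_expected(object$counts, object$p, min_expected)
  (pe$observed - pe$expected) / sqrt(pe$expected)
}

#' Plot observed vs fitted cluster-size distribution
#'
#' @param x A [geom_cluster_fit()] model.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.geomfit <- function(x, ...) {
  n_max <- max(x$counts$size)
  obs <- numeric(n_max); obs[x$counts$size] <- x$counts$count
  obs <- obs / sum(obs)
  fit <- geometric_pmf(seq_len(n_max), x$p)
  bp <- graphics::barplot(obs, names.arg = seq_len(n_max),
                          xlab = "cluster size n",
                          ylab = "fraction of clusters", ...)
  graphics::lines(bp, fit, type = "b", pch = 19)
  graphics::legend("topright", legend = c("observed", "geometric fit"),
                   pch = c(22, 19), lty = c(NA, 1))
  invisible(x)
}

#' Length of a cell chain
#'
#' The extreme elongated form of an aggregate of `n` cells: a linear chain
#' of touching spheres, length `n * d_cell`.
#'
#' @param n Number of cells (>= 1).
#' @param d_cell Cell diameter, m.
#' @return Chain length, m.
#' @examples
#' chain_length(3, 15.5e-6)  # 46.5 um
#' @export
chain_length <- function(n, d_cell) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(d_cell < 0)) stop("d_cell must be non-negative")
  n * d_cell
}

#' Circumscribing diameter of a close-packed three-cell cluster
#'
#' The extreme compact form of a three-cell aggregate: three coplanar,
#' mutually tangent equal spheres. The circumscribing circle has diameter
#' \eqn{d (1 + 2/\sqrt 3)}.
#'
#' @param d_cell Cell diameter, m.
#' @return Cluster diameter, m.
#' @examples
#' close_packed_diameter_3(15.5e-6)  # 33.4 um
#' @export
close_packed_diameter_3 <- function(d_cell) {
  if (any(d_cell < 0)) stop("d_cell must be non-negative")
  d_cell * (1 + 2 / sqrt(3))
}
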