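#' Linear link between mean Kolmogorov length and the geometric parameter
#'
#' Across cultivation systems and types of mechanical power input, the
#' fraction of non-aggregated cells p depends linearly on the volume-averaged
#' Kolmogorov length: \eqn{p = a + b\,\bar\lambda_k}. Fitting this link
#' (ordinary least squares of p on lambda) lets a CFD-derived mean
#' Kolmogorov length predict the whole aggregate-size distribution in
#' silico.
#'
#' `lambda_link()` with no data returns the published default link with
#' intercept 0.92 and slope -4589 per metre.
#'
#' @param lambda_mean Mean Kolmogorov lengths, m (>= 2 distinct values when
#'   fitting).
#' @param p Observed geometric parameters matching `lambda_mean`.
#' @param intercept,slope Coefficients used when no data are given.
#' @return An object of class `"lambda_link"`: list with `intercept`,
#'   `slope` (1/m), and for fitted links `r_squared` and the underlying
#'   `lm` fit.
#' @examples
#' lambda_link()                        # published default
#' lambda_link(c(1.025e-4, 6.123e-5), c(0.433, 0.655))  # two-point fit
#' @export
lambda_link <- function(lambda_mean = NULL, p = NULL,
                        intercept = 0.92, slope = -4589) {
  if (is.null(lambda_mean)) {
    if (!is.finite(intercept) || !is.finite(slope))
      stop("link coefficients must be finite")
    return(structure(list(intercept = intercept, slope = slope,
                          r_squared = NA_real_, fit = NULL),
                     class = "lambda_link"))
  }
  lambda_mean <- as.numeric(lambda_mean); p <- as.numeric(p)
  if (length(lambda_mean) != length(p))
    stop("lambda_mean and p differ in length")
  if (length(unique(lambda_mean)) < 2L)
    stop("need at least 2 distinct lambda values to fit the link")
  fit <- stats::lm(p ~ lambda_mean)
  cf <- stats::coef(fit)
  r2 <- if (length(p) > 2L)
    suppressWarnings(summary(fit)$r.squared) else 1
  structure(list(intercept = unname(cf[1L]), slope = unname(cf[2L]),
                 r_squared = r2, fit = fit),
            class = "lambda_link")
}

#' @export
print.lambda_link <- function(x, digits = 6, ...) {
  cat("Kolmogorov-length link: p = intercept + slope * lambda\n")
  cat(sprintf("  intercept %.*g   slope %.*g 1/m\n",
              digits, x$intercept, digits, x$slope))
  if (is.finite(x$r_squared)) cat(sprintf("  R^2 %.4f\n", x$r_squared))
  invisible(x)
}

#' @export
coef.lambda_link <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict the geometric parameter from a mean Kolmogorov length
#'
#' Evaluates the linear link and clamps the result to \[0, 1\] (the link is
#' unphysical for large lambda; clamping is reported with a warning).
#'
#' @param lambda_mean Mean Kolmogorov length(s), m (>= 0).
#' @param link A [lambda_link()]; default the published coefficients
#'   (0.92, -4589).
#' @return Predicted p in \[0, 1\].
#' @examples
#' predict_p(6.123e-5)  # ~0.639
#' @export
predict_p <- function(lambda_mean, link = lambda_link()) {
  stopifnot(inherits(link, "lambda_link"))
  if (any(lambda_mean < 0)) stop("lambda_mean must be non-negative")
  p <- link$intercept + link$slope * lambda_mean
  if (any(p < 0) || any(p > 1))
    warning("predicted p outside [0, 1]; clamped (the linear link is unphysical there)")
  pmin(pmax(p, 0), 1)
}

#' @export
predict.lambda_link <- function(object, lambda_mean, ...) {
  predict_p(lambda_mean, object)
}

#' Predict a full aggregate-size distribution from a mean Kolmogorov length
#'
#' Composes [predict_p()] with the geometric pmf: the in-silico predicted
#' cluster-size distribution at the time of maximum cell density.
#'
#' @param lambda_mean Mean Kolmogorov length, m.
#' @param link A [lambda_link()].
#' @param n_max Largest cluster size to evaluate.
#' @return Data frame with `size` and `probability` for n = 1..n_max; the
#'   probabilities sum to `1 - (1-p)^n_max`.
#' @export
predict_distribution <- function(lambda_mean, link = lambda_link(),
                                 n_max = 10L) {
  p <- predict_p(lambda_mean, link)
  if (p == 0)
    stop("predicted p is 0; the geometric distribution is degenerate there")
  data.frame(size = seq_len(n_max),
             probability = geometric_pmf(seq_len(n_max), p))
}
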