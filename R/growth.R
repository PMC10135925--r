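#' Growth time series
#'
#' Viable-cell-density time course of a batch cultivation, optionally with a
#' viability trace.
#'
#' @param time Sampling times in h, strictly increasing, >= 2 points.
#' @param vcd Viable cell density in cells/mL, strictly positive.
#' @param viability Optional viability in percent (0-100).
#' @return An object of class `"growth_series"` (a data frame).
#' @export
growth_series <- function(time, vcd, viability = NULL) {
  time <- as.numeric(time); vcd <- as.numeric(vcd)
  if (length(time) < 2L) stop("a growth series needs at least two points")
  if (length(vcd) != length(time)) stop("time and vcd differ in length")
  if (is.unsorted(time, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(vcd <= 0) || any(!is.finite(vcd)))
    stop("VCD must be finite and strictly positive")
  if (!is.null(viability)) {
    viability <- as.numeric(viability)
    if (length(viability) != length(time))
      stop("viability and time differ in length")
    if (any(viability < 0 | viability > 100, na.rm = TRUE))
      stop("viability must lie in [0, 100] percent")
  }
  out <- data.frame(time = time, vcd = vcd)
  if (!is.null(viability)) out$viability <- viability
  structure(out, class = c("growth_series", "data.frame"))
}

#' Maximum specific growth rate
#'
#' Slides a window of width `window` hours over the series and fits, within
#' each window, an ordinary-least-squares line to `ln(VCD)` versus time; the
#' maximum slope over all windows is the maximum specific growth rate
#' \eqn{\mu_{max}}. OLS on the log scale is used rather than two-point
#' ratios for noise robustness.
#'
#' @param series A [growth_series()].
#' @param window Window width in h, default 48 (typical exponential-phase
#'   span of a mammalian batch culture, e.g. 24-72 h).
#' @return List with `mu_max` (1/h), `window_start`, `window_end` (h).
#' @export
mu_max <- function(series, window = 48) {
  stopifnot(inherits(series, "growth_series"))
  t <- series$time; lv <- log(series$vcd)
  best <- -Inf; w_start <- NA_real_; w_end <- NA_real_
  for (i in seq_along(t)) {
    j <- which(t >= t[i] & t <= t[i] + window)
    if (length(j) < 2L) next
    slope <- stats::cov(t[j], lv[j]) / stats::var(t[j])
    if (slope > best) {
      best <- slope; w_start <- t[j][1L]; w_end <- t[j][length(j)]
    }
  }
  if (!is.finite(best)) stop("no window contains at least two points")
  list(mu_max = best, window_start = w_start, window_end = w_end)
}

#' Maximum viable cell density with viability gating
#'
#' The maximum VCD among points whose viability is at or above the floor
#' (default 95%), and the time at which it occurs. Dying cultures can show
#' spurious late VCD readings at low viability; the gate excludes them.
#' When no point passes the gate, the unconditional maximum is returned
#' with a warning.
#'
#' @param series A [growth_series()].
#' @param viability_floor Minimum viability in percent, default 95.
#' @return List with `vcd_max` (cells/mL) and `time` (h).
#' @export
vcd_max <- function(series, viability_floor = 95) {
  stopifnot(inherits(series, "growth_series"))
  keep <- if (!is.null(series$viability))
    which(series$viability >= viability_floor) else seq_len(nrow(series))
  if (!length(keep)) {
    warning("no point passes the viability floor; returning the unconditional maximum")
    keep <- seq_len(nrow(series))
  }
  i <- keep[which.max(series$vcd[keep])]
  list(vcd_max = series$vcd[i], time = series$time[i])
}

#' Percent increase relative to a reference
#'
#' \eqn{100 (a - b)/b}.
#'
#' @param a Value.
#' @param b Reference (> 0).
#' @return Percent change (negative for decreases).
#' @examples
#' percent_increase(5.77e6, 5.38e6)  # 7.2 %
#' @export
percent_increase <- function(a, b) {
  if (any(b <= 0)) stop("reference must be strictly positive")
  100 * (a - b) / b
}

#' Cell-diameter statistics with instrument-class binning
#'
#' Mean and standard deviation of raw cell diameters plus the histogram in
#' fixed-width classes (default 1 micrometre, the resolution of imaging cell
#' counters). Bins are left-closed with integer centres:
#' class c covers \[c - w/2, c + w/2).
#'
#' @param diameters Cell diameters in micrometres.
#' @param bin_width Class width in micrometres, default 1.
#' @param range Declared instrument range, default c(2, 40) micrometres;
#'   values outside it raise an error.
#' @return List with `mean`, `sd` (of the raw values) and `histogram`
#'   (data frame `center`, `count`).
#' @export
diameter_stats <- function(diameters, bin_width = 1, range = c(2, 40)) {
  diameters <- as.numeric(diameters)
  if (!length(diameters)) stop("empty diameter sample")
  if (any(diameters < range[1L] | diameters > range[2L]))
    stop("diameters outside the declared instrument range")
  # floor(x + 1/2) keeps the classes left-closed (round() would tie-to-even)
  center <- floor(diameters / bin_width + 0.5) * bin_width
  tab <- table(center)
  hist <- data.frame(center = as.numeric(names(tab)),
                     count = as.integer(tab))
  list(mean = mean(diameters), sd = stats::sd(diameters), histogram = hist)
}
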