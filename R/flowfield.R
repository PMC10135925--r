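#' Finite-volume flow field
#'
#' Container for per-cell turbulence quantities exported from a finite-volume
#' CFD solution: cell volume, turbulent kinetic energy `k`, specific
#' dissipation rate `omega`, and optionally the dissipation rate `epsilon`
#' and the nine velocity-gradient components. All hydrodynamic-stress
#' statistics in this package operate on this container.
#'
#' @param volume Cell volumes V_i in m^3 (strictly positive).
#' @param k Turbulent kinetic energy per cell in m^2/s^2 (non-negative).
#' @param omega Specific dissipation rate per cell in 1/s (non-negative).
#' @param epsilon Optional dissipation rate per cell in m^2/s^3. When absent
#'   it is derived from `k` and `omega` on demand (see
#'   [epsilon_from_k_omega()]).
#' @param grad_v Optional velocity gradients: an n x 9 matrix with columns
#'   `dudx,dudy,dudz,dvdx,dvdy,dvdz,dwdx,dwdy,dwdz` in 1/s.
#' @param total_volume Declared total liquid volume V in m^3. Defaults to
#'   `sum(volume)`.
#' @param tol Relative tolerance between `sum(volume)` and `total_volume`
#'   below which the mismatch is silent; mismatches up to 1e-2 produce a
#'   warning (exported subsets of multiphase fields routinely lose cells),
#'   larger mismatches are an error.
#'
#' @return An object of class `"flow_field"`.
#' @export
flow_field <- function(volume, k = NULL, omega = NULL, epsilon = NULL,
                       grad_v = NULL, total_volume = NULL, tol = 1e-6) {
  volume <- as.numeric(volume)
  n <- length(volume)
  if (n < 1L) stop("flow_field needs at least one cell")
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("all cell volumes must be finite and strictly positive; first offender at index ",
         which(!is.finite(volume) | volume <= 0)[1L])
  chk <- function(x, name) {
    if (is.null(x)) return(NULL)
    x <- as.numeric(x)
    if (length(x) != n) stop(name, " must have one value per cell")
    bad <- which(!is.finite(x) | x < 0)
    if (length(bad))
      stop("negative or non-finite ", name, " at record index ", bad[1L])
    x
  }
  k <- chk(k, "k")
  omega <- chk(omega, "omega")
  epsilon <- chk(epsilon, "epsilon")
  if (is.null(epsilon) && (is.null(k) || is.null(omega)))
    stop("either epsilon or both k and omega must be supplied")
  if (!is.null(grad_v)) {
    grad_v <- as.matrix(grad_v)
    if (nrow(grad_v) != n || ncol(grad_v) != 9L)
      stop("grad_v must be an n x 9 matrix of velocity-gradient components")
    if (any(!is.finite(grad_v))) stop("grad_v entries must be finite")
  }
  vsum <- sum(volume)
  if (is.null(total_volume)) total_volume <- vsum
  if (total_volume <= 0) stop("total_volume must be strictly positive")
  rel <- abs(vsum - total_volume) / total_volume
  if (rel > 1e-2)
    stop(sprintf("sum of cell volumes differs from total_volume by %.3g relative (> 1e-2)", rel))
  if (rel > tol)
    warning(sprintf(
      "sum of cell volumes differs from total_volume by %.3g relative; statistics are normalised by sum(volume)",
      rel))
  structure(list(volume = volume, k = k, omega = omega, epsilon = epsilon,
                 grad_v = grad_v, total_volume = total_volume),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("Flow field: %d cells, total volume %.4g m^3\n",
              length(x$volume), x$total_volume))
  cat("  fields:", paste(c("volume",
                           if (!is.null(x$k)) "k",
                           if (!is.null(x$omega)) "omega",
                           if (!is.null(x$epsilon)) "epsilon",
                           if (!is.null(x$grad_v)) "grad_v"), collapse = ", "),
      "\n")
  invisible(x)
}

#' Dissipation rate from k and omega
#'
#' Under k-omega-family turbulence closures the local energy dissipation rate
#' is not transported directly; it is recovered as
#' \eqn{\epsilon_i = \beta^* k_i \omega_i} with the model constant
#' \eqn{\beta^* = 0.09}.
#'
#' @param k Turbulent kinetic energy, m^2/s^2 (vector), or a [flow_field()].
#' @param omega Specific dissipation rate, 1/s (ignored when `k` is a
#'   flow field).
#' @param beta_star Model constant, default 0.09.
#' @param overwrite For a flow-field input: replace an already-present
#'   `epsilon` (default `FALSE`; a provided epsilon wins).
#'
#' @return A numeric vector of dissipation rates, or the flow field with its
#'   `epsilon` field filled.
#' @examples
#' epsilon_from_k_omega(1, 1)       # 0.09
#' epsilon_from_k_omega(2.5, 4)     # 0.9
#' @export
epsilon_from_k_omega <- function(k, omega = NULL, beta_star = 0.09,
                                 overwrite = FALSE) {
  if (inherits(k, "flow_field")) {
    field <- k
    if (!is.null(field$epsilon) && !overwrite) return(field)
    if (is.null(field$k) || is.null(field$omega))
      stop("flow field has no k/omega to derive epsilon from")
    field$epsilon <- epsilon_from_k_omega(field$k, field$omega, beta_star)
    return(field)
  }
  k <- as.numeric(k); omega <- as.numeric(omega)
  bad <- which(k < 0 | omega < 0)
  if (length(bad))
    stop("negative k or omega at record index ", bad[1L])
  beta_star * k * omega
}

# internal: per-cell epsilon, deriving from k*omega when not stored
field_epsilon <- function(field) {
  if (!is.null(field$epsilon)) return(field$epsilon)
  epsilon_from_k_omega(field$k, field$omega)
}

#' Kolmogorov length scale
#'
#' The smallest turbulent eddy scale,
#' \eqn{\lambda_k = (\nu^3/\epsilon)^{1/4}}. Eddies smaller than a cell or
#' aggregate are considered potentially damaging to suspension cells.
#'
#' @param nu Kinematic viscosity, m^2/s (scalar > 0).
#' @param epsilon Dissipation rate(s), m^2/s^3.
#' @param on_zero What to do for quiescent cells with `epsilon == 0`:
#'   `"inf"` (default) returns `Inf` with a warning, `"error"` stops.
#'
#' @return Lengths in m, strictly decreasing in `epsilon`.
#' @examples
#' kolmogorov_length(1, 1)                 # 1
#' kolmogorov_length(6.959e-7, 1e-3)       # ~1.355e-4 m
#' @export
kolmogorov_length <- function(nu, epsilon, on_zero = c("inf", "error")) {
  on_zero <- match.arg(on_zero)
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0)
    stop("nu must be a strictly positive scalar")
  epsilon <- as.numeric(epsilon)
  if (any(epsilon < 0, na.rm = TRUE)) stop("epsilon must be non-negative")
  z <- epsilon == 0
  if (any(z)) {
    if (on_zero == "error") stop("epsilon is zero in ", sum(z), " quiescent cell(s)")
    warning(sum(z), " quiescent cell(s) with epsilon = 0; Kolmogorov length is Inf there")
  }
  (nu^3 / epsilon)^0.25
}

#' Volume-weighted mean of a per-cell quantity
#'
#' Finite-volume fields on unstructured meshes have unequal cell volumes, so
#' plain averages are biased; the physically meaningful mean is
#' \eqn{\sum_i q_i V_i / \sum_i V_i}.
#'
#' @param values Per-cell scalar, aligned with the cells of `field`.
#' @param field A [flow_field()], or a numeric vector of cell volumes.
#' @return The volume-weighted mean.
#' @export
volume_weighted_mean <- function(values, field) {
  w <- if (inherits(field, "flow_field")) field$volume else as.numeric(field)
  values <- as.numeric(values)
  if (length(values) != length(w))
    stop("values and cell volumes differ in length (", length(values),
         " vs ", length(w), ")")
  sum(values * w) / sum(w)
}

#' Specific power input from torque
#'
#' \eqn{P/V = 2\pi n M / V}: the mechanical power delivered by a rotating
#' system at frequency `n` against torque `M`, per liquid volume.
#'
#' @param n Rotational frequency, 1/s.
#' @param M Torque, N m.
#' @param V Liquid volume, m^3 (> 0).
#' @return P/V in W/m^3.
#' @export
power_per_volume_from_torque <- function(n, M, V) {
  if (!is.numeric(V) || any(V <= 0)) stop("V must be strictly positive")
  2 * pi * n * M / V
}

#' Specific power input from the dissipation field
#'
#' Volume integral of the dissipation rate,
#' \eqn{P/V = \sum_i \epsilon_i V_i \rho / V}. On unstructured meshes each
#' local rate must be weighted by its control volume. This route typically
#' underestimates the torque route by up to ~50% in RANS solutions.
#'
#' @param field A [flow_field()]. `epsilon` is derived from `k` and `omega`
#'   when not stored.
#' @param fluid A [fluid_properties()].
#' @return P/V in W/m^3.
#' @export
power_per_volume_from_dissipation <- function(field, fluid) {
  stopifnot(inherits(field, "flow_field"), inherits(fluid, "fluid_properties"))
  eps <- field_epsilon(field)
  fluid$density * volume_weighted_mean(eps, field)
}

#' Hydrodynamic heterogeneity
#'
#' \eqn{\Phi = \epsilon_{max}/\bar\epsilon}: the ratio of the spatial maximum
#' dissipation rate to the volume-weighted mean. Orbitally shaken systems are
#' homogeneous (Phi of order 1-20); stirred tanks are strongly heterogeneous
#' (Phi of order 10-400) because dissipation concentrates at the impeller.
#'
#' @param field A [flow_field()].
#' @param max_quantile Quantile used for the "maximum"; default 1 (the raw
#'   cell-wise maximum). Single-cell outliers dominate CFD maxima, so a
#'   trimmed variant (e.g. 0.999) is available.
#' @return Phi >= 1 (dimensionless) for `max_quantile = 1`.
#' @export
heterogeneity <- function(field, max_quantile = 1) {
  stopifnot(inherits(field, "flow_field"))
  eps <- field_epsilon(field)
  m <- volume_weighted_mean(eps, field)
  if (m <= 0) stop("mean dissipation rate is zero; heterogeneity undefined")
  top <- if (max_quantile >= 1) max(eps) else
    as.numeric(stats::quantile(eps, max_quantile, names = FALSE))
  top / m
}

#' Volume-weighted distribution of the Kolmogorov length
#'
#' Histograms the per-cell Kolmogorov lengths with each cell contributing its
#' volume fraction, giving the volume-related probability distribution of the
#' eddy size; also reports the volume-weighted mean and median.
#'
#' @param field A [flow_field()].
#' @param fluid A [fluid_properties()].
#' @param bin_edges Monotone increasing bin edges in m. Default: 200
#'   logarithmic bins spanning `[min/1.05, max*1.05]` of the attained finite
#'   lengths.
#' @param n_bins Number of logarithmic bins for the default scheme.
#'
#' @return An object of class `"lambda_distribution"`: list with `bin_edges`,
#'   `volume_fraction` (sums to 1), `lambda_mean`, `lambda_median`,
#'   `quiescent_volume_fraction` (volume of cells with epsilon = 0, clamped
#'   into the topmost bin so that no volume is dropped).
#' @export
lambda_volume_distribution <- function(field, fluid, bin_edges = NULL,
                                       n_bins = 200L) {
  stopifnot(inherits(field, "flow_field"), inherits(fluid, "fluid_properties"))
  eps <- field_epsilon(field)
  quies <- eps == 0
  lam <- suppressWarnings(
    kolmogorov_length(fluid$kinematic_viscosity, eps))
  fin <- lam[is.finite(lam)]
  if (!length(fin)) stop("all cells are quiescent; no finite Kolmogorov length")
  if (is.null(bin_edges)) {
    lo <- min(fin) / 1.05; hi <- max(fin) * 1.05
    if (lo == hi) { lo <- lo / 1.05; hi <- hi * 1.05 }
    bin_edges <- exp(seq(log(lo), log(hi), length.out = n_bins + 1L))
  }
  bin_edges <- as.numeric(bin_edges)
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  if (min(fin) < bin_edges[1L] || max(fin) > bin_edges[length(bin_edges)])
    warning("bins do not cover the attained Kolmogorov-length range; out-of-range volume is clamped to the edge bins")
  # clamp: quiescent (Inf) and overflow into last bin, underflow into first
  lam_cl <- pmin(pmax(lam, bin_edges[1L]),
                 bin_edges[length(bin_edges)])
  idx <- findInterval(lam_cl, bin_edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  w <- field$volume / sum(field$volume)
  frac <- vapply(seq_len(length(bin_edges) - 1L),
                 function(b) sum(w[idx == b]), numeric(1))
  # volume-weighted mean over finite lambdas only (quiescent volume reported)
  lam_mean <- sum(lam[!quies] * field$volume[!quies]) / sum(field$volume[!quies])
  # volume-weighted median: smallest lambda with cumulative volume >= 1/2
  o <- order(lam)
  cw <- cumsum(w[o])
  lam_median <- lam[o][which(cw >= 0.5)[1L]]
  structure(list(bin_edges = bin_edges, volume_fraction = frac,
                 lambda_mean = lam_mean, lambda_median = lam_median,
                 quiescent_volume_fraction = sum(w[quies])),
            class = "lambda_distribution")
}

#' @export
print.lambda_distribution <- function(x, ...) {
  cat("Volume-weighted Kolmogorov-length distribution\n")
  cat(sprintf("  bins: %d, range %.4g - %.4g m\n",
              length(x$volume_fraction), x$bin_edges[1L],
              x$bin_edges[length(x$bin_edges)]))
  cat(sprintf("  volume-weighted mean   %.4g m\n", x$lambda_mean))
  cat(sprintf("  volume-weighted median %.4g m\n", x$lambda_median))
  if (x$quiescent_volume_fraction > 0)
    cat(sprintf("  quiescent volume fraction %.4g\n", x$quiescent_volume_fraction))
  invisible(x)
}

#' Volume fraction below a critical Kolmogorov length
#'
#' Fraction (and absolute volume) of the liquid in which the Kolmogorov
#' length is below a critical scale, e.g. the cell diameter or the size of a
#' small aggregate; this is the volume where eddies are small enough to be
#' potentially damaging.
#'
#' @param field A [flow_field()].
#' @param fluid A [fluid_properties()].
#' @param lambda_crit Critical length in m (> 0).
#' @return List with `fraction` (in \[0,1\]) and `absolute_volume` in m^3
#'   (fraction times the declared total volume).
#' @export
volume_fraction_below <- function(field, fluid, lambda_crit) {
  stopifnot(inherits(field, "flow_field"), inherits(fluid, "fluid_properties"))
  if (!is.numeric(lambda_crit) || length(lambda_crit) != 1L || lambda_crit <= 0)
    stop("lambda_crit must be a strictly positive scalar")
  eps <- field_epsilon(field)
  lam <- suppressWarnings(kolmogorov_length(fluid$kinematic_viscosity, eps))
  frac <- sum(field$volume[lam < lambda_crit]) / sum(field$volume)
  list(fraction = frac, absolute_volume = frac * field$total_volume)
}

#' Q-criterion (second invariant of the velocity gradient tensor)
#'
#' \eqn{Q = \frac12[(\mathrm{tr}\,\nabla v)^2 -
#' \mathrm{tr}(\nabla v\,\nabla v)]}. Positive values mark regions where
#' vorticity dominates over viscous strain; iso-surfaces of Q are the
#' standard vortex visualisation.
#'
#' @param grad_v A 3x3 velocity-gradient tensor (1/s), or an n x 9 matrix of
#'   row-wise tensors in the column order
#'   `dudx,dudy,dudz,dvdx,dvdy,dvdz,dwdx,dwdy,dwdz`.
#' @return Q in 1/s^2 (scalar or length-n vector).
#' @examples
#' # solid-body rotation at rate w about z: Q = w^2
#' w <- 2.5
#' q_criterion(matrix(c(0, -w, 0, w, 0, 0, 0, 0, 0), 3, byrow = TRUE))
#' @export
q_criterion <- function(grad_v) {
  g <- as.matrix(grad_v)
  if (nrow(g) == 3L && ncol(g) == 3L) {
    if (any(!is.finite(g))) stop("grad_v entries must be finite")
    tr <- sum(diag(g))
    return(0.5 * (tr^2 - sum(diag(g %*% g))))
  }
  if (ncol(g) != 9L)
    stop("grad_v must be a 3x3 tensor or an n x 9 matrix")
  if (any(!is.finite(g))) stop("grad_v entries must be finite")
  tr <- g[, 1L] + g[, 5L] + g[, 9L]
  # tr(G.G) = sum_ij G_ij G_ji, with G row-major (dudx..dwdz)
  trgg <- g[, 1L]^2 + g[, 5L]^2 + g[, 9L]^2 +
    2 * (g[, 2L] * g[, 4L] + g[, 3L] * g[, 7L] + g[, 6L] * g[, 8L])
  0.5 * (tr^2 - trgg)
}

#' Hydrodynamic summary report of a flow field
#'
#' One-call summary of the hydrodynamic-stress statistics: specific power
#' input (dissipation route, and torque route when a torque is supplied),
#' mean dissipation rate, mean and median Kolmogorov length, hydrodynamic
#' heterogeneity, and volume fractions below user thresholds.
#'
#' @param field A [flow_field()].
#' @param fluid A [fluid_properties()].
#' @param lambda_thresholds Critical Kolmogorov lengths (m) to report volume
#'   fractions for.
#' @param n Rotational frequency (1/s) and @param torque torque (N m) for the
#'   torque route; both optional.
#' @param torque see `n`.
#' @return A list (JSON-serialisable) with the statistics above.
#' @export
hydro_report <- function(field, fluid, lambda_thresholds = numeric(),
                         n = NULL, torque = NULL) {
  eps <- field_epsilon(field)
  dist <- lambda_volume_distribution(field, fluid)
  out <- list(
    power_per_volume_dissipation = power_per_volume_from_dissipation(field, fluid),
    power_per_volume_torque = if (!is.null(n) && !is.null(torque))
      power_per_volume_from_torque(n, torque, field$total_volume),
    epsilon_mean = volume_weighted_mean(eps, field),
    lambda_mean = dist$lambda_mean,
    lambda_median = dist$lambda_median,
    heterogeneity = heterogeneity(field),
    volume_fraction_below = lapply(lambda_thresholds, function(l)
      c(list(lambda_crit = l), volume_fraction_below(field, fluid, l)))
  )
  out[!vapply(out, is.null, logical(1))]
}
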