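# All generators are pure functions of their arguments plus the seed: the
# RNG state is saved and restored around every draw, so seeded calls are
# bytewise reproducible and never perturb the caller's stream.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic turbulence field
#'
#' Emulates an exported finite-volume dissipation field with prescribed
#' volume-weighted mean dissipation rate and hydrodynamic heterogeneity
#' (max/mean). Dissipation is drawn log-normal - the standard positively
#' skewed model for dissipation in agitated vessels - with the log-scale
#' spread adjusted by bisection until the heterogeneity matches, then
#' rescaled multiplicatively so the volume-weighted mean matches within
#' 0.1%. `k` and `omega` are back-filled so that
#' `k * omega * 0.09 = epsilon` with a plausible turbulence length scale.
#'
#' @param n_cells Number of cells.
#' @param total_volume Total liquid volume V, m^3.
#' @param epsilon_mean Target volume-weighted mean dissipation rate, m^2/s^3.
#' @param heterogeneity Target max/mean ratio Phi >= 1.
#' @param volume_distribution `"uniform"` or `"lognormal"` cell volumes.
#' @param length_scale Nominal turbulence length scale for the k back-fill,
#'   m; k is set to `(epsilon * length_scale)^(2/3)` (only the product
#'   k * omega is constrained by the field).
#' @param seed Seed for reproducibility.
#' @param tol Relative tolerance on the heterogeneity match, default 5%.
#' @param max_iter Bisection cap, default 100.
#' @return A [flow_field()] with `k`, `omega` and `epsilon` filled.
#' @export
gen_flowfield <- function(n_cells, total_volume, epsilon_mean,
                          heterogeneity = 1,
                          volume_distribution = c("uniform", "lognormal"),
                          length_scale = 8.5e-3, seed = NULL,
                          tol = 0.05, max_iter = 100L) {
  volume_distribution <- match.arg(volume_distribution)
  if (epsilon_mean <= 0) stop("epsilon_mean must be strictly positive")
  if (heterogeneity < 1) stop("heterogeneity must be at least 1")
  if (n_cells < 2L && heterogeneity > 1)
    stop("heterogeneity above 1 is infeasible with fewer than 2 cells")
  with_seed(seed, {
    vol <- switch(volume_distribution,
                  uniform = rep(1, n_cells),
                  lognormal = stats::rlnorm(n_cells, 0, 0.5))
    vol <- vol / sum(vol) * total_volume
    u <- stats::rnorm(n_cells)
    phi_of <- function(sigma) {
      e <- exp(sigma * u)
      max(e) / (sum(e * vol) / sum(vol))
    }
    if (heterogeneity == 1) {
      eps <- rep(epsilon_mean, n_cells)
    } else {
      lo <- 0; hi <- 1
      while (phi_of(hi) < heterogeneity) {
        hi <- hi * 2
        if (hi > 64) stop("target heterogeneity infeasible for this field")
      }
      for (it in seq_len(max_iter)) {
        mid <- (lo + hi) / 2
        phi <- phi_of(mid)
        if (abs(phi - heterogeneity) / heterogeneity < tol * 0.1) break
        if (phi < heterogeneity) lo <- mid else hi <- mid
      }
      eps <- exp(mid * u)
      if (abs(phi_of(mid) - heterogeneity) / heterogeneity > tol)
        stop("heterogeneity bisection did not reach the target within tolerance")
    }
    eps <- eps * epsilon_mean / (sum(eps * vol) / sum(vol))
    k <- (eps * length_scale)^(2 / 3)
    omega <- ifelse(k > 0, eps / (0.09 * k), 0)
    flow_field(volume = vol, k = k, omega = omega, epsilon = eps,
               total_volume = total_volume)
  })
}

#' Generate a geometric cluster-size sample
#'
#' Draws `n_clusters` i.i.d. cluster sizes from the geometric distribution
#' with parameter `p` and tabulates them.
#'
#' @param n_clusters Number of clusters to draw.
#' @param p Geometric parameter in (0, 1].
#' @param seed Seed for reproducibility.
#' @return A [cluster_counts()] object.
#' @export
gen_clusters <- function(n_clusters, p, seed = NULL) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1)
    stop("p must lie in (0, 1]")
  if (n_clusters < 1) stop("n_clusters must be at least 1")
  with_seed(seed, {
    sizes <- stats::rgeom(n_clusters, p) + 1L
    tab <- table(sizes)
    cluster_counts(as.integer(names(tab)), as.numeric(tab))
  })
}

#' Generate a power-law mesh-convergence series
#'
#' Emulates a mesh study on a quantity converging as
#' \eqn{f(h) = f_\infty + C h^p} with the representative spacing
#' \eqn{h = n_c^{-1/3}} (3D convention), optionally with additive noise.
#'
#' @param f_limit Mesh-independent limit value.
#' @param coefficient Error coefficient C.
#' @param order Convergence order p > 0.
#' @param cell_counts Strictly increasing cell counts.
#' @param noise_sd Additive Gaussian noise SD, default 0.
#' @param safety_factor Passed to [mesh_series()].
#' @param seed Seed (only used when `noise_sd > 0`).
#' @return A [mesh_series()].
#' @export
gen_mesh_series <- function(f_limit, coefficient, order, cell_counts,
                            noise_sd = 0, safety_factor = 1.25,
                            seed = NULL) {
  if (order <= 0) stop("order must be positive")
  h <- cell_counts^(-1 / 3)
  f <- f_limit + coefficient * h^order
  if (noise_sd > 0)
    f <- with_seed(seed, f + stats::rnorm(length(f), 0, noise_sd))
  mesh_series(cell_counts, f, safety_factor = safety_factor)
}

#' Generate a synthetic batch growth curve
#'
#' Exponential growth at rate `mu` up to the peak time, then first-order
#' decline; daily sampling over 0-192 h; multiplicative log-normal noise
#' with the given coefficient of variation; viability high through the
#' growth phase and decaying after the peak.
#'
#' @param V0 Inoculation VCD, cells/mL.
#' @param mu Specific growth rate, 1/h.
#' @param t_peak Time of peak VCD, h (default 120).
#' @param decline_rate First-order decline rate after the peak, 1/h.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param t_end End of sampling, h (default 192); samples every 24 h.
#' @param seed Seed for reproducibility.
#' @return A [growth_series()] with a viability column.
#' @export
gen_growth <- function(V0, mu, t_peak = 120, decline_rate = 0.005,
                       noise_cv = 0, t_end = 192, seed = NULL) {
  if (any(c(V0, mu, t_peak) <= 0) || decline_rate < 0 || noise_cv < 0)
    stop("V0, mu, t_peak must be positive; decline_rate, noise_cv non-negative")
  t <- seq(0, t_end, by = 24)
  vcd <- ifelse(t <= t_peak, V0 * exp(mu * t),
                V0 * exp(mu * t_peak) * exp(-decline_rate * (t - t_peak)))
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    vcd <- with_seed(seed,
                     vcd * stats::rlnorm(length(t), -sdlog^2 / 2, sdlog))
  }
  viability <- ifelse(t <= t_peak, 98,
                      pmax(50, 98 - 0.25 * (t - t_peak)))
  growth_series(t, vcd, viability)
}

#' Generate a truncated-normal cell-diameter sample
#'
#' Normal draws truncated to the instrument range (rejection sampling).
#'
#' @param mean Mean diameter, micrometres.
#' @param sd Standard deviation, micrometres (>= 0).
#' @param n Sample size.
#' @param range Instrument range, default c(2, 40) micrometres.
#' @param seed Seed for reproducibility.
#' @return Numeric vector of diameters within `range`.
#' @export
gen_diameters <- function(mean, sd, n, range = c(2, 40), seed = NULL) {
  if (sd < 0) stop("sd must be non-negative")
  if (mean < range[1L] || mean > range[2L])
    stop("mean must lie inside the instrument range")
  if (sd == 0) return(rep(mean, n))
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      d <- stats::rnorm(2L * (n - length(out)), mean, sd)
      out <- c(out, d[d >= range[1L] & d <= range[2L]])
    }
    out[seq_len(n)]
  })
}
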