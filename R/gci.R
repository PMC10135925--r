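#' Mesh series for grid-convergence verification
#'
#' Ordered coarse-to-fine list of (cell count, scalar quantity of interest)
#' pairs, the input to the grid convergence index (GCI) analysis.
#'
#' @param cells Cell counts, strictly increasing (coarsest first).
#' @param qoi Scalar quantity of interest per mesh, same units throughout
#'   (here typically the volume-averaged Kolmogorov length).
#' @param labels Optional mesh labels; default `M1, M2, ...`.
#' @param safety_factor GCI safety factor Fs > 1, default 1.25 (the standard
#'   value for three or more meshes).
#' @return An object of class `"mesh_series"`.
#' @export
mesh_series <- function(cells, qoi, labels = NULL, safety_factor = 1.25) {
  cells <- as.numeric(cells); qoi <- as.numeric(qoi)
  if (length(cells) != length(qoi)) stop("cells and qoi differ in length")
  if (length(cells) < 2L) stop("a mesh series needs at least two meshes")
  if (any(cells <= 0)) stop("cell counts must be positive")
  if (is.unsorted(cells, strictly = TRUE))
    stop("cell counts must be strictly increasing (order coarsest to finest)")
  if (!is.numeric(safety_factor) || safety_factor <= 1)
    stop("safety_factor must exceed 1")
  if (is.null(labels)) labels <- paste0("M", seq_along(cells))
  structure(list(cells = cells, qoi = qoi, labels = labels,
                 safety_factor = safety_factor),
            class = "mesh_series")
}

#' Mesh refinement factor
#'
#' For a 3D mesh the effective refinement factor between two meshes is the
#' cube root of the cell-count ratio, \eqn{r = (n_{fine}/n_{coarse})^{1/3}};
#' systematic studies keep r between about 1.1 and 1.3.
#'
#' @param nc_coarse,nc_fine Cell counts with `nc_fine > nc_coarse > 0`.
#' @param dim Spatial dimension of the mesh (3 by default; 2 uses a square
#'   root).
#' @return r > 1.
#' @examples
#' refinement_factor(0.28e6, 0.54e6)  # 1.24
#' @export
refinement_factor <- function(nc_coarse, nc_fine, dim = 3) {
  if (any(nc_coarse <= 0) || any(nc_fine <= nc_coarse))
    stop("need nc_fine > nc_coarse > 0")
  (nc_fine / nc_coarse)^(1 / dim)
}

#' Relative error between two mesh solutions
#'
#' \eqn{\epsilon_{mn} = |f_{coarse} - f_{fine}| / |f_{coarse}|}, normalised
#' by the coarser-mesh value.
#'
#' @param f_coarse,f_fine Quantity of interest on the coarser / finer mesh.
#' @return Non-negative relative error.
#' @export
relative_error <- function(f_coarse, f_fine) {
  if (any(f_coarse == 0)) stop("coarse-mesh value is zero; relative error undefined")
  abs(f_coarse - f_fine) / abs(f_coarse)
}

#' Observed order of accuracy from three mesh solutions
#'
#' Solves the Richardson-extrapolation relation for the observed
#' (apparent) order p on a mesh triplet with non-constant refinement factor,
#' using the standard sign-corrected fixed-point iteration
#' \deqn{p = \frac{1}{\ln r_{32}}\left|\ln\left|\frac{e_{21}}{e_{32}}\right| +
#' \ln\frac{r_{32}^p - s}{r_{21}^p - s}\right|}
#' where \eqn{e_{21} = f_1 - f_2}, \eqn{e_{32} = f_2 - f_3} and
#' \eqn{s = \mathrm{sign}(e_{21}/e_{32})}. For constant r this reduces to
#' \eqn{\ln(e_{21}/e_{32})/\ln r}. On an exact power-law series
#' \eqn{f(h) = f_\infty + C h^p} the generating order is recovered.
#'
#' @param f1,f2,f3 Quantity of interest on the coarse, mid and fine mesh.
#' @param r21 Refinement factor between coarse and mid mesh.
#' @param r32 Refinement factor between mid and fine mesh.
#' @param tol Fixed-point tolerance, default 1e-10.
#' @param max_iter Iteration cap, default 200.
#' @return List with `order` (p), `oscillatory` (logical: the successive
#'   differences changed sign), `iterations`.
#' @export
observed_order <- function(f1, f2, f3, r21, r32, tol = 1e-10,
                           max_iter = 200L) {
  if (r21 <= 1 || r32 <= 1) stop("refinement factors must exceed 1")
  e21 <- f1 - f2           # coarse-pair difference
  e32 <- f2 - f3           # fine-pair difference
  if (e21 == 0 || e32 == 0)
    stop("successive mesh differences are zero; order is undefined")
  ratio <- e21 / e32
  s <- sign(ratio)
  oscillatory <- s < 0
  # fixed point on p; damped to keep the iteration stable for small p
  p <- 1
  for (it in seq_len(max_iter)) {
    q <- log((r32^p - s) / (r21^p - s))
    p_new <- abs(log(abs(ratio)) + q) / log(r32)
    if (!is.finite(p_new)) stop("observed-order iteration diverged")
    if (abs(p_new - p) < tol) {
      return(list(order = p_new, oscillatory = oscillatory, iterations = it))
    }
    p <- 0.5 * p + 0.5 * p_new
  }
  stop("observed-order iteration did not converge within ", max_iter,
       " iterations")
}

#' Grid convergence index
#'
#' \eqn{GCI = 100\,F_s\,\epsilon_{mn}/(r^{p} - 1)} in percent: the
#' Richardson-extrapolated discretisation-error band with safety factor Fs.
#'
#' @param eps_mn Relative error between the mesh pair.
#' @param r Refinement factor of the pair (> 1).
#' @param pa Observed order of accuracy (> 0).
#' @param Fs Safety factor, default 1.25.
#' @return GCI in percent.
#' @examples
#' gci_value(0.0324, 1.24, 1.95)  # ~7.8 %
#' @export
gci_value <- function(eps_mn, r, pa, Fs = 1.25) {
  if (any(r <= 1)) stop("refinement factor must exceed 1")
  if (any(pa <= 0)) stop("order must be positive")
  denom <- r^pa - 1
  if (any(denom <= 0)) stop("r^pa - 1 must be positive")
  100 * Fs * eps_mn / denom
}

#' Asymptotic-range ratio of two GCI values
#'
#' \eqn{GCI_{coarse} / (r_{coarse}^{p}\,GCI_{fine})}; values near 1 indicate
#' that the solutions are in the asymptotic range of convergence.
#'
#' @param gci_coarse_pair GCI of the coarser mesh pair (percent).
#' @param gci_fine_pair GCI of the finer mesh pair (percent).
#' @param r_coarse_pair Refinement factor of the coarser pair.
#' @param pa Observed order.
#' @return Dimensionless ratio.
#' @export
asymptotic_ratio <- function(gci_coarse_pair, gci_fine_pair, r_coarse_pair,
                             pa) {
  if (any(gci_fine_pair <= 0)) stop("fine-pair GCI must be positive")
  gci_coarse_pair / (r_coarse_pair^pa * gci_fine_pair)
}

#' Full GCI analysis of a mesh series
#'
#' Runs the grid-convergence analysis over every consecutive mesh triplet:
#' pairwise refinement factors and relative errors, the triplet's observed
#' order, both GCI values and the asymptotic-range ratio, plus a recommended
#' mesh (the coarsest mesh whose onward relative error falls below
#' `error_threshold`).
#'
#' @param series A [mesh_series()].
#' @param dim Spatial dimension for refinement factors, default 3.
#' @param error_threshold Relative-error threshold for the mesh
#'   recommendation, default 0.025.
#' @param asymptotic_band Half-width around 1 within which a case's ratio is
#'   called asymptotic, default 0.25.
#' @return An object of class `"gci_analysis"`: a data frame of cases plus
#'   attributes `recommended_mesh` and `asymptotic`.
#' @export
analyze_gci <- function(series, dim = 3, error_threshold = 0.025,
                        asymptotic_band = 0.25) {
  stopifnot(inherits(series, "mesh_series"))
  nmesh <- length(series$cells)
  if (nmesh < 3L) stop("order estimation needs at least three meshes")
  Fs <- series$safety_factor
  cases <- lapply(seq_len(nmesh - 2L), function(i) {
    # triplet i (coarse), i+1 (mid), i+2 (fine)
    r21 <- refinement_factor(series$cells[i], series$cells[i + 1L], dim)
    r32 <- refinement_factor(series$cells[i + 1L], series$cells[i + 2L], dim)
    e21 <- relative_error(series$qoi[i], series$qoi[i + 1L])
    e32 <- relative_error(series$qoi[i + 1L], series$qoi[i + 2L])
    if (e21 == 0 || e32 == 0) {
      # mesh-converged (or constant) triplet: no order is estimable, the
      # error band is zero
      ord <- list(order = NA_real_, oscillatory = FALSE)
      g21 <- if (e21 == 0) 0 else NA_real_
      g32 <- if (e32 == 0) 0 else NA_real_
    } else {
      ord <- observed_order(series$qoi[i], series$qoi[i + 1L],
                            series$qoi[i + 2L], r21, r32)
      g21 <- gci_value(e21, r21, ord$order, Fs)
      g32 <- gci_value(e32, r32, ord$order, Fs)
    }
    data.frame(
      case = i,
      pair_coarse = paste0(series$labels[i], "-", series$labels[i + 1L]),
      pair_fine = paste0(series$labels[i + 1L], "-", series$labels[i + 2L]),
      r_coarse = r21, r_fine = r32,
      eps_coarse = e21, eps_fine = e32,
      order = ord$order, oscillatory = ord$oscillatory,
      gci_coarse = g21, gci_fine = g32,
      asymptotic_ratio = if (isTRUE(g32 > 0))
        asymptotic_ratio(g21, g32, r21, ord$order) else NA_real_
    )
  })
  tab <- do.call(rbind, cases)
  # recommended mesh: coarsest whose relative error to the next finer mesh
  # is below the threshold (constant series => zero error => first mesh)
  onward <- vapply(seq_len(nmesh - 1L), function(i) {
    relative_error(series$qoi[i], series$qoi[i + 1L])
  }, numeric(1))
  ok <- which(onward < error_threshold)
  rec <- if (length(ok)) series$labels[ok[1L]] else series$labels[nmesh]
  structure(tab, class = c("gci_analysis", "data.frame"),
            recommended_mesh = rec,
            asymptotic = !is.na(tab$asymptotic_ratio) &
              abs(tab$asymptotic_ratio - 1) <= asymptotic_band,
            safety_factor = Fs)
}

#' @export
print.gci_analysis <- function(x, digits = 4, ...) {
  cat("Grid convergence index analysis (Fs =",
      attr(x, "safety_factor"), ")\n\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  cat("\nAsymptotic cases:",
      paste(x$case[attr(x, "asymptotic")], collapse = ", "), "\n")
  cat("Recommended mesh:", attr(x, "recommended_mesh"), "\n")
  invisible(x)
}
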