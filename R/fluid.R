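#' Fluid properties
#'
#' Bundle of the physical properties of the liquid phase used throughout the
#' hydrodynamic calculations. The dynamic viscosity is derived as
#' `eta = rho * nu` and kept consistent by construction.
#'
#' @param density Density \eqn{\rho} in kg/m^3.
#' @param kinematic_viscosity Kinematic viscosity \eqn{\nu} in m^2/s.
#' @param surface_tension Optional surface tension \eqn{\sigma} in N/m
#'   (informational; not used by any calculation here).
#'
#' @return An object of class `"fluid_properties"`: a list with fields
#'   `density`, `kinematic_viscosity`, `dynamic_viscosity` and
#'   `surface_tension`.
#'
#' @details The default values are those of water at 310.15 K (37 degrees C,
#'   the cultivation temperature of mammalian cells): density 993.37 kg/m^3,
#'   kinematic viscosity 6.959e-7 m^2/s, surface tension against air
#'   71.968e-3 N/m.
#'
#' @examples
#' w <- fluid_properties()
#' w$dynamic_viscosity  # rho * nu
#' @export
fluid_properties <- function(density = 993.37,
                             kinematic_viscosity = 6.959e-7,
                             surface_tension = 71.968e-3) {
  stopifnot(is.numeric(density), length(density) == 1L, is.finite(density),
            is.numeric(kinematic_viscosity), length(kinematic_viscosity) == 1L,
            is.finite(kinematic_viscosity))
  if (density <= 0) stop("density must be strictly positive")
  if (kinematic_viscosity <= 0) stop("kinematic_viscosity must be strictly positive")
  if (!is.null(surface_tension)) {
    if (!is.numeric(surface_tension) || length(surface_tension) != 1L ||
        !is.finite(surface_tension) || surface_tension <= 0)
      stop("surface_tension must be a strictly positive scalar (or NULL)")
  }
  structure(list(
    density = density,
    kinematic_viscosity = kinematic_viscosity,
    dynamic_viscosity = density * kinematic_viscosity,
    surface_tension = surface_tension
  ), class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat("Fluid properties\n")
  cat(sprintf("  density             %.6g kg/m^3\n", x$density))
  cat(sprintf("  kinematic viscosity %.6g m^2/s\n", x$kinematic_viscosity))
  cat(sprintf("  dynamic viscosity   %.6g Pa s\n", x$dynamic_viscosity))
  if (!is.null(x$surface_tension))
    cat(sprintf("  surface tension     %.6g N/m\n", x$surface_tension))
  invisible(x)
}
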