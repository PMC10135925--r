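#' Shaken-flask operating point
#'
#' @param shaking_frequency n in 1/s.
#' @param shaking_amplitude d0 in m (shaking diameter).
#' @param max_inner_diameter d in m, the maximum inner diameter of the flask.
#' @param fill_volume V in m^3.
#' @param fluid A [fluid_properties()].
#' @param nominal_volume Optional flask nominal volume in m^3; the fill must
#'   stay below it.
#' @return An object of class `"shaken_spec"`.
#' @export
shaken_spec <- function(shaking_frequency, shaking_amplitude,
                        max_inner_diameter, fill_volume,
                        fluid = fluid_properties(), nominal_volume = NULL) {
  vals <- c(shaking_frequency, shaking_amplitude, max_inner_diameter,
            fill_volume)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all shaken-spec fields must be finite and strictly positive")
  if (!is.null(nominal_volume) && fill_volume >= nominal_volume)
    stop("fill_volume must be below the flask nominal volume")
  stopifnot(inherits(fluid, "fluid_properties"))
  structure(list(shaking_frequency = shaking_frequency,
                 shaking_amplitude = shaking_amplitude,
                 max_inner_diameter = max_inner_diameter,
                 fill_volume = fill_volume, fluid = fluid),
            class = "shaken_spec")
}

#' Stirred-tank operating point
#'
#' @param stirrer_speed N in 1/s.
#' @param stirrer_diameter ds in m.
#' @param fill_volume V in m^3.
#' @param fluid A [fluid_properties()].
#' @return An object of class `"stirred_spec"`.
#' @export
stirred_spec <- function(stirrer_speed, stirrer_diameter, fill_volume,
                         fluid = fluid_properties()) {
  vals <- c(stirrer_speed, stirrer_diameter, fill_volume)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all stirred-spec fields must be finite and strictly positive")
  stopifnot(inherits(fluid, "fluid_properties"))
  structure(list(stirrer_speed = stirrer_speed,
                 stirrer_diameter = stirrer_diameter,
                 fill_volume = fill_volume, fluid = fluid),
            class = "stirred_spec")
}

#' Axial Froude number of an orbitally shaken system
#'
#' \eqn{Fr_a = (2\pi n)^2 (d_0/2) / g}: the ratio of the centrifugal
#' acceleration of the shaking orbit to gravity. Values above 0.4 are one of
#' the two criteria for in-phase liquid motion.
#'
#' @param n Shaking frequency, 1/s.
#' @param d0 Shaking amplitude (orbit diameter), m.
#' @param g Gravitational acceleration, default 9.80665 m/s^2.
#' @return List with `Fra` and the in-phase criterion flag
#'   `in_phase (Fra > 0.4)`.
#' @examples
#' axial_froude(130 / 60, 0.05)$Fra  # ~0.47
#' @export
axial_froude <- function(n, d0, g = 9.80665) {
  if (any(n < 0)) stop("shaking frequency must be non-negative")
  fra <- (2 * pi * n)^2 * (d0 / 2) / g
  list(Fra = fra, in_phase = fra > 0.4)
}

#' Phase number of a shaken flask
#'
#' \eqn{Ph = (d_0/d)\,(1 + 3\log_{10} Re_f)} with the film Reynolds number
#' \deqn{Re_f = \frac{\rho n d^2}{\eta}\left[1 - \sqrt{1 -
#' \frac{4}{\pi}\left(\frac{V^{1/3}}{d}\right)^2}\right]^2.}
#' Together with the axial Froude criterion, Ph > 1.26 indicates that the
#' liquid rotates in phase with the shaker; out-of-phase operation collapses
#' the power input and mixing. Only unbaffled flasks are covered (no phase
#' number formula exists for baffled ones).
#'
#' @param spec A [shaken_spec()].
#' @param g Gravitational acceleration for the companion Froude criterion.
#' @return List with `Ph`, `Fra`, `Re_film` and the joint `in_phase` flag
#'   (Ph > 1.26 and Fra > 0.4).
#' @export
phase_number <- function(spec, g = 9.80665) {
  stopifnot(inherits(spec, "shaken_spec"))
  n <- spec$shaking_frequency; d <- spec$max_inner_diameter
  d0 <- spec$shaking_amplitude; V <- spec$fill_volume
  fl <- spec$fluid
  x <- (4 / pi) * (V^(1 / 3) / d)^2
  if (x >= 1)
    stop("flask overfilled: (4/pi) (V^{1/3}/d)^2 >= 1; phase number undefined")
  film <- (1 - sqrt(1 - x))^2
  re_film <- (fl$density * n * d^2 / fl$dynamic_viscosity) * film
  ph <- (d0 / d) * (1 + 3 * log10(re_film))
  fra <- axial_froude(n, d0, g)$Fra
  list(Ph = ph, Fra = fra, Re_film = re_film,
       in_phase = (ph > 1.26) && (fra > 0.4))
}

#' Specific power input of an unbaffled shaken flask
#'
#' Empirical torque-measurement correlation for unbaffled shake flasks:
#' \eqn{P/V = Ne'\,\rho\,n^3 d^4 / V^{2/3}} with the modified power number
#' \eqn{Ne' = 70\,Re^{-1} + 25\,Re^{-0.6} + 1.5\,Re^{-0.2}} and
#' \eqn{Re = \rho n d^2/\eta}. Valid in-phase only; there is no empirical
#' correlation for baffled flasks.
#'
#' @param spec A [shaken_spec()].
#' @param check_phase Warn when the operating point is out of phase
#'   (default TRUE).
#' @return P/V in W/m^3.
#' @export
buchs_power_unbaffled <- function(spec, check_phase = TRUE) {
  stopifnot(inherits(spec, "shaken_spec"))
  n <- spec$shaking_frequency; d <- spec$max_inner_diameter
  V <- spec$fill_volume; fl <- spec$fluid
  re <- fl$density * n * d^2 / fl$dynamic_viscosity
  if (re <= 0) stop("Reynolds number must be positive")
  if (check_phase) {
    ip <- tryCatch(phase_number(spec)$in_phase, error = function(e) FALSE)
    if (!ip)
      warning("operating point is out of phase; the power correlation does not apply")
  }
  ne_prime <- 70 / re + 25 * re^-0.6 + 1.5 * re^-0.2
  ne_prime * fl$density * n^3 * d^4 / V^(2 / 3)
}

#' Modified Reynolds number of a stirred tank
#'
#' \eqn{Re_m = \rho N d_s^2 / \eta = N d_s^2/\nu}.
#'
#' @param spec A [stirred_spec()].
#' @return Dimensionless Reynolds number.
#' @export
reynolds_stirred <- function(spec) {
  stopifnot(inherits(spec, "stirred_spec"))
  fl <- spec$fluid
  fl$density * spec$stirrer_speed * spec$stirrer_diameter^2 /
    fl$dynamic_viscosity
}

#' Newton (power) number of a stirred tank
#'
#' \eqn{Ne = P / (\rho N^3 d_s^5)}: the dimensionless stirrer power draw.
#'
#' @param P Power in W.
#' @param spec A [stirred_spec()].
#' @return Dimensionless Newton number.
#' @export
newton_number <- function(P, spec) {
  stopifnot(inherits(spec, "stirred_spec"))
  if (spec$stirrer_speed <= 0) stop("stirrer speed must be positive")
  fl <- spec$fluid
  P / (fl$density * spec$stirrer_speed^3 * spec$stirrer_diameter^5)
}

#' Stirrer tip speed
#'
#' \eqn{v_{tip} = \pi d_s N}, the theoretical maximum fluid speed in a
#' stirred tank.
#'
#' @param N Stirrer speed, 1/s.
#' @param ds Stirrer diameter, m.
#' @return Tip speed in m/s.
#' @examples
#' tip_speed(180 / 60, 0.085)  # 0.80 m/s
#' @export
tip_speed <- function(N, ds) {
  if (any(N < 0) || any(ds <= 0)) stop("need N >= 0 and ds > 0")
  pi * ds * N
}

#' Tip-speed power correlation for the Minifors 2 (4 L)
#'
#' Published CFD-derived correlation for the 3-blade segment impeller of the
#' Minifors 2 bioreactor at 4 L working volume:
#' \eqn{P/V = 131.79\,v_{tip}^{2.7670}} in W/m^3.
#'
#' @param vtip Tip speed in m/s (>= 0).
#' @param coefficient,exponent Correlation constants; defaults are the
#'   published 4 L values.
#' @return P/V in W/m^3.
#' @export
maschke_power <- function(vtip, coefficient = 131.79, exponent = 2.7670) {
  if (any(vtip < 0)) stop("tip speed must be non-negative")
  coefficient * vtip^exponent
}

#' Oxygen-transfer specification
#'
#' @param kLa Volumetric oxygen mass-transfer coefficient, 1/h.
#' @param qO2 Specific oxygen uptake rate, mol O2 per hour per cell.
#' @param c_star Dissolved-oxygen saturation concentration at the gas-liquid
#'   interface, mol/L.
#' @param c_bulk Dissolved-oxygen concentration in the bulk, mol/L
#'   (default 0, the worst case).
#' @return An object of class `"oxygen_spec"`.
#' @export
oxygen_spec <- function(kLa, qO2, c_star, c_bulk = 0) {
  if (any(c(kLa, qO2, c_star) <= 0))
    stop("kLa, qO2 and c_star must be strictly positive")
  if (c_bulk < 0 || c_bulk >= c_star)
    stop("need 0 <= c_bulk < c_star (no driving force otherwise)")
  structure(list(kLa = kLa, qO2 = qO2, c_star = c_star, c_bulk = c_bulk),
            class = "oxygen_spec")
}

#' Oxygen-transfer-limited maximum cell density
#'
#' At equilibrium between oxygen transfer rate \eqn{OTR = k_La (c^*_{O2} -
#' c_{O2})} and uptake rate \eqn{OUR = c_x q_{O2}}, the supportable biomass
#' concentration is \eqn{c_x = k_La (c^* - c)/q_{O2}}. The result is an
#' upper bound: enhancement factors and other limitations are ignored.
#'
#' @param spec An [oxygen_spec()].
#' @return Theoretical maximum viable cell density in cells/mL.
#' @examples
#' max_supported_vcd(oxygen_spec(16, 1.85e-13, 2.07e-4))  # ~1.8e7 cells/mL
#' @export
max_supported_vcd <- function(spec) {
  stopifnot(inherits(spec, "oxygen_spec"))
  cells_per_litre <- spec$kLa * (spec$c_star - spec$c_bulk) / spec$qO2
  cells_per_litre / 1000
}

#' Oxygen solubility in water (Tromans correlation)
#'
#' Henry-law solubility of oxygen in water via the Tromans temperature
#' correlation,
#' \deqn{c^*_{O2} = p_{O2} \exp\!\left[\frac{0.046 T^2 + 203.357\,T
#' \ln(T/298) - (299.378 + 0.092 T)(T - 298) - 20591}{8.3144\,T}\right]}
#' with T in K, partial pressure in atm and concentration in mol/L; linear
#' in the partial pressure.
#'
#' @param T Temperature in K (valid 273-373 K).
#' @param pO2 Oxygen partial pressure, atm (default dry air at 1 atm,
#'   0.2095 atm).
#' @param x_co2 Optional CO2 mole fraction of the gas phase and
#' @param relative_humidity optional relative humidity (0-1); both reduce
#'   the effective oxygen partial pressure as
#'   `(1 - x_co2 - RH * pH2O(T)/1 atm) * 0.2095` when `pO2` is left at its
#'   default. Off (zero) by default.
#' @return Saturation concentration in mol/L.
#' @export
o2_solubility <- function(T, pO2 = 0.2095, x_co2 = 0, relative_humidity = 0) {
  if (any(T <= 273) || any(T >= 373))
    stop("temperature out of the 273-373 K validity range")
  if (x_co2 > 0 || relative_humidity > 0) {
    # Antoine equation for water vapour pressure (in mmHg, 1 atm = 760 mmHg)
    p_h2o <- 10^(8.07131 - 1730.63 / (233.426 + (T - 273.15))) / 760
    pO2 <- (1 - x_co2 - relative_humidity * p_h2o) * 0.2095
  }
  arg <- (0.046 * T^2 + 203.357 * T * log(T / 298) -
            (299.378 + 0.092 * T) * (T - 298) - 20591) / (8.3144 * T)
  pO2 * exp(arg)
}
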