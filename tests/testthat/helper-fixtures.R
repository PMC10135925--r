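# Shared fixtures built in code.

# Water at 37 degrees C (the cultivation temperature)
water37 <- fluid_properties(density = 993.37, kinematic_viscosity = 6.959e-7)

# Published mesh study of the baffled 500 mL flask: five meshes, QoI is the
# volume-averaged Kolmogorov length over one shaking period.
flask_mesh_series <- function() {
  mesh_series(cells = c(0.28e6, 0.54e6, 0.89e6, 1.40e6, 2.09e6),
              qoi = c(6.906e-5, 6.682e-5, 6.380e-5, 6.123e-5, 5.997e-5))
}

# Published mesh study of the stirred 6 L bench-top bioreactor: four meshes.
stirred_mesh_series <- function() {
  mesh_series(cells = c(1.23e6, 2.50e6, 4.49e6, 7.24e6),
              qoi = c(1.022e-4, 0.980e-4, 0.967e-4, 0.959e-4))
}

# Independent root-scan oracle for the observed order: scans p over (0, 10]
# for the root of the Richardson relation, refining by bisection.
order_oracle <- function(f1, f2, f3, r21, r32) {
  g <- function(p) {
    (f1 - f2) / (f2 - f3) - r32^p * (r21^p - 1) / (r32^p - 1)
  }
  grid <- seq(1e-3, 10, by = 1e-3)
  vals <- vapply(grid, g, numeric(1))
  i <- which(diff(sign(vals)) != 0)[1L]
  stats::uniroot(g, c(grid[i], grid[i + 1L]), tol = 1e-12)$root
}

# two-cell field with volumes/values chosen by hand
two_cell_field <- function() {
  flow_field(volume = c(1, 3), epsilon = c(0, 4))
}
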