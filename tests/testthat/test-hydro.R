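test_that("dissipation rate follows beta* k omega and validates inputs", {
  expect_equal(epsilon_from_k_omega(1, 1), 0.09)
  expect_equal(epsilon_from_k_omega(0, 5), 0)
  expect_equal(epsilon_from_k_omega(2.5, 4), 0.9)
  expect_error(epsilon_from_k_omega(c(1, -1), c(1, 1)), "index 2")

  # flow-field method fills epsilon but never overwrites a provided one
  f <- flow_field(volume = rep(1, 3), k = c(1, 2, 3), omega = c(1, 1, 1))
  f2 <- epsilon_from_k_omega(f)
  expect_equal(f2$epsilon, 0.09 * c(1, 2, 3))
  f3 <- flow_field(volume = 1, k = 1, omega = 1, epsilon = 5)
  expect_equal(epsilon_from_k_omega(f3)$epsilon, 5)
  expect_equal(epsilon_from_k_omega(f3, overwrite = TRUE)$epsilon, 0.09)
})

test_that("Kolmogorov length is (nu^3/eps)^(1/4), decreasing, Inf when quiescent", {
  expect_equal(kolmogorov_length(1, 1), 1)
  expect_equal(kolmogorov_length(6.959e-7, 1e-3),
               (6.959e-7^3 / 1e-3)^0.25)
  expect_equal(round(kolmogorov_length(6.959e-7, 1e-3), 7), 1.355e-4)
  eps <- sort(stats::runif(50, 1e-6, 1))
  expect_true(all(diff(kolmogorov_length(1e-6, eps)) < 0))
  expect_warning(l0 <- kolmogorov_length(1e-6, 0), "quiescent")
  expect_identical(l0, Inf)
  expect_error(kolmogorov_length(1e-6, 0, on_zero = "error"))
})

test_that("volume-weighted reductions match an explicit-loop oracle", {
  f <- flow_field(volume = c(1, 3), epsilon = c(0, 4))
  expect_equal(volume_weighted_mean(c(0, 4), f), 3.0)
  expect_equal(volume_weighted_mean(rep(7.3, 2), f), 7.3)
  expect_error(volume_weighted_mean(1:3, f), "length")

  set.seed(11)
  vol <- stats::runif(1000, 0.1, 2)
  q <- stats::rlnorm(1000)
  f <- flow_field(volume = vol, epsilon = q)
  loop <- 0; tot <- 0
  for (i in seq_len(1000)) { loop <- loop + q[i] * vol[i]; tot <- tot + vol[i] }
  expect_equal(volume_weighted_mean(q, f), loop / tot, tolerance = 1e-12)
  expect_equal(power_per_volume_from_dissipation(f, fluid_properties(1000, 1e-6)),
               1000 * loop / tot, tolerance = 1e-12)
})

test_that("torque and dissipation power routes agree on matched fields", {
  expect_equal(power_per_volume_from_torque(1, 1, 2 * pi), 1)
  expect_equal(power_per_volume_from_torque(3, 0, 0.004), 0)
  expect_equal(power_per_volume_from_torque(130 / 60, 5.44e-4, 1.6e-4),
               2 * pi * (130 / 60) * 5.44e-4 / 1.6e-4)
  expect_error(power_per_volume_from_torque(1, 1, 0), "positive")

  # uniform field: P/V = rho * eps
  f <- flow_field(volume = rep(0.25, 4), epsilon = rep(1, 4),
                  total_volume = 1)
  expect_equal(power_per_volume_from_dissipation(f, fluid_properties(1000, 1e-6)),
               1000)

  # a field generated with prescribed P/V and the matching torque agree
  set.seed(5)
  fl <- water37
  n <- 130 / 60; V <- 1.6e-4
  field <- gen_flowfield(500, V, epsilon_mean = 74 / fl$density,
                         heterogeneity = 5, seed = 21)
  pv <- power_per_volume_from_dissipation(field, fl)
  M <- pv * V / (2 * pi * n)
  expect_equal(power_per_volume_from_torque(n, M, V), pv, tolerance = 1e-9)
})

test_that("heterogeneity is max over volume-weighted mean, scale invariant", {
  f <- flow_field(volume = rep(1, 5), epsilon = rep(2, 5))
  expect_equal(heterogeneity(f), 1)

  # one cell at 10x the uniform rate with negligible volume
  f <- flow_field(volume = c(rep(1, 100), 1e-9), epsilon = c(rep(1, 100), 10))
  expect_equal(heterogeneity(f), 10, tolerance = 1e-6)

  set.seed(2)
  eps <- stats::rlnorm(200)
  f1 <- flow_field(volume = rep(1, 200), epsilon = eps)
  f2 <- flow_field(volume = rep(1, 200), epsilon = 17.3 * eps)
  expect_equal(heterogeneity(f1), heterogeneity(f2))
  expect_true(heterogeneity(f1) >= 1)
  expect_error(heterogeneity(flow_field(volume = 1, epsilon = 0)), "zero")
})

test_that("lambda distribution puts volume fractions in the right bins", {
  fl <- water37
  # uniform field: all volume in one bin
  f <- flow_field(volume = rep(1, 10), epsilon = rep(0.01, 10))
  d <- lambda_volume_distribution(f, fl)
  expect_equal(sum(d$volume_fraction), 1, tolerance = 1e-9)
  expect_equal(max(d$volume_fraction), 1)

  # two dissipation levels with volume split 0.25/0.75
  f <- flow_field(volume = c(0.25, 0.75), epsilon = c(1, 1e-4))
  lam <- kolmogorov_length(fl$kinematic_viscosity, c(1, 1e-4))
  edges <- c(lam[1] * 0.9, lam[1] * 1.1, lam[2] * 1.1)
  d <- lambda_volume_distribution(f, fl, bin_edges = edges)
  expect_equal(d$volume_fraction, c(0.25, 0.75))

  # reported mean is the definitional volume-weighted mean of the lengths
  set.seed(8)
  eps <- stats::rlnorm(300, -3)
  vol <- stats::runif(300)
  f <- flow_field(volume = vol, epsilon = eps)
  d <- lambda_volume_distribution(f, fl)
  expect_equal(d$lambda_mean,
               volume_weighted_mean(
                 kolmogorov_length(fl$kinematic_viscosity, eps), f),
               tolerance = 1e-12)
  expect_error(lambda_volume_distribution(f, fl, bin_edges = c(2, 1, 3)),
               "increasing")
})

test_that("quiescent cells keep the lambda distribution summing to one", {
  fl <- water37
  f <- flow_field(volume = c(1, 1, 2), k = c(1, 1, 0), omega = c(1, 2, 0))
  d <- lambda_volume_distribution(f, fl)
  expect_equal(sum(d$volume_fraction), 1, tolerance = 1e-9)
  expect_equal(d$quiescent_volume_fraction, 0.5)
})

test_that("volume fraction below a critical length behaves as a CDF", {
  fl <- water37
  set.seed(3)
  vol <- stats::runif(200)
  f <- flow_field(volume = vol / sum(vol) * 4e-3,
                  epsilon = stats::rlnorm(200, -2), total_volume = 4e-3)
  lam <- kolmogorov_length(fl$kinematic_viscosity, f$epsilon)
  expect_equal(volume_fraction_below(f, fl, min(lam) * 0.99)$fraction, 0)
  top <- volume_fraction_below(f, fl, max(lam) * 1.01)
  expect_equal(top$fraction, 1)
  expect_equal(top$absolute_volume, 4e-3)
  crit <- sort(stats::runif(20, min(lam), max(lam)))
  fr <- vapply(crit, function(l) volume_fraction_below(f, fl, l)$fraction,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
  # the published fraction at the three-cell critical scale: 0.02077 of 4 L
  expect_equal(0.02077 * 4000, 83.08, tolerance = 1e-3)
})

test_that("Q-criterion matches its closed forms", {
  for (w in c(0.3, 1, 2.5, 40)) {
    rot <- matrix(c(0, -w, 0, w, 0, 0, 0, 0, 0), 3, byrow = TRUE)
    expect_equal(q_criterion(rot), w^2)
    shear <- matrix(c(0, w, 0, 0, 0, 0, 0, 0, 0), 3, byrow = TRUE)
    expect_equal(q_criterion(shear), 0)
    strain <- diag(c(w, -w, 0))
    expect_equal(q_criterion(strain), -w^2)
  }
  # row-wise form agrees with the 3x3 form
  set.seed(4)
  g <- matrix(stats::rnorm(9 * 5), ncol = 9)
  q_rows <- q_criterion(g)
  q_each <- vapply(seq_len(5), function(i)
    q_criterion(matrix(g[i, ], 3, byrow = TRUE)), numeric(1))
  expect_equal(q_rows, q_each)
})

test_that("hydro report gathers the field statistics", {
  fl <- water37
  f <- gen_flowfield(300, 4e-3, 0.01, heterogeneity = 20, seed = 9)
  rep <- hydro_report(f, fl, lambda_thresholds = c(15.5e-6, 33.4e-6),
                      n = 3, torque = 0.01)
  expect_equal(rep$power_per_volume_dissipation,
               fl$density * volume_weighted_mean(f$epsilon, f))
  expect_equal(rep$power_per_volume_torque, 2 * pi * 3 * 0.01 / 4e-3)
  expect_length(rep$volume_fraction_below, 2)
  expect_true(rep$heterogeneity >= 1)
})
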