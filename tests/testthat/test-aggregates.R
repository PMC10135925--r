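test_that("geometric pmf follows (1-p)^(n-1) p and sums geometrically", {
  for (p in c(0.1, 0.433, 0.655, 1)) {
    expect_equal(geometric_pmf(1, p), p)
  }
  expect_equal(round(geometric_pmf(2, 0.655), 4), 0.226)
  for (p in c(0.05, 0.5, 0.97)) {
    for (N in c(5, 50, 200)) {
      expect_equal(sum(geometric_pmf(1:N, p)), 1 - (1 - p)^N,
                   tolerance = 1e-12)
    }
  }
  expect_error(geometric_pmf(0, 0.5), "n must be")
  expect_error(geometric_pmf(1, 0), "p must")
  expect_error(geometric_pmf(1, 1.2), "p must")
})

test_that("singles-fraction estimators distinguish cell and cluster weighting", {
  cc <- cluster_counts(1, 10)
  expect_equal(singles_fraction(cc, "per_cell"), 1)
  expect_equal(singles_fraction(cc, "per_cluster"), 1)
  cc <- cluster_counts(c(1, 2), c(4, 3))
  expect_equal(singles_fraction(cc, "per_cell"), 0.4)
  expect_equal(singles_fraction(cc, "per_cluster"), 4 / 7)

  cc <- gen_clusters(1e5, 0.655, seed = 31)
  expect_equal(singles_fraction(cc, "per_cluster"), 0.655, tolerance = 0.008)
})

test_that("the geometric MLE is the inverse mean cluster size and is consistent", {
  expect_equal(mle_p(cluster_counts(1, 5)), 1)
  expect_equal(mle_p(cluster_counts(c(1, 2), c(2, 1))), 3 / 4)
  cc <- gen_clusters(1e5, 0.433, seed = 17)
  expect_lt(abs(mle_p(cc) - 0.433), 0.005)
  # agrees exactly with per-cluster singles on exactly-geometric proportions
  p <- 0.6
  cc <- cluster_counts(1:12, 1e6 * geometric_pmf(1:12, p) /
                         sum(geometric_pmf(1:12, p)))
  expect_equal(singles_fraction(cc, "per_cluster"),
               geometric_pmf(1, p) / sum(geometric_pmf(1:12, p)))
})

test_that("goodness-of-fit statistics vanish on perfectly geometric data", {
  p <- 0.5
  expected <- 1e4 * geometric_pmf(1:25, p)
  cc <- cluster_counts(1:25, expected)
  # data proportional to the pmf, p supplied externally
  chi <- gof_chi2(cc, p, p_estimated = FALSE)
  g <- gof_g_test(cc, p, p_estimated = FALSE)
  expect_lt(chi$statistic, 1e-3)
  expect_lt(g$statistic, 1e-3)
  expect_equal(chi$df, chi$pooled_bins - 1L)
  # df drops by one when p came from the same data
  expect_equal(gof_chi2(cc, p)$df, chi$df - 1L)
})

test_that("chi-squared and G statistics agree asymptotically", {
  cc <- gen_clusters(1e4, 0.5, seed = 5)
  p_hat <- mle_p(cc)
  chi <- gof_chi2(cc, p_hat)
  g <- gof_g_test(cc, p_hat)
  expect_lt(abs(chi$statistic - g$statistic) / chi$statistic, 0.05)
  expect_equal(chi$df, g$df)
})

test_that("goodness-of-fit tests are calibrated and have power", {
  # type-I error at nominal alpha = 0.05 under the true model
  set.seed(1902)
  p <- 0.5; N <- 500; reps <- 2000
  rej_chi <- 0; rej_g <- 0
  for (i in seq_len(reps)) {
    sizes <- stats::rgeom(N, p) + 1L
    tab <- table(sizes)
    cc <- cluster_counts(as.integer(names(tab)), as.numeric(tab))
    if (gof_chi2(cc, p, p_estimated = FALSE)$p_value < 0.05)
      rej_chi <- rej_chi + 1
    if (gof_g_test(cc, p, p_estimated = FALSE)$p_value < 0.05)
      rej_g <- rej_g + 1
  }
  expect_gt(rej_chi / reps, 0.03); expect_lt(rej_chi / reps, 0.07)
  expect_gt(rej_g / reps, 0.03); expect_lt(rej_g / reps, 0.07)

  # power against a half-and-half mixture of two geometrics
  set.seed(77)
  rej <- 0; reps_pow <- 200
  for (i in seq_len(reps_pow)) {
    sizes <- c(stats::rgeom(N / 2, 0.2), stats::rgeom(N / 2, 0.9)) + 1L
    tab <- table(sizes)
    cc <- cluster_counts(as.integer(names(tab)), as.numeric(tab))
    if (gof_chi2(cc, mle_p(cc))$p_value < 0.05) rej <- rej + 1
  }
  expect_gt(rej / reps_pow, 0.9)
})

test_that("geom_cluster_fit exposes the standard model interface", {
  cc <- gen_clusters(5000, 0.58, seed = 42)
  fit <- geom_cluster_fit(cc)
  expect_s3_class(fit, "geomfit")
  expect_named(coef(fit), "p")
  expect_equal(unname(coef(fit)), singles_fraction(cc, "per_cell"))
  expect_equal(geom_cluster_fit(cc, estimator = "mle")$p, mle_p(cc))

  pr <- predict(fit, n_max = 15)
  expect_equal(pr$probability, geometric_pmf(1:15, fit$p))
  expect_equal(sum(pr$probability), 1 - (1 - fit$p)^15)

  sim1 <- simulate(fit, nsim = 2000, seed = 7)
  sim2 <- simulate(fit, nsim = 2000, seed = 7)
  expect_identical(sim1, sim2)
  expect_s3_class(sim1, "cluster_counts")

  res <- residuals(fit)
  expect_equal(length(res), fit$gof_chi2$pooled_bins)
  expect_equal(sum(res^2), fit$gof_chi2$statistic, tolerance = 1e-10)

  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 1L)
  # printed summary mentions both GOF tests
  out <- capture.output(print(summary(fit)))
  expect_true(any(grepl("chi-squared GOF", out)))
  expect_true(any(grepl("G-test", out)))
})

test_that("lambda link fits, predicts and clamps", {
  # noiseless recovery of an exact line
  lam <- c(0.4, 0.7, 1.0, 1.3, 1.6) * 1e-4
  link <- lambda_link(lam, 0.92 - 4589 * lam)
  expect_equal(link$intercept, 0.92, tolerance = 1e-10)
  expect_equal(link$slope, -4589, tolerance = 1e-6)
  expect_equal(link$r_squared, 1, tolerance = 1e-12)

  # the two flask observations pin a two-point line
  link2 <- lambda_link(c(1.025e-4, 6.123e-5), c(0.433, 0.655))
  expect_equal(link2$slope, -5379, tolerance = 1e-4)
  expect_equal(link2$intercept, 0.984, tolerance = 1e-3)

  # noisy synthetic points recover the slope within 15%
  set.seed(12)
  ok <- 0
  for (i in 1:20) {
    p_noisy <- 0.92 - 4589 * lam + stats::rnorm(5, 0, 0.02)
    l <- lambda_link(lam, p_noisy)
    if (abs(l$slope - (-4589)) / 4589 < 0.15) ok <- ok + 1
  }
  expect_gt(ok / 20, 0.8)
  expect_error(lambda_link(rep(1e-4, 3), c(0.1, 0.2, 0.3)), "distinct")

  # default link and clamping
  expect_equal(predict_p(0), 0.92)
  expect_equal(predict_p(6.123e-5), 0.639, tolerance = 1e-3)
  expect_warning(p0 <- predict_p(2.1e-4), "clamped")
  expect_equal(p0, 0)
  expect_equal(predict(lambda_link(), 6.123e-5), predict_p(6.123e-5))
})

test_that("predicted distributions compose the link with the pmf", {
  d <- predict_distribution(1.025e-4, n_max = 12)
  p <- predict_p(1.025e-4)
  expect_equal(d$probability, geometric_pmf(1:12, p))
  expect_equal(d$probability[1], 0.4496, tolerance = 1e-3)
  expect_true(all(diff(d$probability) < 0))
  expect_error(suppressWarnings(predict_distribution(2.1e-4)), "degenerate")
  # predictions at the flask anchors land near the measured fractions
  expect_lt(abs(predict_p(1.025e-4) - 0.433), 0.05)
  expect_lt(abs(predict_p(6.123e-5) - 0.655), 0.05)
})

test_that("three-cell cluster geometry", {
  expect_equal(chain_length(3, 15.5e-6), 46.5e-6)
  expect_equal(chain_length(1, 12e-6), 12e-6)
  expect_equal(chain_length(5, 15.5e-6), 77.5e-6)
  expect_equal(round(close_packed_diameter_3(15.5e-6) * 1e6, 1), 33.4)
  expect_equal(close_packed_diameter_3(0), 0)
  expect_equal(close_packed_diameter_3(1), 1 + 2 / sqrt(3))
})

test_that("cluster counts validate and aggregate duplicates", {
  expect_error(cluster_counts(0, 5), ">= 1")
  expect_error(cluster_counts(c(1, 2), c(0, 0)), "nonzero")
  cc <- cluster_counts(c(2, 1, 2), c(1, 4, 2))
  expect_equal(cc$size, c(1L, 2L))
  expect_equal(cc$count, c(4, 3))
  expect_equal(attr(cc, "total_cells"), 10)
  expect_equal(attr(cc, "total_clusters"), 7)
})
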