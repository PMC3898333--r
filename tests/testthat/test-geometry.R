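test_that("sphere and ellipsoid volumes match closed forms", {
  expect_equal(sphere_volume(150), pi / 6 * 150^3)
  expect_equal(round(sphere_volume(150)), 1767146)
  expect_equal(signif(sphere_volume(150), 3), 1.77e6)
  expect_equal(sphere_volume(0), 0)
  expect_equal(sphere_volume(100), 523598.78, tolerance = 1e-8)
  expect_error(sphere_volume(-1), "nonnegative")

  expect_equal(ellipsoid_volume(150, 150, 150), sphere_volume(150))
  # reported mean oblate axis ratios b/a = 0.82, c/a = 0.6
  expect_equal(ellipsoid_volume(150, 0.82 * 150, 0.6 * 150), 869435.8,
               tolerance = 1e-6)
  expect_equal(ellipsoid_volume(150, 0, 150), 0)
  expect_error(ellipsoid_volume(150, -1, 150), "nonnegative")
})

test_that("exact IE is the cubed diameter ratio and scales as the cube", {
  expect_equal(ie_exact(150), 1)
  expect_equal(ie_exact(75), 0.125)
  expect_equal(ie_exact(300), 8)
  expect_equal(ie_exact(150), sphere_volume(150) / IE_REFERENCE_VOLUME)
  expect_error(ie_exact(-5), "nonnegative")

  d <- seq(10, 200, by = 7.5)
  expect_equal(ie_exact(2 * d), 8 * ie_exact(d))
  expect_true(all(diff(ie_exact(d)) > 0))
})

test_that("endpoint-mean factors reproduce the conventional factor table", {
  expect_equal(endpoint_mean_factor(150, 150), 1)
  expect_equal(endpoint_mean_factor(50, 100), 1 / 6)
  expect_equal(endpoint_mean_factor(150, 200), oracle_endpoint_factor(150, 200))

  edges <- seq(50, 350, by = 50)
  lo <- edges[-7]; hi <- edges[-1]
  expect_equal(endpoint_mean_factor(lo, hi), oracle_endpoint_factor(lo, hi))
  expect_equal(round(endpoint_mean_factor(lo, hi), 3),
               c(0.167, 0.648, 1.685, 3.500, 6.315, 10.352))
  expect_error(endpoint_mean_factor(200, 150), "exceeds")
})

test_that("density-expectation factor: closed forms, point mass, downward correction", {
  expect_equal(density_expectation_factor(50, 100),
               oracle_uniform_factor(50, 100))
  expect_equal(density_expectation_factor(50, 100), 0.138889,
               tolerance = 1e-5)
  expect_equal(density_expectation_factor(150, 200),
               oracle_uniform_factor(150, 200))
  expect_equal(density_expectation_factor(150, 200), 1.620370,
               tolerance = 1e-5)
  expect_equal(density_expectation_factor(100, 200, density = 150), 1)

  # strict convexity of d^3: uniform factor < endpoint-mean on every bin
  edges <- seq(50, 350, by = 50)
  for (i in 1:6) {
    u <- density_expectation_factor(edges[i], edges[i + 1])
    expect_lt(u, endpoint_mean_factor(edges[i], edges[i + 1]))
    # a decreasing within-bin density corrects even further downward
    dec <- density_expectation_factor(edges[i], edges[i + 1],
                                      density = function(x) exp(-x / 40))
    expect_lt(dec, u)
  }
  expect_error(density_expectation_factor(50, 100, density = function(x) 0 * x),
               "mass")
})

test_that("binned IE uses half-open bins, reports exclusions, honors the overflow policy", {
  empty <- ie_binned(numeric(0))
  expect_equal(empty$total_ie, 0)
  expect_true(all(empty$per_bin_counts == 0))

  one <- ie_binned(150)
  expect_equal(one$total_ie, oracle_endpoint_factor(150, 200))
  expect_equal(unname(one$per_bin_counts["[150,200)"]), 1L)

  expect_equal(ie_binned(c(60, 80, 90))$total_ie, 0.5, tolerance = 1e-9)

  # d = 100 falls in the upper bin of the shared edge
  expect_equal(ie_binned(100)$total_ie, oracle_endpoint_factor(100, 150))

  excl <- ie_binned(c(40, 150))
  expect_equal(excl$excluded, 40)
  expect_equal(excl$total_ie, oracle_endpoint_factor(150, 200))

  expect_error(ie_binned(350), "overflow")
  ext <- ie_binned(c(360, 150), overflow = "extend")
  expect_equal(ext$total_ie,
               oracle_endpoint_factor(350, 400) +
                 oracle_endpoint_factor(150, 200))
})

test_that("binned IE total is permutation invariant and additive over preparations", {
  set.seed(71)
  d <- runif(200, 50, 349)
  sch <- ricordi_scheme()
  t_all <- ie_binned(d, sch)$total_ie
  expect_equal(ie_binned(sample(d), sch)$total_ie, t_all)
  split <- sample(c(TRUE, FALSE), length(d), replace = TRUE)
  expect_equal(ie_binned(d[split], sch)$total_ie +
                 ie_binned(d[!split], sch)$total_ie, t_all)
})

test_that("endpoint-mean binning overestimates the exact IE within every bin", {
  edges <- seq(50, 350, by = 50)
  lo <- edges[-7]; hi <- edges[-1]
  # closed-form Hermite-Hadamard inequality on the cube
  expect_true(all((lo^3 + hi^3) / 2 >= (hi^4 - lo^4) / (4 * (hi - lo))))
  # Monte-Carlo confirmation at 1e5 uniform draws per bin
  set.seed(4)
  sch <- ricordi_scheme()
  for (i in 1:6) {
    d <- runif(1e5, edges[i], edges[i + 1])
    expect_gte(mean(ie_binned(d, sch)$per_islet_ie), mean(ie_exact(d)))
  }
})

test_that("binning scheme construction validates edges, rules, and factors", {
  expect_error(binning_scheme(c(100, 50)), "increasing")
  expect_error(binning_scheme(c(50, 100, 150), rule = "explicit_table"),
               "factors")
  expect_error(binning_scheme(c(50, 100, 150), rule = "explicit_table",
                              factors = c(0.2, 0.1)), "increasing")
  expect_error(binning_scheme(c(50, 100, 150), rule = "explicit_table",
                              factors = 0.5), "one factor per bin")

  mid <- binning_scheme(seq(50, 350, 50), rule = "midpoint_cube")
  expect_true(all(mid$factors < ricordi_scheme()$factors))

  # explicit transcribed factors survive unchanged
  ex <- binning_scheme(seq(50, 350, 50), rule = "explicit_table",
                       factors = c(0.16, 0.65, 1.68, 3.5, 6.3, 10.4))
  expect_equal(ex$factors, c(0.16, 0.65, 1.68, 3.5, 6.3, 10.4))
})

test_that("islet records average repeated diameter measurements", {
  r <- islet_records(rbind(c(140, 160), c(150, NA)))
  expect_equal(r$diameter, c(150, 150))
  expect_equal(r$n_measurements, c(2L, 1L))

  expect_error(islet_records(c(100, -5)), "positive")
  expect_error(islet_records(rbind(c(NA_real_, NA_real_))), "no diameter")
  expect_error(islet_records(100, counted_cells = -2), "nonnegative")
  expect_equal(islet_records(c(60, 70), ids = c("a", "b"))$islet_id,
               c("a", "b"))
})
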