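test_that("r_squared matches hand arithmetic and rejects degenerate input", {
  obs <- c(1, 2, 3)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  expect_equal(r_squared(obs, c(1.1, 2.0, 2.9)), 0.99)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(r_squared(1:3, 1:4), "equal length")
})

test_that("pearson_r matches hand arithmetic and is affine invariant", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, c(1, 2, 3, 5)), 0.98271, tolerance = 1e-5)
  expect_error(pearson_r(x, rep(2, 4)), "constant")
  expect_error(pearson_r(1:2, 1:2), "length >= 3")

  set.seed(12)
  for (i in 1:20) {
    a <- rnorm(15); b <- rnorm(15)
    r0 <- pearson_r(a, b)
    expect_equal(pearson_r(3.2 * a + 7, b), r0)
    expect_equal(pearson_r(a, 0.4 * b - 2), r0)
  }
})

test_that("cv_percent matches hand arithmetic", {
  expect_equal(cv_percent(c(5, 5, 5)), 0)
  expect_equal(cv_percent(c(9, 11)), 14.14214, tolerance = 1e-6)
  expect_equal(cv_percent(c(90, 100, 110)), 10)
  expect_error(cv_percent(c(-5, 5)), "mean")
  expect_error(cv_percent(7), "two replicates")
})

test_that("noiseless cubic data are recovered to numerical precision", {
  d <- seq(50, 325, by = 25)
  fit <- fit_cell_model(calibration_points(d, oracle_cubic(d)))
  expect_equal(fit$model$coefficients,
               c(182.1125, -6.2162, 0.0912, -0.0001), tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$model$valid_range, c(50, 325))
})

test_that("weighted means-level fit matches the normal-equations oracle", {
  ref <- rat_islet_counts()
  pts <- calibration_points(ref$diameter, ref$mean_cells,
                            weight = ref$n_islets)
  fit <- fit_cell_model(pts)
  expect_equal(fit$model$coefficients,
               oracle_poly_fit(ref$diameter, ref$mean_cells, 3,
                               w = ref$n_islets),
               tolerance = 1e-6)
  # fitted curve within 10% of the published-coefficient curve at every
  # category diameter
  pred <- suppressWarnings(predict_cells(fit$model, ref$diameter))
  expect_true(all(abs(pred / oracle_cubic(ref$diameter) - 1) < 0.10))
  # means-level R^2 is near 1; per-islet scatter is what brings it to ~0.8
  expect_gt(fit$r_squared, 0.98)
})

test_that("fitting is scale equivariant", {
  set.seed(3)
  d <- runif(40, 50, 300)
  y <- oracle_cubic(d) + rnorm(40, 0, 100)
  f1 <- fit_cell_model(calibration_points(d, y))
  f2 <- fit_cell_model(calibration_points(d, 3.5 * y))
  expect_equal(f2$model$coefficients, 3.5 * f1$model$coefficients)
  expect_equal(f2$r_squared, f1$r_squared)
})

test_that("fit preconditions are enforced", {
  expect_error(fit_cell_model(calibration_points(1:4, 1:4)), "at least")
  expect_error(fit_cell_model(calibration_points(rep(c(50, 100), 5),
                                                 rnorm(10, 100))),
               "distinct diameters")
  expect_error(fit_cell_model(calibration_points(1:10, 1:10), degree = 0),
               "at least 1")
})

test_that("reconstructed per-islet calibration refits with R^2 near 0.8", {
  r2 <- vapply(1:20, function(s) {
    suppressWarnings(fit_cell_model(simulate_reference_calibration(
      seed = 400 + s)))$r_squared
  }, numeric(1))
  expect_gt(median(r2), 0.75)
  expect_lt(median(r2), 0.88)
})

test_that("ANCOVA on identical groups gives F ~ 0, p ~ 1, invariant to labels", {
  set.seed(5)
  a <- gen_flat_noise(60)
  pts <- calibration_points(rep(a$diameter, 2), rep(a$cells, 2),
                            group = rep(c("g1", "g2"), each = 60))
  res <- ancova_compare(pts)
  expect_equal(res$F, 0, tolerance = 1e-8)
  expect_equal(res$p, 1, tolerance = 1e-8)

  set.seed(6)
  b <- gen_flat_noise(60)
  two <- calibration_points(c(a$diameter, b$diameter), c(a$cells, b$cells),
                            group = rep(c("g1", "g2"), each = 60))
  p0 <- ancova_compare(two)$p
  # permute labels (swap names) and reorder rows: p unchanged
  swapped <- two; swapped$group <- ifelse(two$group == "g1", "g2", "g1")
  expect_equal(ancova_compare(swapped)$p, p0)
  shuffled <- two[sample(nrow(two)), ]
  expect_equal(ancova_compare(shuffled)$p, p0)
})

test_that("ANCOVA holds its nominal size and detects a 30% shift", {
  set.seed(1)
  rejected <- replicate(500, {
    a <- gen_flat_noise(100); b <- gen_flat_noise(100)
    pts <- calibration_points(c(a$diameter, b$diameter),
                              c(a$cells, b$cells),
                              group = rep(c("a", "b"), each = 100))
    ancova_compare(pts)$p < 0.05
  })
  rate <- mean(rejected)
  ci_half <- 2.58 * sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(rate - 0.05), ci_half)

  set.seed(2)
  power <- mean(replicate(200, {
    a <- gen_flat_noise(100); b <- gen_flat_noise(100)
    b$cells <- b$cells * 1.3
    pts <- calibration_points(c(a$diameter, b$diameter),
                              c(a$cells, b$cells),
                              group = rep(c("a", "b"), each = 100))
    ancova_compare(pts)$p < 0.05
  }))
  expect_gte(power, 0.95)
})

test_that("ANCOVA names a group that is too small after truncation", {
  set.seed(9)
  big <- gen_flat_noise(50)
  small <- data.frame(diameter = c(260, 280, 300), cells = c(1, 2, 3))
  pts <- calibration_points(c(big$diameter, small$diameter),
                            c(big$cells, small$cells),
                            group = c(rep("ok", 50), rep("tiny", 3)))
  expect_error(ancova_compare(pts, max_diameter = 250), "tiny")
})
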