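model <- kansas_rat_model()

# ten perfectly reference-sized islets with a known readout
ten150 <- assay_group("ref", readouts = 9430,
                      diameters = list(rep(150, 10)))

test_that("normalization divides by the right denominator", {
  per_cell <- normalize_group(ten150, "cell", model = model)
  expect_equal(per_cell$values, 9430 / (10 * oracle_cubic(150)))
  expect_equal(per_cell$values, 0.97803, tolerance = 1e-5)

  per_ie <- normalize_group(ten150, "ie", estimator = "exact")
  expect_equal(per_ie$values, 943)

  self <- assay_group("ref", readouts = 500,
                      diameters = list(rep(150, 10)), dna_totals = 500)
  expect_equal(normalize_group(self, "dna")$values, 1)

  # islets below the countable minimum make the binned denominator zero
  sub <- assay_group("tiny", readouts = 10, diameters = list(c(30, 40)))
  expect_error(normalize_group(sub, "ie", estimator = "binned"),
               "zero denominator")
  expect_error(normalize_group(ten150, "dna"), "dna_totals")
})

test_that("normalization is linear and SEM shrinks by sqrt(2) on merging", {
  set.seed(44)
  vals <- rnorm(20, 100, 10)
  g1 <- assay_group("g", readouts = vals,
                    diameters = rep(list(rep(150, 5)), 20))
  g2 <- assay_group("g", readouts = 2 * vals,
                    diameters = rep(list(rep(150, 5)), 20))
  n1 <- normalize_group(g1, "cell"); n2 <- normalize_group(g2, "cell")
  expect_equal(n2$values, 2 * n1$values)

  merged <- assay_group("g", readouts = rep(vals, 2),
                        diameters = rep(list(rep(150, 5)), 40))
  nm <- normalize_group(merged, "cell")
  expect_equal(nm$mean, n1$mean)
  # sqrt(2) shrink up to the n-1 finite-sample correction
  expect_equal(nm$sem, n1$sem / sqrt(2), tolerance = 0.02)
})

test_that("per-IE (exact) and per-cell values differ by exactly the model count", {
  per_ie <- normalize_group(ten150, "ie", estimator = "exact")
  per_cell <- normalize_group(ten150, "cell", model = model)
  expect_equal(per_ie$values / per_cell$values,
               predict_cells(model, 150))
})

test_that("the pooled t test matches hand arithmetic", {
  mk <- function(lbl, vals) {
    assay_group(lbl, readouts = vals,
                diameters = rep(list(150), length(vals)),
                dna_totals = rep(1, length(vals)))
  }
  res <- compare_groups(mk("A", c(10, 12)), mk("B", c(20, 22)), basis = "dna")
  expect_equal(res$t, -7.0710678, tolerance = 1e-6)
  expect_equal(res$df, 2)
  expect_equal(res$p, 0.0194193, tolerance = 1e-5)

  same <- compare_groups(mk("A", c(10, 12)), mk("B", c(10, 12)),
                         basis = "dna")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  welch <- compare_groups(mk("A", c(10, 12, 14)), mk("B", c(20, 29, 38)),
                          basis = "dna", welch = TRUE)
  expect_lt(welch$df, 4) # Welch df drops below the pooled n1+n2-2
  expect_error(compare_groups(mk("A", 10), mk("B", c(20, 22)),
                              basis = "dna"), "two replicates")
})

test_that("noise-free readouts proportional to cells: per-IE biased, per-cell exact", {
  cfg <- prep_config(count_noise = "none",
                     per_cell_content = list(dna_pg = c(6.05, 0),
                                             protein_ng = c(0.58, 0)),
                     seed = 31)
  g <- simulate_assay_groups(cfg, n_experiments = 6)
  per_cell_s <- normalize_group(g$small, "cell")
  per_cell_l <- normalize_group(g$large, "cell")
  # readout = sum(model cells) * content and denominator = sum(model cells)
  expect_equal(per_cell_s$values, rep(6.05, 6))
  expect_equal(per_cell_l$values, rep(6.05, 6))

  per_ie_s <- normalize_group(g$small, "ie")
  per_ie_l <- normalize_group(g$large, "ie")
  # deterministic inequality: every small replicate above every large one
  expect_gt(min(per_ie_s$values), max(per_ie_l$values))
})

test_that("a size-dependent analyte reverses sign between bases", {
  cfg <- prep_config(size_effect = 0.15, seed = 5)
  g <- simulate_assay_groups(cfg, analyte = "protein_ng")
  per_ie <- compare_groups(g$small, g$large, "ie")
  per_cell <- compare_groups(g$small, g$large, "cell")
  expect_gt(per_ie$mean_A, per_ie$mean_B)       # per IE: small > large
  expect_lt(per_cell$mean_A, per_cell$mean_B)   # per cell: large > small
  expect_lt(per_ie$p, 0.05)
  expect_lt(per_cell$p, 0.05)
})

test_that("material_for_protein converts per-unit content to a load requirement", {
  expect_equal(material_for_protein(10, 0.80, "ie"), 12.5)
  expect_equal(material_for_protein(10, 0.58, "cell"), 17241.38,
               tolerance = 1e-6)
  expect_equal(material_for_protein(0, 0.80, "ie"), 0)
  expect_error(material_for_protein(10, 0, "ie"), "positive")
})

test_that("assay group construction validates sizes and classes", {
  expect_error(assay_group("g", -1, list(150)), "nonnegative")
  expect_error(assay_group("small", 10, list(c(80, 150)),
                           size_range = c(0, 100)), "size")
  expect_error(assay_group("g", c(1, 2), list(150)), "one vector per")
})
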