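# Seeded simulator for islet preparations, counting experiments, and assay
# readouts. Category means/SEMs/ns of the rat calibration study are the
# variability model: per-islet count noise is normal with SD reconstructed
# as SEM * sqrt(n) per category, linearly interpolated between category
# diameters.

#' Reference per-category cell counts for rat islets
#'
#' Category summaries (mean +/- SEM cells per islet, with per-category
#' sample sizes; 343 islets in total) from the dissociation/cytometry
#' calibration underlying [kansas_rat_model()]. The reconstructed
#' per-category SD is `sem_cells * sqrt(n_islets)`.
#'
#' @return A data frame with columns `diameter` (um), `n_islets`,
#'   `mean_cells`, `sem_cells`, `sd_cells`.
#' @examples
#' rat_islet_counts()
#' @export
rat_islet_counts <- function() {
  d <- data.frame(
    diameter   = seq(50, 325, by = 25),
    n_islets   = c(25L, 48L, 40L, 36L, 33L, 46L, 42L, 31L, 21L, 7L, 5L, 9L),
    mean_cells = c(92, 188, 322, 642, 943, 1308, 1674, 2099, 2731, 2831,
                   3586, 4003),
    sem_cells  = c(11, 15, 24, 48, 60, 68, 91, 94, 137, 216, 689, 506)
  )
  d$sd_cells <- d$sem_cells * sqrt(d$n_islets)
  d
}

#' Configure a synthetic islet preparation
#'
#' @param n_islets Number of islets to draw (ignored when
#'   `size_distribution` allocates per-category counts).
#' @param size_distribution Either
#'   `list(family = "lognormal", meanlog, sdlog, range)` -- a truncated
#'   lognormal over `range` (defaults: median 90 um, sigma-log 0.45 over
#'   50-350 um; a realistic small-islet-heavy preparation, a repository
#'   choice rather than a measured distribution) -- or
#'   `list(family = "categories", diameters, counts)` giving exact
#'   per-diameter allocations (defaults to the reference study's
#'   allocation, [rat_islet_counts()]).
#' @param count_noise Per-islet cell-count noise SD as a function of
#'   diameter: `"reference"` (SD reconstructed from the reference
#'   categories, interpolated; default), `"none"`, a single number, or a
#'   function of diameter.
#' @param per_cell_content Named list of per-cell analyte content, each
#'   `c(mean, sd)`: defaults `dna_pg = c(6.05, 0.69)` and
#'   `protein_ng = c(0.58, 0.06)` (means per cell; SDs act as
#'   between-experiment variation).
#' @param size_effect Relative change in per-cell content per 100 um of
#'   diameter above 150 um (0 = size-independent content; positive values
#'   emulate an analyte, like proinsulin, that is enriched in large-islet
#'   cells).
#' @param axis_ratios Ellipsoid axis ratios `c(b_over_a, c_over_a)` recorded
#'   for shape-aware consumers; defaults `c(0.82, 0.6)`.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return An object of class `prep_config`.
#' @export
prep_config <- function(n_islets = 500,
                        size_distribution = list(family = "lognormal",
                                                 meanlog = log(90),
                                                 sdlog = 0.45,
                                                 range = c(50, 350)),
                        count_noise = "reference",
                        per_cell_content = list(dna_pg = c(6.05, 0.69),
                                                protein_ng = c(0.58, 0.06)),
                        size_effect = 0,
                        axis_ratios = c(b_over_a = 0.82, c_over_a = 0.6),
                        seed = NULL) {
  fam <- size_distribution$family
  if (!fam %in% c("lognormal", "categories")) {
    stop("unknown size distribution family \"", fam, "\"", call. = FALSE)
  }
  if (fam == "lognormal") {
    rng <- size_distribution$range
    if (rng[1] < 20 || rng[2] > 350) {
      stop("size distribution support must lie within the model range ",
           "[20, 350] um", call. = FALSE)
    }
    if (n_islets < 1) stop("`n_islets` must be positive", call. = FALSE)
  } else {
    if (is.null(size_distribution$diameters)) {
      ref <- rat_islet_counts()
      size_distribution$diameters <- ref$diameter
      size_distribution$counts <- ref$n_islets
    }
    if (any(size_distribution$diameters < 20) ||
        any(size_distribution$diameters > 350)) {
      stop("category diameters must lie within the model range [20, 350] um",
           call. = FALSE)
    }
  }
  for (cc in per_cell_content) {
    if (any(cc < 0)) stop("per-cell content means and SDs must be ",
                          "nonnegative", call. = FALSE)
  }
  structure(
    list(n_islets = n_islets, size_distribution = size_distribution,
         count_noise = count_noise, per_cell_content = per_cell_content,
         size_effect = size_effect, axis_ratios = axis_ratios, seed = seed),
    class = "prep_config"
  )
}

noise_sd_fun <- function(count_noise) {
  ref <- rat_islet_counts()
  if (identical(count_noise, "reference")) {
    function(d) approx(ref$diameter, ref$sd_cells, xout = d, rule = 2)$y
  } else if (identical(count_noise, "none")) {
    function(d) rep(0, length(d))
  } else if (is.numeric(count_noise) && length(count_noise) == 1) {
    if (count_noise < 0) stop("count-noise SD must be nonnegative",
                              call. = FALSE)
    function(d) rep(count_noise, length(d))
  } else if (is.function(count_noise)) {
    count_noise
  } else {
    stop("`count_noise` must be \"reference\", \"none\", a number, or a ",
         "function of diameter", call. = FALSE)
  }
}

draw_diameters <- function(config) {
  sdist <- config$size_distribution
  if (sdist$family == "lognormal") {
    rng <- sdist$range
    plo <- stats::plnorm(rng[1], sdist$meanlog, sdist$sdlog)
    phi <- stats::plnorm(rng[2], sdist$meanlog, sdist$sdlog)
    u <- runif(config$n_islets, plo, phi)
    qlnorm(u, sdist$meanlog, sdist$sdlog)
  } else {
    rep(sdist$diameters, sdist$counts)
  }
}

#' Simulate an islet preparation with known true cell counts
#'
#' Draws islet diameters from the configured size distribution and assigns
#' each islet a true cell count: the model prediction at its diameter plus
#' normal noise with the configured diameter-dependent SD, truncated at a
#' minimum of one cell. The truth is carried alongside the observed
#' diameter so estimator properties can be checked against it.
#'
#' @param config A [prep_config()].
#' @param model Generating [cell_count_model()]; default
#'   [kansas_rat_model()].
#' @return A data frame of class `synthetic_prep` with columns `islet_id`,
#'   `diameter`, `true_cells`; the config is attached as attribute
#'   `"config"`.
#' @examples
#' prep <- simulate_prep(prep_config(n_islets = 100, seed = 1))
#' head(prep)
#' @export
simulate_prep <- function(config, model = kansas_rat_model()) {
  stopifnot(inherits(config, "prep_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  d <- draw_diameters(config)
  check_model_range(model, d)
  sd_fun <- noise_sd_fun(config$count_noise)
  mu <- suppressWarnings(predict_cells(model, d))
  cells <- pmax(1, mu + rnorm(length(d), 0, sd_fun(d)))
  out <- data.frame(islet_id = paste0("islet_", seq_along(d)),
                    diameter = d, true_cells = cells,
                    stringsAsFactors = FALSE)
  class(out) <- c("synthetic_prep", "data.frame")
  attr(out, "config") <- config
  out
}

#' Simulate a reconstruction of the reference calibration study
#'
#' Rebuilds per-islet (diameter, cell count) data from the published
#' category summaries: for each category of [rat_islet_counts()], `n_i`
#' counts are drawn from `Normal(mean_i, sem_i * sqrt(n_i))` at the
#' category diameter, truncated at a minimum of one cell (343 islets in
#' total). Unlike [simulate_prep()], which centres counts on the continuous
#' model curve, this generator centres on the published category means --
#' it reconstructs the calibration data the model was fitted to, so a
#' cubic refit recovers the published goodness of fit (R-squared near 0.8).
#'
#' @param seed Optional integer seed.
#' @param reference Category summary table; default [rat_islet_counts()].
#' @return A [calibration_points()] data frame.
#' @export
simulate_reference_calibration <- function(seed = NULL,
                                           reference = rat_islet_counts()) {
  if (!is.null(seed)) set.seed(seed)
  d <- rep(reference$diameter, reference$n_islets)
  mu <- rep(reference$mean_cells, reference$n_islets)
  sdv <- rep(reference$sd_cells, reference$n_islets)
  calibration_points(d, pmax(1, rnorm(length(d), mu, sdv)))
}

#' Simulate a paired counting experiment
#'
#' Emulates counting the same dissociated size categories with two methods
#' (e.g. computer-assisted cytometry vs a hemocytometer): islets are
#' gathered into the nearest diameter category and each method observes the
#' category's true mean count with multiplicative noise of the given CV%.
#' The paired per-category counts feed [pearson_r()] for inter-method
#' reliability.
#'
#' @param prep A [simulate_prep()] result.
#' @param cv_a,cv_b Per-method coefficient of variation (percent, `>= 0`).
#' @param categories Category center diameters (um); default
#'   `seq(50, 250, 50)`.
#' @param seed Optional integer seed.
#' @return A data frame with one row per nonempty category: `category`,
#'   `n_islets`, `true_mean`, `count_a`, `count_b`.
#' @export
simulate_counting_experiment <- function(prep, cv_a = 5, cv_b = 5,
                                         categories = seq(50, 250, by = 50),
                                         seed = NULL) {
  if (cv_a < 0 || cv_b < 0) stop("method CV%% must be nonnegative",
                                 call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  idx <- vapply(prep$diameter, function(x) which.min(abs(categories - x)),
                integer(1))
  out <- do.call(rbind, lapply(seq_along(categories), function(i) {
    sel <- idx == i
    if (!any(sel)) return(NULL)
    tm <- mean(prep$true_cells[sel])
    data.frame(category = categories[i], n_islets = sum(sel), true_mean = tm,
               count_a = max(0, tm * (1 + rnorm(1) * cv_a / 100)),
               count_b = max(0, tm * (1 + rnorm(1) * cv_b / 100)))
  }))
  rownames(out) <- NULL
  out
}

#' Simulate small- and large-islet assay groups
#'
#' Generates replicate assay experiments for two disjoint islet size
#' classes. Each replicate draws its islets (diameters uniform within the
#' class range), assigns true cell counts as in [simulate_prep()], draws a
#' per-experiment per-cell content level (`mean * (1 + N(0,1) * sd/mean)`),
#' applies the optional size effect, and records the total readout
#' `sum(true cells x per-cell content)`. Total DNA is simulated alongside
#' so per-DNA normalization is always available.
#'
#' @param analyte `"dna_pg"` or `"protein_ng"` (keys of the config's
#'   `per_cell_content`).
#' @param config A [prep_config()]; supplies content parameters,
#'   `size_effect`, count noise, and the seed.
#' @param small_range,large_range Disjoint diameter intervals (um) within
#'   the model range; defaults `c(50, 100)` and `c(200, 250)`.
#' @param n_experiments Replicates per group, default 20.
#' @param islets_per_experiment Named vector `c(small = 50, large = 20)`
#'   (the minimum group sizes used in the assay experiments).
#' @param model Generating [cell_count_model()].
#' @return `list(small = assay_group, large = assay_group)`; each group also
#'   carries the per-replicate sum of true cells as attribute
#'   `"true_cells"`.
#' @export
simulate_assay_groups <- function(config = prep_config(),
                                  analyte = c("dna_pg", "protein_ng"),
                                  small_range = c(50, 100),
                                  large_range = c(200, 250),
                                  n_experiments = 20,
                                  islets_per_experiment = c(small = 50,
                                                            large = 20),
                                  model = kansas_rat_model()) {
  analyte <- match.arg(analyte)
  if (small_range[2] > large_range[1] && large_range[2] > small_range[1]) {
    stop("small and large size ranges must be disjoint", call. = FALSE)
  }
  rng <- model$valid_range
  if (small_range[1] < rng[1] || large_range[2] > rng[2]) {
    stop("size ranges must lie within the model range [", rng[1], ", ",
         rng[2], "] um", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  content <- config$per_cell_content[[analyte]]
  dna <- config$per_cell_content[["dna_pg"]]
  sd_fun <- noise_sd_fun(config$count_noise)

  one_group <- function(label, range, n_islets) {
    readouts <- numeric(n_experiments)
    dna_totals <- numeric(n_experiments)
    true_totals <- numeric(n_experiments)
    diameters <- vector("list", n_experiments)
    for (i in seq_len(n_experiments)) {
      d <- runif(n_islets, range[1], range[2])
      mu <- suppressWarnings(predict_cells(model, d))
      cells <- pmax(1, mu + rnorm(n_islets, 0, sd_fun(d)))
      level <- content[1] * max(0, 1 + rnorm(1) * content[2] / content[1])
      per_cell <- level *
        pmax(0, 1 + config$size_effect * (d - 150) / 100)
      dna_level <- dna[1] * max(0, 1 + rnorm(1) * dna[2] / dna[1])
      readouts[i] <- sum(cells * per_cell)
      dna_totals[i] <- sum(cells) * dna_level
      true_totals[i] <- sum(cells)
      diameters[[i]] <- d
    }
    g <- assay_group(label, readouts, diameters, dna_totals = dna_totals)
    attr(g, "true_cells") <- true_totals
    g
  }
  list(small = one_group("small", small_range,
                         islets_per_experiment[["small"]]),
       large = one_group("large", large_range,
                         islets_per_experiment[["large"]]))
}
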