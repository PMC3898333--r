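# Fitting diameter -> cell-count models from counted data, and the
# validity/reliability statistics: R^2, ANCOVA curve comparison across
# animal groups, Pearson correlation between counting methods, CV%.

#' Assemble calibration points
#'
#' @param diameter Islet diameters (um), strictly positive.
#' @param cells Counted cells per islet, nonnegative.
#' @param group Optional group labels (age/sex/method).
#' @param weight Optional positive fit weights (e.g. per-category n when
#'   fitting published category means).
#' @return A data frame of class `calibration_points`.
#' @export
calibration_points <- function(diameter, cells, group = NULL, weight = NULL) {
  check_numeric(diameter, "diameter"); check_numeric(cells, "cells")
  n <- length(diameter)
  if (length(cells) != n) stop("`diameter` and `cells` lengths differ",
                               call. = FALSE)
  if (any(diameter <= 0)) stop("diameters must be strictly positive",
                               call. = FALSE)
  if (any(cells < 0)) stop("cell counts must be nonnegative", call. = FALSE)
  if (is.null(group)) group <- rep(NA_character_, n)
  if (is.null(weight)) weight <- rep(1, n)
  check_numeric(weight, "weight")
  if (any(weight <= 0)) stop("weights must be positive", call. = FALSE)
  structure(
    data.frame(diameter = as.numeric(diameter), cells = as.numeric(cells),
               group = as.character(group), weight = as.numeric(weight),
               stringsAsFactors = FALSE),
    class = c("calibration_points", "data.frame")
  )
}

as_calibration_points <- function(points) {
  if (inherits(points, "calibration_points")) return(points)
  if (is.data.frame(points)) {
    if (!all(c("diameter", "cells") %in% names(points))) {
      stop("calibration data need `diameter` and `cells` columns",
           call. = FALSE)
    }
    return(calibration_points(points$diameter, points$cells,
                              group = points$group, weight = points$weight))
  }
  stop("`points` must be a data frame of calibration points", call. = FALSE)
}

#' Fit a polynomial diameter-to-cell-number model
#'
#' Ordinary (or weighted) least-squares fit of `cells` on a raw polynomial
#' basis in `diameter`. The returned model's validity range is the observed
#' diameter range of the data, and its reference cells-per-IE is the fitted
#' prediction at 150 um when 150 um is inside that range.
#'
#' @param points A data frame with `diameter` and `cells` columns (see
#'   [calibration_points()]).
#' @param degree Polynomial degree, default 3 (the degree that best fits
#'   dissociation counts over 50-325 um).
#' @param weights Optional fit weights; defaults to the points' `weight`
#'   column.
#' @return An object of class `fit_report`: `model` (a
#'   [cell_count_model()]), `r_squared`, `residual_sd` (cells), `n_points`,
#'   `degree`, and `vcov` (coefficient covariance, increasing power order,
#'   for prediction standard errors).
#' @examples
#' ref <- rat_islet_counts()
#' fit_cell_model(calibration_points(ref$diameter, ref$mean_cells,
#'                                   weight = ref$n_islets))
#' @export
fit_cell_model <- function(points, degree = 3, weights = NULL) {
  pts <- as_calibration_points(points)
  if (degree < 1) stop("`degree` must be at least 1", call. = FALSE)
  if (nrow(pts) < degree + 2) {
    stop("need at least degree + 2 = ", degree + 2, " points", call. = FALSE)
  }
  if (length(unique(pts$diameter)) < degree + 1) {
    stop("need at least ", degree + 1, " distinct diameters for a degree-",
         degree, " fit", call. = FALSE)
  }
  w <- if (is.null(weights)) pts$weight else weights
  check_numeric(w, "weights")
  fit <- stats::lm(cells ~ poly(diameter, degree, raw = TRUE), data = pts,
                   weights = w)
  cf <- unname(coef(fit))
  pred <- unname(predict(fit))
  sse <- sum(w * (pts$cells - pred)^2)
  sst <- sum(w * (pts$cells - stats::weighted.mean(pts$cells, w))^2)
  rng <- range(pts$diameter)
  ref <- if (rng[1] <= 150 && 150 <= rng[2]) eval_poly(cf, 150) else NA_real_
  structure(
    list(model = cell_count_model(cf, valid_range = rng,
                                  reference_cells_per_ie = ref,
                                  label = paste0("fitted-degree", degree),
                                  positivity = "warn"),
         r_squared = 1 - sse / sst,
         residual_sd = sqrt(sse / stats::df.residual(fit)),
         n_points = nrow(pts),
         degree = degree,
         # suppressed: summary.lm warns on noiseless (perfect-fit) data
         vcov = unname(suppressWarnings(stats::vcov(fit)))),
    class = "fit_report"
  )
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Polynomial calibration fit (degree ", x$degree, ", n = ", x$n_points,
      ")\n", sep = "")
  cat("  R-squared:", format(x$r_squared, digits = 4),
      "  residual SD:", format(x$residual_sd, digits = 4), "cells\n")
  print(x$model)
  invisible(x)
}

#' Coefficient of determination
#'
#' `1 - SSE/SST` of a set of predictions against observations.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2);
#'   `observed` must not be constant.
#' @return R-squared (can be negative for predictions worse than the mean).
#' @export
r_squared <- function(observed, predicted) {
  check_numeric(observed, "observed"); check_numeric(predicted, "predicted")
  if (length(observed) != length(predicted) || length(observed) < 2) {
    stop("`observed` and `predicted` must have equal length >= 2",
         call. = FALSE)
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("`observed` is constant; R-squared undefined",
                     call. = FALSE)
  1 - sum((observed - predicted)^2) / sst
}

#' Compare calibration curves across groups (ANCOVA)
#'
#' Extra-sum-of-squares F test of whether a single polynomial calibration
#' curve fits all groups against separate per-group curves (all polynomial
#' coefficients free per group, not slope-only, since whole regression
#' curves are compared). Points above `max_diameter` are excluded before
#' fitting: when young animals lack large islets, the shared range is what
#' can be compared (default 250 um).
#'
#' @param points Calibration data with a non-missing `group` column.
#' @param max_diameter Truncation diameter (um), default 250.
#' @param degree Shared polynomial degree, default 3.
#' @return An object of class `ancova_comparison`: `F`, `df1`, `df2`, `p`,
#'   `n_groups`, `n_points`, `max_diameter`.
#' @export
ancova_compare <- function(points, max_diameter = 250, degree = 3) {
  pts <- as_calibration_points(points)
  if (anyNA(pts$group)) stop("every point needs a group label", call. = FALSE)
  groups <- unique(pts$group)
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  pts <- pts[pts$diameter <= max_diameter, , drop = FALSE]
  for (g in groups) {
    sub <- pts[pts$group == g, ]
    if (nrow(sub) < degree + 2 || length(unique(sub$diameter)) < degree + 1) {
      stop("group \"", g, "\" has too few points after truncation at ",
           max_diameter, " um for a degree-", degree, " fit", call. = FALSE)
    }
  }
  pts$group <- factor(pts$group)
  reduced <- stats::lm(cells ~ poly(diameter, degree, raw = TRUE), data = pts)
  full <- stats::lm(cells ~ group * poly(diameter, degree, raw = TRUE),
                    data = pts)
  av <- stats::anova(reduced, full)
  structure(
    list(F = av$F[2], df1 = av$Df[2], df2 = av$Res.Df[2], p = av$`Pr(>F)`[2],
         n_groups = length(groups), n_points = nrow(pts),
         max_diameter = max_diameter),
    class = "ancova_comparison"
  )
}

#' @export
print.ancova_comparison <- function(x, ...) {
  cat("ANCOVA curve comparison across", x$n_groups, "groups (diameters <=",
      x$max_diameter, "um, n =", x$n_points, ")\n")
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g\n", x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric vectors (length >= 3), both nonconstant.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  check_numeric(x, "x"); check_numeric(y, "y")
  if (length(x) != length(y) || length(x) < 3) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  cor(x, y)
}

#' Coefficient of variation (percent)
#'
#' `100 * sample SD / mean` over a set of replicate measurements; the
#' repeatability metric used to audit IE counting (reported intra-technician
#' CVs range up to 42.5%).
#'
#' @param replicates Numeric vector of length >= 2 with positive mean.
#' @return CV in percent.
#' @export
cv_percent <- function(replicates) {
  check_numeric(replicates, "replicates")
  if (length(replicates) < 2) stop("need at least two replicates",
                                   call. = FALSE)
  m <- mean(replicates)
  if (m <= 0) stop("CV%% undefined for nonpositive mean", call. = FALSE)
  100 * sd(replicates) / m
}
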