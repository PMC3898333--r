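# The diameter -> cell-number conversion model: a cubic polynomial in
# measured diameter, calibrated on dissociated rat islets counted by
# computer-assisted cytometry, plus the comparison curves against
# IE-based estimates.

#' Construct a diameter-to-cell-number conversion model
#'
#' A polynomial in islet diameter (um) predicting the total cell number per
#' islet, with an explicit validity range outside which prediction is a hard
#' error (a fitted cubic extrapolates pathologically: the built-in rat model
#' turns negative below ~14 um). Predictions must be strictly positive on
#' the whole validity range.
#'
#' @param coefficients Numeric vector of polynomial coefficients in
#'   increasing order of power: intercept (cells), linear (cells/um),
#'   quadratic (cells/um^2), cubic (cells/um^3). Any degree >= 1 is allowed.
#' @param valid_range Length-2 numeric, admissible diameter interval (um).
#' @param reference_cells_per_ie Cell count of a one-IE (150 um) islet; used
#'   by the IE-implied theoretical curves. Default 943.
#' @param label Short model identifier recorded in reports.
#' @param positivity How to treat a polynomial that is not strictly
#'   positive on the validity range: `"error"` (default) or `"warn"`.
#'   Calibration fits to noisy counts can dip marginally below zero at a
#'   range edge, so [fit_cell_model()] uses `"warn"`.
#' @return An object of class `cell_count_model`.
#' @seealso [kansas_rat_model()], [predict_cells()]
#' @export
cell_count_model <- function(coefficients, valid_range = c(20, 350),
                             reference_cells_per_ie = 943,
                             label = "custom",
                             positivity = c("error", "warn")) {
  positivity <- match.arg(positivity)
  check_numeric(coefficients, "coefficients")
  if (length(coefficients) < 2) {
    stop("need at least intercept and linear coefficients", call. = FALSE)
  }
  check_numeric(valid_range, "valid_range")
  if (length(valid_range) != 2 || valid_range[1] >= valid_range[2] ||
      valid_range[1] <= 0) {
    stop("`valid_range` must be an increasing positive interval",
         call. = FALSE)
  }
  m <- structure(
    list(coefficients = as.numeric(coefficients),
         valid_range = as.numeric(valid_range),
         reference_cells_per_ie = reference_cells_per_ie,
         label = label),
    class = "cell_count_model"
  )
  grid <- seq(valid_range[1], valid_range[2], length.out = 512)
  if (any(eval_poly(m$coefficients, grid) <= 0)) {
    msg <- paste0("model predictions are not strictly positive on the ",
                  "validity range [", valid_range[1], ", ", valid_range[2],
                  "] um")
    if (positivity == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  m
}

#' The built-in rat diameter-to-cell-number model
#'
#' The cubic calibrated on dissociated rat islets:
#' `cells = -0.0001 d^3 + 0.0912 d^2 - 6.2162 d + 182.1125`,
#' valid for diameters of 20-350 um, with a reference count of 943 cells per
#' one-IE (150 um) islet. Coefficients are stored at full published
#' precision.
#'
#' @return A [cell_count_model()].
#' @examples
#' predict_cells(kansas_rat_model(), 150) # 964.18 cells
#' @export
kansas_rat_model <- function() {
  cell_count_model(c(182.1125, -6.2162, 0.0912, -0.0001),
                   valid_range = c(20, 350),
                   reference_cells_per_ie = 943,
                   label = "kansas-rat-2012")
}

eval_poly <- function(coefs, x) {
  # Horner evaluation, coefficients in increasing power
  out <- rep(0, length(x))
  for (a in rev(coefs)) out <- out * x + a
  out
}

#' @export
print.cell_count_model <- function(x, ...) {
  deg <- length(x$coefficients) - 1L
  cat("Diameter -> cell-number model \"", x$label, "\" (degree ", deg, ")\n",
      sep = "")
  cat("  coefficients (increasing power):",
      paste(format(x$coefficients), collapse = ", "), "\n")
  cat("  valid diameter range:", x$valid_range[1], "-", x$valid_range[2],
      "um\n")
  cat("  reference cells per IE:", x$reference_cells_per_ie, "\n")
  invisible(x)
}

check_model_range <- function(model, d, ids = NULL) {
  lo <- model$valid_range[1]; hi <- model$valid_range[2]
  bad <- d < lo | d > hi
  if (any(bad)) {
    what <- if (is.null(ids)) paste(format(d[bad]), collapse = ", ")
            else paste0(ids[bad], " (", format(d[bad]), " um)",
                        collapse = ", ")
    stop("diameter(s) outside the model's validity range [", lo, ", ", hi,
         "] um: ", what, call. = FALSE)
  }
}

#' Predict cell number from islet diameter
#'
#' Evaluates the model polynomial at each diameter. Diameters outside the
#' model's validity range raise an error naming the admissible interval;
#' there is no silent clamping. Because the built-in cubic has a shallow
#' non-monotone dip below ~36 um, a warning is emitted when predictions are
#' requested below 40 um.
#'
#' @param model A [cell_count_model()].
#' @param d Numeric vector of diameters (um) within the validity range.
#' @return Predicted cells per islet.
#' @export
predict_cells <- function(model, d) {
  stopifnot(inherits(model, "cell_count_model"))
  check_numeric(d, "d")
  check_model_range(model, d)
  if (any(d < 40)) {
    warning("predictions below 40 um lie in the non-monotone region of the ",
            "fitted cubic; interpret with care", call. = FALSE)
  }
  eval_poly(model$coefficients, d)
}

#' Total predicted cell number of a preparation
#'
#' @param model A [cell_count_model()].
#' @param islets An [islet_records()] table or numeric diameters (um).
#' @return Sum of [predict_cells()] over all islets (0 for an empty list).
#'   Any out-of-range islet raises an error listing the offending islet ids.
#' @export
total_cells <- function(model, islets) {
  d <- islet_diameters(islets)
  if (length(d) == 0) return(0)
  check_model_range(model, d, ids = islet_ids(islets))
  sum(predict_cells(model, d))
}

#' Cells per islet equivalent as a function of diameter
#'
#' The measured cell number divided by the exact-sphere IE of the same
#' diameter. If IE were an accurate tissue measure this curve would be flat
#' at the reference count; instead it declines with diameter, quantifying
#' how IE overestimates large-islet tissue.
#'
#' @inheritParams predict_cells
#' @return Cells per IE at each diameter.
#' @examples
#' cells_per_ie(kansas_rat_model(), c(100, 150, 250))
#' @export
cells_per_ie <- function(model, d) {
  check_numeric(d, "d")
  if (any(d <= 0)) stop("diameters must be strictly positive", call. = FALSE)
  predict_cells(model, d) / ie_exact(d)
}

#' IE-implied theoretical cell number
#'
#' The cell count an IE-based estimate attributes to an islet of diameter
#' `d`: the reference cells-per-IE times the islet's IE under the chosen
#' estimator. With `estimator = "exact"` this is the smooth sphere-assumption
#' curve; with a binned estimator it is the corresponding step curve.
#'
#' @param d Diameters (um), `>= 0`.
#' @param reference_cells_per_ie Cells in a one-IE islet; default 943.
#' @param estimator `"exact"` (sphere) or `"binned"`.
#' @param scheme [binning_scheme()] used when `estimator = "binned"`.
#' @return Implied cells at each diameter.
#' @examples
#' ie_implied_cells(300)        # 943 * 8 = 7544
#' @export
ie_implied_cells <- function(d, reference_cells_per_ie = 943,
                             estimator = c("exact", "binned"),
                             scheme = ricordi_scheme()) {
  estimator <- match.arg(estimator)
  check_numeric(d, "d")
  ie <- switch(estimator,
    exact = ie_exact(d),
    binned = {
      idx <- findInterval(d, scheme$edges, rightmost.closed = FALSE)
      if (any(idx < 1 | idx > length(scheme$factors))) {
        stop("diameter(s) outside the binning scheme", call. = FALSE)
      }
      scheme$factors[idx]
    }
  )
  reference_cells_per_ie * ie
}

#' Ratio of IE-implied to model-predicted cell number
#'
#' Ratios above 1 mean the IE-based estimate attributes more tissue to the
#' islet than its measured cell content supports. Under the exact-sphere
#' estimator the ratio is below 1 just under 150 um, crosses 1 near 150 um,
#' and rises steeply for larger islets.
#'
#' @inheritParams predict_cells
#' @param estimator `"exact"` or `"binned"` (see [ie_implied_cells()]).
#' @param scheme Binning scheme for `estimator = "binned"`.
#' @param reference_cells_per_ie Reference count; defaults to the model's.
#' @return Dimensionless overestimation ratios.
#' @examples
#' overestimation_ratio(kansas_rat_model(), c(150, 300))
#' @export
overestimation_ratio <- function(model, d, estimator = c("exact", "binned"),
                                 scheme = ricordi_scheme(),
                                 reference_cells_per_ie =
                                   model$reference_cells_per_ie) {
  estimator <- match.arg(estimator)
  ie_implied_cells(d, reference_cells_per_ie, estimator, scheme) /
    predict_cells(model, d)
}
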