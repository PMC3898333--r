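# Sphere/ellipsoid volume math and the IE estimators: exact per-islet
# conversion, conventional endpoint-mean binning, and density-expectation
# (refined) binning. All lengths in um, volumes in um^3.

#' Reference islet-equivalent volume
#'
#' One islet equivalent (IE) is defined as the volume of a perfect sphere of
#' 150 um diameter, `(pi/6) * 150^3` = 1,767,146 um^3 (1.77e6 to 3 s.f.).
#'
#' @format A length-one numeric (um^3).
#' @export
IE_REFERENCE_VOLUME <- pi / 6 * 150^3

#' Reference diameter of one islet equivalent (um)
#' @format A length-one numeric.
#' @export
IE_REFERENCE_DIAMETER <- 150

#' Sphere volume from diameter
#'
#' @param d Numeric vector of sphere diameters (um), all `>= 0`.
#' @return Volumes `(pi/6) d^3` in um^3.
#' @examples
#' sphere_volume(150) # 1,767,146 um^3 = 1 IE
#' @export
sphere_volume <- function(d) {
  check_numeric(d, "d")
  if (any(d < 0)) stop("sphere diameters must be nonnegative", call. = FALSE)
  pi / 6 * d^3
}

#' Ellipsoid volume from full axis lengths
#'
#' Isolated islets are typically oblate rather than spherical: reported mean
#' axis ratios are b/a = 0.82 and c/a = 0.6. This gives the volume of the
#' general ellipsoid with full axes `a`, `b`, `c`; it reduces to
#' [sphere_volume()] when the axes are equal.
#'
#' @param a,b,c Full axis lengths (um), each `>= 0`. Recycled to a common
#'   length.
#' @return Volumes `(pi/6) a b c` in um^3.
#' @export
ellipsoid_volume <- function(a, b, c) {
  check_numeric(a, "a"); check_numeric(b, "b"); check_numeric(c, "c")
  if (any(a < 0) || any(b < 0) || any(c < 0)) {
    stop("ellipsoid axes must be nonnegative", call. = FALSE)
  }
  pi / 6 * a * b * c
}

#' Exact islet-equivalent value of a single diameter
#'
#' Converts each islet individually, with no binning: `ie_exact(d) =
#' (d/150)^3 = sphere_volume(d) / IE_REFERENCE_VOLUME`.
#'
#' @param d Numeric vector of islet diameters (um), `>= 0`.
#' @return IE values (dimensionless).
#' @examples
#' ie_exact(c(75, 150, 300)) # 0.125, 1, 8
#' @export
ie_exact <- function(d) {
  check_numeric(d, "d")
  if (any(d < 0)) stop("islet diameters must be nonnegative", call. = FALSE)
  (d / IE_REFERENCE_DIAMETER)^3
}

#' Conventional (endpoint-mean) bin factor
#'
#' The conventional binned IE count assigns every islet in a diameter bin
#' `[lo, hi)` the factor `(lo^3 + hi^3) / (2 * 150^3)` -- the mean of the
#' exact IE values at the two bin edges. Applied to 50-um bins from 50 to
#' 350 um this derives the conventional published factor table.
#'
#' @param lo,hi Bin edges (um), `0 <= lo <= hi`. Vectorized.
#' @return IE factor per bin.
#' @examples
#' endpoint_mean_factor(150, 200) # 1.68519
#' @export
endpoint_mean_factor <- function(lo, hi) {
  check_numeric(lo, "lo"); check_numeric(hi, "hi")
  if (any(lo < 0)) stop("bin edges must be nonnegative", call. = FALSE)
  if (any(lo > hi)) stop("bin lower edge exceeds upper edge", call. = FALSE)
  (lo^3 + hi^3) / (2 * IE_REFERENCE_DIAMETER^3)
}

#' Midpoint-cube bin factor
#'
#' Assigns the bin the exact IE of its midpoint diameter,
#' `((lo + hi)/2 / 150)^3`. Lies below the endpoint-mean factor on every
#' nondegenerate bin (convexity of the cube).
#'
#' @inheritParams endpoint_mean_factor
#' @return IE factor per bin.
#' @export
midpoint_cube_factor <- function(lo, hi) {
  check_numeric(lo, "lo"); check_numeric(hi, "hi")
  if (any(lo < 0)) stop("bin edges must be nonnegative", call. = FALSE)
  if (any(lo > hi)) stop("bin lower edge exceeds upper edge", call. = FALSE)
  ((lo + hi) / (2 * IE_REFERENCE_DIAMETER))^3
}

#' Density-expectation (refined) bin factor
#'
#' The refined binned estimator replaces the edge average by the expected
#' cubed diameter under a within-bin diameter density:
#' `E[d^3] / 150^3` with the density normalized over `[lo, hi]`. Because
#' `d^3` is strictly convex, the uniform-density factor is strictly below
#' the endpoint-mean factor on every nondegenerate bin -- the downward
#' correction of the refined method. Real preparations are small-islet
#' heavy, so a decreasing density corrects further downward.
#'
#' @param lo,hi Bin edges (um), `0 <= lo < hi` (or `lo == hi` with a point
#'   mass).
#' @param density Either a function giving an (unnormalized) diameter density
#'   on `[lo, hi]`, a single number giving a point-mass diameter, or
#'   `"uniform"` (default).
#' @return IE factor for the bin.
#' @examples
#' density_expectation_factor(150, 200)                    # uniform: 1.62037
#' density_expectation_factor(100, 200, density = 150)     # point mass: 1
#' density_expectation_factor(50, 100, density = function(x) exp(-x / 40))
#' @export
density_expectation_factor <- function(lo, hi, density = "uniform") {
  check_numeric(lo, "lo"); check_numeric(hi, "hi")
  stopifnot(length(lo) == 1, length(hi) == 1)
  if (lo < 0) stop("bin edges must be nonnegative", call. = FALSE)
  if (lo > hi) stop("bin lower edge exceeds upper edge", call. = FALSE)

  if (is.numeric(density)) { # point mass
    if (length(density) != 1 || density < lo || density > hi) {
      stop("point-mass diameter must be a single value inside the bin",
           call. = FALSE)
    }
    return(ie_exact(density))
  }
  if (identical(density, "uniform")) {
    if (hi == lo) return(ie_exact(lo))
    # E[d^3] for U(lo, hi) in closed form
    return((hi^4 - lo^4) / (4 * (hi - lo)) / IE_REFERENCE_DIAMETER^3)
  }
  if (!is.function(density)) {
    stop("`density` must be a function, a point-mass diameter, or \"uniform\"",
         call. = FALSE)
  }
  mass <- stats::integrate(density, lo, hi)$value
  if (!is.finite(mass) || mass <= 0) {
    stop("density has zero or non-finite mass on the bin", call. = FALSE)
  }
  num <- stats::integrate(function(x) x^3 * density(x), lo, hi)$value
  num / mass / IE_REFERENCE_DIAMETER^3
}

#' Construct a diameter binning scheme for binned IE estimation
#'
#' A binning scheme is an ordered set of half-open diameter bins
#' `[edge_i, edge_{i+1})` with one IE conversion factor per bin and a rule
#' recording how the factors were derived. Islets below
#' `min_diameter` are excluded from binned totals (and reported, never
#' silently dropped).
#'
#' @param edges Strictly increasing numeric vector of bin edges (um),
#'   length >= 2.
#' @param rule Factor-derivation rule: `"endpoint_mean"` (conventional),
#'   `"midpoint_cube"`, `"density_expectation"` (requires `density`), or
#'   `"explicit_table"` (requires `factors`, e.g. transcribed published
#'   factors).
#' @param factors Explicit per-bin factors for `rule = "explicit_table"`.
#' @param density Within-bin diameter density for
#'   `rule = "density_expectation"`; see [density_expectation_factor()].
#' @param min_diameter Minimum countable diameter (um); islets below it are
#'   excluded. Default 50 (conventional practice); set to 20 for workflows
#'   using the full cell-count model range.
#' @return An object of class `binning_scheme`.
#' @seealso [ricordi_scheme()], [ie_binned()]
#' @export
binning_scheme <- function(edges,
                           rule = c("endpoint_mean", "midpoint_cube",
                                    "density_expectation", "explicit_table"),
                           factors = NULL, density = "uniform",
                           min_diameter = 50) {
  rule <- match.arg(rule)
  check_numeric(edges, "edges")
  if (length(edges) < 2 || any(diff(edges) <= 0)) {
    stop("`edges` must be strictly increasing with at least two values",
         call. = FALSE)
  }
  if (any(edges < 0)) stop("bin edges must be nonnegative", call. = FALSE)
  n_bins <- length(edges) - 1L
  lo <- edges[-length(edges)]
  hi <- edges[-1]

  factors <- switch(rule,
    endpoint_mean = endpoint_mean_factor(lo, hi),
    midpoint_cube = midpoint_cube_factor(lo, hi),
    density_expectation = vapply(seq_len(n_bins), function(i) {
      density_expectation_factor(lo[i], hi[i], density = density)
    }, numeric(1)),
    explicit_table = {
      if (is.null(factors)) {
        stop("rule \"explicit_table\" requires `factors`", call. = FALSE)
      }
      check_numeric(factors, "factors")
      factors
    }
  )
  if (length(factors) != n_bins) {
    stop("need exactly one factor per bin (", n_bins, " bins)", call. = FALSE)
  }
  if (any(factors <= 0) || any(diff(factors) <= 0)) {
    stop("bin factors must be positive and strictly increasing",
         call. = FALSE)
  }
  structure(
    list(edges = as.numeric(edges), factors = as.numeric(factors),
         rule = rule, min_diameter = min_diameter),
    class = "binning_scheme"
  )
}

#' Conventional 50-um binning scheme
#'
#' The conventional estimator's bins: 50-um increments from `min_diameter`
#' up to `max_diameter`, with endpoint-mean factors. With the defaults the
#' derived factor sequence for bins 50-100, ..., 300-350 is
#' 0.167, 0.648, 1.685, 3.500, 6.315, 10.352.
#'
#' @param max_diameter Upper edge of the last bin (um), default 350.
#' @param min_diameter Lower edge of the first bin (um), default 50.
#' @return A `binning_scheme`.
#' @export
ricordi_scheme <- function(max_diameter = 350, min_diameter = 50) {
  binning_scheme(seq(min_diameter, max_diameter, by = 50),
                 rule = "endpoint_mean", min_diameter = min_diameter)
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat("Diameter binning scheme (", x$rule, ")\n", sep = "")
  cat("  minimum countable diameter:", x$min_diameter, "um\n")
  lab <- bin_labels(x)
  for (i in seq_along(x$factors)) {
    cat(sprintf("  %-10s IE factor %8.4f\n", lab[i], x$factors[i]))
  }
  invisible(x)
}

bin_labels <- function(scheme) {
  e <- scheme$edges
  sprintf("[%g,%g)", e[-length(e)], e[-1])
}

#' Binned islet-equivalent total for a preparation
#'
#' Tallies islets into the scheme's half-open diameter bins and multiplies
#' each bin count by its IE factor (the conventional procedure). Islets
#' below the scheme's minimum countable diameter are excluded and reported
#' in the result; diameters at or above the last edge either raise an error
#' (default) or, with `overflow = "extend"`, are counted in extrapolated
#' 50-um endpoint-mean bins.
#'
#' @param islets An [islet_records()] data frame or a numeric vector of
#'   diameters (um).
#' @param scheme A [binning_scheme()]; default [ricordi_scheme()].
#' @param overflow `"error"` (default) or `"extend"`.
#' @return An object of class `ie_result` with elements `total_ie`,
#'   `per_bin_counts` (named integer vector), `per_islet_ie` (NA for
#'   excluded islets), `excluded` (diameters below the minimum), and
#'   `method`.
#' @examples
#' ie_binned(c(60, 80, 90))       # 3 islets in [50,100): 3 * 0.16667 = 0.5
#' ie_binned(150)                 # falls in [150,200): 1.68519
#' @export
ie_binned <- function(islets, scheme = ricordi_scheme(),
                      overflow = c("error", "extend")) {
  overflow <- match.arg(overflow)
  if (!inherits(scheme, "binning_scheme")) {
    stop("`scheme` must be a binning_scheme", call. = FALSE)
  }
  d <- islet_diameters(islets)
  if (any(d <= 0)) stop("islet diameters must be positive", call. = FALSE)

  edges <- scheme$edges
  factors <- scheme$factors
  last <- edges[length(edges)]
  over <- d >= last
  if (any(over)) {
    if (overflow == "error") {
      stop("diameter(s) ", paste(format(d[over]), collapse = ", "),
           " at or above the last bin edge (", last,
           " um); use overflow = \"extend\" to add 50-um overflow bins",
           call. = FALSE)
    }
    n_extra <- max(1L, ceiling((max(d[over]) - last) / 50 + 1e-9))
    extra_edges <- last + 50 * seq_len(n_extra)
    extra_lo <- c(last, extra_edges[-n_extra])
    factors <- c(factors, endpoint_mean_factor(extra_lo, extra_edges))
    edges <- c(edges, extra_edges)
  }

  below <- d < scheme$min_diameter
  countable <- !below
  idx <- findInterval(d, edges, rightmost.closed = FALSE)
  idx[!countable] <- NA_integer_

  n_bins <- length(edges) - 1L
  counts <- tabulate(idx[countable], nbins = n_bins)
  names(counts) <- sprintf("[%g,%g)", edges[-length(edges)], edges[-1])
  per_islet <- ifelse(countable, factors[idx], NA_real_)

  structure(
    list(total_ie = sum(counts * factors),
         per_bin_counts = counts,
         per_islet_ie = per_islet,
         excluded = d[below],
         method = paste0("binned_", scheme$rule),
         scheme = scheme),
    class = "ie_result"
  )
}

#' @export
print.ie_result <- function(x, ...) {
  cat("IE estimate (", x$method, "): total ", format(x$total_ie), " IE\n",
      sep = "")
  occ <- x$per_bin_counts[x$per_bin_counts > 0]
  if (length(occ)) {
    cat("  islets per bin:",
        paste(names(occ), occ, sep = ": ", collapse = ", "), "\n")
  }
  if (length(x$excluded)) {
    cat("  excluded below minimum countable diameter:", length(x$excluded),
        "islet(s)\n")
  }
  invisible(x)
}

check_numeric <- function(x, name) {
  if (!is.numeric(x) || anyNA(x)) {
    stop("`", name, "` must be numeric with no missing values", call. = FALSE)
  }
  invisible(x)
}
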