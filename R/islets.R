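# Per-islet records. An irregular islet's diameter is the arithmetic mean of
# 2-4 measurements taken at different locations; the number of measurements
# is recorded, not enforced.

#' Construct a table of per-islet records
#'
#' @param diameters Either a numeric vector of single diameter measurements,
#'   or a matrix / data frame with one row per islet and one column per
#'   repeated diameter measurement (`NA` for absent measurements). Repeated
#'   measurements are averaged into the final diameter.
#' @param counted_cells Optional numeric vector of counted cell numbers
#'   (nonnegative), one per islet.
#' @param ids Optional character vector of islet identifiers; defaults to
#'   `"islet_1"`, `"islet_2"`, ...
#' @return A data frame of class `islet_records` with columns `islet_id`,
#'   `diameter` (um), `n_measurements`, and `counted_cells` (NA when not
#'   counted).
#' @examples
#' islet_records(c(60, 150, 300))
#' islet_records(rbind(c(140, 160), c(100, NA)))  # first islet averages to 150
#' @export
islet_records <- function(diameters, counted_cells = NULL, ids = NULL) {
  if (is.matrix(diameters) || is.data.frame(diameters)) {
    m <- as.matrix(diameters)
    storage.mode(m) <- "double"
    n_meas <- rowSums(!is.na(m))
    if (any(n_meas == 0)) {
      stop("islet(s) ", paste(which(n_meas == 0), collapse = ", "),
           " have no diameter measurements", call. = FALSE)
    }
    d <- rowMeans(m, na.rm = TRUE)
  } else {
    check_numeric(diameters, "diameters")
    d <- as.numeric(diameters)
    n_meas <- rep(1L, length(d))
  }
  if (any(d <= 0)) stop("islet diameters must be strictly positive",
                        call. = FALSE)
  n <- length(d)
  if (is.null(ids)) {
    ids <- if (n == 0) character(0) else paste0("islet_", seq_len(n))
  }
  if (length(ids) != n) stop("`ids` length must match islet count",
                             call. = FALSE)
  if (is.null(counted_cells)) {
    counted_cells <- rep(NA_real_, n)
  } else {
    if (length(counted_cells) != n) {
      stop("`counted_cells` length must match islet count", call. = FALSE)
    }
    if (any(counted_cells < 0, na.rm = TRUE)) {
      stop("counted cell numbers must be nonnegative", call. = FALSE)
    }
  }
  structure(
    data.frame(islet_id = as.character(ids), diameter = d,
               n_measurements = as.integer(n_meas),
               counted_cells = as.numeric(counted_cells),
               stringsAsFactors = FALSE),
    class = c("islet_records", "data.frame")
  )
}

# Accept islet_records, any data frame with a diameter column, or a bare
# numeric vector of diameters.
islet_diameters <- function(islets) {
  if (is.data.frame(islets)) {
    if (!"diameter" %in% names(islets)) {
      stop("islet table must have a `diameter` column", call. = FALSE)
    }
    d <- islets$diameter
  } else {
    d <- islets
  }
  check_numeric(d, "diameter")
  as.numeric(d)
}

islet_ids <- function(islets) {
  if (is.data.frame(islets) && "islet_id" %in% names(islets)) {
    as.character(islets$islet_id)
  } else {
    n <- length(islet_diameters(islets))
    if (n == 0) character(0) else paste0("islet_", seq_len(n))
  }
}
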