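# CSV/YAML readers and writers, the spreadsheet-equivalent conversion
# table, and run reports. CSV dialect throughout: comma separator, UTF-8,
# "." decimal, mandatory header.

#' Read an islet list CSV
#'
#' Expected columns: `islet_id`, `d1_um`, and optionally `d2_um`..`d4_um`
#' (blank when fewer measurements were taken). Non-blank repeated
#' measurements are averaged into the final diameter.
#'
#' @param path Path to the CSV file.
#' @return An [islet_records()] data frame. An empty file (header only)
#'   yields an empty record set with a warning.
#' @export
read_islet_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!"islet_id" %in% names(raw) || !"d1_um" %in% names(raw)) {
    stop("islet CSV must have columns `islet_id` and `d1_um`",
         call. = FALSE)
  }
  if (nrow(raw) == 0) {
    warning("islet CSV ", path, " has a header but no rows", call. = FALSE)
    return(islet_records(numeric(0), ids = character(0)))
  }
  dcols <- intersect(paste0("d", 1:4, "_um"), names(raw))
  m <- matrix(NA_real_, nrow(raw), length(dcols))
  for (j in seq_along(dcols)) {
    v <- raw[[dcols[j]]]
    blank <- is.na(v) | v == ""
    num <- suppressWarnings(as.numeric(v))
    bad <- !blank & is.na(num)
    if (any(bad)) {
      stop("non-numeric diameter in column ", dcols[j], ", data row(s) ",
           paste(which(bad), collapse = ", "), " of ", path, call. = FALSE)
    }
    m[, j] <- ifelse(blank, NA_real_, num)
  }
  islet_records(m, ids = raw$islet_id)
}

#' Write an islet record table as CSV
#'
#' Writes one single-diameter measurement per islet in the dialect
#' [read_islet_csv()] reads.
#'
#' @param islets An [islet_records()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_islet_csv <- function(islets, path) {
  d <- islet_diameters(islets)
  out <- data.frame(islet_id = islet_ids(islets),
                    d1_um = num_chr(d), d2_um = "", d3_um = "", d4_um = "")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Full-precision numeric formatting so CSV round trips are bit exact.
num_chr <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
}

#' Diameter-to-cell-number conversion table
#'
#' The spreadsheet-equivalent lookup: for every diameter on a regular grid,
#' the predicted cell number, exact-sphere IE, and cells per IE. With the
#' defaults (20-350 um at 1-um steps) the table has 331 rows.
#'
#' @param model A [cell_count_model()]; default [kansas_rat_model()].
#' @param d_min,d_max Grid limits (um), within the model's validity range.
#' @param step Grid step (um), `> 0`.
#' @return A data frame with columns `diameter_um`, `cells`, `ie_exact`,
#'   `cells_per_ie`.
#' @export
conversion_table <- function(model = kansas_rat_model(), d_min = 20,
                             d_max = 350, step = 1) {
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  if (d_min > d_max) stop("`d_min` must not exceed `d_max`", call. = FALSE)
  check_model_range(model, c(d_min, d_max))
  d <- seq(d_min, d_max, by = step)
  cells <- suppressWarnings(predict_cells(model, d))
  data.frame(diameter_um = d, cells = cells, ie_exact = ie_exact(d),
             cells_per_ie = cells / ie_exact(d))
}

#' Write a numeric table as full-precision CSV
#'
#' Numeric columns are written with 17 significant digits so that reading
#' the file back reproduces the doubles bit-exactly.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  out <- x
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- num_chr(out[[j]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / read a cell-count model as YAML
#'
#' @param model A [cell_count_model()].
#' @param path YAML path.
#' @return `write_cell_model_yaml` returns `path` invisibly;
#'   `read_cell_model_yaml` returns the model. The built-in model name
#'   `"kansas-rat-2012"` may be given in place of a path anywhere a model
#'   file is accepted.
#' @export
write_cell_model_yaml <- function(model, path) {
  stopifnot(inherits(model, "cell_count_model"))
  yaml::write_yaml(list(
    label = model$label,
    coefficients = model$coefficients,
    valid_range = model$valid_range,
    reference_cells_per_ie = model$reference_cells_per_ie
  ), path, precision = 17)
  invisible(path)
}

#' @rdname write_cell_model_yaml
#' @export
read_cell_model_yaml <- function(path) {
  if (identical(path, "kansas-rat-2012")) return(kansas_rat_model())
  x <- yaml::read_yaml(path)
  cell_count_model(as.numeric(x$coefficients),
                   valid_range = as.numeric(x$valid_range),
                   reference_cells_per_ie =
                     as.numeric(x$reference_cells_per_ie),
                   label = x$label)
}

#' Serialize / read a binning scheme as YAML
#'
#' @param scheme A [binning_scheme()].
#' @param path YAML path.
#' @return `write_binning_scheme_yaml` returns `path` invisibly;
#'   `read_binning_scheme_yaml` returns the scheme (explicit factors are
#'   written so derived tables survive the round trip unchanged).
#' @export
write_binning_scheme_yaml <- function(scheme, path) {
  stopifnot(inherits(scheme, "binning_scheme"))
  yaml::write_yaml(list(
    edges = scheme$edges, rule = scheme$rule, factors = scheme$factors,
    min_diameter = scheme$min_diameter
  ), path, precision = 17)
  invisible(path)
}

#' @rdname write_binning_scheme_yaml
#' @export
read_binning_scheme_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  binning_scheme(as.numeric(x$edges), rule = "explicit_table",
                 factors = as.numeric(x$factors),
                 min_diameter = as.numeric(x$min_diameter))
}

#' Read an assay CSV into assay groups
#'
#' Expected columns: `experiment_id`, `group`, `readout_total`, `diameters`
#' (semicolon-separated per-islet diameters in um), and optionally
#' `dna_total`.
#'
#' @param path CSV path.
#' @return A named list of [assay_group()] objects, one per distinct
#'   `group` value.
#' @export
read_assay_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("experiment_id", "group", "readout_total", "diameters")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("assay CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dia <- lapply(strsplit(as.character(raw$diameters), ";", fixed = TRUE),
                as.numeric)
  groups <- unique(raw$group)
  setNames(lapply(groups, function(g) {
    sel <- raw$group == g
    assay_group(g, raw$readout_total[sel], dia[sel],
                dna_totals = if ("dna_total" %in% names(raw))
                  raw$dna_total[sel] else NULL)
  }), groups)
}

#' Write assay groups as CSV
#'
#' @param groups A list of [assay_group()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assay_csv <- function(groups, path) {
  rows <- do.call(rbind, lapply(groups, function(g) {
    data.frame(
      experiment_id = paste0(g$label, "_", seq_along(g$readouts)),
      group = g$label,
      readout_total = num_chr(g$readouts),
      diameters = vapply(g$diameters, function(dd)
        paste(num_chr(dd), collapse = ";"), character(1)),
      dna_total = if (is.null(g$dna_totals)) "" else num_chr(g$dna_totals),
      stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a preparation: per-islet and total quantities
#'
#' The batch form of the conversion workflow: per islet, the predicted cell
#' number, exact IE, and cells/IE; plus totals under the exact and binned
#' IE estimators and the model. Islets below the scheme's minimum countable
#' diameter are excluded from the binned total and listed in the result.
#'
#' @param islets [islet_records()] or numeric diameters (um).
#' @param model A [cell_count_model()].
#' @param scheme A [binning_scheme()] for the binned total.
#' @param overflow Overflow policy passed to [ie_binned()].
#' @return An object of class `conversion_report`: `per_islet` data frame,
#'   `totals` list, `excluded`, `model_label`.
#' @export
convert_islets <- function(islets, model = kansas_rat_model(),
                           scheme = ricordi_scheme(),
                           overflow = c("error", "extend")) {
  d <- islet_diameters(islets)
  cells <- suppressWarnings(predict_cells(model, d))
  binned <- ie_binned(d, scheme, overflow = match.arg(overflow))
  per_islet <- data.frame(
    islet_id = islet_ids(islets), diameter_um = d, cells = cells,
    ie_exact = ie_exact(d), ie_binned = binned$per_islet_ie,
    cells_per_ie = cells / ie_exact(d),
    stringsAsFactors = FALSE)
  structure(
    list(per_islet = per_islet,
         totals = list(n_islets = length(d),
                       total_cells = sum(cells),
                       total_ie_exact = sum(ie_exact(d)),
                       total_ie_binned = binned$total_ie),
         excluded = binned$excluded,
         model_label = model$label),
    class = "conversion_report"
  )
}

#' @export
print.conversion_report <- function(x, ...) {
  t <- x$totals
  cat("Conversion report (model ", x$model_label, "): ", t$n_islets,
      " islets\n", sep = "")
  cat(sprintf("  total cells: %.1f  IE (exact): %.4f  IE (binned): %.4f\n",
              t$total_cells, t$total_ie_exact, t$total_ie_binned))
  if (length(x$excluded)) {
    cat("  excluded from binned total (below minimum countable diameter):",
        length(x$excluded), "islet(s)\n")
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' Writes the per-islet table as full-precision CSV and the totals,
#' parameters, and exclusions as JSON. Rerunning with identical inputs
#' reproduces the files byte-identically (no timestamps in the payload).
#'
#' @param report A `conversion_report` (from [convert_islets()]) or a
#'   `group_comparison` (from [compare_groups()]).
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix, default `"isletquant"`.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, dir, prefix = "isletquant") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir,
                             call. = FALSE)
  files <- character(0)
  if (inherits(report, "conversion_report")) {
    csv <- file.path(dir, paste0(prefix, "_per_islet.csv"))
    write_table_csv(report$per_islet, csv)
    js <- file.path(dir, paste0(prefix, "_totals.json"))
    jsonlite::write_json(
      list(model = report$model_label, totals = report$totals,
           excluded_diameters = report$excluded),
      js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(csv, js)
  } else if (inherits(report, "group_comparison")) {
    js <- file.path(dir, paste0(prefix, "_comparison.json"))
    jsonlite::write_json(unclass(report), js, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <- js
  } else {
    stop("unsupported report type", call. = FALSE)
  }
  invisible(files)
}
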