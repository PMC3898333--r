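# Normalizing assay readouts (DNA, total protein, proinsulin, densitometry)
# per IE, per cell, or per DNA, and comparing islet size groups. The choice
# of denominator is the whole point: per-IE normalization inflates the
# denominator of large islets, so identical per-cell content shows up as
# "small > large".

#' Construct an assay group
#'
#' A set of replicate experiments on islets of one size class. Each
#' replicate has a total assay readout and the diameters of the islets that
#' produced it.
#'
#' @param label Group label, e.g. `"small"` or `"large"`.
#' @param readouts Numeric vector of per-replicate total readouts
#'   (pg DNA, ug protein, densitometry units, ...), nonnegative.
#' @param diameters List of numeric vectors, one per replicate: the
#'   diameters (um) of the islets in that replicate.
#' @param dna_totals Optional per-replicate total DNA (pg), required for
#'   per-DNA normalization.
#' @param size_range Optional length-2 interval; when given, every diameter
#'   must lie inside it (use `c(0, 100)` / `c(200, Inf)` for the
#'   conventional small / large classes).
#' @return An object of class `assay_group`.
#' @export
assay_group <- function(label, readouts, diameters, dna_totals = NULL,
                        size_range = NULL) {
  check_numeric(readouts, "readouts")
  if (any(readouts < 0)) stop("readouts must be nonnegative", call. = FALSE)
  if (!is.list(diameters) || length(diameters) != length(readouts)) {
    stop("`diameters` must be a list with one vector per replicate",
         call. = FALSE)
  }
  for (dd in diameters) {
    check_numeric(dd, "diameters")
    if (any(dd <= 0)) stop("diameters must be strictly positive",
                           call. = FALSE)
    if (!is.null(size_range) && (any(dd < size_range[1]) ||
                                 any(dd > size_range[2]))) {
      stop("group \"", label, "\" contains diameters outside its size ",
           "class [", size_range[1], ", ", size_range[2], "] um",
           call. = FALSE)
    }
  }
  if (!is.null(dna_totals)) {
    check_numeric(dna_totals, "dna_totals")
    if (length(dna_totals) != length(readouts)) {
      stop("`dna_totals` must have one value per replicate", call. = FALSE)
    }
  }
  structure(
    list(label = label, readouts = as.numeric(readouts),
         diameters = lapply(diameters, as.numeric),
         dna_totals = if (is.null(dna_totals)) NULL else
           as.numeric(dna_totals)),
    class = "assay_group"
  )
}

#' @export
print.assay_group <- function(x, ...) {
  cat("Assay group \"", x$label, "\": ", length(x$readouts),
      " replicate(s), ", sum(lengths(x$diameters)), " islets\n", sep = "")
  invisible(x)
}

group_denominators <- function(group, basis, model, estimator, scheme) {
  switch(basis,
    ie = vapply(group$diameters, function(dd) {
      if (estimator == "exact") sum(ie_exact(dd))
      else ie_binned(dd, scheme)$total_ie
    }, numeric(1)),
    cell = vapply(group$diameters, function(dd) {
      total_cells(model, dd)
    }, numeric(1)),
    dna = {
      if (is.null(group$dna_totals)) {
        stop("per-DNA normalization requires `dna_totals` in the group",
             call. = FALSE)
      }
      group$dna_totals
    }
  )
}

#' Normalize an assay group's readouts
#'
#' Divides each replicate's total readout by a per-replicate denominator:
#' total IE (binned or exact-sphere), total model-predicted cells, or
#' measured total DNA.
#'
#' @param group An [assay_group()].
#' @param basis `"ie"`, `"cell"`, or `"dna"`.
#' @param model [cell_count_model()] used for `basis = "cell"`.
#' @param estimator IE estimator for `basis = "ie"`: `"binned"` (the
#'   conventional tally a wet lab records; default) or `"exact"`.
#' @param scheme [binning_scheme()] for the binned estimator.
#' @return An object of class `normalized_readout`: per-replicate `values`,
#'   their `mean`, `sem` (across replicates, matching how assay tables
#'   report n = experiments), `n`, `basis`, `label`.
#' @export
normalize_group <- function(group, basis = c("ie", "cell", "dna"),
                            model = kansas_rat_model(),
                            estimator = c("binned", "exact"),
                            scheme = ricordi_scheme()) {
  basis <- match.arg(basis)
  estimator <- match.arg(estimator)
  stopifnot(inherits(group, "assay_group"))
  den <- group_denominators(group, basis, model, estimator, scheme)
  if (any(den <= 0)) {
    stop("zero denominator in group \"", group$label, "\" under basis \"",
         basis, "\"", call. = FALSE)
  }
  v <- group$readouts / den
  n <- length(v)
  structure(
    list(values = v, mean = mean(v),
         sem = if (n > 1) sd(v) / sqrt(n) else NA_real_,
         n = n, basis = basis, label = group$label),
    class = "normalized_readout"
  )
}

#' @export
print.normalized_readout <- function(x, ...) {
  cat(sprintf("%s: %.4g +/- %.4g per %s (n = %d replicates)\n",
              x$label, x$mean, x$sem, x$basis, x$n))
  invisible(x)
}

#' Compare two islet size groups under a normalization basis
#'
#' Normalizes both groups and compares the per-replicate normalized values
#' with a two-sample Student's t test (pooled variance by default; Welch
#' behind a flag).
#'
#' @param A,B [assay_group()] objects with >= 2 replicates each.
#' @inheritParams normalize_group
#' @param welch Use the Welch (unequal-variance) form instead of the pooled
#'   Student's t test. Default `FALSE`.
#' @return An object of class `group_comparison` with the group means and
#'   SEMs, `t`, `df`, `p`, and the normalization `basis`.
#' @export
compare_groups <- function(A, B, basis = c("ie", "cell", "dna"),
                           model = kansas_rat_model(),
                           estimator = c("binned", "exact"),
                           scheme = ricordi_scheme(), welch = FALSE) {
  basis <- match.arg(basis)
  estimator <- match.arg(estimator)
  na <- length(A$readouts); nb <- length(B$readouts)
  if (na < 2 || nb < 2) {
    stop("need at least two replicates per group for a t test",
         call. = FALSE)
  }
  a <- normalize_group(A, basis, model, estimator, scheme)
  b <- normalize_group(B, basis, model, estimator, scheme)
  tt <- stats::t.test(a$values, b$values, var.equal = !welch)
  structure(
    list(label_A = A$label, mean_A = a$mean, sem_A = a$sem, n_A = a$n,
         label_B = B$label, mean_B = b$mean, sem_B = b$sem, n_B = b$n,
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, basis = basis,
         test = if (welch) "welch" else "student"),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Per-%s comparison (%s t test)\n", x$basis, x$test))
  cat(sprintf("  %s: %.4g +/- %.4g (n = %d)\n", x$label_A, x$mean_A, x$sem_A,
              x$n_A))
  cat(sprintf("  %s: %.4g +/- %.4g (n = %d)\n", x$label_B, x$mean_B, x$sem_B,
              x$n_B))
  cat(sprintf("  t = %.3f, df = %.3g, p = %.4g\n", x$t, x$df, x$p))
  invisible(x)
}

#' Islet material needed for a fixed protein load
#'
#' Converts a per-unit protein content into the amount of islet material
#' (IE or cells) needed to load a fixed protein mass -- the arithmetic
#' behind "IE per 10 ug protein" comparisons. Because large islets carry
#' less protein per IE, markedly more IE of large islets is needed for the
#' same load, while the cell-based requirement is similar across sizes.
#'
#' @param target_ug Protein mass to obtain (ug), `>= 0`.
#' @param protein_per_unit Protein content per unit of material: ug/IE for
#'   `basis = "ie"`, ng/cell for `basis = "cell"`. Must be positive.
#' @param basis `"ie"` or `"cell"`.
#' @return IE or cells needed (0 when `target_ug` is 0).
#' @examples
#' material_for_protein(10, 0.80, "ie")    # 12.5 IE
#' material_for_protein(10, 0.58, "cell")  # 17241 cells
#' @export
material_for_protein <- function(target_ug, protein_per_unit,
                                 basis = c("ie", "cell")) {
  basis <- match.arg(basis)
  check_numeric(target_ug, "target_ug")
  check_numeric(protein_per_unit, "protein_per_unit")
  if (any(target_ug < 0)) stop("`target_ug` must be nonnegative",
                               call. = FALSE)
  if (any(protein_per_unit <= 0)) {
    stop("protein content per unit must be positive", call. = FALSE)
  }
  if (basis == "ie") target_ug / protein_per_unit
  else target_ug * 1000 / protein_per_unit # ug -> ng
}
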