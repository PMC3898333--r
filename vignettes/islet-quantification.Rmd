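---
title: "Quantifying islet tissue: IE estimators, cell-number conversion, and normalization bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying islet tissue: IE estimators, cell-number conversion, and normalization bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletquant)
```

## The measurement problem

Isolated islets of Langerhans range from about 20 to over 400 μm in
diameter. Transplant dosing and laboratory normalization both need a
single number for "how much islet tissue is here", and the standard
answer is the islet equivalent: 1 IE is the volume of a 150-μm sphere,
$(\pi/6)\,150^3 \approx 1.77\times10^6\ \mu m^3$. In the conventional
procedure an operator measures each islet's diameter under a microscope,
tallies islets into 50-μm diameter categories, and multiplies each
category count by a fixed conversion factor.

Two assumptions are baked in. First, sphericity: isolated islets are
typically oblate (mean axis ratios around $b/a = 0.82$ and $c/a = 0.6$),
so a single measured axis inflates the inferred volume. Second,
homogeneity: the tally assumes tissue content scales with nominal sphere
volume, but larger islets contain proportionally more vascular and
intercellular space. Both errors grow with diameter, and both push in
the same direction — the IE overstates the tissue in large islets.

`isletquant` implements three IE estimators and, as the replacement, a
direct conversion from measured diameter to cell number, together with
the calibration, reliability, and normalization machinery needed to
quantify the bias.

## IE estimators

For a diameter $d$ (μm) the exact per-islet conversion is
$\mathrm{IE}(d) = (d/150)^3$. The conventional binned estimator assigns
every islet in the half-open bin $[l, h)$ the endpoint-mean factor

$$f_{\text{conv}}(l,h) = \frac{l^3 + h^3}{2\cdot150^3},$$

which on the six 50-μm bins from 50 to 350 μm derives the conventional
factor sequence 0.167, 0.648, 1.685, 3.500, 6.315, 10.352. Because
$d^3$ is strictly convex, the endpoint mean is an upper bound on the
within-bin average of the exact IE for *any* symmetric spread of
diameters — by the Hermite–Hadamard inequality, uniformly distributed
diameters satisfy

$$\frac{1}{h-l}\int_l^h \Big(\frac{x}{150}\Big)^3 dx
  = \frac{h^4-l^4}{4(h-l)\,150^3} \le f_{\text{conv}}(l,h),$$

strictly so on nondegenerate bins. The refined estimator replaces the
endpoint mean by $E[d^3]/150^3$ under a within-bin diameter density
(`density_expectation_factor`): the uniform density gives the closed
form above, a decreasing density (realistic, since preparations are
small-islet heavy) corrects further downward, and an
`explicit_table` rule accepts transcribed published factors unchanged.

Design choices where the conventional procedure is silent:

* **Bin membership is half-open** $[l, h)$, so a 100-μm islet falls in
  the 100–150 bin. This avoids double counting and matches how the
  category labels are conventionally read.
* **Minimum countable diameter** defaults to 50 μm (conventional
  practice); islets below it are *reported as excluded*, never silently
  dropped. It is configurable down to 20 μm for cell-number workflows.
* **Overflow** above the last bin edge is a hard error by default; with
  `overflow = "extend"` extrapolated 50-μm endpoint-mean bins are
  appended. No published guidance exists for islets above 350 μm, so
  the conservative default is to refuse.

## The diameter-to-cell-number model

The built-in rat model (`kansas_rat_model()`) converts measured diameter
directly to cell number with a cubic fitted to counts of enzymatically
dissociated islets:

$$\hat{y}(d) = -0.0001\,d^3 + 0.0912\,d^2 - 6.2162\,d + 182.1125,
  \qquad 20 \le d \le 350\ \mu m,$$

with 943 cells in a reference one-IE (150 μm) islet. Coefficients are
stored at full published precision and never re-rounded.

Numerical and policy choices:

* **Out-of-range prediction is a hard error**, not extrapolation: a
  fitted cubic turns negative below ~14 μm and its advertised range is
  20–350 μm. Silent extrapolation of a fitted polynomial is the classic
  failure mode, so callers see the admissible interval in the error.
* **The non-monotone dip** of the published cubic (local minimum near
  36 μm, ~72 cells) is retained as-is; a warning is emitted for
  predictions below 40 μm.
* **Positivity**: `cell_count_model()` checks that predictions are
  strictly positive on a 512-point grid over the validity range and
  errors otherwise. For models produced by `fit_cell_model()` this check
  is a warning instead — unconstrained least squares on noisy counts can
  dip marginally below zero at a range edge, and a warning plus the
  diagnostic is more useful than refusing the fit.
* `cells_per_ie(d) = \hat{y}(d)\,/\,(d/150)^3` declines monotonically
  over 50–350 μm; `overestimation_ratio()` (IE-implied over predicted
  cells) crosses 1 just above 150 μm and grows steeply beyond — these
  are the quantitative statements of the IE's large-islet bias, and the
  test suite checks both on a 5-μm grid.

## Calibration and reliability

`fit_cell_model()` is ordinary (or weighted) least squares on a raw
polynomial basis, degree 3 by default, returning coefficients, $R^2 =
1 - SSE/SST$, the residual SD, and the coefficient covariance for
prediction standard errors. The fitted model's validity range is the
observed diameter range — a fitted curve earns no trust outside its
data.

Group comparisons (`ancova_compare()`) use the extra-sum-of-squares $F$
test of one pooled curve against fully separate per-group curves (all
polynomial coefficients free per group, not slope-only, because whole
calibration curves are being compared). The default truncation at
250 μm reflects that young animals lack larger islets, so only the
shared range is comparable. The $F$ test assumes homoscedastic errors;
count noise in real calibration data grows with diameter, which makes
the test anticonservative when applied across the full size range. The
type-I-error simulation in the test suite therefore uses constant-SD
noise (the regime where the test is exact), and users comparing groups
over wide size ranges should prefer variance-stabilized or weighted
fits.

Reliability statistics are the field's standard ones: Pearson's $r$
between counting methods, and CV% ($100\cdot$ sample SD/mean, $n-1$
denominator throughout).

## Normalization and the direction of bias

`normalize_group()` divides each replicate's total readout by total IE
(binned by default — that is what a wet lab records — or exact-sphere),
total model-predicted cells, or measured total DNA. SEMs are computed
across replicate experiments, not across islets, matching how assay
tables report "n experiments". Comparisons use the pooled-variance
Student's t test (Welch behind a flag), and no multiple-testing
correction is applied: comparisons are reported as single pairwise
tests, as they would be in the assay tables they emulate.

The bias mechanism is arithmetic, not statistical: if readout is
proportional to true cell number and cells/IE declines with diameter,
then per-IE values for a small-islet group exceed those of a large-islet
group in every noise-free replicate — the package tests this as a
deterministic inequality — while per-cell values are identical by
construction. With realistic noise the per-IE comparison rejects
"no difference" essentially always at assay-scale replicate counts
(20 per group), while the per-cell comparison rejects at the nominal 5%
rate. When the simulator injects a per-cell content that *rises* with
diameter (the proinsulin scenario, `size_effect > 0`), the two bases
give opposite significant conclusions — the strongest argument that the
normalization basis is not a matter of taste.

`material_for_protein()` is the practical corollary: converting per-IE
and per-cell protein contents into the islet material needed for a fixed
protein load (e.g. a 10-μg Western blot lane) shows that nearly twice
the IE of large islets is needed for the same load, while the cell-based
requirement is nearly size-independent.

## What the simulator emulates — and what it does not

`simulate_prep()` draws diameters from either a truncated lognormal
(default median 90 μm, $\sigma_{\log} = 0.45$, support 50–350 μm — a
realistic small-islet-heavy preparation; this distribution is a package
choice, not a measured one) or an exact per-category allocation. True
cell counts are the model prediction plus normal noise whose SD is
reconstructed per category as $SEM_i\sqrt{n_i}$ from the reference
summaries (12 categories, 50–325 μm, 343 islets) and linearly
interpolated between category diameters; counts are truncated at a
minimum of one cell. Between categories the model curve, not
nearest-category means, supplies the center: the published model is the
continuous object.

`simulate_reference_calibration()` is deliberately different: it centers
each category's draws on the *published category means*, not the model
curve, because it reconstructs the data the model was fitted to. The two
generators answer different questions — parameter recovery from the
model's own data-generating process versus reproduction of the published
goodness of fit ($R^2$ near 0.8) — and conflating them would make the
category-mean check fail precisely where the published means deviate
from the fitted cubic (most visibly at 100 and 275 μm).

Per-cell analyte contents default to 6.05 pg DNA and 0.58 ng protein,
with SDs acting as between-experiment variation; `size_effect` adds a
relative content slope per 100 μm above 150 μm for the
opposite-conclusions scenario. Replicate structure defaults to 20
experiments per size group with 50 small or 20 large islets each.

Not modeled: animal-level clustering (assay replicates are treated as
independent, as in the analyses being emulated), dissociation cell loss,
islet purity, shape variation's effect on measured diameter (axis ratios
are recorded but diameters are taken as measured), and any mechanistic
dead-space model — the declining cells/IE curve is inherited from the
empirical cubic, not derived from vascular volume. Passing simulation
tests therefore show that the estimators and comparisons behave
correctly *given* the published calibration structure; they cannot
validate that structure against new preparations.

## Problem sizes and numerical notes

The test suite and acceptance script use: 343-islet calibration
replicates (the reference allocation); 50–60 seeded replicates for
median-$R^2$ and parameter-recovery checks; 150 replicates of the
normalization-bias simulation; 500 replicates for the ANCOVA size check
and 200 for power; and $10^5$ uniform draws per bin for the Monte-Carlo
Hermite–Hadamard confirmation. These sizes give stable medians and
binomial bands at interactive runtimes.

Parameter recovery is judged against the generating curve at the 12
category diameters with a pooled standard error,
$\sqrt{SE_{\text{fit}}^2 + SEM_i^2}$, combining the fitted prediction's
uncertainty with the category sampling uncertainty; the noiseless-data
check demands coefficient recovery to $10^{-8}$, which raw-basis QR
least squares achieves comfortably at these problem sizes. The
independent test oracle solves the normal equations on a rescaled
diameter axis ($d/300$) because the raw cross-product matrix is
ill-conditioned beyond `solve()`'s default tolerance.

CSV writers emit doubles with 17 significant digits so conversion tables
and simulated preparations round-trip bit-exactly; YAML model and
scheme files keep full precision the same way. All randomness flows
through explicit seeds; identical configuration and seed give identical
output, byte for byte.

## Known limitations

* The built-in model is for rat islets; human islets need their own
  calibration, and none is bundled.
* The refined binned estimator's published factor tables are not
  included; users with access to them should load them via the
  `explicit_table` rule. The `density_expectation` rule reproduces the
  construction, not the transcription.
* Exact reproduction of published assay-table means is not possible from
  summaries alone; the package reproduces their direction and derived
  ratios, and the simulator is tuned to the published per-cell contents,
  not to the table means.
* The ANCOVA is an unweighted homoscedastic $F$ test; see above for when
  that assumption bites.
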