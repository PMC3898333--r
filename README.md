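# isletquant

Quantification of isolated pancreatic islet tissue by cell number and by
islet equivalents (IE), for islet transplantation and islet research
laboratories.

The islet equivalent — the volume of a perfectly spherical islet of 150 μm
diameter, 1 IE = (π/6)·150³ ≈ 1.77 × 10⁶ μm³ — is the standard dosing and
normalization unit for isolated islets. It rests on two fragile
assumptions: that islets are spheres, and that tissue content scales with
nominal sphere volume. Neither holds: isolated islets are oblate
(typical axis ratios b/a ≈ 0.82, c/a ≈ 0.6), and the cell number per IE
*declines* with islet diameter, so IE-based normalization systematically
overestimates the tissue in large islets. `isletquant` implements the
IE estimators, a direct diameter→cell-number conversion that avoids the
sphere assumption, and the machinery to quantify the resulting
normalization bias.

## What is implemented

**IE estimators** (`sphere_volume`, `ie_exact`, `ie_binned`)

* exact sphere: IE(d) = (d/150)³ per islet;
* conventional binned tally: islets are counted into 50-μm diameter bins
  and each bin count is multiplied by the endpoint-mean factor
  (lo³ + hi³)/(2·150³) — the derived factor sequence for the 50–350 μm bins
  is 0.167, 0.648, 1.685, 3.500, 6.315, 10.352;
* refined binning: per-bin factors E[d³]/150³ under a within-bin diameter
  density (`density_expectation_factor`), or an explicit transcribed
  factor table.

**Cell-number conversion** (`kansas_rat_model`, `predict_cells`)

The built-in rat model is the cubic regression of counted cells per
dissociated islet on measured diameter,

    cells(d) = −0.0001 d³ + 0.0912 d² − 6.2162 d + 182.1125,   20 ≤ d ≤ 350 μm,

with 943 cells in a reference one-IE (150 μm) islet. `cells_per_ie()` and
`overestimation_ratio()` give the comparison curves: cells/IE falls from
~2,344 at 50 μm to ~478 at 300 μm, so the exact-sphere IE overestimates a
300-μm islet's tissue roughly two-fold.

**Calibration** (`fit_cell_model`, `ancova_compare`, `pearson_r`,
`cv_percent`): polynomial least squares with R², extra-sum-of-squares
ANCOVA for comparing calibration curves across animal groups, and the
reliability statistics.

**Normalization** (`assay_group`, `normalize_group`, `compare_groups`,
`material_for_protein`): assay readouts (DNA, protein, proinsulin,
densitometry) per IE, per cell, or per DNA, with pooled-variance t
comparisons between small (≤ 100 μm) and large (≥ 200 μm) islet groups.

**Simulation** (`simulate_prep`, `simulate_reference_calibration`,
`simulate_counting_experiment`, `simulate_assay_groups`): seeded
generators that reproduce the calibration study's per-category variability
(12 diameter categories, 343 islets, SD reconstructed as SEM·√n), paired
counting experiments, and small/large assay replicates.

## Worked example

```r
library(isletquant)

islets <- read_islet_csv(system.file("extdata", "example_islets.csv",
                                     package = "isletquant"))
convert_islets(islets)
#> Conversion report (model kansas-rat-2012): 14 islets
#>   total cells: 21825.1  IE (exact): 36.7471  IE (binned): 41.5185
```

The binned (conventional) IE total exceeds the exact-sphere total by 13%
for this 14-islet preparation, and both overstate tissue relative to the
cell count. The conversion table shows why:

```r
tab <- conversion_table()          # 20-350 um at 1-um steps, 331 rows
tab[tab$diameter_um %in% c(50, 150, 300), ]
#>  diameter_um     cells   ie_exact cells_per_ie
#>           50   86.8025 0.03703704    2343.6675
#>          150  964.1825 1.00000000     964.1825
#>          300 3825.2525 8.00000000     478.1566
```

A 300-μm islet counts as 8 IE but contains only ~3,825 cells — 478
cells/IE against 964 at the reference size. Normalizing an assay by IE
therefore deflates large-islet values:

```r
g <- simulate_assay_groups(prep_config(seed = 42), analyte = "dna_pg")
compare_groups(g$small, g$large, basis = "ie")
#> Per-ie comparison (student t test)
#>   small: 7220 +/- 233.5 (n = 20)
#>   large: 3952 +/- 107.7 (n = 20)
#>   t = 12.708, df = 38, p = 2.952e-15
compare_groups(g$small, g$large, basis = "cell")
#> Per-cell comparison (student t test)
#>   small: 5.981 +/- 0.1824 (n = 20)
#>   large: 6.043 +/- 0.1628 (n = 20)
#>   t = -0.254, df = 38, p = 0.8012
```

Both groups were simulated with identical DNA content per cell
(6.05 pg). Per-IE normalization manufactures a highly significant
small-vs-large difference; per-cell normalization correctly recovers
6.05 pg/cell in both groups with no difference.

A command-line interface wrapping these functions is installed at
`inst/exec/isletquant.R` with subcommands `convert`, `table`, `fit`,
`compare`, and `simulate`.

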