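# ramandip

Quantifying the drought tolerance of a soil microbiome from single-cell
Raman spectra after heavy-water (D2O) isotope probing.

## The problem and who this is for

Culture-based assays cannot tell you what fraction of a diverse soil
community keeps metabolizing under drought. Raman-DIP can: cells incubated
with D2O under osmotic stress (PEG) incorporate deuterium only if they stay
metabolically active, which produces a broad carbon-deuterium (C-D) band at
2040-2300 cm^-1 in each cell's Raman spectrum. This package is for
microbial ecologists and spectroscopists who want that analysis as tested,
reusable code: spectral preprocessing, the per-cell deuterium statistic,
drought-tolerant cell counting against reference strains, phenotype
discrimination, and cross-validation of the cell counts against plant
outcomes and gene abundances. Because raw single-cell spectra from such
campaigns are rarely deposited, a seeded synthetic-spectrum generator with
the right statistical structure is part of the package, so every stage is
testable end to end.

## The statistic at the core

For each cell, band areas are integrated over the C-D (2040-2300 cm^-1),
C-H (2800-3100 cm^-1) and biologically silent (2400-2700 cm^-1) windows,
backgrounds are estimated from the silence window (rescaled by band-width
ratio) and subtracted with clamping at zero, and the C-D ratio is

    r = cd / (cd + ch),   cd = max(A_CD - b_CD, 0),  ch = max(A_CH - b_CH, 0)

so r is in [0, 1] and indexes deuterium incorporation, i.e. metabolic
activity. A cell counts as drought-tolerant when, under PEG incubation, its
r strictly exceeds the mean ratio of drought-tolerant reference strains
(DTB) under the same condition. Sample-level percentages of tolerant cells
are then cross-validated with tie-aware Spearman rank correlation against
per-sample outcomes (revived plants, gene-product abundances) and abundance
profiles are compared by Bray-Curtis hierarchical clustering. Phenotype
shifts under stress are discriminated by DAPC (linear discriminant analysis
on retained principal-component scores of the 400-1800 cm^-1 fingerprint)
with control-centroid-to-treated-cell distance summaries and a
normality-gated per-wavenumber t/Wilcoxon screen.

## Worked example

The bundled demo simulates two reference strains (drought-tolerant and
drought-sensitive) under control and PEG conditions, plus five synthetic
soil samples with true active fractions 0.50, 0.22, 0.22, 0.12 and 0.00,
then runs the full pipeline:

```r
library(ramandip)
report <- run_demo(seed = 1)
print(report)
#> == Raman-DIP drought-tolerance report ==
#> seed 1, version 0.1.0
#> thresholds: control 0.0793, PEG 0.0271
#> percent drought-tolerant cells per sample:
#> AC CP BB DP ES
#> 52 24 20 16  0
#> DAPC control-centroid to PEG-cell distances:
#>  role control treated mean_distance sd_distance n_cells
#>   DTB control     PEG      1.652682   0.9516544      20
#>   DSB control     PEG    300.538352   1.3646586      20
#> significant fingerprint wavenumbers (DSB control vs PEG): 863
#> phenotype vs plant revival: Spearman rho = 0.9500 (classical_d2, n = 5), p = 0.03333
```

Reading the output: the per-condition thresholds are the mean C-D ratios of
the tolerant reference cells after full preprocessing (baseline correction
attenuates the broad stretch bands, so these are smaller than raw-spectrum
ratios; the attenuation cancels out of the classification). The five
percentages recover the configured soil gradient (52% counted vs 50%
simulated for AC, and exactly 0% for the inactive ES sample). The
drought-sensitive strain moves far from its control centroid in
discriminant space while the tolerant strain barely moves - the spectral
signature of drought sensitivity - and the tolerant-cell percentages rank-
correlate strongly with the plant-revival vector.

The packaged five-soil validation table reproduces the headline
cross-validation number exactly:

```r
tab <- soil_validation_table()
spearman_rho(tab$percent_tolerant, tab$percent_revived)
#> Spearman rho = 0.9000 (classical_d2, n = 5), p = 0.06667
```

(The p-value here is the exact permutation value over all 5! rank orders;
the t approximation on the same vectors gives ~0.037.)

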