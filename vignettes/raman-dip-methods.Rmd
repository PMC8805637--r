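---
title: "Methods: quantifying microbial drought tolerance from single-cell Raman spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying microbial drought tolerance from single-cell Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement model

When a microbial community is incubated in a medium whose water is partly
replaced by heavy water (D2O), metabolically active cells incorporate
deuterium into newly synthesized biomolecules. In a single-cell Raman
spectrum (SCRS) this shows up as a broad carbon-deuterium (C-D) stretch band
at 2040-2300 cm^-1 that grows at the expense of the carbon-hydrogen (C-H)
band at 2800-3100 cm^-1. The per-cell deuterium-incorporation statistic used
throughout this package is the **C-D ratio**

    r = (A_CD - b_CD) / [(A_CD - b_CD) + (A_CH - b_CH)]

where `A_CD` and `A_CH` are trapezoidal band areas and the background terms
`b` are estimated from the biologically silent 2400-2700 cm^-1 window.
Because the C-D band (260 cm^-1) and the silence window (300 cm^-1) differ
in width, the silence area is rescaled by the width ratio before
subtraction; without that rescaling the C-D band would be systematically
over-corrected by about 15%. Corrected areas are clamped at zero, so `r`
always lies in [0, 1]. If both corrected areas vanish the ratio is defined
as 0 and flagged degenerate rather than raised as an error.

A community's drought tolerance is quantified by incubating it under
osmotic stress (PEG) with D2O and counting the cells whose C-D ratio
**strictly exceeds** a reference threshold: the mean C-D ratio of known
drought-tolerant reference strains (DTB) measured under the matching
condition. Boundary cells count as inactive; with the strict rule a sample
whose cells all sit at or below threshold reports exactly 0%. A fixed-value
threshold mode is also provided for reproducing analyses that report the
reference means directly (0.14 under control incubation, 0.11 under PEG).

## Preprocessing

The preprocessing chain runs in a fixed order - baseline correction,
total-intensity normalization, peak alignment, fingerprint cropping - and
each step appends to the spectrum set's provenance record.

* **ALS baseline** (`als_baseline_correct`): iteratively reweighted
  penalized least squares (a Whittaker smoother with second-difference
  penalty `lambda`, asymmetry weight `p` on points above the fit). Defaults
  `lambda = 1e5`, `p = 0.001`, 10 iterations - the community-standard
  values for 1 cm^-1 grids. Two properties matter in practice:
  (a) on fingerprint-width lines (8-15 cm^-1 FWHM) the lower-envelope fit
  removes polynomial drift while biasing peak areas downward by a few
  percent, more at `lambda = 1e4` (the fit bends on a ~10-point scale and
  begins to climb the flanks of wider peaks); (b) on *broad* bands such as
  the C-D/C-H stretch envelopes (>100 cm^-1 FWHM) the baseline rides well
  into the band, so band areas measured after ALS are substantially
  attenuated relative to the raw generated areas. The attenuation is
  common to reference and sample cells, which is why classification against
  a reference-derived threshold is unaffected, but pipeline-internal
  thresholds are numerically smaller than thresholds computed on raw
  spectra.
* **TotInt normalization** (`normalize_total_intensity`): division by the
  summed intensity; output sums to one, idempotent, scale-invariant. The
  C-D ratio is invariant under it (all band areas scale together), which
  the test suite asserts; we nevertheless compute the ratio after baseline
  correction and normalization so that every downstream statistic sees the
  same objects.
* **Peak alignment** (`align_peaks`): a simplified cluster-based scheme -
  local-maximum peak detection with a 3xMAD prominence threshold,
  integer-step cross-correlation against a reference (the spectrum with the
  highest mean correlation to all others), then recursive segment splitting
  at the largest inter-peak gap. Shifting reassigns intensities to
  neighbouring grid positions without altering values; vacated edge
  positions take the edge value rather than zero to avoid creating fake
  band edges. A best shift that lands on the allowed-window boundary is
  treated as untrustworthy: the spectrum passes through unshifted with a
  warning.
* **Cropping** (`crop_band`): closed-interval selection, typically to the
  400-1800 cm^-1 fingerprint window used for phenotyping. Cropping runs
  last because the C-D ratio needs the high-wavenumber bands; the order of
  alignment before cropping follows the processing order of the upstream
  protocol.

## Phenotype discrimination

`fit_dapc` implements discriminant analysis of principal components: PCA on
the mean-centred cell x wavenumber matrix, then linear discriminant
analysis on the retained scores. The retention policy keeps the fewest PCs
explaining >= 90% of variance, capped at n/3 to limit discriminant
overfitting; both the count and the cap are configurable. PC scores are
rescaled to unit variance before the LDA (the discriminant coordinates are
invariant to this, but it keeps the fit well conditioned when spectra are
on a normalized scale), and each discriminant axis is normalised to unit
pooled within-group variance (divisor n) and oriented so the first group's
centroid is non-positive - making coordinates exactly reproducible, e.g.
under duplication of every cell.

The treatment effect is summarised by the Euclidean distance from the
control group's centroid to each treated cell in the discriminant plane
(with two groups there is a single axis and the distance is 1-D), reported
as mean +- sample SD. Because the axes are in within-group-SD units these
distances are Mahalanobis-like: tolerant phenotypes produce small values,
sensitive ones large values. Per-axis group separation is tested with
two-sided Wilcoxon rank-sum tests.

`peakwise_significance` screens every wavenumber: Shapiro-Wilk on both
groups at alpha = 0.05, a two-sided t test when both pass and the Wilcoxon
rank-sum test otherwise, flagging raw p < 0.01 without multiplicity
correction (a Benjamini-Hochberg option exists but is off by default, to
match the raw-p flagging convention of the upstream analysis). If either
group fails the normality gate the nonparametric branch is taken.
Wavenumbers constant in both groups get p = 1 and a flag.

## Association layer

`spearman_rho` assigns mid-ranks to ties and offers two variants. The
classical d^2 formula `1 - 6*sum(d^2)/(n(n^2-1))` is the default: on the
packaged five-soil validation table (52.2, 21.7, 21.7, 12.5, 0 percent
tolerant cells vs 40, 40, 20, 0, 0 percent revived plants) it gives exactly
0.9, whereas the tie-corrected Pearson-on-ranks variant gives ~0.892; both
are exposed because the difference documents method sensitivity under
ties. For n <= 8 the p-value is computed by exact permutation over all n!
orderings (on the five-soil table: 8 of 120 orderings reach |rho| >= 0.9,
p = 0.0667); larger n uses the t approximation. Note the exact-permutation
p is the honest small-sample value; the t approximation on the same data
gives ~0.037, which is where a "p < 0.05" call on these vectors comes
from.

`bray_curtis` implements `sum|a-b| / sum(a+b)`; `hierarchical_cluster`
feeds the pairwise matrix to average-linkage (UPGMA) agglomeration -
linkage is configurable; UPGMA is the default because only the
dissimilarity, not the linkage, is fixed by convention - and serializes
the dendrogram as Newick with ultrametric branch lengths (leaf depth =
merge height / 2).

## The synthetic-data generator

No raw spectra are publicly deposited for this kind of assay, so the
generator is a first-class, tested module that emulates the statistical
structure the analysis assumes:

* a fingerprint library of 19 Lorentzian lines (Gaussian selectable) at
  literature peak positions with amplitudes 0.2-1.0 and FWHM 10-20 cm^-1;
  Lorentzian is the default because Raman lines are homogeneously
  broadened;
* a broad C-D envelope, Gaussian at 2170 cm^-1 (band midpoint) with FWHM
  120 cm^-1, whose area is `kappa * a * A_CH0` for metabolic activity `a`,
  and a C-H envelope at 2935 cm^-1 (FWHM 150 cm^-1) with area
  `(1 - kappa*a) * A_CH0`; the transfer fraction `kappa = 0.4` mirrors
  media in which 40% of the water is D2O, and total C-H + C-D area is
  conserved. On raw spectra this makes the C-D ratio ~= 0.4 * a;
* the drought-effect signature: drought-sensitive (DSB) profiles under PEG
  multiply each line's amplitude by its `drought_response` factor - lipid
  and carbohydrate lines down (e.g. 1267 cm^-1 x 0.6), protein and
  nucleic-acid lines up (e.g. 1209 cm^-1 x 1.5). Tolerant (DTB) profiles
  are unchanged by condition;
* a two-component per-cell activity law: inactive cells Uniform(0, 0.05),
  active cells Beta-distributed rescaled to (0.2, 1.0) - separable classes
  with substantial cell-to-cell heterogeneity. The DTB reference laws use
  Beta(1.5, 6.5) (mean activity 0.35) under control and Beta(1.2, 11.6)
  (mean 0.275) under PEG, so that reference thresholds on raw spectra
  centre near 0.14 and 0.11;
* cubic-polynomial baseline drift and additive homoscedastic Gaussian
  noise (both chosen for analyzability), on a uniform 1 cm^-1 grid over
  300-3200 cm^-1. The acquisition grid of real instruments is not fixed by
  any convention we could adopt, so 1 cm^-1 is a deliberate choice.

What the generator does **not** emulate - and hence what green tests do not
certify about real data: cosmic-ray spikes, fluorescence photobleaching,
wavelength-dependent instrument response, cell-to-cell variation of the
fingerprint *shape* within a phenotype (only activity varies per cell), and
matrix effects of soil minerals. DAPC separations on synthetic data are
therefore cleaner (larger, less variable distances) than on real spectra;
the tests assert orderings and calibrations, not instrument-scale
magnitudes.

## Numerical choices and degenerate inputs

* Band intervals are closed on both ends; spectra are stored ascending.
* Trapezoidal integration throughout; on a 1 cm^-1 grid with bands whose
  integrand decays at the edges the quadrature error is far below any
  tolerance used here.
* Strict `>` for activity calls; documented in the output (`threshold`
  column) so boundary behaviour is auditable.
* All-zero spectra cannot be normalized (error); all-zero profile pairs
  have undefined Bray-Curtis dissimilarity (flagged, and an error when a
  dendrogram needs the value); constant vectors have undefined rank
  correlation (error).
* One master seed derives every stage seed in the pipeline; identical
  configuration and seed reproduce the run report exactly.

## Problem sizes used by the tests

The bundled demo simulates 20 reference cells per strain and condition and
25 cells per soil sample - the scale of a typical single-cell Raman
campaign (20-25 cells per sample). Calibration suites use 200-cell
populations over 100 seeds (fraction recovery), 20-cell groups over 100
seeds (DAPC contrast) and 200 seeds (screen calibration at 1401
wavenumbers); these sizes give the binomial and Monte-Carlo intervals used
in the assertions their nominal coverage while keeping the whole suite
comfortably runnable on a laptop.

## Known limitations

* The ALS broad-band attenuation described above means pipeline-internal
  C-D ratios are compressed relative to raw-spectrum ratios; comparisons
  are only meaningful within a consistently processed batch.
* The exact-permutation Spearman p is conservative at n = 5 with ties;
  with only five samples, significance calls hinge on the p-value method.
* DAPC distances are reported in within-group-SD units; they are not
  comparable across fits with different retained-PC counts.
* The simplified cluster-based alignment recovers integer grid shifts
  only; sub-grid shifts would require interpolation, which is deliberately
  avoided because it alters intensity values.
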