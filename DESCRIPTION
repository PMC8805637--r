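Package: ramandip
Title: Raman-Deuterium Isotope Probing Analysis of Microbial Drought Tolerance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the drought tolerance of a soil microbiome
    from single-cell Raman spectra acquired after heavy-water (D2O) isotope
    probing. Provides a seeded synthetic spectrum generator with a fingerprint
    peak library and a drought-effect signature, chemometric preprocessing
    (asymmetric least squares baseline correction, total-intensity
    normalization, cluster-based peak alignment, fingerprint cropping), the
    C-D band deuterium-incorporation ratio with silence-region background
    correction and reference-based active-cell classification, discriminant
    analysis of principal components with centroid-distance summaries and
    normality-gated per-wavenumber significance screens, tie-aware Spearman
    rank correlation, Bray-Curtis hierarchical clustering, and a configurable
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
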