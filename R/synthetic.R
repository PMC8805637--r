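#' Synthetic Raman peak
#'
#' One fingerprint line of the synthetic spectrum model: a Lorentzian (or
#' Gaussian) profile at a fixed Raman shift, with a multiplicative
#' `drought_response` factor applied to its amplitude when a drought-sensitive
#' phenotype is simulated under osmotic (PEG) stress.
#'
#' @param center peak position, cm^-1, within 200-3200.
#' @param width full width at half maximum, cm^-1, > 0.
#' @param amplitude peak height, arbitrary intensity units, >= 0.
#' @param assignment free-text biomolecular assignment.
#' @param drought_response multiplicative amplitude factor under simulated
#'   drought stress (> 0; < 1 means the peak shrinks, > 1 grows, 1 unchanged).
#' @return An object of class `synthetic_peak`.
#' @export
synthetic_peak <- function(center, width, amplitude, assignment = "",
                           drought_response = 1) {
  if (center < 200 || center > 3200) {
    stop("peak center must lie within 200-3200 cm^-1, got ", center)
  }
  if (width <= 0) stop("peak width must be > 0")
  if (amplitude < 0) stop("peak amplitude must be >= 0")
  if (drought_response <= 0) stop("drought_response must be > 0")
  structure(
    list(center = center, width = width, amplitude = amplitude,
         assignment = assignment, drought_response = drought_response),
    class = "synthetic_peak"
  )
}

#' Fingerprint peak library
#'
#' Default library of biomolecular fingerprint lines used by the synthetic
#' spectrum generator. Positions and assignments follow the bands that
#' discriminate drought-sensitive from drought-tolerant cells under osmotic
#' stress: protein and nucleic-acid lines (e.g. 1002, 1209, 1240, 1375 cm^-1)
#' gain intensity in stressed sensitive cells while lipid and carbohydrate
#' lines (e.g. 407, 1267, 1441 cm^-1) lose intensity. The `drought_response`
#' column encodes that signature direction as an amplitude factor applied to
#' sensitive cells under PEG.
#'
#' @return A list of [synthetic_peak] objects.
#' @export
fingerprint_peak_library <- function() {
  spec <- list(
    #       center width ampl assignment                         response
    list(    407,  14, 0.30, "carbohydrate skeletal (glucose)",  0.70),
    list(    620,  12, 0.25, "phenylalanine skeletal",           1.30),
    list(    782,  14, 0.35, "cytosine/uracil ring breathing",   1.20),
    list(    853,  14, 0.30, "tyrosine ring breathing",          1.10),
    list(    922,  12, 0.25, "L-alanine R-CH3",                  1.30),
    list(    936,  12, 0.30, "carbohydrate/protein C-C stretch", 1.25),
    list(    950,  12, 0.20, "cholesterol",                      1.25),
    list(   1002,  10, 1.00, "phenylalanine ring breathing",     1.30),
    list(   1032,  12, 0.35, "phenylalanine C-N stretch",        0.75),
    list(   1102,  16, 0.40, "phosphate backbone stretch",       1.00),
    list(   1209,  14, 0.45, "protein C-C6H5 stretch (Phe/Trp)", 1.50),
    list(   1240,  16, 0.50, "nucleic acid ring (T/C/A)",        1.30),
    list(   1267,  14, 0.55, "lipid =C-H deformation",           0.60),
    list(   1375,  14, 0.35, "nucleic acid (T/A/G)",             1.30),
    list(   1441,  18, 0.60, "lipid CH2 scissoring",             0.70),
    list(   1476,  14, 0.30, "amide II / purine bases",          1.25),
    list(   1545,  14, 0.30, "protein C=C stretch (Tyr)",        1.25),
    list(   1573,  14, 0.35, "guanine/adenine, amide II",        0.80),
    list(   1658,  20, 0.70, "amide I / unsaturated lipid",      0.85)
  )
  lapply(spec, function(p) {
    synthetic_peak(p[[1]], p[[2]], p[[3]], p[[4]], p[[5]])
  })
}

#' Phenotype profile for the spectrum generator
#'
#' Bundles the fingerprint peak library with the cell's simulated phenotype:
#' its role (drought-tolerant DTB or drought-sensitive DSB), incubation
#' condition, and metabolic activity. Metabolic activity governs deuterium
#' incorporation: in a medium where a fraction `kappa` of the water is heavy
#' water, a fully active cell transfers a fraction `kappa` of its C-H band
#' area into the broad C-D band, so C-D area grows as
#' `kappa * activity * ch_area` while C-H area shrinks to
#' `(1 - kappa * activity) * ch_area`. DSB profiles under PEG additionally
#' apply each peak's `drought_response` factor (the drought-effect signature);
#' DTB fingerprints are unchanged by condition.
#'
#' @param role `"DTB"` or `"DSB"`.
#' @param condition `"control"` or `"PEG"`.
#' @param metabolic_activity fraction in `[0, 1]`.
#' @param peaks list of [synthetic_peak]; default [fingerprint_peak_library()].
#' @param shape `"lorentzian"` (default; Raman lines are homogeneously
#'   broadened) or `"gaussian"`.
#' @param kappa C-H to C-D transfer fraction at full activity; the default
#'   0.4 mirrors incubation media in which 40 percent of the water is D2O.
#' @param ch_area total C-H band area (intensity * cm^-1) of an unlabeled
#'   cell.
#' @return An object of class `phenotype_profile`.
#' @export
phenotype_profile <- function(role = c("DTB", "DSB"),
                              condition = c("control", "PEG"),
                              metabolic_activity = 0.5,
                              peaks = fingerprint_peak_library(),
                              shape = c("lorentzian", "gaussian"),
                              kappa = 0.4, ch_area = 60) {
  role <- match.arg(role)
  condition <- match.arg(condition)
  shape <- match.arg(shape)
  if (metabolic_activity < 0 || metabolic_activity > 1) {
    stop("metabolic_activity must lie in [0, 1]")
  }
  if (kappa <= 0 || kappa > 1) stop("kappa must lie in (0, 1]")
  if (ch_area <= 0) stop("ch_area must be > 0")
  stopifnot(all(vapply(peaks, inherits, logical(1), "synthetic_peak")))
  if (role == "DSB" && condition == "PEG") {
    peaks <- lapply(peaks, function(p) {
      p$amplitude <- p$amplitude * p$drought_response
      p
    })
  }
  structure(
    list(role = role, condition = condition,
         metabolic_activity = metabolic_activity, peaks = peaks,
         shape = shape, kappa = kappa, ch_area = ch_area),
    class = "phenotype_profile"
  )
}

# Unit-height line profile matrix: one column per peak, summed with amplitudes.
peak_component <- function(axis, center, fwhm, shape) {
  if (shape == "lorentzian") {
    hw <- fwhm / 2
    hw^2 / ((axis - center)^2 + hw^2)
  } else {
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    exp(-(axis - center)^2 / (2 * sigma^2))
  }
}

fingerprint_signal <- function(profile, axis) {
  sig <- numeric(length(axis))
  for (p in profile$peaks) {
    sig <- sig + p$amplitude * peak_component(axis, p$center, p$width,
                                              profile$shape)
  }
  sig
}

# Unit-area Gaussian used for the broad C-D / C-H stretch envelopes.
unit_area_gaussian <- function(axis, center, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  stats::dnorm(axis, center, sigma)
}

cd_envelope <- function(axis) unit_area_gaussian(axis, 2170, 120)
ch_envelope <- function(axis) unit_area_gaussian(axis, 2935, 150)

polynomial_baseline <- function(axis, coefficients) {
  if (length(coefficients) == 0L) return(numeric(length(axis)))
  t <- (axis - min(axis)) / diff(range(axis))
  drop(outer(t, seq_along(coefficients) - 1, `^`) %*% coefficients)
}

#' Default wavenumber axis
#'
#' Uniform 1 cm^-1 grid over 300-3200 cm^-1, wide enough to contain the
#' fingerprint window and the C-D, silence and C-H bands.
#'
#' @return Numeric vector of wavenumbers.
#' @export
default_axis <- function() seq(300, 3200, by = 1)

check_axis_covers <- function(axis, bands = default_bands()[c("cd", "ch")]) {
  for (b in bands) {
    if (min(axis) > b$lower || max(axis) < b$upper) {
      stop("axis does not cover the ", b$name, " band [", b$lower, ", ",
           b$upper, "] cm^-1")
    }
  }
  invisible(TRUE)
}

#' Generate one synthetic single-cell Raman spectrum
#'
#' Sums the fingerprint peak profiles of a [phenotype_profile()] with a broad
#' C-D stretch envelope (Gaussian centred at 2170 cm^-1, FWHM 120 cm^-1)
#' whose area is proportional to metabolic activity, a C-H stretch envelope
#' whose area shrinks correspondingly, a polynomial baseline drift and
#' additive homoscedastic Gaussian noise. The 2400-2700 cm^-1 silence region
#' carries no signal beyond baseline and noise. Identical inputs and seed
#' reproduce the spectrum bit for bit.
#'
#' @param profile a [phenotype_profile()].
#' @param axis strictly increasing wavenumber grid covering at least the C-D
#'   and C-H bands; default [default_axis()].
#' @param noise_sd standard deviation of additive noise, intensity units.
#' @param baseline_coefficients polynomial coefficients (constant first) of
#'   the baseline on the axis rescaled to `[0, 1]`.
#' @param seed integer RNG seed; `NULL` draws from the current RNG state.
#' @param cell_id identifier for the generated cell.
#' @return An [scrs_set] containing one spectrum; the true simulated activity
#'   is stored in the metadata column `activity`.
#' @examples
#' pr <- phenotype_profile("DTB", "control", metabolic_activity = 0.4)
#' s <- generate_spectrum(pr, noise_sd = 0.001, seed = 1)
#' @export
generate_spectrum <- function(profile, axis = default_axis(), noise_sd = 0.002,
                              baseline_coefficients = c(0.05, 0.02),
                              seed = NULL, cell_id = "cell1") {
  stopifnot(inherits(profile, "phenotype_profile"))
  if (is.unsorted(axis, strictly = TRUE)) {
    stop("axis must be strictly increasing")
  }
  check_axis_covers(axis)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  a <- profile$metabolic_activity
  signal <- fingerprint_signal(profile, axis) +
    profile$kappa * a * profile$ch_area * cd_envelope(axis) +
    (1 - profile$kappa * a) * profile$ch_area * ch_envelope(axis) +
    polynomial_baseline(axis, baseline_coefficients)
  noise <- with_seed(seed, stats::rnorm(length(axis), 0, noise_sd))
  meta <- data.frame(cell_id = cell_id, sample = "synthetic",
                     condition = profile$condition, role = profile$role,
                     activity = a)
  scrs_set(axis, signal + noise, meta, provenance = "simulate")
}

#' Population specification for the synthetic generator
#'
#' Describes a simulated community: how many cells, what fraction are
#' metabolically active, the two-component activity law (inactive cells
#' uniform on `[0, inactive_max]`; active cells Beta(`shape1`, `shape2`)
#' rescaled to `[active_min, active_max]` - separable classes with
#' substantial cell-to-cell heterogeneity), plus noise, baseline and seed.
#'
#' @param n_cells number of cells, >= 1.
#' @param fraction_active fraction of active cells in `[0, 1]`.
#' @param activity_distribution list with elements `inactive_max`, `shape1`,
#'   `shape2`, `active_min`, `active_max`.
#' @param noise_sd additive noise standard deviation, >= 0.
#' @param baseline_coefficients polynomial baseline coefficients.
#' @param seed integer RNG seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_cells, fraction_active,
                            activity_distribution = list(
                              inactive_max = 0.05, shape1 = 2, shape2 = 2,
                              active_min = 0.2, active_max = 1.0),
                            noise_sd = 0.002,
                            baseline_coefficients = c(0.05, 0.02),
                            seed = 1L) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (fraction_active < 0 || fraction_active > 1) {
    stop("fraction_active must lie in [0, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  ad <- activity_distribution
  stopifnot(all(c("inactive_max", "shape1", "shape2", "active_min",
                  "active_max") %in% names(ad)))
  structure(
    list(n_cells = as.integer(n_cells), fraction_active = fraction_active,
         activity_distribution = ad, noise_sd = noise_sd,
         baseline_coefficients = baseline_coefficients,
         seed = as.integer(seed)),
    class = "population_spec"
  )
}

#' Generate a synthetic cell population
#'
#' Draws per-cell active/inactive labels and activities from the population's
#' two-component activity law, then builds all spectra on the template
#' profile's fingerprint (vectorised: the fingerprint is computed once, the
#' C-D and C-H envelopes are scaled per cell by its activity). True per-cell
#' activity and the true label are stored in the metadata (`activity`,
#' `true_active`) for recovery tests.
#'
#' @param spec a [population_spec()].
#' @param profile_template a [phenotype_profile()]; its `metabolic_activity`
#'   is ignored in favour of the drawn per-cell activities.
#' @param sample sample label stored in the metadata.
#' @return An [scrs_set] of `n_cells` spectra.
#' @examples
#' pop <- generate_population(population_spec(10, 0.3, seed = 7),
#'                            phenotype_profile("DTB", "PEG"))
#' table(pop$metadata$true_active)
#' @export
generate_population <- function(spec, profile_template,
                                sample = "synthetic") {
  stopifnot(inherits(spec, "population_spec"),
            inherits(profile_template, "phenotype_profile"))
  axis <- default_axis()
  n <- spec$n_cells
  ad <- spec$activity_distribution
  draws <- with_seed(spec$seed, {
    active <- stats::runif(n) < spec$fraction_active
    act <- numeric(n)
    act[!active] <- stats::runif(sum(!active), 0, ad$inactive_max)
    act[active] <- ad$active_min + (ad$active_max - ad$active_min) *
      stats::rbeta(sum(active), ad$shape1, ad$shape2)
    noise <- matrix(stats::rnorm(n * length(axis), 0, spec$noise_sd), nrow = n)
    list(active = active, act = act, noise = noise)
  })
  base <- fingerprint_signal(profile_template, axis) +
    polynomial_baseline(axis, spec$baseline_coefficients)
  g_cd <- cd_envelope(axis)
  g_ch <- ch_envelope(axis)
  kappa <- profile_template$kappa
  ch_area <- profile_template$ch_area
  m <- matrix(base, nrow = n, ncol = length(axis), byrow = TRUE) +
    (kappa * ch_area * draws$act) %o% g_cd +
    (ch_area * (1 - kappa * draws$act)) %o% g_ch +
    draws$noise
  meta <- data.frame(
    cell_id = sprintf("%s_c%03d", sample, seq_len(n)),
    sample = sample,
    condition = profile_template$condition,
    role = profile_template$role,
    activity = draws$act,
    true_active = draws$active
  )
  scrs_set(axis, m, meta, provenance = "simulate")
}

#' Five-soil validation table
#'
#' Packaged per-sample summary used to cross-validate the Raman-derived
#' phenotype against plant behaviour: the percentage of drought-tolerant
#' cells counted in each agricultural soil (corn AC, pepper CP, bean BB,
#' pepper DP, sweet potato ES) and the percentage of pea plants that revived
#' after re-watering when grown in that soil.
#'
#' @return A data.frame with columns `sample`, `percent_tolerant`,
#'   `percent_revived`.
#' @export
soil_validation_table <- function() {
  data.frame(
    sample = c("AC", "CP", "BB", "DP", "ES"),
    percent_tolerant = c(52.2, 21.7, 21.7, 12.5, 0),
    percent_revived = c(40, 40, 20, 0, 0)
  )
}

#' Generate linked per-sample association tables
#'
#' Simulates the sample-level tables used by the association layer: a
#' phenotype column `x` (percent drought-tolerant cells) plus one linked
#' response column and optional pure-noise columns. The link is built on a
#' bivariate Gaussian copula with Pearson parameter `2*sin(pi*rho/6)`, so
#' the Spearman rank correlation of the linked pair equals `true_rho` in
#' expectation; `true_rho = 1` (or -1) produces an exact monotone link.
#'
#' @param n_samples number of samples, >= 3.
#' @param true_rho target Spearman correlation in `[-1, 1]`.
#' @param seed integer RNG seed.
#' @param n_noise_columns number of additional unlinked columns.
#' @return A data.frame with columns `sample`, `x`, `linked`, and
#'   `noise1..noiseK`.
#' @export
generate_association_tables <- function(n_samples, true_rho, seed = 1L,
                                        n_noise_columns = 0L) {
  if (n_samples < 3) stop("n_samples must be >= 3")
  if (abs(true_rho) > 1) stop("requested |rho| must be <= 1")
  with_seed(seed, {
    z1 <- stats::rnorm(n_samples)
    if (abs(true_rho) == 1) {
      z2 <- sign(true_rho) * z1
    } else {
      r <- 2 * sin(pi * true_rho / 6)
      z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n_samples)
    }
    out <- data.frame(
      sample = sprintf("S%02d", seq_len(n_samples)),
      x = round(100 * stats::pnorm(z1), 1),
      linked = round(100 * stats::pnorm(z2), 1)
    )
    for (k in seq_len(n_noise_columns)) {
      out[[paste0("noise", k)]] <- round(100 * stats::runif(n_samples), 1)
    }
    out
  })
}
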