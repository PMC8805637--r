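# Shared fixtures built in code.

# Truncated-Lorentzian area over [lo, hi] for a peak of height A, FWHM w at c.
lorentz_area <- function(A, w, c, lo, hi) {
  hw <- w / 2
  A * hw * (atan((hi - c) / hw) - atan((lo - c) / hw))
}

# Analytic area of all library peaks of a profile over a window.
profile_window_area <- function(profile, lo, hi) {
  sum(vapply(profile$peaks, function(p) {
    lorentz_area(p$amplitude, p$width, p$center, lo, hi)
  }, numeric(1)))
}

# Truncated-Gaussian area for a band envelope of total area `area`.
gauss_trunc <- function(area, fwhm, centre, lo, hi) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  area * (pnorm(hi, centre, sigma) - pnorm(lo, centre, sigma))
}

# Small three-cell set with distinct constant-plus-peak spectra.
tiny_set <- function() {
  axis <- seq(400, 700, by = 1)
  peak <- function(c) exp(-(axis - c)^2 / 50)
  m <- rbind(0.1 + peak(480), 0.2 + peak(520), 0.3 + peak(610))
  scrs_set(axis, m, data.frame(cell_id = c("a", "b", "c")))
}

quiet_pipeline <- function(cfg) suppressMessages(run_pipeline(cfg))

# Down-scaled pipeline configuration for fast end-to-end tests.
small_config <- function(seed = 1L, ...) {
  cfg <- default_config()
  cfg$seed <- as.integer(seed)
  cfg$simulate$n_reference_cells <- 8L
  cfg$simulate$n_soil_cells <- 10L
  extra <- list(...)
  for (nm in names(extra)) cfg[[nm]] <- extra[[nm]]
  cfg
}
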