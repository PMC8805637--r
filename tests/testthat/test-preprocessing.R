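test_that("long and wide CSV round-trip a spectrum set", {
  s <- tiny_set()
  for (fmt in c("long", "wide")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_spectra(s, path, format = fmt, seed = 42)
    expect_match(readLines(path, n = 1), "# seed: 42", fixed = TRUE)
    back <- read_spectra(path, format = fmt)
    expect_equal(back$wavenumbers, s$wavenumbers)
    expect_equal(unname(back$intensities), unname(s$intensities),
                 tolerance = 1e-12)
    expect_identical(back$metadata$cell_id, s$metadata$cell_id)
  }
})

test_that("metadata TSV round-trips and attaches on read", {
  s <- tiny_set()
  sp <- withr::local_tempfile(fileext = ".csv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_spectra(s, sp, format = "long")
  write_metadata(s, mp)
  back <- read_spectra(sp, format = "long", metadata = mp)
  expect_identical(back$metadata$sample, s$metadata$sample)
})

test_that("malformed spectra files are rejected with the offending cell", {
  s <- tiny_set()
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s, path, format = "wide")
  wdf <- read.csv(path, check.names = FALSE)
  wdf[2, 5] <- NA
  write.csv(wdf, path, row.names = FALSE)
  expect_error(read_spectra(path, format = "wide"), "cell b")

  lpath <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s, lpath, format = "long")
  df <- read.csv(lpath)
  df2 <- rbind(df, df[1, ])  # duplicate (cell_id, wavenumber)
  write.csv(df2, lpath, row.names = FALSE)
  expect_error(read_spectra(lpath, format = "long"), "duplicate")

  write.csv(df[c("cell_id", "wavenumber")], lpath, row.names = FALSE)
  expect_error(read_spectra(lpath, format = "long"), "intensity")
})

test_that("shuffled long rows read back identically", {
  s <- tiny_set()
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s, path, format = "long")
  df <- read.csv(path)
  set.seed(1)
  write.csv(df[sample(nrow(df)), ], path, row.names = FALSE)
  back <- read_spectra(path, format = "long")
  expect_equal(unname(back$intensities[back$metadata$cell_id == "b", ]),
               unname(s$intensities["b", ]))
})

test_that("ALS removes pure baselines", {
  ramp <- seq(0, 5, length.out = 500)
  corrected <- als_baseline_correct(ramp)
  expect_lt(max(abs(corrected)) / diff(range(ramp)), 1e-3)
  expect_equal(als_baseline_correct(rep(0, 100)), rep(0, 100),
               tolerance = 1e-12)
})

test_that("ALS recovers peak areas over a cubic baseline across lambda", {
  axis <- seq(300, 2000, by = 1)
  peaks <- list(c(700, 8, 1.0), c(1100, 8, 0.8), c(1500, 8, 0.6))
  signal <- Reduce(`+`, lapply(peaks, function(p) {
    p[3] * (p[2] / 2)^2 / ((axis - p[1])^2 + (p[2] / 2)^2)
  }))
  t <- (axis - 300) / 1700
  baseline <- 2 + 3 * t - 4 * t^2 + 2 * t^3
  y <- signal + baseline
  for (lam in c(1e4, 1e5, 1e6)) {
    corrected <- als_baseline_correct(y, lambda = lam)
    for (p in peaks) {
      got <- integrate_band(corrected, band("w", p[1] - 10, p[1] + 10), axis)
      want <- sum(vapply(peaks, function(q) {
        lorentz_area(q[3], q[2], q[1], p[1] - 10, p[1] + 10)
      }, numeric(1)))
      expect_lt(abs(got - want) / want, 0.05)
    }
  }
  expect_error(als_baseline_correct(c(1, 2)), "3 points")
  expect_error(als_baseline_correct(1:10, lambda = -1), "lambda")
  expect_error(als_baseline_correct(1:10, p = 1.5), "p must")
})

test_that("TotInt normalization sums to one, is idempotent and scale-free", {
  s <- tiny_set()
  n1 <- normalize_total_intensity(s)
  expect_true(all(abs(rowSums(n1$intensities) - 1) < 1e-12))
  n2 <- normalize_total_intensity(n1)
  expect_equal(n1$intensities, n2$intensities, tolerance = 1e-14)
  scaled <- scrs_set(s$wavenumbers, s$intensities * 7, s$metadata)
  expect_equal(normalize_total_intensity(scaled)$intensities,
               n1$intensities, tolerance = 1e-14)
  expect_equal(normalize_total_intensity(rep(2, 10)), rep(0.1, 10))
  expect_error(normalize_total_intensity(rep(0, 10)), "zero")
})

test_that("alignment recovers known integer shifts exactly", {
  pop <- generate_population(population_spec(2, 1, noise_sd = 5e-4, seed = 3),
                             phenotype_profile("DTB", "control"))
  for (shift in c(-5L, -2L, 2L, 4L)) {
    m <- pop$intensities
    n <- ncol(m)
    if (shift > 0) m[2, ] <- c(rep(m[2, 1], shift), m[2, 1:(n - shift)])
    else m[2, ] <- c(m[2, (1 - shift):n], rep(m[2, n], -shift))
    shifted <- scrs_set(pop$wavenumbers, m, pop$metadata)
    aligned <- align_peaks(shifted, reference = 1)
    expect_identical(aligned$metadata$alignment_shift[2], -shift)
    interior <- 20:(n - 20)
    expect_lt(max(abs(aligned$intensities[2, interior] -
                        pop$intensities[2, interior])), 1e-12)
  }
})

test_that("identical spectra align with zero shift", {
  pop <- generate_population(population_spec(1, 1, noise_sd = 0, seed = 3),
                             phenotype_profile("DTB", "control"))
  m <- rbind(pop$intensities, pop$intensities, pop$intensities)
  s <- scrs_set(pop$wavenumbers, m,
                data.frame(cell_id = c("a", "b", "c")))
  aligned <- align_peaks(s)
  expect_identical(aligned$metadata$alignment_shift, c(0L, 0L, 0L))
  expect_equal(aligned$intensities, s$intensities, ignore_attr = TRUE)
})

test_that("a shift at the window edge is refused with a warning", {
  pop <- generate_population(population_spec(2, 1, noise_sd = 0, seed = 3),
                             phenotype_profile("DTB", "control"))
  m <- pop$intensities
  n <- ncol(m)
  big <- 8L
  m[2, ] <- c(rep(m[2, 1], big), m[2, 1:(n - big)])
  s <- scrs_set(pop$wavenumbers, m, pop$metadata)
  expect_warning(aligned <- align_peaks(s, reference = 1, max_shift = 5L,
                                        segmented = FALSE),
                 "window")
  expect_equal(aligned$intensities[2, ], m[2, ], ignore_attr = TRUE)
})

test_that("alignment preserves intensity values", {
  pop <- generate_population(population_spec(2, 1, noise_sd = 1e-3, seed = 6),
                             phenotype_profile("DTB", "control"))
  m <- pop$intensities
  n <- ncol(m)
  m[2, ] <- c(rep(m[2, 1], 3), m[2, 1:(n - 3)])
  aligned <- align_peaks(scrs_set(pop$wavenumbers, m, pop$metadata),
                         reference = 1, segmented = FALSE)
  # shifted row is a rearrangement (plus edge padding) of the original values
  expect_true(all(aligned$intensities[2, 1:(n - 10)] %in% m[2, ]))
})

test_that("cropping uses closed intervals", {
  s <- scrs_set(seq(300, 3200, 1), matrix(1, 1, 2901),
                data.frame(cell_id = "a"))
  fp <- crop_band(s, default_bands()$fingerprint)
  expect_length(fp$wavenumbers, 1401L)
  expect_equal(range(fp$wavenumbers), c(400, 1800))
  full <- crop_band(s, band("all", 300, 3200))
  expect_equal(full$intensities, s$intensities)
  expect_error(crop_band(s, band("off", 5000, 6000)), "overlap")
})

test_that("preprocessing provenance records the fixed stage order", {
  pop <- generate_population(population_spec(3, 1, seed = 8),
                             phenotype_profile("DTB", "control"))
  out <- preprocess_spectra(pop, crop = default_bands()$fingerprint)
  steps <- out$provenance
  expect_match(steps[2], "als_baseline")
  expect_match(steps[3], "normalize")
  expect_match(steps[4], "align")
  expect_match(steps[5], "crop")
})
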