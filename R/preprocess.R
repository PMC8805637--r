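#' Asymmetric least squares (ALS) baseline correction
#'
#' Estimates a smooth baseline by iteratively reweighted penalized least
#' squares (Whittaker smoother with a second-difference penalty `lambda`):
#' points above the current baseline get small weight `p`, points below get
#' weight `1 - p`, so the fit hugs the valleys between peaks. The estimated
#' baseline is subtracted; the axis is unchanged.
#'
#' @param x an [scrs_set] or a numeric intensity vector.
#' @param lambda smoothness penalty, > 0. Larger values give stiffer
#'   baselines; `1e5` suits 1 cm^-1 grids with broad drift.
#' @param p asymmetry weight in (0, 1) given to points above the baseline.
#' @param n_iter number of reweighting iterations, >= 1.
#' @return Same type as `x`, baseline-subtracted.
#' @references Eilers & Boelens (2005), "Baseline correction with asymmetric
#'   least squares smoothing".
#' @examples
#' ramp <- seq(0, 1, length.out = 200)
#' max(abs(als_baseline_correct(ramp)))  # ~0: pure baseline removed
#' @export
als_baseline_correct <- function(x, lambda = 1e5, p = 0.001, n_iter = 10) {
  if (lambda <= 0) stop("lambda must be > 0")
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (inherits(x, "scrs_set")) {
    penalty <- als_penalty(length(x$wavenumbers), lambda)
    corrected <- t(apply(x$intensities, 1L, als_baseline_vector,
                         lambda = lambda, p = p, n_iter = n_iter,
                         penalty = penalty))
    out <- scrs_set(x$wavenumbers, corrected, x$metadata, x$provenance)
    return(record_step(out, sprintf("als_baseline(lambda=%g,p=%g)", lambda, p)))
  }
  als_baseline_vector(as.numeric(x), lambda, p, n_iter)
}

als_penalty <- function(n, lambda) {
  if (n < 3) stop("spectrum must have at least 3 points")
  d2 <- Matrix::bandSparse(n - 2, n,
                           k = 0:2,
                           diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                            rep(1, n - 2)))
  lambda * Matrix::crossprod(d2)
}

als_baseline_vector <- function(y, lambda, p, n_iter, penalty = NULL) {
  n <- length(y)
  if (is.null(penalty)) penalty <- als_penalty(n, lambda)
  w <- rep(1, n)
  z <- y
  for (i in seq_len(n_iter)) {
    wmat <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(wmat + penalty, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (identical(w_new, w) && i > 1L) break
    w <- w_new
  }
  y - z
}

#' Total-intensity (TotInt) normalization
#'
#' Divides each spectrum by its summed intensity so that the normalized
#' intensities sum to one. Idempotent and invariant to uniform rescaling.
#'
#' @param x an [scrs_set] or a numeric intensity vector.
#' @return Same type as `x`, normalized per spectrum.
#' @export
normalize_total_intensity <- function(x) {
  if (inherits(x, "scrs_set")) {
    tot <- rowSums(x$intensities)
    if (any(tot == 0)) {
      stop("zero total intensity in cell(s): ",
           paste(x$metadata$cell_id[tot == 0], collapse = ", "))
    }
    out <- scrs_set(x$wavenumbers, x$intensities / tot, x$metadata,
                    x$provenance)
    return(record_step(out, "normalize_totint"))
  }
  tot <- sum(x)
  if (tot == 0) stop("cannot normalize an all-zero spectrum")
  x / tot
}

# Local-maximum peak detection with a prominence threshold of
# `k_mad` times the median absolute deviation of the signal.
detect_peaks <- function(y, k_mad = 3) {
  n <- length(y)
  if (n < 3) return(integer())
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  thr <- stats::median(y) + k_mad * stats::mad(y)
  idx[y[idx] > thr]
}

# Best integer lag of `y` against reference `ref` within +/- max_shift,
# by direct cross-correlation. Positive lag means y is shifted right.
best_lag <- function(ref, y, max_shift) {
  lags <- -max_shift:max_shift
  cc <- vapply(lags, function(L) {
    if (L >= 0) {
      a <- ref[seq_len(length(ref) - L)]
      b <- y[(1 + L):length(y)]
    } else {
      a <- ref[(1 - L):length(ref)]
      b <- y[seq_len(length(y) + L)]
    }
    sum(a * b)
  }, numeric(1))
  lags[which.max(cc)]
}

shift_vector <- function(y, lag) {
  # positive lag moves the spectrum left by `lag` grid steps; vacated
  # positions are filled with the edge value to avoid fake band edges.
  n <- length(y)
  if (lag == 0) return(y)
  if (lag > 0) c(y[(1 + lag):n], rep(y[n], lag))
  else c(rep(y[1], -lag), y[seq_len(n + lag)])
}

align_segment <- function(ref, y, lo, hi, max_shift, min_points) {
  # Recursive cluster-style alignment: align the segment by integer
  # cross-correlation, then split at the largest inter-peak gap of the
  # reference and refine the halves.
  seg <- lo:hi
  if (length(seg) < min_points) return(y)
  lag <- best_lag(ref[seg], y[seg], max_shift)
  if (abs(lag) == max_shift) return(y)  # untrustworthy boundary optimum
  y[seg] <- shift_vector(y[seg], lag)
  pk <- detect_peaks(ref[seg])
  if (length(pk) >= 2L) {
    gaps <- diff(pk)
    cut <- pk[which.max(gaps)] + max(gaps) %/% 2L
    left <- lo:(lo + cut - 1L)
    right <- (lo + cut):hi
    if (length(left) >= min_points && length(right) >= min_points) {
      y <- align_segment(ref, y, lo, lo + cut - 1L, max_shift, min_points)
      y <- align_segment(ref, y, lo + cut, hi, max_shift, min_points)
    }
  }
  y
}

#' Peak alignment across a spectrum set
#'
#' Aligns every spectrum to a reference by integer-step cross-correlation,
#' with recursive segment splitting at the largest inter-peak gap of the
#' reference (a simplified cluster-based alignment). The reference is the
#' spectrum with the highest mean correlation to all others, unless fixed by
#' index. Shifting only reassigns intensities to neighbouring grid positions;
#' values themselves are unchanged, and vacated edge positions are filled
#' with the edge value. A spectrum with no detectable peaks, or whose best
#' shift hits the allowed window boundary, is passed through unshifted with a
#' warning.
#'
#' @param x an [scrs_set] with at least 2 spectra.
#' @param reference `"auto"` (highest mean correlation) or a cell index.
#' @param max_shift maximum allowed shift in grid steps.
#' @param segmented logical; refine segment-wise after the global shift.
#' @param min_points smallest segment length that is still aligned.
#' @return The aligned [scrs_set].
#' @export
align_peaks <- function(x, reference = "auto", max_shift = 10L,
                        segmented = TRUE, min_points = 50L) {
  stopifnot(inherits(x, "scrs_set"))
  n <- n_cells(x)
  if (n < 2) stop("alignment needs at least 2 spectra")
  m <- x$intensities
  if (identical(reference, "auto")) {
    cc <- stats::cor(t(m))
    ref_i <- which.max(rowSums(cc) - 1)
  } else {
    ref_i <- as.integer(reference)
    stopifnot(ref_i >= 1, ref_i <= n)
  }
  ref <- m[ref_i, ]
  np <- ncol(m)
  shifts <- integer(n)
  for (i in seq_len(n)) {
    if (i == ref_i) next
    if (length(detect_peaks(m[i, ])) == 0L) {
      warning("no detectable peaks in cell ", x$metadata$cell_id[i],
              "; passed through unshifted")
      next
    }
    lag <- best_lag(ref, m[i, ], max_shift)
    if (abs(lag) == max_shift) {
      warning("best shift for cell ", x$metadata$cell_id[i],
              " hit the allowed window (+/-", max_shift,
              " steps); passed through unshifted")
      next
    }
    shifts[i] <- -lag
    y <- shift_vector(m[i, ], lag)
    if (segmented) {
      pk <- detect_peaks(ref)
      if (length(pk) >= 2L) {
        gaps <- diff(pk)
        cut <- pk[which.max(gaps)] + max(gaps) %/% 2L
        if (cut >= min_points && (np - cut) >= min_points) {
          y <- align_segment(ref, y, 1L, cut, max_shift, min_points)
          y <- align_segment(ref, y, cut + 1L, np, max_shift, min_points)
        }
      }
    }
    m[i, ] <- y
  }
  meta <- x$metadata
  meta$alignment_shift <- shifts  # grid steps the spectrum was moved by
  out <- scrs_set(x$wavenumbers, m, meta, x$provenance)
  record_step(out, sprintf("align_peaks(ref=%s,max_shift=%d)",
                           x$metadata$cell_id[ref_i], max_shift))
}

#' Standard preprocessing pipeline
#'
#' Applies, in this fixed order: ALS baseline correction, total-intensity
#' normalization, peak alignment (skipped for single-spectrum sets), and -
#' when `crop` is not `NULL` - cropping to the given band. Band integration
#' for the C-D ratio must run before cropping, since the fingerprint window
#' excludes the C-D/C-H/silence bands.
#'
#' @param x an [scrs_set].
#' @param lambda,p,n_iter ALS parameters, see [als_baseline_correct()].
#' @param align logical; align peaks across cells.
#' @param max_shift alignment window in grid steps.
#' @param crop optional [band] to crop to (e.g. the fingerprint window).
#' @return The preprocessed [scrs_set]; `provenance` records the steps.
#' @export
preprocess_spectra <- function(x, lambda = 1e5, p = 0.001, n_iter = 10,
                               align = TRUE, max_shift = 10L, crop = NULL) {
  stopifnot(inherits(x, "scrs_set"))
  x <- als_baseline_correct(x, lambda = lambda, p = p, n_iter = n_iter)
  x <- normalize_total_intensity(x)
  if (align && n_cells(x) >= 2) x <- align_peaks(x, max_shift = max_shift)
  if (!is.null(crop)) x <- crop_band(x, crop)
  x
}
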