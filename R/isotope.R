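#' Integrate spectral intensity over a band
#'
#' Trapezoidal integral of intensity over the closed band interval, in
#' intensity times cm^-1. The band must lie within the axis.
#'
#' @param x an [scrs_set] (one area per cell) or a numeric intensity vector.
#' @param band a [band].
#' @param wavenumbers axis for vector input; ignored for sets.
#' @return Numeric area(s).
#' @examples
#' integrate_band(rep(2, 301), band("silence", 2400, 2700), 2400:2700)  # 600
#' @export
integrate_band <- function(x, band, wavenumbers = NULL) {
  stopifnot(inherits(band, "band"))
  if (inherits(x, "scrs_set")) {
    wn <- x$wavenumbers
    m <- x$intensities
  } else {
    wn <- wavenumbers
    if (is.null(wn)) stop("wavenumbers required for vector input")
    m <- matrix(x, nrow = 1L)
  }
  if (band$lower < min(wn) || band$upper > max(wn)) {
    stop("band ", format(band), " lies outside the axis [",
         min(wn), ", ", max(wn), "]")
  }
  keep <- wn >= band$lower & wn <= band$upper
  xs <- wn[keep]
  sub <- m[, keep, drop = FALSE]
  w <- diff(xs)
  areas <- as.numeric((sub[, -ncol(sub), drop = FALSE] +
                         sub[, -1L, drop = FALSE]) %*% w) / 2
  if (inherits(x, "scrs_set")) stats::setNames(areas, x$metadata$cell_id)
  else areas
}

#' Per-cell band areas for the deuterium statistic
#'
#' Integrates the C-D (2040-2300 cm^-1), C-H (2800-3100 cm^-1) and silence
#' (2400-2700 cm^-1) bands for every cell.
#'
#' @param x an [scrs_set] on an axis covering all three bands.
#' @param bands band list as from [default_bands()].
#' @return A `band_areas` data.frame with columns `cell_id`, `cd_area`,
#'   `ch_area`, `silence_area` and attributes recording the band widths.
#' @export
band_areas <- function(x, bands = default_bands()) {
  stopifnot(inherits(x, "scrs_set"))
  out <- data.frame(
    cell_id = x$metadata$cell_id,
    cd_area = unname(integrate_band(x, bands$cd)),
    ch_area = unname(integrate_band(x, bands$ch)),
    silence_area = unname(integrate_band(x, bands$silence)),
    row.names = NULL
  )
  attr(out, "cd_width") <- band_width(bands$cd)
  attr(out, "ch_width") <- band_width(bands$ch)
  attr(out, "silence_width") <- band_width(bands$silence)
  class(out) <- c("band_areas", "data.frame")
  out
}

#' C-D ratio: the deuterium-incorporation statistic
#'
#' For each cell, the silence-region area provides the background estimate.
#' Because the bands differ in width (C-D spans 260 cm^-1, C-H and silence
#' 300 cm^-1), the background is rescaled by the width ratio before
#' subtraction; corrected areas are clamped at zero so that noise cannot
#' drive them negative. The statistic is
#' `corrected_cd / (corrected_cd + corrected_ch)`, which lies in `[0, 1]`;
#' when both corrected areas are zero the ratio is defined as 0 and the cell
#' is flagged degenerate.
#'
#' @param areas a [band_areas()] data.frame, or a data.frame with columns
#'   `cd_area`, `ch_area`, `silence_area` (band widths then default to
#'   260/300/300 cm^-1).
#' @return The input data.frame with added columns `corrected_cd`,
#'   `corrected_ch`, `cd_ratio`, `degenerate`.
#' @examples
#' cd_ratio(data.frame(cd_area = 30, ch_area = 120, silence_area = 15))
#' # background_cd = 15 * 260/300 = 13 -> ratio = 17/122
#' @export
cd_ratio <- function(areas) {
  stopifnot(all(c("cd_area", "ch_area", "silence_area") %in% names(areas)))
  cd_w <- attr(areas, "cd_width") %||% 260
  ch_w <- attr(areas, "ch_width") %||% 300
  sil_w <- attr(areas, "silence_width") %||% 300
  bg_cd <- areas$silence_area * cd_w / sil_w
  bg_ch <- areas$silence_area * ch_w / sil_w
  corrected_cd <- pmax(areas$cd_area - bg_cd, 0)
  corrected_ch <- pmax(areas$ch_area - bg_ch, 0)
  denom <- corrected_cd + corrected_ch
  ratio <- ifelse(denom == 0, 0, corrected_cd / denom)
  areas$corrected_cd <- corrected_cd
  areas$corrected_ch <- corrected_ch
  areas$cd_ratio <- ratio
  areas$degenerate <- denom == 0
  areas
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference threshold from drought-tolerant cells
#'
#' The activity threshold is the arithmetic mean of the C-D ratios of
#' reference drought-tolerant (DTB) cells measured under the matching
#' condition; cells above it count as highly metabolically active.
#'
#' @param reference_ratios numeric vector of C-D ratios from DTB reference
#'   cells, length >= 1.
#' @return The mean ratio (scalar).
#' @examples
#' compute_threshold(c(0.10, 0.12, 0.14))  # 0.12
#' @export
compute_threshold <- function(reference_ratios) {
  reference_ratios <- as.numeric(reference_ratios)
  if (length(reference_ratios) == 0L) {
    stop("empty reference set: need at least one DTB reference ratio")
  }
  if (anyNA(reference_ratios)) stop("reference ratios contain NA")
  mean(reference_ratios)
}

#' Classify cells as metabolically active
#'
#' A cell is called active when its C-D ratio strictly exceeds the threshold
#' (boundary cells are inactive). Under PEG treatment, active cells are the
#' drought-tolerant cells of the sample.
#'
#' @param ratios numeric vector of per-cell C-D ratios (or a data.frame from
#'   [cd_ratio()], in which case its `cd_ratio` column is used).
#' @param threshold finite activity threshold.
#' @return A list with `calls` (data.frame: `cell_id` if available,
#'   `cd_ratio`, `threshold`, `is_active`), `n_active`, and
#'   `percent_active` (0-100).
#' @examples
#' classify_active(c(0.16, 0.12, 0.05, 0.11), 0.11)$percent_active  # 50
#' @export
classify_active <- function(ratios, threshold) {
  cell_id <- NULL
  if (is.data.frame(ratios)) {
    cell_id <- ratios$cell_id
    ratios <- ratios$cd_ratio
  }
  ratios <- unname(as.numeric(ratios))
  if (length(ratios) == 0L) stop("empty cell list")
  threshold <- unname(threshold)
  if (!is.finite(threshold)) stop("threshold must be finite")
  is_active <- ratios > threshold
  calls <- data.frame(cd_ratio = ratios, threshold = threshold,
                      is_active = is_active)
  if (!is.null(cell_id)) calls <- cbind(cell_id = cell_id, calls)
  list(calls = calls, n_active = sum(is_active),
       percent_active = 100 * mean(is_active))
}

#' Protein/lipid marker ratio
#'
#' Ratio of the integrated area around the 1209 cm^-1 protein marker to the
#' area around the 1267 cm^-1 lipid marker; an indicator of the
#' drought-effect signature (proteins up, lipids down in stressed sensitive
#' cells). When the lipid window area is not positive the ratio is undefined
#' and flagged rather than raised.
#'
#' @param x an [scrs_set].
#' @param half_width marker window half width, cm^-1 (default 8).
#' @return Data.frame with `cell_id`, `protein_area`, `lipid_area`, `ratio`,
#'   `undefined`.
#' @export
marker_ratio <- function(x, half_width = 8) {
  stopifnot(inherits(x, "scrs_set"))
  mb <- marker_bands(half_width)
  protein <- integrate_band(x, mb$protein)
  lipid <- integrate_band(x, mb$lipid)
  undefined <- lipid <= 0
  ratio <- ifelse(undefined, NA_real_, protein / lipid)
  if (any(undefined)) {
    warning("lipid window area <= 0 for cell(s): ",
            paste(x$metadata$cell_id[undefined], collapse = ", "),
            "; ratio undefined")
  }
  data.frame(cell_id = x$metadata$cell_id, protein_area = as.numeric(protein),
             lipid_area = as.numeric(lipid), ratio = ratio,
             undefined = undefined, row.names = NULL)
}

#' C-D ratios straight from a spectrum set
#'
#' Convenience wrapper: [band_areas()] then [cd_ratio()], keeping sample and
#' condition labels alongside.
#'
#' @param x an [scrs_set] whose axis covers the C-D, C-H and silence bands.
#' @return Data.frame of per-cell areas and ratios with `sample` and
#'   `condition` columns.
#' @export
cd_ratios_of <- function(x) {
  out <- cd_ratio(band_areas(x))
  out$sample <- x$metadata$sample
  out$condition <- x$metadata$condition
  out
}
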