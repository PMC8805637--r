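#' Single-cell Raman spectrum collection
#'
#' An `scrs_set` holds one spectrum per cell on a shared, strictly increasing
#' wavenumber axis, together with per-cell metadata and an append-only
#' provenance record of the preprocessing steps applied.
#'
#' @param wavenumbers numeric vector, cm^-1, strictly increasing, finite.
#' @param intensities numeric matrix, one row per cell, `length(wavenumbers)`
#'   columns; all values finite.
#' @param metadata data.frame with one row per cell. Must contain `cell_id`
#'   (unique); columns `sample`, `condition` (`"control"` or `"PEG"`) and
#'   `role` (`"DTB"`, `"DSB"`, `"soil"` or `"unknown"`) are filled with
#'   defaults when absent. Extra columns (e.g. true simulated activity) are
#'   kept as-is.
#' @param provenance character vector of processing steps already applied.
#' @return An object of class `scrs_set`.
#' @examples
#' s <- scrs_set(1:10, matrix(runif(20), 2), data.frame(cell_id = c("a", "b")))
#' n_cells(s)
#' @export
scrs_set <- function(wavenumbers, intensities, metadata,
                     provenance = character()) {
  wavenumbers <- as.numeric(wavenumbers)
  if (is.null(dim(intensities))) {
    intensities <- matrix(intensities, nrow = 1L)
  }
  intensities <- as.matrix(intensities)
  if (anyNA(wavenumbers) || any(!is.finite(wavenumbers))) {
    stop("wavenumbers must be finite")
  }
  if (is.unsorted(wavenumbers, strictly = TRUE)) {
    stop("wavenumbers must be strictly increasing")
  }
  if (ncol(intensities) != length(wavenumbers)) {
    stop("intensities has ", ncol(intensities), " columns but the axis has ",
         length(wavenumbers), " points")
  }
  if (any(!is.finite(intensities))) {
    bad <- which(rowSums(!is.finite(intensities)) > 0L)
    stop("non-finite intensities in cell(s): ",
         paste(metadata$cell_id[bad], collapse = ", "))
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (is.null(metadata$cell_id)) stop("metadata must contain a cell_id column")
  metadata$cell_id <- as.character(metadata$cell_id)
  if (anyDuplicated(metadata$cell_id)) {
    stop("duplicate cell_id: ",
         metadata$cell_id[anyDuplicated(metadata$cell_id)])
  }
  if (nrow(metadata) != nrow(intensities)) {
    stop("metadata has ", nrow(metadata), " rows for ",
         nrow(intensities), " spectra")
  }
  if (is.null(metadata$sample)) metadata$sample <- "sample1"
  if (is.null(metadata$condition)) metadata$condition <- "control"
  if (is.null(metadata$role)) metadata$role <- "unknown"
  if (!all(metadata$condition %in% c("control", "PEG"))) {
    stop("condition must be 'control' or 'PEG'")
  }
  if (!all(metadata$role %in% c("DTB", "DSB", "soil", "unknown"))) {
    stop("role must be one of DTB, DSB, soil, unknown")
  }
  rownames(intensities) <- metadata$cell_id
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         metadata = metadata, provenance = as.character(provenance)),
    class = "scrs_set"
  )
}

#' @export
print.scrs_set <- function(x, ...) {
  cat(sprintf("<scrs_set> %d cells x %d wavenumbers [%g, %g] cm^-1\n",
              n_cells(x), length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  tab <- table(x$metadata$sample, x$metadata$condition)
  print(tab)
  if (length(x$provenance)) {
    cat("processing:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Number of cells in a spectrum set
#' @param x an [scrs_set].
#' @return Integer count of spectra.
#' @export
n_cells <- function(x) {
  stopifnot(inherits(x, "scrs_set"))
  nrow(x$intensities)
}

#' @export
as.matrix.scrs_set <- function(x, ...) {
  m <- x$intensities
  colnames(m) <- x$wavenumbers
  m
}

#' Subset a spectrum set by cell
#' @param x an [scrs_set].
#' @param i cell indices (numeric, logical, or cell_id character).
#' @param ... unused.
#' @return An [scrs_set] with the selected cells.
#' @export
`[.scrs_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$metadata$cell_id)
  scrs_set(x$wavenumbers, x$intensities[i, , drop = FALSE],
           x$metadata[i, , drop = FALSE], x$provenance)
}

record_step <- function(x, step) {
  x$provenance <- c(x$provenance, step)
  x
}

#' Crop spectra to a wavenumber band
#'
#' Keeps axis points with `lower <= wavenumber <= upper` (closed interval).
#' Typically used to restrict phenotype analysis to the 400-1800 cm^-1
#' fingerprint window.
#'
#' @param x an [scrs_set].
#' @param band a [band].
#' @return The cropped [scrs_set].
#' @examples
#' s <- scrs_set(300:3200, matrix(1, 1, 2901), data.frame(cell_id = "a"))
#' length(crop_band(s, default_bands()$fingerprint)$wavenumbers)  # 1401
#' @export
crop_band <- function(x, band) {
  stopifnot(inherits(x, "scrs_set"), inherits(band, "band"))
  keep <- x$wavenumbers >= band$lower & x$wavenumbers <= band$upper
  if (!any(keep)) {
    stop("band ", format(band), " does not overlap the axis [",
         min(x$wavenumbers), ", ", max(x$wavenumbers), "]")
  }
  out <- scrs_set(x$wavenumbers[keep], x$intensities[, keep, drop = FALSE],
                  x$metadata, x$provenance)
  record_step(out, sprintf("crop[%g,%g]", band$lower, band$upper))
}

#' Write spectra to CSV
#'
#' Long format has columns `cell_id, wavenumber, intensity`; wide format has
#' one row per cell (first column `cell_id`, remaining columns named by
#' wavenumber). A commented header line records the generator seed when one
#' is supplied.
#'
#' @param x an [scrs_set].
#' @param path output file.
#' @param format `"long"` or `"wide"`.
#' @param seed optional integer recorded in a `# seed:` comment line.
#' @return `path`, invisibly.
#' @seealso [read_spectra()], [write_metadata()]
#' @export
write_spectra <- function(x, path, format = c("long", "wide"), seed = NULL) {
  stopifnot(inherits(x, "scrs_set"))
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  if (format == "long") {
    df <- data.frame(
      cell_id = rep(x$metadata$cell_id, each = length(x$wavenumbers)),
      wavenumber = rep(x$wavenumbers, times = n_cells(x)),
      intensity = as.vector(t(x$intensities))
    )
    utils::write.csv(df, con, row.names = FALSE)
  } else {
    df <- data.frame(cell_id = x$metadata$cell_id, x$intensities,
                     check.names = FALSE)
    colnames(df) <- c("cell_id", format(x$wavenumbers, trim = TRUE,
                                        scientific = FALSE))
    utils::write.csv(df, con, row.names = FALSE)
  }
  invisible(path)
}

#' Write per-cell metadata as TSV
#' @param x an [scrs_set].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(x, path) {
  stopifnot(inherits(x, "scrs_set"))
  utils::write.table(x$metadata, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read spectra from CSV
#'
#' Inverse of [write_spectra()]. Long rows may arrive in any order; they are
#' sorted by (`cell_id`, `wavenumber`), and cell order follows first
#' appearance in the file. Missing intensities, duplicate
#' (`cell_id`, `wavenumber`) pairs and non-monotone axes are rejected.
#'
#' @param path CSV file written by [write_spectra()] (comment lines starting
#'   with `#` are ignored).
#' @param format `"long"` or `"wide"`.
#' @param metadata optional data.frame (or TSV path) of per-cell metadata to
#'   attach; defaults to bare `cell_id`s.
#' @return An [scrs_set].
#' @export
read_spectra <- function(path, format = c("long", "wide"), metadata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (is.character(metadata) && length(metadata) == 1L) {
    metadata <- utils::read.delim(metadata, stringsAsFactors = FALSE)
  }
  if (format == "long") {
    need <- c("cell_id", "wavenumber", "intensity")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    if (anyNA(df$intensity)) {
      bad <- df[which(is.na(df$intensity))[1L], ]
      stop("NA intensity for cell ", bad$cell_id,
           " at wavenumber ", bad$wavenumber)
    }
    cells <- unique(df$cell_id)
    df <- df[order(match(df$cell_id, cells), df$wavenumber), ]
    if (anyDuplicated(df[c("cell_id", "wavenumber")])) {
      bad <- df[anyDuplicated(df[c("cell_id", "wavenumber")]), ]
      stop("duplicate (cell_id, wavenumber): ", bad$cell_id, ", ",
           bad$wavenumber)
    }
    axis <- sort(unique(df$wavenumber))
    counts <- table(df$cell_id)
    if (any(counts != length(axis))) {
      stop("cells do not share a common axis: ",
           paste(names(counts)[counts != length(axis)], collapse = ", "))
    }
    m <- matrix(df$intensity, nrow = length(cells), byrow = TRUE)
    if (is.null(metadata)) metadata <- data.frame(cell_id = cells)
    scrs_set(axis, m, metadata)
  } else {
    if (names(df)[1L] != "cell_id") stop("missing column(s): cell_id")
    axis <- as.numeric(names(df)[-1L])
    if (anyNA(axis)) stop("wide-format column names must be wavenumbers")
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (anyNA(m)) {
      bad <- which(rowSums(is.na(m)) > 0L)[1L]
      stop("NA intensity for cell ", df$cell_id[bad])
    }
    if (is.null(metadata)) metadata <- data.frame(cell_id = df$cell_id)
    scrs_set(axis, m, metadata)
  }
}
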