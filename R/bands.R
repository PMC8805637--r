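#' Named wavenumber interval
#'
#' A `band` is a closed interval on the Raman-shift axis, used for band
#' integration and cropping. All wavenumbers are in cm^-1 and intervals are
#' closed on both ends.
#'
#' @param name character label, e.g. `"cd"`.
#' @param lower,upper interval bounds in cm^-1, `lower < upper`.
#' @return An object of class `band` with fields `name`, `lower`, `upper`.
#' @examples
#' band("cd", 2040, 2300)
#' @export
band <- function(name, lower, upper) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper) {
    stop("band '", name, "': need finite lower < upper, got [",
         lower, ", ", upper, "]")
  }
  structure(list(name = name, lower = lower, upper = upper), class = "band")
}

#' @export
print.band <- function(x, ...) {
  cat(sprintf("<band> %s: [%g, %g] cm^-1\n", x$name, x$lower, x$upper))
  invisible(x)
}

#' @export
format.band <- function(x, ...) sprintf("%s[%g,%g]", x$name, x$lower, x$upper)

#' Width of a band in cm^-1
#' @param x a [band].
#' @return Numeric width `upper - lower`.
#' @export
band_width <- function(x) {
  stopifnot(inherits(x, "band"))
  x$upper - x$lower
}

#' Standard analysis bands
#'
#' The four wavenumber windows used throughout the deuterium-probing analysis:
#' the C-D stretch band (2040-2300 cm^-1, grows with deuterium incorporation),
#' the C-H stretch band (2800-3100 cm^-1, shrinks as C-H bonds are replaced by
#' C-D), the biologically silent region (2400-2700 cm^-1, background
#' reference), and the biomolecular fingerprint window (400-1800 cm^-1, used
#' for phenotyping).
#'
#' @return Named list of [band] objects: `cd`, `ch`, `silence`, `fingerprint`.
#' @examples
#' default_bands()$cd
#' @export
default_bands <- function() {
  list(
    cd          = band("cd", 2040, 2300),
    ch          = band("ch", 2800, 3100),
    silence     = band("silence", 2400, 2700),
    fingerprint = band("fingerprint", 400, 1800)
  )
}

#' Marker windows for the protein/lipid ratio
#'
#' Symmetric windows around the 1209 cm^-1 protein marker (phenylalanine /
#' tryptophan ring stretch) and the 1267 cm^-1 lipid marker. The half width
#' defaults to 8 cm^-1: the 16 cm^-1 windows cover typical linewidths without
#' overlapping at the 58 cm^-1 marker separation.
#'
#' @param half_width window half width in cm^-1.
#' @return Named list of [band] objects `protein` and `lipid`.
#' @export
marker_bands <- function(half_width = 8) {
  stopifnot(half_width > 0)
  list(
    protein = band("protein_1209", 1209 - half_width, 1209 + half_width),
    lipid   = band("lipid_1267", 1267 - half_width, 1267 + half_width)
  )
}
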