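#' Annular-array transducer specification
#'
#' Spherically curved annular array described by its radius of curvature
#' and the outer aperture diameter of each concentric element. Defaults
#' follow the nominal geometry of a 4-element 500 kHz annular array
#' (radius of curvature 63.2 mm; outer apertures 32.8, 46, 55.9, 64 mm).
#' Only outer apertures are specified; the inner edge of element k sits a
#' configurable kerf beyond the outer edge of element k-1.
#'
#' @param roc_mm Radius of curvature in mm.
#' @param element_outer_diameters_mm Strictly increasing outer diameters
#'   (mm); the largest must not exceed `2 * roc_mm`.
#' @param frequency_hz Drive frequency (Hz).
#' @param element_phases Per-element phase offsets in radians (default all
#'   zero: focus at the geometric centre of curvature).
#' @param kerf_mm Radial gap between adjacent elements (mm).
#' @param source_amplitude Surface velocity amplitude (arbitrary units).
#' @return A `transducer_spec`.
#' @export
transducer_spec <- function(roc_mm = 63.2,
                            element_outer_diameters_mm = c(32.8, 46, 55.9, 64),
                            frequency_hz = 500e3,
                            element_phases = NULL,
                            kerf_mm = 0.5,
                            source_amplitude = 1) {
  d <- element_outer_diameters_mm
  if (any(diff(d) <= 0)) stop("element diameters must be strictly increasing")
  if (max(d) > 2 * roc_mm) stop("largest aperture exceeds 2 * radius of curvature")
  if (is.null(element_phases)) element_phases <- rep(0, length(d))
  if (length(element_phases) != length(d))
    stop("one phase per element required")
  structure(list(roc_mm = roc_mm, element_outer_diameters_mm = d,
                 frequency_hz = frequency_hz, element_phases = element_phases,
                 kerf_mm = kerf_mm, source_amplitude = source_amplitude),
            class = "transducer_spec")
}

#' @export
print.transducer_spec <- function(x, ...) {
  cat(sprintf(
    "<transducer_spec> %d-element annular array, ROC %.1f mm, apertures %s mm, %.0f kHz\n",
    length(x$element_outer_diameters_mm), x$roc_mm,
    paste(x$element_outer_diameters_mm, collapse = "/"),
    x$frequency_hz / 1e3))
  invisible(x)
}

# Radial bands [inner, outer] (mm) occupied by each element in the aperture
# plane; element 1 is a disc, later elements are annuli separated by kerf.
element_bands <- function(transducer) {
  a <- transducer$element_outer_diameters_mm / 2
  inner <- c(0, utils::head(a, -1) + transducer$kerf_mm)
  cbind(inner = inner, outer = a)
}
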