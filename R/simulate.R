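#' Sample the annular array as a 2D arc source
#'
#' Cross-section of the spherically curved array in a plane through its
#' axis: an arc of radius `roc_mm` centred on the focus, with gaps where
#' the element kerfs fall. The beam axis runs along +v (second plane
#' coordinate); the bowl apex sits at `focus - (0, roc)`. Arc samples are
#' deposited onto the nearest grid cell with arc-length weights.
#'
#' @param transducer A [transducer_spec()].
#' @param focus_uv_mm Length-2 focus position in plane coordinates (mm).
#' @param spacing_mm Grid spacing of the target 2D grid (mm).
#' @param grid_dim Length-2 grid dimensions.
#' @param origin_mm Length-2 world position of grid cell (1,1).
#' @return List with `idx` (two-column matrix of grid indices) and `amp`
#'   (complex amplitudes).
#' @export
arc_source_2d <- function(transducer, focus_uv_mm, spacing_mm, grid_dim,
                          origin_mm = c(0, 0)) {
  R <- transducer$roc_mm
  bands <- element_bands(transducer)
  theta_max <- asin(min(max(bands[, "outer"]) / R, 1))
  dtheta <- (spacing_mm / 2) / R
  theta <- seq(-theta_max, theta_max, by = dtheta)
  r_lat <- R * sin(abs(theta))
  el <- rep(NA_integer_, length(theta))
  for (e in seq_len(nrow(bands)))
    el[r_lat >= bands[e, "inner"] & r_lat <= bands[e, "outer"]] <- e
  keep <- !is.na(el)
  theta <- theta[keep]; el <- el[keep]
  u <- focus_uv_mm[1] + R * sin(theta)
  v <- focus_uv_mm[2] - R * cos(theta)
  i <- round((u - origin_mm[1]) / spacing_mm) + 1L
  j <- round((v - origin_mm[2]) / spacing_mm) + 1L
  ok <- i >= 1 & i <= grid_dim[1] & j >= 1 & j <= grid_dim[2]
  if (!all(ok)) stop("transducer arc does not fit inside the 2D grid")
  amp <- transducer$source_amplitude * R * dtheta *
    exp(1i * transducer$element_phases[el])
  lin <- paste(i, j)
  agg <- rowsum(cbind(Re(amp), Im(amp)), lin)
  ij <- do.call(rbind, lapply(strsplit(rownames(agg), " "), as.integer))
  list(idx = ij, amp = complex(real = agg[, 1], imaginary = agg[, 2]))
}

#' Simulate the array field on a 2D medium slice
#'
#' Builds the in-plane arc source for the array focused at `focus_uv_mm`
#' (beam along +v) and runs the continuous-wave Helmholtz solver.
#'
#' @param medium A [medium_slice_2d()].
#' @param transducer A [transducer_spec()].
#' @param focus_uv_mm Focus position in the slice's world coordinates (mm).
#' @param pml_cells PML thickness.
#' @return A `pressure_field_2d`.
#' @export
simulate_field_2d <- function(medium, transducer, focus_uv_mm,
                              pml_cells = 16) {
  src <- arc_source_2d(transducer, focus_uv_mm, medium$spacing,
                       dim(medium$c), medium$origin)
  cw_steady_state_2d(medium, src$idx, src$amp, transducer$frequency_hz,
                     pml_cells = pml_cells)
}

#' Simulation configuration and dispatch
#'
#' A single entry point over the available backends: `internal2d` (the
#' heterogeneous 2D Helmholtz solver), `rayleigh` (homogeneous water via
#' the Rayleigh integral), and `external` (writes an exchange bundle for a
#' full-wave 3D solver and re-imports its output; never falls back
#' silently).
#'
#' @param transducer A [transducer_spec()].
#' @param backend One of `"internal2d"`, `"rayleigh"`, `"external"`.
#' @param medium A [medium_slice_2d()] (internal2d backend).
#' @param focus_uv_mm Focus position for the 2D backend (mm).
#' @param field_points_mm n x 3 matrix of field points (rayleigh backend).
#' @param c_water Water sound speed (m/s).
#' @param exchange_dir,import_path External-backend bundle directory and
#'   (optional) path of the externally computed amplitude volume.
#' @param pml_cells PML thickness for the internal solver.
#' @return A `sim_config`.
#' @export
sim_config <- function(transducer, backend = c("internal2d", "rayleigh",
                                               "external"),
                       medium = NULL, focus_uv_mm = NULL,
                       field_points_mm = NULL, c_water = 1500,
                       exchange_dir = NULL, import_path = NULL,
                       pml_cells = 16) {
  backend <- match.arg(backend)
  structure(list(transducer = transducer, backend = backend, medium = medium,
                 focus_uv_mm = focus_uv_mm, field_points_mm = field_points_mm,
                 c_water = c_water, exchange_dir = exchange_dir,
                 import_path = import_path, pml_cells = pml_cells),
            class = "sim_config")
}

#' @rdname sim_config
#' @param config A `sim_config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  switch(config$backend,
    internal2d = {
      if (is.null(config$medium) || is.null(config$focus_uv_mm))
        stop("internal2d backend needs `medium` and `focus_uv_mm`")
      simulate_field_2d(config$medium, config$transducer,
                        config$focus_uv_mm, config$pml_cells)
    },
    rayleigh = {
      if (is.null(config$field_points_mm))
        stop("rayleigh backend needs `field_points_mm`")
      rayleigh_pressure(config$transducer, config$field_points_mm,
                        c = config$c_water)
    },
    external = {
      if (is.null(config$exchange_dir))
        stop("external backend needs `exchange_dir`")
      write_exchange_bundle(config, config$exchange_dir)
      if (is.null(config$import_path) || !file.exists(config$import_path))
        stop("external backend unavailable: no imported field at ",
             if (is.null(config$import_path)) "<unset>" else config$import_path,
             "; bundle written to ", config$exchange_dir)
      read_volume(config$import_path, kind = "pressure")
    })
}

#' Fields on which two simulation configs differ
#'
#' Used to assert that paired CT-vs-pseudo-CT runs differ only in the
#' medium maps.
#'
#' @param a,b `sim_config` objects.
#' @return Character vector of differing top-level fields.
#' @export
config_diff_fields <- function(a, b) {
  keys <- union(names(a), names(b))
  keys[!vapply(keys, function(k) identical(a[[k]], b[[k]]), TRUE)]
}

# Exchange bundle for an external full-wave backend: medium maps as NIfTI,
# source point samples as CSV (position, normal, phase, weight), grid spec
# as JSON.
write_exchange_bundle <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- config$transducer
  src <- sample_bowl_source(tr, c = config$c_water)
  nrm <- sweep(cbind(0, 0, tr$roc_mm)[rep(1, nrow(src$points)), ] - src$points,
               1, tr$roc_mm, "/")
  utils::write.csv(
    data.frame(x_mm = src$points[, 1], y_mm = src$points[, 2],
               z_mm = src$points[, 3],
               nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
               phase_rad = src$phases, weight_mm2 = src$weights),
    file.path(dir, "source_points.csv"), row.names = FALSE)
  if (!is.null(config$medium)) {
    m <- config$medium
    for (f in c("c", "rho", "alpha")) {
      v <- volume(array(m[[f]], c(dim(m$c), 1L)), m$spacing, c(m$origin, 0),
                  kind = "arbitrary")
      write_volume(v, file.path(dir, paste0("medium_", f, ".nii.gz")))
    }
  }
  jsonlite::write_json(
    list(frequency_hz = tr$frequency_hz, roc_mm = tr$roc_mm,
         element_outer_diameters_mm = tr$element_outer_diameters_mm,
         kerf_mm = tr$kerf_mm, c_water = config$c_water,
         focus_uv_mm = config$focus_uv_mm,
         spacing_mm = if (!is.null(config$medium)) config$medium$spacing),
    file.path(dir, "grid_spec.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
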