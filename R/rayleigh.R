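#' O'Neil on-axis solution for a focused bowl
#'
#' Closed-form continuous-wave on-axis pressure of a solid spherical-cap
#' radiator of uniform normal velocity in a homogeneous lossless medium.
#' With the bowl apex at axial position 0 and the geometric focus at the
#' radius of curvature, the on-axis complex pressure is
#' `p(z) = rho c u0 * R/(R - z) * (exp(i k r_b) - exp(i k z))`, where
#' `r_b(z)` is the distance from the axial point to the bowl rim; the
#' removable singularity at the focus is evaluated by its analytic limit.
#'
#' @param roc_mm Radius of curvature (mm).
#' @param aperture_mm Outer aperture diameter (mm), `< 2 * roc_mm`.
#' @param freq Frequency (Hz).
#' @param c Sound speed (m/s).
#' @param axial_positions_mm Axial positions z (mm, from the bowl apex).
#' @param rho Density (kg/m^3).
#' @param u0 Surface velocity amplitude.
#' @return Complex pressures at the requested positions.
#' @export
oneil_axial_bowl <- function(roc_mm, aperture_mm, freq, c = 1500,
                             axial_positions_mm, rho = 1000, u0 = 1) {
  if (aperture_mm >= 2 * roc_mm) stop("aperture must be below 2 * ROC")
  R <- roc_mm / 1000
  a <- aperture_mm / 2000
  z <- axial_positions_mm / 1000
  k <- 2 * pi * freq / c
  h <- R - sqrt(R^2 - a^2)
  rb <- sqrt((z - h)^2 + a^2)
  p <- complex(length.out = length(z))
  near <- abs(R - z) < 1e-9
  p[!near] <- rho * c * u0 * R / (R - z[!near]) *
    (exp(1i * k * rb[!near]) - exp(1i * k * z[!near]))
  if (any(near))
    p[near] <- rho * c * u0 * 1i * k * h * exp(1i * k * z[near])
  p
}

#' Point-sample the annular-array bowl surface
#'
#' Deterministic ring sampling of the spherical cap at (at least) the
#' requested points-per-wavelength density, keeping only surface points
#' within the element bands (annular gaps excluded). Rings use an even
#' number of azimuthal samples so the point set is mirror-symmetric about
#' both lateral axes. The bowl apex is at the origin with the axis along
#' +z and the geometric focus at `(0, 0, roc_mm)`.
#'
#' @param transducer A [transducer_spec()].
#' @param c Sound speed used to set the wavelength (m/s).
#' @param ppw Surface points per wavelength (>= 4; default 6).
#' @return List with `points` (n x 3 matrix, mm), `weights` (areas, mm^2),
#'   `phases` (radians).
#' @export
sample_bowl_source <- function(transducer, c = 1500, ppw = 6) {
  if (ppw < 4) stop("under-sampled source: need at least 4 points per wavelength")
  lambda_mm <- c / transducer$frequency_hz * 1000
  delta <- lambda_mm / ppw
  R <- transducer$roc_mm
  bands <- element_bands(transducer)
  theta_max <- asin(min(max(bands[, "outer"]) / R, 1))
  n_theta <- max(2L, ceiling(R * theta_max / delta))
  dtheta <- theta_max / n_theta
  pts <- list(); wts <- list(); phs <- list()
  for (j in seq_len(n_theta)) {
    th <- (j - 0.5) * dtheta
    r_ring <- R * sin(th)
    el <- which(r_ring >= bands[, "inner"] & r_ring <= bands[, "outer"])
    if (length(el) == 0L) next
    n_phi <- max(4L, 2L * ceiling(pi * R * sin(th) / delta))
    phi <- (seq_len(n_phi) - 1) * 2 * pi / n_phi
    ring <- cbind(R * sin(th) * cos(phi),
                  R * sin(th) * sin(phi),
                  R - R * cos(th))
    pts[[length(pts) + 1L]] <- ring
    wts[[length(wts) + 1L]] <- rep(R^2 * sin(th) * dtheta * 2 * pi / n_phi, n_phi)
    phs[[length(phs) + 1L]] <- rep(transducer$element_phases[el[1]], n_phi)
  }
  if (length(pts) == 0L) stop("no source points generated")
  list(points = do.call(rbind, pts), weights = unlist(wts),
       phases = unlist(phs))
}

#' Rayleigh-Sommerfeld pressure of the annular array in water
#'
#' Continuous-wave Rayleigh integral over the point-sampled bowl surface:
#' `p(r) = i rho c k u0 / (2 pi) * sum_j w_j exp(i (k R_j + phi_j)) / R_j`.
#' Deterministic for a given sampling density.
#'
#' @param transducer A [transducer_spec()].
#' @param field_points_mm n x 3 matrix of field positions (mm, same frame
#'   as [sample_bowl_source()]).
#' @param c,rho Medium sound speed (m/s) and density (kg/m^3).
#' @param ppw Source surface sampling density (points per wavelength).
#' @param source Optional precomputed source sampling (from
#'   [sample_bowl_source()]).
#' @return Complex pressures at the field points.
#' @export
rayleigh_pressure <- function(transducer, field_points_mm, c = 1500,
                              rho = 1000, ppw = 6, source = NULL) {
  if (is.null(source)) source <- sample_bowl_source(transducer, c, ppw)
  k <- 2 * pi * transducer$frequency_hz / c / 1000  # rad per mm
  sp <- source$points
  amp <- source$weights * exp(1i * source$phases)
  pref <- 1i * rho * c * (2 * pi * transducer$frequency_hz / c) *
    transducer$source_amplitude / (2 * pi) * 1e-6  # weights in mm^2 -> m^2
  fp <- as.matrix(field_points_mm)
  out <- complex(length.out = nrow(fp))
  chunk <- max(1L, floor(2e6 / nrow(sp)))
  for (s in seq(1L, nrow(fp), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(fp))
    dx <- outer(fp[s:e, 1], sp[, 1], "-")
    dy <- outer(fp[s:e, 2], sp[, 2], "-")
    dz <- outer(fp[s:e, 3], sp[, 3], "-")
    Rm <- sqrt(dx^2 + dy^2 + dz^2)  # mm
    out[s:e] <- (exp(1i * k * Rm) / (Rm / 1000)) %*% amp
  }
  pref * out
}

#' Free-field focal dimensions of the annular array
#'
#' Computes the water-path continuous-wave field of the array via the
#' Rayleigh integral and measures the -6 dB (half-maximum pressure) focal
#' dimensions: the full width through the focus perpendicular to the beam
#' axis and the extent along the axis. Crossings are located by linear
#' interpolation of the amplitude profiles.
#'
#' @param transducer A [transducer_spec()].
#' @param c Water sound speed (m/s).
#' @param ppw Source sampling density.
#' @param axial_step_mm,lateral_step_mm Profile sampling steps (mm).
#' @return List with `width_mm`, `length_mm`, `focus_z_mm`,
#'   `peak_amplitude`, and the sampled `axial` / `lateral` profiles.
#' @export
free_field_focus <- function(transducer, c = 1500, ppw = 6,
                             axial_step_mm = 0.1, lateral_step_mm = 0.05) {
  src <- sample_bowl_source(transducer, c, ppw)
  z <- seq(0.3 * transducer$roc_mm, 1.8 * transducer$roc_mm, by = axial_step_mm)
  ax <- abs(rayleigh_pressure(transducer, cbind(0, 0, z), c, source = src))
  iz <- which.max(ax)
  zf <- z[iz]
  x <- seq(-8, 8, by = lateral_step_mm)
  lat <- abs(rayleigh_pressure(transducer, cbind(x, 0, zf), c, source = src))
  width <- half_max_extent(x, lat)
  len <- half_max_extent(z, ax)
  list(width_mm = width, length_mm = len, focus_z_mm = zf,
       peak_amplitude = max(ax),
       axial = data.frame(z_mm = z, amplitude = ax),
       lateral = data.frame(x_mm = x, amplitude = lat))
}

# Full width of the region where profile >= half its maximum, with linear
# interpolation at the crossings around the global peak.
half_max_extent <- function(pos, amp) {
  ipk <- which.max(amp)
  half <- amp[ipk] / 2
  lo <- ipk
  while (lo > 1 && amp[lo - 1] >= half) lo <- lo - 1
  hi <- ipk
  while (hi < length(amp) && amp[hi + 1] >= half) hi <- hi + 1
  left <- if (lo == 1) pos[1] else {
    stats::approx(amp[c(lo - 1, lo)], pos[c(lo - 1, lo)], xout = half)$y
  }
  right <- if (hi == length(amp)) pos[hi] else {
    stats::approx(amp[c(hi + 1, hi)], pos[c(hi + 1, hi)], xout = half)$y
  }
  right - left
}
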