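#' Piecewise-linear CT number to mass density conversion
#'
#' Monotone non-decreasing map from Hounsfield units to mass density
#' (kg/m^3) through standard tissue anchor points: air (1.2 kg/m^3 at
#' -1000 HU), fat (about 930 at -98), soft tissue (about 1030 at 14),
#' the soft-tissue/bone transition (about 1119 at 120), and cranial bone
#' (about 1975 at 1600 HU, 2800 at 3000 HU). Inputs outside
#' \[-1024, 3000\] are clamped with a warning.
#'
#' @param hu Numeric vector or array of CT numbers.
#' @return Densities in kg/m^3, same shape as `hu`.
#' @export
hu_to_density <- function(hu) {
  if (any(hu < -1024 | hu > 3000, na.rm = TRUE)) {
    warning("HU values outside [-1024, 3000] clamped before conversion")
    hu <- pmin(pmax(hu, -1024), 3000)
  }
  bp_hu <- c(-1024, -1000, -98, 14, 120, 1600, 3000)
  bp_rho <- c(1.2, 1.2, 930, 1030, 1119, 1975, 2800)
  out <- stats::approx(bp_hu, bp_rho, xout = as.vector(hu), rule = 2)$y
  if (!is.null(dim(hu))) dim(out) <- dim(hu)
  out
}

#' Density to sound speed within the skull
#'
#' Applies the linear skull relationship `c = 1.33 * rho + 167` (sound
#' speed in m/s, density in kg/m^3). When a skull mask is given, voxels
#' outside it keep the supplied soft-tissue reference speed.
#'
#' @param density Densities in kg/m^3 (vector or array).
#' @param skull_mask Optional logical array selecting skull voxels.
#' @param soft_tissue_c Reference sound speed outside the skull (m/s).
#' @return Sound speeds in m/s, same shape as `density`.
#' @export
density_to_sound_speed <- function(density, skull_mask = NULL,
                                   soft_tissue_c = 1500) {
  if (any(density < 0, na.rm = TRUE)) stop("density must be non-negative")
  c_skull <- 1.33 * density + 167
  if (is.null(skull_mask)) return(c_skull)
  sel <- if (inherits(skull_mask, "skull_mask")) skull_mask$data else skull_mask
  out <- array(soft_tissue_c, dim(density))
  out[sel] <- c_skull[sel]
  out
}

#' Four-class tissue segmentation of a CT-like head volume
#'
#' Labels each voxel background (0), skin (1), brain (2), or skull (3).
#' Skull is bone-threshold HU within the head, closed (radius 1) and
#' hole-filled; brain is the interior soft tissue enclosed by the skull;
#' skin is the remaining head tissue.
#'
#' @param ct `skull_volume` in HU.
#' @param head_mask Head `skull_mask`.
#' @param bone_threshold_hu Bone threshold (default 300 HU).
#' @return Integer label array with attribute `"labels"`.
#' @export
segment_tissues <- function(ct, head_mask, bone_threshold_hu = 300) {
  stopifnot_aligned(ct, head_mask)
  d <- dim(ct$data)
  skull <- ct$data > bone_threshold_hu & head_mask$data
  # radius-1 closing bridges thin through-thickness gaps (e.g. low-HU
  # diploe) without filling the cranial cavity
  if (any(skull)) skull <- binary_close(skull, radius = 1) & head_mask$data
  # brain: soft tissue enclosed by the skull = head components not reaching
  # the skull's outside
  soft <- head_mask$data & !skull
  lab <- array(0L, d)
  if (any(skull)) {
    interior <- enclosed_interior(skull, head_mask$data)
    if (!any(interior)) stop("no enclosed interior found inside the skull")
    brain <- soft & interior
  } else {
    stop("no enclosed interior found: no skull voxels above threshold")
  }
  lab[head_mask$data] <- 1L              # skin by default
  lab[brain] <- 2L
  lab[skull] <- 3L
  attr(lab, "labels") <- c(background = 0L, skin = 1L, brain = 2L, skull = 3L)
  lab
}

# Voxels strictly inside the closed skull shell: flood the complement of the
# skull from the grid boundary (6-connectivity); whatever is not reached and
# not skull is interior.
enclosed_interior <- function(skull, head) {
  free <- !skull
  free & !flood_from_border(free)
}

#' Acoustic medium property maps
#'
#' Converts a CT/pseudo-CT volume into co-registered sound-speed, density,
#' and attenuation maps plus the tissue label map. Within the skull, density
#' follows [hu_to_density()] and sound speed [density_to_sound_speed()];
#' soft tissue and background receive the reference values; skull
#' attenuation is a single constant.
#'
#' @param ct `skull_volume` in HU.
#' @param head_mask Head `skull_mask`.
#' @param reference List of reference properties:
#'   `water_c`, `water_rho`, `water_alpha`; optional `skin_c`, `skin_rho`,
#'   `brain_c`, `brain_rho` (default water-like); `skull_alpha`
#'   (dB/MHz/cm, default 8); `bone_threshold_hu` (default 300).
#' @return A `medium_maps` list: `sound_speed`, `density`, `attenuation`
#'   (3D arrays), `label_map`, `spacing`.
#' @export
build_medium <- function(ct, head_mask, reference = medium_reference()) {
  ref <- utils::modifyList(medium_reference(), reference)
  lab <- segment_tissues(ct, head_mask, ref$bone_threshold_hu)
  d <- dim(ct$data)
  rho <- array(ref$water_rho, d)
  cc <- array(ref$water_c, d)
  alpha <- array(ref$water_alpha, d)
  rho[lab == 1L] <- ref$skin_rho
  cc[lab == 1L] <- ref$skin_c
  rho[lab == 2L] <- ref$brain_rho
  cc[lab == 2L] <- ref$brain_c
  sk <- lab == 3L
  rho[sk] <- hu_to_density(pmax(ct$data[sk], ref$bone_threshold_hu))
  cc[sk] <- 1.33 * rho[sk] + 167
  alpha[sk] <- ref$skull_alpha
  structure(list(sound_speed = cc, density = rho, attenuation = alpha,
                 label_map = lab, spacing = ct$spacing, origin = ct$origin),
            class = "medium_maps")
}

#' Default reference acoustic properties
#'
#' Water/background, skin and brain default to water-like values
#' (c = 1500 m/s, rho = 1000 kg/m^3, lossless); skull attenuation defaults
#' to 8 dB/MHz/cm. All values are configurable assumptions.
#' @return Named list of reference properties.
#' @export
medium_reference <- function() {
  list(water_c = 1500, water_rho = 1000, water_alpha = 0,
       skin_c = 1500, skin_rho = 1000,
       brain_c = 1500, brain_rho = 1000,
       skull_alpha = 8, bone_threshold_hu = 300)
}
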