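#' Synthetic head-phantom specification
#'
#' Describes a layered ellipsoidal head phantom: an outer skin/scalp
#' ellipsoid, a skull shell (outer table / diploe / inner table HU profile,
#' optionally with smoothly varying thickness peaking posteriorly, mimicking
#' the occipital protuberance), and an interior brain compartment. The
#' paired ZTE-like image is synthesised so that bone intensity is exactly
#' linear in HU under `zte_mapping`, soft tissue sits near 1, and air near
#' 0; the T1w-like image has structured soft tissue and signal-poor bone.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param voxel_spacing_mm Isotropic voxel spacing in mm.
#' @param head_radii_mm Ellipsoid semi-axes (x = left-right,
#'   y = anterior-posterior, z = inferior-superior) in mm.
#' @param skull_thickness_mm Length-2: mean shell thickness and the
#'   amplitude of its smooth directional variation, in mm.
#' @param skull_hu_profile Length-2: peak cortical HU and diploe HU dip.
#' @param skull_density_variation Fractional amplitude of a smooth, seeded,
#'   subject-specific modulation of the bone HU profile (default 0.12).
#'   Real skulls vary in mineral density in ways not predictable from the
#'   head shape; this field carries that information into the CT and (via
#'   the linear bone mapping) the ZTE, but not the T1w, mirroring the bone
#'   contrast available to each modality. The default keeps the modulated
#'   HU range inside the classical conversion's fixed bone band.
#' @param soft_tissue_hu Soft-tissue HU (default 42).
#' @param air_hu Air HU (default -1000).
#' @param skin_thickness_mm Scalp thickness between skin surface and outer
#'   skull table, in mm.
#' @param zte_mapping [hu_mapping()] used to synthesise ZTE from CT in bone.
#' @param noise_sd Named list of additive Gaussian noise SDs per modality
#'   (`ct` in HU, `zte` and `t1w` in normalised units).
#' @param bias_amplitude Peak fractional deviation of the optional
#'   multiplicative bias field (0 disables it).
#' @param seed Integer RNG seed; identical specs and seeds give
#'   bit-identical phantoms.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(192, 224, 208),
                         voxel_spacing_mm = 1.0,
                         head_radii_mm = c(70, 90, 80),
                         skull_thickness_mm = c(6, 2),
                         skull_hu_profile = c(cortical = 1700, diploe = 900),
                         skull_density_variation = 0.12,
                         soft_tissue_hu = 42,
                         air_hu = -1000,
                         skin_thickness_mm = 5,
                         zte_mapping = hu_mapping(-2085, 2329),
                         noise_sd = list(ct = 20, zte = 0.015, t1w = 0.03),
                         bias_amplitude = 0,
                         seed = 1L) {
  if (any(head_radii_mm <= 0)) stop("head radii must be positive")
  if (skull_thickness_mm[1] <= 0) stop("mean skull thickness must be positive")
  if (length(skull_thickness_mm) == 1L) skull_thickness_mm <- c(skull_thickness_mm, 0)
  if (bias_amplitude < 0) stop("bias amplitude must be non-negative")
  if (skull_density_variation < 0 || skull_density_variation >= 1)
    stop("skull_density_variation must be in [0, 1)")
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_spacing_mm = voxel_spacing_mm,
               head_radii_mm = head_radii_mm,
               skull_thickness_mm = skull_thickness_mm,
               skull_hu_profile = skull_hu_profile,
               skull_density_variation = skull_density_variation,
               soft_tissue_hu = soft_tissue_hu, air_hu = air_hu,
               skin_thickness_mm = skin_thickness_mm,
               zte_mapping = zte_mapping, noise_sd = noise_sd,
               bias_amplitude = bias_amplitude, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  check_phantom_fits(spec)
  spec
}

check_phantom_fits <- function(spec) {
  need <- 2 * spec$head_radii_mm + 20 * spec$voxel_spacing_mm
  have <- (spec$grid_shape - 1) * spec$voxel_spacing_mm
  if (any(need > have))
    stop("grid too small for head: need a 10-voxel margin around the head ",
         "on every axis")
  invisible(TRUE)
}

# Evaluate an expression with a locally-seeded RNG, restoring global state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Per-axis squared normalised coordinates summed into a 3D array.
ellipsoid_u2 <- function(coords, centre, radii) {
  v <- lapply(1:3, function(a) ((coords[[a]] - centre[a]) / radii[a])^2)
  outer(outer(v[[1]], v[[2]], "+"), v[[3]], "+")
}

#' Generate a synthetic CT head phantom with masks
#'
#' Builds concentric ellipsoidal air/skin/skull/brain layers. Skull voxels
#' carry a through-thickness HU profile that peaks at the cortical tables
#' and dips to the diploe HU at mid-depth, so every noiseless skull HU lies
#' in `[diploe, cortical]`. Masks are consistent by construction
#' (skull and brain inside head, mutually disjoint).
#'
#' @param spec A [phantom_spec()].
#' @return List with `ct` (`skull_volume`, HU), and `head`, `skull`, `brain`
#'   masks (`skull_mask`).
#' @export
generate_ct_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  check_phantom_fits(spec)
  d <- spec$grid_shape; h <- spec$voxel_spacing_mm
  coords <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * h)
  centre <- vapply(coords, function(v) mean(range(v)), 0)
  a <- spec$head_radii_mm
  skin <- spec$skin_thickness_mm
  t0 <- spec$skull_thickness_mm[1]; tamp <- spec$skull_thickness_mm[2]

  u_head <- ellipsoid_u2(coords, centre, a)
  head <- u_head <= 1
  uo2 <- ellipsoid_u2(coords, centre, a - skin)
  outer_in <- uo2 <= 1

  if (tamp > 0) {
    # thickness peaks on the posterior (-y) side: t = t0 + tamp*(1 - uy)/2
    dy <- coords[[2]] - centre[2]
    r2 <- ellipsoid_u2(coords, centre, c(1, 1, 1))  # squared distance (mm^2)
    r <- sqrt(pmax(r2, 1e-12))
    uy <- sweep(array(0, d), 2, dy, "+") / r
    tdir <- t0 + tamp * (1 - uy) / 2
    rm(r2, r, uy)
  } else {
    tdir <- t0
  }
  ai <- lapply(1:3, function(axi) a[axi] - skin - tdir)
  vsq <- function(axi) {
    off2 <- (coords[[axi]] - centre[axi])^2
    arr <- if (is.array(ai[[axi]])) ai[[axi]] else array(ai[[axi]], d)
    sweep(array(0, d), axi, off2, "+") / arr^2
  }
  ui2 <- vsq(1) + vsq(2) + vsq(3)
  inner_in <- ui2 <= 1

  skull <- outer_in & !inner_in
  brain <- inner_in
  # through-thickness depth fraction: 0 at outer table, 1 at inner table
  uo <- sqrt(pmax(uo2, 0)); ui <- sqrt(pmax(ui2, 0))
  s <- (1 - uo) / pmax((1 - uo) + (ui - 1), 1e-9)
  s <- pmin(pmax(s, 0), 1)

  cort <- spec$skull_hu_profile[[1]]; dipl <- spec$skull_hu_profile[[2]]
  hu <- array(spec$air_hu, d)
  hu[head] <- spec$soft_tissue_hu
  profile <- dipl + (cort - dipl) * cos(pi * s[skull])^2
  v <- spec$skull_density_variation
  if (v > 0) {
    # smooth subject-specific mineral-density modulation of the bone HU
    g <- with_seed(spec$seed + 500L, {
      ph <- stats::runif(3, 0, 2 * pi)
      wl <- stats::runif(3, 30, 80)
      gx <- cos(2 * pi * coords[[1]] / wl[1] + ph[1])
      gy <- cos(2 * pi * coords[[2]] / wl[2] + ph[2])
      gz <- cos(2 * pi * coords[[3]] / wl[3] + ph[3])
      outer(outer(gx, gy, "+"), gz, "+")
    })
    g <- g / max(abs(g))
    profile <- profile * (1 + v * g[skull])
  }
  hu[skull] <- profile

  sd_ct <- spec$noise_sd$ct
  hu_ceiling <- cort * (1 + v)
  if (sd_ct > 0) {
    hu <- hu + with_seed(spec$seed, array(stats::rnorm(prod(d), 0, sd_ct), d))
    hu <- pmin(hu, hu_ceiling + 3 * sd_ct)
  }
  list(ct = volume(hu, h, kind = "HU"),
       head = mask_volume(head, h),
       skull = mask_volume(skull, h),
       brain = mask_volume(brain, h))
}

#' Synthesise a normalised ZTE-like volume from a CT phantom
#'
#' Inverts the classical linear bone mapping so that, with zero noise, the
#' classical conversion applied to the synthetic ZTE returns the bone HU
#' exactly. Soft tissue is set to 1 (the soft-tissue peak the classical
#' normalisation looks for) and air outside the head to 0.
#'
#' @param ct CT `skull_volume` in HU.
#' @param skull_mask,head_mask Aligned `skull_mask` objects.
#' @param mapping [hu_mapping()] with non-zero slope.
#' @param noise_sd Additive Gaussian noise SD (normalised units).
#' @param seed RNG seed.
#' @return `skull_volume` of kind `MR_normalised`.
#' @export
generate_zte_from_ct <- function(ct, skull_mask, head_mask,
                                 mapping = hu_mapping(-2085, 2329),
                                 noise_sd = 0, seed = 1L) {
  stopifnot_aligned(ct, skull_mask); stopifnot_aligned(ct, head_mask)
  if (mapping$slope == 0) stop("degenerate mapping: slope must be non-zero")
  d <- dim(ct$data)
  z <- array(0, d)
  z[head_mask$data] <- 1
  sk <- skull_mask$data
  z[sk] <- (ct$data[sk] - mapping$intercept) / mapping$slope
  if (noise_sd > 0)
    z <- z + with_seed(seed, array(stats::rnorm(prod(d), 0, noise_sd), d))
  volume(z, ct$spacing, ct$origin, kind = "MR_normalised")
}

#' Synthesise a T1w-like volume from a CT phantom
#'
#' Soft tissue receives a smooth, structured intensity pattern (low-order
#' cosine modes); bone is dark with intensity essentially uncorrelated with
#' HU, emulating the poor bone contrast of T1-weighted imaging.
#'
#' @param ct CT `skull_volume`.
#' @param masks List with `head`, `skull` masks (as from
#'   [generate_ct_phantom()]).
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed RNG seed.
#' @return `skull_volume` of kind `MR_raw`.
#' @export
generate_t1w_from_ct <- function(ct, masks, noise_sd = 0.03, seed = 1L) {
  stopifnot_aligned(ct, masks$head); stopifnot_aligned(ct, masks$skull)
  d <- dim(ct$data); h <- ct$spacing
  coords <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * h[a])
  with_seed(seed + 1L, {
    ph <- stats::runif(6, 0, 2 * pi)
    wl <- stats::runif(3, 40, 80)  # mm wavelengths of the structure
    sx <- sin(2 * pi * coords[[1]] / wl[1] + ph[1])
    sy <- sin(2 * pi * coords[[2]] / wl[2] + ph[2])
    sz <- cos(2 * pi * coords[[3]] / wl[3] + ph[3])
    struct <- outer(outer(sx, sy, "+"), sz, "+") / 3
    t1 <- array(0, d)
    soft <- masks$head$data & !masks$skull$data
    t1[soft] <- 1 + 0.3 * struct[soft]
    t1[masks$skull$data] <- 0.12
    if (noise_sd > 0) t1 <- t1 + array(stats::rnorm(prod(d), 0, noise_sd), d)
    volume(t1, ct$spacing, ct$origin, kind = "MR_raw")
  })
}

#' Apply a smooth multiplicative bias field
#'
#' Emulates the intensity non-uniformity that bias-field correction removes
#' in real MR data. The generated field has mean exactly 1 over the head
#' mask and a peak fractional deviation of at most `amplitude`.
#'
#' @param vol `skull_volume` to modulate.
#' @param amplitude Peak fractional deviation (>= 0); 0 is the identity.
#' @param seed RNG seed.
#' @param head_mask Optional `skull_mask` over which the field mean is
#'   constrained to 1 (defaults to the whole grid).
#' @return Modulated `skull_volume`.
#' @export
apply_bias_field <- function(vol, amplitude, seed = 1L, head_mask = NULL) {
  if (amplitude < 0) stop("bias amplitude must be non-negative")
  if (amplitude == 0) return(vol)
  d <- dim(vol$data)
  sel <- if (is.null(head_mask)) array(TRUE, d) else head_mask$data
  coords <- lapply(1:3, function(a) seq(0, 1, length.out = d[a]))
  g <- with_seed(seed + 7L, {
    ph <- stats::runif(3, 0, 2 * pi)
    fx <- cos(2 * pi * coords[[1]] * 1 + ph[1])
    fy <- cos(2 * pi * coords[[2]] * 1 + ph[2])
    fz <- cos(2 * pi * coords[[3]] * 0.5 + ph[3])
    outer(outer(fx, fy, "+"), fz, "+")
  })
  g <- g - mean(g[sel])
  g <- g / max(abs(g))
  field <- 1 + amplitude * g
  out <- vol
  out$data <- vol$data * field
  out
}

#' Generate a full paired phantom (CT, ZTE, T1w, masks)
#'
#' @param spec A [phantom_spec()].
#' @return List with `ct`, `zte`, `t1w` volumes and `head`, `skull`,
#'   `brain` masks.
#' @export
generate_phantom <- function(spec) {
  ph <- generate_ct_phantom(spec)
  zte <- generate_zte_from_ct(ph$ct, ph$skull, ph$head, spec$zte_mapping,
                              noise_sd = spec$noise_sd$zte,
                              seed = spec$seed + 1000L)
  t1w <- generate_t1w_from_ct(ph$ct, ph, noise_sd = spec$noise_sd$t1w,
                              seed = spec$seed + 2000L)
  if (spec$bias_amplitude > 0) {
    zte <- apply_bias_field(zte, spec$bias_amplitude, spec$seed + 3000L, ph$head)
    t1w <- apply_bias_field(t1w, spec$bias_amplitude, spec$seed + 4000L, ph$head)
  }
  c(ph, list(zte = zte, t1w = t1w))
}

#' Read / write a phantom spec as YAML
#' @param spec A `phantom_spec`; `path` a file path.
#' @return `read_phantom_spec` returns a `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  x <- unclass(spec)
  x$zte_mapping <- list(slope = spec$zte_mapping$slope,
                        intercept = spec$zte_mapping$intercept)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  x$zte_mapping <- hu_mapping(x$zte_mapping$slope, x$zte_mapping$intercept)
  do.call(phantom_spec, x)
}
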