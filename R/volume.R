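#' 3D scalar volume with voxel geometry
#'
#' A lightweight container for a 3D scalar grid together with its voxel
#' spacing (mm), world origin (mm), and intensity semantics. World
#' coordinates follow `world = origin + index * spacing` with 0-based voxel
#' indices, so voxel `[1,1,1]` in R sits at `origin`.
#'
#' @param data 3D numeric array.
#' @param spacing_mm Per-axis voxel size in mm (length 1 or 3).
#' @param origin_mm World position of voxel (0,0,0) in mm (length 3).
#' @param kind Intensity semantics, one of `"HU"`, `"MR_raw"`,
#'   `"MR_normalised"`, `"pressure"`, `"arbitrary"`.
#' @return An object of class `skull_volume`.
#' @export
volume <- function(data, spacing_mm = 1, origin_mm = c(0, 0, 0),
                   kind = c("HU", "MR_raw", "MR_normalised", "pressure",
                            "arbitrary")) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0)) stop("voxel spacing must be positive")
  structure(
    list(data = data, spacing = spacing_mm,
         origin = rep_len(as.numeric(origin_mm), 3L), kind = kind),
    class = "skull_volume"
  )
}

#' Binary mask aligned to a volume
#'
#' @param data 3D logical (or 0/1) array.
#' @inheritParams volume
#' @return An object of class `skull_mask`.
#' @export
mask_volume <- function(data, spacing_mm = 1, origin_mm = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  d <- array(as.logical(data), dim(data))
  structure(
    list(data = d, spacing = rep_len(as.numeric(spacing_mm), 3L),
         origin = rep_len(as.numeric(origin_mm), 3L)),
    class = "skull_mask"
  )
}

#' @export
dim.skull_volume <- function(x) dim(x$data)

#' @export
dim.skull_mask <- function(x) dim(x$data)

#' @export
print.skull_volume <- function(x, ...) {
  cat(sprintf("<skull_volume [%s]> %s, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"), x$kind,
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.skull_mask <- function(x, ...) {
  cat(sprintf("<skull_mask [%s]> %d voxels set, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

stopifnot_aligned <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("volumes/masks are not aligned: shapes differ")
  if (max(abs(a$spacing - b$spacing)) > 1e-9)
    stop("volumes/masks are not aligned: spacings differ")
  invisible(TRUE)
}

#' World coordinates of the voxel centres along each axis
#' @param x A `skull_volume` or `skull_mask`.
#' @return List of three numeric vectors (mm).
#' @export
voxel_coords <- function(x) {
  d <- dim(x$data)
  lapply(1:3, function(a) x$origin[a] + (seq_len(d[a]) - 1) * x$spacing[a])
}

#' Read / write volumes as NIfTI
#'
#' The affine encodes the voxel spacing and origin; intensity semantics are
#' not stored in the file and must be supplied on read.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param kind Intensity semantics to attach on read.
#' @return `read_volume` returns a `skull_volume`; `write_volume` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path, kind = "HU") {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  aff <- RNifti::xform(img)
  volume(array(as.numeric(img), dim(img)[1:3]), spacing_mm = sp,
         origin_mm = aff[1:3, 4], kind = kind)
}

#' @rdname read_volume
#' @param vol A `skull_volume` or `skull_mask`.
#' @export
write_volume <- function(vol, path) {
  dat <- if (is.logical(vol$data)) array(as.integer(vol$data), dim(vol$data)) else vol$data
  img <- RNifti::asNifti(dat)
  aff <- diag(4)
  diag(aff)[1:3] <- vol$spacing
  aff[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Trilinear resampling to a new isotropic grid spacing
#'
#' Resamples onto a grid with the requested spacing covering the same world
#' extent; world coordinates are preserved (the origin is unchanged).
#' Linear fields are reproduced exactly by trilinear interpolation.
#'
#' @param vol A `skull_volume`.
#' @param target_spacing_mm New isotropic spacing (mm), default 0.5.
#' @param fill Value used outside the original grid (defaults to the
#'   volume's edge values via clamping).
#' @return Resampled `skull_volume`.
#' @export
resample_volume <- function(vol, target_spacing_mm = 0.5, fill = NULL) {
  if (target_spacing_mm <= 0) stop("target spacing must be positive")
  d <- dim(vol$data)
  extent <- (d - 1) * vol$spacing
  nd <- pmax(2L, as.integer(floor(extent / target_spacing_mm)) + 1L)
  # continuous (0-based) source index of each target voxel centre
  ax <- lapply(1:3, function(a) {
    (seq_len(nd[a]) - 1) * target_spacing_mm / vol$spacing[a]
  })
  out <- trilinear_sample(vol$data, ax[[1]], ax[[2]], ax[[3]])
  volume(out, spacing_mm = target_spacing_mm, origin_mm = vol$origin,
         kind = vol$kind)
}

# Sample arr at the tensor-product grid of continuous 0-based coordinates.
trilinear_sample <- function(arr, cx, cy, cz) {
  d <- dim(arr)
  clamp <- function(v, hi) pmin(pmax(v, 0), hi)
  cx <- clamp(cx, d[1] - 1); cy <- clamp(cy, d[2] - 1); cz <- clamp(cz, d[3] - 1)
  i0 <- pmin(floor(cx), d[1] - 2); fx <- cx - i0
  j0 <- pmin(floor(cy), d[2] - 2); fy <- cy - j0
  k0 <- pmin(floor(cz), d[3] - 2); fz <- cz - k0
  nx <- length(cx); ny <- length(cy); nz <- length(cz)
  out <- array(0, c(nx, ny, nz))
  # interpolate along z in slabs to bound memory
  wx0 <- 1 - fx; wy0 <- 1 - fy
  for (k in seq_len(nz)) {
    s0 <- arr[, , k0[k] + 1]
    s1 <- arr[, , k0[k] + 2]
    s <- s0 * (1 - fz[k]) + s1 * fz[k]
    # bilinear in-plane via matrix gathers
    a00 <- s[cbind(rep(i0 + 1, ny), rep(j0 + 1, each = nx))]
    a10 <- s[cbind(rep(i0 + 2, ny), rep(j0 + 1, each = nx))]
    a01 <- s[cbind(rep(i0 + 1, ny), rep(j0 + 2, each = nx))]
    a11 <- s[cbind(rep(i0 + 2, ny), rep(j0 + 2, each = nx))]
    w00 <- rep(wx0, ny) * rep(wy0, each = nx)
    w10 <- rep(fx, ny) * rep(wy0, each = nx)
    w01 <- rep(wx0, ny) * rep(fy, each = nx)
    w11 <- rep(fx, ny) * rep(fy, each = nx)
    out[, , k] <- a00 * w00 + a10 * w10 + a01 * w01 + a11 * w11
  }
  out
}

#' Dice overlap coefficient between two masks
#' @param a,b `skull_mask` objects or logical arrays.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  am <- if (inherits(a, "skull_mask")) a$data else a
  bm <- if (inherits(b, "skull_mask")) b$data else b
  2 * sum(am & bm) / (sum(am) + sum(bm))
}
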