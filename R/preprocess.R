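#' Reference histogram for midway equalisation
#'
#' Midway histogram specification maps each image's quantile function to the
#' average of the training cohort's quantile functions. The reference stores
#' the quantile grid and the averaged inverse CDF, computed over masked
#' voxels of the training images only.
#'
#' @param volumes List of `skull_volume`s (training set).
#' @param masks List of aligned `skull_mask`s (head masks).
#' @param n_quantiles Number of uniform quantiles (default 1024).
#' @return A `midway_reference` with fields `q` and `inv_cdf`.
#' @export
build_midway_reference <- function(volumes, masks, n_quantiles = 1024) {
  if (length(volumes) == 0L) stop("need at least one training volume")
  if (length(masks) != length(volumes)) stop("one mask per volume required")
  q <- seq(0, 1, length.out = n_quantiles)
  inv <- rowMeans(vapply(seq_along(volumes), function(i) {
    stopifnot_aligned(volumes[[i]], masks[[i]])
    v <- volumes[[i]]$data[masks[[i]]$data]
    stats::quantile(v, q, names = FALSE, type = 7)
  }, numeric(n_quantiles)))
  inv <- cummax(inv)  # enforce a non-decreasing inverse CDF
  structure(list(q = q, inv_cdf = inv), class = "midway_reference")
}

#' Read / write a midway reference as JSON
#' @param reference A `midway_reference`; `path` a file path.
#' @return `read_midway_reference` returns a `midway_reference`.
#' @export
write_midway_reference <- function(reference, path) {
  jsonlite::write_json(list(q = reference$q, inv_cdf = reference$inv_cdf),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_midway_reference
#' @export
read_midway_reference <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(list(q = x$q, inv_cdf = x$inv_cdf), class = "midway_reference")
}

#' Midway histogram equalisation against a reference
#'
#' Applies the monotone intensity transform that sends the image's masked
#' quantile function to the reference inverse CDF. Voxels outside the mask
#' are transformed with the same map (extrapolated flat at the ends), so
#' rank order is preserved everywhere.
#'
#' @param vol `skull_volume` to equalise.
#' @param reference A `midway_reference` from [build_midway_reference()].
#' @param mask `skull_mask` defining the histogram support.
#' @return Equalised `skull_volume`.
#' @export
midway_equalize <- function(vol, reference, mask) {
  stopifnot(inherits(reference, "midway_reference"))
  stopifnot_aligned(vol, mask)
  v <- vol$data[mask$data]
  own <- stats::quantile(v, reference$q, names = FALSE, type = 7)
  if (max(own) - min(own) < .Machine$double.eps * max(1, abs(max(own)))) {
    warning("constant-intensity input: midway equalisation is a passthrough")
    return(vol)
  }
  # F_img via the image's own inverse CDF, then the reference inverse CDF
  own_u <- !duplicated(own)
  f <- stats::approx(own[own_u], reference$q[own_u], xout = vol$data,
                     rule = 2, ties = "ordered")$y
  out <- stats::approx(reference$q, reference$inv_cdf, xout = f, rule = 2)$y
  vol$data <- array(out, dim(vol$data))
  vol$kind <- "MR_normalised"
  vol
}

#' Z-score normalisation with externally supplied statistics
#'
#' @param vol `skull_volume`.
#' @param mean,sd Training-set statistics; `sd` must be positive.
#' @return Normalised `skull_volume`; `(v - mean)/sd` voxelwise.
#' @export
zscore_normalize <- function(vol, mean, sd) {
  if (sd <= 0) stop("sd must be positive")
  vol$data <- (vol$data - mean) / sd
  vol$kind <- if (vol$kind == "HU") "HU" else "MR_normalised"
  vol
}

#' Pad a volume to a cube, recording the offsets
#'
#' Centred zero-padding to `edge` voxels per axis. HU volumes are padded
#' with -1000 (air) and MR volumes with 0, so padding always reads as empty
#' space. The recorded offsets allow an exact crop back.
#'
#' @param vol `skull_volume` or `skull_mask`.
#' @param edge Target edge length in voxels (default 256).
#' @return List with `volume` (padded) and `offsets` (integer length-3,
#'   voxels prepended per axis).
#' @export
pad_to_cube <- function(vol, edge = 256) {
  d <- dim(vol$data)
  if (any(d > edge)) stop("volume dimension exceeds the requested cube edge")
  off <- as.integer(floor((edge - d) / 2))
  fill <- if (!inherits(vol, "skull_mask") && vol$kind == "HU") -1000 else 0
  out <- array(if (is.logical(vol$data)) as.logical(fill) else fill,
               rep(edge, 3))
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), off[3] + seq_len(d[3])] <-
    vol$data
  res <- vol
  res$data <- out
  res$origin <- vol$origin - off * vol$spacing
  list(volume = res, offsets = off)
}

#' @rdname pad_to_cube
#' @param padded The list returned by `pad_to_cube`.
#' @param original_dim Integer length-3 dimensions before padding.
#' @export
crop_from_cube <- function(padded, original_dim) {
  off <- padded$offsets
  res <- padded$volume
  res$data <- padded$volume$data[off[1] + seq_len(original_dim[1]),
                                 off[2] + seq_len(original_dim[2]),
                                 off[3] + seq_len(original_dim[3]), drop = FALSE]
  res$origin <- padded$volume$origin + off * padded$volume$spacing
  res
}

#' Head mask from an MR volume by thresholding and filling
#'
#' Otsu threshold on the intensity histogram (separating air from the
#' head), filling of enclosed cavities (dark bone and everything inside
#' it), largest connected component, then a light morphological closing
#' (radius 2) and a final fill.
#'
#' @param vol MR-like `skull_volume`.
#' @return `skull_mask` of the head.
#' @export
head_mask_from_mr <- function(vol) {
  v <- vol$data
  rng <- range(v)
  if (diff(rng) <= 0) stop("cannot build a head mask from a constant volume")
  vn <- (v - rng[1]) / diff(rng)
  # global Otsu over the whole histogram separates air from the head
  thr <- EBImage::otsu(EBImage::Image(matrix(as.vector(vn), ncol = 1L)),
                       range = c(0, 1))
  fg <- array(vn > thr, dim(v))
  if (!any(fg)) stop("empty head mask: no suprathreshold voxels")
  fg <- fill_holes_3d(fg)
  fg <- largest_component(fg, connectivity = 6)
  fg <- binary_close(fg, radius = 2)
  fg <- fill_holes_3d(fg)
  mask_volume(fg, vol$spacing, vol$origin)
}
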