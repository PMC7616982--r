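#' Linear ZTE-to-HU mapping
#'
#' Holds the slope and intercept of the linear bone mapping from
#' soft-tissue-normalised ZTE intensity to Hounsfield units. The default
#' calibration is `CT = -2085 * ZTE + 2329`; a physically meaningful bone
#' mapping has negative slope (ZTE signal falls as mineral density, and
#' hence HU, rises).
#'
#' @param slope HU per normalised-ZTE unit.
#' @param intercept HU at ZTE = 0.
#' @return A `hu_mapping` object.
#' @export
hu_mapping <- function(slope = -2085, intercept = 2329) {
  structure(list(slope = as.numeric(slope), intercept = as.numeric(intercept)),
            class = "hu_mapping")
}

#' @export
print.hu_mapping <- function(x, ...) {
  cat(sprintf("<hu_mapping> CT = %.6g * ZTE + %.6g\n", x$slope, x$intercept))
  invisible(x)
}

#' Normalise a ZTE volume by its soft-tissue histogram peak
#'
#' Locates the soft-tissue mode of the masked intensity histogram (a kernel
#' density argmax over the head) and divides by it, so soft tissue sits at
#' intensity 1. Expects a bias-corrected ZTE volume.
#'
#' @param zte ZTE `skull_volume`.
#' @param head_mask Aligned head `skull_mask`.
#' @param n_bins Histogram resolution used to locate the peak.
#' @return Normalised `skull_volume` with attribute `"scale"` holding the
#'   peak value divided out.
#' @export
soft_tissue_normalize <- function(zte, head_mask, n_bins = 256) {
  stopifnot_aligned(zte, head_mask)
  v <- zte$data[head_mask$data]
  rng <- range(v)
  if (diff(rng) <= 0) stop("no unambiguous soft-tissue peak: constant intensities")
  h <- graphics::hist(v, breaks = seq(rng[1], rng[2], length.out = n_bins + 1),
                      plot = FALSE)
  dens <- stats::density(v, n = 512)
  peak <- dens$x[which.max(dens$y)]
  if (peak <= 0) {
    stop("no unambiguous soft-tissue peak located (mode at ", signif(peak, 4),
         "); histogram counts: ", paste(utils::head(h$counts, 20), collapse = ","))
  }
  out <- zte
  out$data <- zte$data / peak
  out$kind <- "MR_normalised"
  attr(out, "scale") <- peak
  out
}

#' Skull mask from a normalised ZTE volume
#'
#' Thresholds the normalised intensities to the bone band (bone/air and
#' bone/soft-tissue boundaries at 0.2 and 0.75), restricts to the head,
#' takes the largest 26-connected component, fills enclosed intra-bone
#' holes, and applies a radius-1 3D closing. (Hole filling is restricted
#' to cavities small relative to the bone mask so the cranial cavity,
#' which a closed vault encloses, is never absorbed.)
#'
#' @param norm_zte Soft-tissue-normalised ZTE `skull_volume`.
#' @param head_mask Head `skull_mask`.
#' @param lower,upper Bone intensity band (defaults 0.2 and 0.75).
#' @return Skull `skull_mask`.
#' @export
skull_mask_from_zte <- function(norm_zte, head_mask, lower = 0.2, upper = 0.75) {
  stopifnot_aligned(norm_zte, head_mask)
  band <- norm_zte$data >= lower & norm_zte$data <= upper & head_mask$data
  if (!any(band))
    stop("empty skull mask: no voxels in the bone intensity band ",
         "(thresholding values not suitable for this image)")
  m <- largest_component(band, connectivity = 26)
  m <- fill_small_holes_3d(m)
  m <- binary_close(m, radius = 1)
  m <- m & head_mask$data
  mask_volume(m, norm_zte$spacing, norm_zte$origin)
}

#' Calibrate the linear ZTE-to-HU mapping by total least squares
#'
#' Fits the line through the sample mean along the leading eigenvector of
#' the 2x2 covariance of paired (ZTE, CT) samples — the first principal
#' component of the joint density, minimising orthogonal distances rather
#' than vertical ones.
#'
#' @param zte_values,ct_values Paired numeric samples from within the skull.
#' @return A [hu_mapping()] with attributes `"r_squared"` and `"n"`.
#' @export
calibrate_linear_pca <- function(zte_values, ct_values) {
  ok <- is.finite(zte_values) & is.finite(ct_values)
  x <- zte_values[ok]; y <- ct_values[ok]
  if (length(unique(paste(x, y))) < 2L) stop("need at least two distinct pairs")
  cv <- stats::cov(cbind(x, y))
  if (!all(is.finite(cv)) || sum(abs(cv)) == 0) stop("degenerate covariance")
  e <- eigen(cv, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (abs(v[1]) < .Machine$double.eps) stop("degenerate covariance: vertical principal axis")
  slope <- v[2] / v[1]
  intercept <- mean(y) - slope * mean(x)
  m <- hu_mapping(slope, intercept)
  attr(m, "r_squared") <- if (stats::var(y) > 0) stats::cor(x, y)^2 else NA_real_
  attr(m, "n") <- length(x)
  m
}

#' Classical ZTE to pseudo-CT conversion
#'
#' Within the skull mask, HU = slope * ZTE + intercept (clamped below at
#' -1000, the physical floor of the HU scale). Non-skull voxels inside the
#' head are assigned soft tissue (42 HU) and voxels outside the head air
#' (-1000 HU).
#'
#' @param norm_zte Soft-tissue-normalised ZTE `skull_volume`.
#' @param skull_mask,head_mask Aligned `skull_mask`s.
#' @param mapping [hu_mapping()] (default slope -2085, intercept 2329).
#' @param soft_tissue_hu,air_hu Constants for the non-bone classes.
#' @return Pseudo-CT `skull_volume` in HU.
#' @export
zte_to_pct <- function(norm_zte, skull_mask, head_mask,
                       mapping = hu_mapping(),
                       soft_tissue_hu = 42, air_hu = -1000) {
  stopifnot_aligned(norm_zte, skull_mask)
  stopifnot_aligned(norm_zte, head_mask)
  d <- dim(norm_zte$data)
  hu <- array(air_hu, d)
  hu[head_mask$data] <- soft_tissue_hu
  sk <- skull_mask$data
  hu[sk] <- pmax(mapping$slope * norm_zte$data[sk] + mapping$intercept, -1000)
  volume(hu, norm_zte$spacing, norm_zte$origin, kind = "HU")
}

#' End-to-end classical pipeline: ZTE volume to pseudo-CT
#'
#' Convenience wrapper: soft-tissue normalisation, skull-mask extraction,
#' optional per-image calibration against a paired CT, and HU assignment.
#'
#' @param zte Bias-corrected ZTE `skull_volume`.
#' @param head_mask Head `skull_mask`.
#' @param mapping [hu_mapping()] to apply; ignored when `calibrate_with` is
#'   given.
#' @param calibrate_with Optional paired CT `skull_volume`; when supplied
#'   the mapping is recalibrated on this subject's skull voxels.
#' @return List with `pct` (`skull_volume`), `skull_mask`, and `mapping`.
#' @export
classical_pct <- function(zte, head_mask, mapping = hu_mapping(),
                          calibrate_with = NULL) {
  nz <- soft_tissue_normalize(zte, head_mask)
  sk <- skull_mask_from_zte(nz, head_mask)
  if (!is.null(calibrate_with)) {
    mapping <- calibrate_linear_pca(nz$data[sk$data],
                                    calibrate_with$data[sk$data])
  }
  list(pct = zte_to_pct(nz, sk, head_mask, mapping),
       skull_mask = sk, mapping = mapping)
}
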