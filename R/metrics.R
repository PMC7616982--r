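#' Image-space error metrics between a pseudo-CT and a reference CT
#'
#' Mean absolute error and root-mean-squared error of the HU differences
#' over a mask (whole head or skull only).
#'
#' @param pct,ct Aligned `skull_volume`s in HU.
#' @param mask `skull_mask` defining the evaluation region.
#' @param region Label recorded in the output (e.g. `"head"`, `"skull"`).
#' @return One-row tibble: `region`, `mae_hu`, `rmse_hu`, `n_voxels`.
#' @export
image_metrics <- function(pct, ct, mask, region = "head") {
  stopifnot_aligned(pct, ct); stopifnot_aligned(pct, mask)
  if (!any(mask$data)) stop("empty evaluation mask")
  d <- pct$data[mask$data] - ct$data[mask$data]
  tibble::tibble(region = region,
                 mae_hu = mean(abs(d)),
                 rmse_hu = sqrt(mean(d^2)),
                 n_voxels = sum(mask$data))
}

#' Evaluation skull mask from a ground-truth CT
#'
#' Bone threshold intersected with the head mask.
#'
#' @param ct Ground-truth CT `skull_volume`.
#' @param head_mask Head `skull_mask`.
#' @param threshold_hu Bone threshold in HU (default 300).
#' @return Skull `skull_mask`.
#' @export
skull_mask_from_ct <- function(ct, head_mask, threshold_hu = 300) {
  stopifnot_aligned(ct, head_mask)
  m <- ct$data > threshold_hu & head_mask$data
  if (!any(m)) stop("empty skull mask: no voxels above the bone threshold")
  mask_volume(m, ct$spacing, ct$origin)
}

#' Focal metrics of a pressure field
#'
#' Peak amplitude within the brain mask, the world position of the arg-max
#' cell (no sub-voxel refinement by default), and the -6 dB focal volume:
#' the measure of in-mask cells whose amplitude is at least half the peak
#' (threshold on pressure amplitude, not intensity). Works on 3D volumes
#' (mm^3) and on 2D field slices (mm^2).
#'
#' @param field `skull_volume` (kind pressure), `pressure_field_2d`, or a
#'   numeric array with attributes supplied via `spacing`/`origin`.
#' @param brain_mask Logical array / `skull_mask` restricting the search;
#'   `NULL` uses the whole grid.
#' @param spacing,origin Geometry overrides when `field` is a bare array.
#' @param refine_peak Quadratic sub-cell refinement of the peak position
#'   (off by default).
#' @return List with `peak_amplitude`, `peak_position_mm`,
#'   `focal_volume` (mm^d), `ndim`.
#' @export
focal_metrics <- function(field, brain_mask = NULL, spacing = NULL,
                          origin = NULL, refine_peak = FALSE) {
  if (inherits(field, "pressure_field_2d")) {
    amp <- field$amplitude; spacing <- rep(field$spacing, 2)
    origin <- field$origin
  } else if (inherits(field, "skull_volume")) {
    amp <- abs(field$data); spacing <- field$spacing; origin <- field$origin
  } else {
    amp <- abs(field)
    if (is.null(spacing)) spacing <- rep(1, length(dim(amp)))
    spacing <- rep_len(spacing, length(dim(amp)))
    if (is.null(origin)) origin <- rep(0, length(dim(amp)))
  }
  d <- dim(amp)
  sel <- if (is.null(brain_mask)) array(TRUE, d) else {
    if (inherits(brain_mask, "skull_mask")) brain_mask$data else brain_mask
  }
  if (!any(sel)) stop("empty brain mask")
  masked <- amp
  masked[!sel] <- -Inf
  ipk <- arrayInd(which.max(masked), d)
  peak <- amp[ipk]
  pos <- origin + (as.numeric(ipk) - 1) * spacing
  if (refine_peak) pos <- refine_quadratic(amp, ipk, spacing, origin)
  nvox <- sum(masked >= peak / 2)
  list(peak_amplitude = peak,
       peak_position_mm = pos,
       focal_volume = nvox * prod(spacing),
       ndim = length(d))
}

# 1D quadratic (three-point) refinement per axis around the arg-max cell.
refine_quadratic <- function(amp, ipk, spacing, origin) {
  d <- dim(amp)
  pos <- origin + (as.numeric(ipk) - 1) * spacing
  for (a in seq_along(d)) {
    i <- ipk[a]
    if (i > 1 && i < d[a]) {
      idx <- lapply(seq_along(d), function(x) ipk[x])
      get_at <- function(off) {
        idx[[a]] <- i + off
        do.call(`[`, c(list(amp), idx))
      }
      y0 <- get_at(-1L); y1 <- get_at(0L); y2 <- get_at(1L)
      den <- y0 - 2 * y1 + y2
      if (abs(den) > .Machine$double.eps)
        pos[a] <- pos[a] + spacing[a] * 0.5 * (y0 - y2) / den
    }
  }
  pos
}

#' Compare focal metrics of a test field against a reference
#'
#' Percent differences `|test - ref| / ref * 100` for peak pressure and
#' focal volume, and the Euclidean peak-position shift in mm.
#'
#' @param reference,test Lists from [focal_metrics()].
#' @param subject,target,pct_kind Optional identifiers carried into the
#'   record.
#' @return One-row tibble comparison record.
#' @export
compare_fields <- function(reference, test, subject = NA, target = NA_character_,
                           pct_kind = NA_character_) {
  if (reference$peak_amplitude == 0) stop("zero reference peak amplitude")
  tibble::tibble(
    subject = subject, target = target, pct_kind = pct_kind,
    focal_pressure_diff_percent =
      abs(test$peak_amplitude - reference$peak_amplitude) /
      reference$peak_amplitude * 100,
    focal_position_shift_mm =
      sqrt(sum((test$peak_position_mm - reference$peak_position_mm)^2)),
    focal_volume_diff_percent =
      abs(test$focal_volume - reference$focal_volume) /
      reference$focal_volume * 100)
}

#' Aggregate comparison records into a summary table
#'
#' Mean and sample (n-1) standard deviation of each focal-difference
#' metric per (target, pct_kind) cell, plus pooled "All" rows per
#' pct_kind.
#'
#' @param records Tibble of rows from [compare_fields()].
#' @return Tibble with columns `target`, `pct_kind`, `n`, and mean/sd of
#'   the three metrics.
#' @export
aggregate_report <- function(records) {
  if (nrow(records) == 0L) stop("no comparison records to aggregate")
  metrics <- c("focal_pressure_diff_percent", "focal_position_shift_mm",
               "focal_volume_diff_percent")
  summarise_cell <- function(df, target_label) {
    out <- tibble::tibble(target = target_label,
                          pct_kind = df$pct_kind[1], n = nrow(df))
    for (m in metrics) {
      out[[paste0(m, "_mean")]] <- mean(df[[m]])
      out[[paste0(m, "_sd")]] <- if (nrow(df) > 1) stats::sd(df[[m]]) else 0
    }
    out
  }
  cells <- split(records, list(records$target, records$pct_kind), drop = TRUE)
  per <- lapply(cells, function(df) summarise_cell(df, df$target[1]))
  pooled <- lapply(split(records, records$pct_kind),
                   function(df) summarise_cell(df, "All"))
  out <- do.call(rbind, c(per, pooled))
  rownames(out) <- NULL
  out[order(out$target, out$pct_kind), ]
}
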