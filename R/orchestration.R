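#' Experiment configuration over a phantom cohort
#'
#' Defines a cohort of synthetic subjects (per-subject jittered phantom
#' geometry), the pseudo-CT methods to run, the acoustic targets, and the
#' seeds, for the image-space and acoustic comparison experiments.
#'
#' @param n_subjects Cohort size.
#' @param base_spec A [phantom_spec()] template; per-subject radii and
#'   skull thickness are jittered around it.
#' @param methods Pseudo-CT methods: subset of `"classical"`,
#'   `"learned_zte"`, `"learned_t1w"`.
#' @param targets Acoustic targets: subset of `"V1"` (occipital pole,
#'   posterior beam) and `"M1"` (superior-lateral point, vertical beam).
#' @param models Named list of trained `unet_model`s for the learned
#'   methods (`zte`, `t1w`).
#' @param transducer A [transducer_spec()].
#' @param sim_spacing_mm Simulation grid spacing (default 0.5).
#' @param seed Cohort seed.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 3,
                              base_spec = phantom_spec(),
                              methods = "classical",
                              targets = c("V1", "M1"),
                              models = list(),
                              transducer = transducer_spec(),
                              sim_spacing_mm = 0.5,
                              seed = 1L) {
  stopifnot(length(methods) >= 1, length(targets) >= 1)
  methods <- match.arg(methods, c("classical", "learned_zte", "learned_t1w"),
                       several.ok = TRUE)
  structure(list(n_subjects = as.integer(n_subjects), base_spec = base_spec,
                 methods = methods, targets = targets, models = models,
                 transducer = transducer, sim_spacing_mm = sim_spacing_mm,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# Cohort of per-subject phantom specs with jittered geometry.
cohort_specs <- function(config) {
  base <- config$base_spec
  with_seed(config$seed, {
    lapply(seq_len(config$n_subjects), function(s) {
      sp <- base
      sp$head_radii_mm <- base$head_radii_mm * stats::runif(3, 0.96, 1.04)
      sp$skull_thickness_mm[1] <- base$skull_thickness_mm[1] *
        stats::runif(1, 0.85, 1.15)
      sp$seed <- base$seed + 101L * s
      check_phantom_fits(sp)
      sp
    })
  })
}

# Pseudo-CT volumes for the requested methods on one phantom subject.
subject_pcts <- function(phantom, config) {
  out <- list()
  for (m in config$methods) {
    res <- tryCatch(switch(m,
      classical = classical_pct(phantom$zte, phantom$head)$pct,
      learned_zte = predict_volume(config$models$zte, phantom$zte,
                                   phantom$head),
      learned_t1w = predict_volume(config$models$t1w, phantom$t1w,
                                   phantom$head)),
      error = function(e) e)
    out[[pct_kind_label(m)]] <- res
  }
  out
}

pct_kind_label <- function(method) {
  c(classical = "cCT", learned_zte = "zCT", learned_t1w = "tCT")[[method]]
}

#' Image-evaluation experiment over a phantom cohort
#'
#' For every subject and pseudo-CT method, computes MAE and RMSE against
#' the ground-truth phantom CT over the head mask and the skull mask
#' (derived by thresholding the ground-truth CT). Failures are recorded
#' per subject and the run continues.
#'
#' @param config An [experiment_config()].
#' @return List with `per_subject` (tibble), `summary` (mean +/- sd per
#'   mask and method), `failures` (tibble of subject, method, reason).
#' @export
run_image_experiment <- function(config) {
  specs <- cohort_specs(config)
  rows <- list(); fails <- list()
  for (s in seq_along(specs)) {
    ph <- generate_phantom(specs[[s]])
    skull_eval <- skull_mask_from_ct(ph$ct, ph$head)
    pcts <- subject_pcts(ph, config)
    for (kind in names(pcts)) {
      p <- pcts[[kind]]
      if (inherits(p, "error")) {
        fails[[length(fails) + 1L]] <- tibble::tibble(
          subject = s, pct_kind = kind, reason = conditionMessage(p))
        next
      }
      for (reg in c("head", "skull")) {
        msk <- if (reg == "head") ph$head else skull_eval
        im <- image_metrics(p, ph$ct, msk, region = reg)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject = s, pct_kind = kind, region = reg,
          mae_hu = im$mae_hu, rmse_hu = im$rmse_hu, n_voxels = im$n_voxels)
      }
    }
  }
  per <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(
    split(per, list(per$region, per$pct_kind), drop = TRUE),
    function(df) tibble::tibble(
      region = df$region[1], pct_kind = df$pct_kind[1], n = nrow(df),
      mae_hu_mean = mean(df$mae_hu),
      mae_hu_sd = if (nrow(df) > 1) stats::sd(df$mae_hu) else 0,
      rmse_hu_mean = mean(df$rmse_hu),
      rmse_hu_sd = if (nrow(df) > 1) stats::sd(df$rmse_hu) else 0)))
  rownames(summ) <- NULL
  list(per_subject = per, summary = summ,
       failures = if (length(fails)) do.call(rbind, fails) else
         tibble::tibble(subject = integer(), pct_kind = character(),
                        reason = character()))
}

# ---- acoustic experiment helpers ----------------------------------------

# Geometric target definition on a phantom: returns the 2D medium slice
# axes, the in-plane focus position, and the brain mask slice, with the
# beam axis along +v.
phantom_target_slice <- function(phantom, target, maps) {
  d <- dim(phantom$ct$data)
  h <- phantom$ct$spacing[1]
  br <- phantom$brain$data
  idx <- which(br, arr.ind = TRUE)
  ctr <- round(colMeans(idx))
  if (target == "V1") {
    # central sagittal plane; occipital pole = minimum-y brain voxel;
    # beam travels along +y from the posterior side.
    # orient (u = z, v = y): matrix[u, v] = a[i0, v, u]
    i0 <- ctr[1]
    ymin <- min(idx[idx[, 1] == i0, 2])
    zc <- ctr[3]
    get2d <- function(a) t(a[i0, , ])
    focus_uv <- c((zc - 1) * h, (ymin - 1) * h + 5)
    list(get2d = get2d, focus_uv = focus_uv,
         brain2d = t(br[i0, , ]), spacing = h)
  } else {
    # coronal plane through the brain centroid; superior-lateral target;
    # beam travels downward, so flip z to put the transducer at low v
    j0 <- ctr[2]
    nx <- d[1]; nz <- d[3]
    xoff <- ctr[1] + round(0.45 * (max(idx[, 1]) - ctr[1]))
    in_plane <- idx[idx[, 2] == j0 & idx[, 1] == xoff, , drop = FALSE]
    ztop <- if (nrow(in_plane)) max(in_plane[, 3]) else ctr[3]
    get2d <- function(a) a[, j0, nz:1]
    focus_uv <- c((xoff - 1) * h, (nz - ztop) * h + 5)
    list(get2d = get2d, focus_uv = focus_uv,
         brain2d = br[, j0, nz:1], spacing = h)
  }
}

# Bilinear resampling of a matrix to a finer isotropic spacing.
resample_matrix <- function(m, spacing, target) {
  arr <- array(rep(m, 2L), c(dim(m), 2L))
  d <- dim(m)
  cx <- (seq_len(max(2L, floor((d[1] - 1) * spacing / target) + 1L)) - 1) *
    target / spacing
  cy <- (seq_len(max(2L, floor((d[2] - 1) * spacing / target) + 1L)) - 1) *
    target / spacing
  trilinear_sample(arr, cx, cy, 0)[, , 1]
}

# Build the simulation window around the beam path: a water-filled frame
# covering the transducer arc, the skull entry, and the focal region,
# cropped laterally to the aperture plus a margin so run times stay
# bounded. Overlapping parts of the property maps are copied in; the rest
# reads as water.
embed_for_transducer <- function(maps2d, spacing, focus_uv, transducer,
                                 water = medium_reference(),
                                 lateral_margin_mm = 12,
                                 post_focal_mm = 30) {
  R <- transducer$roc_mm
  half_ap <- max(transducer$element_outer_diameters_mm) / 2
  d <- dim(maps2d$c)
  # window extents in world coordinates of the slice
  u_lo <- focus_uv[1] - (half_ap + lateral_margin_mm)
  u_hi <- focus_uv[1] + (half_ap + lateral_margin_mm)
  v_lo <- focus_uv[2] - R - 6
  v_hi <- focus_uv[2] + post_focal_mm
  iu <- round(u_lo / spacing):round(u_hi / spacing)   # 0-based cells
  iv <- round(v_lo / spacing):round(v_hi / spacing)
  emb <- function(m, fill) {
    out <- matrix(fill, length(iu), length(iv))
    ok_u <- iu >= 0 & iu < d[1]
    ok_v <- iv >= 0 & iv < d[2]
    out[ok_u, ok_v] <- m[iu[ok_u] + 1L, iv[ok_v] + 1L]
    out
  }
  med <- medium_slice_2d(emb(maps2d$c, water$water_c),
                         emb(maps2d$rho, water$water_rho),
                         emb(maps2d$alpha, water$water_alpha),
                         spacing_mm = spacing)
  list(medium = med,
       focus_uv = focus_uv - spacing * c(iu[1], iv[1]),
       brain2d = emb(maps2d$brain, 0) >= 0.5)
}

# Single connected component covering >= 95 % of the reference skull.
check_skull_continuity <- function(pct_skull, ref_skull, min_coverage = 0.95) {
  big <- largest_component(pct_skull$data, connectivity = 26)
  cov <- sum(big & ref_skull$data) / sum(ref_skull$data)
  list(ok = cov >= min_coverage, coverage = cov,
       reason = if (cov >= min_coverage) NA_character_ else
         sprintf("skull_discontinuous(coverage=%.3f)", cov))
}

# Simulate one subject/target for a given HU volume and return focal
# metrics in the embedded 2D frame.
simulate_target <- function(hu_vol, head_mask, brain_mask, target_def,
                            config) {
  maps3 <- build_medium(hu_vol, head_mask)
  sp <- target_def$spacing
  tgt <- config$sim_spacing_mm
  maps2d <- list(c = resample_matrix(target_def$get2d(maps3$sound_speed), sp, tgt),
                 rho = resample_matrix(target_def$get2d(maps3$density), sp, tgt),
                 alpha = resample_matrix(target_def$get2d(maps3$attenuation), sp, tgt),
                 brain = resample_matrix(target_def$brain2d * 1, sp, tgt))
  emb <- embed_for_transducer(maps2d, tgt, target_def$focus_uv,
                              config$transducer)
  field <- simulate_field_2d(emb$medium, config$transducer, emb$focus_uv)
  focal_metrics(field, brain_mask = emb$brain2d)
}

#' Acoustic comparison experiment over a phantom cohort
#'
#' For every subject, target pose, and pseudo-CT method, runs the internal
#' 2D continuous-wave solver on medium maps derived from the ground-truth
#' CT and from the pseudo-CT (all other simulation parameters identical),
#' and compares the focal metrics. Subjects whose pseudo-CT skull is
#' discontinuous are excluded with a machine-readable reason; solver
#' failures skip the subject/target pair and are logged.
#'
#' @param config An [experiment_config()].
#' @return List with `records` (tibble of comparison rows), `summary`
#'   (Table-2-style aggregate), `exclusions` (tibble).
#' @export
run_acoustic_experiment <- function(config) {
  specs <- cohort_specs(config)
  recs <- list(); excl <- list()
  for (s in seq_along(specs)) {
    ph <- generate_phantom(specs[[s]])
    ref_skull <- skull_mask_from_ct(ph$ct, ph$head)
    pcts <- subject_pcts(ph, config)
    usable <- character(0)
    for (kind in names(pcts)) {
      p <- pcts[[kind]]
      if (inherits(p, "error")) {
        excl[[length(excl) + 1L]] <- tibble::tibble(
          subject = s, target = NA_character_, pct_kind = kind,
          reason = paste0("pct_failed(", conditionMessage(p), ")"))
        next
      }
      cont <- tryCatch(
        check_skull_continuity(skull_mask_from_ct(p, ph$head), ref_skull),
        error = function(e) list(ok = FALSE,
                                 reason = paste0("skull_mask_failed(",
                                                 conditionMessage(e), ")")))
      if (!cont$ok) {
        excl[[length(excl) + 1L]] <- tibble::tibble(
          subject = s, target = NA_character_, pct_kind = kind,
          reason = cont$reason)
        next
      }
      usable <- c(usable, kind)
    }
    if (length(usable) == 0L) next
    for (tg in config$targets) {
      tdef <- phantom_target_slice(ph, tg)
      ref_fm <- tryCatch(simulate_target(ph$ct, ph$head, ph$brain, tdef,
                                         config),
                         error = function(e) e)
      if (inherits(ref_fm, "error")) {
        excl[[length(excl) + 1L]] <- tibble::tibble(
          subject = s, target = tg, pct_kind = NA_character_,
          reason = paste0("ref_solver_failed(", conditionMessage(ref_fm), ")"))
        next
      }
      for (kind in usable) {
        res <- tryCatch({
          fm <- simulate_target(pcts[[kind]], ph$head, ph$brain, tdef, config)
          compare_fields(ref_fm, fm, subject = s, target = tg,
                         pct_kind = kind)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          excl[[length(excl) + 1L]] <- tibble::tibble(
            subject = s, target = tg, pct_kind = kind,
            reason = paste0("solver_failed(", conditionMessage(res), ")"))
        } else {
          recs[[length(recs) + 1L]] <- res
        }
      }
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    tibble::tibble(subject = integer(), target = character(),
                   pct_kind = character(),
                   focal_pressure_diff_percent = numeric(),
                   focal_position_shift_mm = numeric(),
                   focal_volume_diff_percent = numeric())
  list(records = records,
       summary = if (nrow(records)) aggregate_report(records) else NULL,
       exclusions = if (length(excl)) do.call(rbind, excl) else
         tibble::tibble(subject = integer(), target = character(),
                        pct_kind = character(), reason = character()))
}
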