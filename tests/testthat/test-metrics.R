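test_that("image metrics match hand arithmetic and satisfy MAE <= RMSE", {
  d <- c(4, 4, 2)
  ct <- volume(array(0, d), 1, kind = "HU")
  m <- array(FALSE, d); m[1:2, 1, 1] <- TRUE
  pct <- ct; pct$data[1, 1, 1] <- 3; pct$data[2, 1, 1] <- 4
  im <- image_metrics(pct, ct, mask_volume(m, 1), region = "skull")
  expect_equal(im$mae_hu, 3.5)
  expect_equal(im$rmse_hu, sqrt(12.5), tolerance = 1e-9)
  expect_equal(im$n_voxels, 2L)
  # identical volumes and constant offsets
  expect_equal(image_metrics(ct, ct, mask_volume(m, 1))$mae_hu, 0)
  off <- ct; off$data <- off$data + 50
  imo <- image_metrics(off, ct, mask_volume(m, 1))
  expect_equal(imo$mae_hu, 50); expect_equal(imo$rmse_hu, 50)
  # property: MAE <= RMSE on random errors
  set.seed(1)
  rnd <- ct; rnd$data <- array(rnorm(prod(d), 0, 30), d)
  imr <- image_metrics(rnd, ct, mask_volume(array(TRUE, d), 1))
  expect_lte(imr$mae_hu, imr$rmse_hu)
  expect_error(image_metrics(ct, ct, mask_volume(array(FALSE, d), 1)),
               "empty")
})

test_that("evaluation skull mask is the thresholded CT intersected with the head", {
  ph <- clean_phantom()
  sk <- skull_mask_from_ct(ph$ct, ph$head)
  expect_gte(dice(sk, ph$skull), 0.95)
  expect_true(all(sk$data <= ph$head$data))
  sk500 <- skull_mask_from_ct(ph$ct, ph$head, threshold_hu = 500)
  expect_true(all(sk500$data <= sk$data))
  expect_error(skull_mask_from_ct(ph$ct, ph$head, threshold_hu = 5000),
               "empty")
})

test_that("-6 dB focal volume of a Gaussian field matches the closed form", {
  sigma <- 6; h <- 0.4
  co <- (0:120) * h - 24
  r2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  amp <- exp(-r2 / (2 * sigma^2))
  fm <- focal_metrics(amp, spacing = h, origin = c(-24, -24, -24))
  analytic <- 4 / 3 * pi * (sigma * sqrt(2 * log(2)))^3
  expect_lt(abs(fm$focal_volume - analytic) / analytic, 0.03)
  expect_equal(fm$peak_position_mm, c(0, 0, 0))
  expect_equal(fm$peak_amplitude, 1)
  # single non-zero voxel -> one voxel volume
  one <- array(0, c(5, 5, 5)); one[3, 3, 3] <- 2
  f1 <- focal_metrics(one, spacing = 1)
  expect_equal(f1$focal_volume, 1)
  # amplitude scaling: peak scales, position and volume invariant
  f10 <- focal_metrics(amp * 10, spacing = h, origin = c(-24, -24, -24))
  expect_equal(f10$peak_amplitude, 10)
  expect_equal(f10$peak_position_mm, fm$peak_position_mm)
  expect_equal(f10$focal_volume, fm$focal_volume)
  # rigid grid translation moves the reported position rigidly
  ft <- focal_metrics(amp, spacing = h, origin = c(-24, -24, -24) + c(3, 4, 5))
  expect_equal(ft$peak_position_mm, c(3, 4, 5))
  expect_error(focal_metrics(amp, brain_mask = array(FALSE, dim(amp))),
               "empty")
})

test_that("field comparison records match hand arithmetic", {
  ref <- list(peak_amplitude = 1, peak_position_mm = c(0, 0, 0),
              focal_volume = 100)
  same <- compare_fields(ref, ref)
  expect_equal(same$focal_pressure_diff_percent, 0)
  expect_equal(same$focal_position_shift_mm, 0)
  expect_equal(same$focal_volume_diff_percent, 0)
  test <- list(peak_amplitude = 1.10, peak_position_mm = c(0.6, 0, 0.8),
               focal_volume = 100)
  cr <- compare_fields(ref, test)
  expect_equal(cr$focal_pressure_diff_percent, 10, tolerance = 1e-9)
  expect_equal(cr$focal_position_shift_mm, 1.0, tolerance = 1e-12)
  bad <- list(peak_amplitude = 0, peak_position_mm = c(0, 0, 0),
              focal_volume = 1)
  expect_error(compare_fields(bad, test), "zero reference")
})

test_that("aggregate report computes per-cell and pooled mean/SD", {
  rec <- function(s, tg, p) tibble::tibble(
    subject = s, target = tg, pct_kind = "cCT",
    focal_pressure_diff_percent = p,
    focal_position_shift_mm = p / 10,
    focal_volume_diff_percent = 2 * p)
  records <- rbind(rec(1, "V1", 4), rec(2, "V1", 6), rec(1, "M1", 5))
  rep <- aggregate_report(records)
  v1 <- rep[rep$target == "V1", ]
  expect_equal(v1$focal_pressure_diff_percent_mean, 5)
  expect_equal(v1$focal_pressure_diff_percent_sd, sd(c(4, 6)))
  one <- rep[rep$target == "M1", ]
  expect_equal(one$focal_pressure_diff_percent_sd, 0)
  all_row <- rep[rep$target == "All", ]
  expect_equal(all_row$n, 3L)
  expect_equal(all_row$n, sum(rep$n[rep$target != "All"]))
})
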