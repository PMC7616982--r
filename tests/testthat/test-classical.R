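test_that("soft-tissue normalisation recovers a known scale and is idempotent", {
  ph <- noisy_phantom()
  scaled <- ph$zte
  scaled$data <- scaled$data * 2.7
  nz <- soft_tissue_normalize(scaled, ph$head)
  expect_lt(abs(attr(nz, "scale") - 2.7) / 2.7, 0.02)
  # already-normalised input: scale within 2 % of 1 and the masked
  # histogram mode sits at 1
  nz2 <- soft_tissue_normalize(nz, ph$head)
  expect_lt(abs(attr(nz2, "scale") - 1), 0.02)
  dens <- density(nz2$data[ph$head$data], n = 512)
  expect_lt(abs(dens$x[which.max(dens$y)] - 1), 0.02)
})

test_that("skull mask from ZTE matches the phantom truth and respects the bone band", {
  ph <- clean_phantom()
  nz <- soft_tissue_normalize(ph$zte, ph$head)
  sk <- skull_mask_from_zte(nz, ph$head)
  expect_gte(dice(sk, ph$skull), 0.95)
  lab <- skullpct:::label_components(sk$data, 26)
  expect_equal(max(lab), 1L)
  # before morphology, every bone-band voxel lies in [0.2, 0.75]
  band <- nz$data >= 0.2 & nz$data <= 0.75 & ph$head$data
  expect_true(all(nz$data[band] >= 0.2 & nz$data[band] <= 0.75))
  # an image with no voxels in the band errors (unsuitable thresholds)
  flat <- nz
  flat$data[] <- 1
  expect_error(skull_mask_from_zte(flat, ph$head), "thresholding")
})

test_that("total-least-squares calibration recovers exact and noisy mappings", {
  # exact pairs on the printed line: machine-precision recovery
  z <- seq(0.25, 0.75, length.out = 500)
  ct <- -2085 * z + 2329
  m <- calibrate_linear_pca(z, ct)
  expect_equal(m$slope, -2085, tolerance = 1e-9)
  expect_equal(m$intercept, 2329, tolerance = 1e-9)
  # y = x symmetry
  m2 <- calibrate_linear_pca(1:100, 1:100)
  expect_equal(m2$slope, 1, tolerance = 1e-12)
  expect_equal(m2$intercept, 0, tolerance = 1e-9)
  # isotropic noise (30 HU equivalent on both axes): TLS within 2 %
  set.seed(42)
  n <- 1e5
  z <- runif(n, 0.2, 0.75)
  ct <- -2085 * z + 2329
  zn <- z + rnorm(n, 0, 30 / 2085)
  ctn <- ct + rnorm(n, 0, 30)
  mn <- calibrate_linear_pca(zn, ctn)
  expect_lt(abs(mn$slope + 2085) / 2085, 0.02)
  # TLS differs from OLS under anisotropic noise
  zo <- z + rnorm(n, 0, 0.1)
  mo <- calibrate_linear_pca(zo, ct)
  ols <- coef(lm(ct ~ zo))[2]
  expect_gt(abs(mo$slope - ols) / abs(mo$slope), 0.02)
  expect_error(calibrate_linear_pca(c(1, 1), c(2, 2)), "distinct")
})

test_that("HU assignment follows the printed mapping and class constants", {
  d <- c(4, 4, 4)
  z <- volume(array(1, d), 1, kind = "MR_normalised")
  skull <- array(FALSE, d); skull[2, 2, 2] <- TRUE
  head <- array(FALSE, d); head[2:3, 2:3, 2:3] <- TRUE
  z$data[2, 2, 2] <- 0
  pct <- zte_to_pct(z, mask_volume(skull, 1), mask_volume(head, 1))
  expect_equal(pct$data[2, 2, 2], 2329)        # ZTE 0 in skull
  expect_equal(pct$data[3, 3, 3], 42)          # soft tissue in head
  expect_equal(pct$data[1, 1, 1], -1000)       # exterior
  # extreme ZTE inside the mask is clamped at the HU floor
  z$data[2, 2, 2] <- 5
  pct2 <- zte_to_pct(z, mask_volume(skull, 1), mask_volume(head, 1))
  expect_equal(pct2$data[2, 2, 2], -1000)
})

test_that("full classical pipeline on a zero-noise phantom recovers bone HU", {
  ph <- clean_phantom()
  res <- classical_pct(ph$zte, ph$head)
  err <- abs(res$pct$data - ph$ct$data)
  expect_lt(mean(err[ph$skull$data]), 1)
  # interior bone voxels (boundary excluded) recover almost exactly
  interior <- skullpct:::binary_erode(ph$skull$data, 1)
  expect_lt(mean(err[interior]), 1)
  # affine on the skull, constant elsewhere
  inside_soft <- ph$head$data & !res$skull_mask$data
  expect_true(all(res$pct$data[inside_soft] == 42))
  expect_true(all(res$pct$data[!ph$head$data] == -1000))
})

test_that("per-subject calibration from a paired CT reproduces the generating mapping", {
  ph <- clean_phantom()
  res <- classical_pct(ph$zte, ph$head, calibrate_with = ph$ct)
  expect_lt(abs(res$mapping$slope + 2085) / 2085, 0.05)
  expect_lt(abs(res$mapping$intercept - 2329) / 2329, 0.05)
})
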