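test_that("noiseless skull HU stays within the cortical/diploe bounds and masks are consistent", {
  # without density modulation, the through-thickness profile is exactly
  # bounded by the diploe dip and the cortical peak
  spec0 <- desk_spec(noise = FALSE)
  spec0$skull_density_variation <- 0
  ph0 <- generate_ct_phantom(spec0)
  hu0 <- ph0$ct$data[ph0$skull$data]
  expect_true(all(hu0 >= spec0$skull_hu_profile[["diploe"]] - 1e-9))
  expect_true(all(hu0 <= spec0$skull_hu_profile[["cortical"]] + 1e-9))
  # with the default modulation the bounds widen by its amplitude
  ph <- clean_phantom()
  spec <- desk_spec(noise = FALSE)
  v <- spec$skull_density_variation
  hu <- ph$ct$data[ph$skull$data]
  expect_true(all(hu >= spec$skull_hu_profile[["diploe"]] * (1 - v) - 1e-9))
  expect_true(all(hu <= spec$skull_hu_profile[["cortical"]] * (1 + v) + 1e-9))
  expect_true(all(ph$skull$data <= ph$head$data))
  expect_true(all(ph$brain$data <= ph$head$data))
  expect_false(any(ph$skull$data & ph$brain$data))
})

test_that("generation is bit-identical for identical spec and seed", {
  a <- generate_phantom(desk_spec(seed = 5))
  b <- generate_phantom(desk_spec(seed = 5))
  expect_identical(a$ct$data, b$ct$data)
  expect_identical(a$zte$data, b$zte$data)
  expect_identical(a$t1w$data, b$t1w$data)
})

test_that("skull mask volume matches the analytic ellipsoid-shell volume", {
  spec <- phantom_spec(grid_shape = c(182, 222, 202), voxel_spacing_mm = 1,
                       head_radii_mm = c(70, 90, 80),
                       skull_thickness_mm = c(6, 0),
                       noise_sd = list(ct = 0, zte = 0, t1w = 0))
  ph <- generate_ct_phantom(spec)
  skin <- spec$skin_thickness_mm
  a_out <- spec$head_radii_mm - skin
  a_in <- a_out - spec$skull_thickness_mm[1]
  v_analytic <- 4 / 3 * pi * (prod(a_out) - prod(a_in))
  v_mask <- sum(ph$skull$data) * prod(ph$ct$spacing)
  expect_lt(abs(v_mask - v_analytic) / v_analytic, 0.05)
})

test_that("CT HU range honours air outside the head and the noise-clamped ceiling", {
  ph <- noisy_phantom()
  spec <- desk_spec(noise = TRUE)
  outside <- !ph$head$data
  expect_lt(max(abs(ph$ct$data[outside] + 1000)),
            6 * spec$noise_sd$ct)
  expect_lte(max(ph$ct$data),
             spec$skull_hu_profile[["cortical"]] *
               (1 + spec$skull_density_variation) + 3 * spec$noise_sd$ct)
})

test_that("synthetic ZTE inverts the printed linear bone mapping", {
  ph <- clean_phantom()
  sk <- ph$skull$data
  # bone voxel at HU = intercept maps to ZTE 0
  m <- hu_mapping(-2085, 2329)
  ct <- ph$ct
  ct$data[which(sk)[1]] <- 2329
  z <- generate_zte_from_ct(ct, ph$skull, ph$head, m, noise_sd = 0)
  expect_equal(z$data[which(sk)[1]], 0)
  # round trip through the classical mapping recovers bone HU exactly
  pct <- zte_to_pct(z, ph$skull, ph$head, m)
  expect_equal(pct$data[sk], ct$data[sk], tolerance = 1e-12)
  expect_error(generate_zte_from_ct(ct, ph$skull, ph$head, hu_mapping(0, 10)),
               "degenerate")
})

test_that("synthetic ZTE noise SD is recovered by Monte Carlo", {
  ph <- clean_phantom()
  z0 <- generate_zte_from_ct(ph$ct, ph$skull, ph$head, noise_sd = 0)
  z1 <- generate_zte_from_ct(ph$ct, ph$skull, ph$head, noise_sd = 0.02,
                             seed = 11)
  dd <- (z1$data - z0$data)[ph$skull$data]
  expect_gt(length(dd), 1e4)
  expect_lt(abs(sd(dd) - 0.02) / 0.02, 0.1)
})

test_that("T1w bone is dark and carries less HU information than ZTE", {
  ph <- clean_phantom()
  sk <- ph$skull$data
  soft <- ph$head$data & !sk
  expect_lt(mean(ph$t1w$data[sk]), mean(ph$t1w$data[soft]))
  phn <- noisy_phantom()
  skn <- phn$skull$data
  r_t1 <- abs(cor(abs(phn$ct$data[skn]), phn$t1w$data[skn]))
  r_zte <- abs(cor(phn$zte$data[skn], phn$ct$data[skn]))
  expect_lt(r_t1, r_zte)
  # determinism
  a <- generate_t1w_from_ct(ph$ct, ph, noise_sd = 0.03, seed = 4)
  b <- generate_t1w_from_ct(ph$ct, ph, noise_sd = 0.03, seed = 4)
  expect_identical(a$data, b$data)
})

test_that("bias field has unit mean over the head, bounded deviation, and amplitude 0 is the identity", {
  ph <- clean_phantom()
  expect_identical(apply_bias_field(ph$zte, 0), ph$zte)
  amp <- 0.2
  zb <- apply_bias_field(ph$zte, amp, seed = 2, head_mask = ph$head)
  field <- zb$data / ifelse(ph$zte$data == 0, NA, ph$zte$data)
  inside <- ph$head$data & !is.na(field)
  expect_lt(abs(mean(field[inside]) - 1), 0.01)
  expect_lte(max(abs(field[inside] - 1)), amp + 1e-9)
  expect_error(apply_bias_field(ph$zte, -0.1), "non-negative")
})

test_that("a grid too small for the head is rejected", {
  expect_error(phantom_spec(grid_shape = c(40, 40, 40), voxel_spacing_mm = 1,
                            head_radii_mm = c(70, 90, 80)),
               "grid too small")
})

test_that("phantom specs round-trip through YAML", {
  spec <- desk_spec(seed = 9)
  f <- tempfile(fileext = ".yaml")
  write_phantom_spec(spec, f)
  spec2 <- read_phantom_spec(f)
  expect_equal(spec2$head_radii_mm, spec$head_radii_mm)
  expect_equal(spec2$zte_mapping$slope, spec$zte_mapping$slope)
  expect_identical(generate_ct_phantom(spec2)$ct$data,
                   generate_ct_phantom(spec)$ct$data)
})
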