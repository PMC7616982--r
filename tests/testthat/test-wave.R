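test_that("O'Neil solution behaves at its limits and matches the Rayleigh integral", {
  # focus limit equals the analytic expression rho c u0 k h
  R <- 63.2; ap <- 64; f <- 500e3; cc <- 1500
  h <- (R - sqrt(R^2 - (ap / 2)^2)) / 1000
  k <- 2 * pi * f / cc
  p_focus <- abs(oneil_axial_bowl(R, ap, f, cc, R))
  expect_equal(p_focus, 1000 * cc * k * h, tolerance = 1e-9)
  # continuous through the singularity
  p_near <- abs(oneil_axial_bowl(R, ap, f, cc, c(R - 1e-4, R + 1e-4)))
  expect_lt(max(abs(p_near - p_focus)) / p_focus, 1e-3)
  # |p| approximately symmetric about the focus for a low-gain bowl
  lo <- abs(oneil_axial_bowl(40, 12, f, cc, 40 - c(1, 2, 3)))
  hi <- abs(oneil_axial_bowl(40, 12, f, cc, 40 + c(1, 2, 3)))
  expect_lt(max(abs(lo - hi) / lo), 0.2)
  # solid bowl Rayleigh integral vs closed form on axis, 6 PPW sampling
  solid <- transducer_spec(element_outer_diameters_mm = 64, kerf_mm = 0)
  z <- seq(25, 105, by = 0.5)
  pr <- abs(rayleigh_pressure(solid, cbind(0, 0, z)))
  po <- abs(oneil_axial_bowl(R, 64, f, cc, z))
  expect_lt(max(abs(pr - po)) / max(po), 0.01)
  expect_error(sample_bowl_source(solid, ppw = 3), "under-sampled")
})

test_that("Rayleigh solver converges in source density and is laterally symmetric and linear", {
  solid <- transducer_spec(element_outer_diameters_mm = 64, kerf_mm = 0)
  z <- seq(45, 80, by = 1)
  po <- abs(oneil_axial_bowl(63.2, 64, 500e3, 1500, z))
  errs <- vapply(c(4, 6, 9), function(ppw) {
    pr <- abs(rayleigh_pressure(solid, cbind(0, 0, z), ppw = ppw))
    max(abs(pr - po)) / max(po)
  }, 0)
  expect_true(all(diff(errs) < 0))
  # mirrored lateral samples agree to < 0.5 %
  tr <- transducer_spec()
  pts <- rbind(cbind(c(1, 2, 3), 0, 63.2), cbind(-c(1, 2, 3), 0, 63.2),
               cbind(0, c(1, 2, 3), 63.2), cbind(0, -c(1, 2, 3), 63.2))
  p <- abs(rayleigh_pressure(tr, pts))
  expect_lt(max(abs(p[1:3] - p[4:6]) / p[1:3]), 0.005)
  expect_lt(max(abs(p[7:9] - p[10:12]) / p[7:9]), 0.005)
  # linearity in source amplitude
  tr2 <- transducer_spec(source_amplitude = 3)
  p2 <- abs(rayleigh_pressure(tr2, pts))
  expect_equal(p2, 3 * p, tolerance = 1e-12)
})

test_that("transducer geometry invariants are enforced", {
  expect_error(transducer_spec(element_outer_diameters_mm = c(46, 32.8)),
               "increasing")
  expect_error(transducer_spec(roc_mm = 20,
                               element_outer_diameters_mm = c(30, 45)),
               "exceeds")
  b <- skullpct:::element_bands(transducer_spec())
  expect_equal(unname(b[, "outer"]), c(32.8, 46, 55.9, 64) / 2)
  expect_equal(unname(b[, "inner"]), c(0, c(32.8, 46, 55.9) / 2 + 0.5))
})

test_that("internal CW solver reproduces the homogeneous oracle and basic physics", {
  # small bowl keeps the domain cheap: water focus at 30 mm
  tr <- small_bowl()
  h <- 0.5
  nu <- 140; nv <- 140                     # 70 x 70 mm window
  med <- medium_slice_2d(matrix(1500, nu, nv), matrix(1000, nu, nv),
                         spacing_mm = h)
  focus <- c(35, 41)
  fld <- simulate_field_2d(med, tr, focus)
  src <- arc_source_2d(tr, focus, h, c(nu, nv))
  sxy <- cbind((src$idx[, 1] - 1) * h, (src$idx[, 2] - 1) * h)
  vline <- seq(24, 56, by = h)
  g <- abs(greens_2d(sxy, src$amp, cbind(35, vline), tr$frequency_hz))
  a <- fld$amplitude[71, round(vline / h) + 1]
  # amplitude profile within 2 % of the oracle (peak-normalised)
  expect_lt(max(abs(a / max(a) - g / max(g))), 0.02)
  # focal position within one grid cell of the oracle prediction
  expect_lt(abs(vline[which.max(a)] - vline[which.max(g)]), h + 1e-9)
  # a skull-like slab reduces the transmitted peak
  cs <- matrix(1500, nu, nv); rs <- matrix(1000, nu, nv)
  slab <- round(20 / h):round(26 / h)
  cs[, slab] <- 2800; rs[, slab] <- 1900
  al <- matrix(0, nu, nv); al[, slab] <- 8
  med2 <- medium_slice_2d(cs, rs, al, spacing_mm = h)
  fld2 <- simulate_field_2d(med2, tr, focus)
  post <- round(30 / h):nv
  expect_lt(max(fld2$amplitude[, post]), max(fld$amplitude[, post]))
})

test_that("internal solver is linear in source amplitude and translation-equivariant", {
  tr <- small_bowl()
  h <- 1
  med <- medium_slice_2d(matrix(1500, 70, 76), matrix(1000, 70, 76),
                         spacing_mm = h)
  f1 <- simulate_field_2d(med, tr, c(35, 38))
  tr3 <- small_bowl(); tr3$source_amplitude <- 3
  f3 <- simulate_field_2d(med, tr3, c(35, 38))
  expect_equal(f3$amplitude, 3 * f1$amplitude, tolerance = 1e-9)
  # rigid translation of transducer and medium moves the field rigidly
  med_t <- medium_slice_2d(matrix(1500, 70, 84), matrix(1000, 70, 84),
                           spacing_mm = h)
  f1t <- simulate_field_2d(med_t, tr, c(35, 38 + 8))
  expect_equal(f1t$amplitude[, 9:84], f1$amplitude, tolerance = 0.02 * max(f1$amplitude))
})

test_that("solver guards reject under-resolved grids and CFL violations", {
  med <- medium_slice_2d(matrix(1500, 20, 20), matrix(1000, 20, 20),
                         spacing_mm = 2)
  expect_error(cw_steady_state_2d(med, cbind(10, 2), 1 + 0i, 500e3,
                                  ppw_min = 2),
               "under-resolved")
  med2 <- medium_slice_2d(matrix(4500, 40, 40), matrix(1000, 40, 40),
                          spacing_mm = 0.5)
  expect_error(cw_steady_state_2d(med2, cbind(20, 2), 1 + 0i, 500e3,
                                  ppp = 20),
               "CFL")
})

test_that("run_simulation dispatches per backend and never falls back silently", {
  tr <- small_bowl()
  cfgr <- sim_config(tr, backend = "rayleigh",
                     field_points_mm = cbind(0, 0, c(25, 30, 35)))
  p1 <- run_simulation(cfgr)
  p2 <- run_simulation(cfgr)
  expect_identical(p1, p2)
  # CT-vs-pCT style configs differ only in the medium
  med <- medium_slice_2d(matrix(1500, 30, 30), matrix(1000, 30, 30),
                         spacing_mm = 1)
  med2 <- medium_slice_2d(matrix(1510, 30, 30), matrix(1000, 30, 30),
                          spacing_mm = 1)
  ca <- sim_config(tr, "internal2d", medium = med, focus_uv_mm = c(15, 15))
  cb <- sim_config(tr, "internal2d", medium = med2, focus_uv_mm = c(15, 15))
  expect_identical(config_diff_fields(ca, cb), "medium")
  # external backend writes a bundle, then errors without an import
  dir <- tempfile()
  ce <- sim_config(tr, "external", medium = med, exchange_dir = dir)
  expect_error(run_simulation(ce), "backend unavailable")
  expect_true(file.exists(file.path(dir, "source_points.csv")))
  expect_true(file.exists(file.path(dir, "grid_spec.json")))
})
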