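make_vol <- function(data, kind = "MR_raw") volume(data, 1, kind = kind)

test_that("midway reference of one image is its own inverse CDF; point masses average", {
  d <- c(8, 8, 4)
  v1 <- make_vol(array(runif(prod(d)), d))
  m <- mask_volume(array(TRUE, d), 1)
  ref <- build_midway_reference(list(v1), list(m))
  expect_equal(ref$inv_cdf,
               unname(quantile(v1$data, ref$q, type = 7)), tolerance = 1e-12)
  f <- tempfile(fileext = ".json")
  write_midway_reference(ref, f)
  ref_rt <- read_midway_reference(f)
  expect_equal(ref_rt$inv_cdf, ref$inv_cdf, tolerance = 1e-12)
  # two constant images 0 and 10 -> reference constant 5
  v0 <- make_vol(array(0, d)); v10 <- make_vol(array(10, d))
  ref2 <- build_midway_reference(list(v0, v10), list(m, m))
  expect_true(all(abs(ref2$inv_cdf - 5) < 1e-12))
  # uniform U(0,1) and U(0,3): median of the averaged inverse CDFs ~ 1.0
  set.seed(1)
  u1 <- make_vol(array(runif(4e4), c(40, 40, 25)))
  u3 <- make_vol(array(runif(4e4, 0, 3), c(40, 40, 25)))
  mm <- mask_volume(array(TRUE, c(40, 40, 25)), 1)
  ref3 <- build_midway_reference(list(u1, u3), list(mm, mm))
  expect_equal(ref3$inv_cdf[[round(length(ref3$q) / 2)]], 1.0, tolerance = 0.05)
  expect_error(build_midway_reference(list(), list()), "at least one")
})

test_that("midway equalisation is monotone, idempotent against own reference, and contracts histograms", {
  ph <- noisy_phantom()
  m <- ph$head
  ref_own <- build_midway_reference(list(ph$zte), list(m))
  eq <- midway_equalize(ph$zte, ref_own, m)
  inside <- m$data
  expect_lt(max(abs(eq$data[inside] - ph$zte$data[inside])), 0.02)
  # monotone: rank order preserved
  s <- sample(which(inside), 2000)
  expect_true(all(diff(eq$data[s][order(ph$zte$data[s])]) >= -1e-12))
  # equalising two phantoms to a common reference shrinks the Wasserstein
  # distance between their masked histograms
  ph2 <- generate_phantom(desk_spec(seed = 7))
  refc <- build_midway_reference(list(ph$zte, ph2$zte), list(m, ph2$head))
  w1 <- function(a, b) mean(abs(quantile(a, refc$q) - quantile(b, refc$q)))
  before <- w1(ph$zte$data[inside] * 1.3, ph2$zte$data[ph2$head$data])
  e1 <- midway_equalize(volume(ph$zte$data * 1.3, 2, kind = "MR_raw"), refc, m)
  e2 <- midway_equalize(ph2$zte, refc, ph2$head)
  after <- w1(e1$data[inside], e2$data[ph2$head$data])
  expect_lt(after, before)
  # constant input warns and passes through
  cv <- volume(array(1, dim(m$data)), 2, kind = "MR_raw")
  expect_warning(midway_equalize(cv, refc, m), "constant")
})

test_that("z-score normalisation matches its definition and inverts exactly", {
  ph <- noisy_phantom()
  v <- ph$zte
  mu <- mean(v$data); sd_ <- sd(v$data)
  z <- zscore_normalize(v, mu, sd_)
  expect_equal(mean(z$data), 0, tolerance = 1e-10)
  expect_equal(sd(z$data), 1, tolerance = 1e-10)
  back <- z$data * sd_ + mu
  expect_equal(back, v$data, tolerance = 1e-12)
  expect_identical(zscore_normalize(v, 0, 1)$data, v$data)
  expect_error(zscore_normalize(v, 0, 0), "positive")
})

test_that("cube padding is centred, uses air for HU, and round-trips", {
  hu <- volume(array(100, c(240, 200, 220)), 1, kind = "HU")
  p <- pad_to_cube(hu, 256)
  expect_equal(dim(p$volume$data), rep(256L, 3))
  expect_equal(p$offsets, as.integer(c(8, 28, 18)))
  expect_equal(p$volume$data[1, 1, 1], -1000)
  back <- crop_from_cube(p, dim(hu$data))
  expect_equal(back$data, hu$data)
  expect_equal(back$origin, hu$origin)
  # already-cubic input: identity with zero offsets
  cube <- volume(array(0, c(64, 64, 64)), 1, kind = "MR_raw")
  p2 <- pad_to_cube(cube, 64)
  expect_equal(p2$offsets, rep(0L, 3))
  expect_identical(p2$volume$data, cube$data)
  expect_error(pad_to_cube(hu, 128), "exceeds")
})

test_that("head mask from noiseless MR equals the generating mask; degenerate input errors", {
  ph <- clean_phantom()
  hm <- head_mask_from_mr(ph$zte)
  expect_identical(hm$data, ph$head$data)
  # noisy volumes still reach Dice >= 0.98 and a single component
  ph2 <- noisy_phantom()
  for (mod in c("zte", "t1w")) {
    hm2 <- head_mask_from_mr(ph2[[mod]])
    expect_gte(dice(hm2, ph2$head), 0.98)
    lab <- skullpct:::label_components(hm2$data, 6)
    expect_equal(max(lab), 1L)
  }
  flat <- volume(array(0, c(8, 8, 8)), 1, kind = "MR_raw")
  expect_error(head_mask_from_mr(flat), "constant")
})
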