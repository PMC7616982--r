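test_that("masked L1 loss matches hand arithmetic and its invariants", {
  pred <- matrix(c(1, 2, 3, 4), 4, 1)
  targ <- matrix(0, 4, 1)
  m1 <- matrix(1, 4, 1)
  expect_equal(as.numeric(masked_l1_loss(pred, targ, m1)), 2.5)
  # half mask, N still counts image pixels
  mh <- matrix(c(1, 1, 0, 0), 4, 1)
  expect_equal(as.numeric(masked_l1_loss(pred, targ, mh)), 0.75)
  expect_equal(as.numeric(masked_l1_loss(targ, targ, m1)), 0)
  expect_warning(masked_l1_loss(pred, targ, matrix(0, 4, 1)), "all-zero")
  # invariant to values outside the mask
  pred2 <- pred; pred2[3:4] <- 99
  expect_equal(as.numeric(masked_l1_loss(pred2, targ, mh)),
               as.numeric(masked_l1_loss(pred, targ, mh)))
  # non-negative on random cases
  set.seed(2)
  for (i in 1:20) {
    p <- matrix(rnorm(12), 12, 1); y <- matrix(rnorm(12), 12, 1)
    m <- matrix(rbinom(12, 1, 0.6), 12, 1)
    l <- as.numeric(suppressWarnings(masked_l1_loss(p, y, m)))
    expect_gte(l, 0)
  }
})

test_that("slice stacks have one stack per slice with replicated edges", {
  d <- c(8, 8, 12)
  v <- volume(array(seq_len(prod(d)), d), 1, kind = "MR_normalised")
  m <- mask_volume(array(TRUE, d), 1)
  ct <- volume(array(0, d), 1, kind = "HU")
  st <- make_slice_stacks(v, m, ct, n = 5)
  expect_length(st, d[3])
  expect_equal(st[[4]]$centre, 4L)
  # centre column equals the slice itself
  expect_equal(st[[4]]$x[, 3], as.vector(v$data[, , 4]))
  # below-volume neighbours replicate slice 1
  expect_equal(st[[1]]$x[, 1], as.vector(v$data[, , 1]))
  expect_equal(st[[1]]$x[, 2], as.vector(v$data[, , 1]))
  # n = 1: the stack is the slice
  s1 <- make_slice_stacks(v, m, ct, n = 1)
  expect_equal(s1[[7]]$x[, 1], as.vector(v$data[, , 7]))
  expect_error(make_slice_stacks(v, m, ct, n = 4), "odd")
})

test_that("affine augmentation is seeded, identity at zero ranges, and keeps masks binary", {
  hw <- c(16, 16)
  set.seed(3)
  stack <- matrix(rnorm(prod(hw) * 3), prod(hw), 3)
  y <- rnorm(prod(hw)); m <- as.numeric(runif(prod(hw)) > 0.4)
  zero_cfg <- training_config(rotation_deg = 0, translate_frac = 0,
                              shear_deg = 0)
  id <- augment_pair(stack, y, m, hw, zero_cfg, seed = 1)
  expect_equal(id$x, stack, tolerance = 1e-12)
  expect_equal(id$y, y, tolerance = 1e-12)
  expect_equal(id$m, m)
  cfg <- training_config()
  a1 <- augment_pair(stack, y, m, hw, cfg, seed = 9)
  a2 <- augment_pair(stack, y, m, hw, cfg, seed = 9)
  expect_identical(a1, a2)
  expect_true(all(a1$m %in% c(0, 1)))
})

test_that("U-Net gradients agree with finite differences", {
  cfg <- unet_config(levels = 2, convs_per_level = c(1, 1),
                     base_channels = 2, input_slices = 3,
                     output_scale = 1)
  model <- build_unet(cfg, c(8, 8), seed = 7)
  set.seed(42)
  X <- matrix(rnorm(8 * 8 * 3 * 2), 8 * 8 * 3, 2)
  Y <- matrix(rnorm(64 * 2), 64, 2)
  M <- matrix(rbinom(128, 1, 0.8), 64, 2)
  loss_t <- function() {
    f <- unet_forward(model, X, training = TRUE)
    as.numeric(masked_l1_loss(f$y, Y, M))
  }
  f <- unet_forward(model, X, training = TRUE)
  l <- masked_l1_loss(f$y, Y, M)
  unet_backward(model, attr(l, "grad"), f$cache)
  lays <- skullpct:::model_layers(model)
  for (li in seq_along(lays)) {
    lay <- lays[[li]]
    for (pn in intersect(c("W", "b", "gamma", "beta"), names(as.list(lay)))) {
      g <- lay[[paste0("g", pn)]]
      if (is.null(g)) next
      for (k in sample(length(lay[[pn]]), min(2, length(lay[[pn]])))) {
        eps <- 1e-5
        orig <- lay[[pn]][k]
        lay[[pn]][k] <- orig + eps; lp <- loss_t()
        lay[[pn]][k] <- orig - eps; lm <- loss_t()
        lay[[pn]][k] <- orig
        expect_equal(g[k], (lp - lm) / (2 * eps),
                     tolerance = 1e-3,
                     label = sprintf("grad layer %d %s[%d]", li, pn, k))
      }
    }
  }
})

test_that("parameter count of the full configured network matches hand arithmetic", {
  cfg <- unet_config()  # 5 levels, (2,2,3,3,3) convs, base 64, stack 11
  ch <- c(64, 128, 256, 512, 512)
  convs <- c(2, 2, 3, 3, 3)
  n_expected <- 0
  cin <- 11
  for (l in 1:5) {
    for (i in seq_len(convs[l])) {
      n_expected <- n_expected + ch[l] * (9 * cin) + ch[l]  # conv W + b
      n_expected <- n_expected + 2 * ch[l]                  # bn gamma + beta
      cin <- ch[l]
    }
  }
  for (l in 4:1) {
    n_expected <- n_expected + 4 * ch[l] * cin + ch[l]      # transposed conv
    cc <- 2 * ch[l]
    for (i in seq_len(convs[l])) {
      n_expected <- n_expected + ch[l] * (9 * cc) + ch[l] + 2 * ch[l]
      cc <- ch[l]
    }
    cin <- ch[l]
  }
  n_expected <- n_expected + 1 * ch[1] + 1                  # final 1x1 conv
  expect_equal(unet_n_parameters(cfg, input_hw = 16), n_expected)
})

test_that("identity-task training drives the loss toward zero and is seed-reproducible", {
  d <- c(32, 32, 20)
  set.seed(5)
  v <- volume(array(rnorm(prod(d)), d), 1, kind = "MR_normalised")
  m <- mask_volume(array(TRUE, d), 1)
  tgt <- v; tgt$kind <- "HU"
  stacks <- make_slice_stacks(v, m, tgt, n = 1)
  cfg <- unet_config_mini(input_slices = 1)
  cfg$output_scale <- 1
  tc <- training_config(batch_size = 10, lr = 1e-2, epochs = 20,
                        augment = FALSE, seed = 2)
  r1 <- train_unet(stacks, cfg, tc)
  expect_lt(tail(r1$history$train_loss, 1), 0.35 * r1$history$train_loss[1])
  r2 <- train_unet(stacks, cfg, tc)
  expect_identical(r1$history$train_loss, r2$history$train_loss)
})

test_that("predicted volumes have the input shape with air outside the head", {
  ph <- memo("train_phantoms", lapply(1:6, function(s) generate_phantom(train_spec(s))))[[1]]
  cfg <- unet_config_mini()
  model <- build_unet(cfg, c(64, 64), seed = 1)
  pred <- predict_volume(model, ph$zte, ph$head)
  expect_equal(dim(pred$data), dim(ph$zte$data))
  expect_true(all(pred$data[!ph$head$data] == -1000))
  expect_equal(pred$kind, "HU")
})

test_that("model state round-trips through serialisation", {
  cfg <- unet_config_mini(input_slices = 1)
  model <- build_unet(cfg, c(16, 16), seed = 3)
  st <- unet_state(model)
  model2 <- unet_load_state(st)
  X <- matrix(rnorm(16 * 16), 256, 1)
  expect_identical(unet_forward(model, X)$y, unet_forward(model2, X)$y)
  f <- tempfile(fileext = ".json")
  save_unet(model, f)
  model3 <- load_unet(f)
  expect_equal(unet_forward(model3, X)$y, unet_forward(model, X)$y,
               tolerance = 1e-8)
})
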