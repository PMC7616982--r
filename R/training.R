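#' Training configuration for the slice-stack network
#'
#' Mirrors the reference schedule: Adam at learning rate 1e-4 decayed by
#' reduce-on-plateau (patience 5, factor 0.2) down to 1e-6, mini-batches
#' of 32, and random affine augmentation (rotations within +/-10 degrees,
#' translations within +/-5 % of the image size, shears parallel to x of
#' +/-2.5 degrees, bilinear resampling).
#'
#' @param batch_size Mini-batch size (>= 1).
#' @param lr,lr_min Initial and floor learning rates.
#' @param patience,factor Reduce-on-plateau scheduling parameters.
#' @param epochs Training epochs.
#' @param augment Logical; apply affine augmentation per sample.
#' @param rotation_deg,translate_frac,shear_deg Augmentation ranges.
#' @param seed RNG seed controlling shuffling, dropout, augmentation.
#' @return A `training_config`.
#' @export
training_config <- function(batch_size = 32, lr = 1e-4, lr_min = 1e-6,
                            patience = 5, factor = 0.2, epochs = 300,
                            augment = TRUE, rotation_deg = 10,
                            translate_frac = 0.05, shear_deg = 2.5,
                            seed = 1L) {
  if (batch_size < 1) stop("batch size must be at least 1")
  if (lr <= 0 || lr_min <= 0) stop("learning-rate bounds must be positive")
  structure(list(batch_size = as.integer(batch_size), lr = lr, lr_min = lr_min,
                 patience = patience, factor = factor,
                 epochs = as.integer(epochs), augment = augment,
                 rotation_deg = rotation_deg, translate_frac = translate_frac,
                 shear_deg = shear_deg, seed = as.integer(seed)),
            class = "training_config")
}

#' Build slice stacks from a volume
#'
#' One stack per transverse (third-axis) slice: `n` consecutive in-plane
#' slices centred on the prediction target, with out-of-volume neighbours
#' replicated from the nearest valid slice. The paired target and mask
#' slices come from the aligned target volume and mask.
#'
#' @param vol Input MR `skull_volume`.
#' @param mask `skull_mask` (the training mask m_i).
#' @param target Target CT `skull_volume` (may be `NULL` for inference).
#' @param n Odd stack size.
#' @return List of `slice_stack`s, each with fields `x` (matrix
#'   `(H*W) x n`), `y`, `m` (vectors, `NULL` without target), `centre`.
#' @export
make_slice_stacks <- function(vol, mask, target = NULL, n = 11) {
  if (n %% 2 == 0) stop("stack size n must be odd")
  d <- dim(vol$data)
  hw <- d[1] * d[2]
  half <- (n - 1) / 2
  lapply(seq_len(d[3]), function(k) {
    ks <- pmin(pmax(k + (-half:half), 1L), d[3])
    x <- matrix(vol$data[, , ks], hw, n)
    structure(list(
      x = x,
      y = if (!is.null(target)) as.vector(target$data[, , k]),
      m = as.vector(mask$data[, , k]) * 1,
      centre = k, hw = c(d[1], d[2])), class = "slice_stack")
  })
}

#' Masked L1 training loss
#'
#' Per item, `(1/N_i) * || m_i * (y_i - yhat_i) ||_1` with `N_i` the
#' number of pixels in the image (not the mask cardinality), averaged over
#' the batch.
#'
#' @param prediction,target Matrices `(H*W) x N`.
#' @param mask Matrix of 0/1 weights, same shape.
#' @param pixel_count `N_i`; defaults to the number of rows.
#' @return Scalar loss; attribute `"grad"` holds the gradient w.r.t. the
#'   prediction.
#' @export
masked_l1_loss <- function(prediction, target, mask,
                           pixel_count = nrow(prediction)) {
  stopifnot(identical(dim(prediction), dim(target)),
            identical(dim(prediction), dim(mask)))
  if (all(mask == 0)) warning("all-zero mask: loss contribution is 0")
  n <- ncol(prediction)
  err <- mask * (prediction - target)
  loss <- sum(abs(err)) / (pixel_count * n)
  structure(loss, grad = mask * sign(err) / (pixel_count * n))
}

#' Random affine augmentation of a stack / target / mask triple
#'
#' Draws one affine transform (rotation, translation, x-parallel shear)
#' and applies it identically, with bilinear interpolation, to every slice
#' of the input stack, the target, and the mask; the mask is re-binarised
#' at 0.5.
#'
#' @param stack Matrix `(H*W) x n` of input slices.
#' @param target,mask Vectors of length `H*W`.
#' @param hw Length-2 in-plane dimensions.
#' @param config A [training_config()] (ranges; set all to 0 for identity).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return List `x`, `y`, `m` transformed.
#' @export
augment_pair <- function(stack, target, mask, hw, config, seed = NULL) {
  draw <- function() {
    th <- stats::runif(1, -config$rotation_deg, config$rotation_deg) * pi / 180
    sh <- stats::runif(1, -config$shear_deg, config$shear_deg) * pi / 180
    tx <- stats::runif(1, -config$translate_frac, config$translate_frac) * hw[1]
    ty <- stats::runif(1, -config$translate_frac, config$translate_frac) * hw[2]
    list(theta = th, shear = sh, tx = tx, ty = ty)
  }
  par <- if (is.null(seed)) draw() else with_seed(seed, draw())
  warp <- affine_warp_idx(hw, par)
  wf <- function(v) {
    as.vector(warp$w00 * v[warp$i00] + warp$w10 * v[warp$i10] +
                warp$w01 * v[warp$i01] + warp$w11 * v[warp$i11])
  }
  list(x = apply(stack, 2, wf),
       y = if (!is.null(target)) wf(target),
       m = as.numeric(wf(mask) >= 0.5))
}

# Precompute bilinear gather indices and weights for an inverse-mapped
# affine transform about the image centre.
affine_warp_idx <- function(hw, par) {
  h <- hw[1]; w <- hw[2]
  cx <- (h + 1) / 2; cy <- (w + 1) / 2
  gi <- rep(seq_len(h), w) - cx
  gj <- rep(seq_len(w), each = h) - cy
  # forward transform: shear (parallel to x) then rotation then translation;
  # apply the inverse to output coordinates
  ct <- cos(-par$theta); st <- sin(-par$theta)
  xi <- ct * (gi - par$tx) - st * (gj - par$ty)
  yj <- st * (gi - par$tx) + ct * (gj - par$ty)
  xi <- xi - tan(par$shear) * yj
  xi <- xi + cx; yj <- yj + cy
  xi <- pmin(pmax(xi, 1), h); yj <- pmin(pmax(yj, 1), w)
  i0 <- pmin(floor(xi), h - 1); j0 <- pmin(floor(yj), w - 1)
  fx <- xi - i0; fy <- yj - j0
  lin <- function(i, j) i + (j - 1) * h
  list(i00 = lin(i0, j0), i10 = lin(i0 + 1, j0),
       i01 = lin(i0, j0 + 1), i11 = lin(i0 + 1, j0 + 1),
       w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy),
       w01 = (1 - fx) * fy, w11 = fx * fy)
}

#' Train the slice-stack U-Net
#'
#' Mini-batch Adam on the masked L1 loss with per-sample affine
#' augmentation, reduce-on-plateau learning-rate scheduling on the
#' (masked) validation loss, and per-epoch loss history. Seeded runs are
#' reproducible.
#'
#' @param stacks List of training `slice_stack`s (from
#'   [make_slice_stacks()]).
#' @param unet_cfg A [unet_config()].
#' @param train_cfg A [training_config()].
#' @param val_stacks Optional validation stacks (no augmentation).
#' @param verbose Print per-epoch losses.
#' @return List with `model`, `history` (tibble: epoch, train_loss,
#'   val_loss, lr).
#' @export
train_unet <- function(stacks, unet_cfg, train_cfg, val_stacks = NULL,
                       verbose = FALSE) {
  if (length(stacks) == 0L) stop("empty training set")
  hw <- stacks[[1]]$hw
  n_slices <- ncol(stacks[[1]]$x)
  if (n_slices != unet_cfg$input_slices)
    stop("stack size does not match the network's input_slices")
  model <- build_unet(unet_cfg, hw, seed = train_cfg$seed)
  history <- list()
  with_seed(train_cfg$seed + 1L, {
    lr <- train_cfg$lr
    tstep <- 0
    best_val <- Inf
    wait <- 0
    for (epoch in seq_len(train_cfg$epochs)) {
      ord <- sample(length(stacks))
      ep_loss <- 0; n_batches <- 0
      for (s in seq(1L, length(stacks), by = train_cfg$batch_size)) {
        ids <- ord[s:min(s + train_cfg$batch_size - 1L, length(stacks))]
        batch <- lapply(stacks[ids], function(st) {
          if (train_cfg$augment)
            augment_pair(st$x, st$y, st$m, hw, train_cfg)
          else list(x = st$x, y = st$y, m = st$m)
        })
        X <- vapply(batch, function(b) as.vector(b$x),
                    numeric(prod(hw) * n_slices))
        Y <- vapply(batch, function(b) b$y, numeric(prod(hw)))
        M <- vapply(batch, function(b) b$m, numeric(prod(hw)))
        fwd <- unet_forward(model, X, training = TRUE)
        loss <- masked_l1_loss(fwd$y, Y, M)
        if (!is.finite(loss))
          stop("training diverged: non-finite loss at epoch ", epoch)
        unet_backward(model, attr(loss, "grad"), fwd$cache)
        tstep <- tstep + 1
        adam_step(model, lr, tstep)
        ep_loss <- ep_loss + as.numeric(loss); n_batches <- n_batches + 1
      }
      train_loss <- ep_loss / n_batches
      val_loss <- if (!is.null(val_stacks)) {
        eval_loss(model, val_stacks)
      } else train_loss
      # reduce-on-plateau
      if (val_loss < best_val - 1e-12) {
        best_val <- val_loss; wait <- 0
      } else {
        wait <- wait + 1
        if (wait > train_cfg$patience) {
          lr <- max(lr * train_cfg$factor, train_cfg$lr_min)
          wait <- 0
        }
      }
      history[[epoch]] <- tibble::tibble(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss, lr = lr)
      if (verbose)
        message(sprintf("epoch %3d  train %.4g  val %.4g  lr %.2g",
                        epoch, train_loss, val_loss, lr))
    }
    bn_recalibrate(model, stacks, train_cfg$batch_size)
  })
  list(model = model, history = do.call(rbind, history))
}

# Recalibrate batch-normalisation running statistics with one pass over
# the training set: running mean/var are set to the exact average of the
# per-batch statistics, closing the train/eval normalisation gap that
# small, heterogeneous slice batches otherwise leave.
bn_recalibrate <- function(model, stacks, batch_size = 32) {
  bn_layers <- Filter(function(l) l$type == "bn", model_layers(model))
  for (l in bn_layers) { l$momentum_saved <- l$momentum }
  hw <- stacks[[1]]$hw
  starts <- seq(1L, length(stacks), by = batch_size)
  for (bi in seq_along(starts)) {
    for (l in bn_layers) l$momentum <- 1 / bi
    ids <- starts[bi]:min(starts[bi] + batch_size - 1L, length(stacks))
    X <- vapply(stacks[ids], function(st) as.vector(st$x),
                numeric(prod(hw) * ncol(stacks[[1]]$x)))
    unet_forward(model, X, training = TRUE)
  }
  for (l in bn_layers) { l$momentum <- l$momentum_saved }
  invisible(model)
}

# Mean masked L1 loss over a stack list in evaluation mode.
eval_loss <- function(model, stacks, batch_size = 32) {
  hw <- stacks[[1]]$hw
  total <- 0
  for (s in seq(1L, length(stacks), by = batch_size)) {
    ids <- s:min(s + batch_size - 1L, length(stacks))
    X <- vapply(stacks[ids], function(st) as.vector(st$x),
                numeric(prod(hw) * ncol(stacks[[1]]$x)))
    Y <- vapply(stacks[ids], function(st) st$y, numeric(prod(hw)))
    M <- vapply(stacks[ids], function(st) st$m, numeric(prod(hw)))
    fwd <- unet_forward(model, X, training = FALSE)
    total <- total + as.numeric(masked_l1_loss(fwd$y, Y, M)) * length(ids)
  }
  total / length(stacks)
}

#' Reconstruct a 3D pseudo-CT volume slice by slice
#'
#' Builds slice stacks over the input MR volume, predicts each centre
#' slice in evaluation mode, and re-stacks the predictions into a 3D HU
#' volume; voxels outside the head mask are set to -1000.
#'
#' @param model A trained `unet_model`.
#' @param mr_volume Input MR `skull_volume`.
#' @param head_mask Head `skull_mask`.
#' @param batch_size Slices predicted per forward pass.
#' @return Pseudo-CT `skull_volume` in HU.
#' @export
predict_volume <- function(model, mr_volume, head_mask,
                           batch_size = 16) {
  stopifnot_aligned(mr_volume, head_mask)
  d <- dim(mr_volume$data)
  if (any(d[1:2] != model$input_hw))
    stop("in-plane dimensions do not match the trained model")
  stacks <- make_slice_stacks(mr_volume, head_mask, target = NULL,
                              n = model$config$input_slices)
  out <- array(-1000, d)
  hw <- prod(d[1:2])
  for (s in seq(1L, length(stacks), by = batch_size)) {
    ids <- s:min(s + batch_size - 1L, length(stacks))
    X <- vapply(stacks[ids], function(st) as.vector(st$x),
                numeric(hw * model$config$input_slices))
    pred <- unet_forward(model, X, training = FALSE)$y
    for (q in seq_along(ids)) out[, , ids[q]] <- pred[, q]
  }
  out[!head_mask$data] <- -1000
  volume(out, mr_volume$spacing, mr_volume$origin, kind = "HU")
}
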