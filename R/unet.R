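#' U-Net configuration for slice-stack regression
#'
#' Five-level encoder/decoder with skip connections on all but the deepest
#' level, 3x3 zero-padded stride-1 convolutions each followed by ReLU and
#' batch normalisation, 2x2 stride-2 max pooling, 2x2 stride-2 transposed
#' convolutions followed by dropout on the decoder path, and a final 1x1
#' convolution mapping the feature vector to Hounsfield units. Channel
#' widths start at `base_channels` and double at each encoder level except
#' the deepest; the decoder mirrors the encoder. The network input is a
#' stack of `input_slices` consecutive transverse slices and the output is
#' the single centre slice.
#'
#' @param levels Number of resolution levels (default 5).
#' @param convs_per_level Convolutions per encoder level
#'   (default `c(2, 2, 3, 3, 3)`).
#' @param base_channels First-level channel width (default 64).
#' @param input_slices Stack size n (odd; default 11).
#' @param dropout_p Decoder dropout probability (0.1 for T1w, 0 for ZTE).
#' @param output_scale Fixed factor applied to the final 1x1 convolution's
#'   output. The default 1 maps features to Hounsfield units directly;
#'   the miniature configuration uses 1000 so the HU dynamic range is
#'   reachable from unit-scale batch-normalised features within a short
#'   training budget.
#' @return A `unet_config`.
#' @export
unet_config <- function(levels = 5, convs_per_level = c(2, 2, 3, 3, 3),
                        base_channels = 64, input_slices = 11,
                        dropout_p = 0, output_scale = 1) {
  if (input_slices %% 2 == 0) stop("input stack size must be odd")
  if (length(convs_per_level) != levels)
    stop("convs_per_level must have one entry per level")
  structure(list(levels = levels, convs_per_level = convs_per_level,
                 base_channels = base_channels, input_slices = input_slices,
                 dropout_p = dropout_p, output_scale = output_scale),
            class = "unet_config")
}

#' @rdname unet_config
#' @export
unet_config_mini <- function(input_slices = 3, dropout_p = 0,
                             base_channels = 8) {
  unet_config(levels = 2, convs_per_level = c(2, 2),
              base_channels = base_channels, input_slices = input_slices,
              dropout_p = dropout_p, output_scale = 1000)
}

# Channel width at each encoder level (deepest level is not doubled).
unet_channels <- function(config) {
  L <- config$levels
  ch <- config$base_channels * 2^(seq_len(L) - 1)
  if (L > 1) ch[L] <- ch[L - 1]
  ch
}

#' Build a U-Net model for a given slice size
#'
#' @param config A [unet_config()].
#' @param input_hw In-plane slice size (length 1 or 2); each dimension
#'   must be divisible by `2^(levels - 1)`.
#' @param seed RNG seed for the He-initialised weights.
#' @return A `unet_model` (mutable layer environments plus topology).
#' @export
build_unet <- function(config, input_hw = 64, seed = 1L) {
  input_hw <- rep_len(as.integer(input_hw), 2L)
  L <- config$levels
  if (any(input_hw %% 2^(L - 1) != 0))
    stop("in-plane dims must be divisible by 2^(levels-1)")
  ch <- unet_channels(config)
  e <- function(l) list2env(l, envir = new.env(parent = emptyenv()))
  model <- with_seed(seed, {
    rng <- function(n) stats::rnorm(n)
    enc <- vector("list", L); pools <- vector("list", L - 1)
    h <- input_hw[1]; w <- input_hw[2]
    cin <- config$input_slices
    dims <- list()
    for (l in seq_len(L)) {
      blk <- list()
      for (i in seq_len(config$convs_per_level[l])) {
        cout <- ch[l]
        blk[[length(blk) + 1L]] <- e(new_conv(cin, cout, 3L, h, w, rng))
        blk[[length(blk) + 1L]] <- e(new_batchnorm(cout, h * w))
        cin <- cout
      }
      enc[[l]] <- blk
      dims[[l]] <- c(h, w)
      if (l < L) {
        pools[[l]] <- e(new_maxpool(h, w, ch[l]))
        h <- h %/% 2L; w <- w %/% 2L
      }
    }
    dec <- vector("list", L - 1)
    for (l in rev(seq_len(L - 1))) {
      hw_up <- dims[[l]]
      up <- e(new_convtranspose(cin, ch[l], hw_up[1] %/% 2L, hw_up[2] %/% 2L, rng))
      blk <- list()
      cc <- 2L * ch[l]  # after skip concatenation
      for (i in seq_len(config$convs_per_level[l])) {
        blk[[length(blk) + 1L]] <- e(new_conv(cc, ch[l], 3L, hw_up[1], hw_up[2], rng))
        blk[[length(blk) + 1L]] <- e(new_batchnorm(ch[l], hw_up[1] * hw_up[2]))
        cc <- ch[l]
      }
      dec[[l]] <- list(up = up, convs = blk)
      cin <- ch[l]
    }
    final <- e(new_conv(ch[1], 1L, 1L, input_hw[1], input_hw[2], rng))
    list(enc = enc, pools = pools, dec = dec, final = final)
  })
  structure(list(config = config, input_hw = input_hw, channels = ch,
                 enc = model$enc, pools = model$pools, dec = model$dec,
                 final = model$final),
            class = "unet_model")
}

# Conv -> ReLU -> BatchNorm block step
block_forward <- function(blk, x, training) {
  caches <- vector("list", length(blk))
  for (i in seq_along(blk)) {
    lay <- blk[[i]]
    if (lay$type == "conv") {
      r <- conv_forward(lay, x)
      rr <- relu_forward(r$y)
      caches[[i]] <- list(conv = r$cache, relu = rr$cache)
      x <- rr$y
    } else {
      r <- bn_forward(lay, x, training)
      caches[[i]] <- r$cache
      x <- r$y
    }
  }
  list(y = x, caches = caches)
}

block_backward <- function(blk, dy, caches, n) {
  for (i in rev(seq_along(blk))) {
    lay <- blk[[i]]
    if (lay$type == "conv") {
      dy <- relu_backward(dy, caches[[i]]$relu)
      g <- conv_backward(lay, dy, caches[[i]]$conv, n)
      lay$gW <- g$dW; lay$gb <- g$db
      dy <- g$dx
    } else {
      g <- bn_backward(lay, dy, caches[[i]])
      lay$ggamma <- g$dgamma; lay$gbeta <- g$dbeta
      dy <- g$dx
    }
  }
  dy
}

#' Forward pass of the U-Net
#'
#' @param model A `unet_model`.
#' @param x Input matrix `(H*W*input_slices) x N`.
#' @param training Logical; enables batch statistics and dropout.
#' @return List with `y` (prediction, `(H*W) x N`) and `cache` (for the
#'   backward pass).
#' @export
unet_forward <- function(model, x, training = FALSE) {
  L <- model$config$levels
  skips <- vector("list", L - 1)
  cache <- list(enc = vector("list", L), pool = vector("list", L - 1),
                dec = vector("list", L - 1))
  for (l in seq_len(L)) {
    r <- block_forward(model$enc[[l]], x, training)
    cache$enc[[l]] <- r$caches
    x <- r$y
    if (l < L) {
      skips[[l]] <- x
      p <- pool_forward(model$pools[[l]], x)
      cache$pool[[l]] <- p$cache
      x <- p$y
    }
  }
  for (l in rev(seq_len(L - 1))) {
    up <- convt_forward(model$dec[[l]]$up, x)
    dr <- dropout_forward(up$y, model$config$dropout_p, training, stats::runif)
    nskip <- nrow(skips[[l]])
    x <- rbind(dr$y, skips[[l]])
    r <- block_forward(model$dec[[l]]$convs, x, training)
    cache$dec[[l]] <- list(up = up$cache, drop = dr$cache, convs = r$caches,
                           n_up = nrow(up$y))
    x <- r$y
  }
  fin <- conv_forward(model$final, x)
  cache$final <- fin$cache
  list(y = fin$y * model$config$output_scale, cache = cache)
}

#' Backward pass: writes gradients into the layer environments
#'
#' @param model A `unet_model`.
#' @param dy Gradient of the loss w.r.t. the prediction (`(H*W) x N`).
#' @param cache Cache from [unet_forward()].
#' @return Invisibly, the gradient w.r.t. the input.
#' @export
unet_backward <- function(model, dy, cache) {
  n <- ncol(dy)
  L <- model$config$levels
  dy <- dy * model$config$output_scale
  g <- conv_backward(model$final, dy, cache$final, n)
  model$final$gW <- g$dW; model$final$gb <- g$db
  dy <- g$dx
  dskips <- vector("list", L - 1)
  for (l in seq_len(L - 1)) {
    cc <- cache$dec[[l]]
    dy <- block_backward(model$dec[[l]]$convs, dy, cc$convs, n)
    n_up <- cc$n_up
    d_up <- dy[seq_len(n_up), , drop = FALSE]
    dskips[[l]] <- dy[n_up + seq_len(nrow(dy) - n_up), , drop = FALSE]
    d_up <- dropout_backward(d_up, cc$drop)
    g <- convt_backward(model$dec[[l]]$up, d_up, cc$up, n)
    model$dec[[l]]$up$gW <- g$dW; model$dec[[l]]$up$gb <- g$db
    dy <- g$dx
  }
  for (l in rev(seq_len(L))) {
    if (l < L) {
      dy <- pool_backward(model$pools[[l]], dy, cache$pool[[l]], n)
      dy <- dy + dskips[[l]]
    }
    dy <- block_backward(model$enc[[l]], dy, cache$enc[[l]], n)
  }
  invisible(dy)
}

# All trainable layer environments of a model, in a stable order.
model_layers <- function(model) {
  out <- list()
  for (l in seq_along(model$enc)) out <- c(out, model$enc[[l]])
  for (l in seq_along(model$dec)) {
    out <- c(out, list(model$dec[[l]]$up), model$dec[[l]]$convs)
  }
  c(out, list(model$final))
}

#' Number of trainable parameters of a U-Net
#'
#' @param model A `unet_model` (or a [unet_config()] plus `input_hw`).
#' @param input_hw Slice size when `model` is a config.
#' @return Integer parameter count.
#' @export
unet_n_parameters <- function(model, input_hw = 64) {
  if (inherits(model, "unet_config")) model <- build_unet(model, input_hw)
  sum(vapply(model_layers(model), function(l) {
    length(l$W %||% NULL) + length(l$b %||% NULL) +
      length(l$gamma %||% NULL) + length(l$beta %||% NULL)
  }, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One Adam step over all trainable layers; gradient fields (gW, gb,
# ggamma, gbeta) must have been filled by unet_backward.
adam_step <- function(model, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (lay in model_layers(model)) {
    for (pn in c("W", "b", "gamma", "beta")) {
      if (is.null(lay[[pn]])) next
      gn <- paste0("g", pn)
      g <- lay[[gn]]
      if (is.null(g)) next
      mn <- paste0("adam_m_", pn); vn <- paste0("adam_v_", pn)
      if (is.null(lay[[mn]])) { lay[[mn]] <- g * 0; lay[[vn]] <- g * 0 }
      lay[[mn]] <- beta1 * lay[[mn]] + (1 - beta1) * g
      lay[[vn]] <- beta2 * lay[[vn]] + (1 - beta2) * g^2
      mh <- lay[[mn]] / (1 - beta1^t)
      vh <- lay[[vn]] / (1 - beta2^t)
      lay[[pn]] <- lay[[pn]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  invisible(model)
}

#' Serialise / restore model weights
#'
#' Weights and batch-norm statistics as a plain named list of numeric
#' objects (JSON- or RDS-friendly), with the config embedded.
#'
#' @param model A `unet_model`.
#' @return `unet_state` returns a list; `unet_load_state` a `unet_model`.
#' @export
unet_state <- function(model) {
  layers <- model_layers(model)
  st <- lapply(layers, function(l) {
    keep <- intersect(c("W", "b", "gamma", "beta", "run_mean", "run_var"),
                      names(as.list(l)))
    mget(keep, envir = l)
  })
  list(config = unclass(model$config), input_hw = model$input_hw, layers = st)
}

#' @rdname unet_state
#' @param path File path (JSON).
#' @export
save_unet <- function(model, path) {
  jsonlite::write_json(unet_state(model), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname unet_state
#' @export
load_unet <- function(path) {
  st <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                           simplifyMatrix = TRUE)
  st$layers <- lapply(st$layers, function(l) Filter(Negate(is.null), l))
  unet_load_state(st)
}

#' @rdname unet_state
#' @param state A list from `unet_state`.
#' @export
unet_load_state <- function(state) {
  cfg <- do.call(unet_config, state$config[c("levels", "convs_per_level",
                                             "base_channels", "input_slices",
                                             "dropout_p", "output_scale")])
  model <- build_unet(cfg, state$input_hw)
  layers <- model_layers(model)
  stopifnot(length(layers) == length(state$layers))
  for (i in seq_along(layers)) {
    for (nm in names(state$layers[[i]])) {
      v <- state$layers[[i]][[nm]]
      old <- layers[[i]][[nm]]
      if (is.matrix(old)) v <- matrix(unlist(v), nrow(old), ncol(old))
      layers[[i]][[nm]] <- v
    }
  }
  model
}
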