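#' U-Net lung-field segmentation
#'
#' A standard 4-down/4-up encoder-decoder with two 3x3 convolutions per
#' stage, channel-doubling widths, 2x2 max pooling, nearest-neighbour
#' upsampling followed by a 3x3 convolution, skip concatenations, dropout
#' at the bottleneck and a sigmoid 1x1 output head. Trained with binary
#' cross-entropy and Adam; the probability map is thresholded at 0.5 to
#' give the binary lung mask whose pixel count is the lung area `A_Lung`.
#'
#' At full scale the network runs on 512x512 letterboxed CLAHE images with
#' base width 64; the desk profile used throughout the test suite runs on
#' 64x64 phantoms with base width 16.
#'
#' @name segmentation
NULL

#' Segmentation training configuration
#'
#' @param epochs maximum training epochs (clinical recipe: 100).
#' @param batch_size minibatch size (default 2).
#' @param learning_rate Adam learning rate (clinical recipe: 1e-4).
#' @param dropout_rate bottleneck dropout probability in `[0, 1)`.
#' @param early_stop_patience epochs without validation improvement
#'   before stopping (default 10).
#' @param input_size square input frame in pixels; must be divisible
#'   by 16.
#' @param base_width channels of the first encoder stage.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return a `seg_config` list.
#' @export
seg_config <- function(epochs = 100L, batch_size = 2L, learning_rate = 1e-4,
                       dropout_rate = 0.2, early_stop_patience = 10L,
                       input_size = 512L, base_width = 64L, seed = 1L) {
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate > 0,
            dropout_rate >= 0, dropout_rate < 1, early_stop_patience >= 1,
            input_size >= 16, input_size %% 16 == 0, base_width >= 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, dropout_rate = dropout_rate,
                 early_stop_patience = as.integer(early_stop_patience),
                 input_size = as.integer(input_size),
                 base_width = as.integer(base_width), seed = as.integer(seed)),
            class = "seg_config")
}

#' Desk-scale segmentation profile
#'
#' The CPU-friendly recipe used by the package's own tests: 64x64 inputs,
#' base width 16, up to 30 epochs with early-stopping patience 5, and a
#' 1e-3 learning rate (the clinical 1e-4 is unnecessarily conservative
#' for a network this small).
#'
#' @param seed integer seed.
#' @param ... overrides passed to [seg_config()].
#' @export
seg_config_desk <- function(seed = 1L, ...) {
  args <- list(epochs = 30L, learning_rate = 1e-3, early_stop_patience = 5L,
               input_size = 64L, base_width = 16L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(seg_config, args)
}

unet_init <- function(base_width) {
  c0 <- base_width
  p <- list()
  p$e11 <- nn_conv_init(3, 1, c0);        p$e12 <- nn_conv_init(3, c0, c0)
  p$e21 <- nn_conv_init(3, c0, 2 * c0);   p$e22 <- nn_conv_init(3, 2 * c0, 2 * c0)
  p$e31 <- nn_conv_init(3, 2 * c0, 4 * c0); p$e32 <- nn_conv_init(3, 4 * c0, 4 * c0)
  p$e41 <- nn_conv_init(3, 4 * c0, 8 * c0); p$e42 <- nn_conv_init(3, 8 * c0, 8 * c0)
  p$b1 <- nn_conv_init(3, 8 * c0, 16 * c0); p$b2 <- nn_conv_init(3, 16 * c0, 16 * c0)
  p$u4 <- nn_conv_init(3, 16 * c0, 8 * c0)
  p$d41 <- nn_conv_init(3, 16 * c0, 8 * c0); p$d42 <- nn_conv_init(3, 8 * c0, 8 * c0)
  p$u3 <- nn_conv_init(3, 8 * c0, 4 * c0)
  p$d31 <- nn_conv_init(3, 8 * c0, 4 * c0);  p$d32 <- nn_conv_init(3, 4 * c0, 4 * c0)
  p$u2 <- nn_conv_init(3, 4 * c0, 2 * c0)
  p$d21 <- nn_conv_init(3, 4 * c0, 2 * c0);  p$d22 <- nn_conv_init(3, 2 * c0, 2 * c0)
  p$u1 <- nn_conv_init(3, 2 * c0, c0)
  p$d11 <- nn_conv_init(3, 2 * c0, c0);      p$d12 <- nn_conv_init(3, c0, c0)
  p$out <- nn_conv_init(1, c0, 1, gain = 1)
  p
}

cat3 <- function(a, b) array(c(a, b), c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))

unet_forward <- function(params, x, train = FALSE, dropout_rate = 0) {
  cache <- list(x = x)
  enc_stage <- function(x, n1, n2) {
    a1 <- nn_relu_fw(nn_conv_fw(x, params[[n1]]))
    a2 <- nn_relu_fw(nn_conv_fw(a1, params[[n2]]))
    list(a1 = a1, a2 = a2)
  }
  s1 <- enc_stage(x, "e11", "e12");  p1 <- .maxpool_fw(s1$a2)
  s2 <- enc_stage(p1$y, "e21", "e22"); p2 <- .maxpool_fw(s2$a2)
  s3 <- enc_stage(p2$y, "e31", "e32"); p3 <- .maxpool_fw(s3$a2)
  s4 <- enc_stage(p3$y, "e41", "e42"); p4 <- .maxpool_fw(s4$a2)
  sb <- enc_stage(p4$y, "b1", "b2")
  bott <- sb$a2
  drop_mask <- NULL
  if (train && dropout_rate > 0) {
    drop_mask <- array((stats::runif(length(bott)) >= dropout_rate) /
                         (1 - dropout_rate), dim(bott))
    bott <- bott * drop_mask
  }
  dec_stage <- function(below, skip, nu, n1, n2) {
    up_in <- .upsample2_fw(below)
    u <- nn_relu_fw(nn_conv_fw(up_in, params[[nu]]))
    cat <- cat3(u, skip)
    a1 <- nn_relu_fw(nn_conv_fw(cat, params[[n1]]))
    a2 <- nn_relu_fw(nn_conv_fw(a1, params[[n2]]))
    list(up_in = up_in, u = u, cat = cat, a1 = a1, a2 = a2)
  }
  d4 <- dec_stage(bott, s4$a2, "u4", "d41", "d42")
  d3 <- dec_stage(d4$a2, s3$a2, "u3", "d31", "d32")
  d2 <- dec_stage(d3$a2, s2$a2, "u2", "d21", "d22")
  d1 <- dec_stage(d2$a2, s1$a2, "u1", "d11", "d12")
  z <- nn_conv_fw(d1$a2, params$out)
  y <- nn_sigmoid_fw(z)
  cache <- list(x = x, s1 = s1, p1 = p1, s2 = s2, p2 = p2, s3 = s3, p3 = p3,
                s4 = s4, p4 = p4, sb = sb, drop_mask = drop_mask, bott = bott,
                d4 = d4, d3 = d3, d2 = d2, d1 = d1, z = z, y = y)
  cache
}

# backward pass from dz = dL/d(logits); returns a flat grad list
unet_backward <- function(params, cache, dz) {
  grads <- list()
  g <- nn_conv_bw(cache$d1$a2, params$out, dz)
  grads <- acc_grad(grads, "out", g$dw, g$db)
  da <- g$dx
  dec_bw <- function(dec, below, skip_dim, nu, n1, n2, da) {
    d2_ <- nn_relu_bw(dec$a2, da)
    g2 <- nn_conv_bw(dec$a1, params[[n2]], d2_)
    grads <<- acc_grad(grads, n2, g2$dw, g2$db)
    d1_ <- nn_relu_bw(dec$a1, g2$dx)
    g1 <- nn_conv_bw(dec$cat, params[[n1]], d1_)
    grads <<- acc_grad(grads, n1, g1$dw, g1$db)
    cu <- dim(dec$u)[3]
    dcat <- g1$dx
    du <- dcat[, , seq_len(cu), drop = FALSE]
    dskip <- dcat[, , cu + seq_len(skip_dim), drop = FALSE]
    du <- nn_relu_bw(dec$u, du)
    gu <- nn_conv_bw(dec$up_in, params[[nu]], du)
    grads <<- acc_grad(grads, nu, gu$dw, gu$db)
    dbelow <- .upsample2_bw(gu$dx)
    list(dbelow = dbelow, dskip = dskip)
  }
  b1 <- dec_bw(cache$d1, cache$d2$a2, dim(cache$s1$a2)[3], "u1", "d11", "d12", da)
  b2 <- dec_bw(cache$d2, cache$d3$a2, dim(cache$s2$a2)[3], "u2", "d21", "d22", b1$dbelow)
  b3 <- dec_bw(cache$d3, cache$d4$a2, dim(cache$s3$a2)[3], "u3", "d31", "d32", b2$dbelow)
  b4 <- dec_bw(cache$d4, cache$bott, dim(cache$s4$a2)[3], "u4", "d41", "d42", b3$dbelow)

  dbott <- b4$dbelow
  if (!is.null(cache$drop_mask)) dbott <- dbott * cache$drop_mask

  enc_bw <- function(stage, xin, n1, n2, da) {
    d2_ <- nn_relu_bw(stage$a2, da)
    g2 <- nn_conv_bw(stage$a1, params[[n2]], d2_)
    grads <<- acc_grad(grads, n2, g2$dw, g2$db)
    d1_ <- nn_relu_bw(stage$a1, g2$dx)
    g1 <- nn_conv_bw(xin, params[[n1]], d1_)
    grads <<- acc_grad(grads, n1, g1$dw, g1$db)
    g1$dx
  }
  # pool gradients: route decoder skip grads + pooled grads back through encoder
  pool_bw <- function(pool, below_grad, skip_grad, stage_a2) {
    d <- .maxpool_bw(below_grad, pool$idx, dim(stage_a2)[1], dim(stage_a2)[2],
                     dim(stage_a2)[3])
    d + skip_grad
  }
  din_b <- enc_bw(cache$sb, cache$p4$y, "b1", "b2", dbott)
  da4 <- pool_bw(cache$p4, din_b, b4$dskip, cache$s4$a2)
  din4 <- enc_bw(cache$s4, cache$p3$y, "e41", "e42", da4)
  da3 <- pool_bw(cache$p3, din4, b3$dskip, cache$s3$a2)
  din3 <- enc_bw(cache$s3, cache$p2$y, "e31", "e32", da3)
  da2 <- pool_bw(cache$p2, din3, b2$dskip, cache$s2$a2)
  din2 <- enc_bw(cache$s2, cache$p1$y, "e21", "e22", da2)
  da1 <- pool_bw(cache$p1, din2, b1$dskip, cache$s1$a2)
  enc_bw(cache$s1, cache$x, "e11", "e12", da1)
  grads
}

bce_loss <- function(y, target, eps = 1e-7) {
  y <- pmin(pmax(y, eps), 1 - eps)
  -mean(target * log(y) + (1 - target) * log(1 - y))
}

#' Train the U-Net lung segmenter
#'
#' @param train_samples list of `list(image = matrix, mask = 0/1 matrix)`
#'   at the configured input size (preprocessed: CLAHE + normalization +
#'   letterbox).
#' @param val_samples held-out samples in the same format, used for early
#'   stopping.
#' @param config a [seg_config()].
#' @return a `unet_model`: parameters at the best validation epoch plus
#'   the per-epoch loss history.
#' @export
train_unet <- function(train_samples, val_samples, config = seg_config_desk()) {
  stopifnot(inherits(config, "seg_config"))
  if (length(train_samples) == 0) stop("empty training set", call. = FALSE)
  if (length(train_samples) < 2 && config$epochs > 0)
    stop("need at least 2 training samples", call. = FALSE)
  for (s in c(train_samples, val_samples))
    if (!all(dim(s$image) == config$input_size))
      stop("sample frame does not match config input_size", call. = FALSE)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)
  params <- unet_init(config$base_width)

  model <- structure(list(params = params, config = config,
                          history = data.frame(), best_epoch = 0L),
                     class = "unet_model")
  if (config$epochs == 0) return(model)

  opt <- adam_init(params)
  as_cube <- function(m) array(m, c(dim(m), 1))
  sample_loss <- function(p, s) {
    cache <- unet_forward(p, as_cube(s$image))
    bce_loss(cache$y, as_cube(s$mask))
  }
  best_val <- Inf; best_params <- params; best_epoch <- 0L
  hist <- vector("list", config$epochs)
  stale <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(length(train_samples))
    tr_loss <- 0
    for (start in seq(1, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, length(ord))]
      grads <- NULL
      for (i in idx) {
        s <- train_samples[[i]]
        cache <- unet_forward(params, as_cube(s$image), train = TRUE,
                              dropout_rate = config$dropout_rate)
        target <- as_cube(s$mask)
        loss <- bce_loss(cache$y, target)
        if (!is.finite(loss))
          stop("NaN/Inf training loss at epoch ", epoch, call. = FALSE)
        tr_loss <- tr_loss + loss
        dz <- (cache$y - target) / length(target) / length(idx)
        g <- unet_backward(params, cache, dz)
        grads <- if (is.null(grads)) g
                 else stats::setNames(Map(`+`, grads, g[names(grads)]), names(grads))
      }
      step <- adam_step(params, grads, opt, config$learning_rate)
      params <- step$params; opt <- step$state
    }
    tr_loss <- tr_loss / length(ord)
    val_loss <- if (length(val_samples) > 0)
      mean(vapply(val_samples, function(s) sample_loss(params, s), 0)) else tr_loss
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tr_loss,
                                val_loss = val_loss)
    if (val_loss < best_val - 1e-6) {
      best_val <- val_loss; best_params <- params; best_epoch <- epoch
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$early_stop_patience) break
    }
  }
  model$params <- best_params
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  model$best_epoch <- best_epoch
  model
}

#' Predict the binary lung mask for one image
#'
#' @param model a `unet_model` from [train_unet()].
#' @param image numeric matrix at the model's input size.
#' @return a `lung_mask` (see [lung_mask()]).
#' @export
predict_lung_mask <- function(model, image) {
  stopifnot(inherits(model, "unet_model"))
  assert_image(image)
  if (!all(dim(image) == model$config$input_size))
    stop("image frame does not match the model input size", call. = FALSE)
  cache <- unet_forward(model$params, array(image, c(dim(image), 1)))
  lung_mask((cache$y[, , 1] >= 0.5) * 1L)
}

#' Binary lung mask container
#'
#' @param mask 0/1 (or logical) matrix.
#' @return a `lung_mask`: list with `mask` (integer 0/1 matrix), `a_lung`
#'   (count of 1-pixels) and `frame_size`.
#' @export
lung_mask <- function(mask) {
  if (is.logical(mask)) mask <- mask * 1L
  if (!all(mask %in% c(0L, 1L))) stop("mask must be strictly binary", call. = FALSE)
  structure(list(mask = matrix(as.integer(mask), nrow(mask)),
                 a_lung = as.integer(sum(mask)),
                 frame_size = dim(mask)),
            class = "lung_mask")
}

as_lung_mask <- function(x) {
  if (inherits(x, "lung_mask")) x else lung_mask(x)
}

#' Resize a binary mask with bilinear interpolation
#'
#' Bilinearly interpolates the 0/1 raster and re-binarizes at 0.5, the
#' same resampling the clinical pipeline uses to carry the 512-frame lung
#' mask into the 1024 scoring frame. `A_Lung` is recomputed at the new
#' scale.
#'
#' @param mask a `lung_mask` (or binary matrix).
#' @param target target square side in pixels.
#' @return a `lung_mask` at `target` resolution.
#' @export
resize_mask <- function(mask, target) {
  mask <- as_lung_mask(mask)
  target <- as.integer(target)
  if (target < max(mask$frame_size) %/% 8L)
    stop("degenerate downscale: target below 1/8 of the mask frame",
         call. = FALSE)
  cont <- resize_bilinear(mask$mask + 0, target, target)
  lung_mask(cont >= 0.5)
}

#' Save / load a segmentation model
#'
#' Single-file checkpoint containing config and weights.
#'
#' @param model a `unet_model`.
#' @param path checkpoint path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
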