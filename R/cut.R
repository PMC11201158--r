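#' Virtual-normal synthesis by contrastive unpaired translation
#'
#' Maps a diseased radiograph to a lesion-free counterpart. Two backends
#' share one interface: the *oracle* backend returns the phantom's paired
#' normal (so the deterministic scoring algorithm can be tested in
#' isolation), and the *CUT* backend is a reduced-scale contrastive
#' unpaired translation model — a residual generator trained against a
#' patch discriminator with a least-squares adversarial loss plus a
#' patchwise contrastive (InfoNCE) correspondence loss between encoder
#' features of the input and the output, with identity terms (contrastive
#' and pixel-space) on normal-domain images.
#'
#' @name translation
NULL

#' CUT training configuration
#'
#' @param epochs training epochs over the diseased set (desk default 30;
#'   the clinical recipe trains for 250).
#' @param batch_size minibatch size (default 2).
#' @param learning_rate Adam learning rate (default 2e-4, beta1 = 0.5).
#' @param image_size square input frame (desk default 64).
#' @param ngf,ndf base widths of generator and discriminator.
#' @param n_res number of residual blocks at the bottleneck width.
#' @param num_patches contrastive patches sampled per tapped layer.
#' @param nce_temperature softmax temperature of the contrastive loss.
#' @param lambda_gan,lambda_nce loss weights.
#' @param lambda_idt weight of the pixel-space identity loss
#'   `mean((G(z) - z)^2)` on normal-domain images; anchors the generator
#'   to leave normal-looking tissue untouched.
#' @param seed integer seed.
#' @return a `cut_config` list.
#' @export
cut_config <- function(epochs = 30L, batch_size = 2L, learning_rate = 2e-4,
                       image_size = 64L, ngf = 8L, ndf = 8L, n_res = 2L,
                       num_patches = 64L, nce_temperature = 0.07,
                       lambda_gan = 1, lambda_nce = 1, lambda_idt = 2,
                       seed = 1L) {
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate > 0, image_size >= 16,
            image_size %% 2 == 0, ngf >= 1, ndf >= 1, n_res >= 2,
            num_patches >= 2, nce_temperature > 0, lambda_gan >= 0,
            lambda_nce >= 0, lambda_idt >= 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, image_size = as.integer(image_size),
                 ngf = as.integer(ngf), ndf = as.integer(ndf),
                 n_res = as.integer(n_res), num_patches = as.integer(num_patches),
                 nce_temperature = nce_temperature, lambda_gan = lambda_gan,
                 lambda_nce = lambda_nce, lambda_idt = lambda_idt,
                 seed = as.integer(seed)),
            class = "cut_config")
}

cut_init <- function(config) {
  ngf <- config$ngf; ndf <- config$ndf
  g <- list(c1 = nn_conv_init(3, 1, ngf),
            d1 = nn_conv_init(3, ngf, 2 * ngf))
  for (i in seq_len(config$n_res)) {
    g[[paste0("res", i, "a")]] <- nn_conv_init(3, 2 * ngf, 2 * ngf)
    g[[paste0("res", i, "b")]] <- nn_conv_init(3, 2 * ngf, 2 * ngf,
                                               gain = 1)  # gentle residuals
  }
  # the residual head sees upsampled deep features plus the full-res stem,
  # so lesion corrections can carry fine spatial detail
  g$u1 <- nn_conv_init(3, 3 * ngf, ngf)
  g$out <- nn_conv_init(3, ngf, 1, gain = 1)
  d <- list(dsc1 = nn_conv_init(3, 1, ndf),
            dsc2 = nn_conv_init(3, ndf, 2 * ndf),
            dsc3 = nn_conv_init(3, 2 * ndf, 1, gain = 1))
  hdim <- 32L
  mlp <- list()
  for (l in c("d1", "res1", "res")) {
    cin <- 2L * ngf
    mlp[[paste0(l, "_w1")]] <- matrix(stats::rnorm(cin * hdim, sd = 1 / sqrt(cin)),
                                      cin, hdim)
    mlp[[paste0(l, "_b1")]] <- rep(0, hdim)
    mlp[[paste0(l, "_w2")]] <- matrix(stats::rnorm(hdim * hdim, sd = 1 / sqrt(hdim)),
                                      hdim, hdim)
    mlp[[paste0(l, "_b2")]] <- rep(0, hdim)
  }
  list(g = g, d = d, mlp = mlp)
}

# encoder part of the generator; taps are the contrastive feature layers
cut_enc_forward <- function(g, x, n_res) {
  a_c1 <- nn_relu_fw(nn_conv_fw(x, g$c1))
  a_d1 <- nn_relu_fw(nn_conv_fw(a_c1, g$d1, stride = 2L))
  h <- a_d1
  res <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    ra <- g[[paste0("res", i, "a")]]; rb <- g[[paste0("res", i, "b")]]
    hi <- nn_relu_fw(nn_conv_fw(h, ra))
    oi <- nn_conv_fw(hi, rb)
    res[[i]] <- list(xin = h, h = hi)
    h <- h + oi
    res[[i]]$out <- h
  }
  list(x = x, a_c1 = a_c1, a_d1 = a_d1, res = res, feat_top = h)
}

# residual head: the generator predicts an intensity correction added to
# the input, so an untrained generator is near-identity and training only
# has to learn the lesion-removing residual
cut_gen_forward <- function(g, x, n_res) {
  enc <- cut_enc_forward(g, x, n_res)
  up_in <- .upsample2_fw(enc$feat_top)
  cat_u <- cat3(up_in, enc$a_c1)
  a_u1 <- nn_relu_fw(nn_conv_fw(cat_u, g$u1))
  z <- nn_conv_fw(a_u1, g$out)
  delta <- tanh(z)
  y_raw <- x + delta
  y <- pmin(pmax(y_raw, 0), 1)
  c(enc, list(up_in = up_in, cat_u = cat_u, a_u1 = a_u1, z = z,
              delta = delta, y_raw = y_raw, y = y))
}

# backward through the encoder alone, starting from gradients at the tap
# features; returns grads and the gradient at the encoder input
cut_enc_backward <- function(g, cache, n_res, d_d1 = 0, d_top = 0,
                             d_res1 = 0, d_c1 = 0, grads = list()) {
  d <- d_top
  for (i in rev(seq_len(n_res))) {
    if (i == 1 && n_res > 1) d <- d + d_res1
    blk <- cache$res[[i]]
    ra <- paste0("res", i, "a"); rb <- paste0("res", i, "b")
    gb <- nn_conv_bw(blk$h, g[[rb]], d)
    grads <- acc_grad(grads, rb, gb$dw, gb$db)
    dh <- nn_relu_bw(blk$h, gb$dx)
    ga <- nn_conv_bw(blk$xin, g[[ra]], dh)
    grads <- acc_grad(grads, ra, ga$dw, ga$db)
    d <- d + ga$dx                      # skip path
  }
  d <- d + d_d1
  d <- nn_relu_bw(cache$a_d1, d)
  g1 <- nn_conv_bw(cache$a_c1, g$d1, d, stride = 2L)
  grads <- acc_grad(grads, "d1", g1$dw, g1$db)
  dc1 <- nn_relu_bw(cache$a_c1, g1$dx + d_c1)
  g0 <- nn_conv_bw(cache$x, g$c1, dc1)
  grads <- acc_grad(grads, "c1", g0$dw, g0$db)
  list(grads = grads, dx = g0$dx)
}

# backward through the whole generator from dL/dy
cut_gen_backward <- function(g, cache, n_res, dy, grads = list()) {
  dz <- dy * (cache$y_raw >= 0 & cache$y_raw <= 1) * (1 - cache$delta^2)
  go <- nn_conv_bw(cache$a_u1, g$out, dz)
  grads <- acc_grad(grads, "out", go$dw, go$db)
  du <- nn_relu_bw(cache$a_u1, go$dx)
  gu <- nn_conv_bw(cache$cat_u, g$u1, du)
  grads <- acc_grad(grads, "u1", gu$dw, gu$db)
  cup <- dim(cache$up_in)[3]
  d_top <- .upsample2_bw(gu$dx[, , seq_len(cup), drop = FALSE])
  d_c1 <- gu$dx[, , cup + seq_len(dim(cache$a_c1)[3]), drop = FALSE]
  cut_enc_backward(g, cache, n_res, d_top = d_top, d_c1 = d_c1,
                   grads = grads)$grads
}

cut_disc_forward <- function(d, x) {
  a1 <- nn_lrelu_fw(nn_conv_fw(x, d$dsc1, stride = 2L))
  a2 <- nn_lrelu_fw(nn_conv_fw(a1, d$dsc2, stride = 2L))
  z <- nn_conv_fw(a2, d$dsc3)
  list(x = x, a1 = a1, a2 = a2, z = z)
}

cut_disc_backward <- function(d, cache, dz, grads = list()) {
  g3 <- nn_conv_bw(cache$a2, d$dsc3, dz)
  grads <- acc_grad(grads, "dsc3", g3$dw, g3$db)
  d2 <- nn_lrelu_bw(cache$a2, g3$dx)
  g2 <- nn_conv_bw(cache$a1, d$dsc2, d2, stride = 2L)
  grads <- acc_grad(grads, "dsc2", g2$dw, g2$db)
  d1 <- nn_lrelu_bw(cache$a1, g2$dx)
  g1 <- nn_conv_bw(cache$x, d$dsc1, d1, stride = 2L)
  grads <- acc_grad(grads, "dsc1", g1$dw, g1$db)
  list(grads = grads, dx = g1$dx)
}

# gather channel vectors at flat spatial indices of a (H,W,C) map
gather_patches <- function(feat, idx) {
  hw <- dim(feat)[1] * dim(feat)[2]
  m <- matrix(feat, hw, dim(feat)[3])
  m[idx, , drop = FALSE]
}

mlp_forward <- function(mlp, prefix, q) {
  w1 <- mlp[[paste0(prefix, "_w1")]]; b1 <- mlp[[paste0(prefix, "_b1")]]
  w2 <- mlp[[paste0(prefix, "_w2")]]; b2 <- mlp[[paste0(prefix, "_b2")]]
  h1 <- q %*% w1
  h1 <- sweep(h1, 2, b1, `+`)
  a1 <- nn_relu_fw(h1)
  v <- sweep(a1 %*% w2, 2, b2, `+`)
  nrm <- sqrt(rowSums(v * v)) + 1e-10
  list(q = q, a1 = a1, v = v, nrm = nrm, e = v / nrm)
}

mlp_backward <- function(mlp, prefix, cache, de, grads) {
  # through L2 row normalization
  dv <- (de - cache$e * rowSums(de * cache$e)) / cache$nrm
  grads[[paste0(prefix, "_w2")]] <- add_or(grads[[paste0(prefix, "_w2")]],
                                           t(cache$a1) %*% dv)
  grads[[paste0(prefix, "_b2")]] <- add_or(grads[[paste0(prefix, "_b2")]],
                                           colSums(dv))
  da1 <- dv %*% t(mlp[[paste0(prefix, "_w2")]])
  da1 <- nn_relu_bw(cache$a1, da1)
  grads[[paste0(prefix, "_w1")]] <- add_or(grads[[paste0(prefix, "_w1")]],
                                           t(cache$q) %*% da1)
  grads[[paste0(prefix, "_b1")]] <- add_or(grads[[paste0(prefix, "_b1")]],
                                           colSums(da1))
  list(grads = grads, dq = da1 %*% t(mlp[[paste0(prefix, "_w1")]]))
}

add_or <- function(a, b) if (is.null(a)) b else a + b

# InfoNCE over matched patch embeddings; keys are treated as constants
nce_loss_grad <- function(q, k, temp) {
  m <- nrow(q)
  logits <- (q %*% t(k)) / temp
  logits <- logits - apply(logits, 1, max)
  p <- exp(logits); p <- p / rowSums(p)
  loss <- -mean(log(p[cbind(1:m, 1:m)] + 1e-12))
  dlog <- p; dlog[cbind(1:m, 1:m)] <- dlog[cbind(1:m, 1:m)] - 1
  dq <- (dlog %*% k) / temp / m
  list(loss = loss, dq = dq)
}

# PatchNCE between an input image's encoder features (keys) and the
# re-encoded output's features (queries). Returns the loss, gradients for
# the MLPs and the tap-feature gradients of the query pass.
cut_nce <- function(model, enc_in, enc_out, config) {
  # correspondence is enforced on structural feature levels (the stride-2
  # stage and the residual blocks), not on near-raw intensities, so the
  # adversarial lesion removal is not penalized as a correspondence error
  get_feat <- function(enc, key) switch(key,
    a_d1 = enc$a_d1, res1 = enc$res[[1]]$out, feat_top = enc$feat_top)
  taps <- list(d1 = list(feat = "a_d1", mlp = "d1"),
               res1 = list(feat = "res1", mlp = "res1"),
               res = list(feat = "feat_top", mlp = "res"))
  ntap <- length(taps)
  total <- 0; mlp_grads <- list()
  dfeat <- list(a_d1 = 0, res1 = 0, feat_top = 0)
  for (tp in taps) {
    fk <- get_feat(enc_in, tp$feat); fq <- get_feat(enc_out, tp$feat)
    hw <- dim(fk)[1] * dim(fk)[2]
    np <- min(config$num_patches, hw)
    idx <- sample.int(hw, np)
    ck <- mlp_forward(model$mlp, tp$mlp, gather_patches(fk, idx))
    cq <- mlp_forward(model$mlp, tp$mlp, gather_patches(fq, idx))
    nce <- nce_loss_grad(cq$e, ck$e, config$nce_temperature)
    total <- total + nce$loss / ntap
    bk <- mlp_backward(model$mlp, tp$mlp, cq, nce$dq / ntap, mlp_grads)
    mlp_grads <- bk$grads
    dm <- matrix(0, hw, dim(fq)[3])
    dm[idx, ] <- bk$dq
    dfeat[[tp$feat]] <- dfeat[[tp$feat]] + array(dm, dim(fq))
  }
  list(loss = total, mlp_grads = mlp_grads, dfeat = dfeat)
}

#' Train a CUT virtual-normal generator
#'
#' Unpaired training: the generator learns to map diseased images into
#' the normal domain (least-squares adversarial loss against a patch
#' discriminator) while the patchwise contrastive loss ties each output
#' patch to the input patch at the same location, preserving anatomy. An
#' identity contrastive term on normal-domain images discourages
#' unnecessary edits. Keys of the contrastive loss are treated as
#' constants in the backward pass (one-sided gradient).
#'
#' Disease is confined to the lung, so image patches outside the lung
#' carry no domain signal and only add gradient noise; when lung masks are
#' supplied the adversarial loss is therefore evaluated over
#' lung-overlapping patches only (in production these masks come from the
#' segmentation stage; on phantoms from the generator's ground truth).
#'
#' @param diseased_images list of numeric matrices (diseased domain).
#' @param normal_images list of numeric matrices (normal domain,
#'   unpaired).
#' @param config a [cut_config()].
#' @param diseased_masks,normal_masks optional lists of binary lung masks
#'   matching the image lists; when NULL every patch is weighted equally.
#' @return a `cut_model` with generator weights, config and per-epoch
#'   loss history.
#' @export
train_cut <- function(diseased_images, normal_images, config = cut_config(),
                      diseased_masks = NULL, normal_masks = NULL) {
  stopifnot(inherits(config, "cut_config"))
  if (length(diseased_images) == 0 || length(normal_images) == 0)
    stop("both image sets must be nonempty", call. = FALSE)
  for (im in c(diseased_images, normal_images))
    if (!all(dim(im) == config$image_size))
      stop("image frame does not match config image_size", call. = FALSE)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)
  model <- cut_init(config)
  model$config <- config
  class(model) <- "cut_model"
  if (config$epochs == 0) {
    model$history <- data.frame()
    return(model)
  }

  opt_g <- adam_init(model$g); opt_d <- adam_init(model$d)
  opt_m <- adam_init(model$mlp)
  as_cube <- function(m) array(m, c(dim(m), 1))
  nres <- config$n_res
  hist <- vector("list", config$epochs)

  # per-image adversarial patch weights at the discriminator's output grid
  zdim <- config$image_size %/% 4L
  patch_w <- function(mask) {
    if (is.null(mask)) return(array(1, c(zdim, zdim, 1)))
    f <- config$image_size %/% zdim
    pm <- matrix(0, zdim, zdim)
    for (i in seq_len(zdim)) for (j in seq_len(zdim))
      pm[i, j] <- mean(mask[(f * i - f + 1):(f * i), (f * j - f + 1):(f * j)])
    array((pm > 0.2) * 1, c(zdim, zdim, 1))
  }
  w_dis <- lapply(seq_along(diseased_images), function(i)
    patch_w(if (is.null(diseased_masks)) NULL else diseased_masks[[i]]))
  w_nor <- lapply(seq_along(normal_images), function(i)
    patch_w(if (is.null(normal_masks)) NULL else normal_masks[[i]]))

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(length(diseased_images))
    ep <- c(g_gan = 0, d = 0, nce = 0)
    for (start in seq(1, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, length(ord))]
      nb <- length(idx)
      zidx <- sample.int(length(normal_images), nb, replace = TRUE)
      caches_x <- lapply(idx, function(i)
        cut_gen_forward(model$g, as_cube(diseased_images[[i]]), nres))

      # --- discriminator step ---
      d_grads <- list(); d_loss <- 0
      for (b in seq_len(nb)) {
        z <- as_cube(normal_images[[zidx[b]]])
        wN <- w_nor[[zidx[b]]]; wD <- w_dis[[idx[b]]]
        swN <- max(sum(wN), 1); swD <- max(sum(wD), 1)
        cr <- cut_disc_forward(model$d, z)
        cf <- cut_disc_forward(model$d, caches_x[[b]]$y)
        d_loss <- d_loss + 0.5 * (sum(wN * (cr$z - 1)^2) / swN +
                                    sum(wD * cf$z^2) / swD)
        d_grads <- cut_disc_backward(model$d, cr, wN * (cr$z - 1) / swN / nb,
                                     d_grads)$grads
        d_grads <- cut_disc_backward(model$d, cf, wD * cf$z / swD / nb,
                                     d_grads)$grads
      }
      st <- adam_step(model$d, d_grads, opt_d, config$learning_rate, beta1 = 0.5)
      model$d <- st$params; opt_d <- st$state

      # --- generator + MLP step ---
      g_grads <- list(); m_grads <- list(); g_gan <- 0; g_nce <- 0
      for (b in seq_len(nb)) {
        cx <- caches_x[[b]]
        z <- as_cube(normal_images[[zidx[b]]])
        wD <- w_dis[[idx[b]]]; swD <- max(sum(wD), 1)
        # adversarial pull toward the normal domain
        cf <- cut_disc_forward(model$d, cx$y)
        g_gan <- g_gan + config$lambda_gan * sum(wD * (cf$z - 1)^2) / swD
        dy_gan <- config$lambda_gan *
          cut_disc_backward(model$d, cf, 2 * wD * (cf$z - 1) / swD)$dx
        # contrastive correspondence x -> y
        enc_y <- cut_enc_forward(model$g, cx$y, nres)
        ncex <- cut_nce(model, cx, enc_y, config)
        bq <- cut_enc_backward(model$g, enc_y, nres,
                               d_d1 = ncex$dfeat$a_d1 * config$lambda_nce,
                               d_res1 = ncex$dfeat$res1 * config$lambda_nce,
                               d_top = ncex$dfeat$feat_top * config$lambda_nce)
        g_grads <- merge_grads(g_grads, scale_grads(bq$grads, 1 / nb))
        dy <- dy_gan + bq$dx
        g_grads <- cut_gen_backward(model$g, cx, nres, dy / nb, g_grads)
        # identity contrastive term on a normal image
        cz <- cut_gen_forward(model$g, z, nres)
        enc_yz <- cut_enc_forward(model$g, cz$y, nres)
        ncez <- cut_nce(model, cz, enc_yz, config)
        bz <- cut_enc_backward(model$g, enc_yz, nres,
                               d_d1 = ncez$dfeat$a_d1 * config$lambda_nce,
                               d_res1 = ncez$dfeat$res1 * config$lambda_nce,
                               d_top = ncez$dfeat$feat_top * config$lambda_nce)
        g_grads <- merge_grads(g_grads, scale_grads(bz$grads, 1 / nb))
        # pixel-space identity anchor on the normal-domain image
        dy_idt <- 2 * config$lambda_idt * (cz$y - z) / length(z)
        g_grads <- cut_gen_backward(model$g, cz, nres, (bz$dx + dy_idt) / nb,
                                    g_grads)
        g_nce <- g_nce + config$lambda_nce * (ncex$loss + ncez$loss) / 2 +
          config$lambda_idt * mean((cz$y - z)^2)
        m_grads <- merge_grads(
          m_grads,
          scale_grads(merge_grads(ncex$mlp_grads, ncez$mlp_grads),
                      config$lambda_nce / nb))
      }
      if (!all(vapply(list(d_loss, g_gan, g_nce), is.finite, TRUE)))
        stop("NaN/Inf loss at epoch ", epoch, call. = FALSE)
      st <- adam_step(model$g, g_grads, opt_g, config$learning_rate, beta1 = 0.5)
      model$g <- st$params; opt_g <- st$state
      st <- adam_step(model$mlp, m_grads, opt_m, config$learning_rate, beta1 = 0.5)
      model$mlp <- st$params; opt_m <- st$state
      ep <- ep + c(g_gan = g_gan / nb, d = d_loss / nb, nce = g_nce / nb)
    }
    nb_steps <- ceiling(length(ord) / config$batch_size)
    hist[[epoch]] <- data.frame(epoch = epoch,
                                loss_g_gan = ep[["g_gan"]] / nb_steps,
                                loss_d = ep[["d"]] / nb_steps,
                                loss_nce = ep[["nce"]] / nb_steps)
  }
  model$history <- do.call(rbind, hist)
  model
}

merge_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- add_or(a[[nm]], b[[nm]])
  a
}
scale_grads <- function(g, s) lapply(g, function(x) x * s)

#' Ground-truth oracle virtual-normal backend
#'
#' A test double: registers phantom samples and, when asked for the
#' virtual normal of a diseased image, returns that sample's paired
#' normal exactly. Lets every downstream stage be verified against the
#' generator's pixel-count ground truth.
#'
#' @param samples list of `phantom_sample`.
#' @return an `oracle_backend`.
#' @export
oracle_backend <- function(samples) {
  structure(list(samples = samples), class = "oracle_backend")
}

#' Generate a virtual normal image
#'
#' @param backend an `oracle_backend` or trained `cut_model`.
#' @param image diseased image matrix in the backend's frame.
#' @return a `virtual_normal`: list with `image`, `backend_id`.
#' @export
generate_virtual_normal <- function(backend, image) {
  UseMethod("generate_virtual_normal")
}

#' @export
generate_virtual_normal.oracle_backend <- function(backend, image) {
  for (s in backend$samples)
    if (identical(dim(s$diseased), dim(image)) &&
        isTRUE(all(s$diseased == image)))
      return(structure(list(image = s$paired_normal, backend_id = "oracle"),
                       class = "virtual_normal"))
  stop("no registered pair for this image in the oracle backend",
       call. = FALSE)
}

#' @export
generate_virtual_normal.cut_model <- function(backend, image) {
  assert_image(image)
  if (!all(dim(image) == backend$config$image_size))
    stop("image frame does not match the generator input size", call. = FALSE)
  cache <- cut_gen_forward(backend$g, array(image, c(dim(image), 1)),
                           backend$config$n_res)
  structure(list(image = pmin(pmax(cache$y[, , 1], 0), 1), backend_id = "cut"),
            class = "virtual_normal")
}
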