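# Finite-difference checks of the hand-written backward passes. The network
# code is the one numerical component with no independent reference in the
# package, so its gradients are verified against numerical differentiation.

ns <- asNamespace("ildquant")

test_that("convolution forward matches a naive direct computation", {
  naive_conv <- function(x, warr, b, stride, pad) {
    k <- dim(warr)[1]; cout <- dim(warr)[4]
    H <- dim(x)[1]; W <- dim(x)[2]; cin <- dim(x)[3]
    Ho <- (H + 2 * pad - k) %/% stride + 1
    Wo <- (W + 2 * pad - k) %/% stride + 1
    xp <- array(0, c(H + 2 * pad, W + 2 * pad, cin))
    xp[pad + (1:H), pad + (1:W), ] <- x
    out <- array(0, c(Ho, Wo, cout))
    for (co in 1:cout) for (i in 1:Ho) for (j in 1:Wo) {
      hs <- (i - 1) * stride + 1; ws <- (j - 1) * stride + 1
      out[i, j, co] <- sum(xp[hs:(hs + k - 1), ws:(ws + k - 1), , drop = FALSE] *
                             warr[, , , co]) + b[co]
    }
    out
  }
  set.seed(2)
  x <- array(rnorm(10 * 8 * 2), c(10, 8, 2))
  warr <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3)); b <- rnorm(3)
  wm <- matrix(warr, 3 * 3 * 2, 3)
  for (stride in 1:2)
    expect_equal(ns$.conv2d_fw(x, wm, b, 3L, stride, 1L),
                 naive_conv(x, warr, b, stride, 1), tolerance = 1e-12)
})

test_that("U-Net gradients agree with numerical differentiation", {
  set.seed(3)
  params <- ns$unet_init(2L)
  x <- array(runif(32 * 32), c(32, 32, 1))
  target <- array((runif(32 * 32) > 0.5) * 1, c(32, 32, 1))
  fw <- function(p) ns$bce_loss(ns$unet_forward(p, x)$y, target)
  cache <- ns$unet_forward(params, x)
  g <- ns$unet_backward(params, cache, (cache$y - target) / length(target))
  L0 <- fw(params); eps <- 1e-6
  for (nm in c("e11", "e32", "b2", "u4", "d41", "d12", "out")) {
    gw <- g[[paste0(nm, ".w")]]
    i <- which(abs(gw) == max(abs(gw)))[1]
    p2 <- params; p2[[nm]]$w[i] <- p2[[nm]]$w[i] + eps
    expect_equal(gw[i], (fw(p2) - L0) / eps, tolerance = 1e-3)
  }
})

test_that("translation-network gradients agree with numerical differentiation", {
  set.seed(5)
  cfg <- cut_config(image_size = 16L, ngf = 3L, ndf = 3L, num_patches = 8L)
  model <- ns$cut_init(cfg)
  eps <- 1e-6
  # encoder with fixed linear functionals at the tap features
  x <- array(runif(16 * 16), c(16, 16, 1))
  enc <- ns$cut_enc_forward(model$g, x, 2L)
  C1 <- array(rnorm(length(enc$a_d1)), dim(enc$a_d1))
  C2 <- array(rnorm(length(enc$res[[1]]$out)), dim(enc$res[[1]]$out))
  C3 <- array(rnorm(length(enc$feat_top)), dim(enc$feat_top))
  fenc <- function(g) {
    e <- ns$cut_enc_forward(g, x, 2L)
    sum(e$a_d1 * C1) + sum(e$res[[1]]$out * C2) + sum(e$feat_top * C3)
  }
  be <- ns$cut_enc_backward(model$g, enc, 2L, d_d1 = C1, d_res1 = C2,
                            d_top = C3)
  L0 <- fenc(model$g)
  for (nm in c("c1", "d1", "res1a", "res2b")) {
    gw <- be$grads[[paste0(nm, ".w")]]
    i <- which(abs(gw) == max(abs(gw)))[1]
    g2 <- model$g; g2[[nm]]$w[i] <- g2[[nm]]$w[i] + eps
    expect_equal(gw[i], (fenc(g2) - L0) / eps, tolerance = 1e-3)
  }
  # full generator + discriminator adversarial path
  fgan <- function(g) {
    cx <- ns$cut_gen_forward(g, x, 2L)
    mean((ns$cut_disc_forward(model$d, cx$y)$z - 1)^2)
  }
  cx <- ns$cut_gen_forward(model$g, x, 2L)
  cf <- ns$cut_disc_forward(model$d, cx$y)
  dy <- ns$cut_disc_backward(model$d, cf, 2 * (cf$z - 1) / length(cf$z))$dx
  gg <- ns$cut_gen_backward(model$g, cx, 2L, dy, list())
  L0 <- fgan(model$g)
  for (nm in c("u1", "out", "c1")) {
    gw <- gg[[paste0(nm, ".w")]]
    i <- which(abs(gw) == max(abs(gw)))[1]
    g2 <- model$g; g2[[nm]]$w[i] <- g2[[nm]]$w[i] + eps
    expect_equal(gw[i], (fgan(g2) - L0) / eps, tolerance = 1e-3)
  }
  # contrastive loss gradient wrt the query embeddings
  q <- matrix(rnorm(12), 4); q <- q / sqrt(rowSums(q^2))
  k <- matrix(rnorm(12), 4); k <- k / sqrt(rowSums(k^2))
  n0 <- ns$nce_loss_grad(q, k, 0.07)
  i <- 5; q2 <- q; q2[i] <- q2[i] + eps
  expect_equal(n0$dq[i],
               (ns$nce_loss_grad(q2, k, 0.07)$loss - n0$loss) / eps,
               tolerance = 1e-3)
})
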