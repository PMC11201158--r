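#' @useDynLib ildquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- low-level building blocks -------------------------------------------
# Feature maps are numeric arrays dim c(H, W, C). Convolution parameters are
# a list(w = (k*k*cin) x cout matrix, b = cout vector, k = kernel size).

nn_conv_init <- function(k, cin, cout, gain = sqrt(2)) {
  sd <- gain / sqrt(k * k * cin)
  list(w = matrix(stats::rnorm(k * k * cin * cout, sd = sd), k * k * cin, cout),
       b = rep(0, cout), k = k)
}

nn_conv_fw <- function(x, p, stride = 1L, pad = (p$k - 1L) %/% 2L) {
  .conv2d_fw(x, p$w, p$b, as.integer(p$k), as.integer(stride), as.integer(pad))
}

nn_conv_bw <- function(x, p, dout, stride = 1L, pad = (p$k - 1L) %/% 2L) {
  .conv2d_bw(x, p$w, dout, as.integer(p$k), as.integer(stride), as.integer(pad))
}

nn_relu_fw <- function(x) (x > 0) * x
nn_relu_bw <- function(x, dout) (x > 0) * dout

nn_lrelu_fw <- function(x, a = 0.2) ifelse(x > 0, x, a * x)
nn_lrelu_bw <- function(x, dout, a = 0.2) ifelse(x > 0, dout, a * dout)

nn_sigmoid_fw <- function(x) 1 / (1 + exp(-x))
# derivative expressed through the forward output y
nn_sigmoid_bw <- function(y, dout) y * (1 - y) * dout

# ---- Adam optimiser over a flat named list of parameter arrays ------------

nn_flatten_params <- function(params) {
  out <- list()
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.list(p) && !is.null(p$w)) {
      out[[paste0(nm, ".w")]] <- p$w
      out[[paste0(nm, ".b")]] <- p$b
    } else {
      out[[nm]] <- p
    }
  }
  out
}

adam_init <- function(params) {
  flat <- nn_flatten_params(params)
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0),
       t = 0L)
}

# grads: flat named list matching nn_flatten_params(params); entries may be
# missing (treated as zero / skipped).
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    upd <- lr * mhat / (sqrt(vhat) + eps)
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2 && parts[2] %in% c("w", "b")) {
      params[[parts[1]]][[parts[2]]] <- params[[parts[1]]][[parts[2]]] - upd
    } else {
      params[[nm]] <- params[[nm]] - upd
    }
  }
  list(params = params, state = state)
}

# accumulate conv grads into a flat grad list
acc_grad <- function(grads, name, dw, db) {
  wn <- paste0(name, ".w"); bn <- paste0(name, ".b")
  if (is.null(grads[[wn]])) {
    grads[[wn]] <- dw; grads[[bn]] <- db
  } else {
    grads[[wn]] <- grads[[wn]] + dw; grads[[bn]] <- grads[[bn]] + db
  }
  grads
}
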