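# Minimal tensor primitives used by the attention operators, the model
# forward pass and the micro trainer. Feature maps are (H, W, C) arrays;
# conv weights are (k, k, Cin, Cout) arrays so that column-major flattening
# matches the im2col patch layout produced in src/conv_ops.cpp.

sigmoid_ <- function(x) 1 / (1 + exp(-x))

silu_ <- function(x) x * sigmoid_(x)

silu_grad_ <- function(x) {
  s <- sigmoid_(x)
  s * (1 + x * (1 - s))
}

# 2-D convolution. Returns the output map; with keep_cols = TRUE also the
# im2col matrix needed by the backward pass.
nn_conv <- function(x, w, b = NULL, stride = 1L, pad = NULL,
                    groups = 1L, keep_cols = FALSE) {
  d <- dim(x)
  k <- dim(w)[1]
  cin <- dim(w)[3] * groups
  cout <- dim(w)[4]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  stopifnot(d[3] == cin)
  if (groups == 1L) {
    cols0 <- im2col_cpp(as.numeric(x), d[1], d[2], d[3], k, stride, pad)
    wm <- matrix(w, nrow = k * k * cin, ncol = cout)
    y <- crossprod(cols0, wm)
    cols <- cols0
  } else {
    cpg_in <- cin %/% groups
    cpg_out <- cout %/% groups
    cols <- vector("list", groups)
    y <- NULL
    for (g in seq_len(groups)) {
      xi <- x[, , ((g - 1L) * cpg_in + 1L):(g * cpg_in), drop = FALSE]
      cols[[g]] <- im2col_cpp(as.numeric(xi), d[1], d[2], cpg_in, k, stride, pad)
      wg <- w[, , , ((g - 1L) * cpg_out + 1L):(g * cpg_out), drop = FALSE]
      wm <- matrix(wg, nrow = k * k * cpg_in, ncol = cpg_out)
      yg <- crossprod(cols[[g]], wm)
      y <- if (is.null(y)) yg else cbind(y, yg)
    }
  }
  ho <- (d[1] + 2L * pad - k) %/% stride + 1L
  wo <- (d[2] + 2L * pad - k) %/% stride + 1L
  if (!is.null(b)) y <- sweep(y, 2L, b, "+")
  out <- array(y, dim = c(ho, wo, cout))
  if (keep_cols) list(out = out, cols = cols, in_dim = d) else out
}

# Backward pass of nn_conv for groups = 1: given upstream gradient dy
# (Ho, Wo, Cout) and the cached im2col matrix, returns gradients for the
# input, weights and bias.
nn_conv_bwd <- function(dy, w, cols, in_dim, stride = 1L, pad = NULL) {
  k <- dim(w)[1]
  cin <- dim(w)[3]
  cout <- dim(w)[4]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  dym <- matrix(dy, ncol = cout)              # (Ho*Wo, Cout)
  dw <- array(cols %*% dym, dim = dim(w))     # (k*k*Cin, Cout)
  db <- colSums(dym)
  wm <- matrix(w, nrow = k * k * cin, ncol = cout)
  dcols <- wm %*% t(dym)                      # (k*k*Cin, Ho*Wo)
  dx <- col2im_cpp(dcols, in_dim[1], in_dim[2], cin, k, stride, pad)
  list(dx = dx, dw = dw, db = db)
}

nn_maxpool <- function(x, k, stride = 1L, pad = NULL) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  d <- dim(x)
  maxpool_cpp(as.numeric(x), d[1], d[2], d[3], k, stride, pad)
}

nn_upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

nn_concat <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  arr <- array(unlist(xs, use.names = FALSE),
               dim = c(d[1], d[2], sum(vapply(xs, function(z) dim(z)[3], 0L))))
  arr
}

# He-style fan-in initialization for a conv weight tensor.
init_conv_w <- function(k, cin, cout, gain = 1) {
  sd <- gain * sqrt(2 / (k * k * cin))
  array(rnorm(k * k * cin * cout, sd = sd), dim = c(k, k, cin, cout))
}
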