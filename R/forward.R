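# Runtime instantiation of a model spec and the inference forward pass.
# Weight tensors are allocated from the same primitive expansion the
# profiler counts, keyed by primitive name, so the instantiated model and
# the closed-form accounting can never disagree.

#' Instantiate a model spec with weights
#'
#' Allocates every learned tensor of the expanded graph (He-initialized
#' convolutions, identity batch norms, zero biases; the final class conv
#' bias is set to a low-prior logit).
#'
#' @param spec A `model_spec` from [build_model()] or [build_micro()].
#' @param seed Integer seed for the weight draw.
#' @return A `bdet_model` (list of `spec` and named weight tensors).
#' @export
init_model <- function(spec, seed = 0L) {
  prims <- model_primitives(spec)
  W <- list()
  with_local_seed(seed, {
    for (i in seq_len(nrow(prims))) {
      p <- prims[i, ]
      if (p$type == "conv") {
        w <- init_conv_w(p$k, p$cin / p$g, p$cout)
        b <- if (p$bias) {
          if (grepl("cls3$", p$name)) rep(-4.6, p$cout) else numeric(p$cout)
        } else NULL
        W[[p$name]] <- list(w = w, b = b)
      } else {
        W[[p$name]] <- list(g = rep(1, p$cout), be = numeric(p$cout))
      }
    }
  })
  structure(list(spec = spec, W = W), class = "bdet_model")
}

# Total elements across instantiated tensors (must equal count_params).
model_weight_count <- function(model) {
  sum(vapply(model$W, function(t) sum(lengths(lapply(t, as.numeric)))
             - (if (is.null(t$b)) 0 else 0), 0))
}

# conv (+ optional BN affine) (+ optional SiLU) by primitive base name
fwd_conv_bn <- function(x, base, W, stride = 1L, groups = 1L, act = TRUE) {
  cv <- W[[paste0(base, ".conv")]]
  if (is.null(cv)) cv <- W[[base]]
  y <- nn_conv(x, cv$w, b = cv$b, stride = stride, groups = groups)
  bn <- W[[paste0(base, ".bn")]]
  if (!is.null(bn)) {
    y <- sweep(y, 3L, bn$g, "*")
    y <- sweep(y, 3L, bn$be, "+")
  }
  if (act) silu_(y) else y
}

fwd_bottleneck <- function(x, base, W, shortcut = TRUE) {
  y <- fwd_conv_bn(fwd_conv_bn(x, paste0(base, ".cv1"), W),
                   paste0(base, ".cv2"), W)
  if (shortcut && identical(dim(x), dim(y))) x + y else y
}

fwd_c3k <- function(x, base, W, n = 2) {
  a <- fwd_conv_bn(x, paste0(base, ".cv1"), W)
  b <- fwd_conv_bn(x, paste0(base, ".cv2"), W)
  for (i in seq_len(n)) a <- fwd_bottleneck(a, paste0(base, ".m", i), W)
  fwd_conv_bn(nn_concat(a, b), paste0(base, ".cv3"), W)
}

fwd_c3k2 <- function(x, base, W, n = 1, c3k = FALSE) {
  y <- fwd_conv_bn(x, paste0(base, ".cv1"), W)
  c <- dim(y)[3] %/% 2L
  parts <- list(y[, , 1:c, drop = FALSE], y[, , (c + 1):(2 * c), drop = FALSE])
  for (i in seq_len(n)) {
    last <- parts[[length(parts)]]
    nxt <- if (c3k) fwd_c3k(last, paste0(base, ".m", i), W)
           else fwd_bottleneck(last, paste0(base, ".m", i), W)
    parts[[length(parts) + 1L]] <- nxt
  }
  fwd_conv_bn(do.call(nn_concat, parts), paste0(base, ".cv2"), W)
}

fwd_sppf <- function(x, base, W) {
  y <- fwd_conv_bn(x, paste0(base, ".cv1"), W)
  p1 <- nn_maxpool(y, 5L)
  p2 <- nn_maxpool(p1, 5L)
  p3 <- nn_maxpool(p2, 5L)
  fwd_conv_bn(nn_concat(y, p1, p2, p3), paste0(base, ".cv2"), W)
}

softmax_rows <- function(m) {
  m <- exp(m - apply(m, 1, max))
  m / rowSums(m)
}

fwd_psa_attn <- function(x, base, W) {
  d <- dim(x)
  c <- d[3]
  heads <- max(1L, c %/% 64L)
  head_dim <- c %/% heads
  key_dim <- head_dim %/% 2L
  qkv <- fwd_conv_bn(x, paste0(base, ".qkv"), W, act = FALSE)
  N <- d[1] * d[2]
  qkv_m <- matrix(qkv, nrow = N)             # (N, 2c), per-head channel blocks
  outm <- matrix(0, N, c)
  per <- 2L * key_dim + head_dim
  for (h in seq_len(heads)) {
    off <- (h - 1L) * per
    q <- qkv_m[, off + seq_len(key_dim), drop = FALSE]
    k <- qkv_m[, off + key_dim + seq_len(key_dim), drop = FALSE]
    v <- qkv_m[, off + 2L * key_dim + seq_len(head_dim), drop = FALSE]
    attn <- softmax_rows(q %*% t(k) / sqrt(key_dim))
    outm[, (h - 1L) * head_dim + seq_len(head_dim)] <- attn %*% v
  }
  vall <- qkv_m[, as.vector(sapply(seq_len(heads), function(h)
    (h - 1L) * per + 2L * key_dim + seq_len(head_dim))), drop = FALSE]
  pe <- fwd_conv_bn(array(vall, dim = c(d[1], d[2], c)),
                    paste0(base, ".pe"), W, groups = c, act = FALSE)
  fwd_conv_bn(array(outm, dim = c(d[1], d[2], c)) + pe,
              paste0(base, ".proj"), W, act = FALSE)
}

fwd_c2psa <- function(x, base, W, n = 1) {
  y <- fwd_conv_bn(x, paste0(base, ".cv1"), W)
  c <- dim(y)[3] %/% 2L
  a <- y[, , 1:c, drop = FALSE]
  b <- y[, , (c + 1):(2 * c), drop = FALSE]
  for (i in seq_len(n)) {
    nm <- paste0(base, ".m", i)
    b <- b + fwd_psa_attn(b, paste0(nm, ".attn"), W)
    f <- fwd_conv_bn(b, paste0(nm, ".ffn1"), W)
    b <- b + fwd_conv_bn(f, paste0(nm, ".ffn2"), W, act = FALSE)
  }
  fwd_conv_bn(nn_concat(a, b), paste0(base, ".cv2"), W)
}

# spatial attention map from an (H, W, C) map and a conv primitive
sa_gate_hwc <- function(x, cv) {
  d <- dim(x)
  xm <- matrix(x, ncol = d[3])
  dmax <- xm[, 1]
  if (d[3] > 1) for (j in 2:d[3]) dmax <- pmax(dmax, xm[, j])
  desc <- array(c(dmax, rowMeans(xm)), dim = c(d[1], d[2], 2))
  amap <- nn_conv(desc, cv$w, b = cv$b)
  sigmoid_(amap[, , 1])
}

fwd_spatial <- function(x, base, W) {
  g <- sa_gate_hwc(x, W[[paste0(base, ".sa")]])
  x * array(g, dim = dim(x))
}

fwd_dual_channel <- function(x, base, W, cfg) {
  cin <- dim(x)[3]
  z <- silu_(nn_conv(x, W[[paste0(base, ".context")]]$w,
                     W[[paste0(base, ".context")]]$b, groups = cin))
  y1 <- silu_(nn_conv(z, W[[paste0(base, ".branch1")]]$w,
                      W[[paste0(base, ".branch1")]]$b))
  y2 <- silu_(nn_conv(z, W[[paste0(base, ".branch2")]]$w,
                      W[[paste0(base, ".branch2")]]$b))
  fused <- nn_conv(nn_concat(y1, y2), W[[paste0(base, ".fuse")]]$w,
                   W[[paste0(base, ".fuse")]]$b)
  g <- sa_gate_hwc(fused, W[[paste0(base, ".sa")]])
  x * array(g, dim = dim(x))
}

# Shuffle3D on an (H, W, C) map: group-interleave channel permutation,
# then the per-channel spatial-inhibition gate.
shuffle3d_hwc <- function(x, groups = 4L, p = energy_gate_params()) {
  d <- dim(x)
  g <- if (d[3] %% groups == 0L) groups else 1L
  perm <- shuffle_permutation(d[3], shuffle_spec(g))
  x <- x[, , perm, drop = FALSE]
  hw <- d[1] * d[2]
  e <- rep(colSums(matrix(x, ncol = d[3])) / (hw - 1), each = hw)
  u <- (x - e)^2 / (4 * (e + p$alpha)) + p$beta
  sigmoid_(u) * x
}

fwd_detect_level <- function(x, base, W, a) {
  if (identical(a$style, "micro")) {
    box <- fwd_conv_bn(x, paste0(base, ".box1"), W)
    box <- fwd_conv_bn(box, paste0(base, ".box3"), W, act = FALSE)
    cls <- fwd_conv_bn(x, paste0(base, ".cls1"), W)
    cls <- fwd_conv_bn(cls, paste0(base, ".cls3"), W, act = FALSE)
    return(list(box = box, cls = cls))
  }
  if (isTRUE(a$shuffle)) {
    xb <- shuffle3d_hwc(x)
    box <- fwd_conv_bn(xb, paste0(base, ".box2"), W)
    box <- fwd_conv_bn(box, paste0(base, ".box3"), W, act = FALSE)
    cls <- fwd_conv_bn(shuffle3d_hwc(x), paste0(base, ".cls1b"), W)
  } else {
    box <- fwd_conv_bn(x, paste0(base, ".box1"), W)
    box <- fwd_conv_bn(box, paste0(base, ".box2"), W)
    box <- fwd_conv_bn(box, paste0(base, ".box3"), W, act = FALSE)
    cls <- fwd_conv_bn(x, paste0(base, ".cls1a"), W, groups = dim(x)[3])
    cls <- fwd_conv_bn(cls, paste0(base, ".cls1b"), W)
  }
  if (!is.null(W[[paste0(base, ".cls2a.conv")]])) {
    cls <- fwd_conv_bn(cls, paste0(base, ".cls2a"), W, groups = dim(cls)[3])
    cls <- fwd_conv_bn(cls, paste0(base, ".cls2b"), W)
  }
  cls <- fwd_conv_bn(cls, paste0(base, ".cls3"), W, act = FALSE)
  list(box = box, cls = cls)
}

#' Forward pass of an instantiated model
#'
#' Runs an image through the graph and returns the three raw head outputs.
#'
#' @param model A `bdet_model` from [init_model()].
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @return A list of three per-level lists with `box`
#'   (`h x w x 4*reg_max` logits) and `cls` (`h x w x nc` logits).
#' @export
forward_model <- function(model, image) {
  spec <- model$spec
  W <- model$W
  outs <- vector("list", length(spec$nodes))
  val <- function(i) if (i == 0L) image else outs[[i]]
  heads <- NULL
  for (i in seq_along(spec$nodes)) {
    nd <- spec$nodes[[i]]
    a <- nd$args
    x <- val(nd$from[1])
    outs[[i]] <- switch(nd$kind,
      CBS = fwd_conv_bn(x, nd$name, W, stride = a$s),
      C3K2 = fwd_c3k2(x, nd$name, W, n = a$n, c3k = a$c3k),
      SPPF = fwd_sppf(x, nd$name, W),
      C2PSA = fwd_c2psa(x, nd$name, W, n = a$n),
      DualChannel = fwd_dual_channel(x, nd$name, W, a$cfg),
      SpatialAttention = fwd_spatial(x, nd$name, W),
      Shuffle3D = shuffle3d_hwc(x),
      Upsample = nn_upsample2(x),
      Concat = do.call(nn_concat, lapply(nd$from, val)),
      DetectHead = {
        heads <- lapply(seq_along(nd$from), function(li)
          fwd_detect_level(val(nd$from[li]), paste0(nd$name, ".l", li), W, a))
        NULL
      })
  }
  heads
}
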