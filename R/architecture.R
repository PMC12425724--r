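# Declarative model graphs for the YOLOv11n-scale detector and its
# attention-modified variants, with exact parameter and FLOP accounting.
#
# A model spec is an ordered DAG of nodes; every node expands into a flat
# table of primitive operations (convolutions and batch-norm layers), and
# both the profiler and the runtime instantiation consume that same
# expansion, so closed-form counts and instantiated models cannot drift
# apart.

make_divisible <- function(x, divisor = 8) {
  as.integer(max(divisor, divisor * round(x / divisor)))
}

# ---- primitive expansion -------------------------------------------------

prim <- function(name, type, cin = 0, cout = 0, k = 1, g = 1,
                 bias = FALSE, bn = FALSE, rel = 1) {
  data.frame(name = name, type = type, cin = cin, cout = cout, k = k,
             g = g, bias = bias, bn = bn, rel = rel,
             stringsAsFactors = FALSE)
}

# Convolution + batch norm (the CBS block without its activation, which
# carries no parameters).
p_conv_bn <- function(name, cin, cout, k, g = 1, rel = 1) {
  rbind(prim(paste0(name, ".conv"), "conv", cin, cout, k, g,
             bias = FALSE, bn = FALSE, rel = rel),
        prim(paste0(name, ".bn"), "bn", cout, cout, rel = rel))
}

p_bottleneck <- function(name, c1, c2, k1 = 3, k2 = 3, e = 0.5) {
  c_ <- floor(c2 * e)
  rbind(p_conv_bn(paste0(name, ".cv1"), c1, c_, k1),
        p_conv_bn(paste0(name, ".cv2"), c_, c2, k2))
}

p_c3k <- function(name, c1, c2, n = 2, e = 0.5) {
  c_ <- floor(c2 * e)
  out <- rbind(p_conv_bn(paste0(name, ".cv1"), c1, c_, 1),
               p_conv_bn(paste0(name, ".cv2"), c1, c_, 1),
               p_conv_bn(paste0(name, ".cv3"), 2 * c_, c2, 1))
  for (i in seq_len(n))
    out <- rbind(out, p_bottleneck(paste0(name, ".m", i), c_, c_, 3, 3, 1.0))
  out
}

p_c3k2 <- function(name, c1, c2, n = 1, c3k = FALSE, e = 0.5) {
  c <- floor(c2 * e)
  out <- rbind(p_conv_bn(paste0(name, ".cv1"), c1, 2 * c, 1),
               p_conv_bn(paste0(name, ".cv2"), (2 + n) * c, c2, 1))
  for (i in seq_len(n)) {
    blk <- if (c3k) p_c3k(paste0(name, ".m", i), c, c, 2)
           else p_bottleneck(paste0(name, ".m", i), c, c, 3, 3, 0.5)
    out <- rbind(out, blk)
  }
  out
}

p_sppf <- function(name, c1, c2) {
  c_ <- c1 %/% 2
  rbind(p_conv_bn(paste0(name, ".cv1"), c1, c_, 1),
        p_conv_bn(paste0(name, ".cv2"), 4 * c_, c2, 1))
}

p_c2psa <- function(name, c1, n = 1) {
  c <- c1 %/% 2
  out <- rbind(p_conv_bn(paste0(name, ".cv1"), c1, 2 * c, 1),
               p_conv_bn(paste0(name, ".cv2"), 2 * c, c1, 1))
  for (i in seq_len(n)) {
    nm <- paste0(name, ".m", i)
    out <- rbind(out,
                 p_conv_bn(paste0(nm, ".attn.qkv"), c, 2 * c, 1),
                 p_conv_bn(paste0(nm, ".attn.proj"), c, c, 1),
                 p_conv_bn(paste0(nm, ".attn.pe"), c, c, 3, g = c),
                 p_conv_bn(paste0(nm, ".ffn1"), c, 2 * c, 1),
                 p_conv_bn(paste0(nm, ".ffn2"), 2 * c, c, 1))
  }
  out
}

p_dual_channel <- function(name, c1, cfg = NULL) {
  if (is.null(cfg)) cfg <- dual_channel_config(c1)
  cb <- cfg$branch_channels
  k <- cfg$branch_kernels
  rbind(prim(paste0(name, ".context"), "conv", c1, c1, cfg$context_kernel,
             g = c1, bias = TRUE),
        prim(paste0(name, ".branch1"), "conv", c1, cb, k[1], bias = TRUE),
        prim(paste0(name, ".branch2"), "conv", c1, cb, k[2], bias = TRUE),
        prim(paste0(name, ".fuse"), "conv", 2 * cb, c1, cfg$fuse_kernel,
             bias = TRUE),
        prim(paste0(name, ".sa"), "conv", 2, 1, cfg$sa$kernel, bias = TRUE))
}

p_spatial <- function(name, kernel = 7) {
  prim(paste0(name, ".sa"), "conv", 2, 1, kernel, bias = TRUE)
}

# One detection head level. `shuffle` replaces the first CBS of the box
# branch and the first depthwise conv of the class branch with the
# parameter-free Shuffle3D operator; the following layer then reads the
# head's incoming channel count directly.
p_detect_level <- function(name, x, c2h, c3h, nc, reg_max, shuffle) {
  box <- if (shuffle) {
    rbind(p_conv_bn(paste0(name, ".box2"), x, c2h, 3),
          prim(paste0(name, ".box3"), "conv", c2h, 4 * reg_max, 1, bias = TRUE))
  } else {
    rbind(p_conv_bn(paste0(name, ".box1"), x, c2h, 3),
          p_conv_bn(paste0(name, ".box2"), c2h, c2h, 3),
          prim(paste0(name, ".box3"), "conv", c2h, 4 * reg_max, 1, bias = TRUE))
  }
  cls <- if (shuffle) {
    rbind(p_conv_bn(paste0(name, ".cls1b"), x, c3h, 1),
          p_conv_bn(paste0(name, ".cls2a"), c3h, c3h, 3, g = c3h),
          p_conv_bn(paste0(name, ".cls2b"), c3h, c3h, 1),
          prim(paste0(name, ".cls3"), "conv", c3h, nc, 1, bias = TRUE))
  } else {
    rbind(p_conv_bn(paste0(name, ".cls1a"), x, x, 3, g = x),
          p_conv_bn(paste0(name, ".cls1b"), x, c3h, 1),
          p_conv_bn(paste0(name, ".cls2a"), c3h, c3h, 3, g = c3h),
          p_conv_bn(paste0(name, ".cls2b"), c3h, c3h, 1),
          prim(paste0(name, ".cls3"), "conv", c3h, nc, 1, bias = TRUE))
  }
  rbind(box, cls)
}

p_detect_micro_level <- function(name, x, hh, nc, reg_max) {
  rbind(prim(paste0(name, ".box1"), "conv", x, hh, 3, bias = TRUE),
        prim(paste0(name, ".box3"), "conv", hh, 4 * reg_max, 1, bias = TRUE),
        prim(paste0(name, ".cls1"), "conv", x, hh, 3, bias = TRUE),
        prim(paste0(name, ".cls3"), "conv", hh, nc, 1, bias = TRUE))
}

# Expand one graph node into primitives given its input channel count.
expand_node <- function(node, c1) {
  a <- node$args
  switch(node$kind,
    CBS = if (isTRUE(a$plain))
      prim(node$name, "conv", c1, a$c2, a$k, bias = TRUE, rel = 1 / a$s)
    else p_conv_bn(node$name, c1, a$c2, a$k, rel = 1 / a$s),
    C3K2 = p_c3k2(node$name, c1, a$c2, a$n, a$c3k, a$e),
    SPPF = p_sppf(node$name, c1, a$c2),
    C2PSA = p_c2psa(node$name, c1, a$n),
    DualChannel = p_dual_channel(node$name, c1, a$cfg),
    SpatialAttention = p_spatial(node$name),
    Shuffle3D = ,
    Upsample = ,
    Concat = prim("none", "conv")[0, ],
    DetectHead = {
      out <- NULL
      for (i in seq_along(a$ch)) {
        lvl <- if (identical(a$style, "micro"))
          p_detect_micro_level(paste0(node$name, ".l", i), a$ch[i], a$hh,
                               a$nc, a$reg_max)
        else
          p_detect_level(paste0(node$name, ".l", i), a$ch[i], a$c2h, a$c3h,
                         a$nc, a$reg_max, a$shuffle)
        out <- rbind(out, lvl)
      }
      out
    },
    stop("unknown node kind: ", node$kind))
}

# ---- graph construction --------------------------------------------------

new_node <- function(kind, from, name, args = list()) {
  list(kind = kind, from = from, name = name, args = args)
}

#' Build a detector model graph
#'
#' Constructs the n-scale single-stage detector graph (backbone 0-10 with
#' the stacked C3K2 stages, SPPF and a post-SPPF attention block; an
#' FPN-style neck 11-22 fusing three scales through upsampling and
#' concatenation; three detection heads at strides 8, 16 and 32) or one of
#' its attention-modified variants:
#'
#' * `"baseline"` - the unmodified YOLOv11n layout with C2PSA after SPPF.
#' * `"ha"` - the full modification: the C2PSA block is replaced by
#'   dual-channel attention, the first CBS (box branch) and first depthwise
#'   conv (class branch) of every detection head are replaced by the
#'   parameter-free Shuffle3D operator, and a standalone spatial-attention
#'   gate is applied to the network input.
#' * `"shuffle3d"` - only the head substitutions applied.
#' * `"dualchannel"` - only the C2PSA-to-dual-channel substitution applied.
#'
#' @param variant One of `"baseline"`, `"ha"`, `"shuffle3d"`,
#'   `"dualchannel"`.
#' @param num_classes Number of object classes (default 4).
#' @param input_size Nominal square input size (default 640); must be
#'   divisible by 32.
#' @param width,depth Channel and depth multipliers of the n scale.
#' @param max_channels Channel cap before the width multiplier.
#' @param reg_max Number of distribution-focal bins per box side.
#' @param spatial Whether the standalone input spatial-attention gate is
#'   present (defaults to `TRUE` only for `"ha"`).
#' @return A `model_spec` object.
#' @examples
#' spec <- build_baseline(num_classes = 4)
#' count_params(spec)$params_millions
#' @export
build_model <- function(variant = c("baseline", "ha", "shuffle3d",
                                    "dualchannel"),
                        num_classes = 4L, input_size = 640L,
                        width = 0.25, depth = 0.50, max_channels = 1024L,
                        reg_max = 16L, spatial = NULL) {
  variant <- match.arg(variant)
  if (num_classes < 1L) stop("build_model: num_classes must be >= 1")
  use_dual <- variant %in% c("ha", "dualchannel")
  use_shuffle <- variant %in% c("ha", "shuffle3d")
  use_spatial <- if (is.null(spatial)) identical(variant, "ha") else spatial

  ch <- function(c) make_divisible(min(c, max_channels) * width)
  rep_n <- function(n) max(1L, round(n * depth))
  nodes <- list()
  idx <- function() length(nodes)
  add <- function(kind, from, name, args = list()) {
    nodes[[length(nodes) + 1L]] <<- new_node(kind, from, name, args)
    idx()
  }

  src <- 0L  # network input
  if (use_spatial)
    src <- add("SpatialAttention", src, "pre.spatial")
  src <- add("CBS", src, "b0", list(c2 = ch(64), k = 3, s = 2))    # P1
  src <- add("CBS", src, "b1", list(c2 = ch(128), k = 3, s = 2))   # P2
  src <- add("C3K2", src, "b2", list(c2 = ch(256), n = rep_n(2), c3k = FALSE, e = 0.25))
  src <- add("CBS", src, "b3", list(c2 = ch(256), k = 3, s = 2))   # P3
  p3_mid <- add("C3K2", src, "b4", list(c2 = ch(512), n = rep_n(2), c3k = FALSE, e = 0.25))
  src <- add("CBS", p3_mid, "b5", list(c2 = ch(512), k = 3, s = 2))  # P4
  p4_mid <- add("C3K2", src, "b6", list(c2 = ch(512), n = rep_n(2), c3k = TRUE, e = 0.5))
  src <- add("CBS", p4_mid, "b7", list(c2 = ch(1024), k = 3, s = 2)) # P5
  src <- add("C3K2", src, "b8", list(c2 = ch(1024), n = rep_n(2), c3k = TRUE, e = 0.5))
  src <- add("SPPF", src, "b9", list(c2 = ch(1024)))
  p5_top <- if (use_dual)
    add("DualChannel", src, "b10", list(cfg = NULL))
  else
    add("C2PSA", src, "b10", list(n = rep_n(2)))

  u1 <- add("Upsample", p5_top, "n11")
  cat1 <- add("Concat", c(u1, p4_mid), "n12")
  n13 <- add("C3K2", cat1, "n13", list(c2 = ch(512), n = rep_n(2), c3k = FALSE, e = 0.5))
  u2 <- add("Upsample", n13, "n14")
  cat2 <- add("Concat", c(u2, p3_mid), "n15")
  p3 <- add("C3K2", cat2, "n16", list(c2 = ch(256), n = rep_n(2), c3k = FALSE, e = 0.5))
  d1 <- add("CBS", p3, "n17", list(c2 = ch(256), k = 3, s = 2))
  cat3 <- add("Concat", c(d1, n13), "n18")
  p4 <- add("C3K2", cat3, "n19", list(c2 = ch(512), n = rep_n(2), c3k = FALSE, e = 0.5))
  d2 <- add("CBS", p4, "n20", list(c2 = ch(512), k = 3, s = 2))
  cat4 <- add("Concat", c(d2, p5_top), "n21")
  p5 <- add("C3K2", cat4, "n22", list(c2 = ch(1024), n = rep_n(2), c3k = TRUE, e = 0.5))

  head_ch <- c(NA, NA, NA)  # resolved below after channel propagation
  add("DetectHead", c(p3, p4, p5), "head",
      list(nc = as.integer(num_classes), reg_max = as.integer(reg_max),
           shuffle = use_shuffle, ch = head_ch,
           c2h = NA, c3h = NA))

  spec <- structure(list(nodes = nodes, num_classes = as.integer(num_classes),
                         input_size = as.integer(input_size),
                         strides = c(8L, 16L, 32L),
                         reg_max = as.integer(reg_max),
                         variant = variant),
                    class = "model_spec")
  resolve_channels(spec)
}

#' @rdname build_model
#' @param ... Passed on to [build_model()].
#' @export
build_baseline <- function(num_classes = 4L, ...)
  build_model("baseline", num_classes = num_classes, ...)

#' @rdname build_model
#' @export
build_ha <- function(num_classes = 4L, ...)
  build_model("ha", num_classes = num_classes, ...)

#' Build the micro detector used for CPU-scale training
#'
#' A small fully-convolutional detector with the same three-stride head
#' geometry (8, 16, 32) as the full models but a plain conv backbone
#' (bias, SiLU, no normalization) and light two-conv heads, so that the
#' complete forward/backward pass runs in milliseconds on one CPU core.
#'
#' @param num_classes Number of classes (default 4).
#' @param input_size Square input size; 64 by default.
#' @param reg_max Distribution-focal bins per box side (default 8).
#' @param channels Output widths of the five stride-2 backbone convs.
#' @param head_width Hidden width of the head branches.
#' @return A `model_spec` with `head_style = "micro"`.
#' @export
build_micro <- function(num_classes = 4L, input_size = 64L, reg_max = 8L,
                        channels = c(8L, 16L, 32L, 48L, 64L),
                        head_width = 32L) {
  nodes <- list()
  add <- function(kind, from, name, args = list()) {
    nodes[[length(nodes) + 1L]] <<- new_node(kind, from, name, args)
    length(nodes)
  }
  src <- 0L
  for (i in seq_along(channels))
    src <- add("CBS", src, paste0("s", i),
               list(c2 = as.integer(channels[i]), k = 3, s = 2, plain = TRUE))
  add("DetectHead", c(3L, 4L, 5L), "head",
      list(nc = as.integer(num_classes), reg_max = as.integer(reg_max),
           style = "micro", hh = as.integer(head_width), shuffle = FALSE,
           ch = c(NA, NA, NA)))
  spec <- structure(list(nodes = nodes, num_classes = as.integer(num_classes),
                         input_size = as.integer(input_size),
                         strides = c(8L, 16L, 32L),
                         reg_max = as.integer(reg_max),
                         variant = "micro"),
                    class = "model_spec")
  resolve_channels(spec)
}

# Propagate channel counts along the graph, check arithmetic consistency
# and fill in the detect-head widths.
resolve_channels <- function(spec) {
  nodes <- spec$nodes
  out_ch <- integer(length(nodes))
  ch_of <- function(i) if (i == 0L) 3L else out_ch[i]
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    c1 <- ch_of(nd$from[1])
    out_ch[i] <- switch(nd$kind,
      CBS = , C3K2 = , SPPF = nd$args$c2,
      C2PSA = , DualChannel = , Shuffle3D = , SpatialAttention = ,
      Upsample = c1,
      Concat = sum(vapply(nd$from, ch_of, 0L)),
      DetectHead = {
        ch <- vapply(nd$from, ch_of, 0L)
        nodes[[i]]$args$ch <- ch
        nodes[[i]]$args$c2h <- max(16L, ch[1] %/% 4L, 4L * spec$reg_max)
        nodes[[i]]$args$c3h <- max(ch[1], min(spec$num_classes, 100L))
        0L
      })
    if (nd$kind == "DualChannel" && is.null(nd$args$cfg))
      nodes[[i]]$args$cfg <- dual_channel_config(c1)
  }
  spec$nodes <- nodes
  spec$out_channels <- out_ch
  spec
}

# Input channel count of node i (first source).
node_in_channels <- function(spec, i) {
  f <- spec$nodes[[i]]$from[1]
  if (f == 0L) 3L else spec$out_channels[f]
}

# ---- profiling -----------------------------------------------------------

# Flat primitive table of a whole model, with per-primitive spatial scale
# relative to the network input.
model_primitives <- function(spec) {
  nodes <- spec$nodes
  scale <- numeric(length(nodes))  # output scale of each node
  scale_of <- function(i) if (i == 0L) 1 else scale[i]
  out <- NULL
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    in_scale <- scale_of(nd$from[1])
    scale[i] <- switch(nd$kind,
      CBS = in_scale / nd$args$s,
      Upsample = in_scale * 2,
      in_scale)
    prims <- expand_node(nd, node_in_channels(spec, i))
    if (nrow(prims) > 0) {
      if (nd$kind == "DetectHead") {
        lvl_scale <- vapply(nd$from, scale_of, 0)
        li <- as.integer(sub("^head\\.l([0-9]+)\\..*$", "\\1", prims$name))
        prims$scale <- lvl_scale[li] * prims$rel
      } else {
        prims$scale <- in_scale * prims$rel
      }
      prims$node <- nd$name
      out <- rbind(out, prims)
    }
  }
  out
}

prim_params <- function(p) {
  ifelse(p$type == "conv",
         p$cin / p$g * p$k^2 * p$cout + ifelse(p$bias, p$cout, 0),
         2 * p$cout)  # batch norm affine pair
}

#' Count learned parameters of a model spec
#'
#' Counts every learned tensor in the expanded graph: convolution kernels,
#' biases and batch-norm affine pairs. Deterministic and closed-form; the
#' runtime instantiation allocates exactly these tensors.
#'
#' @param spec A `model_spec` from [build_model()].
#' @return A `profile_report` with `params_total`, `params_millions` and a
#'   per-node breakdown table.
#' @export
count_params <- function(spec) {
  p <- model_primitives(spec)
  p$params <- prim_params(p)
  by_node <- aggregate(params ~ node, p, sum)
  total <- sum(p$params)
  structure(list(params_total = total,
                 params_millions = total / 1e6,
                 per_node = by_node,
                 primitives = p),
            class = "profile_report")
}

#' Count FLOPs of a model spec at a given input size
#'
#' The convention follows the profiler the printed complexities come from:
#' one multiply-accumulate counts as 2 FLOPs; convolutions contribute
#' `out_positions * cout * (k^2 * cin / g + bias)` MACs, batch-norm layers
#' `4 * elements`, and elementwise activations, pooling, upsampling,
#' concatenation and the attention matrix products contribute nothing.
#'
#' @inheritParams count_params
#' @param input_size Square input resolution; must be divisible by 32.
#' @return A `profile_report` with `macs`, `gflops`, parameter totals and a
#'   per-node breakdown.
#' @export
count_flops <- function(spec, input_size = spec$input_size) {
  if (input_size %% 32 != 0)
    stop("count_flops: input_size must be divisible by 32")
  p <- model_primitives(spec)
  pos <- (input_size * p$scale)^2
  p$macs <- ifelse(p$type == "conv",
                   pos * p$cout * (p$k^2 * p$cin / p$g + ifelse(p$bias, 1, 0)),
                   4 * pos * p$cout)
  p$params <- prim_params(p)
  macs <- sum(p$macs)
  by_node <- aggregate(cbind(params, macs) ~ node, p, sum)
  structure(list(params_total = sum(p$params),
                 params_millions = sum(p$params) / 1e6,
                 macs = macs,
                 gflops = 2 * macs / 1e9,
                 input_size = input_size,
                 per_node = by_node,
                 primitives = p),
            class = "profile_report")
}

#' Anchor positions of the three detection heads
#'
#' @param input_size Square input resolution.
#' @param strides Head strides (default 8, 16, 32).
#' @return Total number of candidate predictions (e.g. 8400 at 640).
#' @export
anchor_count <- function(input_size = 640L, strides = c(8L, 16L, 32L)) {
  as.integer(sum((input_size %/% strides)^2))
}

#' @export
print.profile_report <- function(x, ...) {
  cat(sprintf("params: %s (%.2f M)\n",
              format(x$params_total, big.mark = ","), x$params_millions))
  if (!is.null(x$gflops))
    cat(sprintf("GFLOPs: %.1f at input %d (2 x MACs, conv/BN convention)\n",
                x$gflops, x$input_size))
  invisible(x)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec: %s, %d classes, input %d\n", x$variant,
              x$num_classes, x$input_size))
  for (i in seq_along(x$nodes)) {
    nd <- x$nodes[[i]]
    cat(sprintf("%3d %-18s from=%s ch=%d\n", i, nd$kind,
                paste(nd$from, collapse = ","), x$out_channels[i]))
  }
  invisible(x)
}
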