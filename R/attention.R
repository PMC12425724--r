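# Attention operators on feature maps. A feature map is a 4-axis numeric
# array indexed (batch, channel, row, col); every operator is shape
# preserving and acts multiplicatively on its input.

assert_feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4 || any(d < 1))
    stop("feature map must be a 4-axis array (batch, channel, row, col)")
  if (!all(is.finite(x)))
    stop("feature map contains non-finite values")
  invisible(d)
}

#' Channel shuffle specification
#'
#' @param groups Positive integer; must divide the channel count of any
#'   feature map the shuffle is applied to. `groups = 1` is the identity.
#' @param mode `"group"` (deterministic group-interleave permutation, the
#'   default) or `"random"` (seeded uniform permutation).
#' @param seed Integer seed, used only in `"random"` mode.
#' @export
shuffle_spec <- function(groups = 4L, mode = c("group", "random"), seed = 0L) {
  mode <- match.arg(mode)
  groups <- as.integer(groups)
  if (groups < 1L) stop("shuffle_spec: groups must be a positive integer")
  structure(list(groups = groups, mode = mode, seed = as.integer(seed)),
            class = "shuffle_spec")
}

# The channel permutation (1-based) realized by a spec on C channels.
shuffle_permutation <- function(C, spec) {
  if (C %% spec$groups != 0L)
    stop("channel_shuffle: groups (", spec$groups,
         ") does not divide channel count (", C, ")")
  if (spec$mode == "group") {
    as.vector(matrix(seq_len(C), nrow = spec$groups, byrow = TRUE))
  } else {
    with_local_seed(spec$seed, sample.int(C))
  }
}

# Run code under a temporary RNG state so library calls stay reproducible
# without clobbering the caller's stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Shuffle the channel axis of a feature map
#'
#' Permutes channels to break the fixed channel order so that subsequent
#' operators mix information across channel groups. In `"group"` mode the
#' permutation is the reshape-transpose interleave used by shuffle
#' networks; in `"random"` mode it is a seeded uniform permutation. Per
#' spatial location the multiset of values is unchanged.
#'
#' @param x Feature map, array `(batch, channel, row, col)`.
#' @param spec A [shuffle_spec()].
#' @export
channel_shuffle <- function(x, spec = shuffle_spec()) {
  d <- assert_feature_map(x)
  perm <- shuffle_permutation(d[2], spec)
  x[, perm, , , drop = FALSE]
}

#' Regulators of the spatial-inhibition energy gate
#'
#' @param alpha Small positive regulator in the energy denominator
#'   (default `1e-4`).
#' @param beta Additive regulator (default 0.5).
#' @param variance If `TRUE`, the denominator uses the variance-style term
#'   `sum((x - e)^2) / (H W - 1)` instead of the mean-style term
#'   `sum(x) / (H W - 1)`; the default keeps the mean-style form.
#' @export
energy_gate_params <- function(alpha = 1e-4, beta = 0.5, variance = FALSE) {
  if (alpha <= 0) stop("energy_gate_params: alpha must be positive")
  structure(list(alpha = alpha, beta = beta, variance = isTRUE(variance)),
            class = "energy_gate_params")
}

#' Spatial-inhibition energy gate
#'
#' For each (batch, channel) slice of size `H x W`, positions that deviate
#' from the slice mean-like statistic `e = sum(x) / (H W - 1)` receive a
#' larger energy `u = (x - e)^2 / (4 (sum(x)/(H W - 1) + alpha)) + beta`
#' and the slice is gated multiplicatively: `out = sigmoid(u) * x`. Since
#' the sigmoid lies in (0, 1), `|out| < |x|` wherever `x != 0`.
#'
#' @inheritParams channel_shuffle
#' @param p An [energy_gate_params()].
#' @export
energy_gate <- function(x, p = energy_gate_params()) {
  d <- assert_feature_map(x)
  hw <- d[3] * d[4]
  if (hw < 2)
    stop("energy_gate: degenerate input, needs H * W >= 2")
  s <- if (d[3] == 1L && d[4] == 1L) x else
    apply(x, c(1, 2), sum)                     # (b, c)
  e <- array(s / (hw - 1), dim = d)            # broadcast over (row, col)
  denom_term <- if (p$variance) {
    array(apply((x - e)^2, c(1, 2), sum) / (hw - 1), dim = d)
  } else e
  u <- (x - e)^2 / (4 * (denom_term + p$alpha)) + p$beta
  sigmoid_(u) * x
}

#' Shuffle3D attention
#'
#' Parameter-free attention composing [channel_shuffle()] with the
#' spatial-inhibition [energy_gate()]: channels are first permuted, then
#' each (batch, channel) slice is gated by its own energy map. Introduces
#' no learned parameters and preserves the input shape; the shuffled
#' channel order is kept after gating.
#'
#' @inheritParams channel_shuffle
#' @inheritParams energy_gate
#' @export
shuffle3d <- function(x, spec = shuffle_spec(), p = energy_gate_params()) {
  energy_gate(channel_shuffle(x, spec), p)
}

#' Spatial attention configuration
#'
#' @param kernel Odd positive convolution kernel size (default 7).
#' @param weights Conv kernel as an array of dim `(kernel, kernel, 2, 1)`
#'   (2 input channels: max- and mean-pooled descriptors; 1 output
#'   channel). Defaults to zeros, under which the attention map is
#'   identically `sigmoid(0) = 0.5`.
#' @param bias Scalar bias of the convolution (default 0).
#' @details Stride is 1 and padding `(kernel - 1) / 2`, so the spatial
#'   shape is preserved.
#' @export
spatial_attention_config <- function(kernel = 7L, weights = NULL, bias = 0) {
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L)
    stop("spatial_attention_config: kernel must be odd and positive")
  if (is.null(weights)) weights <- array(0, dim = c(kernel, kernel, 2, 1))
  if (!identical(dim(weights), as.integer(c(kernel, kernel, 2, 1))))
    stop("spatial_attention_config: invalid weight shape, need (k, k, 2, 1)")
  structure(list(kernel = kernel, padding = (kernel - 1L) %/% 2L,
                 stride = 1L, weights = weights, bias = bias),
            class = "spatial_attention_config")
}

# Sigmoid spatial map (b, h, w) driving spatial attention.
spatial_attention_map <- function(x, cfg) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 3, 4, 2)), ncol = d[2])  # (b*h*w, c)
  d_mean <- rowMeans(xm)
  d_max <- xm[, 1]
  if (d[2] > 1) for (j in 2:d[2]) d_max <- pmax(d_max, xm[, j])
  gate <- array(0, dim = c(d[1], d[3], d[4]))
  for (b in seq_len(d[1])) {
    idx <- seq(b, by = d[1], length.out = d[3] * d[4])
    desc <- array(c(d_max[idx], d_mean[idx]), dim = c(d[3], d[4], 2))
    amap <- nn_conv(desc, cfg$weights, b = cfg$bias,
                    stride = cfg$stride, pad = cfg$padding)
    gate[b, , ] <- sigmoid_(amap[, , 1])
  }
  gate
}

#' Spatial attention
#'
#' Channel-wise max and mean pooling produce two `1 x H x W` spatial
#' descriptors, which are concatenated, convolved to a single channel with
#' a `kernel x kernel` filter and squashed through a sigmoid into an
#' attention map in (0, 1); the map is broadcast-multiplied with the input.
#'
#' @inheritParams channel_shuffle
#' @param cfg A [spatial_attention_config()].
#' @export
spatial_attention <- function(x, cfg = spatial_attention_config()) {
  d <- assert_feature_map(x)
  gate <- spatial_attention_map(x, cfg)
  x * broadcast_gate(gate, d)
}

# Expand a (b, h, w) spatial gate to (b, c, h, w).
broadcast_gate <- function(gate, d) {
  aperm(array(gate, dim = c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
}

#' Dual-channel attention configuration
#'
#' Two parallel convolutions with distinct kernel sizes capture features at
#' different receptive fields; their concatenation is fused back to the
#' input width by a pointwise convolution, a spatial-attention map is
#' computed from the fused tensor, and the input is multiplied by that map.
#' A depthwise context convolution precedes the branches.
#'
#' @param channels_in Channel count of the input feature map.
#' @param branch_kernels Pair of distinct odd kernel sizes (default 3, 5).
#' @param branch_channels Output channels of each branch (default
#'   `channels_in / 8`, the width at which the block stays lighter than the
#'   multi-head attention block it replaces).
#' @param fuse_kernel Kernel of the fuse convolution (default 1).
#' @param context_kernel Kernel of the depthwise context convolution
#'   (default 3).
#' @param weights Optional named list of learned tensors (`context`,
#'   `branch1`, `branch2`, `fuse` plus `*_b` biases); zeros by default,
#'   under which the block reduces to `0.5 * x`.
#' @param sa A [spatial_attention_config()] for the internal spatial gate.
#' @export
dual_channel_config <- function(channels_in,
                                branch_kernels = c(3L, 5L),
                                branch_channels = max(1L, channels_in %/% 8L),
                                fuse_kernel = 1L,
                                context_kernel = 3L,
                                weights = NULL,
                                sa = spatial_attention_config()) {
  channels_in <- as.integer(channels_in)
  k <- as.integer(branch_kernels)
  if (length(k) != 2 || k[1] == k[2] || any(k %% 2L == 0L))
    stop("dual_channel_config: branch_kernels must be two distinct odd sizes")
  cb <- as.integer(branch_channels)
  if (is.null(weights)) {
    weights <- list(
      context = array(0, dim = c(context_kernel, context_kernel, 1, channels_in)),
      context_b = numeric(channels_in),
      branch1 = array(0, dim = c(k[1], k[1], channels_in, cb)),
      branch1_b = numeric(cb),
      branch2 = array(0, dim = c(k[2], k[2], channels_in, cb)),
      branch2_b = numeric(cb),
      fuse = array(0, dim = c(fuse_kernel, fuse_kernel, 2L * cb, channels_in)),
      fuse_b = numeric(channels_in))
  }
  if (dim(weights$fuse)[3] != 2L * cb || dim(weights$fuse)[4] != channels_in)
    stop("dual_channel_config: fuse conv must map 2*branch_channels back to channels_in")
  structure(list(channels_in = channels_in, branch_kernels = k,
                 branch_channels = cb, fuse_kernel = as.integer(fuse_kernel),
                 context_kernel = as.integer(context_kernel),
                 weights = weights, sa = sa),
            class = "dual_channel_config")
}

# Learned parameter count of a dual-channel block (used by the profiler;
# must stay in lockstep with dual_channel()).
dual_channel_params <- function(cfg) {
  cin <- cfg$channels_in; cb <- cfg$branch_channels; k <- cfg$branch_kernels
  ctx <- cin * cfg$context_kernel^2 + cin
  b1 <- cin * cb * k[1]^2 + cb
  b2 <- cin * cb * k[2]^2 + cb
  fuse <- 2 * cb * cin * cfg$fuse_kernel^2 + cin
  sa <- 2 * cfg$sa$kernel^2 + 1
  ctx + b1 + b2 + fuse + sa
}

#' Dual-channel attention
#'
#' @inheritParams channel_shuffle
#' @param cfg A [dual_channel_config()]; its `channels_in` must match the
#'   input map.
#' @param sa Optional override of the spatial-attention configuration in
#'   `cfg`.
#' @export
dual_channel <- function(x, cfg, sa = NULL) {
  d <- assert_feature_map(x)
  if (d[2] != cfg$channels_in)
    stop("dual_channel: invalid config, channels_in (", cfg$channels_in,
         ") does not match input channels (", d[2], ")")
  if (!is.null(sa)) cfg$sa <- sa
  w <- cfg$weights
  fused <- array(0, dim = c(d[1], cfg$channels_in, d[3], d[4]))
  for (b in seq_len(d[1])) {
    xb <- aperm(array(x[b, , , ], dim = d[2:4]), c(2, 3, 1))  # (h, w, c)
    z <- silu_(nn_conv(xb, w$context, w$context_b, groups = cfg$channels_in))
    y1 <- silu_(nn_conv(z, w$branch1, w$branch1_b))
    y2 <- silu_(nn_conv(z, w$branch2, w$branch2_b))
    f <- nn_conv(nn_concat(y1, y2), w$fuse, w$fuse_b)
    fused[b, , , ] <- aperm(f, c(3, 1, 2))
  }
  gate <- spatial_attention_map(fused, cfg$sa)
  x * broadcast_gate(gate, d)
}
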