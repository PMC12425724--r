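# Attention operators: channel shuffle, spatial-inhibition energy gate,
# Shuffle3D composition, spatial attention and dual-channel attention.

test_that("channel shuffle realizes the group-interleave permutation", {
  x <- array(0, dim = c(1, 4, 2, 2))
  for (c in 1:4) x[1, c, , ] <- c
  y <- channel_shuffle(x, shuffle_spec(groups = 2))
  expect_equal(y[1, , 1, 1], c(1, 3, 2, 4))  # 0-based order (0,2,1,3)

  # groups = 1 is the identity
  z <- array(rnorm(2 * 6 * 3 * 3), dim = c(2, 6, 3, 3))
  expect_identical(channel_shuffle(z, shuffle_spec(groups = 1)), z)

  # C = 6, groups = 3 against an explicit index-permutation oracle
  oracle <- integer(6)
  g <- 3; cpg <- 2
  k <- 0
  for (j in seq_len(cpg)) for (i in seq_len(g)) {  # transpose enumeration
    k <- k + 1
    oracle[k] <- (i - 1) * cpg + j
  }
  expect_equal(oracle, c(1, 3, 5, 2, 4, 6))        # 0-based (0,2,4,1,3,5)
  expect_equal(braindet:::shuffle_permutation(6, shuffle_spec(3)), oracle)

  expect_error(channel_shuffle(z, shuffle_spec(groups = 4)), "divide")
})

test_that("channel shuffle conserves the per-location multiset of values", {
  set.seed(42)
  for (rep in 1:8) {
    g <- sample(c(1, 2, 4), 1)
    d <- c(sample(1:3, 1), g * sample(1:4, 1), sample(2:6, 1), sample(2:6, 1))
    x <- array(rnorm(prod(d)), dim = d)
    mode <- sample(c("group", "random"), 1)
    y <- channel_shuffle(x, shuffle_spec(g, mode, seed = rep))
    expect_identical(dim(y), dim(x))
    for (b in seq_len(d[1])) for (i in seq_len(d[3])) for (j in seq_len(d[4]))
      expect_equal(sort(y[b, , i, j]), sort(x[b, , i, j]))
  }
})

test_that("random shuffle mode is seeded and deterministic", {
  x <- array(rnorm(1 * 8 * 2 * 2), dim = c(1, 8, 2, 2))
  y1 <- channel_shuffle(x, shuffle_spec(2, "random", seed = 5))
  y2 <- channel_shuffle(x, shuffle_spec(2, "random", seed = 5))
  y3 <- channel_shuffle(x, shuffle_spec(2, "random", seed = 6))
  expect_identical(y1, y2)
  expect_false(identical(y1, y3))
})

test_that("energy gate matches the scalar formula and its contracts", {
  # zero input stays zero
  z <- array(0, dim = c(1, 2, 3, 3))
  expect_equal(energy_gate(z), z)

  # constant slice of ones on 2x2: independent scalar evaluation
  e <- 4 / 3
  u <- (1 - e)^2 / (4 * (e + 1e-4)) + 0.5
  expected <- 1 / (1 + exp(-u)) * 1
  x <- array(1, dim = c(1, 1, 2, 2))
  expect_equal(energy_gate(x)[1, 1, 1, 1], expected, tolerance = 1e-12)
  expect_equal(expected, 0.6273422, tolerance = 1e-6)

  # shape contract on a random map
  r <- array(rnorm(2 * 8 * 5 * 7), dim = c(2, 8, 5, 7))
  expect_identical(dim(energy_gate(r)), dim(r))

  # multiplicative gate bound |out| <= |in|
  out <- energy_gate(r)
  expect_true(all(abs(out) <= abs(r)))
  expect_true(all(abs(out[r != 0]) < abs(r[r != 0])))

  # degenerate and non-finite inputs
  expect_error(energy_gate(array(1, dim = c(1, 1, 1, 1))), "degenerate")
  bad <- r; bad[1] <- NA
  expect_error(energy_gate(bad), "non-finite")

  # the variance-denominator variant is a distinct, finite gating
  v <- energy_gate(r, energy_gate_params(variance = TRUE))
  expect_true(all(is.finite(v)))
  expect_false(identical(v, out))
})

test_that("shuffle3d composes shuffle and gate and stays parameter-free", {
  x <- array(rnorm(1 * 4 * 3 * 3), dim = c(1, 4, 3, 3))
  expect_equal(shuffle3d(x, shuffle_spec(groups = 1)), energy_gate(x))
  z <- array(0, dim = c(2, 4, 2, 2))
  expect_equal(shuffle3d(z), z)

  # constant channels: composition of the two component oracles
  xc <- array(0, dim = c(1, 4, 2, 2))
  vals <- c(0.3, -1.2, 2.5, 0.7)
  for (c in 1:4) xc[1, c, , ] <- vals[c]
  got <- shuffle3d(xc, shuffle_spec(groups = 2))
  perm <- c(1, 3, 2, 4)
  gate_scalar <- function(v) {
    e <- 4 * v / 3
    u <- (v - e)^2 / (4 * (e + 1e-4)) + 0.5
    v / (1 + exp(-u))
  }
  for (c in 1:4)
    expect_equal(got[1, c, , ], matrix(gate_scalar(vals[perm[c]]), 2, 2),
                 tolerance = 1e-12)

  # the graph node contributes zero learned parameters
  nd <- braindet:::new_node("Shuffle3D", 1L, "s")
  expect_identical(nrow(braindet:::expand_node(nd, 64L)), 0L)
})

test_that("spatial attention matches a nested-loop convolution oracle", {
  # zero kernel forces the 0.5 gate
  x <- array(rnorm(2 * 3 * 4 * 4), dim = c(2, 3, 4, 4))
  expect_equal(spatial_attention(x), 0.5 * x)

  # constant over channels: both descriptors equal that constant map
  xc <- array(rep(rnorm(16), each = 2 * 3), dim = c(2, 3, 4, 4))
  for (b in 1:2) {
    m <- apply(xc[b, , , ], c(2, 3), max)
    a <- apply(xc[b, , , ], c(2, 3), mean)
    expect_equal(m, a)
  }

  set.seed(1)
  w <- array(rnorm(7 * 7 * 2), dim = c(7, 7, 2, 1))
  cfg <- spatial_attention_config(7, w, bias = 0.3)
  xs <- array(rnorm(1 * 3 * 8 * 8), dim = c(1, 3, 8, 8))
  got <- spatial_attention(xs, cfg)
  dmax <- apply(xs, c(1, 3, 4), max)
  dmean <- apply(xs, c(1, 3, 4), mean)
  conv <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    s <- 0.3
    for (ki in 1:7) for (kj in 1:7) {
      ii <- i + ki - 4; jj <- j + kj - 4
      if (ii >= 1 && ii <= 8 && jj >= 1 && jj <= 8)
        s <- s + dmax[1, ii, jj] * w[ki, kj, 1, 1] +
          dmean[1, ii, jj] * w[ki, kj, 2, 1]
    }
    conv[i, j] <- s
  }
  gate <- 1 / (1 + exp(-conv))
  want <- xs
  for (c in 1:3) want[1, c, , ] <- xs[1, c, , ] * gate
  expect_equal(got, want, tolerance = 1e-12)

  expect_true(all(abs(got) <= abs(xs)))
  expect_error(spatial_attention_config(7, array(0, c(5, 5, 2, 1))),
               "invalid weight shape")
  expect_error(spatial_attention_config(4), "odd")
})

test_that("dual-channel attention honors its wiring contracts", {
  z <- array(0, dim = c(1, 16, 6, 6))
  cfg <- dual_channel_config(16)
  expect_equal(dual_channel(z, cfg), z)  # multiplicative in x

  x <- array(rnorm(2 * 64 * 20 * 20), dim = c(2, 64, 20, 20))
  y <- dual_channel(x, dual_channel_config(64))
  expect_identical(dim(y), dim(x))
  expect_equal(y, 0.5 * x)  # zero-weight configuration

  expect_error(dual_channel(x, dual_channel_config(32)), "channels_in")
  expect_error(dual_channel_config(16, branch_kernels = c(3, 3)), "distinct")

  # closed-form parameter arithmetic vs the profiler's expansion
  cfg128 <- dual_channel_config(128, branch_kernels = c(3, 5),
                                branch_channels = 64)
  closed <- (128 * 9 + 128) +                  # depthwise 3x3 context
    (128 * 64 * 9 + 64) + (128 * 64 * 25 + 64) +  # branches
    (128 * 128 * 1 + 128) +                    # 1x1 fuse
    (2 * 49 + 1)                               # spatial-attention conv
  expect_identical(braindet:::dual_channel_params(cfg128), closed)
  nd <- braindet:::new_node("DualChannel", 1L, "dc", list(cfg = cfg128))
  prims <- braindet:::expand_node(nd, 128L)
  expect_equal(sum(braindet:::prim_params(prims)), closed)
})

test_that("attention operators preserve shape for randomized maps", {
  set.seed(7)
  for (rep in 1:5) {
    d <- as.integer(c(sample(1:2, 1), 4 * sample(1:3, 1), sample(7:12, 1),
                      sample(7:12, 1)))
    x <- array(rnorm(prod(d)), dim = d)
    expect_identical(dim(shuffle3d(x)), d)
    expect_identical(dim(spatial_attention(x)), d)
    expect_identical(dim(dual_channel(x, dual_channel_config(d[2]))), d)
  }
})
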