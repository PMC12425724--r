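# IoU / CIoU family, hook reweighting, distribution focal loss and the
# weighted three-term total, with rasterization and finite-difference
# oracles.

test_that("iou matches closed cases and the rasterization oracle", {
  b <- box(0.5, 0.5, 1, 1)
  expect_equal(iou(b, b), 1)
  expect_equal(iou(box(0, 0, 1, 1), box(5, 5, 1, 1)), 0)

  p <- box_from_corners(0, 0, 2, 2)
  t <- box_from_corners(1, 1, 3, 3)
  expect_equal(iou(p, t), 1 / 7)
  expect_equal(raster_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7,
               tolerance = 1e-9)

  expect_error(box(0, 0, 0, 1), "invalid box")
})

test_that("the fast raster count agrees with dense cell enumeration", {
  set.seed(3)
  for (i in 1:5) {
    pc <- random_box_corners(); tc <- random_box_corners()
    expect_equal(raster_iou(pc, tc), raster_iou_dense(pc, tc),
                 tolerance = 1e-12)
  }
})

test_that("iou is symmetric, translation and scale invariant", {
  set.seed(11)
  for (i in 1:50) {
    pc <- random_box_corners(); tc <- random_box_corners()
    p <- box_from_corners(pc[1], pc[2], pc[3], pc[4])
    t <- box_from_corners(tc[1], tc[2], tc[3], tc[4])
    expect_equal(iou(p, t), iou(t, p))
    sh <- runif(2, -3, 3)
    p2 <- box(p$cx + sh[1], p$cy + sh[2], p$w, p$h)
    t2 <- box(t$cx + sh[1], t$cy + sh[2], t$w, t$h)
    expect_equal(iou(p2, t2), iou(p, t), tolerance = 1e-12)
    k <- runif(1, 0.5, 4)
    p3 <- box(k * p$cx, k * p$cy, k * p$w, k * p$h)
    t3 <- box(k * t$cx, k * t$cy, k * t$w, k * t$h)
    expect_equal(iou(p3, t3), iou(p, t), tolerance = 1e-12)
    # aspect penalty is scale invariant too
    expect_equal(ciou(p3, t3)$aspect_v, ciou(p, t)$aspect_v,
                 tolerance = 1e-12)
  }
})

test_that("ciou breakdown matches an independent scalar transcription", {
  b <- box(1, 2, 3, 4)
  cb <- ciou(b, b)
  expect_equal(cb$iou, 1)
  expect_equal(cb$center_term, 0)
  expect_equal(cb$aspect_v, 0)
  expect_equal(cb$ciou, 1)

  # same center and aspect ratio, different scale: arctan terms cancel
  cb2 <- ciou(box(0, 0, 2, 1), box(0, 0, 4, 2))
  expect_equal(cb2$aspect_v, 0)
  expect_equal(cb2$ciou, cb2$iou)

  p <- box(0, 0, 2, 1); t <- box(1, 1, 1, 2)
  cb3 <- ciou(p, t)
  expect_equal(cb3$ciou, ciou_scalar(c(0, 0, 2, 1), c(1, 1, 1, 2)),
               tolerance = 1e-12)
  # spelled-out components of the same pair: overlap (0.5,1)x(0,0.5)
  expect_equal(cb3$iou, 0.25 / (2 + 2 - 0.25))
  expect_equal(cb3$aspect_v,
               4 / pi^2 * (atan(1 / 2) - atan(2 / 1))^2)

  set.seed(23)
  for (i in 1:50) {
    pv <- c(runif(2, -1, 1), runif(2, 0.2, 2))
    tv <- c(runif(2, -1, 1), runif(2, 0.2, 2))
    got <- ciou(box(pv[1], pv[2], pv[3], pv[4]),
                box(tv[1], tv[2], tv[3], tv[4]))
    expect_equal(got$ciou, ciou_scalar(pv, tv), tolerance = 1e-12)
    expect_lte(got$ciou, got$iou)
    expect_gt(got$ciou, -2)
    expect_lte(got$ciou, 1)
  }
})

test_that("hook function analytics: minimum, symmetry, domain", {
  expect_equal(hook(1), 1)         # a = b = 0.5 minimum
  expect_equal(hook(2), 1.25)
  xs <- c(0.1, 0.25, 0.5, 1, 2, 4, 10)
  expect_equal(hook(xs), hook(1 / xs))   # forced by a = b
  expect_error(hook(0), "domain")
  expect_error(hook(-1), "domain")
  expect_error(hook_params(a = 0, b = 1), "a > 0")

  hp <- hook_params(a = 2, b = 0.5)
  grid <- seq(1e-3, 10, by = 1e-3)
  expect_equal(grid[which.min(hook(grid, hp))], sqrt(0.5 / 2),
               tolerance = 1e-3)
})

test_that("hkciou equals a*L^2 + b and reweights gradients as designed", {
  b <- box(3, 3, 2, 2)
  expect_equal(hkciou_loss(b, b), 0.5)     # L = 0 -> b

  set.seed(5)
  hp <- hook_params()
  for (i in 1:30) {
    p <- box(runif(1, -1, 1), runif(1, -1, 1), runif(1, 0.2, 2),
             runif(1, 0.2, 2))
    t <- box(runif(1, -1, 1), runif(1, -1, 1), runif(1, 0.2, 2),
             runif(1, 0.2, 2))
    L <- 1 - ciou(p, t)$ciou
    expect_equal(hkciou_loss(p, t), 0.5 * L^2 + 0.5, tolerance = 1e-12)
    if (L > 1e-6)  # identity with the hook-times-loss product form
      expect_equal(hkciou_loss(p, t), hook(L) * L, tolerance = 1e-12)
    # metric mode applies the same form to the CIoU value
    expect_equal(hkciou_loss(p, t, hook_params(mode = "metric")),
                 0.5 * (1 - L)^2 + 0.5, tolerance = 1e-12)
  }

  # worked values: L = 1 -> 1; L = 2 -> 2.5 > plain 2; L = 0.5 -> 0.625
  f <- function(L) hp$a * L^2 + hp$b
  expect_equal(f(1), 1)
  expect_equal(f(2), 2.5)
  expect_gt(f(2), 2)
  expect_equal(f(0.5), 0.625)
  # gradient ordering: 2aL at L=2 exceeds the plain unit slope, which
  # exceeds 2aL at L=0.5
  expect_gt(2 * hp$a * 2, 1)
  expect_lt(2 * hp$a * 0.5, 1)
})

test_that("analytic loss gradients match central finite differences", {
  set.seed(99)
  for (i in 1:100) {
    pv <- c(runif(2, -1, 1), runif(2, 0.3, 2))
    tv <- c(runif(2, -1, 1), runif(2, 0.3, 2))
    t <- box(tv[1], tv[2], tv[3], tv[4])
    p <- box(pv[1], pv[2], pv[3], pv[4])
    pc <- box_corners(p)
    cg <- braindet:::ciou_grad(p, t)
    fd <- fd_grad(function(x)
      ciou(box_from_corners(x[1], x[2], x[3], x[4]), t)$ciou, pc)
    expect_equal(cg$grad, fd, tolerance = 1e-4)
    for (type in c("ciou", "hkciou")) {
      bl <- braindet:::bbox_loss_grad(p, t, type)
      fd2 <- fd_grad(function(x) {
        pb <- box_from_corners(x[1], x[2], x[3], x[4])
        if (type == "ciou") 1 - ciou(pb, t)$ciou else hkciou_loss(pb, t)
      }, pc)
      expect_equal(bl$grad, fd2, tolerance = 1e-4)
    }
  }
})

test_that("distribution focal loss covers its closed cases", {
  pm <- rep(0, 16); pm[4] <- 1
  expect_equal(dfl_loss(pm, 3), 0)
  expect_equal(dfl_loss(rep(1 / 16, 16), 7.3), log(16), tolerance = 1e-9)
  d <- rep(0, 16); d[6] <- 0.75; d[7] <- 0.25
  expect_equal(dfl_loss(d, 5.25), -(0.75 * log(0.75) + 0.25 * log(0.25)),
               tolerance = 1e-6)
  expect_equal(dfl_loss(d, 5.25), 0.5623, tolerance = 1e-4)
  expect_error(dfl_loss(rep(1 / 16, 16), 16), "target outside")
  expect_error(dfl_loss(rep(1, 16), 3), "probability")
})

test_that("total loss is the stored weighted sum of its parts", {
  lb <- total_loss(0, 0, 0)
  expect_equal(lb$total, 0)
  expect_equal(total_loss(0.2, 0.3, 0.5, loss_weights(1, 1, 1))$total, 1)
  w <- loss_weights()   # 7.5 / 1.5 / 0.5 defaults
  lb3 <- total_loss(1, 1, 1, w)
  expect_equal(lb3$total, 9.5)
  expect_equal(lb3$total,
               w$w_box * lb3$l_box + w$w_obj * lb3$l_obj + w$w_cls * lb3$l_cls)
  expect_error(total_loss(-1, 0, 0), "non-negative")
  expect_error(loss_weights(0, 0, 0), "not all zero")
  # the dfl alias feeds the confidence slot
  expect_equal(loss_weights(w_dfl = 2)$w_obj, 2)
})
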