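# Anchors, target assignment, trainer gradients, prediction/NMS and the
# mAP evaluator.

test_that("anchor grids have the expected geometry", {
  a <- make_anchors(64L)
  expect_identical(nrow(a), 64L + 16L + 4L)
  expect_equal(sort(unique(a$stride)), c(8, 16, 32))
  a8 <- a[a$stride == 8, ]
  expect_equal(sort(unique(a8$x)), (1:8 - 0.5) * 8)
  expect_identical(nrow(make_anchors(640L)), 8400L)
})

test_that("target assignment follows center-in-box with scale ranges", {
  anch <- make_anchors(64L)
  # no ground truth -> no positives
  expect_identical(nrow(assign_targets(anch, NULL, 8)), 0L)
  empty_gt <- data.frame(class_id = integer(0), cx = numeric(0),
                         cy = numeric(0), w = numeric(0), h = numeric(0))
  expect_identical(nrow(assign_targets(anch, empty_gt, 8)), 0L)

  # a small box covering exactly one stride-8 cell center
  gt <- data.frame(class_id = 1L, cx = 12, cy = 12, w = 7, h = 7)
  pos <- assign_targets(anch, gt, 8)
  expect_identical(nrow(pos), 1L)
  expect_equal(anch$x[pos$anchor], 12)
  expect_equal(anch$y[pos$anchor], 12)
  expect_equal(anch$stride[pos$anchor], 8)
  # regression targets reconstruct the box sides in stride units
  expect_equal(pos$l, (12 - 8.5) / 8)
  expect_equal(pos$r, (15.5 - 12) / 8)

  # nested boxes over one anchor: smaller area wins; checked against an
  # exhaustive enumeration oracle over all (anchor, box) pairs
  gt2 <- data.frame(class_id = c(0L, 3L), cx = c(20, 20), cy = c(20, 20),
                    w = c(24, 10), h = c(24, 10))
  pos2 <- assign_targets(anch, gt2, 8)
  rng <- braindet:::stride_scale_range(c(8L, 16L, 32L))
  oracle <- list()
  for (ai in seq_len(nrow(anch))) {
    best <- 0; barea <- Inf
    for (gi in 1:2) {
      r <- rng[rng$stride == anch$stride[ai], ]
      longer <- max(gt2$w[gi], gt2$h[gi])
      if (!(longer > r$lo && longer <= r$hi)) next
      if (abs(anch$x[ai] - gt2$cx[gi]) < gt2$w[gi] / 2 &&
          abs(anch$y[ai] - gt2$cy[gi]) < gt2$h[gi] / 2 &&
          gt2$w[gi] * gt2$h[gi] < barea) {
        best <- gi; barea <- gt2$w[gi] * gt2$h[gi]
      }
    }
    if (best > 0) oracle[[length(oracle) + 1]] <- c(ai, best)
  }
  om <- do.call(rbind, oracle)
  shared <- pos2[pos2$anchor %in% om[, 1], ]
  expect_equal(shared$gt, om[match(shared$anchor, om[, 1]), 2])
  # the anchor inside both boxes took the smaller one
  inner <- pos2[anch$x[pos2$anchor] == 20 & anch$y[pos2$anchor] == 20 &
                  anch$stride[pos2$anchor] == 8, ]
  expect_identical(inner$gt, 2L)

  # a sub-cell box still receives its nearest anchor as a positive
  tiny <- data.frame(class_id = 2L, cx = 17, cy = 17, w = 3, h = 3)
  pos3 <- assign_targets(anch, tiny, 8)
  expect_identical(nrow(pos3), 1L)
  expect_equal(anch$stride[pos3$anchor], 8)
})

test_that("trainer gradients match finite differences through the model", {
  man <- micro_manifest()
  spec <- build_micro(channels = c(4L, 6L, 8L, 10L, 12L), head_width = 8L)
  model <- init_model(spec, seed = 3)
  items <- braindet:::load_split(man, "train", 64L)
  img <- items[[1]]$image
  gt <- braindet:::labels_to_pixels(items[[1]]$labels, 64L)
  w <- loss_weights()
  loss_of <- function(m) {
    fw <- braindet:::micro_forward(m, img)
    braindet:::micro_loss_grads(fw$heads, gt, 64L, spec$reg_max,
                                spec$strides, "hkciou", hook_params(),
                                w)$breakdown$total
  }
  fw <- braindet:::micro_forward(model, img, keep = TRUE)
  lg <- braindet:::micro_loss_grads(fw$heads, gt, 64L, spec$reg_max,
                                    spec$strides, "hkciou", hook_params(), w)
  g <- braindet:::micro_backward(model, fw, lg$dheads)
  set.seed(8)
  for (nm in c("s1", "s3", "head.l1.box1", "head.l1.cls3")) {
    idx <- sample(length(model$W[[nm]]$w), 3)
    for (ix in idx) {
      h <- 1e-5
      mp <- model; mp$W[[nm]]$w[ix] <- mp$W[[nm]]$w[ix] + h
      mm <- model; mm$W[[nm]]$w[ix] <- mm$W[[nm]]$w[ix] - h
      fd <- (loss_of(mp) - loss_of(mm)) / (2 * h)
      expect_equal(g[[nm]]$w[ix], fd, tolerance = 1e-3)
    }
  }
})

test_that("a zero learning rate leaves the parameters unchanged", {
  man <- micro_manifest()
  spec <- build_micro()
  m0 <- init_model(spec, seed = 5)
  fit <- train(m0, man, train_config(epochs = 1, lr0 = 0, seed = 5,
                                     hflip = FALSE, intensity_jitter = 0))
  expect_identical(fit$model$W, m0$W)
})

test_that("short training runs decrease the loss for both box losses", {
  man <- micro_manifest()
  for (lt in c("ciou", "hkciou")) {
    fit <- train(build_micro(), man,
                 train_config(epochs = 3, seed = 21, loss = lt))
    expect_true(all(is.finite(fit$history$total)))
    expect_lt(tail(fit$history$total, 1), fit$history$total[1])
  }
})

test_that("training is deterministic under a fixed seed", {
  man <- micro_manifest()
  cfg <- train_config(epochs = 1, seed = 13)
  f1 <- train(build_micro(), man, cfg)
  f2 <- train(build_micro(), man, cfg)
  expect_identical(f1$model$W, f2$model$W)
  expect_identical(f1$history, f2$history)
})

test_that("prediction decodes, filters and suppresses correctly", {
  man <- micro_manifest()
  m <- init_model(build_micro(), seed = 2)
  img <- braindet:::load_image(file.path(man$path, man$files$train[1]))
  # an impossible confidence threshold yields no detections
  expect_identical(nrow(predict_image(m, img, conf_threshold = 1.0)), 0L)
  d <- predict_image(m, img, conf_threshold = 0)
  expect_true(all(d$w > 0 & d$h > 0))
  expect_true(all(d$confidence >= 0 & d$confidence <= 1))

  # duplicate boxes of one class collapse to a single detection
  dup <- data.frame(class_id = c(1L, 1L), cx = 0.5, cy = 0.5, w = 0.2,
                    h = 0.2, confidence = c(0.9, 0.8))
  expect_identical(nrow(nms(dup, 0.7)), 1L)
  # same geometry in different classes is kept
  dup2 <- dup; dup2$class_id <- c(1L, 2L)
  expect_identical(nrow(nms(dup2, 0.7)), 2L)

  # 50 random boxes against the O(n^2) reference suppressor
  set.seed(31)
  rb <- data.frame(class_id = sample(0:2, 50, TRUE),
                   cx = runif(50, 0.2, 0.8), cy = runif(50, 0.2, 0.8),
                   w = runif(50, 0.05, 0.3), h = runif(50, 0.05, 0.3),
                   confidence = runif(50))
  expect_equal(nms(rb, 0.5), nms_oracle(rb, 0.5), ignore_attr = TRUE)
})

test_that("mAP evaluator handles the canonical closed cases", {
  gt <- data.frame(image_id = 1L, class_id = 0L, cx = 0.5, cy = 0.5,
                   w = 0.4, h = 0.4)
  perfect <- cbind(gt, confidence = 1)
  ev <- evaluate_map(perfect, gt, num_classes = 1)
  expect_equal(ev$map50, 1)
  expect_equal(ev$map50_95, 1)

  none <- perfect[0, ]
  ev0 <- evaluate_map(none, gt, num_classes = 1)
  expect_equal(ev0$map50, 0)
  expect_equal(ev0$map50_95, 0)

  # single detection at IoU exactly 0.60: passes thresholds .50/.55/.60
  gt2 <- data.frame(image_id = 1L, class_id = 0L, cx = 0.5, cy = 0.5,
                    w = 1, h = 1)
  det2 <- data.frame(image_id = 1L, class_id = 0L, cx = 0.5, cy = 0.3,
                     w = 1, h = 0.6, confidence = 0.9)
  expect_equal(iou(box(det2$cx, det2$cy, det2$w, det2$h),
                   box(gt2$cx, gt2$cy, gt2$w, gt2$h)), 0.6)
  ev2 <- evaluate_map(det2, gt2, num_classes = 1)
  expect_equal(ev2$map50, 1)
  expect_equal(ev2$map50_95, 0.3)
  expect_lte(ev2$map50_95, ev2$map50)

  expect_error(evaluate_map(transform(det2, class_id = 7L), gt2, 4),
               "vocabulary")
})

test_that("mAP is monotone under added hits and trailing false positives", {
  set.seed(12)
  gt <- data.frame(image_id = rep(1:4, each = 2), class_id = rep(0:1, 4),
                   cx = runif(8, 0.3, 0.7), cy = runif(8, 0.3, 0.7),
                   w = runif(8, 0.1, 0.3), h = runif(8, 0.1, 0.3))
  det <- cbind(gt[c(1, 4, 6), ], confidence = c(0.9, 0.8, 0.7))
  base <- evaluate_map(det, gt, num_classes = 2)
  # adding a correct detection never lowers AP
  more <- rbind(det, cbind(gt[7, ], confidence = 0.65))
  better <- evaluate_map(more, gt, num_classes = 2)
  expect_gte(better$map50 + 1e-12, base$map50)
  expect_gte(better$map50_95 + 1e-12, base$map50_95)
  # a false positive ranked below every true positive cannot change the
  # interpolated AP
  fp <- data.frame(image_id = 2L, class_id = 0L, cx = 0.05, cy = 0.05,
                   w = 0.05, h = 0.05, confidence = 0.01)
  ev_fp <- evaluate_map(rbind(det, fp), gt, num_classes = 2)
  expect_equal(ev_fp$map50, base$map50)
  expect_equal(ev_fp$map50_95, base$map50_95)
})

test_that("evaluator agrees with the reference implementation", {
  set.seed(77)
  for (rep in 1:20) {
    n_img <- sample(2:4, 1)
    gt <- NULL; det <- NULL
    for (im in seq_len(n_img)) {
      ng <- sample(1:3, 1)
      g <- data.frame(image_id = im, class_id = sample(0:2, ng, TRUE),
                      cx = runif(ng, 0.25, 0.75), cy = runif(ng, 0.25, 0.75),
                      w = runif(ng, 0.1, 0.35), h = runif(ng, 0.1, 0.35))
      gt <- rbind(gt, g)
      # noisy copies of the truth plus clutter
      nd <- sample(0:4, 1)
      if (nd > 0) {
        pick <- sample(ng, nd, replace = TRUE)
        d <- g[pick, ]
        d$cx <- d$cx + rnorm(nd, 0, 0.04)
        d$cy <- d$cy + rnorm(nd, 0, 0.04)
        d$w <- pmax(0.05, d$w * runif(nd, 0.7, 1.3))
        d$h <- pmax(0.05, d$h * runif(nd, 0.7, 1.3))
        d$confidence <- runif(nd)
        det <- rbind(det, d)
      }
    }
    if (is.null(det)) next
    got <- evaluate_map(det, gt, num_classes = 3)
    ref <- reference_map(det, gt, num_classes = 3)
    expect_equal(got$map50, ref$map50, tolerance = 1e-6)
    expect_equal(got$map50_95, ref$map50_95, tolerance = 1e-6)
  }
})
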