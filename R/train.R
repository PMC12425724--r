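# Micro training harness: anchor generation, target assignment, SGD with
# momentum on the micro detector, DFL box decoding and prediction. The
# trainer implements its own backward pass (conv transposes via col2im,
# SiLU and softmax-expectation chain rules, analytic CIoU/HKCIoU box
# gradients), so no external autograd is involved.

#' Anchor points of a detector at a given input size
#'
#' One anchor per feature-map cell center per stride.
#'
#' @param input_size Square input size in pixels.
#' @param strides Head strides.
#' @return Data frame with columns `x, y, stride, level`.
#' @export
make_anchors <- function(input_size, strides = c(8L, 16L, 32L)) {
  out <- NULL
  for (li in seq_along(strides)) {
    s <- strides[li]
    n <- input_size %/% s
    cx <- ((seq_len(n)) - 0.5) * s
    out <- rbind(out, data.frame(x = rep(cx, each = n),
                                 y = rep(cx, times = n),
                                 stride = s, level = li))
  }
  out
}

# Scale range (longer box side, pixels) handled by each stride: up to 4
# cells of that stride (half the distribution-focal range), unbounded at
# the coarsest stride.
stride_scale_range <- function(strides) {
  hi <- ifelse(seq_along(strides) == length(strides), Inf, 4 * strides)
  lo <- c(0, hi[-length(hi)])
  data.frame(stride = strides, lo = lo, hi = hi)
}

#' Assign ground-truth boxes to anchor points
#'
#' An anchor is positive for a ground-truth box when its point lies inside
#' the box and the box's longer side falls inside the anchor stride's
#' scale range (each stride handles sides up to four of its cells -- 32 px
#' at stride 8, 64 px at stride 16 -- and the coarsest stride takes the
#' rest). When several boxes claim one anchor the smallest
#' box area wins; a box containing no anchor center is assigned the
#' nearest free anchor of its stride so every ground-truth box has at
#' least one positive. Each positive carries its class and the four
#' anchor-to-side distances in stride units (the DFL regression target).
#'
#' @param anchors Data frame from [make_anchors()].
#' @param gt Data frame with `class_id, cx, cy, w, h` in pixels.
#' @param reg_max Number of DFL bins (targets are clamped to
#'   `reg_max - 1`).
#' @return Data frame with one row per positive anchor: `anchor, gt,
#'   class_id, l, t, r, b`.
#' @export
assign_targets <- function(anchors, gt, reg_max = 16L) {
  empty <- data.frame(anchor = integer(0), gt = integer(0),
                      class_id = integer(0), l = numeric(0), t = numeric(0),
                      r = numeric(0), b = numeric(0))
  if (is.null(gt) || nrow(gt) == 0) return(empty)
  rng <- stride_scale_range(unique(anchors$stride))
  out <- NULL
  for (ai in seq_len(nrow(anchors))) {
    ax <- anchors$x[ai]; ay <- anchors$y[ai]; s <- anchors$stride[ai]
    r <- rng[rng$stride == s, ]
    longer <- pmax(gt$w, gt$h)
    inside <- ax > gt$cx - gt$w / 2 & ax < gt$cx + gt$w / 2 &
      ay > gt$cy - gt$h / 2 & ay < gt$cy + gt$h / 2
    ok <- which(inside & longer > r$lo & longer <= r$hi)
    if (length(ok) == 0) next
    gi <- ok[which.min(gt$w[ok] * gt$h[ok])]
    out <- rbind(out, pos_row(ai, gi, anchors, gt, reg_max))
  }
  # guarantee at least one positive per ground-truth box: a box too small
  # to contain any anchor center is assigned the nearest free anchor of
  # the stride whose scale range covers it
  for (gi in seq_len(nrow(gt))) {
    if (!is.null(out) && gi %in% out$gt) next
    longer <- max(gt$w[gi], gt$h[gi])
    s_ok <- rng$stride[longer > rng$lo & longer <= rng$hi][1]
    cand <- which(anchors$stride == s_ok)
    if (!is.null(out)) cand <- setdiff(cand, out$anchor)
    if (length(cand) == 0) next
    dd <- (anchors$x[cand] - gt$cx[gi])^2 + (anchors$y[cand] - gt$cy[gi])^2
    out <- rbind(out, pos_row(cand[which.min(dd)], gi, anchors, gt, reg_max))
  }
  if (is.null(out)) empty else out
}

pos_row <- function(ai, gi, anchors, gt, reg_max) {
  ax <- anchors$x[ai]; ay <- anchors$y[ai]; s <- anchors$stride[ai]
  mx <- reg_max - 1 - 1e-3
  data.frame(
    anchor = ai, gt = gi, class_id = gt$class_id[gi],
    l = min(max((ax - (gt$cx[gi] - gt$w[gi] / 2)) / s, 0), mx),
    t = min(max((ay - (gt$cy[gi] - gt$h[gi] / 2)) / s, 0), mx),
    r = min(max(((gt$cx[gi] + gt$w[gi] / 2) - ax) / s, 0), mx),
    b = min(max(((gt$cy[gi] + gt$h[gi] / 2) - ay) / s, 0), mx))
}

#' Training configuration
#'
#' Defaults follow the study's optimizer settings (SGD, initial learning
#' rate 0.01, momentum 0.937, weight decay 0.0005) at micro scale: 20
#' epochs, batch 8, 64 px inputs, 3 warmup epochs with linearly increasing
#' learning rate.
#'
#' @param epochs,batch_size,imgsz,seed Run geometry and seeding.
#' @param lr0,momentum,weight_decay SGD hyperparameters.
#' @param warmup_epochs Linear learning-rate warmup span.
#' @param loss `"ciou"` or `"hkciou"` box regression loss.
#' @param hook_a,hook_b Hook coefficients when `loss = "hkciou"`.
#' @param weights A [loss_weights()] object.
#' @param hflip Random horizontal flip augmentation.
#' @param intensity_jitter Random brightness jitter amplitude (0 disables).
#' @export
train_config <- function(epochs = 20L, batch_size = 8L, imgsz = 64L,
                         seed = 0L, lr0 = 0.01, momentum = 0.937,
                         weight_decay = 5e-4, warmup_epochs = 3L,
                         loss = c("ciou", "hkciou"),
                         hook_a = 0.5, hook_b = 0.5,
                         weights = loss_weights(),
                         hflip = TRUE, intensity_jitter = 0.05) {
  loss <- match.arg(loss)
  if (epochs < 1 || batch_size < 1 || lr0 < 0)
    stop("train_config: need positive epochs and batch size, lr0 >= 0")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 imgsz = as.integer(imgsz), seed = as.integer(seed),
                 lr0 = lr0, momentum = momentum,
                 weight_decay = weight_decay,
                 warmup_epochs = as.integer(warmup_epochs), loss = loss,
                 hook = hook_params(hook_a, hook_b), weights = weights,
                 hflip = hflip, intensity_jitter = intensity_jitter),
            class = "train_config")
}

# ---- micro forward with caches + backward ----

micro_layout <- function(spec) {
  kinds <- vapply(spec$nodes, function(n) n$kind, "")
  hi <- which(kinds == "DetectHead")
  if (length(hi) != 1 || !identical(spec$nodes[[hi]]$args$style, "micro"))
    stop("trainer supports micro specs (plain conv backbone + micro head)")
  if (!all(kinds[-hi] == "CBS"))
    stop("trainer supports micro specs (plain conv backbone + micro head)")
  list(backbone = seq_len(hi - 1L), head = hi,
       taps = spec$nodes[[hi]]$from)
}

micro_forward <- function(model, img, keep = FALSE) {
  spec <- model$spec
  W <- model$W
  lay <- micro_layout(spec)
  acts <- vector("list", length(lay$backbone))
  caches <- list(backbone = vector("list", length(lay$backbone)),
                 heads = vector("list", 3))
  x <- img
  for (i in lay$backbone) {
    cv <- W[[spec$nodes[[i]]$name]]
    r <- nn_conv(x, cv$w, cv$b, stride = spec$nodes[[i]]$args$s,
                 keep_cols = keep)
    z <- if (keep) r$out else r
    if (keep) caches$backbone[[i]] <- list(cols = r$cols,
                                           in_dim = r$in_dim, z = z)
    x <- silu_(z)
    acts[[i]] <- x
  }
  base <- spec$nodes[[lay$head]]$name
  heads <- vector("list", 3)
  for (li in 1:3) {
    f <- acts[[lay$taps[li]]]
    nb <- paste0(base, ".l", li)
    c1 <- W[[paste0(nb, ".box1")]]; c3 <- W[[paste0(nb, ".box3")]]
    k1 <- W[[paste0(nb, ".cls1")]]; k3 <- W[[paste0(nb, ".cls3")]]
    rb <- nn_conv(f, c1$w, c1$b, keep_cols = keep)
    zb <- if (keep) rb$out else rb
    ab <- silu_(zb)
    rb2 <- nn_conv(ab, c3$w, c3$b, keep_cols = keep)
    box <- if (keep) rb2$out else rb2
    rc <- nn_conv(f, k1$w, k1$b, keep_cols = keep)
    zc <- if (keep) rc$out else rc
    ac <- silu_(zc)
    rc2 <- nn_conv(ac, k3$w, k3$b, keep_cols = keep)
    cls <- if (keep) rc2$out else rc2
    heads[[li]] <- list(box = box, cls = cls)
    if (keep)
      caches$heads[[li]] <- list(zb = zb, zc = zc,
                                 cols_b1 = rb$cols, in_b1 = rb$in_dim,
                                 cols_b3 = rb2$cols, in_b3 = rb2$in_dim,
                                 cols_c1 = rc$cols, in_c1 = rc$in_dim,
                                 cols_c3 = rc2$cols, in_c3 = rc2$in_dim)
  }
  list(heads = heads, acts = acts, caches = caches, layout = lay)
}

# Backward through the micro graph; dheads is a list of per-level
# list(box =, cls =) gradients. Returns named list of weight gradients.
micro_backward <- function(model, fw, dheads) {
  spec <- model$spec
  W <- model$W
  lay <- fw$layout
  base <- spec$nodes[[lay$head]]$name
  grads <- list()
  dacts <- vector("list", length(lay$backbone))
  addg <- function(name, dw, db) {
    g <- grads[[name]]
    if (is.null(g)) grads[[name]] <<- list(w = dw, b = db)
    else grads[[name]] <<- list(w = g$w + dw, b = g$b + db)
  }
  for (li in 1:3) {
    ca <- fw$caches$heads[[li]]
    nb <- paste0(base, ".l", li)
    ti <- lay$taps[li]
    # box branch
    bb <- nn_conv_bwd(dheads[[li]]$box, W[[paste0(nb, ".box3")]]$w,
                      ca$cols_b3, ca$in_b3)
    addg(paste0(nb, ".box3"), bb$dw, bb$db)
    dz <- bb$dx * silu_grad_(ca$zb)
    b1 <- nn_conv_bwd(dz, W[[paste0(nb, ".box1")]]$w, ca$cols_b1, ca$in_b1)
    addg(paste0(nb, ".box1"), b1$dw, b1$db)
    df <- b1$dx
    # cls branch
    cb <- nn_conv_bwd(dheads[[li]]$cls, W[[paste0(nb, ".cls3")]]$w,
                      ca$cols_c3, ca$in_c3)
    addg(paste0(nb, ".cls3"), cb$dw, cb$db)
    dz <- cb$dx * silu_grad_(ca$zc)
    c1 <- nn_conv_bwd(dz, W[[paste0(nb, ".cls1")]]$w, ca$cols_c1, ca$in_c1)
    addg(paste0(nb, ".cls1"), c1$dw, c1$db)
    df <- df + c1$dx
    dacts[[ti]] <- if (is.null(dacts[[ti]])) df else dacts[[ti]] + df
  }
  for (i in rev(lay$backbone)) {
    if (is.null(dacts[[i]])) next
    ca <- fw$caches$backbone[[i]]
    nm <- spec$nodes[[i]]$name
    dz <- dacts[[i]] * silu_grad_(ca$z)
    bw <- nn_conv_bwd(dz, W[[nm]]$w, ca$cols, ca$in_dim,
                      stride = spec$nodes[[i]]$args$s)
    addg(nm, bw$dw, bw$db)
    if (i > 1) {
      j <- i - 1L
      dacts[[j]] <- if (is.null(dacts[[j]])) bw$dx else dacts[[j]] + bw$dx
    }
  }
  grads
}

# ---- loss + gradient on one image ----

side_block <- function(s, reg_max) ((s - 1) * reg_max + 1):(s * reg_max)

# Computes the three-term loss and the gradients w.r.t. the raw head
# outputs for one image. gt is in pixels.
micro_loss_grads <- function(heads, gt, imgsz, reg_max, strides,
                             loss_type, hp, w) {
  nc <- dim(heads[[1]]$cls)[3]
  anchors <- make_anchors(imgsz, strides)
  pos <- assign_targets(anchors, gt, reg_max)
  npos <- max(1L, nrow(pos))
  bins <- 0:(reg_max - 1)
  dheads <- lapply(heads, function(h)
    list(box = array(0, dim = dim(h$box)), cls = array(0, dim = dim(h$cls))))

  l_cls <- 0
  offset <- 0L
  anch_per_level <- table(factor(anchors$level, levels = 1:3))
  for (li in 1:3) {
    cl <- heads[[li]]$cls
    d <- dim(cl)
    zm <- matrix(cl, ncol = nc)           # rows: (row-major within level)
    # anchors for level li were built x-major: x = rep(each=n), y = rep(times)
    # feature map array is (row=y, col=x): element (y, x) at index y + (x-1)*n
    # anchor j has x index (j-1) %/% n + 1, y index (j-1) %% n + 1 -> matches
    # column-major layout of the (h, w) map exactly.
    Y <- matrix(0, nrow(zm), nc)
    if (nrow(pos) > 0) {
      sel <- pos[anchors$level[pos$anchor] == li, , drop = FALSE]
      if (nrow(sel) > 0) {
        aj <- sel$anchor - offset
        Y[cbind(aj, sel$class_id + 1L)] <- 1
      }
    }
    P <- sigmoid_(zm)
    eps <- 1e-9
    l_cls <- l_cls + sum(-(Y * log(P + eps) + (1 - Y) * log(1 - P + eps)))
    dheads[[li]]$cls <- array((P - Y) * (w$w_cls / npos), dim = d)
    offset <- offset + as.integer(anch_per_level[li])
  }
  l_cls <- l_cls / npos

  l_iou <- 0; l_dfl <- 0
  if (nrow(pos) > 0) {
    for (pi in seq_len(nrow(pos))) {
      ai <- pos$anchor[pi]
      li <- anchors$level[ai]
      s <- anchors$stride[ai]
      n <- imgsz %/% s
      aj <- ai - c(0L, cumsum(as.integer(anch_per_level)))[li]
      yj <- (aj - 1L) %% n + 1L
      xj <- (aj - 1L) %/% n + 1L
      z <- heads[[li]]$box[yj, xj, ]
      dz <- numeric(length(z))
      pmat <- matrix(0, reg_max, 4)
      dists <- numeric(4)
      for (sd_ in 1:4) {
        blk <- side_block(sd_, reg_max)
        e <- exp(z[blk] - max(z[blk]))
        p <- e / sum(e)
        pmat[, sd_] <- p
        dists[sd_] <- sum(p * bins)
      }
      ax <- anchors$x[ai]; ay <- anchors$y[ai]
      pb <- c(ax - dists[1] * s, ay - dists[2] * s,
              ax + dists[3] * s, ay + dists[4] * s)
      pw <- max(pb[3] - pb[1], 1e-3); ph <- max(pb[4] - pb[2], 1e-3)
      pred <- box((pb[1] + pb[3]) / 2, (pb[2] + pb[4]) / 2, pw, ph)
      gi <- pos$gt[pi]
      tgt <- box(gt$cx[gi], gt$cy[gi], gt$w[gi], gt$h[gi])
      bl <- bbox_loss_grad(pred, tgt, loss_type, hp)
      l_iou <- l_iou + bl$value
      ddist <- c(-bl$grad[1] * s, -bl$grad[2] * s,
                 bl$grad[3] * s, bl$grad[4] * s)
      tdist <- c(pos$l[pi], pos$t[pi], pos$r[pi], pos$b[pi])
      for (sd_ in 1:4) {
        blk <- side_block(sd_, reg_max)
        p <- pmat[, sd_]
        # box-loss chain through the softmax expectation
        g <- (w$w_box / npos) * ddist[sd_] * p * (bins - dists[sd_])
        # DFL: softmax cross-entropy against the two adjacent bins
        tl <- floor(tdist[sd_]); wr <- tdist[sd_] - tl
        yv <- numeric(reg_max)
        yv[tl + 1] <- 1 - wr
        if (wr > 0) yv[tl + 2] <- wr
        l_dfl <- l_dfl - sum(yv * log(p + 1e-12))
        g <- g + (w$w_obj / (npos * 4)) * (p - yv)
        dz[blk] <- g
      }
      dheads[[li]]$box[yj, xj, ] <- dheads[[li]]$box[yj, xj, ] + dz
    }
    l_iou <- l_iou / nrow(pos)
    l_dfl <- l_dfl / (nrow(pos) * 4)
  }
  total <- w$w_box * l_iou + w$w_obj * l_dfl + w$w_cls * l_cls
  list(dheads = dheads, n_pos = nrow(pos),
       breakdown = structure(list(l_box = l_iou + l_dfl, l_obj = l_dfl,
                                  l_cls = l_cls, total = total),
                             class = "loss_breakdown"))
}

# ---- data plumbing ----

load_split <- function(manifest, split, imgsz) {
  rels <- manifest$files[[split]]
  lapply(seq_along(rels), function(i) {
    img <- load_image(file.path(manifest$path, rels[i]))
    if (dim(img)[1] != imgsz)
      stop("image size ", dim(img)[1], " does not match imgsz ", imgsz,
           "; generate the dataset at the training resolution")
    lbl <- read_yolo_labels(file.path(manifest$path,
                                      label_path_for(rels[i])))
    list(image = img, labels = lbl, id = i)
  })
}

labels_to_pixels <- function(lbl, imgsz) {
  if (nrow(lbl) == 0) return(lbl)
  data.frame(class_id = lbl$class_id, cx = lbl$cx * imgsz,
             cy = lbl$cy * imgsz, w = lbl$w * imgsz, h = lbl$h * imgsz)
}

#' Train a micro detector
#'
#' Runs SGD (momentum 0.937, weight decay 5e-4, initial learning rate 0.01
#' with linear warmup) over the manifest's training split, computing the
#' three-term detection loss (CIoU or HKCIoU box regression + distribution
#' focal loss on the positives, binary cross-entropy classification over
#' all anchors) and backpropagating through the micro graph. Deterministic
#' given `cfg$seed`.
#'
#' @param model A `model_spec` from [build_micro()] or an already
#'   initialized `bdet_model`.
#' @param data A `dataset_manifest` (see [generate_dataset()]).
#' @param cfg A [train_config()].
#' @return A `bdet_fit`: list with the trained `model`, per-epoch
#'   `history` (loss components) and `cfg`.
#' @export
train <- function(model, data, cfg = train_config()) {
  if (inherits(model, "model_spec")) model <- init_model(model, cfg$seed)
  spec <- model$spec
  items <- load_split(data, "train", cfg$imgsz)
  n <- length(items)
  vel <- list()
  history <- NULL
  it <- 0L
  warm_its <- cfg$warmup_epochs * ceiling(n / cfg$batch_size)
  set.seed(cfg$seed)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(n)
    ep_losses <- c(l_box = 0, l_obj = 0, l_cls = 0, total = 0)
    nb <- 0L
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      it <- it + 1L
      lr <- cfg$lr0 * if (it <= warm_its) it / warm_its else 1
      gacc <- list()
      bl_sum <- c(0, 0, 0, 0)
      for (ii in idx) {
        img <- items[[ii]]$image
        lbl <- items[[ii]]$labels
        if (cfg$hflip && runif(1) < 0.5) {
          img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
          if (nrow(lbl) > 0) lbl$cx <- 1 - lbl$cx
        }
        if (cfg$intensity_jitter > 0)
          img <- pmin(pmax(img + runif(1, -1, 1) * cfg$intensity_jitter, 0), 1)
        fw <- micro_forward(model, img, keep = TRUE)
        lg <- micro_loss_grads(fw$heads, labels_to_pixels(lbl, cfg$imgsz),
                               cfg$imgsz, spec$reg_max, spec$strides,
                               cfg$loss, cfg$hook, cfg$weights)
        if (!is.finite(lg$breakdown$total))
          stop("training diverged: non-finite loss at epoch ", ep)
        bl_sum <- bl_sum + unlist(lg$breakdown)
        g <- micro_backward(model, fw, lg$dheads)
        for (nm in names(g)) {
          if (is.null(gacc[[nm]])) gacc[[nm]] <- g[[nm]]
          else gacc[[nm]] <- list(w = gacc[[nm]]$w + g[[nm]]$w,
                                  b = gacc[[nm]]$b + g[[nm]]$b)
        }
      }
      m <- length(idx)
      for (nm in names(gacc)) {
        gw <- gacc[[nm]]$w / m + cfg$weight_decay * model$W[[nm]]$w
        gb <- gacc[[nm]]$b / m
        if (is.null(vel[[nm]])) vel[[nm]] <- list(w = gw * 0, b = gb * 0)
        vel[[nm]]$w <- cfg$momentum * vel[[nm]]$w + gw
        vel[[nm]]$b <- cfg$momentum * vel[[nm]]$b + gb
        model$W[[nm]]$w <- model$W[[nm]]$w - lr * vel[[nm]]$w
        model$W[[nm]]$b <- model$W[[nm]]$b - lr * vel[[nm]]$b
      }
      ep_losses <- ep_losses + bl_sum / m
      nb <- nb + 1L
    }
    history <- rbind(history, data.frame(epoch = ep,
                                         t(ep_losses / nb)))
  }
  structure(list(model = model, history = history, cfg = cfg),
            class = "bdet_fit")
}

#' Run detection on one image
#'
#' Forward pass, DFL decoding of the box distributions, confidence
#' filtering and per-class greedy NMS.
#'
#' @param model A `bdet_model` (or `bdet_fit`).
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param conf_threshold Minimum class confidence (default 0.25).
#' @param nms_iou NMS IoU threshold (default 0.7).
#' @param max_det Detection cap per image.
#' @return Data frame `class_id, cx, cy, w, h, confidence` with normalized
#'   coordinates.
#' @export
predict_image <- function(model, image, conf_threshold = 0.25,
                          nms_iou = 0.7, max_det = 100L) {
  if (inherits(model, "bdet_fit")) model <- model$model
  spec <- model$spec
  imgsz <- dim(image)[1]
  heads <- if (identical(spec$variant, "micro"))
    micro_forward(model, image)$heads else forward_model(model, image)
  reg_max <- spec$reg_max
  bins <- 0:(reg_max - 1)
  det <- NULL
  for (li in 1:3) {
    cl <- heads[[li]]$cls
    bx <- heads[[li]]$box
    d <- dim(cl)
    P <- sigmoid_(matrix(cl, ncol = d[3]))
    conf <- apply(P, 1, max)
    cls <- max.col(P) - 1L
    keep <- which(conf >= conf_threshold)
    if (length(keep) == 0) next
    s <- imgsz %/% d[1]
    bm <- matrix(bx, ncol = 4 * reg_max)
    dists <- matrix(0, length(keep), 4)
    for (sd_ in 1:4) {
      blk <- side_block(sd_, reg_max)
      zz <- bm[keep, blk, drop = FALSE]
      ee <- exp(zz - apply(zz, 1, max))
      pp <- ee / rowSums(ee)
      dists[, sd_] <- pp %*% bins
    }
    # cell (row=y, col=x) at column-major index y + (x-1)*h
    yj <- (keep - 1L) %% d[1] + 1L
    xj <- (keep - 1L) %/% d[1] + 1L
    ax <- (xj - 0.5) * s; ay <- (yj - 0.5) * s
    x1 <- pmax(ax - dists[, 1] * s, 0); y1 <- pmax(ay - dists[, 2] * s, 0)
    x2 <- pmin(ax + dists[, 3] * s, imgsz); y2 <- pmin(ay + dists[, 4] * s, imgsz)
    ok <- which(x2 > x1 & y2 > y1)
    if (length(ok) == 0) next
    det <- rbind(det, data.frame(
      class_id = cls[keep][ok],
      cx = ((x1 + x2) / 2)[ok] / imgsz, cy = ((y1 + y2) / 2)[ok] / imgsz,
      w = (x2 - x1)[ok] / imgsz, h = (y2 - y1)[ok] / imgsz,
      confidence = conf[keep][ok]))
  }
  if (is.null(det))
    return(data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0), confidence = numeric(0)))
  det <- nms(det, nms_iou)
  head(det[order(-det$confidence), , drop = FALSE], max_det)
}

#' Evaluate a detector on a manifest split
#'
#' @param model A `bdet_model` or `bdet_fit`.
#' @param data A `dataset_manifest`.
#' @param split `"val"` (default) or `"train"`.
#' @param conf_threshold Low detection threshold used for PR sweeping.
#' @param nms_iou NMS IoU threshold.
#' @return An `eval_result` from [evaluate_map()].
#' @export
evaluate_model <- function(model, data, split = "val", conf_threshold = 0.05,
                           nms_iou = 0.7) {
  if (inherits(model, "bdet_fit")) model <- model$model
  imgsz <- model$spec$input_size
  items <- load_split(data, split, imgsz)
  det <- NULL; gt <- NULL
  for (it in items) {
    d <- predict_image(model, it$image, conf_threshold, nms_iou)
    if (nrow(d) > 0) det <- rbind(det, cbind(image_id = it$id, d))
    if (nrow(it$labels) > 0) gt <- rbind(gt, cbind(image_id = it$id, it$labels))
  }
  if (is.null(det))
    det <- data.frame(image_id = integer(0), class_id = integer(0),
                      cx = numeric(0), cy = numeric(0), w = numeric(0),
                      h = numeric(0), confidence = numeric(0))
  if (is.null(gt))
    gt <- data.frame(image_id = integer(0), class_id = integer(0),
                     cx = numeric(0), cy = numeric(0), w = numeric(0),
                     h = numeric(0))
  evaluate_map(det, gt, num_classes = length(data$names))
}
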