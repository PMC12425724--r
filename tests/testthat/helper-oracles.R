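# Independent oracles used across the suite. Each one is a separate
# implementation of the quantity it checks, written directly from the
# defining formula or as a brute-force enumeration, and never calls the
# package code path it validates.

# Exact cell-count rasterization IoU on a grid of pitch `p`, for boxes
# whose corners lie on that grid (the count is then exact). Cells are
# identified by their centers; the per-axis counts enumerate the grid.
raster_iou <- function(pc, tc, p = 1e-3) {
  count_axis <- function(a1, a2) {
    # number of cell centers (k + 0.5) * p inside [a1, a2]
    max(0L, floor(a2 / p - 0.5) - ceiling(a1 / p - 0.5) + 1L)
  }
  ix1 <- max(pc[1], tc[1]); ix2 <- min(pc[3], tc[3])
  iy1 <- max(pc[2], tc[2]); iy2 <- min(pc[4], tc[4])
  ninter <- if (ix2 > ix1 && iy2 > iy1)
    count_axis(ix1, ix2) * count_axis(iy1, iy2) else 0
  na <- count_axis(pc[1], pc[3]) * count_axis(pc[2], pc[4])
  nb <- count_axis(tc[1], tc[3]) * count_axis(tc[2], tc[4])
  ninter / (na + nb - ninter)
}

# Fully explicit rasterization (every cell center tested individually);
# used on a few pairs to validate the fast counting form above.
raster_iou_dense <- function(pc, tc, p = 1e-3) {
  lim <- c(min(pc[1], tc[1]), min(pc[2], tc[2]),
           max(pc[3], tc[3]), max(pc[4], tc[4]))
  cx <- seq(floor(lim[1] / p), ceiling(lim[3] / p)) * p + p / 2
  cy <- seq(floor(lim[2] / p), ceiling(lim[4] / p)) * p + p / 2
  inx_p <- cx > pc[1] & cx < pc[3]; iny_p <- cy > pc[2] & cy < pc[4]
  inx_t <- cx > tc[1] & cx < tc[3]; iny_t <- cy > tc[2] & cy < tc[4]
  np <- sum(outer(iny_p, inx_p, "&"))
  nt <- sum(outer(iny_t, inx_t, "&"))
  ni <- sum(outer(iny_p & iny_t, inx_p & inx_t, "&"))
  ni / (np + nt - ni)
}

# random boxes with corners snapped to the 1e-3 grid (so the raster count
# is exact), extents bounded away from zero
random_box_corners <- function() {
  x1 <- round(runif(1, 0, 0.6), 3); y1 <- round(runif(1, 0, 0.6), 3)
  w <- round(runif(1, 0.1, 0.4), 3); h <- round(runif(1, 0.1, 0.4), 3)
  c(x1, y1, x1 + w, y1 + h)
}

# Independent scalar transcription of the complete-IoU formula (analytic
# intersection areas, no shared code with ciou()).
ciou_scalar <- function(p, t) {
  pc <- c(p[1] - p[3] / 2, p[2] - p[4] / 2, p[1] + p[3] / 2, p[2] + p[4] / 2)
  tc <- c(t[1] - t[3] / 2, t[2] - t[4] / 2, t[1] + t[3] / 2, t[2] + t[4] / 2)
  iw <- max(0, min(pc[3], tc[3]) - max(pc[1], tc[1]))
  ih <- max(0, min(pc[4], tc[4]) - max(pc[2], tc[2]))
  inter <- iw * ih
  i <- inter / (p[3] * p[4] + t[3] * t[4] - inter)
  rho2 <- (p[1] - t[1])^2 + (p[2] - t[2])^2
  cw <- max(pc[3], tc[3]) - min(pc[1], tc[1])
  ch <- max(pc[4], tc[4]) - min(pc[2], tc[2])
  v <- 4 / pi^2 * (atan(t[3] / t[4]) - atan(p[3] / p[4]))^2
  a <- if (i == 1 && v == 0) 0 else v / (1 - i + v)
  i - rho2 / (cw^2 + ch^2) - a * v
}

# central finite differences of f at x
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}

# Reference mAP implementation, independent of evaluate_map(): per class
# and threshold it enumerates matches the same greedy way but computes the
# 101-point AP by an explicit per-recall-point scan.
reference_map <- function(det, gt, num_classes, thrs = seq(0.5, 0.95, 0.05)) {
  corner <- function(d) cbind(d$cx - d$w / 2, d$cy - d$h / 2,
                              d$cx + d$w / 2, d$cy + d$h / 2)
  one_iou <- function(a, b) {
    iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- iw * ih
    inter / ((a[3] - a[1]) * (a[4] - a[2]) +
               (b[3] - b[1]) * (b[4] - b[2]) - inter)
  }
  ap_mat <- matrix(NA_real_, num_classes, length(thrs))
  for (cls in 0:(num_classes - 1)) {
    g <- gt[gt$class_id == cls, , drop = FALSE]
    d <- det[det$class_id == cls, , drop = FALSE]
    d <- d[order(-d$confidence), , drop = FALSE]
    if (nrow(g) == 0) next
    gc <- corner(g); dc <- corner(d)
    for (ti in seq_along(thrs)) {
      used <- rep(FALSE, nrow(g))
      tp <- rep(FALSE, nrow(d))
      for (i in seq_len(nrow(d))) {
        best <- -1; bj <- 0
        for (j in seq_len(nrow(g))) {
          if (used[j] || g$image_id[j] != d$image_id[i]) next
          ij <- one_iou(dc[i, ], gc[j, ])
          if (ij > best) { best <- ij; bj <- j }
        }
        if (bj > 0 && best >= thrs[ti]) { used[bj] <- TRUE; tp[i] <- TRUE }
      }
      rec <- cumsum(tp) / nrow(g)
      prec <- cumsum(tp) / seq_along(tp)
      ap <- 0
      for (rp in seq(0, 1, 0.01)) {
        ok <- which(rec >= rp)
        ap <- ap + (if (length(ok)) max(prec[ok[1]:length(prec)]) else 0)
      }
      ap_mat[cls + 1, ti] <- ap / 101
    }
  }
  list(ap = ap_mat,
       map50 = mean(ap_mat[, 1], na.rm = TRUE),
       map50_95 = mean(rowMeans(ap_mat), na.rm = TRUE))
}

# Brute-force greedy NMS oracle (O(n^2), explicit pairwise loops).
nms_oracle <- function(det, thr) {
  det <- det[order(-det$confidence), , drop = FALSE]
  corner <- cbind(det$cx - det$w / 2, det$cy - det$h / 2,
                  det$cx + det$w / 2, det$cy + det$h / 2)
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (det$class_id[j] != det$class_id[i]) next
      iw <- max(0, min(corner[i, 3], corner[j, 3]) -
                  max(corner[i, 1], corner[j, 1]))
      ih <- max(0, min(corner[i, 4], corner[j, 4]) -
                  max(corner[i, 2], corner[j, 2]))
      inter <- iw * ih
      un <- (corner[i, 3] - corner[i, 1]) * (corner[i, 4] - corner[i, 2]) +
        (corner[j, 3] - corner[j, 1]) * (corner[j, 4] - corner[j, 2]) - inter
      if (inter / un > thr) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  det[keep, , drop = FALSE]
}

# shared micro dataset (generated once per test session)
micro_manifest <- local({
  man <- NULL
  function(scale = 100 / 4737, seed = 17) {
    if (is.null(man)) {
      dir <- file.path(tempdir(), sprintf("braindet_ds_%d", seed))
      man <<- generate_dataset(dir, scale = scale, image_size = 64L,
                               seed = seed)
    }
    man
  }
})
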