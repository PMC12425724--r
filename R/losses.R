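# IoU / CIoU family, the hook reweighting and the distribution focal loss.
# Boxes are axis-aligned rectangles; the center/extent form (cx, cy, w, h)
# is the user-facing representation (it is also the YOLO label convention),
# corners (x1, y1, x2, y2) are used internally for the geometry.

#' Construct an axis-aligned bounding box
#'
#' @param cx,cy Center coordinates (pixels or normalized units).
#' @param w,h Strictly positive width and height.
#' @return An object of class `bdet_box`.
#' @examples
#' b <- box(0.5, 0.5, 0.2, 0.3)
#' box_corners(b)
#' @export
box <- function(cx, cy, w, h) {
  if (!all(is.finite(c(cx, cy, w, h)))) stop("box: non-finite coordinates")
  if (w <= 0 || h <= 0) stop("box: invalid box, extents must be positive")
  structure(list(cx = cx, cy = cy, w = w, h = h), class = "bdet_box")
}

#' @rdname box
#' @param x1,y1,x2,y2 Corner coordinates with `x1 < x2`, `y1 < y2`.
#' @export
box_from_corners <- function(x1, y1, x2, y2) {
  box((x1 + x2) / 2, (y1 + y2) / 2, x2 - x1, y2 - y1)
}

#' @rdname box
#' @param b A `bdet_box` or a numeric vector `c(cx, cy, w, h)`.
#' @return `box_corners` returns `c(x1, y1, x2, y2)`.
#' @export
box_corners <- function(b) {
  b <- as_box(b)
  c(b$cx - b$w / 2, b$cy - b$h / 2, b$cx + b$w / 2, b$cy + b$h / 2)
}

#' @rdname box
#' @export
as_box <- function(b) {
  if (inherits(b, "bdet_box")) return(b)
  if (is.numeric(b) && length(b) == 4) return(box(b[1], b[2], b[3], b[4]))
  stop("cannot interpret object as a box")
}

#' Intersection over union of two boxes
#'
#' @param p,t Predicted and target boxes (see [box()]).
#' @return IoU in `[0, 1]`; symmetric in its arguments and 0 for disjoint
#'   boxes.
#' @export
iou <- function(p, t) {
  pc <- box_corners(p); tc <- box_corners(t)
  iw <- max(0, min(pc[3], tc[3]) - max(pc[1], tc[1]))
  ih <- max(0, min(pc[4], tc[4]) - max(pc[2], tc[2]))
  inter <- iw * ih
  union <- (pc[3] - pc[1]) * (pc[4] - pc[2]) +
    (tc[3] - tc[1]) * (tc[4] - tc[2]) - inter
  inter / union
}

#' Complete IoU with its penalty breakdown
#'
#' CIoU augments IoU with a normalized center-distance penalty and an
#' aspect-ratio consistency penalty:
#' \deqn{CIoU = IoU - \rho^2/c^2 - \alpha v}
#' where \eqn{\rho} is the center distance, \eqn{c} the diagonal of the
#' smallest enclosing box, \eqn{v = (4/\pi^2)(\arctan(w^t/h^t) -
#' \arctan(w^p/h^p))^2} measures aspect-ratio mismatch and
#' \eqn{\alpha = v / (1 - IoU + v)} trades the two off (defined as 0 when
#' the boxes coincide).
#'
#' @inheritParams iou
#' @return A list of class `ciou_breakdown` with fields `iou`,
#'   `center_term`, `aspect_v`, `alpha_tradeoff`, `ciou`.
#' @export
ciou <- function(p, t) {
  p <- as_box(p); t <- as_box(t)
  i <- iou(p, t)
  pc <- box_corners(p); tc <- box_corners(t)
  rho2 <- (p$cx - t$cx)^2 + (p$cy - t$cy)^2
  cw <- max(pc[3], tc[3]) - min(pc[1], tc[1])
  ch <- max(pc[4], tc[4]) - min(pc[2], tc[2])
  c2 <- cw^2 + ch^2
  center_term <- rho2 / c2
  v <- (4 / pi^2) * (atan(t$w / t$h) - atan(p$w / p$h))^2
  alpha <- if (i == 1 && v == 0) 0 else v / (1 - i + v)
  structure(list(iou = i, center_term = center_term, aspect_v = v,
                 alpha_tradeoff = alpha,
                 ciou = i - center_term - alpha * v),
            class = "ciou_breakdown")
}

#' Hook reweighting function
#'
#' `f(x) = a x + b / x`, strictly convex on `x > 0` with its unique minimum
#' at `sqrt(b / a)`; with the default `a = b = 0.5` the minimum sits at
#' `x = 1` where `f(1) = 1`.
#'
#' @param x Positive evaluation point(s).
#' @param hp Hook hyperparameters, see [hook_params()].
#' @export
hook <- function(x, hp = hook_params()) {
  if (any(x <= 0)) stop("hook: domain error, x must be positive")
  hp$a * x + hp$b / x
}

#' @rdname hook
#' @param a,b Positive coefficients of the linear and reciprocal terms
#'   (`a * b > 0` is required); both default to 0.5.
#' @param mode `"loss"` applies the hook to the CIoU *loss* `L = 1 - CIoU`
#'   (the default); `"metric"` applies it to the CIoU value itself.
#' @export
hook_params <- function(a = 0.5, b = 0.5, mode = c("loss", "metric")) {
  mode <- match.arg(mode)
  if (!(a > 0 && b > 0)) stop("hook_params: need a > 0 and b > 0 (a*b > 0)")
  structure(list(a = a, b = b, mode = mode), class = "hook_params")
}

#' Hook-reweighted CIoU loss (HKCIoU)
#'
#' The box regression loss `L = 1 - CIoU` is multiplied by the hook
#' `a L + b / L`, which algebraically simplifies to `a L^2 + b`. The
#' simplified form is what is evaluated (it is finite at `L = 0`, where the
#' value is `b`), and its gradient in `L` is `2 a L`: steeper than the plain
#' CIoU loss for poor boxes (`L > 1`) and flatter for good ones (`L < 1`).
#' In `"metric"` mode the same form is applied to the CIoU value instead.
#'
#' @inheritParams iou
#' @param hp Hook hyperparameters, see [hook_params()].
#' @export
hkciou_loss <- function(p, t, hp = hook_params()) {
  ci <- ciou(p, t)$ciou
  x <- if (hp$mode == "loss") 1 - ci else ci
  hp$a * x^2 + hp$b
}

#' Distribution focal loss for one box side
#'
#' The continuous regression target `t` in bin units is supervised through
#' the two adjacent integer bins: `-( (l+1-t) log p_l + (t-l) log p_{l+1} )`
#' with `l = floor(t)`. Zero when the distribution is a point mass on an
#' integer target.
#'
#' @param pred_distribution Probability vector over `reg_max` bins
#'   (non-negative, summing to 1).
#' @param target_offset Real target in `[0, reg_max - 1]`.
#' @export
dfl_loss <- function(pred_distribution, target_offset) {
  n <- length(pred_distribution)
  if (abs(sum(pred_distribution) - 1) > 1e-6 || any(pred_distribution < 0))
    stop("dfl_loss: pred_distribution must be a probability vector")
  if (target_offset < 0 || target_offset > n - 1)
    stop("dfl_loss: target outside [0, reg_max - 1]")
  l <- floor(target_offset)
  wr <- target_offset - l
  wl <- 1 - wr
  eps <- 1e-12
  ll <- wl * log(pred_distribution[l + 1] + eps)
  lr <- if (wr > 0) wr * log(pred_distribution[l + 2] + eps) else 0
  -(ll + lr)
}

#' Loss weights for the three-term detection loss
#'
#' @param w_box,w_obj,w_cls Non-negative weights for the box-regression,
#'   confidence and classification terms; they must not all be zero. In the
#'   anchor-free head the confidence term has no separate output and the
#'   objectness weight acts on the distribution-focal component of the box
#'   branch (see the methods vignette), so `w_dfl` is accepted as an alias.
#' @export
loss_weights <- function(w_box = 7.5, w_obj = 1.5, w_cls = 0.5,
                         w_dfl = NULL) {
  if (!is.null(w_dfl)) w_obj <- w_dfl
  if (any(c(w_box, w_obj, w_cls) < 0) || all(c(w_box, w_obj, w_cls) == 0))
    stop("loss_weights: weights must be non-negative and not all zero")
  structure(list(w_box = w_box, w_obj = w_obj, w_cls = w_cls),
            class = "loss_weights")
}

#' Weighted three-term detection loss
#'
#' `total = w_box * l_box + w_obj * l_obj + w_cls * l_cls`, keeping the
#' components alongside the weighted sum.
#'
#' @param lb,lo,lc Finite, non-negative box / confidence / classification
#'   terms.
#' @param w A [loss_weights()] object.
#' @return A list of class `loss_breakdown` with fields `l_box`, `l_obj`,
#'   `l_cls`, `total`.
#' @export
total_loss <- function(lb, lo, lc, w = loss_weights()) {
  terms <- c(lb, lo, lc)
  if (any(!is.finite(terms)) || any(terms < 0))
    stop("total_loss: components must be finite and non-negative")
  structure(list(l_box = lb, l_obj = lo, l_cls = lc,
                 total = w$w_box * lb + w$w_obj * lo + w$w_cls * lc),
            class = "loss_breakdown")
}

# ---- analytic gradients (w.r.t. the predicted box corners) ----

# Gradient of ciou(p, t)$ciou w.r.t. the predicted corners
# (x1, y1, x2, y2), treating all terms -- including the alpha tradeoff --
# as functions of the prediction. Returns list(value, grad).
ciou_grad <- function(p, t) {
  p <- as_box(p); t <- as_box(t)
  pc <- box_corners(p); tc <- box_corners(t)
  wp <- p$w; hp_ <- p$h
  ap <- wp * hp_
  at <- t$w * t$h

  iw <- min(pc[3], tc[3]) - max(pc[1], tc[1])
  ih <- min(pc[4], tc[4]) - max(pc[2], tc[2])
  ipos <- iw > 0 && ih > 0
  inter <- if (ipos) iw * ih else 0
  un <- ap + at - inter
  i <- inter / un

  # d inter / d corners (subgradient 0 at the non-differentiable ties)
  diw <- c(if (ipos && pc[1] > tc[1]) -1 else 0, 0,
           if (ipos && pc[3] < tc[3]) 1 else 0, 0)
  dih <- c(0, if (ipos && pc[2] > tc[2]) -1 else 0,
           0, if (ipos && pc[4] < tc[4]) 1 else 0)
  dinter <- if (ipos) ih * diw + iw * dih else c(0, 0, 0, 0)
  dap <- c(-hp_, -wp, hp_, wp)
  dun <- dap - dinter
  di <- (dinter * un - inter * dun) / un^2

  dcx <- p$cx - t$cx
  dcy <- p$cy - t$cy
  rho2 <- dcx^2 + dcy^2
  drho2 <- c(dcx, dcy, dcx, dcy)
  cw <- max(pc[3], tc[3]) - min(pc[1], tc[1])
  ch <- max(pc[4], tc[4]) - min(pc[2], tc[2])
  c2 <- cw^2 + ch^2
  dcw <- c(if (pc[1] < tc[1]) -1 else 0, 0, if (pc[3] > tc[3]) 1 else 0, 0)
  dch <- c(0, if (pc[2] < tc[2]) -1 else 0, 0, if (pc[4] > tc[4]) 1 else 0)
  dc2 <- 2 * cw * dcw + 2 * ch * dch
  dcenter <- (drho2 * c2 - rho2 * dc2) / c2^2

  delta <- atan(t$w / t$h) - atan(wp / hp_)
  v <- (4 / pi^2) * delta^2
  dv_dwp <- (4 / pi^2) * 2 * delta * (-hp_ / (wp^2 + hp_^2))
  dv_dhp <- (4 / pi^2) * 2 * delta * (wp / (wp^2 + hp_^2))
  dv <- c(-dv_dwp, -dv_dhp, dv_dwp, dv_dhp)

  if (i == 1 && v == 0) {
    alpha <- 0
    dalpha <- c(0, 0, 0, 0)
  } else {
    den <- 1 - i + v
    alpha <- v / den
    dalpha <- (dv * (1 - i) + v * di) / den^2
  }

  value <- i - rho2 / c2 - alpha * v
  grad <- di - dcenter - (dalpha * v + alpha * dv)
  list(value = value, grad = grad, iou = i, iou_grad = di)
}

# Value and corner gradient of the configured box regression loss
# ("ciou": L = 1 - CIoU; "hkciou": a L^2 + b).
bbox_loss_grad <- function(p, t, type = c("ciou", "hkciou"),
                           hp = hook_params()) {
  type <- match.arg(type)
  cg <- ciou_grad(p, t)
  L <- 1 - cg$value
  if (type == "ciou") {
    list(value = L, grad = -cg$grad)
  } else {
    list(value = hp$a * L^2 + hp$b, grad = -2 * hp$a * L * cg$grad)
  }
}
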