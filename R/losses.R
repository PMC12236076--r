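# IoU-family bounding-box regression losses: IoU, GIoU, WIoU v1/v3 with the
# non-monotonic focusing coefficient, the Focaler interval remapping, and the
# composite Focaler-WIoUv3 objective used in the decoder's box head.
#
# All functions operate on corner-form boxes (x1, y1, x2, y2), either a
# length-4 vector or an n x 4 matrix, and are written against the package's
# generic array math, so the same formulas run on plain numerics (public API)
# and on autodiff tensors (training path). A tiny denominator guard makes
# every degenerate case (zero-area, zero-union, zero-enclosure) finite with
# the conventional value instead of NaN.

.box_eps <- 1e-12

as_box_matrix <- function(x) {
  if (is_tensor(x)) return(x)
  if (is.null(dim(x))) {
    stopifnot(length(x) == 4L)
    return(matrix(x, 1L, 4L))
  }
  stopifnot(ncol(x) == 4L)
  x
}

t_cbind <- function(...) {
  xs <- list(...)
  if (any(vapply(xs, is_tensor, logical(1)))) tg_concat_cols(xs) else do.call(cbind, xs)
}

#' Convert center-form boxes to corner form
#' @param b vector `(cx, cy, w, h)` or an n x 4 matrix.
#' @return corner-form box(es) `(x1, y1, x2, y2)`.
#' @export
box_cxcywh_to_xyxy <- function(b) {
  b <- as_box_matrix(b)
  cx <- t_col(b, 1); cy <- t_col(b, 2); w <- t_col(b, 3); h <- t_col(b, 4)
  t_cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

#' Convert corner-form boxes to center form
#' @export
box_xyxy_to_cxcywh <- function(b) {
  b <- as_box_matrix(b)
  x1 <- b[, 1]; y1 <- b[, 2]; x2 <- b[, 3]; y2 <- b[, 4]
  cbind((x1 + x2) / 2, (y1 + y2) / 2, x2 - x1, y2 - y1)
}

# shared geometry for the loss family
box_geometry <- function(pred, gt) {
  pred <- as_box_matrix(pred); gt <- as_box_matrix(gt)
  px1 <- t_col(pred, 1); py1 <- t_col(pred, 2)
  px2 <- t_col(pred, 3); py2 <- t_col(pred, 4)
  gx1 <- t_col(gt, 1); gy1 <- t_col(gt, 2)
  gx2 <- t_col(gt, 3); gy2 <- t_col(gt, 4)
  iw <- t_pmax(t_pmin2(px2, gx2) - t_pmax2(px1, gx1), 0)
  ih <- t_pmax(t_pmin2(py2, gy2) - t_pmax2(py1, gy1), 0)
  inter <- iw * ih
  area_p <- t_pmax(px2 - px1, 0) * t_pmax(py2 - py1, 0)
  area_g <- t_pmax(gx2 - gx1, 0) * t_pmax(gy2 - gy1, 0)
  union <- area_p + area_g - inter
  ew <- t_pmax2(px2, gx2) - t_pmin2(px1, gx1)   # smallest enclosing box
  eh <- t_pmax2(py2, gy2) - t_pmin2(py1, gy1)
  list(inter = inter, union = union, ew = ew, eh = eh,
       pcx = (px1 + px2) / 2, pcy = (py1 + py2) / 2,
       gcx = (gx1 + gx2) / 2, gcy = (gy1 + gy2) / 2)
}

#' Intersection over union of box pairs
#'
#' @param pred,gt corner-form boxes, length-4 vectors or n x 4 matrices
#'   (paired row-wise).
#' @return IoU in `[0, 1]`; 0 when the union is empty.
#' @examples
#' box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 1/7
#' @export
box_iou <- function(pred, gt) {
  g <- box_geometry(pred, gt)
  g$inter / (g$union + .box_eps)
}

#' GIoU loss, 1 - (IoU - (enclosure - union) / enclosure)
#' @export
giou_loss <- function(pred, gt) {
  g <- box_geometry(pred, gt)
  iou <- g$inter / (g$union + .box_eps)
  enc <- g$ew * g$eh
  giou <- iou - (enc - g$union) / (enc + .box_eps)
  1 - giou
}

#' Running-mean state for the WIoUv3 focusing coefficient
#'
#' Holds the exponential moving average of the IoU loss that normalizes the
#' outlier degree `beta`.
#' @param momentum update rate of the moving average, in (0, 1].
#' @export
wiou_state <- function(momentum = 0.01) {
  stopifnot(momentum > 0, momentum <= 1)
  s <- new.env(parent = emptyenv())
  s$mean <- NA_real_
  s$momentum <- momentum
  class(s) <- "wiou_state"
  s
}

#' WIoU hyper-parameters
#'
#' `alpha` and `delta` shape the non-monotonic focusing coefficient,
#' `beta / (delta * alpha^(beta - delta))`; defaults follow the WIoUv3
#' reference setting.
#' @export
wiou_params <- function(alpha = 1.9, delta = 3, momentum = 0.01) {
  stopifnot(alpha > 1, delta > 0, momentum > 0, momentum <= 1)
  list(alpha = alpha, delta = delta, momentum = momentum)
}

#' Focaler interval parameters (lower and upper IoU thresholds)
#' @export
focaler_params <- function(d = 0, u = 0.95) {
  if (!(d >= 0 && d < u && u <= 1))
    stop("focaler_params: need 0 <= d < u <= 1")
  list(d = d, u = u)
}

#' WIoU v1 loss: distance-weighted IoU loss
#'
#' `R_WIoU * L_IoU` with `R_WIoU = exp(center_dist^2 / (Wg^2 + Hg^2))`,
#' the enclosing-box dimensions treated as gradient-detached.
#' @export
wiou_v1_loss <- function(pred, gt) {
  g <- box_geometry(pred, gt)
  l_iou <- 1 - g$inter / (g$union + .box_eps)
  d2 <- (g$pcx - g$gcx)^2 + (g$pcy - g$gcy)^2
  denom <- t_detach(g$ew)^2 + t_detach(g$eh)^2
  r_wiou <- t_exp(d2 / (denom + .box_eps))
  r_wiou * l_iou
}

#' WIoU v3 loss with the non-monotonic focusing coefficient
#'
#' The WIoUv1 loss scaled by the focusing coefficient
#' `beta / (delta * alpha^(beta - delta))`, where the outlier degree
#' `beta` is the (detached) IoU loss over its running mean. The state is
#' updated by exponential moving average when `update = TRUE`.
#' @export
wiou_v3_loss <- function(pred, gt, state, params = wiou_params(),
                         update = TRUE) {
  stopifnot(inherits(state, "wiou_state"))
  g <- box_geometry(pred, gt)
  l_iou <- 1 - g$inter / (g$union + .box_eps)
  l_iou_det <- t_detach(l_iou)
  mu <- state$mean
  beta <- if (is.na(mu) || mu <= 0) rep(1, length(l_iou_det)) else l_iou_det / mu
  r <- beta / (params$delta * params$alpha^(beta - params$delta))
  if (update) {
    m <- state$momentum
    batch <- mean(l_iou_det)
    state$mean <- if (is.na(mu)) batch else (1 - m) * mu + m * batch
  }
  r * wiou_v1_loss(pred, gt)
}

#' Focaler remapping of IoU onto a difficulty interval
#'
#' Piecewise linear: 0 below `d`, `(IoU - d) / (u - d)` on `[d, u]`,
#' 1 above `u`.
#' @param iou numeric IoU value(s) in `[0, 1]`.
#' @param params see [focaler_params()].
#' @export
focaler_iou <- function(iou, params = focaler_params()) {
  t_pmin(t_pmax((iou - params$d) / (params$u - params$d), 0), 1)
}

#' Composite Focaler-WIoUv3 loss
#'
#' `L = L_WIoUv3 + IoU - IoU_Focaler`: the WIoUv3 loss with an additive
#' correction that re-centers the objective on the Focaler difficulty
#' interval. With `d = 0, u = 1` the correction vanishes and the loss
#' equals WIoUv3.
#' @export
focaler_wiou_v3_loss <- function(pred, gt, state, wparams = wiou_params(),
                                 fparams = focaler_params(), update = TRUE) {
  iou <- box_iou(pred, gt)
  wiou_v3_loss(pred, gt, state, wparams, update = update) +
    iou - focaler_iou(iou, fparams)
}

#' Box-regression objective for a matched detection batch
#'
#' The standard detection-transformer box objective with the GIoU term
#' replaced by Focaler-WIoUv3: `w_l1 * sum(|pred - gt|) / n +
#' w_iou * sum(L_FocalerWIoUv3) / n`. Returns 0 on an empty match set.
#'
#' @param pred_boxes,gt_boxes matched corner-form boxes (n x 4).
#' @param weight_l1,weight_iou relative term weights (detection-transformer
#'   defaults 5 and 2).
#' @export
detection_box_objective <- function(pred_boxes, gt_boxes, state,
                                    wparams = wiou_params(),
                                    fparams = focaler_params(),
                                    weight_l1 = 5, weight_iou = 2,
                                    update = TRUE) {
  n <- if (is_tensor(pred_boxes)) nrow(pred_boxes$v) else nrow(as_box_matrix(pred_boxes))
  if (is.null(n) || n == 0L) return(0)
  l1 <- t_sum(t_abs(pred_boxes - gt_boxes)) / n
  li <- t_sum(focaler_wiou_v3_loss(pred_boxes, gt_boxes, state,
                                   wparams, fparams, update = update)) / n
  weight_l1 * l1 + weight_iou * li
}
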