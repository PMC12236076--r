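# Training harness: the full detection objective (classification + L1 +
# IoU-family box loss over Hungarian-matched query/target pairs, with
# auxiliary supervision on every decoder layer and the query-selection
# stage) and a small Adam loop used to overfit seeded synthetic scenes as
# an end-to-end smoke check.

# numerically stable binary cross-entropy with logits
tg_bce_logits <- function(z, target, weight = NULL) {
  vz <- tg_val(z)
  val <- pmax(vz, 0) - vz * target + log1p(exp(-abs(vz)))
  if (!is.null(weight)) val <- val * weight
  tg_node(val, list(list(p = z, fn = function(g) {
    d <- (1 / (1 + exp(-vz)) - target)
    if (!is.null(weight)) d <- d * weight
    g * d
  })))
}

# Hungarian matching on detached predictions; returns query index per gt
match_queries <- function(logits, boxes, gt_cls, gt_xyxy, weights) {
  probs <- 1 / (1 + exp(-tg_val(logits)))
  pb <- tg_val(boxes)
  ng <- length(gt_cls)
  nq <- nrow(pb)
  pxy <- box_cxcywh_to_xyxy(pb)
  cost <- matrix(0, ng, nq)
  gt_cxcywh <- box_xyxy_to_cxcywh(gt_xyxy)
  for (gi in seq_len(ng)) {
    l1 <- rowSums(abs(pb - matrix(gt_cxcywh[gi, ], nq, 4, byrow = TRUE)))
    gl <- giou_loss(pxy, matrix(gt_xyxy[gi, ], nq, 4, byrow = TRUE))
    cost[gi, ] <- -weights$cls * probs[, gt_cls[gi] + 1L] +
      weights$l1 * l1 + weights$iou * gl
  }
  hungarian_assign(cost)
}

# objective for one prediction stage
stage_loss <- function(stage, gt_cls, gt_xyxy, model, wstate, weights,
                       update_state = TRUE) {
  logits <- stage$logits
  boxes <- stage$boxes
  nq <- nrow(tg_val(logits))
  nc <- ncol(tg_val(logits))
  ng <- length(gt_cls)
  assign_q <- match_queries(logits, boxes, gt_cls, gt_xyxy, weights)
  target <- matrix(0, nq, nc)
  wmat <- matrix(weights$neg, nq, nc)
  for (gi in seq_len(ng)) {
    target[assign_q[gi], gt_cls[gi] + 1L] <- 1
    wmat[assign_q[gi], ] <- 1
  }
  denom <- max(1, ng)
  l_cls <- t_sum(tg_bce_logits(logits, target, wmat)) / denom
  if (ng == 0L) return(weights$cls * l_cls)
  pred_sel <- box_cxcywh_to_xyxy(t_rows(boxes, assign_q))
  if (model$loss_type == "focaler_wiou") {
    lf <- model$config$loss
    box_term <- detection_box_objective(
      pred_sel, gt_xyxy, wstate,
      wparams = wiou_params(lf$wiou$alpha, lf$wiou$delta, lf$wiou$momentum),
      fparams = focaler_params(lf$focaler$d, lf$focaler$u),
      weight_l1 = weights$l1, weight_iou = weights$iou,
      update = update_state)
  } else {
    l1 <- t_sum(t_abs(pred_sel - gt_xyxy)) / ng
    li <- t_sum(giou_loss(pred_sel, gt_xyxy)) / ng
    box_term <- weights$l1 * l1 + weights$iou * li
  }
  weights$cls * l_cls + box_term
}

#' Full detection objective for one image
#'
#' Classification (weighted binary cross-entropy), L1 and the configured
#' IoU-family loss (Focaler-WIoUv3 or GIoU) over Hungarian-matched pairs,
#' summed over the final layer, auxiliary decoder layers and the
#' query-selection stage.
#'
#' @param model a `phrf_model`; `image` an `(H, W, 3)` array.
#' @param records annotation data frame for the image.
#' @param wstate a [wiou_state()] carried across iterations.
#' @return scalar loss tensor.
#' @export
detection_loss <- function(model, image, records, wstate, train = TRUE) {
  pred <- ph_fwd(model, image, train = train)
  gt_cls <- records$class_id
  gt_xyxy <- box_cxcywh_to_xyxy(as.matrix(records[, c("cx", "cy", "w", "h")]))
  weights <- model$config$loss$weights
  total <- NULL
  stages <- c(pred$stages, list(pred$enc))
  for (si in seq_along(stages)) {
    l <- stage_loss(stages[[si]], gt_cls, gt_xyxy, model, wstate, weights,
                    update_state = (si == length(pred$stages)))
    total <- if (is.null(total)) l else total + l
  }
  total
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p$v * 0),
       v = lapply(params, function(p) p$v * 0), t = 0)
}

adam_step <- function(params, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$g)) next
    g <- p$g
    st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
    st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * g * g
    p$v <- p$v - lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + eps)
  }
  st
}

#' Overfit a model on a small synthetic set (end-to-end smoke training)
#'
#' Runs the full objective with Adam over the given scenes, then evaluates
#' the trained model on those same training images (an overfit check, not a
#' generalization measure). Aborts with a diagnostic on a non-finite loss.
#'
#' Training runs at batch size one, so the final evaluation normalizes
#' each map with its own statistics (`batch_stats` in
#' [predict_detections()]): running-average estimates collected one image
#' at a time track the most recent images rather than the set and are not
#' a faithful inference statistic in this regime.
#'
#' @param model a `phrf_model`.
#' @param scenes list of scenes from [make_synthetic_dataset()].
#' @param epochs passes over the set; `lr` Adam step size.
#' @param score_threshold confidence cut for the final evaluation.
#' @param seed RNG seed for the epoch shuffling.
#' @param verbose print per-epoch mean loss.
#' @return list: `history` (mean loss per epoch), `metrics`
#'   (see [evaluate_detections()]), `detections`.
#' @export
smoke_train <- function(model, scenes, epochs = 40L, lr = 1e-3,
                        score_threshold = 0.3, seed = 1L, verbose = FALSE) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  params <- ph_parameters(model)
  opt <- adam_init(params)
  wstate <- wiou_state(model$config$loss$wiou$momentum)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    tot <- 0
    for (i in sample(seq_along(scenes))) {
      sc <- scenes[[i]]
      tg_zero_grad(params)
      loss <- detection_loss(model, sc$image, sc$records, wstate, train = TRUE)
      lv <- tg_val(loss)
      if (!is.finite(lv))
        stop("smoke_train: non-finite loss at epoch ", ep, ", scene ", i,
             " (running IoU-loss mean ", format(wstate$mean), ")")
      tg_backward(loss)
      opt <- adam_step(params, opt, lr)
      tot <- tot + lv
    }
    history[ep] <- tot / length(scenes)
    if (verbose) cat(sprintf("epoch %3d  loss %.4f\n", ep, history[ep]))
  }
  dets <- predict_detections(model, lapply(scenes, `[[`, "image"),
                             score_threshold = score_threshold,
                             batch_stats = TRUE)
  gts <- do.call(rbind, lapply(seq_along(scenes), function(i) {
    r <- scenes[[i]]$records
    xy <- box_cxcywh_to_xyxy(as.matrix(r[, c("cx", "cy", "w", "h")]))
    data.frame(image = i, class = r$class_id, x1 = xy[, 1], y1 = xy[, 2],
               x2 = xy[, 3], y2 = xy[, 4])
  }))
  metrics <- evaluate_detections(dets, gts)
  list(history = history, metrics = metrics, detections = dets, truths = gts)
}

# walk a module tree collecting batch-norm state environments
bn_states <- function(m) {
  out <- list()
  walk <- function(mod) {
    if (!is.null(mod$state)) out[[length(out) + 1L]] <<- mod$state
    for (s in mod$mods) walk(s)
  }
  walk(m)
  out
}

#' Recalibrate batch-norm running statistics over a set of images
#'
#' Replaces the exponential-moving-average running statistics with the
#' cumulative average of the per-image batch statistics over the given
#' images — the standard fix when training ran at batch size one, where
#' EMA estimates track the most recent images rather than the set.
#'
#' @param model a `phrf_model` (or any module tree).
#' @param images list of `(H, W, 3)` arrays.
#' @export
bn_recalibrate <- function(model, images) {
  sts <- bn_states(model)
  for (s in sts) {
    s$mean[] <- 0
    s$var[] <- 0
    s$n <- 0L
    s$collect <- TRUE
  }
  for (img in images) invisible(ph_fwd(model, img, train = TRUE))
  for (s in sts) s$collect <- FALSE
  invisible(model)
}
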