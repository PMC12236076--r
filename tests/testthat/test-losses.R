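# IoU-family losses against hand-evaluated oracles and their invariants.

pred <- c(0, 0, 2, 2)
gt <- c(1, 1, 3, 3)

test_that("IoU, GIoU and WIoUv1 reproduce hand-evaluated values", {
  expect_equal(box_iou(pred, pred), 1, tolerance = 1e-9)
  expect_equal(box_iou(c(0, 0, 1, 1), c(2, 2, 3, 3)), 0, tolerance = 1e-9)
  expect_equal(box_iou(pred, gt), 1 / 7, tolerance = 1e-6)
  expect_equal(giou_loss(pred, pred), 0, tolerance = 1e-9)
  expect_equal(giou_loss(pred, gt), 1 - (1 / 7 - 2 / 9), tolerance = 1e-6)
  # far-separated unit boxes: GIoU -> -1, loss -> 2
  far <- giou_loss(c(0, 0, 1, 1), c(1e5, 1e5, 1e5 + 1, 1e5 + 1))
  expect_gt(far, 1.99)
  expect_lt(far, 2)
  expect_equal(wiou_v1_loss(pred, pred), 0, tolerance = 1e-9)
  # centers (1,1) vs (2,2), enclosure 3x3: R = exp(2/18), L_IoU = 6/7
  expect_equal(wiou_v1_loss(pred, gt), exp(1 / 9) * 6 / 7, tolerance = 1e-6)
})

test_that("R_WIoU is always >= 1", {
  set.seed(42)
  for (i in 1:200) {
    a <- sort(runif(2)); b <- sort(runif(2))
    p <- c(a[1], b[1], a[2], b[2])
    g <- p + runif(4, -0.3, 0.3)
    g <- c(pmin(g[1], g[3]), pmin(g[2], g[4]), pmax(g[1], g[3]), pmax(g[2], g[4]))
    li <- 1 - box_iou(p, g)
    w1 <- wiou_v1_loss(p, g)
    expect_gte(w1 + 1e-12, li)  # ratio R >= 1
  }
})

test_that("the non-monotonic focusing coefficient matches its closed form", {
  # beta = 1, alpha = 1.9, delta = 3 -> r = 1.9^2 / 3
  st <- wiou_state()
  l <- wiou_v3_loss(pred, gt, st, wiou_params(alpha = 1.9, delta = 3),
                    update = FALSE)
  expect_equal(l, (1.9^2 / 3) * wiou_v1_loss(pred, gt), tolerance = 1e-6)
  # beta = delta -> r = 1: set the running mean so that beta equals delta
  st2 <- wiou_state()
  st2$mean <- (6 / 7) / 3
  l2 <- wiou_v3_loss(pred, gt, st2, update = FALSE)
  expect_equal(l2, wiou_v1_loss(pred, gt), tolerance = 1e-9)
})

test_that("running-mean state updates by exponential moving average", {
  st <- wiou_state(momentum = 0.5)
  wiou_v3_loss(pred, gt, st)           # first update seeds the mean
  expect_equal(st$mean, 6 / 7, tolerance = 1e-9)
  wiou_v3_loss(pred, pred, st)         # batch loss 0
  expect_equal(st$mean, 0.5 * 6 / 7, tolerance = 1e-9)
})

test_that("Focaler remapping is the stated piecewise-linear function", {
  fp <- focaler_params(d = 0, u = 0.95)
  expect_equal(focaler_iou(0, fp), 0)
  expect_equal(focaler_iou(0.97, fp), 1)
  expect_equal(focaler_iou(0.5, fp), 0.5 / 0.95, tolerance = 1e-6)
  fp2 <- focaler_params(d = 0.2, u = 0.8)
  expect_equal(focaler_iou(0.2, fp2), 0)
  expect_equal(focaler_iou(0.8, fp2), 1)
  ious <- seq(0, 1, by = 0.001)
  vals <- focaler_iou(ious, fp2)
  expect_true(all(diff(vals) >= -1e-12))           # non-decreasing
  expect_lt(max(abs(diff(vals))), 0.0025)          # continuous (no jumps)
  expect_error(focaler_params(d = 0.9, u = 0.5))
})

test_that("the composite loss composes its terms exactly", {
  st <- wiou_state()
  st$mean <- 3 * (6 / 7)  # beta = 1/3... choose so r can be computed
  # force r = 1 by beta = delta: mean = L_IoU / delta
  st$mean <- (6 / 7) / 3
  l <- focaler_wiou_v3_loss(pred, gt, st, fparams = focaler_params(0, 0.95),
                            update = FALSE)
  expect_equal(l, exp(1 / 9) * 6 / 7 + 1 / 7 - (1 / 7) / 0.95,
               tolerance = 1e-6)
  # identity interval: with d = 0, u = 1 the Focaler correction vanishes
  st2 <- wiou_state(); st3 <- wiou_state()
  set.seed(7)
  for (i in 1:50) {
    p <- c(0, 0, 1 + runif(1), 1 + runif(1))
    g <- c(runif(1), runif(1), 2, 2)
    expect_equal(
      focaler_wiou_v3_loss(p, g, st2, fparams = focaler_params(0, 1),
                           update = FALSE),
      wiou_v3_loss(p, g, st3, update = FALSE), tolerance = 1e-12)
  }
  # identical boxes -> exactly 0
  st4 <- wiou_state()
  expect_equal(focaler_wiou_v3_loss(pred, pred, st4), 0, tolerance = 1e-9)
})

test_that("GIoU degenerates to IoU at complete overlap and enclosure", {
  # coincident boxes
  expect_equal(1 - giou_loss(pred, pred), box_iou(pred, pred))
  # prediction exactly enclosing the truth: enclosing box = prediction
  p <- c(0, 0, 4, 4); g <- c(1, 1, 3, 3)
  expect_equal(1 - giou_loss(p, g), box_iou(p, g), tolerance = 1e-9)
})

test_that("losses are finite over a randomized sweep with degenerate boxes", {
  set.seed(99)
  st <- wiou_state()
  n <- 300
  mk <- function() {
    r <- runif(4, -2, 2)
    if (runif(1) < 0.15) r[3] <- r[1]  # zero-width
    if (runif(1) < 0.15) r[4] <- r[2]  # zero-height
    c(min(r[1], r[3]), min(r[2], r[4]), max(r[1], r[3]), max(r[2], r[4]))
  }
  for (i in seq_len(n)) {
    p <- mk(); g <- mk()
    vals <- c(box_iou(p, g), giou_loss(p, g), wiou_v1_loss(p, g),
              wiou_v3_loss(p, g, st), focaler_wiou_v3_loss(p, g, st))
    expect_true(all(is.finite(vals)))
    expect_gte(box_iou(p, g), 0)
    expect_lte(box_iou(p, g), 1)
  }
})

test_that("loss monotonicity under nested translation", {
  # sliding a unit box away from a coincident unit box: IoU loss and GIoU
  # loss both never decrease
  shifts <- seq(0, 2, by = 0.05)
  li <- vapply(shifts, function(s)
    1 - box_iou(c(s, 0, s + 1, 1), c(0, 0, 1, 1)), numeric(1))
  lg <- vapply(shifts, function(s)
    giou_loss(c(s, 0, s + 1, 1), c(0, 0, 1, 1)), numeric(1))
  expect_true(all(diff(li) >= -1e-12))
  expect_true(all(diff(lg) >= -1e-12))
})

test_that("box objective reduces correctly and has finite gradients", {
  st <- wiou_state()
  expect_identical(detection_box_objective(matrix(numeric(0), 0, 4),
                                           matrix(numeric(0), 0, 4), st), 0)
  # single pair: objective = w_l1 * L1 + w_iou * focaler-wiou loss
  stA <- wiou_state(); stB <- wiou_state()
  obj <- detection_box_objective(matrix(pred, 1), matrix(gt, 1), stA,
                                 weight_l1 = 5, weight_iou = 2,
                                 update = FALSE)
  expect_equal(obj, 5 * sum(abs(pred - gt)) +
                 2 * focaler_wiou_v3_loss(pred, gt, stB, update = FALSE),
               tolerance = 1e-9)
  # perfect matches -> 0
  stC <- wiou_state()
  expect_equal(detection_box_objective(matrix(pred, 1), matrix(pred, 1), stC),
               0, tolerance = 1e-9)
  # finite-difference check for overlapping, touching, disjoint pairs.
  # The analytic gradient detaches the enclosing-box normalizer of R_WIoU
  # (by design, for training stability); a plain central difference
  # perturbs it, so agreement is approximate, and exact where the
  # detached factor is locally constant.
  for (g2 in list(c(1, 1, 3, 3), c(2, 0, 3, 1), c(5, 5, 6, 6))) {
    stD <- wiou_state()
    pt <- phrfdetr:::tg_tensor(matrix(pred, 1), rg = TRUE)
    loss <- detection_box_objective(pt, matrix(g2, 1), stD, update = FALSE)
    phrfdetr:::tg_backward(loss)
    expect_true(all(is.finite(pt$g)))
    eps <- 1e-6
    for (j in c(1, 3)) {
      stE <- wiou_state(); stF <- wiou_state()
      pp <- matrix(pred, 1); pp[j] <- pp[j] + eps
      pm <- matrix(pred, 1); pm[j] <- pm[j] - eps
      fd <- (detection_box_objective(pp, matrix(g2, 1), stE, update = FALSE) -
               detection_box_objective(pm, matrix(g2, 1), stF, update = FALSE)) /
        (2 * eps)
      expect_true(is.finite(fd))
      expect_lt(abs(unname(pt$g[j]) - unname(fd)),
                0.1 * max(1, abs(fd)))
    }
  }
})
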