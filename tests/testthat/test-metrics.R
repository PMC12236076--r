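# Detection metrics: precision/recall/F1 closed forms, AP against a
# brute-force ranked-list oracle, confusion matrices.

mk_dets <- function(image, class, score, boxes) {
  data.frame(image = image, class = class, score = score,
             x1 = boxes[, 1], y1 = boxes[, 2], x2 = boxes[, 3], y2 = boxes[, 4])
}
mk_gts <- function(image, class, boxes) {
  data.frame(image = image, class = class,
             x1 = boxes[, 1], y1 = boxes[, 2], x2 = boxes[, 3], y2 = boxes[, 4])
}
unit_boxes <- function(n, spacing = 2) {
  if (n == 0) return(matrix(numeric(0), 0, 4))
  cbind((seq_len(n) - 1) * spacing, 0, (seq_len(n) - 1) * spacing + 1, 1)
}

test_that("precision, recall and F1 match their closed forms", {
  # 10 gts; 10 detections of which 9 hit -> P = 0.9, R = 0.9
  gb <- unit_boxes(10)
  db <- gb
  db[10, ] <- db[10, ] + 50  # one detection far off
  ev <- evaluate_detections(mk_dets(1, 0, seq(0.95, 0.5, length.out = 10), db),
                            mk_gts(1, 0, gb))
  expect_equal(ev$precision, 0.9)
  expect_equal(ev$recall, 0.9)
  expect_equal(ev$tp, 9)
  expect_equal(ev$fp, 1)
  expect_equal(ev$fn, 1)
  expect_equal(ev$f1, 2 * 0.9 * 0.9 / 1.8)
  # harmonic-mean identity on random rates
  set.seed(3)
  p <- runif(50); r <- runif(50)
  expect_equal(f1_score(p, r), 2 * p * r / (p + r), tolerance = 1e-15)
})

test_that("AP matches the brute-force ranked-list oracle", {
  # toy ranking: scores .9/.8/.7, hits at ranks 1 and 3, 2 gts
  tp <- c(TRUE, FALSE, TRUE)
  expect_equal(average_precision(tp, 2), ap_oracle(tp, 2), tolerance = 1e-12)
  # randomized ranked lists
  set.seed(11)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    ngt <- sample(1:6, 1)
    tp <- runif(n) < 0.5
    if (sum(tp) > ngt) tp[which(tp)[seq_len(sum(tp) - ngt)]] <- FALSE
    expect_equal(average_precision(tp, ngt), ap_oracle(tp, ngt),
                 tolerance = 1e-12)
  }
  # perfect ranking -> AP 1; all misses -> AP 0
  expect_equal(average_precision(c(TRUE, TRUE), 2), 1)
  expect_equal(average_precision(c(FALSE, FALSE), 2), 0)
})

test_that("end-to-end evaluation on a constructed scene set", {
  # two classes on two images, one localization miss and one class error
  g1 <- unit_boxes(2); g2 <- unit_boxes(2)
  gts <- rbind(mk_gts(1, c(0, 1), g1), mk_gts(2, c(0, 1), g2))
  d1 <- mk_dets(1, c(0, 1), c(0.9, 0.8), g1)            # both correct
  d2a <- mk_dets(2, 0, 0.85, g2[1, , drop = FALSE] + 10) # localization miss
  d2b <- mk_dets(2, 0, 0.7, g2[2, , drop = FALSE])       # wrong class
  ev <- evaluate_detections(rbind(d1, d2a, d2b), gts)
  expect_equal(ev$tp, 2)
  expect_equal(ev$precision, 0.5)
  expect_equal(ev$recall, 0.5)
  # class 0: 1 TP of 2 gts + 2 FPs; class 1: 1 TP of 2 gts
  expect_equal(nrow(ev$per_class), 2)
  expect_true(all(ev$per_class$ap50 >= 0 & ev$per_class$ap50 <= 1))
  expect_gte(ev$map50, 0)
  expect_lte(ev$map50, 1)
})

test_that("mAP is invariant to permuting equal-scored detections", {
  gb <- unit_boxes(4)
  dets <- mk_dets(1, 0, rep(0.5, 4), gb)
  ev1 <- evaluate_detections(dets, mk_gts(1, 0, gb))
  ev2 <- evaluate_detections(dets[c(3, 1, 4, 2), ], mk_gts(1, 0, gb))
  expect_equal(ev1$map50, ev2$map50)
  expect_equal(ev1$map50, 1)
})

test_that("empty ground truth with nonempty detections gives P = 0", {
  ev <- evaluate_detections(mk_dets(1, 0, 0.9, unit_boxes(1)),
                            mk_gts(integer(0), integer(0), unit_boxes(0)))
  expect_equal(ev$precision, 0)
})

test_that("confusion matrix: identity, background column, class swap", {
  gb <- unit_boxes(5)
  gts <- mk_gts(1, 0:4, gb)
  # perfect detections -> identity on the class block
  cm <- confusion_matrix_det(mk_dets(1, 0:4, rep(0.9, 5), gb), gts,
                             n_classes = 5)
  expect_equal(unname(cm[1:5, 1:5]), diag(5))
  expect_equal(sum(cm[, 6]), 0)
  expect_equal(sum(cm[6, ]), 0)
  # no detections -> all gts in the background column
  cm2 <- confusion_matrix_det(mk_dets(integer(0), integer(0), numeric(0),
                                      unit_boxes(0)), gts, n_classes = 5)
  expect_equal(unname(cm2[1:5, 6]), rep(1, 5))
  expect_equal(sum(cm2[, 1:5]), 0)
  # one class swap -> exactly one off-diagonal entry
  cls <- c(0, 1, 2, 3, 2)  # last box called class 2 instead of 4
  cm3 <- confusion_matrix_det(mk_dets(1, cls, rep(0.9, 5), gb), gts,
                              n_classes = 5)
  offdiag <- cm3[1:5, 1:5]; diag(offdiag) <- 0
  expect_equal(sum(offdiag), 1)
  expect_equal(cm3["4", "2"], 1)
  # row normalization keeps rows summing to 1 (or 0)
  cm4 <- confusion_matrix_det(mk_dets(1, cls, rep(0.9, 5), gb), gts,
                              n_classes = 5, normalize = TRUE)
  expect_true(all(rowSums(cm4) %in% c(0, 1)))
})
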