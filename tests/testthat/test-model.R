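# Variant factory, complexity accounting, NMS-free prediction, matching.

test_that("the variant toggle table matches the ablation design", {
  vt <- variant_table()
  expect_equal(vt$variant,
               c("basic", "m1_pgrnet", "m2_hilo", "m3_retc3", "m4_loss",
                 "m5", "m6", "final"))
  expect_equal(rowSums(vt[, -1]), c(0, 1, 1, 1, 1, 2, 3, 4))
  expect_true(all(unlist(vt[vt$variant == "final", -1])))
  expect_error(build_variant("m7"), "unknown variant")
})

test_that("profiling matches Eq-style closed forms on a single convolution", {
  # 3x3 conv, 64 -> 64, output 80x80: params 36,864; MACs 80*80*36,864
  m <- ph_conv(64, 64, 3, norm = FALSE, act = "identity", bias = FALSE)
  pr <- ph_profile(m, c(80, 80, 64))
  expect_equal(pr$params, 36864)
  expect_equal(pr$macs, 80 * 80 * 36864)
  # serialized size: 2^20 params at 2 bytes -> exactly 2 MB
  expect_equal(1048576 * 2 / 1024^2, 2)
})

test_that("tiny builds run forward and profile consistently", {
  cfg <- tiny_config()
  for (v in c("basic", "final")) {
    mdl <- build_variant(v, cfg, seed = 1)
    pr <- profile_model(mdl, c(64L, 64L))  # errors if closed != actual
    expect_gt(pr$params, 0)
    expect_equal(pr$flops, 2 * pr$macs)
    expect_equal(pr$size_mb, pr$params * 2 / 1024^2)
    x <- rand_map(64, 64, 3, seed = 7)
    pred <- ph_fwd(mdl, x)
    expect_equal(dim(phrfdetr:::tg_val(pred$final$logits)), c(20, 5))
    expect_equal(dim(phrfdetr:::tg_val(pred$final$boxes)), c(20, 4))
    b <- phrfdetr:::tg_val(pred$final$boxes)
    expect_true(all(b > 0 & b < 1))
  }
})

test_that("prediction is NMS-free, thresholded, sorted and deterministic", {
  cfg <- tiny_config()
  mdl <- build_variant("final", cfg, seed = 2)
  img <- generate_scene(scene_spec(size = 64, scenario = "multi", seed = 3))$image
  none <- predict_detections(mdl, img, score_threshold = 1.0)
  expect_equal(nrow(none), 0)
  all_d <- predict_detections(mdl, img, score_threshold = 0)
  expect_lte(nrow(all_d), cfg$decoder$queries)
  expect_true(all(diff(all_d$score) <= 0))
  expect_true(all(all_d$x2 >= all_d$x1 & all_d$y2 >= all_d$y1))
  expect_true(all(all_d$class %in% 0:4))
  # identical inputs give identical outputs
  two <- predict_detections(mdl, list(img, img), score_threshold = 0)
  d1 <- two[two$image == 1, -1]; d2 <- two[two$image == 2, -1]
  rownames(d1) <- rownames(d2) <- NULL
  expect_equal(d1, d2)
})

test_that("Hungarian assignment is optimal on exhaustive small cases", {
  set.seed(12)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  for (trial in 1:20) {
    n <- sample(2:4, 1); m <- n + sample(0:3, 1)
    cost <- matrix(runif(n * m), n, m)
    a <- hungarian_assign(cost)
    expect_equal(anyDuplicated(a), 0)
    best <- Inf
    for (cols in combn(m, n, simplify = FALSE))
      for (p in perms(cols))
        best <- min(best, sum(cost[cbind(1:n, p)]))
    expect_equal(sum(cost[cbind(1:n, a)]), best, tolerance = 1e-12)
  }
})

test_that("one training step decreases the objective on a fixed scene", {
  cfg <- tiny_config()
  mdl <- build_variant("final", cfg, seed = 5)
  sc <- generate_scene(scene_spec(size = 64, scenario = "single", seed = 4))
  st <- wiou_state()
  params <- ph_parameters(mdl)
  l0 <- phrfdetr:::tg_val(detection_loss(mdl, sc$image, sc$records, st))
  opt <- phrfdetr:::adam_init(params)
  for (k in 1:8) {
    phrfdetr:::tg_zero_grad(params)
    loss <- detection_loss(mdl, sc$image, sc$records, st, train = TRUE)
    phrfdetr:::tg_backward(loss)
    opt <- phrfdetr:::adam_step(params, opt, 2e-3)
  }
  l1 <- phrfdetr:::tg_val(detection_loss(mdl, sc$image, sc$records, st))
  expect_lt(l1, l0)
  expect_true(is.finite(l1))
})

test_that("GIoU and Focaler-WIoUv3 objectives both descend on the same set", {
  sc <- generate_scene(scene_spec(size = 64, scenario = "single", seed = 9))
  losses <- sapply(c("m6", "final"), function(v) {  # m6 = GIoU, final = Focaler
    mdl <- build_variant(v, tiny_config(), seed = 3)
    st <- wiou_state()
    params <- ph_parameters(mdl)
    opt <- phrfdetr:::adam_init(params)
    l0 <- phrfdetr:::tg_val(detection_loss(mdl, sc$image, sc$records, st))
    for (k in 1:6) {
      phrfdetr:::tg_zero_grad(params)
      loss <- detection_loss(mdl, sc$image, sc$records, st, train = TRUE)
      phrfdetr:::tg_backward(loss)
      opt <- phrfdetr:::adam_step(params, opt, 2e-3)
    }
    l1 <- phrfdetr:::tg_val(detection_loss(mdl, sc$image, sc$records, st))
    c(l0, l1)
  })
  expect_lt(losses[2, 1], losses[1, 1])
  expect_lt(losses[2, 2], losses[1, 2])
})

test_that("YAML round-trips the configuration", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(dim = 64L, hilo = list(alpha = 0.25),
                        decoder = list(queries = 50L)), f)
  cfg <- phrf_config_yaml(f)
  expect_equal(cfg$dim, 64L)
  expect_equal(cfg$hilo$alpha, 0.25)
  expect_equal(cfg$hilo$window, 2L)       # untouched defaults survive
  expect_equal(cfg$decoder$queries, 50L)
  expect_equal(cfg$decoder$layers, 3L)
})
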