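# PGRBlock / PGRNet structural and numerical properties.

test_that("pgr_block preserves shape for any channel count divisible by 4", {
  for (C in c(16, 32, 64, 128)) {
    set.seed(C)
    m <- pgr_block(C)
    x <- rand_map(6, 5, C, seed = C)
    y <- phrfdetr:::tg_val(ph_fwd(m, x))
    expect_equal(dim(y), dim(x))
    expect_true(all(is.finite(y)))
  }
  expect_error(pgr_block(30), "divisible by 4")
})

test_that("zero weights with normalization disabled give the exact identity", {
  set.seed(1)
  m <- pgr_block(16, use_norm = FALSE)
  ph_zero_weights(m)
  x <- rand_map(5, 7, 16)
  y <- phrfdetr:::tg_val(ph_fwd(m, x))
  expect_equal(max(abs(y - x)), 0)
})

test_that("untouched channel slices pass through bit-identically", {
  set.seed(2)
  C <- 32
  m <- pgr_block(C, use_norm = FALSE)
  x <- rand_map(4, 4, C)
  y3 <- phrfdetr:::tg_val(ph_fwd(m$mods$c3, x))
  y5 <- phrfdetr:::tg_val(ph_fwd(m$mods$c5, y3[, , 1:(C / 2), drop = FALSE]))
  out <- phrfdetr:::tg_val(ph_fwd(m, x))
  resid <- out - x  # undo the residual add (float-exactness up to the add)
  # 3x3-stage pass-through: output channels C/2+1..C carry y3's second half
  expect_equal(resid[, , (C / 2 + 1):C], y3[, , (C / 2 + 1):C],
               tolerance = 1e-12)
  # 5x5-stage pass-through: channels C/4+1..C/2 carry y5's second quarter
  expect_equal(resid[, , (C / 4 + 1):(C / 2)],
               y5[, , (C / 4 + 1):(C / 2)], tolerance = 1e-12)
})

test_that("trainable conv weights match the closed-form kernel sum", {
  # norm off, bias off: 3x3 over C + 5x5 over C/2 + 7x7 over C/4
  m <- pgr_block(64, use_norm = FALSE)
  expect_equal(ph_nparams(m), 3 * 3 * 64 * 64 + 5 * 5 * 32 * 32 + 7 * 7 * 16 * 16)
  expect_equal(ph_nparams(m), 75008)
  expect_equal(ph_nparams_closed(m), ph_nparams(m))
  # arbitrary specs: closed form equals the framework count
  for (C in c(16, 48, 96)) {
    mm <- pgr_block(C)
    expect_equal(ph_nparams_closed(mm), ph_nparams(mm))
  }
})

test_that("gradients reach the block input through conv and residual paths", {
  set.seed(5)
  m <- pgr_block(16)
  x <- phrfdetr:::tg_tensor(rand_map(4, 4, 16), rg = TRUE)
  y <- phrfdetr:::t_sum(ph_fwd(m, x, train = TRUE))
  phrfdetr:::tg_backward(y)
  expect_true(all(is.finite(x$g)))
  expect_gt(min(abs(x$g)), 0)  # no dead input coordinate
  # conv path alive: some conv weight receives gradient
  wg <- m$mods$c5$par$w$g
  expect_false(is.null(wg))
  expect_gt(max(abs(wg)), 0)
})

test_that("grouped convolution has 1/g the parameters at equal shapes", {
  x <- rand_fm(1, 64, 8, 8)
  std <- group_conv(x, 64, k = 3, groups = 1)
  grp <- group_conv(x, 64, k = 3, groups = 4)
  expect_equal(ph_nparams(std$module), 3 * 3 * 64 * 64)  # 36,864
  expect_equal(ph_nparams(grp$module), 3 * 3 * (64 / 4) * 64)  # 9,216
  expect_equal(ph_nparams(std$module) / ph_nparams(grp$module), 4)
  expect_equal(dim(std$value), dim(grp$value))
  expect_error(group_conv(x, 64, groups = 5), "divisible")
})

test_that("PGRNet has five 3x3 convolutions, four PGRBlocks, strides 8/16/32", {
  set.seed(1)
  bb <- build_pgrnet(pgrnet_spec(c(16, 32, 64), 8))
  audit <- backbone_audit(bb)
  expect_equal(audit$conv3x3, 5)
  expect_equal(audit$pgr_blocks, 4)
  x <- rand_map(64, 64, 3)
  py <- ph_fwd(bb, x)
  expect_equal(dim(phrfdetr:::tg_val(py$p3)), c(8, 8, 16))
  expect_equal(dim(phrfdetr:::tg_val(py$p4)), c(4, 4, 32))
  expect_equal(dim(phrfdetr:::tg_val(py$p5)), c(2, 2, 64))
  # profile agrees with the numeric forward shapes
  pr <- ph_profile(bb, c(64, 64, 3))
  expect_equal(pr$out$p3, c(8, 8, 16))
  expect_equal(pr$out$p5, c(2, 2, 64))
  expect_equal(pr$params, ph_nparams(bb))
  expect_error(pgrnet_spec(c(30, 64, 128)), "divisible by 4")
})
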