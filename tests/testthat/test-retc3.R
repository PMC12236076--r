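# Spatial-decay masks, MaSA decomposition, RetBlock and RetC3.

val <- phrfdetr:::tg_val

test_that("spatial decay mask matches its closed form", {
  expect_equal(spatial_decay_mask(3, 0.5),
               matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3, 3))
  expect_equal(spatial_decay_mask(4, 1), matrix(1, 4, 4))
  expect_equal(spatial_decay_mask(1, 0.3), matrix(1, 1, 1))
  expect_error(spatial_decay_mask(3, 0), "gamma")
  expect_error(spatial_decay_mask(3, -0.2), "gamma")
})

test_that("decay masks are symmetric with unit diagonal, entries in (0,1]", {
  set.seed(2)
  for (i in 1:20) {
    L <- sample(1:12, 1)
    g <- runif(1, 0.05, 1)
    M <- spatial_decay_mask(L, g)
    expect_equal(M, t(M))
    expect_equal(unname(diag(M)), rep(1, L))
    expect_true(all(M > 0 & M <= 1))
  }
})

test_that("a single token reduces MaSA to the value/output projections", {
  set.seed(3)
  m <- masa_attention(8, heads = 2)
  x <- rand_map(1, 1, 8, seed = 3)
  y <- val(ph_fwd(m, x))
  tok <- matrix(x, 1, 8)
  ref <- val(ph_fwd(m$mods$o, ph_fwd(m$mods$v, phrfdetr:::tg_tensor(tok))))
  expect_equal(matrix(y, 1, 8), ref, tolerance = 1e-12)
})

test_that("gamma = 1 equals decomposed attention without a decay mask", {
  set.seed(4)
  m1 <- masa_attention(8, heads = 2, gammas = c(1, 1))
  x <- rand_map(4, 5, 8, seed = 4)
  y1 <- val(ph_fwd(m1, x))
  # reference: same projections, per-line softmax attention with no mask
  ref_axis <- function(Q, K, V, H, W, axis) {
    out <- matrix(0, H * W, ncol(Q))
    lines <- if (axis == "v")
      lapply(seq_len(W), function(l) (l - 1) * H + seq_len(H))
    else lapply(seq_len(H), function(l) seq(l, by = H, length.out = W))
    for (rows in lines) for (h in 1:2) {
      cs <- ((h - 1) * 4 + 1):(h * 4)
      S <- Q[rows, cs] %*% t(K[rows, cs]) / sqrt(4)
      A <- exp(S - apply(S, 1, max))
      A <- A / rowSums(A)
      out[rows, cs] <- A %*% V[rows, cs]
    }
    out
  }
  tok <- matrix(aperm(x, c(3, 1, 2)), 4 * 5, 8, byrow = TRUE)
  tok <- val(phrfdetr:::tokens_from_map(phrfdetr:::tg_tensor(x)))
  Q <- val(ph_fwd(m1$mods$q, tok)); K <- val(ph_fwd(m1$mods$k, tok))
  V <- val(ph_fwd(m1$mods$v, tok))
  y_v <- ref_axis(Q, K, V, 4, 5, "v")
  y_h <- ref_axis(Q, K, y_v, 4, 5, "h")
  ref <- val(ph_fwd(m1$mods$o, phrfdetr:::tg_tensor(y_h)))
  expect_equal(matrix(y1, 20, 8), unname(ref), tolerance = 1e-12)
})

test_that("as gamma shrinks every token attends only to itself", {
  set.seed(5)
  x <- rand_map(4, 4, 8, seed = 5)
  m_self <- masa_attention(8, heads = 2, gammas = c(1, 1))
  # self-only reference: value/output projections per token
  tok <- val(phrfdetr:::tokens_from_map(phrfdetr:::tg_tensor(x)))
  ref <- val(ph_fwd(m_self$mods$o, ph_fwd(m_self$mods$v,
                                          phrfdetr:::tg_tensor(tok))))
  # off-diagonal contamination scales linearly with gamma once gamma is
  # small against the softmax score ratios, so probe the small-gamma regime
  dev <- c()
  for (g in c(1e-2, 1e-3, 1e-4, 1e-5)) {
    mg <- masa_attention(8, heads = 2, gammas = c(g, g))
    for (nm in c("q", "k", "v", "o"))
      mg$mods[[nm]]$par <- m_self$mods[[nm]]$par  # share projections
    yg <- val(ph_fwd(mg, x))
    dev <- c(dev, max(abs(matrix(yg, 16, 8) - ref)))
  }
  expect_true(all(diff(dev) < 0))     # monotone convergence
  expect_lt(dev[length(dev)], 1e-2)   # near the self-only limit
})

test_that("decomposed attention cost is sub-quadratic, full attention is not", {
  d <- 32
  sizes <- c(8, 16, 32)
  masa <- vapply(sizes, function(s) phrfdetr:::masa_macs(d, s, s), numeric(1))
  full <- vapply(sizes, function(s) phrfdetr:::full_attention_macs(d, s, s),
                 numeric(1))
  # token count quadruples at each step: full-attention cost grows ~16x,
  # decomposed stays well below the quadratic envelope
  r_masa <- masa[-1] / masa[-3]
  r_full <- full[-1] / full[-3]
  expect_true(all(r_masa < 9))
  expect_true(all(r_full > r_masa))
  expect_gt(r_full[2], 12)
  expect_lt(masa[3], full[3] / 4)
})

test_that("RetBlock preserves shape; zeroed branches give the identity", {
  set.seed(6)
  m <- ret_block(16, heads = 2)
  x <- rand_map(4, 6, 16, seed = 6)
  expect_equal(dim(val(ph_fwd(m, x))), dim(x))
  # zero the MaSA output projection and FFN: block = identity + positional
  ph_zero_weights(m$mods$attn$mods$o)
  ph_zero_weights(m$mods$ffn)
  y <- val(ph_fwd(m, x))
  pos <- val(ph_fwd(m$mods$cpe, x))
  expect_equal(y, x + pos, tolerance = 1e-12)
  # with the positional depthwise conv also zeroed: exact identity
  ph_zero_weights(m$mods$cpe)
  m$mods$cpe$par$b$v[] <- 0
  expect_equal(val(ph_fwd(m, x)), x, tolerance = 0)
})

test_that("RetBlock parameter count matches the closed-form sum", {
  for (d in c(16, 32)) {
    m <- ret_block(d, heads = 2, ffn_ratio = 2)
    closed <- 9 * d + d +             # depthwise positional conv + bias
      4 * (d * d + d) +               # q/k/v/out projections
      2 * (2 * d) +                   # two layer norms
      (d * 2 * d + 2 * d) + (2 * d * d + d)  # FFN in/out
    expect_equal(ph_nparams(m), closed)
    expect_equal(ph_nparams_closed(m), closed)
  }
})

test_that("RetC3 wiring: shape preservation, depth 0, odd channels", {
  set.seed(7)
  m <- retc3_block(32, 32, hidden = 16, depth = 2, heads = 2)
  x <- rand_map(6, 6, 32, seed = 7)
  expect_equal(dim(val(ph_fwd(m, x))), c(6, 6, 32))
  # depth 0: a pure 1x1 bottleneck pair
  m0 <- retc3_block(32, 32, hidden = 16, depth = 0)
  expect_equal(dim(val(ph_fwd(m0, x))), c(6, 6, 32))
  expect_null(m0$mods$m)
  expect_error(retc3_block(33, 32, hidden = 16), "even")
  # profile consistency
  pr <- ph_profile(m, c(6, 6, 32))
  expect_equal(pr$params, ph_nparams(m))
  expect_equal(pr$out, c(6, 6, 32))
})
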