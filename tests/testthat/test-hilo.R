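# HiLo attention: window locality, pooling identities, parameter neutrality.

val <- phrfdetr:::tg_val

test_that("Hi-Fi windows are local: no interaction across windows", {
  set.seed(3)
  m <- hifi_attention(dim = 16, heads = 2, head_dim = 4, window = 2)
  x <- rand_map(4, 4, 16, seed = 3)
  y <- val(ph_fwd(m, x))
  # perturb a token in the top-left window; the bottom-right window output
  # must be unchanged
  x2 <- x
  x2[1, 1, ] <- x2[1, 1, ] + 5
  y2 <- val(ph_fwd(m, x2))
  expect_equal(y2[3:4, 3:4, ], y[3:4, 3:4, ])
  expect_gt(max(abs(y2[1:2, 1:2, ] - y[1:2, 1:2, ])), 0)
})

test_that("a single window equals global attention on the Hi-Fi heads", {
  set.seed(4)
  H <- 4
  m <- hifi_attention(dim = 16, heads = 2, head_dim = 4, window = H)
  x <- rand_map(H, H, 16, seed = 4)
  y <- val(ph_fwd(m, x))
  # reference: plain multi-head attention with the same projections
  tok <- phrfdetr:::tokens_from_map(x)
  Q <- ph_fwd(m$mods$q, tok); K <- ph_fwd(m$mods$k, tok); V <- ph_fwd(m$mods$v, tok)
  O <- ph_fwd(m$mods$o, phrfdetr:::mha_core(Q, K, V, 2, 4))
  ref <- val(phrfdetr:::map_from_tokens(O, H, H))
  expect_equal(y, ref, tolerance = 1e-12)
})

test_that("Lo-Fi with s = 1 equals standard attention on its heads", {
  set.seed(5)
  m <- lofi_attention(dim = 16, heads = 2, head_dim = 4, window = 1)
  x <- rand_map(3, 5, 16, seed = 5)
  y <- val(ph_fwd(m, x))
  tok <- phrfdetr:::tokens_from_map(x)
  Q <- ph_fwd(m$mods$q, tok); K <- ph_fwd(m$mods$k, tok); V <- ph_fwd(m$mods$v, tok)
  O <- ph_fwd(m$mods$o, phrfdetr:::mha_core(Q, K, V, 2, 4))
  expect_equal(y, val(phrfdetr:::map_from_tokens(O, 3, 5)), tolerance = 1e-12)
})

test_that("Lo-Fi pools keys/values to ceil(H/s) * ceil(W/s) tokens", {
  m <- lofi_attention(dim = 8, heads = 2, head_dim = 4, window = 2)
  for (hw in list(c(4, 4), c(6, 8), c(5, 7))) {
    x <- rand_map(hw[1], hw[2], 8, seed = hw[1] * 10 + hw[2])
    pooled <- phrfdetr:::tg_avgpool2d(
      phrfdetr:::tg_reflect_pad_to(phrfdetr:::tg_tensor(x), 2), 2)
    expect_equal(dim(val(pooled))[1:2], c(ceiling(hw[1] / 2), ceiling(hw[2] / 2)))
    expect_equal(dim(val(ph_fwd(m, x))), c(hw[1], hw[2], 8))
  }
})

test_that("constant fields give position-independent Lo-Fi output", {
  m <- lofi_attention(dim = 8, heads = 2, head_dim = 4, window = 2)
  x <- array(0.7, c(4, 6, 8))
  y <- val(ph_fwd(m, x))
  expect_lt(max(apply(y, 3, function(p) diff(range(p)))), 1e-12)
})

test_that("permuting tokens inside one pooling cell leaves pooled K/V fixed", {
  set.seed(6)
  x <- rand_map(4, 4, 8, seed = 6)
  xp <- x
  # swap the two top rows inside the first 2x2 cell
  xp[1:2, 1, ] <- x[2:1, 1, ]
  p1 <- val(phrfdetr:::tg_avgpool2d(phrfdetr:::tg_tensor(x), 2))
  p2 <- val(phrfdetr:::tg_avgpool2d(phrfdetr:::tg_tensor(xp), 2))
  expect_equal(p1, p2, tolerance = 1e-15)
})

test_that("HiLo splits heads by the lo fraction and never exceeds MHA params", {
  d <- 32; nh <- 4
  mha_params <- ph_nparams(ph_mha(d, nh))
  for (a in c(0, 0.25, 0.5, 0.75, 1)) {
    m <- hilo_attention(d, nh, lo_fraction = a, window = 2)
    expect_equal(m$lo_heads, floor(a * nh))
    expect_equal(m$lo_heads + m$hi_heads, nh)
    expect_lte(ph_nparams(m), mha_params)
    # degenerate splits run and preserve shape
    x <- rand_map(4, 4, d, seed = 10 + a * 4)
    expect_equal(dim(val(ph_fwd(m, x))), c(4, 4, d))
  }
})

test_that("Lo-Fi attention cost scales with the pooled token count", {
  m2 <- lofi_attention(dim = 32, heads = 4, head_dim = 8, window = 2)
  m4 <- lofi_attention(dim = 32, heads = 4, head_dim = 8, window = 4)
  # doubling s quarters the pooled tokens: compare the attention-score term
  attn_term <- function(m, H, W) {
    np <- ceiling(H / m$window) * ceiling(W / m$window)
    2 * H * W * np * m$d_branch
  }
  expect_equal(attn_term(m2, 16, 16) / attn_term(m4, 16, 16), 4)
  # and the full profiled cost strictly decreases with s
  expect_lt(phrfdetr:::lofi_macs(m4, 16, 16), phrfdetr:::lofi_macs(m2, 16, 16))
})

test_that("AIFI-HiLo preserves shape and stays within AIFI parameters", {
  set.seed(8)
  d <- 32
  base <- aifi_block(d, heads = 4, ffn_hidden = 64)
  swap <- aifi_hilo_block(d, heads = 4, ffn_hidden = 64)
  x <- rand_map(5, 5, d, seed = 8)
  expect_equal(dim(val(ph_fwd(swap, x))), c(5, 5, d))
  expect_equal(dim(val(ph_fwd(base, x))), c(5, 5, d))
  expect_lte(ph_nparams(swap), ph_nparams(base))
  # non-square map with window 2 is pad-and-cropped, never an error
  x2 <- rand_map(5, 7, d, seed = 9)
  expect_equal(dim(val(ph_fwd(swap, x2))), c(5, 7, d))
})
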