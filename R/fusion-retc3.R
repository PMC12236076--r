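# Cross-scale feature fusion blocks. The baseline CCFF path fuses with
# RepC3 (re-parameterizable 3x3 conv stack); the lightweight variant swaps
# in RetC3, a C3-style block whose branch stacks RetBlocks built on MaSA:
# decomposed one-dimensional attention (vertical then horizontal) whose
# post-softmax scores are multiplied by an exponential spatial-decay mask
# gamma^|n-m| and renormalized, plus a depthwise-conv positional term and
# an FFN. Decomposition makes the attention cost linear rather than
# quadratic in the token count.

# --- RepConv / RepC3 (baseline fusion) --------------------------------------

# training-form RepConv: parallel 3x3 and 1x1 conv+norm branches, summed.
# The fused inference graph collapses to a single 3x3 convolution, which is
# what the FLOP accountant charges.
ph_repconv <- function(c, act = "silu") {
  m <- ph_module_new("ph_repconv")
  m$c <- c; m$act <- act
  m$mods$k3 <- ph_conv(c, c, 3L, act = "identity")
  m$mods$k1 <- ph_conv(c, c, 1L, pad = 0L, act = "identity")
  m
}

#' @export
ph_fwd.ph_repconv <- function(m, x, train = FALSE, ...) {
  ph_act(ph_fwd(m$mods$k3, x, train = train) +
           ph_fwd(m$mods$k1, x, train = train), m$act)
}

#' @export
ph_profile.ph_repconv <- function(m, inshape) {
  list(out = inshape, macs = inshape[1] * inshape[2] * 9 * m$c^2,
       params = ph_nparams_closed(m))
}

#' RepC3 fusion block (baseline)
#'
#' Two 1x1 projections; `depth` RepConvs on the first branch; the branches
#' are summed and projected back out.
#' @export
repc3_block <- function(cin, cout, hidden, depth = 3L) {
  m <- ph_module_new("ph_repc3")
  m$cin <- cin; m$cout <- cout; m$hidden <- hidden; m$depth <- depth
  m$mods$cv1 <- ph_conv(cin, hidden, 1L, pad = 0L)
  m$mods$cv2 <- ph_conv(cin, hidden, 1L, pad = 0L)
  m$mods$m <- ph_sequential(lapply(seq_len(depth), function(i) ph_repconv(hidden)))
  if (hidden != cout)
    m$mods$cv3 <- ph_conv(hidden, cout, 1L, pad = 0L, act = "identity")
  m
}

#' @export
ph_fwd.ph_repc3 <- function(m, x, train = FALSE, ...) {
  y <- ph_fwd(m$mods$m, ph_fwd(m$mods$cv1, x, train = train), train = train) +
    ph_fwd(m$mods$cv2, x, train = train)
  if (!is.null(m$mods$cv3)) y <- ph_fwd(m$mods$cv3, y, train = train)
  y
}

#' @export
ph_profile.ph_repc3 <- function(m, inshape) {
  hw <- inshape[1] * inshape[2]
  macs <- 2 * hw * m$cin * m$hidden + m$depth * hw * 9 * m$hidden^2
  if (!is.null(m$mods$cv3)) macs <- macs + hw * m$hidden * m$cout
  list(out = c(inshape[1], inshape[2], m$cout), macs = macs,
       params = ph_nparams_closed(m))
}

# --- MaSA -------------------------------------------------------------------

#' Exponential spatial-decay mask
#'
#' `M[n, m] = gamma^|n - m|` along one spatial axis: symmetric, unit
#' diagonal, entries in (0, 1].
#' @param length axis length L.
#' @param gamma decay factor in (0, 1].
#' @export
spatial_decay_mask <- function(length, gamma) {
  if (!(gamma > 0 && gamma <= 1))
    stop("spatial_decay_mask: gamma must be in (0, 1]")
  stopifnot(length >= 1)
  idx <- seq_len(length)
  gamma^abs(outer(idx, idx, "-"))
}

# log-spaced per-head decay schedule (stronger decay on early heads)
masa_gamma_schedule <- function(heads, gamma_min = 0.6, gamma_max = 0.98) {
  exp(seq(log(gamma_min), log(gamma_max), length.out = heads))
}

#' MaSA: decomposed attention with spatial decay
#'
#' Attention runs along the vertical axis with an H x H decay mask, then
#' along the horizontal axis with a W x W mask; in each pass the softmax
#' scores are multiplied elementwise by the mask and renormalized, keeping
#' every row a convex combination.
#'
#' @param dim token width; `heads` attention heads; `gammas` per-head decay
#'   factors (default log-spaced in `[0.6, 0.98]`).
#' @export
masa_attention <- function(dim, heads, gammas = NULL) {
  stopifnot(dim %% heads == 0L)
  if (is.null(gammas)) gammas <- masa_gamma_schedule(heads)
  stopifnot(length(gammas) == heads, all(gammas > 0), all(gammas <= 1))
  m <- ph_module_new("ph_masa")
  m$dim <- dim; m$heads <- heads; m$dh <- dim %/% heads
  m$gammas <- gammas
  m$mods$q <- ph_linear(dim, dim)
  m$mods$k <- ph_linear(dim, dim)
  m$mods$v <- ph_linear(dim, dim)
  m$mods$o <- ph_linear(dim, dim)
  m
}

# one decomposed pass: attention within each line of the grid (all lines
# and heads fused into a single grouped-attention node)
masa_axis_pass <- function(Q, K, V, m, H, W, axis) {
  L <- if (axis == "v") H else W
  nlines <- if (axis == "v") W else H
  masks <- lapply(m$gammas, function(g) spatial_decay_mask(L, g))
  lines <- lapply(seq_len(nlines), function(l) {
    if (axis == "v") (l - 1L) * H + seq_len(H)     # one column, contiguous
    else seq(l, by = H, length.out = W)            # one row, strided
  })
  tg_attention(Q, K, V, m$heads, m$dh, q_groups = lines, kv_groups = lines,
               masks = masks)
}

#' @export
ph_fwd.ph_masa <- function(m, x, train = FALSE, ...) {
  d <- dim(tg_val(x))
  H <- d[1]; W <- d[2]
  tok <- tokens_from_map(x)
  Q <- ph_fwd(m$mods$q, tok)
  K <- ph_fwd(m$mods$k, tok)
  V <- ph_fwd(m$mods$v, tok)
  y1 <- masa_axis_pass(Q, K, V, m, H, W, "v")
  y2 <- masa_axis_pass(Q, K, y1, m, H, W, "h")
  map_from_tokens(ph_fwd(m$mods$o, y2), H, W)
}

masa_macs <- function(dim, H, W) {
  ntok <- H * W
  proj <- 4 * ntok * dim^2
  # per axis: scores + apply within each line
  attn <- 2 * W * H^2 * dim + 2 * H * W^2 * dim
  proj + attn
}

#' @export
ph_profile.ph_masa <- function(m, inshape) {
  list(out = inshape, macs = masa_macs(m$dim, inshape[1], inshape[2]),
       params = ph_nparams_closed(m))
}

# reference cost of full (non-decomposed) 2-D attention, for the
# sub-quadratic complexity comparison
full_attention_macs <- function(dim, H, W) {
  ntok <- H * W
  4 * ntok * dim^2 + 2 * ntok^2 * dim
}

# --- RetBlock / RetC3 -------------------------------------------------------

#' RetBlock: MaSA transformer unit with positional enhancement
#'
#' `x + dwconv(x)` (local positional term), then pre-norm MaSA and FFN with
#' residual connections.
#' @export
ret_block <- function(dim, heads = 4L, gammas = NULL, ffn_ratio = 2) {
  m <- ph_module_new("ph_ret_block")
  m$dim <- dim; m$heads <- heads; m$ffn_ratio <- ffn_ratio
  m$mods$cpe <- ph_conv(dim, dim, 3L, groups = dim, norm = FALSE,
                        act = "identity", bias = TRUE)
  m$mods$ln1 <- ph_layernorm(dim)
  m$mods$attn <- masa_attention(dim, heads, gammas)
  m$mods$ln2 <- ph_layernorm(dim)
  m$mods$ffn <- ph_ffn(dim, as.integer(round(dim * ffn_ratio)), act = "relu")
  m
}

#' @export
ph_fwd.ph_ret_block <- function(m, x, train = FALSE, ...) {
  d <- dim(tg_val(x))
  x <- x + ph_fwd(m$mods$cpe, x, train = train)
  tok <- tokens_from_map(x)
  a <- tokens_from_map(
    ph_fwd(m$mods$attn, map_from_tokens(ph_fwd(m$mods$ln1, tok), d[1], d[2]),
           train = train))
  tok <- tok + a
  tok <- tok + ph_fwd(m$mods$ffn, ph_fwd(m$mods$ln2, tok))
  map_from_tokens(tok, d[1], d[2])
}

#' @export
ph_profile.ph_ret_block <- function(m, inshape) {
  hw <- inshape[1] * inshape[2]
  macs <- hw * 9 * m$dim +                       # depthwise positional conv
    masa_macs(m$dim, inshape[1], inshape[2]) +
    ffn_macs(m$mods$ffn, hw)
  list(out = inshape, macs = macs, params = ph_nparams_closed(m))
}

#' RetC3 fusion block
#'
#' C3-style wiring: two 1x1 projections; the first branch passes through
#' `depth` RetBlocks; branch outputs are concatenated and projected out.
#' @export
retc3_block <- function(cin, cout, hidden, depth = 3L, heads = 4L,
                        gammas = NULL) {
  if (cin %% 2L != 0L) stop("retc3_block: channel count must be even")
  m <- ph_module_new("ph_retc3")
  m$cin <- cin; m$cout <- cout; m$hidden <- hidden; m$depth <- depth
  m$mods$cv1 <- ph_conv(cin, hidden, 1L, pad = 0L)
  m$mods$cv2 <- ph_conv(cin, hidden, 1L, pad = 0L)
  if (depth > 0L)
    m$mods$m <- ph_sequential(lapply(seq_len(depth), function(i)
      ret_block(hidden, heads, gammas)))
  m$mods$cv3 <- ph_conv(2L * hidden, cout, 1L, pad = 0L, act = "identity")
  m
}

#' @export
ph_fwd.ph_retc3 <- function(m, x, train = FALSE, ...) {
  a <- ph_fwd(m$mods$cv1, x, train = train)
  if (!is.null(m$mods$m)) a <- ph_fwd(m$mods$m, a, train = train)
  b <- ph_fwd(m$mods$cv2, x, train = train)
  ph_fwd(m$mods$cv3, tg_concat_ch(list(a, b)), train = train)
}

#' @export
ph_profile.ph_retc3 <- function(m, inshape) {
  hw <- inshape[1] * inshape[2]
  macs <- 2 * hw * m$cin * m$hidden + hw * 2 * m$hidden * m$cout
  if (!is.null(m$mods$m))
    macs <- macs + ph_profile(m$mods$m, c(inshape[1], inshape[2], m$hidden))$macs
  list(out = c(inshape[1], inshape[2], m$cout), macs = macs,
       params = ph_nparams_closed(m))
}

# --- hybrid encoder (AIFI + CCFF) -------------------------------------------

# fusion-block factory: kind "repc3" or "retc3"; `hidden` chosen per level
make_fusion_block <- function(kind, cin, cout, hidden, depth, heads, gammas) {
  if (kind == "repc3") repc3_block(cin, cout, hidden, depth)
  else retc3_block(cin, cout, hidden, depth, heads, gammas)
}

#' Hybrid encoder: AIFI(-HiLo) on p5 plus cross-scale feature fusion
#'
#' @param in_channels backbone pyramid widths `(c3, c4, c5)`.
#' @param dim encoder width.
#' @param cfg configuration list, see [phrf_config()].
#' @param use_hilo swap the AIFI attention for HiLo.
#' @param fusion `"repc3"` or `"retc3"`.
#' @export
hybrid_encoder <- function(in_channels, dim = 256L, cfg = phrf_config(),
                           use_hilo = FALSE, fusion = "repc3") {
  m <- ph_module_new("ph_encoder")
  m$dim <- dim; m$fusion <- fusion
  m$mods$proj3 <- ph_conv(in_channels[1], dim, 1L, pad = 0L, act = "identity")
  m$mods$proj4 <- ph_conv(in_channels[2], dim, 1L, pad = 0L, act = "identity")
  m$mods$proj5 <- ph_conv(in_channels[3], dim, 1L, pad = 0L, act = "identity")
  m$mods$aifi <- if (use_hilo)
    aifi_hilo_block(dim, cfg$encoder$heads, cfg$encoder$ffn,
                    cfg$hilo$alpha, cfg$hilo$window)
  else aifi_block(dim, cfg$encoder$heads, cfg$encoder$ffn)
  m$mods$lat5 <- ph_conv(dim, dim, 1L, pad = 0L)
  m$mods$lat4 <- ph_conv(dim, dim, 1L, pad = 0L)
  m$mods$down3 <- ph_conv(dim, dim, 3L, stride = 2L)
  m$mods$down4 <- ph_conv(dim, dim, 3L, stride = 2L)
  fcfg <- if (fusion == "repc3") cfg$repc3 else cfg$retc3
  gam <- if (fusion == "retc3")
    masa_gamma_schedule(cfg$retc3$heads, cfg$retc3$gamma_min, cfg$retc3$gamma_max)
  else NULL
  mk <- function(pos) make_fusion_block(fusion, 2L * dim, dim,
                                        fcfg$hidden[[pos]], fcfg$depth,
                                        cfg$retc3$heads, gam)
  m$mods$fus_td4 <- mk("p4_td")
  m$mods$fus_td3 <- mk("p3")
  m$mods$fus_bu4 <- mk("p4_bu")
  m$mods$fus_bu5 <- mk("p5")
  m
}

#' @export
ph_fwd.ph_encoder <- function(m, x, train = FALSE, ...) {
  p3 <- ph_fwd(m$mods$proj3, x$p3, train = train)
  p4 <- ph_fwd(m$mods$proj4, x$p4, train = train)
  p5 <- ph_fwd(m$mods$proj5, x$p5, train = train)
  f5 <- ph_fwd(m$mods$aifi, p5, train = train)
  l5 <- ph_fwd(m$mods$lat5, f5, train = train)
  f4 <- ph_fwd(m$mods$fus_td4, tg_concat_ch(list(tg_upsample2(l5), p4)),
               train = train)
  l4 <- ph_fwd(m$mods$lat4, f4, train = train)
  f3 <- ph_fwd(m$mods$fus_td3, tg_concat_ch(list(tg_upsample2(l4), p3)),
               train = train)
  d3 <- ph_fwd(m$mods$down3, f3, train = train)
  n4 <- ph_fwd(m$mods$fus_bu4, tg_concat_ch(list(d3, l4)), train = train)
  d4 <- ph_fwd(m$mods$down4, n4, train = train)
  n5 <- ph_fwd(m$mods$fus_bu5, tg_concat_ch(list(d4, l5)), train = train)
  list(p3 = f3, p4 = n4, p5 = n5)
}

#' @export
ph_profile.ph_encoder <- function(m, inshape) {
  # inshape: list of pyramid shapes p3/p4/p5 from the backbone profile
  s3 <- inshape$p3; s4 <- inshape$p4; s5 <- inshape$p5
  d <- m$dim
  macs <- 0
  add <- function(mod, sh) {
    pr <- ph_profile(mod, sh)
    macs <<- macs + pr$macs
    pr$out
  }
  o3 <- add(m$mods$proj3, s3)
  o4 <- add(m$mods$proj4, s4)
  o5 <- add(m$mods$proj5, s5)
  o5 <- add(m$mods$aifi, o5)
  l5 <- add(m$mods$lat5, o5)
  f4 <- add(m$mods$fus_td4, c(o4[1], o4[2], 2L * d))
  l4 <- add(m$mods$lat4, f4)
  f3 <- add(m$mods$fus_td3, c(o3[1], o3[2], 2L * d))
  d3 <- add(m$mods$down3, f3)
  n4 <- add(m$mods$fus_bu4, c(d3[1], d3[2], 2L * d))
  d4 <- add(m$mods$down4, n4)
  n5 <- add(m$mods$fus_bu5, c(d4[1], d4[2], 2L * d))
  list(out = list(p3 = f3, p4 = n4, p5 = n5), macs = macs,
       params = ph_nparams_closed(m))
}
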