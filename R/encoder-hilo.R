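# Intra-scale feature interaction on the deepest pyramid level: the
# baseline AIFI transformer block (full multi-head self-attention with 2-D
# sinusoidal positions), and AIFI-HiLo, where the attention is split into a
# high-frequency branch (non-overlapping window attention on (1-a)*Nh
# heads) and a low-frequency branch (full-resolution queries against
# average-pooled keys/values on the remaining floor(a*Nh) heads), whose
# outputs are concatenated. Each branch carries its own output projection
# on its sub-dimension, so the split never adds parameters over standard
# multi-head attention.

#' High-frequency windowed attention branch
#'
#' Self-attention computed independently inside each s x s non-overlapping
#' window, on the high-frequency head subset.
#'
#' @param dim full embedding width d.
#' @param heads number of Hi-Fi heads (head width = d / total heads).
#' @param head_dim per-head width.
#' @param window window side s.
#' @export
hifi_attention <- function(dim, heads, head_dim, window = 2L) {
  m <- ph_module_new("ph_hifi")
  m$dim <- dim; m$heads <- heads; m$dh <- head_dim
  m$d_branch <- heads * head_dim
  m$window <- as.integer(window)
  if (heads > 0L) {
    m$mods$q <- ph_linear(dim, m$d_branch)
    m$mods$k <- ph_linear(dim, m$d_branch)
    m$mods$v <- ph_linear(dim, m$d_branch)
    m$mods$o <- ph_linear(m$d_branch, m$d_branch)
  }
  m
}

# window-partition row-index groups for an H x W token grid
# (row index fastest); one group per non-overlapping s x s window
win_partition_groups <- function(H, W, s) {
  nh <- H %/% s; nw <- W %/% s
  groups <- vector("list", nh * nw)
  at <- 0L
  for (wj in seq_len(nw)) for (wi in seq_len(nh)) {
    rows <- rep((wi - 1L) * s + seq_len(s), times = s)
    cols <- rep((wj - 1L) * s + seq_len(s), each = s)
    at <- at + 1L
    groups[[at]] <- rows + (cols - 1L) * H
  }
  groups
}

#' @export
ph_fwd.ph_hifi <- function(m, x, train = FALSE, ...) {
  # x: (H, W, C) map; returns (H, W, d_branch) map
  d <- dim(tg_val(x))
  if (m$heads == 0L) stop("hifi_attention: branch has zero heads")
  s <- m$window
  xp <- tg_reflect_pad_to(x, s)
  dp <- dim(tg_val(xp))
  if (s > min(dp[1], dp[2]))
    stop("hifi_attention: window larger than padded map")
  tok <- tokens_from_map(xp)
  groups <- win_partition_groups(dp[1], dp[2], s)
  Q <- ph_fwd(m$mods$q, tok); K <- ph_fwd(m$mods$k, tok); V <- ph_fwd(m$mods$v, tok)
  O <- tg_attention(Q, K, V, m$heads, m$dh, q_groups = groups,
                    kv_groups = groups)
  y <- map_from_tokens(ph_fwd(m$mods$o, O), dp[1], dp[2])
  tg_crop_hw(y, d[1], d[2])
}

hifi_macs <- function(m, H, W) {
  if (m$heads == 0L) return(0)
  s <- m$window
  Hp <- ceiling(H / s) * s; Wp <- ceiling(W / s) * s
  ntok <- Hp * Wp
  proj <- ntok * m$dim * m$d_branch * 3 + ntok * m$d_branch^2
  nwin <- (Hp %/% s) * (Wp %/% s)
  attn <- nwin * 2 * (s * s)^2 * m$d_branch
  proj + attn
}

#' Low-frequency pooled-attention branch
#'
#' Keys and values come from s x s average-pooled tokens; queries stay at
#' full resolution; standard attention on the low-frequency head subset.
#' @inheritParams hifi_attention
#' @export
lofi_attention <- function(dim, heads, head_dim, window = 2L) {
  m <- ph_module_new("ph_lofi")
  m$dim <- dim; m$heads <- heads; m$dh <- head_dim
  m$d_branch <- heads * head_dim
  m$window <- as.integer(window)
  if (heads > 0L) {
    m$mods$q <- ph_linear(dim, m$d_branch)
    m$mods$k <- ph_linear(dim, m$d_branch)
    m$mods$v <- ph_linear(dim, m$d_branch)
    m$mods$o <- ph_linear(m$d_branch, m$d_branch)
  }
  m
}

#' @export
ph_fwd.ph_lofi <- function(m, x, train = FALSE, kv_map = NULL, ...) {
  d <- dim(tg_val(x))
  if (m$heads == 0L) stop("lofi_attention: branch has zero heads")
  s <- m$window
  if (is.null(kv_map)) kv_map <- x
  pooled <- if (s > 1L) tg_avgpool2d(tg_reflect_pad_to(kv_map, s), s) else kv_map
  tok <- tokens_from_map(x)
  ptok <- tokens_from_map(pooled)
  Q <- ph_fwd(m$mods$q, tok)
  K <- ph_fwd(m$mods$k, ptok)
  V <- ph_fwd(m$mods$v, ptok)
  O <- ph_fwd(m$mods$o, mha_core(Q, K, V, m$heads, m$dh))
  map_from_tokens(O, d[1], d[2])
}

lofi_macs <- function(m, H, W) {
  if (m$heads == 0L) return(0)
  s <- m$window
  np <- ceiling(H / s) * ceiling(W / s)
  ntok <- H * W
  proj <- ntok * m$dim * m$d_branch + 2 * np * m$dim * m$d_branch +
    ntok * m$d_branch^2
  attn <- 2 * ntok * np * m$d_branch
  proj + attn
}

#' HiLo attention: concatenated high/low-frequency branches
#'
#' @param dim embedding width d.
#' @param num_heads total heads Nh.
#' @param lo_fraction a in `[0, 1]`: the Lo-Fi branch receives
#'   `floor(a * Nh)` heads, Hi-Fi the remaining `(1 - a) * Nh`.
#' @param window window side / pooling size s.
#' @export
hilo_attention <- function(dim, num_heads, lo_fraction = 0.5, window = 2L) {
  stopifnot(dim %% num_heads == 0L, lo_fraction >= 0, lo_fraction <= 1)
  m <- ph_module_new("ph_hilo")
  m$dim <- dim; m$num_heads <- num_heads
  m$dh <- dim %/% num_heads
  m$lo_heads <- as.integer(floor(lo_fraction * num_heads))
  m$hi_heads <- num_heads - m$lo_heads
  m$window <- as.integer(window)
  m$mods$hifi <- hifi_attention(dim, m$hi_heads, m$dh, window)
  m$mods$lofi <- lofi_attention(dim, m$lo_heads, m$dh, window)
  m
}

#' @export
ph_fwd.ph_hilo <- function(m, x, train = FALSE, kv_map = NULL, ...) {
  outs <- list()
  if (m$hi_heads > 0L)
    outs <- c(outs, list(ph_fwd(m$mods$hifi, x, train = train)))
  if (m$lo_heads > 0L)
    outs <- c(outs, list(ph_fwd(m$mods$lofi, x, train = train, kv_map = kv_map)))
  if (length(outs) == 1L) return(outs[[1]])
  tg_concat_ch(outs)
}

hilo_macs <- function(m, H, W) {
  hifi_macs(m$mods$hifi, H, W) + lofi_macs(m$mods$lofi, H, W)
}

#' @export
ph_profile.ph_hilo <- function(m, inshape) {
  list(out = inshape, macs = hilo_macs(m, inshape[1], inshape[2]),
       params = ph_nparams_closed(m))
}

# --- AIFI blocks ------------------------------------------------------------

#' Baseline AIFI block: transformer encoder layer on the deepest level
#'
#' Flatten to tokens, add 2-D sinusoidal positions (queries and keys only),
#' full multi-head self-attention, feed-forward, residual + layer norm
#' (post-norm), reshape back.
#' @export
aifi_block <- function(dim, heads = 8L, ffn_hidden = 1024L) {
  m <- ph_module_new("ph_aifi")
  m$dim <- dim; m$heads <- heads; m$ffn_hidden <- ffn_hidden
  m$mods$attn <- ph_mha(dim, heads)
  m$mods$ln1 <- ph_layernorm(dim)
  m$mods$ffn <- ph_ffn(dim, ffn_hidden, act = "relu")
  m$mods$ln2 <- ph_layernorm(dim)
  m
}

#' @export
ph_fwd.ph_aifi <- function(m, x, train = FALSE, ...) {
  d <- dim(tg_val(x))
  tok <- tokens_from_map(x)
  pos <- pos_embed_2d(d[1], d[2], m$dim)
  a <- ph_fwd(m$mods$attn, tok, qpos = pos, kpos = pos)
  y <- ph_fwd(m$mods$ln1, tok + a)
  z <- ph_fwd(m$mods$ln2, y + ph_fwd(m$mods$ffn, y))
  map_from_tokens(z, d[1], d[2])
}

#' @export
ph_profile.ph_aifi <- function(m, inshape) {
  ntok <- inshape[1] * inshape[2]
  macs <- mha_macs(m$dim, ntok, ntok) + ffn_macs(m$mods$ffn, ntok)
  list(out = inshape, macs = macs, params = ph_nparams_closed(m))
}

#' AIFI-HiLo block: AIFI wiring with HiLo attention swapped in
#'
#' Positional encodings enter the attention inputs for queries/keys as in
#' AIFI; the HiLo value path reads the raw tokens.
#' @export
aifi_hilo_block <- function(dim, heads = 8L, ffn_hidden = 1024L,
                            lo_fraction = 0.5, window = 2L) {
  m <- ph_module_new("ph_aifi_hilo")
  m$dim <- dim; m$heads <- heads; m$ffn_hidden <- ffn_hidden
  m$mods$attn <- hilo_attention(dim, heads, lo_fraction, window)
  m$mods$ln1 <- ph_layernorm(dim)
  m$mods$ffn <- ph_ffn(dim, ffn_hidden, act = "relu")
  m$mods$ln2 <- ph_layernorm(dim)
  m
}

#' @export
ph_fwd.ph_aifi_hilo <- function(m, x, train = FALSE, ...) {
  d <- dim(tg_val(x))
  pos <- array(pos_embed_2d(d[1], d[2], m$dim), c(d[1], d[2], m$dim))
  a <- ph_fwd(m$mods$attn, x + pos, train = train, kv_map = x)
  tok <- tokens_from_map(x)
  atok <- tokens_from_map(a)
  y <- ph_fwd(m$mods$ln1, tok + atok)
  z <- ph_fwd(m$mods$ln2, y + ph_fwd(m$mods$ffn, y))
  map_from_tokens(z, d[1], d[2])
}

#' @export
ph_profile.ph_aifi_hilo <- function(m, inshape) {
  macs <- hilo_macs(m$mods$attn, inshape[1], inshape[2]) +
    ffn_macs(m$mods$ffn, inshape[1] * inshape[2])
  list(out = inshape, macs = macs, params = ph_nparams_closed(m))
}
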