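# Detection decoder: encoder tokens from all pyramid levels form the
# memory; a query-selection stage scores every token and keeps the top
# `queries` as initial object queries with anchor-conditioned reference
# boxes; three transformer layers (self-attention, cross-attention over the
# shared projected memory, FFN) iteratively refine class logits and boxes.
# Boxes are predicted as normalized center-form coordinates through a
# sigmoid; no NMS is applied anywhere.

qlogit <- function(p, eps = 1e-4) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

#' Detection decoder module
#'
#' @param dim model width; `nc` classes; `nq` object queries;
#'   `nlayers` decoder layers; `heads` attention heads; `ffn` FFN width.
#' @export
phrf_decoder <- function(dim = 256L, nc = 5L, nq = 300L, nlayers = 3L,
                         heads = 8L, ffn = 1024L) {
  m <- ph_module_new("ph_decoder")
  m$dim <- dim; m$nc <- nc; m$nq <- nq; m$nlayers <- nlayers
  m$heads <- heads; m$dh <- dim %/% heads; m$ffn <- ffn
  m$mods$enc_out <- ph_linear(dim, dim)
  m$mods$enc_ln <- ph_layernorm(dim)
  m$mods$enc_cls <- ph_linear(dim, nc)
  m$mods$enc_box1 <- ph_linear(dim, dim)
  m$mods$enc_box2 <- ph_linear(dim, 4L)
  # memory keys/values are projected once and shared across layers
  m$mods$kv_k <- ph_linear(dim, dim)
  m$mods$kv_v <- ph_linear(dim, dim)
  m$mods$qpos1 <- ph_linear(4L, dim)
  m$mods$qpos2 <- ph_linear(dim, dim)
  m$par$lvl_embed <- tg_tensor(matrix(stats::rnorm(3 * dim, sd = 0.02), 3, dim),
                               rg = TRUE)
  for (i in seq_len(nlayers)) {
    li <- ph_module_new("ph_dec_layer")
    li$dim <- dim
    li$mods$self_attn <- ph_mha(dim, heads)
    li$mods$ln1 <- ph_layernorm(dim)
    li$mods$q_cross <- ph_linear(dim, dim)
    li$mods$o_cross <- ph_linear(dim, dim)
    li$mods$ln2 <- ph_layernorm(dim)
    li$mods$ffn <- ph_ffn(dim, ffn, act = "relu")
    li$mods$ln3 <- ph_layernorm(dim)
    li$mods$cls_head <- ph_linear(dim, nc)
    li$mods$box1 <- ph_linear(dim, dim)
    li$mods$box2 <- ph_linear(dim, 4L)
    m$mods[[paste0("layer", i)]] <- li
  }
  m
}

# anchors for every token of every level: grid centers with a
# level-scaled prior size
decoder_anchors <- function(shapes) {
  out <- vector("list", length(shapes))
  for (l in seq_along(shapes)) {
    H <- shapes[[l]][1]; W <- shapes[[l]][2]
    cy <- rep((seq_len(H) - 0.5) / H, times = W)
    cx <- rep((seq_len(W) - 0.5) / W, each = H)
    wh <- 0.05 * 2^(l - 1)
    out[[l]] <- cbind(cx, cy, rep(wh, H * W), rep(wh, H * W))
  }
  do.call(rbind, out)
}

#' @export
ph_fwd.ph_decoder <- function(m, x, train = FALSE, ...) {
  # x: list p3/p4/p5 of (H, W, dim) maps
  lvls <- list(x$p3, x$p4, x$p5)
  shapes <- lapply(lvls, function(v) dim(tg_val(v)))
  toks <- lapply(lvls, tokens_from_map)
  mem <- tg_concat_rows(toks)
  pos <- do.call(rbind, lapply(shapes, function(s)
    pos_embed_2d(s[1], s[2], m$dim)))
  lvl_rows <- rep(1:3, vapply(shapes, function(s) s[1] * s[2], numeric(1)))
  lvl_add <- t_rows(m$par$lvl_embed, lvl_rows)
  mem_k_in <- mem + pos + lvl_add
  K <- ph_fwd(m$mods$kv_k, mem_k_in)
  V <- ph_fwd(m$mods$kv_v, mem)
  # query selection by classification score (uncertainty-minimal pick)
  h <- ph_fwd(m$mods$enc_ln, ph_fwd(m$mods$enc_out, mem))
  logits_all <- ph_fwd(m$mods$enc_cls, h)
  score <- apply(tg_val(logits_all), 1L, max)
  nq <- min(m$nq, length(score))
  sel <- order(-score)[seq_len(nq)]
  anchors <- decoder_anchors(shapes)[sel, , drop = FALSE]
  h_sel <- t_rows(h, sel)
  delta0 <- ph_fwd(m$mods$enc_box2, t_relu(ph_fwd(m$mods$enc_box1, h_sel)))
  ref <- t_sigmoid(delta0 + qlogit(anchors))
  enc_stage <- list(logits = t_rows(logits_all, sel), boxes = ref)
  q <- tg_tensor(t_detach(h_sel))  # content queries, gradient-detached
  stages <- vector("list", m$nlayers)
  for (i in seq_len(m$nlayers)) {
    li <- m$mods[[paste0("layer", i)]]
    rd <- t_detach(ref)
    qp <- ph_fwd(m$mods$qpos2, t_relu(ph_fwd(m$mods$qpos1, rd)))
    a <- ph_fwd(li$mods$self_attn, q, qpos = qp, kpos = qp)
    q <- ph_fwd(li$mods$ln1, q + a)
    Qc <- ph_fwd(li$mods$q_cross, q + qp)
    cr <- ph_fwd(li$mods$o_cross, mha_core(Qc, K, V, m$heads, m$dh))
    q <- ph_fwd(li$mods$ln2, q + cr)
    q <- ph_fwd(li$mods$ln3, q + ph_fwd(li$mods$ffn, q))
    logits <- ph_fwd(li$mods$cls_head, q)
    delta <- ph_fwd(li$mods$box2, t_relu(ph_fwd(li$mods$box1, q)))
    ref <- t_sigmoid(delta + qlogit(rd))
    stages[[i]] <- list(logits = logits, boxes = ref)
  }
  list(enc = enc_stage, stages = stages, final = stages[[m$nlayers]])
}

#' @export
ph_profile.ph_decoder <- function(m, inshape) {
  # inshape: list of pyramid shapes from the encoder profile
  Ts <- vapply(inshape, function(s) s[1] * s[2], numeric(1))
  T <- sum(Ts)
  d <- m$dim; nq <- m$nq
  macs <- T * d * d            # enc_out
  macs <- macs + T * d * m$nc  # enc_cls
  macs <- macs + nq * (d * d + d * 4)  # selected-query box head
  macs <- macs + 2 * T * d * d # shared K/V projection
  per_layer <- mha_macs(d, nq, nq) +          # self-attention
    2 * nq * d * d + 2 * nq * T * d +         # cross q/o proj + attention
    nq * 2 * d * m$ffn +                      # FFN
    nq * (4 * d + d * d) +                    # query positional MLP
    nq * (d * m$nc + d * d + d * 4)           # heads
  macs <- macs + m$nlayers * per_layer
  list(out = NULL, macs = macs, params = ph_nparams_closed(m))
}

#' @export
ph_nparams_closed.ph_decoder <- function(m) {
  sum(vapply(m$mods, ph_nparams_closed, numeric(1))) + length(m$par$lvl_embed$v)
}
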