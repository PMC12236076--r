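# Module system: small neural building blocks over the autodiff core.
# Every module knows how to run forward numerically and how to account for
# its trainable parameters (closed form, kernel-width x kernel-height x
# C_in x C_out per convolution) and multiply-accumulate cost at a given
# input size. Feature maps are (H, W, C) arrays internally; the public API
# uses (N, C, H, W) as is conventional for detection frameworks.

ph_module_new <- function(cls) {
  m <- new.env(parent = emptyenv())
  m$par <- list()
  m$mods <- list()
  class(m) <- c(cls, "ph_module")
  m
}

#' Run a module forward
#' @param m a `ph_module`.
#' @param x input (layout depends on the module).
#' @param train logical; training mode (affects normalization statistics).
#' @param ... passed to methods.
#' @export
ph_fwd <- function(m, x, train = FALSE, ...) UseMethod("ph_fwd")

#' Profile a module: output shape, multiply-accumulates, closed-form params
#' @param m a `ph_module`.
#' @param inshape input shape `c(H, W, C)`.
#' @export
ph_profile <- function(m, inshape) UseMethod("ph_profile")

#' Collect the trainable parameter tensors of a module tree
#' @export
ph_parameters <- function(m) {
  out <- list()
  if (length(m$par)) out <- c(out, unname(m$par))
  for (sub in m$mods) out <- c(out, ph_parameters(sub))
  out
}

#' Count trainable parameters by summing tensor sizes (framework-count route)
#' @export
ph_nparams <- function(m) {
  sum(vapply(ph_parameters(m), function(p) length(p$v), numeric(1)))
}

#' Closed-form parameter count of a module tree
#' @export
ph_nparams_closed <- function(m) UseMethod("ph_nparams_closed")

#' @export
ph_nparams_closed.ph_module <- function(m) {
  # default: recurse over submodules; leaf classes override
  sum(vapply(m$mods, ph_nparams_closed, numeric(1)), 0)
}

conv_out_hw <- function(hw, k, stride, pad) {
  (hw + 2L * pad - k) %/% stride + 1L
}

same_pad <- function(k) (k - 1L) %/% 2L

ph_act <- function(x, act) {
  switch(act,
    silu = t_silu(x),
    relu = t_relu(x),
    identity = x,
    stop("unknown activation: ", act))
}

# --- conv + norm + activation ----------------------------------------------

#' Convolution block (conv + batch norm + activation)
#'
#' Bias is disabled whenever normalization is active, so the closed-form
#' parameter count stays `k^2 C_in C_out / g (+ 2 C_out norm affine)`.
#'
#' @param cin,cout channel counts.
#' @param k kernel side.
#' @param stride stride.
#' @param pad padding; `"same"` keeps stride-1 spatial dims.
#' @param groups channel groups (grouped convolution uses `1/g` the
#'   parameters of the standard convolution).
#' @param norm include batch normalization.
#' @param act activation name (`"silu"`, `"relu"`, `"identity"`).
#' @param bias force a bias term (default: only when `norm = FALSE`).
#' @export
ph_conv <- function(cin, cout, k = 3L, stride = 1L, pad = "same", groups = 1L,
                    norm = TRUE, act = "silu", bias = !norm) {
  m <- ph_module_new("ph_conv")
  if (identical(pad, "same")) pad <- same_pad(k)
  m$cin <- cin; m$cout <- cout; m$k <- as.integer(k)
  m$stride <- as.integer(stride); m$pad <- as.integer(pad)
  m$groups <- as.integer(groups)
  m$norm <- isTRUE(norm); m$act <- act; m$bias <- isTRUE(bias)
  if (cin %% groups != 0L || cout %% groups != 0L)
    stop("ph_conv: channels not divisible by groups")
  fan_in <- k * k * cin / groups
  m$par$w <- tg_tensor(matrix(stats::rnorm(cout * fan_in, sd = sqrt(2 / fan_in)),
                              cout, fan_in), rg = TRUE)
  if (m$bias) m$par$b <- tg_tensor(numeric(cout), rg = TRUE)
  if (m$norm) {
    m$par$gamma <- tg_tensor(rep(1, cout), rg = TRUE)
    m$par$beta <- tg_tensor(numeric(cout), rg = TRUE)
    m$state <- new.env(parent = emptyenv())
    m$state$mean <- numeric(cout)
    m$state$var <- rep(1, cout)
  }
  m
}

#' @export
ph_fwd.ph_conv <- function(m, x, train = FALSE, ...) {
  y <- tg_conv2d(x, m$par$w, m$par$b, k = m$k, stride = m$stride,
                 pad = m$pad, groups = m$groups)
  if (m$norm) {
    # train = "stats": normalize with this map's statistics but leave the
    # running estimates untouched (deterministic batch-of-one inference)
    use_batch <- isTRUE(train) || identical(train, "stats")
    y <- tg_bn2d(y, m$par$gamma, m$par$beta, m$state,
                 training = use_batch, update = isTRUE(train))
  }
  ph_act(y, m$act)
}

#' @export
ph_nparams_closed.ph_conv <- function(m) {
  m$k^2 * (m$cin / m$groups) * m$cout +
    (if (m$bias) m$cout else 0) + (if (m$norm) 2 * m$cout else 0)
}

#' @export
ph_profile.ph_conv <- function(m, inshape) {
  stopifnot(inshape[3] == m$cin)
  ho <- conv_out_hw(inshape[1], m$k, m$stride, m$pad)
  wo <- conv_out_hw(inshape[2], m$k, m$stride, m$pad)
  list(out = c(ho, wo, m$cout),
       macs = ho * wo * m$k^2 * (m$cin / m$groups) * m$cout,
       params = ph_nparams_closed(m))
}

#' Set all convolution weights of a module tree to zero (ablation helper)
#' @export
ph_zero_weights <- function(m) {
  for (p in ph_parameters(m)) {
    if (is.matrix(p$v)) p$v[] <- 0
  }
  invisible(m)
}

# --- sequential -------------------------------------------------------------

#' Sequential container
#' @param ... modules, or a single list of modules.
#' @export
ph_sequential <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1]]) && !inherits(mods[[1]], "ph_module"))
    mods <- mods[[1]]
  m <- ph_module_new("ph_sequential")
  m$mods <- mods
  m
}

#' @export
ph_fwd.ph_sequential <- function(m, x, train = FALSE, ...) {
  for (sub in m$mods) x <- ph_fwd(sub, x, train = train, ...)
  x
}

#' @export
ph_profile.ph_sequential <- function(m, inshape) {
  macs <- 0
  for (sub in m$mods) {
    pr <- ph_profile(sub, inshape)
    macs <- macs + pr$macs
    inshape <- pr$out
  }
  list(out = inshape, macs = macs, params = ph_nparams_closed(m))
}

# --- max pooling (parameter free) ------------------------------------------

ph_maxpool <- function(k = 3L, stride = 2L, pad = 1L) {
  m <- ph_module_new("ph_maxpool")
  m$k <- k; m$stride <- stride; m$pad <- pad
  m
}

#' @export
ph_fwd.ph_maxpool <- function(m, x, train = FALSE, ...) {
  tg_maxpool2d(x, m$k, m$stride, m$pad)
}

#' @export
ph_profile.ph_maxpool <- function(m, inshape) {
  ho <- conv_out_hw(inshape[1], m$k, m$stride, m$pad)
  wo <- conv_out_hw(inshape[2], m$k, m$stride, m$pad)
  list(out = c(ho, wo, inshape[3]), macs = 0, params = 0)
}

# --- token-space layers -----------------------------------------------------

#' Linear layer on a (tokens x dim) matrix
#' @export
ph_linear <- function(din, dout, bias = TRUE) {
  m <- ph_module_new("ph_linear")
  m$din <- din; m$dout <- dout; m$bias <- isTRUE(bias)
  m$par$w <- tg_tensor(matrix(stats::rnorm(din * dout, sd = sqrt(1 / din)),
                              din, dout), rg = TRUE)
  if (m$bias) m$par$b <- tg_tensor(numeric(dout), rg = TRUE)
  m
}

#' @export
ph_fwd.ph_linear <- function(m, x, train = FALSE, ...) {
  y <- tg_matmul(x, m$par$w)
  if (m$bias) y <- t_addrow(y, m$par$b)
  y
}

#' @export
ph_nparams_closed.ph_linear <- function(m) {
  m$din * m$dout + (if (m$bias) m$dout else 0)
}

linear_macs <- function(m, ntok) ntok * m$din * m$dout

#' Layer normalization over the feature dimension
#' @export
ph_layernorm <- function(d) {
  m <- ph_module_new("ph_layernorm")
  m$d <- d
  m$par$gamma <- tg_tensor(rep(1, d), rg = TRUE)
  m$par$beta <- tg_tensor(numeric(d), rg = TRUE)
  m
}

#' @export
ph_fwd.ph_layernorm <- function(m, x, train = FALSE, ...) {
  t_layernorm_rows(x, m$par$gamma, m$par$beta)
}

#' @export
ph_nparams_closed.ph_layernorm <- function(m) 2 * m$d

#' Two-layer feed-forward block on tokens
#' @export
ph_ffn <- function(d, hidden, act = "relu") {
  m <- ph_module_new("ph_ffn")
  m$d <- d; m$hidden <- hidden; m$act <- act
  m$mods$fc1 <- ph_linear(d, hidden)
  m$mods$fc2 <- ph_linear(hidden, d)
  m
}

#' @export
ph_fwd.ph_ffn <- function(m, x, train = FALSE, ...) {
  ph_fwd(m$mods$fc2, ph_act(ph_fwd(m$mods$fc1, x), m$act))
}

ffn_macs <- function(m, ntok) ntok * 2 * m$d * m$hidden

#' Multi-head attention over token matrices
#'
#' Self-attention when `kv` is `NULL`; positional encodings are added to
#' queries and keys only. An optional post-softmax multiplicative mask with
#' row renormalization supports spatial-decay attention variants.
#' @export
ph_mha <- function(d, nheads) {
  if (d %% nheads != 0L) stop("ph_mha: dim not divisible by heads")
  m <- ph_module_new("ph_mha")
  m$d <- d; m$nheads <- nheads; m$dh <- d %/% nheads
  m$mods$q <- ph_linear(d, d)
  m$mods$k <- ph_linear(d, d)
  m$mods$v <- ph_linear(d, d)
  m$mods$o <- ph_linear(d, d)
  m
}

mha_core <- function(Q, K, V, nheads, dh, mask = NULL) {
  masks <- if (is.null(mask)) NULL else rep(list(mask), nheads)
  tg_attention(Q, K, V, nheads, dh, masks = masks)
}

#' @export
ph_fwd.ph_mha <- function(m, x, train = FALSE, kv = NULL, qpos = NULL,
                          kpos = NULL, mask = NULL, kv_proj = NULL, ...) {
  if (is.null(kv)) kv <- x
  xq <- if (is.null(qpos)) x else x + qpos
  xk <- if (is.null(kpos)) kv else kv + kpos
  Q <- ph_fwd(m$mods$q, xq)
  if (is.null(kv_proj)) {
    K <- ph_fwd(m$mods$k, xk)
    V <- ph_fwd(m$mods$v, kv)
  } else {
    K <- kv_proj$K
    V <- kv_proj$V
  }
  O <- mha_core(Q, K, V, m$nheads, m$dh, mask = mask)
  ph_fwd(m$mods$o, O)
}

mha_macs <- function(d, tq, tk, kv_proj_counted = TRUE) {
  proj <- tq * d * d + tq * d * d  # q and output projections
  if (kv_proj_counted) proj <- proj + 2 * tk * d * d
  proj + 2 * tq * tk * d
}

# --- positional encodings ---------------------------------------------------

# 2-D sine/cosine positional embedding for an H x W token grid (numeric,
# not trainable); tokens ordered column-major (row index fastest).
pos_embed_2d <- function(H, W, d, temperature = 10000) {
  stopifnot(d %% 4 == 0)
  dq <- d %/% 4
  omega <- 1 / temperature^((seq_len(dq) - 1) / dq)
  gy <- rep(seq_len(H) - 1, times = W)
  gx <- rep(seq_len(W) - 1, each = H)
  outx <- outer(gx, omega)
  outy <- outer(gy, omega)
  cbind(sin(outx), cos(outx), sin(outy), cos(outy))
}

# flatten (H, W, C) to tokens (H*W x C), row index fastest
tokens_from_map <- function(x) {
  d <- dim(tg_val(x))
  t_reshape(x, c(d[1] * d[2], d[3]))
}

map_from_tokens <- function(x, H, W) {
  d <- dim(tg_val(x))
  t_reshape(x, c(H, W, d[2]))
}
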