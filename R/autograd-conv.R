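# Convolution, normalization and pooling primitives for the autodiff core.
# Feature maps are stored channel-last as (H, W, C) arrays; convolution is
# im2col + BLAS matmul with cached patch indices.

.tg_idx_cache <- new.env(parent = emptyenv())

# patch-extraction linear indices for a padded (Hp, Wp, C) slab
tg_im2col_idx <- function(Hp, Wp, C, k, stride, Ho, Wo) {
  key <- paste(Hp, Wp, C, k, stride, Ho, Wo, sep = "_")
  idx <- .tg_idx_cache[[key]]
  if (!is.null(idx)) return(idx)
  off <- as.vector(outer(seq_len(k), (seq_len(k) - 1L) * Hp, "+"))     # k^2 in-plane
  off <- as.vector(outer(off, (seq_len(C) - 1L) * Hp * Wp, "+"))       # x channels
  st <- as.vector(outer((seq_len(Ho) - 1L) * stride,
                        (seq_len(Wo) - 1L) * stride * Hp, "+"))
  idx <- outer(off, st, "+")                                           # (k^2*C, Ho*Wo)
  attr(idx, "ui") <- sort(unique(as.vector(idx)))  # scatter targets, cached
  .tg_idx_cache[[key]] <- idx
  idx
}

tg_pad_zero <- function(v, p) {
  if (p == 0L) return(v)
  d <- dim(v)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  out[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), ] <- v
  out
}

#' 2-D convolution with optional channel groups
#'
#' @param x `(H, W, C)` array or tensor.
#' @param w weight tensor shaped `(C_out, k^2 * C_in / groups)`.
#' @param b optional bias tensor of length `C_out`.
#' @keywords internal
tg_conv2d <- function(x, w, b = NULL, k, stride = 1L, pad = 0L, groups = 1L) {
  vx <- tg_val(x)
  vw <- tg_val(w)
  d <- dim(vx)
  H <- d[1]; W <- d[2]; C <- d[3]
  if (C %% groups != 0L) stop("conv2d: input channels not divisible by groups")
  cout <- nrow(vw)
  if (cout %% groups != 0L) stop("conv2d: output channels not divisible by groups")
  cing <- C %/% groups
  coutg <- cout %/% groups
  if (ncol(vw) != k * k * cing)
    stop("conv2d: weight shape mismatch")
  xp <- tg_pad_zero(vx, pad)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  if (Ho < 1L || Wo < 1L) stop("conv2d: kernel larger than padded input")
  idx0 <- tg_im2col_idx(Hp, Wp, cing, k, stride, Ho, Wo)
  cols <- vector("list", groups)
  out <- matrix(0, cout, Ho * Wo)
  for (gi in seq_len(groups)) {
    idx <- if (groups == 1L) idx0 else idx0 + (gi - 1L) * cing * Hp * Wp
    Xc <- xp[idx]
    dim(Xc) <- dim(idx)
    cols[[gi]] <- Xc
    rows <- ((gi - 1L) * coutg + 1L):(gi * coutg)
    out[rows, ] <- vw[rows, , drop = FALSE] %*% Xc
  }
  if (!is.null(b)) out <- out + tg_val(b)
  y <- array(t(out), c(Ho, Wo, cout))
  parents <- list(
    list(p = x, fn = function(g) {
      G <- t(matrix(g, Ho * Wo, cout))
      dxp <- numeric(Hp * Wp * C)
      ui0 <- attr(idx0, "ui")
      for (gi in seq_len(groups)) {
        offg <- (gi - 1L) * cing * Hp * Wp
        idx <- if (groups == 1L) idx0 else idx0 + offg
        rows <- ((gi - 1L) * coutg + 1L):(gi * coutg)
        dcol <- crossprod(vw[rows, , drop = FALSE], G[rows, , drop = FALSE])
        acc <- rowsum(as.vector(dcol), group = as.vector(idx), reorder = TRUE)
        ii <- if (groups == 1L) ui0 else ui0 + offg
        dxp[ii] <- dxp[ii] + acc[, 1]
      }
      dim(dxp) <- c(Hp, Wp, C)
      if (pad > 0L)
        dxp <- dxp[(pad + 1L):(pad + H), (pad + 1L):(pad + W), , drop = FALSE]
      dxp
    }),
    list(p = w, fn = function(g) {
      G <- t(matrix(g, Ho * Wo, cout))
      dW <- matrix(0, cout, k * k * cing)
      for (gi in seq_len(groups)) {
        rows <- ((gi - 1L) * coutg + 1L):(gi * coutg)
        dW[rows, ] <- tcrossprod(G[rows, , drop = FALSE], cols[[gi]])
      }
      dW
    }))
  if (!is.null(b))
    parents[[3]] <- list(p = b, fn = function(g)
      rowSums(t(matrix(g, Ho * Wo, cout))))
  tg_node(y, parents)
}

#' Batch normalization over the spatial plane of one feature map
#'
#' In training mode the statistics of the current map are used and, when
#' `update` is true, the running estimates in `state` are refreshed; in
#' inference mode the running estimates are applied. `training = TRUE`
#' with `update = FALSE` gives deterministic per-map normalization without
#' side effects (used when predicting in the batch-of-one regime).
#' @keywords internal
tg_bn2d <- function(x, gamma, beta, state, training = FALSE, update = TRUE,
                    momentum = 0.1, eps = 1e-5) {
  vx <- tg_val(x)
  d <- dim(vx)
  n <- d[1] * d[2]
  xm <- matrix(vx, n, d[3])
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu, "-")
    va <- colMeans(xc * xc)
    if (update) {
      if (isTRUE(state$collect)) {
        # cumulative averaging pass (running-statistics recalibration)
        state$n <- state$n + 1L
        w <- 1 / state$n
        state$mean <- (1 - w) * state$mean + w * mu
        state$var <- (1 - w) * state$var + w * va * n / max(1, n - 1)
      } else {
        state$mean <- (1 - momentum) * state$mean + momentum * mu
        state$var <- (1 - momentum) * state$var +
          momentum * va * n / max(1, n - 1)
      }
    }
  } else {
    mu <- state$mean
    va <- state$var
    xc <- sweep(xm, 2L, mu, "-")
  }
  inv <- 1 / sqrt(va + eps)
  xh <- sweep(xc, 2L, inv, "*")
  ym <- sweep(sweep(xh, 2L, tg_val(gamma), "*"), 2L, tg_val(beta), "+")
  y <- array(ym, d)
  tg_node(y, list(
    list(p = x, fn = function(g) {
      gm <- matrix(g, n, d[3])
      gg <- sweep(gm, 2L, tg_val(gamma), "*")
      if (training) {
        dx <- sweep(gg, 2L, colMeans(gg), "-") -
          xh * matrix(colMeans(gg * xh), n, d[3], byrow = TRUE)
        dx <- sweep(dx, 2L, inv, "*")
      } else {
        dx <- sweep(gg, 2L, inv, "*")
      }
      array(dx, d)
    }),
    list(p = gamma, fn = function(g) colSums(matrix(g, n, d[3]) * xh)),
    list(p = beta, fn = function(g) colSums(matrix(g, n, d[3])))))
}

#' Non-overlapping s x s average pooling
#' @keywords internal
tg_avgpool2d <- function(x, s) {
  vx <- tg_val(x)
  d <- dim(vx)
  if (d[1] %% s != 0L || d[2] %% s != 0L)
    stop("avgpool2d: spatial dims must be divisible by the pool size")
  Ho <- d[1] %/% s; Wo <- d[2] %/% s
  v5 <- array(vx, c(s, Ho, s, Wo, d[3]))
  vp <- aperm(v5, c(1, 3, 2, 4, 5))
  y <- array(colMeans(matrix(vp, s * s)), c(Ho, Wo, d[3]))
  tg_node(y, list(list(p = x, fn = function(g) {
    gs <- array(rep(as.vector(g) / (s * s), each = s * s), c(s, s, Ho, Wo, d[3]))
    array(aperm(gs, c(1, 3, 2, 4, 5)), d)
  })))
}

#' Max pooling (possibly overlapping windows)
#' @keywords internal
tg_maxpool2d <- function(x, k, stride, pad = 0L) {
  vx <- tg_val(x)
  d <- dim(vx)
  xp <- tg_pad_zero(vx, pad)
  if (pad > 0L) xp[xp == 0 & tg_pad_zero(array(1, d), pad) == 0] <- -Inf
  Hp <- d[1] + 2L * pad; Wp <- d[2] + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  idx1 <- tg_im2col_idx(Hp, Wp, 1L, k, stride, Ho, Wo)
  y <- array(0, c(Ho, Wo, d[3]))
  arg <- matrix(0L, Ho * Wo, d[3])
  for (ch in seq_len(d[3])) {
    idx <- idx1 + (ch - 1L) * Hp * Wp
    patch <- xp[idx]
    dim(patch) <- dim(idx)
    w <- max.col(t(patch), ties.method = "first")
    sel <- idx[cbind(w, seq_len(ncol(idx)))]
    arg[, ch] <- sel
    y[, , ch] <- patch[cbind(w, seq_len(ncol(idx)))]
  }
  tg_node(y, list(list(p = x, fn = function(g) {
    dxp <- numeric(Hp * Wp * d[3])
    acc <- rowsum(as.vector(g), group = as.vector(arg))
    ii <- as.integer(rownames(acc))
    dxp[ii] <- dxp[ii] + acc[, 1]
    dim(dxp) <- c(Hp, Wp, d[3])
    if (pad > 0L)
      dxp <- dxp[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), , drop = FALSE]
    dxp
  })))
}

# gather rows/columns of the spatial plane (used for nearest upsampling,
# reflect padding and cropping); backward scatter-adds
tg_gather_hw <- function(x, ri, ci) {
  vx <- tg_val(x)
  d <- dim(vx)
  y <- vx[ri, ci, , drop = FALSE]
  tg_node(y, list(list(p = x, fn = function(g) {
    lin_r <- rep(ri, times = length(ci))
    lin_c <- rep(ci, each = length(ri))
    base <- lin_r + (lin_c - 1L) * d[1]
    dx <- numeric(d[1] * d[2] * d[3])
    for (ch in seq_len(d[3])) {
      acc <- rowsum(as.vector(g[, , ch]), group = base)
      ii <- as.integer(rownames(acc)) + (ch - 1L) * d[1] * d[2]
      dx[ii] <- dx[ii] + acc[, 1]
    }
    dim(dx) <- d
    dx
  })))
}

tg_upsample2 <- function(x) {
  d <- dim(tg_val(x))
  tg_gather_hw(x, rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L))
}

# reflect-pad H and W up to multiples of s (no-op when already aligned)
tg_reflect_pad_to <- function(x, s) {
  d <- dim(tg_val(x))
  ph <- (s - d[1] %% s) %% s
  pw <- (s - d[2] %% s) %% s
  if (ph == 0L && pw == 0L) return(x)
  if (d[1] - 1L < ph || d[2] - 1L < pw)
    stop("reflect pad: map too small for window")
  ri <- c(seq_len(d[1]), d[1] - seq_len(ph))
  ci <- c(seq_len(d[2]), d[2] - seq_len(pw))
  tg_gather_hw(x, ri, ci)
}

tg_crop_hw <- function(x, H, W) {
  d <- dim(tg_val(x))
  if (d[1] == H && d[2] == W) return(x)
  tg_gather_hw(x, seq_len(H), seq_len(W))
}

# channel slice of an (H, W, C) map; backward zero-fills
t_chan <- function(x, idx) {
  vx <- tg_val(x)
  d <- dim(vx)
  y <- vx[, , idx, drop = FALSE]
  if (!is_tensor(x)) return(y)
  tg_node(y, list(list(p = x, fn = function(g) {
    dx <- array(0, d)
    dx[, , idx] <- g
    dx
  })))
}

# concatenate (H, W, Ci) maps along the channel axis
tg_concat_ch <- function(xs) {
  vs <- lapply(xs, tg_val)
  d1 <- dim(vs[[1]])
  ncs <- vapply(vs, function(v) dim(v)[3], integer(1))
  y <- array(0, c(d1[1], d1[2], sum(ncs)))
  at <- 0L
  for (i in seq_along(vs)) {
    y[, , at + seq_len(ncs[i])] <- vs[[i]]
    at <- at + ncs[i]
  }
  if (!any(vapply(xs, is_tensor, logical(1)))) return(y)
  ends <- cumsum(ncs)
  starts <- ends - ncs + 1L
  parents <- lapply(seq_along(xs), function(i) {
    a <- starts[i]; b <- ends[i]
    list(p = xs[[i]], fn = function(g) g[, , a:b, drop = FALSE])
  })
  tg_node(y, parents)
}
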