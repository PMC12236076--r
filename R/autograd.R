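# Minimal reverse-mode automatic differentiation over base-R arrays.
#
# A tensor is an environment holding a value `v`, an accumulated gradient `g`,
# and the list of parent edges `parents`, each edge carrying a vector-Jacobian
# product closure. Node ids increase in creation order, so creation order is a
# valid topological order of the tape and backward() simply walks ids downward.

.tg <- new.env(parent = emptyenv())
.tg$id <- 0L

tg_next_id <- function() {
  .tg$id <- .tg$id + 1L
  .tg$id
}

#' Create a tensor
#'
#' Wraps a numeric array/matrix/vector for use with the package's
#' reverse-mode autodiff core.
#'
#' @param v numeric array, matrix or vector.
#' @param rg logical; does this tensor require a gradient?
#' @return an object of class `nanotensor`.
#' @keywords internal
tg_tensor <- function(v, rg = FALSE) {
  t <- new.env(parent = emptyenv())
  t$v <- v
  t$g <- NULL
  t$parents <- NULL
  t$track <- isTRUE(rg)
  t$id <- tg_next_id()
  class(t) <- "nanotensor"
  t
}

is_tensor <- function(x) inherits(x, "nanotensor")

tg_val <- function(x) if (is_tensor(x)) x$v else x

# Build an interior node. `parents` is a list of list(p = tensor, fn = vjp).
tg_node <- function(v, parents) {
  keep <- NULL
  for (e in parents) {
    if (inherits(e$p, "nanotensor") && e$p$track)
      keep <- c(keep, list(e))
  }
  t <- tg_tensor(v, rg = FALSE)
  t$track <- length(keep) > 0L
  if (t$track) t$parents <- keep
  t
}

tg_accum <- function(p, g) {
  if (is.null(p$g)) p$g <- g else p$g <- p$g + g
  invisible(NULL)
}

#' Backpropagate from a scalar tensor
#' @keywords internal
tg_backward <- function(t) {
  stopifnot(is_tensor(t), length(t$v) == 1L)
  # collect reachable tracked nodes, marking visits with a per-call stamp
  stamp <- .tg$stamp <- (if (is.null(.tg$stamp)) 0L else .tg$stamp) + 1L
  nodes <- vector("list", 256L)
  n <- 0L
  stack <- list(t)
  while (length(stack)) {
    x <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (identical(x$vis, stamp)) next
    x$vis <- stamp
    n <- n + 1L
    if (n > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[n]] <- x
    for (e in x$parents) stack[[length(stack) + 1L]] <- e$p
  }
  nodes <- nodes[seq_len(n)]
  ord <- order(vapply(nodes, function(x) x$id, integer(1)), decreasing = TRUE)
  t$g <- 1
  for (x in nodes[ord]) {
    if (is.null(x$g) || is.null(x$parents)) next
    for (e in x$parents) tg_accum(e$p, e$fn(x$g))
  }
  invisible(t)
}

tg_zero_grad <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# --- elementwise arithmetic -------------------------------------------------

# keep dim attribute of a reference value
tg_shape_like <- function(g, ref) {
  if (!is.null(dim(ref))) dim(g) <- dim(ref)
  g
}

#' @export
Ops.nanotensor <- function(e1, e2) {
  op <- .Generic
  if (missing(e2)) { # unary
    v1 <- tg_val(e1)
    if (op == "-") {
      return(tg_node(-v1, list(list(p = e1, fn = function(g) -g))))
    } else if (op == "+") {
      return(e1)
    }
    stop("unsupported unary op for nanotensor: ", op)
  }
  v1 <- tg_val(e1); v2 <- tg_val(e2)
  l1 <- length(v1); l2 <- length(v2)
  if (!(l1 == l2 || l1 == 1L || l2 == 1L))
    stop("nanotensor Ops: shapes must match or one operand be scalar")
  red1 <- function(g) if (l1 == 1L && length(g) > 1L) sum(g) else g
  red2 <- function(g) if (l2 == 1L && length(g) > 1L) sum(g) else g
  switch(op,
    "+" = tg_node(v1 + v2, list(
      list(p = e1, fn = function(g) red1(g)),
      list(p = e2, fn = function(g) red2(g)))),
    "-" = tg_node(v1 - v2, list(
      list(p = e1, fn = function(g) red1(g)),
      list(p = e2, fn = function(g) red2(-g)))),
    "*" = tg_node(v1 * v2, list(
      list(p = e1, fn = function(g) red1(g * v2)),
      list(p = e2, fn = function(g) red2(g * v1)))),
    "/" = tg_node(v1 / v2, list(
      list(p = e1, fn = function(g) red1(g / v2)),
      list(p = e2, fn = function(g) red2(-g * v1 / (v2 * v2))))),
    "^" = {
      if (is_tensor(e2)) stop("nanotensor ^: exponent must be numeric")
      tg_node(v1^v2, list(list(p = e1, fn = function(g) g * v2 * v1^(v2 - 1))))
    },
    stop("unsupported op for nanotensor: ", op)
  )
}

t_exp <- function(x) {
  if (!is_tensor(x)) return(exp(x))
  y <- exp(x$v)
  tg_node(y, list(list(p = x, fn = function(g) g * y)))
}

t_log <- function(x) {
  if (!is_tensor(x)) return(log(x))
  tg_node(log(x$v), list(list(p = x, fn = function(g) g / x$v)))
}

t_sqrt <- function(x) {
  if (!is_tensor(x)) return(sqrt(x))
  y <- sqrt(x$v)
  tg_node(y, list(list(p = x, fn = function(g) g * 0.5 / y)))
}

t_sigmoid <- function(x) {
  if (!is_tensor(x)) return(1 / (1 + exp(-x)))
  y <- 1 / (1 + exp(-x$v))
  tg_node(y, list(list(p = x, fn = function(g) g * y * (1 - y))))
}

t_silu <- function(x) {
  if (!is_tensor(x)) return(x / (1 + exp(-x)))
  s <- 1 / (1 + exp(-x$v))
  y <- x$v * s
  tg_node(y, list(list(p = x, fn = function(g) g * (s * (1 + x$v * (1 - s))))))
}

t_relu <- function(x) {
  if (!is_tensor(x)) return(pmax(x, 0))
  m <- x$v > 0
  tg_node(x$v * m, list(list(p = x, fn = function(g) g * m)))
}

# clamp against a numeric bound (scalar or same shape)
t_pmax <- function(x, c) {
  if (!is_tensor(x)) return(pmax(x, c))
  m <- x$v >= c
  tg_node(pmax(x$v, c), list(list(p = x, fn = function(g) g * m)))
}

t_pmin <- function(x, c) {
  if (!is_tensor(x)) return(pmin(x, c))
  m <- x$v <= c
  tg_node(pmin(x$v, c), list(list(p = x, fn = function(g) g * m)))
}

# elementwise max/min of two tensors (ties routed to the first argument)
t_pmax2 <- function(a, b) {
  if (!is_tensor(a) && !is_tensor(b)) return(pmax(a, b))
  va <- tg_val(a); vb <- tg_val(b)
  m <- va >= vb
  tg_node(pmax(va, vb), list(
    list(p = a, fn = function(g) g * m),
    list(p = b, fn = function(g) g * !m)))
}

t_pmin2 <- function(a, b) {
  if (!is_tensor(a) && !is_tensor(b)) return(pmin(a, b))
  va <- tg_val(a); vb <- tg_val(b)
  m <- va <= vb
  tg_node(pmin(va, vb), list(
    list(p = a, fn = function(g) g * m),
    list(p = b, fn = function(g) g * !m)))
}

t_sum <- function(x) {
  if (!is_tensor(x)) return(sum(x))
  sh <- x$v
  tg_node(sum(x$v), list(list(p = x, fn = function(g) tg_shape_like(rep(g, length(sh)), sh))))
}

t_mean <- function(x) {
  if (!is_tensor(x)) return(mean(x))
  n <- length(x$v)
  sh <- x$v
  tg_node(mean(x$v), list(list(p = x, fn = function(g) tg_shape_like(rep(g / n, n), sh))))
}

t_abs <- function(x) {
  if (!is_tensor(x)) return(abs(x))
  s <- sign(x$v)
  tg_node(abs(x$v), list(list(p = x, fn = function(g) g * s)))
}

# stop-gradient
t_detach <- function(x) if (is_tensor(x)) x$v else x

# --- matrix / indexing ops --------------------------------------------------

tg_matmul <- function(a, b, transA = FALSE, transB = FALSE) {
  va <- tg_val(a); vb <- tg_val(b)
  A <- if (transA) t(va) else va
  B <- if (transB) t(vb) else vb
  y <- A %*% B
  if (!is_tensor(a) && !is_tensor(b)) return(y)
  tg_node(y, list(
    list(p = a, fn = function(g) {
      d <- g %*% t(B)
      if (transA) t(d) else d
    }),
    list(p = b, fn = function(g) {
      d <- t(A) %*% g
      if (transB) t(d) else d
    })))
}

# rows of a matrix (gather); backward scatter-adds
t_rows <- function(x, idx) {
  if (!is_tensor(x)) return(tg_val(x)[idx, , drop = FALSE])
  v <- x$v
  tg_node(v[idx, , drop = FALSE], list(list(p = x, fn = function(g) {
    d <- matrix(0, nrow(v), ncol(v))
    acc <- rowsum(g, group = idx)  # handles duplicated indices
    d[as.integer(rownames(acc)), ] <- acc
    d
  })))
}

t_cols <- function(x, idx) {
  if (!is_tensor(x)) return(tg_val(x)[, idx, drop = FALSE])
  v <- x$v
  tg_node(v[, idx, drop = FALSE], list(list(p = x, fn = function(g) {
    d <- matrix(0, nrow(v), ncol(v))
    d[, idx] <- g
    d
  })))
}

t_col <- function(x, j) {
  if (!is_tensor(x)) {
    v <- x
    if (is.null(dim(v))) stop("t_col expects a matrix")
    return(v[, j])
  }
  v <- x$v
  tg_node(v[, j], list(list(p = x, fn = function(g) {
    d <- matrix(0, nrow(v), ncol(v))
    d[, j] <- g
    d
  })))
}

tg_concat_cols <- function(xs) {
  vs <- lapply(xs, tg_val)
  y <- do.call(cbind, vs)
  if (!any(vapply(xs, is_tensor, logical(1)))) return(y)
  nc <- vapply(vs, function(v) if (is.null(dim(v))) 1L else ncol(v), integer(1))
  ends <- cumsum(nc)
  starts <- ends - nc + 1L
  parents <- lapply(seq_along(xs), function(i) {
    a <- starts[i]; b <- ends[i]
    vec <- is.null(dim(vs[[i]]))
    list(p = xs[[i]], fn = function(g) {
      d <- g[, a:b, drop = FALSE]
      if (vec) as.vector(d) else d
    })
  })
  tg_node(y, parents)
}

tg_concat_rows <- function(xs) {
  vs <- lapply(xs, tg_val)
  y <- do.call(rbind, vs)
  if (!any(vapply(xs, is_tensor, logical(1)))) return(y)
  nr <- vapply(vs, nrow, integer(1))
  ends <- cumsum(nr)
  starts <- ends - nr + 1L
  parents <- lapply(seq_along(xs), function(i) {
    a <- starts[i]; b <- ends[i]
    list(p = xs[[i]], fn = function(g) g[a:b, , drop = FALSE])
  })
  tg_node(y, parents)
}

t_reshape <- function(x, dims) {
  if (!is_tensor(x)) { dim(x) <- dims; return(x) }
  v <- x$v
  old <- dim(v)
  y <- v
  dim(y) <- dims
  tg_node(y, list(list(p = x, fn = function(g) { dim(g) <- old; g })))
}

t_aperm <- function(x, perm) {
  if (!is_tensor(x)) return(aperm(x, perm))
  inv <- order(perm)
  tg_node(aperm(x$v, perm), list(list(p = x, fn = function(g) aperm(g, inv))))
}

# add a row vector b (length = ncol(X)) to every row of X
t_addrow <- function(X, b) {
  vX <- tg_val(X); vb <- tg_val(b)
  y <- sweep(vX, 2L, vb, "+")
  if (!is_tensor(X) && !is_tensor(b)) return(y)
  tg_node(y, list(
    list(p = X, fn = function(g) g),
    list(p = b, fn = function(g) colSums(g))))
}

t_rowsums <- function(x) {
  if (!is_tensor(x)) return(rowSums(x))
  v <- x$v
  tg_node(rowSums(v), list(list(p = x, fn = function(g)
    matrix(g, nrow(v), ncol(v)))))
}

# multiply row i of X by s[i]
t_scale_rows <- function(X, s) {
  vX <- tg_val(X); vs <- tg_val(s)
  y <- vX * vs
  if (!is_tensor(X) && !is_tensor(s)) return(y)
  tg_node(y, list(
    list(p = X, fn = function(g) g * vs),
    list(p = s, fn = function(g) rowSums(g * vX))))
}

# row-wise softmax
t_softmax_rows <- function(x) {
  vx <- tg_val(x)
  m <- apply(vx, 1L, max)
  e <- exp(vx - m)
  y <- e / rowSums(e)
  if (!is_tensor(x)) return(y)
  tg_node(y, list(list(p = x, fn = function(g)
    (g - rowSums(g * y)) * y)))
}

# row-wise layer normalization with affine parameters
t_layernorm_rows <- function(x, gamma, beta, eps = 1e-5) {
  vx <- tg_val(x)
  mu <- rowMeans(vx)
  xc <- vx - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xh <- xc * inv
  y <- sweep(xh * tg_val(gamma)[col(xh)], 2L, tg_val(beta), "+")
  # y = xh * gamma (broadcast over rows) + beta
  d <- ncol(vx)
  tg_node(y, list(
    list(p = x, fn = function(g) {
      gg <- g * tg_val(gamma)[col(g)]
      # backward through normalization, per row
      (gg - rowMeans(gg) - xh * rowMeans(gg * xh)) * inv
    }),
    list(p = gamma, fn = function(g) colSums(g * xh)),
    list(p = beta, fn = function(g) colSums(g))))
}

# --- fused grouped multi-head attention -------------------------------------
# One tape node for a whole attention pass: rows of Q attend to rows of K/V
# within matched groups (windows, grid lines, or everything), per head, with
# an optional post-softmax multiplicative mask (renormalized). The backward
# pass for all three inputs is computed once and memoized.
tg_attention <- function(Q, K, V, heads, dh, q_groups = NULL,
                         kv_groups = NULL, masks = NULL) {
  vQ <- tg_val(Q); vK <- tg_val(K); vV <- tg_val(V)
  tq <- nrow(vQ)
  if (is.null(q_groups)) {
    q_groups <- list(seq_len(tq))
    kv_groups <- list(seq_len(nrow(vK)))
  }
  sc <- 1 / sqrt(dh)
  out <- matrix(0, tq, heads * dh)
  cache <- vector("list", length(q_groups))
  for (gi in seq_along(q_groups)) {
    qi <- q_groups[[gi]]; ki <- kv_groups[[gi]]
    hc <- vector("list", heads)
    for (h in seq_len(heads)) {
      cs <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(vQ[qi, cs, drop = FALSE], vK[ki, cs, drop = FALSE]) * sc
      E <- exp(S - S[cbind(seq_len(nrow(S)), max.col(S))])
      A0 <- E / rowSums(E)
      if (!is.null(masks)) {
        Am <- A0 * masks[[h]]
        rs <- rowSums(Am)
        A <- Am / rs
      } else {
        A <- A0
        rs <- NULL
      }
      out[qi, cs] <- A %*% vV[ki, cs, drop = FALSE]
      hc[[h]] <- list(A0 = A0, A = A, rs = rs)
    }
    cache[[gi]] <- hc
  }
  bw <- new.env(parent = emptyenv())
  ensure_bw <- function(g) {
    if (!is.null(bw$done) && identical(bw$g_id, g[1L] + length(g)))
      return(invisible(NULL))
    dQ <- matrix(0, nrow(vQ), ncol(vQ))
    dK <- matrix(0, nrow(vK), ncol(vK))
    dV <- matrix(0, nrow(vV), ncol(vV))
    for (gi in seq_along(q_groups)) {
      qi <- q_groups[[gi]]; ki <- kv_groups[[gi]]
      for (h in seq_len(heads)) {
        cs <- ((h - 1L) * dh + 1L):(h * dh)
        cc <- cache[[gi]][[h]]
        gO <- g[qi, cs, drop = FALSE]
        dV[ki, cs] <- dV[ki, cs] + crossprod(cc$A, gO)
        gA <- tcrossprod(gO, vV[ki, cs, drop = FALSE])
        if (!is.null(masks)) {
          drs <- -rowSums(gA * cc$A) / cc$rs
          dA0 <- (gA / cc$rs + drs) * masks[[h]]
        } else {
          dA0 <- gA
        }
        dS <- (dA0 - rowSums(dA0 * cc$A0)) * cc$A0
        dQ[qi, cs] <- dQ[qi, cs] + dS %*% vK[ki, cs, drop = FALSE] * sc
        dK[ki, cs] <- dK[ki, cs] + crossprod(dS, vQ[qi, cs, drop = FALSE]) * sc
      }
    }
    bw$dQ <- dQ; bw$dK <- dK; bw$dV <- dV
    bw$done <- TRUE
    bw$g_id <- g[1L] + length(g)
    invisible(NULL)
  }
  tg_node(out, list(
    list(p = Q, fn = function(g) { ensure_bw(g); bw$dQ }),
    list(p = K, fn = function(g) { ensure_bw(g); bw$dK }),
    list(p = V, fn = function(g) { ensure_bw(g); bw$dV })))
}
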