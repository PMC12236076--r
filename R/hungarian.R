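# Hungarian algorithm (Kuhn-Munkres with potentials, O(n^2 m)) for the
# bipartite matching between ground-truth boxes (rows) and object queries
# (columns). Requires nrow <= ncol.

#' Minimum-cost one-to-one assignment
#'
#' @param cost numeric matrix (n x m, n <= m).
#' @return integer vector of length n: the column assigned to each row.
#' @export
hungarian_assign <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L) return(integer(0))
  if (n > m) stop("hungarian_assign: need nrow <= ncol")
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)     # p[j+1]: row matched to column j (0 = free)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1L)
    used <- logical(m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j + 1L]) {
          minv[j + 1L] <- cur
          way[j + 1L] <- j0
        }
        if (minv[j + 1L] < delta) {
          delta <- minv[j + 1L]
          j1 <- j
        }
      }
      for (j in 0L:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}
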