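# Optimal one-to-one assignment (Hungarian algorithm, shortest augmenting
# path with potentials, O(n^3)). Used to match signatures to cluster
# centroids and extracted signatures to simulation truth. Written in-package
# because no linear sum assignment solver ships with the supported
# dependency set; verified against exhaustive permutation search in tests.

hungarian_min <- function(a) {
  n <- nrow(a); m <- ncol(a)
  stopifnot(n <= m, all(is.finite(a)))
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)    # p[j+1]: row matched to column j (0 = free)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- a[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
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

# score: n x m matrix; returns for each row the assigned column, maximizing
# (default) or minimizing the total score over one-to-one assignments of
# min(n, m) pairs
solve_assignment <- function(score, maximize = TRUE) {
  score <- as.matrix(score)
  cost <- if (maximize) max(score) - score else score
  if (nrow(cost) <= ncol(cost)) {
    hungarian_min(cost)
  } else {
    back <- hungarian_min(t(cost))  # columns -> rows
    ans <- integer(nrow(cost))
    ans[back] <- seq_along(back)
    ans
  }
}
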