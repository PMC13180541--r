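# Minimum-cost one-to-one assignment (Jonker-Volgenant style shortest
# augmenting paths). Used by set-prediction matching; no assignment solver
# is shipped with the environment's R packages, so this is self-contained.

#' Solve the rectangular linear assignment problem
#'
#' Finds the assignment of rows (workers) to columns (jobs) minimising the
#' total cost. With more rows than columns, some rows stay unassigned (0).
#'
#' @param cost numeric matrix (n x m), finite entries
#' @return integer vector of length n; `out[i]` is the column assigned to
#'   row i, or 0 if row i is unassigned
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  if (any(!is.finite(cost))) stop("assignment cost matrix has non-finite entries")
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(integer(n))
  # Augment over the smaller side; transpose when jobs outnumber workers.
  if (m <= n) {
    a <- .jv_assign(t(cost))      # assign each of m rows (jobs) to workers
    out <- integer(n)
    for (j in seq_len(m)) if (a[j] > 0L) out[a[j]] <- j
    out
  } else {
    a <- .jv_assign(cost)         # assign each of n rows to columns
    a
  }
}

# Shortest-augmenting-path assignment for an r x c cost matrix with r <= c.
# Returns for each row the assigned column index.
.jv_assign <- function(C) {
  r <- nrow(C); cc <- ncol(C)
  stopifnot(r <= cc)
  INF <- Inf
  u <- numeric(r + 1L)
  v <- numeric(cc + 1L)
  p <- integer(cc + 1L)           # p[j]: row matched to column j (0 = free)
  for (i in seq_len(r)) {
    p[cc + 1L] <- i
    j0 <- cc + 1L
    minv <- rep(INF, cc)
    used <- rep(FALSE, cc + 1L)
    way <- integer(cc)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(cc)) {
        if (!used[j]) {
          cur <- C[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(cc + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == cc + 1L) break
    }
  }
  out <- integer(r)
  for (j in seq_len(cc)) if (p[j] > 0L) out[p[j]] <- j
  out
}
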