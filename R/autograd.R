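# Reverse-mode tape engine over base-R arrays.
#
# Feature maps use the internal layout (H, W, B, C), which makes the
# (positions x channels) matrix view a free reshape; token blocks are
# (N, B, D); batched 3D tensors are (n, m, K) with K = heads*batch folded.
# Public entry points convert from the user-facing (B, C, H, W) convention
# at the boundary (see the helpers in tensor.R).

.ag_env <- new.env(parent = emptyenv())
.ag_env$epoch <- 0L
.ag_env$profile <- NULL
.ag_env$grad_enabled <- TRUE

# Evaluate an expression with gradient tracking disabled (inference mode).
ag_no_grad <- function(expr) {
  old <- .ag_env$grad_enabled
  .ag_env$grad_enabled <- FALSE
  on.exit(.ag_env$grad_enabled <- old)
  expr
}

.ag_new <- function(v, parents = NULL, bw = NULL) {
  track <- FALSE
  if (!is.null(parents) && .ag_env$grad_enabled) {
    for (p in parents) if (p$track) { track <- TRUE; break }
  }
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$g <- NULL
  if (track) {
    n$parents <- parents
    n$bw <- bw
  } else {
    n$parents <- NULL
    n$bw <- NULL
  }
  n$track <- track
  class(n) <- "ag_node"
  n
}

#' @keywords internal
ag_const <- function(x) .ag_new(if (is.null(dim(x))) x else x)

#' Create a trainable leaf node
#' @keywords internal
ag_param <- function(x) {
  n <- .ag_new(x)
  n$track <- TRUE
  n
}

as_node <- function(x) if (inherits(x, "ag_node")) x else ag_const(x)

ag_value <- function(x) if (inherits(x, "ag_node")) x$v else x

#' Zero the stored gradient of a leaf node
#' @keywords internal
ag_zero_grad <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# MAC profiling hooks -----------------------------------------------------

ag_profile_start <- function() {
  .ag_env$profile <- new.env(parent = emptyenv())
  .ag_env$profile$macs <- 0
  invisible(NULL)
}

ag_profile_stop <- function() {
  macs <- if (is.null(.ag_env$profile)) 0 else .ag_env$profile$macs
  .ag_env$profile <- NULL
  macs
}

.ag_count_macs <- function(n) {
  pr <- .ag_env$profile
  if (!is.null(pr)) pr$macs <- pr$macs + n
  invisible(NULL)
}

# Backward pass ------------------------------------------------------------

.ag_accum <- function(p, g) {
  if (is.null(p$g)) p$g <- g else p$g <- p$g + g
  invisible(NULL)
}

#' Backpropagate from a root node
#'
#' Accumulates gradients into every tracked ancestor's `$g` slot.
#' @param root an `ag_node`
#' @param grad seed gradient (defaults to ones of the root's shape)
#' @keywords internal
ag_backward <- function(root, grad = NULL) {
  if (!root$track) return(invisible(NULL))
  if (is.null(grad)) {
    grad <- root$v
    grad[] <- 1
  }
  epoch <- .ag_env$epoch <- .ag_env$epoch + 1L
  # iterative post-order DFS over tracked nodes
  topo <- vector("list", 1024L)
  nt <- 0L
  stack_node <- vector("list", 1024L)
  stack_idx <- integer(1024L)
  sp <- 1L
  stack_node[[1L]] <- root
  stack_idx[1L] <- 0L
  root$.epoch <- epoch
  while (sp > 0L) {
    nd <- stack_node[[sp]]
    i <- stack_idx[sp] + 1L
    ps <- nd$parents
    if (!is.null(ps) && i <= length(ps)) {
      stack_idx[sp] <- i
      p <- ps[[i]]
      if (p$track && !identical(p$.epoch, epoch)) {
        p$.epoch <- epoch
        sp <- sp + 1L
        if (sp > length(stack_node)) {
          length(stack_node) <- 2L * sp
          length(stack_idx) <- 2L * sp
        }
        stack_node[[sp]] <- p
        stack_idx[sp] <- 0L
      }
    } else {
      nt <- nt + 1L
      if (nt > length(topo)) length(topo) <- 2L * nt
      topo[[nt]] <- nd
      stack_node[sp] <- list(NULL)
      sp <- sp - 1L
    }
  }
  root$g <- if (is.null(root$g)) grad else root$g + grad
  for (k in seq(nt, 1L)) {
    nd <- topo[[k]]
    if (is.null(nd$bw) || is.null(nd$g)) next
    gs <- nd$bw(nd$g)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      if (ps[[j]]$track && !is.null(gs[[j]])) .ag_accum(ps[[j]], gs[[j]])
    }
    if (!identical(nd, root) && is.null(nd$keep_grad)) nd$g <- NULL
  }
  invisible(NULL)
}

# Elementwise arithmetic ----------------------------------------------------

.ag_same_or_scalar <- function(a, b) {
  length(b) == 1L || identical(dim(a), dim(b)) ||
    (is.null(dim(a)) && is.null(dim(b)) && length(a) == length(b))
}

ag_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  stopifnot(.ag_same_or_scalar(a$v, b$v) || .ag_same_or_scalar(b$v, a$v))
  .ag_new(a$v + b$v, list(a, b), function(g) {
    ga <- if (length(a$v) == 1L && length(g) > 1L) sum(g) else g
    gb <- if (length(b$v) == 1L && length(g) > 1L) sum(g) else g
    list(ga, gb)
  })
}

ag_sub <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  .ag_new(a$v - b$v, list(a, b), function(g) {
    ga <- if (length(a$v) == 1L && length(g) > 1L) sum(g) else g
    gb <- if (length(b$v) == 1L && length(g) > 1L) -sum(g) else -g
    list(ga, gb)
  })
}

ag_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$v; bv <- b$v
  .ag_new(av * bv, list(a, b), function(g) {
    ga <- g * bv
    gb <- g * av
    if (length(av) == 1L && length(g) > 1L) ga <- sum(ga)
    if (length(bv) == 1L && length(g) > 1L) gb <- sum(gb)
    list(ga, gb)
  })
}

ag_scale <- function(a, s) {
  a <- as_node(a)
  .ag_new(a$v * s, list(a), function(g) list(g * s))
}

ag_add_const <- function(a, c) {
  a <- as_node(a)
  .ag_new(a$v + c, list(a), function(g) list(g))
}

ag_neg <- function(a) ag_scale(a, -1)

# Broadcast a row-vector (length C) across the columns of an (N, C) matrix.
ag_add_colvec <- function(x, b) {
  x <- as_node(x); b <- as_node(b)
  n <- nrow(x$v)
  stopifnot(ncol(x$v) == length(b$v))
  .ag_new(x$v + rep(b$v, each = n), list(x, b), function(g) {
    list(g, colSums(g))
  })
}

ag_mul_colvec <- function(x, b) {
  x <- as_node(x); b <- as_node(b)
  n <- nrow(x$v)
  xv <- x$v; bv <- b$v
  stopifnot(ncol(xv) == length(bv))
  .ag_new(xv * rep(bv, each = n), list(x, b), function(g) {
    list(g * rep(bv, each = n), colSums(g * xv))
  })
}

# Multiply an (N, C) matrix by a per-row column vector (length N).
ag_mul_rowvec <- function(x, r) {
  x <- as_node(x); r <- as_node(r)
  xv <- x$v; rv <- as.vector(r$v)
  stopifnot(nrow(xv) == length(rv))
  .ag_new(xv * rv, list(x, r), function(g) {
    list(g * rv, rowSums(g * xv))
  })
}

# Activations (fused nodes) -------------------------------------------------

ag_sigmoid <- function(x) {
  x <- as_node(x)
  y <- 1 / (1 + exp(-x$v))
  .ag_new(y, list(x), function(g) list(g * y * (1 - y)))
}

ag_relu <- function(x) {
  x <- as_node(x)
  y <- pmax(x$v, 0)
  if (!is.null(dim(x$v))) dim(y) <- dim(x$v)
  .ag_new(y, list(x), function(g) list(g * (x$v > 0)))
}

ag_silu <- function(x) {
  x <- as_node(x)
  s <- 1 / (1 + exp(-x$v))
  y <- x$v * s
  .ag_new(y, list(x), function(g) list(g * (s + y * (1 - s))))
}

ag_gelu <- function(x) {
  x <- as_node(x)
  xv <- x$v
  ph <- stats::pnorm(xv)
  y <- xv * ph
  .ag_new(y, list(x), function(g) list(g * (ph + xv * stats::dnorm(xv))))
}

# Positive kernel map phi(x) = ELU(x) + 1
ag_elu1 <- function(x) {
  x <- as_node(x)
  xv <- x$v
  neg <- xv < 0
  y <- xv + 1
  y[neg] <- exp(xv[neg])
  if (!is.null(dim(xv))) dim(y) <- dim(xv)
  .ag_new(y, list(x), function(g) {
    d <- xv
    d[] <- 1
    d[neg] <- y[neg]       # exp(x) for x < 0
    list(g * d)
  })
}

ag_exp <- function(x) {
  x <- as_node(x)
  y <- exp(x$v)
  .ag_new(y, list(x), function(g) list(g * y))
}

ag_log <- function(x) {
  x <- as_node(x)
  .ag_new(log(x$v), list(x), function(g) list(g / x$v))
}

ag_abs <- function(x) {
  x <- as_node(x)
  .ag_new(abs(x$v), list(x), function(g) list(g * sign(x$v)))
}

ag_pow_const <- function(x, p) {
  x <- as_node(x)
  .ag_new(x$v^p, list(x), function(g) list(g * p * x$v^(p - 1)))
}

ag_recip <- function(x) {
  x <- as_node(x)
  y <- 1 / x$v
  .ag_new(y, list(x), function(g) list(-g * y * y))
}

ag_clamp <- function(x, lo, hi) {
  x <- as_node(x)
  y <- pmin(pmax(x$v, lo), hi)
  if (!is.null(dim(x$v))) dim(y) <- dim(x$v)
  .ag_new(y, list(x), function(g) list(g * (x$v > lo & x$v < hi)))
}

# Elementwise max of two same-shape tensors (gradient follows the winner;
# ties split evenly so the map stays sub-differentiable and symmetric).
ag_pmax2 <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$v; bv <- b$v
  y <- pmax(av, bv)
  if (!is.null(dim(av))) dim(y) <- dim(av)
  .ag_new(y, list(a, b), function(g) {
    wa <- (av > bv) + 0.5 * (av == bv)
    list(g * wa, g * (1 - wa))
  })
}

ag_pmin2 <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$v; bv <- b$v
  y <- pmin(av, bv)
  if (!is.null(dim(av))) dim(y) <- dim(av)
  .ag_new(y, list(a, b), function(g) {
    wa <- (av < bv) + 0.5 * (av == bv)
    list(g * wa, g * (1 - wa))
  })
}

# Reductions ---------------------------------------------------------------

ag_sum <- function(x) {
  x <- as_node(x)
  .ag_new(sum(x$v), list(x), function(g) {
    gg <- x$v
    gg[] <- as.numeric(g)
    list(gg)
  })
}

ag_mean <- function(x) {
  x <- as_node(x)
  n <- length(x$v)
  .ag_new(mean(x$v), list(x), function(g) {
    gg <- x$v
    gg[] <- as.numeric(g) / n
    list(gg)
  })
}

# Column means of an (N, C) matrix -> length-C vector (kept as 1 x C matrix).
ag_colmeans <- function(x) {
  x <- as_node(x)
  n <- nrow(x$v)
  .ag_new(matrix(colMeans(x$v), 1L), list(x), function(g) {
    list(matrix(rep(as.vector(g) / n, each = n), n))
  })
}

ag_rowsums <- function(x) {
  x <- as_node(x)
  m <- ncol(x$v)
  .ag_new(rowSums(x$v), list(x), function(g) {
    list(matrix(rep(as.vector(g), m), ncol = m))
  })
}

# Structural ops ------------------------------------------------------------

ag_reshape <- function(x, dims) {
  x <- as_node(x)
  od <- dim(x$v)
  v <- x$v
  dim(v) <- dims
  .ag_new(v, list(x), function(g) {
    dim(g) <- od
    list(g)
  })
}

ag_aperm <- function(x, perm) {
  x <- as_node(x)
  inv <- order(perm)
  .ag_new(aperm(x$v, perm), list(x), function(g) list(aperm(g, inv)))
}

# Concatenate feature maps (H, W, B, C) along the channel axis (dim 4).
ag_concat_ch <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  da <- dim(a$v); db <- dim(b$v)
  stopifnot(length(da) == 4L, all(da[1:3] == db[1:3]))
  # channel is the slowest-varying dim, so this is a flat copy
  v <- c(a$v, b$v)
  dim(v) <- c(da[1], da[2], da[3], da[4] + db[4])
  na <- length(a$v)
  .ag_new(v, list(a, b), function(g) {
    ga <- g[seq_len(na)]
    dim(ga) <- da
    gb <- g[na + seq_len(length(g) - na)]
    dim(gb) <- db
    list(ga, gb)
  })
}

ag_slice_ch <- function(x, idx) {
  x <- as_node(x)
  d <- dim(x$v)
  .ag_new(x$v[, , , idx, drop = FALSE], list(x), function(g) {
    gg <- array(0, d)
    gg[, , , idx] <- g
    list(gg)
  })
}

# Gather rows of an (N, C) matrix (used by query selection and matching).
ag_take_rows <- function(x, idx) {
  x <- as_node(x)
  d <- dim(x$v)
  .ag_new(x$v[idx, , drop = FALSE], list(x), function(g) {
    gg <- matrix(0, d[1], d[2])
    # accumulate in case of duplicated indices
    for (k in seq_along(idx)) gg[idx[k], ] <- gg[idx[k], ] + g[k, ]
    list(gg)
  })
}

# Nearest-neighbour 2x upsampling of (H, W, B, C).
ag_upsample2x <- function(x) {
  x <- as_node(x)
  d <- dim(x$v)
  ri <- rep(seq_len(d[1]), each = 2L)
  ci <- rep(seq_len(d[2]), each = 2L)
  .ag_new(x$v[ri, ci, , , drop = FALSE], list(x), function(g) {
    H2 <- 2L * d[1]
    g1 <- g[seq(1L, H2, 2L), , , , drop = FALSE] +
          g[seq(2L, H2, 2L), , , , drop = FALSE]
    W2 <- 2L * d[2]
    list(g1[, seq(1L, W2, 2L), , , drop = FALSE] +
         g1[, seq(2L, W2, 2L), , , drop = FALSE])
  })
}

# Concatenate 3D arrays (n_i, m, K) along dim 1.
ag_concat_rows <- function(nodes) {
  nodes <- lapply(nodes, as_node)
  ds <- lapply(nodes, function(n) dim(n$v))
  ns <- vapply(ds, `[`, 0, 1L)
  m <- ds[[1]][2]; K <- ds[[1]][3]
  v <- array(0, c(sum(ns), m, K))
  off <- 0L
  for (i in seq_along(nodes)) {
    v[off + seq_len(ns[i]), , ] <- nodes[[i]]$v
    off <- off + ns[i]
  }
  .ag_new(v, nodes, function(g) {
    out <- vector("list", length(nodes))
    off <- 0L
    for (i in seq_along(nodes)) {
      out[[i]] <- g[off + seq_len(ns[i]), , , drop = FALSE]
      off <- off + ns[i]
    }
    out
  })
}

# Extract batch slice b of a token node (n, B, m) as an (n, m) matrix.
ag_slice_batch <- function(x, b) {
  x <- as_node(x)
  d <- dim(x$v)
  v <- x$v[, b, , drop = FALSE]
  dim(v) <- d[c(1, 3)]
  .ag_new(v, list(x), function(g) {
    gg <- array(0, d)
    gg[, b, ] <- g
    list(gg)
  })
}

# Stack a list of (n, m) matrices into a token node (n, B, m).
ag_stack_batch <- function(nodes) {
  nodes <- lapply(nodes, as_node)
  d <- dim(nodes[[1]]$v)
  B <- length(nodes)
  v <- array(0, c(d[1], B, d[2]))
  for (b in seq_len(B)) v[, b, ] <- nodes[[b]]$v
  .ag_new(v, nodes, function(g) {
    lapply(seq_len(B), function(b) {
      gb <- g[, b, , drop = FALSE]
      dim(gb) <- d
      gb
    })
  })
}

# Broadcast-add a (1, D) node across rows and batch of an (N, B, D) node.
ag_add_rowvec3 <- function(x, r) {
  x <- as_node(x); r <- as_node(r)
  d <- dim(x$v)
  rv <- as.vector(r$v)
  stopifnot(length(rv) == d[3])
  add <- rep(rv, each = d[1] * d[2])
  .ag_new(x$v + add, list(x, r), function(g) {
    gm <- g
    dim(gm) <- c(d[1] * d[2], d[3])
    list(g, matrix(colSums(gm), 1L))
  })
}

# Row-wise maximum of an (N, M) matrix -> length-N vector; gradient goes to
# the (first) argmax entry of each row.
ag_rowmax <- function(x) {
  x <- as_node(x)
  xv <- x$v
  idx <- max.col(xv, ties.method = "first")
  v <- xv[cbind(seq_len(nrow(xv)), idx)]
  .ag_new(v, list(x), function(g) {
    gg <- matrix(0, nrow(xv), ncol(xv))
    gg[cbind(seq_len(nrow(xv)), idx)] <- g
    list(gg)
  })
}

# Matrix products -----------------------------------------------------------

ag_matmul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$v; bv <- b$v
  .ag_count_macs(nrow(av) * ncol(av) * ncol(bv))
  .ag_new(av %*% bv, list(a, b), function(g) {
    list(if (a$track) tcrossprod(g, bv) else NULL,
         if (b$track) crossprod(av, g) else NULL)
  })
}

# Batched matmul: (n, m, K) x (m, p, K) -> (n, p, K); the loop lives inside
# one node so large attention stacks stay cheap on the tape.
ag_bmm <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$v; bv <- b$v
  da <- dim(av); db <- dim(bv)
  stopifnot(length(da) == 3L, length(db) == 3L, da[2] == db[1], da[3] == db[3])
  K <- da[3]
  .ag_count_macs(da[1] * da[2] * db[2] * K)
  v <- array(0, c(da[1], db[2], K))
  for (k in seq_len(K)) {
    v[, , k] <- matrix(av[, , k], da[1], da[2]) %*%
      matrix(bv[, , k], db[1], db[2])
  }
  .ag_new(v, list(a, b), function(g) {
    ga <- if (a$track) array(0, da) else NULL
    gb <- if (b$track) array(0, db) else NULL
    for (k in seq_len(K)) {
      gk <- matrix(g[, , k], da[1], db[2])
      if (a$track) {
        ga[, , k] <- tcrossprod(gk, matrix(bv[, , k], db[1], db[2]))
      }
      if (b$track) {
        gb[, , k] <- crossprod(matrix(av[, , k], da[1], da[2]), gk)
      }
    }
    list(ga, gb)
  })
}

ag_transpose <- function(x) {
  x <- as_node(x)
  .ag_new(t(x$v), list(x), function(g) list(t(g)))
}

# Batched transpose of (n, m, K) -> (m, n, K).
ag_btranspose <- function(x) ag_aperm(x, c(2L, 1L, 3L))

# Softmax across columns, per row; works on (N, M) or batched (N, M, K).
ag_softmax_rows <- function(x) {
  x <- as_node(x)
  xv <- x$v
  d <- dim(xv)
  soft <- function(m) {
    mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
    e <- exp(m - mx)
    e / rowSums(e)
  }
  if (length(d) == 3L) {
    y <- xv
    for (k in seq_len(d[3])) y[, , k] <- soft(matrix(xv[, , k], d[1], d[2]))
  } else {
    y <- soft(xv)
  }
  .ag_new(y, list(x), function(g) {
    if (length(d) == 3L) {
      gg <- g
      for (k in seq_len(d[3])) {
        yk <- matrix(y[, , k], d[1], d[2])
        gk <- matrix(g[, , k], d[1], d[2])
        gg[, , k] <- yk * (gk - rowSums(gk * yk))
      }
      list(gg)
    } else {
      list(y * (g - rowSums(g * y)))
    }
  })
}

# Layer normalization across columns of an (N, C) matrix, affine.
ag_layernorm_cols <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  xv <- x$v
  n <- nrow(xv); C <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  gv <- as.vector(gamma$v); bv <- as.vector(beta$v)
  y <- xhat * rep(gv, each = n) + rep(bv, each = n)
  .ag_new(y, list(x, gamma, beta), function(g) {
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxhat <- g * rep(gv, each = n)
    dx <- istd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    list(dx, dgamma, dbeta)
  })
}

# Batch normalization of (H, W, B, C) per channel; train mode uses batch
# statistics (and updates `state`, an environment with running_mean/var).
ag_batchnorm <- function(x, gamma, beta, state, training = FALSE,
                         eps = 1e-5, momentum = 0.1) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  xv <- x$v
  d <- dim(xv)
  C <- d[4]
  n <- d[1] * d[2] * d[3]
  xm <- xv
  dim(xm) <- c(n, C)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm * xm) - mu * mu
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var +
      momentum * va * n / max(n - 1, 1)
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (xm - rep(mu, each = n)) * rep(istd, each = n)
  gv <- as.vector(gamma$v); bvv <- as.vector(beta$v)
  y <- xhat * rep(gv, each = n) + rep(bvv, each = n)
  dim(y) <- d
  .ag_new(y, list(x, gamma, beta), function(g) {
    gm <- g
    dim(gm) <- c(n, C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxhat <- gm * rep(gv, each = n)
    if (training) {
      dx <- rep(istd, each = n) *
        (dxhat - rep(colMeans(dxhat), each = n) -
           xhat * rep(colMeans(dxhat * xhat), each = n))
    } else {
      dx <- dxhat * rep(istd, each = n)
    }
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

# Convolutions --------------------------------------------------------------

.ag_pad_hw <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

# Patch-index matrix for im2col on a padded (Hp, Wp, B, C) block.
# Rows are ordered (i, j, b) with i fastest; columns (di, dj, c).
.ag_im2col_idx <- function(Hp, Wp, B, C, kh, kw, stride) {
  Ho <- (Hp - kh) %/% stride + 1L
  Wo <- (Wp - kw) %/% stride + 1L
  i0 <- rep(seq(1L, by = stride, length.out = Ho), Wo)
  j0 <- rep(seq(1L, by = stride, length.out = Wo), each = Ho)
  base <- i0 + (j0 - 1L) * Hp                 # length Ho*Wo
  base <- as.vector(outer(base, (seq_len(B) - 1L) * (Hp * Wp), `+`))
  di <- rep(seq_len(kh) - 1L, kw)
  dj <- rep(seq_len(kw) - 1L, each = kh)
  off <- di + dj * Hp                          # length kh*kw
  offc <- as.vector(outer(off, (seq_len(C) - 1L) * (Hp * Wp * B), `+`))
  idx <- outer(base, offc, `+`)                # (Ho*Wo*B) x (kh*kw*C)
  list(idx = idx, Ho = Ho, Wo = Wo)
}

# Full convolution: x (H, W, B, Cin), w (kh, kw, Cin, Cout), b length Cout.
ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  x <- as_node(x); w <- as_node(w)
  if (!is.null(b)) b <- as_node(b)
  xv <- x$v; wv <- w$v
  d <- dim(xv); dw <- dim(wv)
  stopifnot(d[4] == dw[3])
  kh <- dw[1]; kw <- dw[2]; Cin <- dw[3]; Cout <- dw[4]
  B <- d[3]
  xp <- .ag_pad_hw(xv, pad)
  dp <- dim(xp)
  ii <- .ag_im2col_idx(dp[1], dp[2], B, Cin, kh, kw, stride)
  Ho <- ii$Ho; Wo <- ii$Wo
  np <- Ho * Wo
  ncol_p <- kh * kw * Cin
  P <- xp[ii$idx]
  dim(P) <- c(np * B, ncol_p)
  Wm <- wv
  dim(Wm) <- c(ncol_p, Cout)
  .ag_count_macs(np * B * ncol_p * Cout)
  Y <- P %*% Wm
  if (!is.null(b)) Y <- Y + rep(as.vector(b$v), each = np * B)
  dim(Y) <- c(Ho, Wo, B, Cout)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  .ag_new(Y, parents, function(g) {
    gm <- g
    dim(gm) <- c(np * B, Cout)
    dW <- NULL
    if (w$track) {
      dW <- crossprod(P, gm)
      dim(dW) <- c(kh, kw, Cin, Cout)
    }
    db <- if (is.null(b) || !b$track) NULL else colSums(gm)
    dx <- NULL
    if (x$track) {
      # col2im scatter-add; within one patch column all indices are distinct
      dP <- tcrossprod(gm, Wm)                      # (np*B, ncol_p)
      dxp <- numeric(prod(dp))
      for (j in seq_len(ncol_p)) {
        ij <- ii$idx[, j]
        dxp[ij] <- dxp[ij] + dP[, j]
      }
      dim(dxp) <- dp
      dx <- if (pad > 0L) {
        dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE]
      } else {
        dxp
      }
    }
    out <- list(dx, dW)
    if (!is.null(b)) out <- c(out, list(db))
    out
  })
}

# Depthwise convolution: x (H, W, B, C), w (kh, kw, C); stride 1,
# "same" padding. Implemented as a sum over kernel taps with per-channel
# scalar weights, which keeps the whole op one tape node.
ag_dwconv2d <- function(x, w, pad = NULL) {
  x <- as_node(x); w <- as_node(w)
  xv <- x$v; wv <- w$v
  d <- dim(xv); dw <- dim(wv)
  stopifnot(d[4] == dw[3])
  kh <- dw[1]; kw <- dw[2]; C <- d[4]; B <- d[3]
  if (is.null(pad)) pad <- (kh - 1L) %/% 2L
  xp <- .ag_pad_hw(xv, pad)
  H <- d[1]; W <- d[2]
  hwb <- H * W * B
  .ag_count_macs(H * W * kh * kw * C * B)
  y <- array(0, d)
  for (dj in seq_len(kw)) {
    for (di in seq_len(kh)) {
      xs <- xp[di:(di + H - 1L), dj:(dj + W - 1L), , , drop = FALSE]
      wt <- rep(wv[di, dj, ], each = hwb)
      y <- y + xs * wt
    }
  }
  .ag_new(y, list(x, w), function(g) {
    dW <- if (w$track) array(0, dw) else NULL
    dxp <- if (x$track) array(0, dim(xp)) else NULL
    for (dj in seq_len(kw)) {
      for (di in seq_len(kh)) {
        if (w$track) {
          xs <- xp[di:(di + H - 1L), dj:(dj + W - 1L), , , drop = FALSE]
          pr <- g * xs
          dim(pr) <- c(hwb, C)
          dW[di, dj, ] <- colSums(pr)
        }
        if (x$track) {
          wt <- rep(wv[di, dj, ], each = hwb)
          dxp[di:(di + H - 1L), dj:(dj + W - 1L), , ] <-
            dxp[di:(di + H - 1L), dj:(dj + W - 1L), , , drop = FALSE] + g * wt
        }
      }
    }
    dx <- NULL
    if (x$track) {
      dx <- if (pad > 0L) {
        dxp[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
      } else {
        dxp
      }
    }
    list(dx, dW)
  })
}

# Pointwise (1x1) convolution on (H, W, B, C) via a single matmul; the
# reshape to an (HWB, C) matrix is free in this layout.
ag_conv1x1 <- function(x, w, b = NULL) {
  x <- as_node(x); w <- as_node(w)
  if (!is.null(b)) b <- as_node(b)
  xv <- x$v
  d <- dim(xv)
  Cin <- d[4]
  wv <- w$v
  if (length(dim(wv)) == 4L) dim(wv) <- c(Cin, dim(wv)[4])
  Cout <- ncol(wv)
  n <- d[1] * d[2] * d[3]
  xm <- xv
  dim(xm) <- c(n, Cin)
  .ag_count_macs(n * Cin * Cout)
  ym <- xm %*% wv
  if (!is.null(b)) ym <- ym + rep(as.vector(b$v), each = n)
  dim(ym) <- c(d[1], d[2], d[3], Cout)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  .ag_new(ym, parents, function(g) {
    gm <- g
    dim(gm) <- c(n, Cout)
    dW <- NULL
    if (w$track) {
      dW <- crossprod(xm, gm)
      if (length(dim(w$v)) == 4L) dim(dW) <- dim(w$v)
    }
    db <- if (is.null(b) || !b$track) NULL else colSums(gm)
    dx <- NULL
    if (x$track) {
      dx <- tcrossprod(gm, wv)
      dim(dx) <- d
    }
    out <- list(dx, dW)
    if (!is.null(b)) out <- c(out, list(db))
    out
  })
}

# Optimizer -----------------------------------------------------------------

#' AdamW optimizer state for a named list of leaf nodes
#' @keywords internal
adamw_init <- function(params) {
  st <- list(m = lapply(params, function(p) { z <- p$v; z[] <- 0; z }),
             v = lapply(params, function(p) { z <- p$v; z[] <- 0; z }),
             t = 0L)
  st
}

#' One AdamW step; decoupled weight decay
#' @keywords internal
adamw_step <- function(params, state, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 1e-4, clip = 5) {
  state$t <- state$t + 1L
  # global gradient-norm clipping
  sq <- 0
  for (p in params) if (!is.null(p$g)) sq <- sq + sum(p$g^2)
  gn <- sqrt(sq)
  sc <- if (is.finite(gn) && gn > clip) clip / gn else 1
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$g)) next
    g <- p$g * sc
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mh <- state$m[[nm]] / b1t
    vh <- state$v[[nm]] / b2t
    p$v <- p$v - lr * (mh / (sqrt(vh) + eps) + weight_decay * p$v)
  }
  ag_zero_grad(params)
  state
}
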