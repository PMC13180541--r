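# Shared helpers: numeric differentiation, tiny model configs, and a
# brute-force reference for the magnitude-aware attention core.

# Make package internals (tape ops, nn_* building blocks) visible to the
# tests regardless of whether the package is loaded via load_all or
# installed: the white-box tests probe the engine directly.
local({
  ns <- asNamespace("mridetr")
  for (nm in ls(ns, all.names = TRUE)) {
    obj <- get(nm, envir = ns)
    if (is.function(obj) && !exists(nm, envir = parent.env(environment()),
                                    inherits = FALSE)) {
      assign(nm, obj, envir = parent.env(environment()))
    }
  }
})

num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Smallest model configuration that exercises every code path quickly.
tiny_model_config <- function(backbone = "cspmambaout",
                              intra_scale = "aifi_mala",
                              aggregation = "retblockc3", seed = 0L,
                              num_queries = 10L) {
  model_config(backbone = backbone, intra_scale = intra_scale,
               aggregation = aggregation, hidden_dim = 16L, num_heads = 2L,
               num_queries = num_queries, decoder_layers = 1L,
               num_classes = 4L, image_size = 96L,
               widths = c(8L, 16L, 24L, 32L), depths = c(1L, 1L, 1L, 1L),
               n_ret = 1L, repc3_depth = 1L, seed = seed)
}

# Triple-loop reference implementation of the magnitude-aware linear
# attention core (Eq.-level oracle, one head): Q, K, V are (N, d) matrices
# of already RoPE-rotated queries/keys.
mala_core_loop_ref <- function(Qr, Kr, V, eps) {
  phi <- function(m) ifelse(m < 0, exp(m), m + 1)
  N <- nrow(Qr); d <- ncol(Qr)
  pQ <- phi(Qr); pK <- phi(Kr)
  Kbar <- colMeans(pK)
  Vbar <- colMeans(V)
  out <- matrix(0, N, d)
  for (n in seq_len(N)) {
    z <- sum(pQ[n, ] * Kbar)
    acc <- numeric(d)
    for (m in seq_len(N)) {
      acc <- acc + sum(pQ[n, ] * pK[m, ]) * V[m, ]
    }
    out[n, ] <- acc * (1 + 1 / (z + eps)) - z * Vbar
  }
  out
}

# Per-query loop oracle for full Manhattan self-attention (one head).
masa_full_loop_ref <- function(Qm, Km, Vm, D) {
  N <- nrow(Qm); d <- ncol(Qm)
  out <- matrix(0, N, d)
  for (n in seq_len(N)) {
    s <- as.vector(Qm[n, ] %*% t(Km)) / sqrt(d)
    a <- exp(s - max(s)); a <- a / sum(a)
    a <- a * D[n, ]
    out[n, ] <- as.vector(a %*% Vm)
  }
  out
}

# Grid helpers: public (C, H, W) array filled from a token matrix whose
# rows follow row-major (r*W + c) order.
grid_from_tokens <- function(tok, C, H, W) {
  a <- array(0, c(C, H, W))
  n <- 1L
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    a[, r, cc] <- tok[n, ]
    n <- n + 1L
  }
  a
}

tokens_from_grid <- function(a) {
  C <- dim(a)[1]; H <- dim(a)[2]; W <- dim(a)[3]
  tok <- matrix(0, H * W, C)
  n <- 1L
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    tok[n, ] <- a[, r, cc]
    n <- n + 1L
  }
  tok
}
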