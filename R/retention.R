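# Spatial retention aggregation: full and decomposed Manhattan
# self-attention (softmax attention elementwise-masked by gamma^d, d the
# Manhattan distance; rows are NOT renormalised after masking), local
# context enhancement, the RetBlock transformer unit, the dual-path
# RetBlockC3 wrapper, and the RepC3 baseline it replaces.

# Full MaSA on token nodes (N, d, K) with constant mask (N, N[, K]).
nn_masa_full_tok <- function(Q, K, V, mask) {
  dh <- dim(ag_value(Q))[2]
  A <- ag_softmax_rows(ag_scale(ag_bmm(Q, ag_btranspose(K)), 1 / sqrt(dh)))
  A <- ag_mul_bcast(A, mask)
  ag_bmm(A, V)
}

# Elementwise product with a constant mask; the mask recycles over trailing
# batch slices (column-major layout makes this exact).
ag_mul_bcast <- function(a, mask) {
  a <- as_node(a)
  mv <- as.vector(mask)
  stopifnot(length(a$v) %% length(mv) == 0)
  .ag_new(a$v * mv, list(a), function(g) list(g * mv))
}

#' Full Manhattan self-attention (quadratic oracle path)
#'
#' Per head: \eqn{A = \mathrm{softmax}(QK^T/\sqrt{d}) \odot D}, output
#' \eqn{AV}, where D is the Manhattan decay matrix of `decay`. Rows are not
#' renormalised after masking (retention convention). Quadratic in the
#' token count, so restricted to grids with at most 4096 positions; larger
#' grids should use [masa_decomposed()].
#'
#' @param Q,K,V feature grids of identical shape, (B, C, H, W) or (C, H, W),
#'   with H, W matching `decay`
#' @param decay a [manhattan_decay()] spec
#' @return grid shaped like `V`
#' @export
masa_full <- function(Q, K, V, decay) {
  d <- dim(Q)
  qh <- .to_hwbc(Q); kh <- .to_hwbc(K); vh <- .to_hwbc(V)
  dh <- dim(qh)
  H <- dh[1]; W <- dh[2]; B <- dh[3]; C <- dh[4]
  if (H * W > 4096) {
    stop("grid has ", H * W, " positions; the full MaSA path is quadratic. ",
         "Use masa_decomposed() for large grids.")
  }
  stopifnot(decay$H == H, decay$W == W)
  # decay$D is row-major (n = r*W + c); internal tokens are column-major
  # (h fastest), so permute D into the internal order:
  # internal index n_int = h + (w-1)*H maps to row-major n_rm = (h-1)*W + w
  h <- rep(seq_len(H), W)
  w <- rep(seq_len(W), each = H)
  n_rm <- (h - 1L) * W + w
  Dint <- decay$D[n_rm, n_rm, drop = FALSE]
  tok <- function(x) .tok_heads(ag_const(x), 1L)
  out <- ag_value(.untok_heads(nn_masa_full_tok(tok(qh), tok(kh), tok(vh),
                                                Dint), H, W, B, C, 1L))
  .to_orig(out, d)
}

# Decomposed MaSA on grid nodes (H, W, B, C): a horizontal pass per row with
# the column decay, then a vertical pass per column with the row decay.
# gammas: per-head decay rates (length num_heads).
nn_masa_decomposed <- function(Q, K, V, num_heads, gammas) {
  d <- dim(ag_value(Q))
  H <- d[1]; W <- d[2]; B <- d[3]; C <- d[4]
  nh <- num_heads
  dh <- C %/% nh
  d_col <- array(0, c(W, W, nh))
  d_row <- array(0, c(H, H, nh))
  for (i in seq_len(nh)) {
    d_col[, , i] <- gammas[i]^abs(outer(seq_len(W), seq_len(W), `-`))
    d_row[, , i] <- gammas[i]^abs(outer(seq_len(H), seq_len(H), `-`))
  }
  # horizontal: batch slices ordered (row, head, batch), row fastest
  to_rows <- function(x) {
    ag_reshape(ag_aperm(ag_reshape(x, c(H, W, B, dh, nh)),
                        c(2L, 4L, 1L, 5L, 3L)), c(W, dh, H * nh * B))
  }
  from_rows <- function(x) {
    ag_reshape(ag_aperm(ag_reshape(x, c(W, dh, H, nh, B)),
                        c(3L, 1L, 5L, 2L, 4L)), c(H, W, B, C))
  }
  hidx <- rep(rep(seq_len(nh), each = H), B)
  maskW <- d_col[, , hidx, drop = FALSE]
  hout <- from_rows(nn_masa_full_tok(to_rows(Q), to_rows(K), to_rows(V),
                                     maskW))
  # vertical: batch slices ordered (column, head, batch), column fastest
  to_cols <- function(x) {
    ag_reshape(ag_aperm(ag_reshape(x, c(H, W, B, dh, nh)),
                        c(1L, 4L, 2L, 5L, 3L)), c(H, dh, W * nh * B))
  }
  from_cols <- function(x) {
    ag_reshape(ag_aperm(ag_reshape(x, c(H, dh, W, nh, B)),
                        c(1L, 3L, 5L, 2L, 4L)), c(H, W, B, C))
  }
  vidx <- rep(rep(seq_len(nh), each = W), B)
  maskH <- d_row[, , vidx, drop = FALSE]
  from_cols(nn_masa_full_tok(to_cols(Q), to_cols(K), to_cols(hout), maskH))
}

#' Decomposed Manhattan self-attention
#'
#' Two one-dimensional attention passes: per row with the column decay
#' factor \eqn{\gamma^{|c_1-c_2|}}, then per column with the row decay
#' factor, applied to the horizontal output. Linear in one axis at a time;
#' never builds an (HW) x (HW) matrix. Exactly equal to [masa_full()] on
#' 1 x N and N x 1 grids.
#'
#' @inheritParams masa_full
#' @return grid shaped like `V`
#' @export
masa_decomposed <- function(Q, K, V, decay) {
  d <- dim(Q)
  qh <- .to_hwbc(Q); kh <- .to_hwbc(K); vh <- .to_hwbc(V)
  dhh <- dim(qh)
  stopifnot(decay$H == dhh[1], decay$W == dhh[2])
  out <- ag_value(nn_masa_decomposed(ag_const(qh), ag_const(kh), ag_const(vh),
                                     1L, decay$gamma))
  .to_orig(out, d)
}

#' Local context enhancement
#'
#' 5x5 depthwise convolution of V (padding 2, zero bias); added to the
#' attention output by the caller.
#' @param V feature grid
#' @param params a list with a `lce` depthwise kernel, e.g. from
#'   [retblock_params()]
#' @return grid shaped like `V`
#' @export
lce <- function(V, params) {
  d <- dim(V)
  out <- ag_value(ag_dwconv2d(ag_const(.to_hwbc(V)), params$lce))
  .to_orig(out, d)
}

#' Parameters of one RetBlock
#'
#' Pre-norm transformer unit: layer norm, fused QKV projection, rotary
#' encoding of Q and K, decomposed Manhattan self-attention with a per-head
#' decay schedule \eqn{\gamma_i = 1 - 2^{-5-i}}, local context enhancement
#' of V, output projection, and a feed-forward residual (ratio 2, GELU).
#'
#' @param channels channel count C
#' @param num_heads attention heads (head_dim must be divisible by 4)
#' @param gammas per-head decay rates; default [decay_schedule()]
#' @param ffn_ratio feed-forward expansion ratio
#' @return named list of arrays plus configuration fields
#' @export
retblock_params <- function(channels, num_heads = 4L, gammas = NULL,
                            ffn_ratio = 2L) {
  C <- as.integer(channels)
  if (C %% num_heads != 0) stop("channels must be divisible by num_heads")
  dh <- C %/% num_heads
  if (dh %% 4 != 0) stop("head_dim (", dh, ") must be divisible by 4")
  if (is.null(gammas)) gammas <- decay_schedule(num_heads)
  if (any(gammas <= 0 | gammas > 1)) stop("gammas must lie in (0, 1]")
  hid <- as.integer(ffn_ratio * C)
  list(channels = C, num_heads = as.integer(num_heads), gammas = gammas,
       ffn_ratio = ffn_ratio, rope = build_axial_frequencies(dh),
       ln1_g = .ones(C), ln1_b = .zeros(C),
       wqkv = .init_lin(C, 3L * C), bqkv = .zeros(3L * C),
       lce = .init_dw(5L, C),
       wproj = .init_lin(C, C), bproj = .zeros(C),
       ln2_g = .ones(C), ln2_b = .zeros(C),
       ffn_w1 = .init_lin(C, hid), ffn_b1 = .zeros(hid),
       ffn_w2 = .init_lin(hid, C), ffn_b2 = .zeros(C))
}

nn_retblock <- function(x, p, cfg) {
  d <- dim(ag_value(x))
  H <- d[1]; W <- d[2]; B <- d[3]; C <- d[4]
  nh <- cfg$num_heads
  t <- nn_ln_grid(x, p$ln1_g, p$ln1_b)
  qkv <- ag_conv1x1(t, p$wqkv, p$bqkv)
  Q <- ag_slice_ch(qkv, seq_len(C))
  K <- ag_slice_ch(qkv, C + seq_len(C))
  V <- ag_slice_ch(qkv, 2L * C + seq_len(C))
  # RelPos2d: rotary phase on Q/K plus the gamma decay masks
  cs <- .rope_cos_sin(cfg$rope, H, W)
  rot <- function(z) {
    .untok_heads(ag_rope(.tok_heads(z, nh), cs$cosA, cs$sinA),
                 H, W, B, C, nh)
  }
  attn <- nn_masa_decomposed(rot(Q), rot(K), V, nh, cfg$gammas)
  enh <- ag_dwconv2d(V, p$lce)
  x1 <- ag_add(x, ag_conv1x1(ag_add(attn, enh), p$wproj, p$bproj))
  t2 <- nn_ln_grid(x1, p$ln2_g, p$ln2_b)
  ffn <- ag_conv1x1(ag_gelu(ag_conv1x1(t2, p$ffn_w1, p$ffn_b1)),
                    p$ffn_w2, p$ffn_b2)
  ag_add(x1, ffn)
}

#' Apply one RetBlock
#' @param X feature grid, (B, C, H, W) or (C, H, W)
#' @param params a [retblock_params()] list
#' @return grid shaped like `X`
#' @export
retblock <- function(X, params) {
  .check_grid_channels(X, params$channels, "retblock")
  d <- dim(X)
  p <- .wrap_tree(params)
  .to_orig(ag_value(nn_retblock(ag_const(.to_hwbc(X)), p, params)), d)
}

#' Parameters of a RetBlockC3 aggregation block
#'
#' Dual-path design: path A is a 1x1 convolution followed by `n_ret`
#' RetBlocks; path B is a 1x1 shortcut convolution; the two paths are summed
#' elementwise.
#'
#' @param in_ch,out_ch channel counts
#' @param n_ret number of RetBlocks on path A
#' @param num_heads attention heads inside each RetBlock
#' @return nested list of arrays plus configuration fields
#' @export
retblockc3_params <- function(in_ch, out_ch, n_ret = 1L, num_heads = 4L) {
  list(in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
       n_ret = as.integer(n_ret),
       wa = .init_lin(in_ch, out_ch), ba = .zeros(out_ch),
       wb = .init_lin(in_ch, out_ch), bb = .zeros(out_ch),
       blocks = lapply(seq_len(n_ret),
                       function(i) retblock_params(out_ch, num_heads)))
}

nn_retblockc3 <- function(x, p, cfg) {
  a <- ag_conv1x1(x, p$wa, p$ba)
  for (i in seq_len(cfg$n_ret)) a <- nn_retblock(a, p$blocks[[i]],
                                                 cfg$blocks[[i]])
  b <- ag_conv1x1(x, p$wb, p$bb)
  ag_add(a, b)
}

#' Apply a RetBlockC3 block
#' @param X feature grid, (B, C, H, W) or (C, H, W)
#' @param params a [retblockc3_params()] list
#' @return grid with `out_ch` channels
#' @export
retblockc3 <- function(X, params) {
  .check_grid_channels(X, params$in_ch, "retblockc3")
  d <- dim(X)
  p <- .wrap_tree(params)
  .to_orig(ag_value(nn_retblockc3(ag_const(.to_hwbc(X)), p, params)), d)
}

# RepC3 baseline --------------------------------------------------------------

#' Parameters of the RepC3 baseline aggregation block
#'
#' A stack of `depth` reparameterisable units. Each unit sums a 3x3
#' convolution branch, a 1x1 convolution branch (both batch-normalised) and
#' the batch-normalised input, then applies SiLU.
#'
#' @param channels channel count (input = output)
#' @param depth number of stacked units (default 3)
#' @return nested list of arrays plus configuration fields
#' @export
repc3_params <- function(channels, depth = 3L) {
  C <- as.integer(channels)
  unit <- function() {
    list(w3 = .init_conv(3L, 3L, C, C), bn3 = .bn_params(C),
         w1 = .init_lin(C, C), bn1 = .bn_params(C),
         bn0 = .bn_params(C))
  }
  list(channels = C, depth = as.integer(depth),
       units = lapply(seq_len(depth), function(i) unit()))
}

nn_repc3 <- function(x, p, cfg, training = FALSE) {
  bn <- function(z, pp, cc) ag_batchnorm(z, pp$g, pp$b, cc$state, training)
  for (i in seq_along(p$units)) {
    u <- p$units[[i]]; cu <- cfg$units[[i]]
    x <- ag_silu(ag_add(ag_add(
      bn(ag_conv2d(x, u$w3, NULL, stride = 1L, pad = 1L), u$bn3, cu$bn3),
      bn(ag_conv1x1(x, u$w1, NULL), u$bn1, cu$bn1)),
      bn(x, u$bn0, cu$bn0)))
  }
  x
}

#' Apply the RepC3 baseline block
#' @param X feature grid, (B, C, H, W) or (C, H, W)
#' @param params a [repc3_params()] list
#' @param training use batch statistics (TRUE) or running statistics (FALSE)
#' @return grid shaped like `X`
#' @export
repc3_baseline <- function(X, params, training = FALSE) {
  .check_grid_channels(X, params$channels, "repc3_baseline")
  d <- dim(X)
  p <- .wrap_tree(params)
  out <- ag_value(nn_repc3(ag_const(.to_hwbc(X)), p, params, training))
  .to_orig(out, d)
}
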