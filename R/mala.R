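# AIFI-MALA: magnitude-aware linear attention intra-scale block, and the
# standard softmax-attention (MHSA) baseline it replaces.
#
# The linear-attention core keeps the query magnitude that plain kernelised
# attention discards: with phi = ELU(.)+1 and hat denoting RoPE rotation,
#   z   = phi(Qhat) mean_i(phi(Khat)_i)^T
#   out = phi(Qhat)[phi(Khat)^T V] * (1 + (z+eps)^-1) - z * Vbar
# computed without ever materialising an N x N attention matrix.

#' Positive kernel map used by linear attention
#'
#' \eqn{\phi(x) = \mathrm{ELU}(x) + 1}, strictly positive for all real input.
#' @param x numeric vector/array
#' @return same shape as `x`
#' @export
kernel_map <- function(x) {
  y <- x + 1
  neg <- x < 0
  y[neg] <- exp(x[neg])
  if (!is.null(dim(x))) dim(y) <- dim(x)
  y
}

#' Parameters for the AIFI-MALA block
#'
#' All four projections (Q, K, V, O) come from one fused pointwise
#' convolution producing 4C channels; the local positional term is a 5x5
#' depthwise kernel; the feed-forward hidden width is `ffn_ratio * C`.
#' Weights are drawn from the current RNG stream.
#'
#' @param embed_dim channels C (divisible by `num_heads`; head_dim must be
#'   divisible by 4 for the rotary encoding)
#' @param num_heads number of attention heads
#' @param epsilon stability constant of the magnitude correction
#' @param ffn_ratio feed-forward expansion ratio
#' @return a named list of plain arrays plus configuration fields
#' @export
mala_params <- function(embed_dim, num_heads = 4L, epsilon = 1e-6,
                        ffn_ratio = 4L) {
  C <- as.integer(embed_dim)
  if (C %% num_heads != 0) stop("embed_dim must be divisible by num_heads")
  dh <- C %/% num_heads
  if (dh %% 4 != 0) stop("head_dim (", dh, ") must be divisible by 4")
  if (epsilon <= 0) stop("epsilon must be positive")
  hid <- as.integer(ffn_ratio * C)
  list(embed_dim = C, num_heads = as.integer(num_heads), epsilon = epsilon,
       ffn_ratio = ffn_ratio,
       rope = build_axial_frequencies(dh),
       wqkvo = .init_lin(C, 4L * C), bqkvo = .zeros(4L * C),
       dw = .init_dw(5L, C),
       wproj = .init_lin(C, C), bproj = .zeros(C),
       ffn_w1 = .init_lin(C, hid), ffn_b1 = .zeros(hid),
       ffn_w2 = .init_lin(hid, C), ffn_b2 = .zeros(C),
       ln1_g = .ones(C), ln1_b = .zeros(C),
       ln2_g = .ones(C), ln2_b = .zeros(C))
}

# Layer normalisation over the channel axis per spatial position, on a
# (H, W, B, C) node; the matrix view is a free reshape in this layout.
nn_ln_grid <- function(x, gamma, beta) {
  d <- dim(ag_value(x))
  xm <- ag_reshape(x, c(d[1] * d[2] * d[3], d[4]))
  ag_reshape(ag_layernorm_cols(xm, gamma, beta), d)
}

# Head-token views: (H, W, B, C) grid node <-> (N, dh, nh*B) token node,
# token order h fastest, slice order (head, batch).
.tok_heads <- function(x, nh) {
  d <- dim(ag_value(x))
  dh <- d[4] %/% nh
  ag_reshape(ag_aperm(ag_reshape(x, c(d[1] * d[2], d[3], dh, nh)),
                      c(1L, 3L, 4L, 2L)), c(d[1] * d[2], dh, nh * d[3]))
}

.untok_heads <- function(x, H, W, B, C, nh) {
  dh <- C %/% nh
  ag_reshape(ag_aperm(ag_reshape(x, c(H * W, dh, nh, B)), c(1L, 4L, 2L, 3L)),
             c(H, W, B, C))
}

# Magnitude-aware linear attention core on grid nodes (H, W, B, C).
nn_mala_core <- function(Q, K, V, num_heads, rope, epsilon) {
  d <- dim(ag_value(Q))
  H <- d[1]; W <- d[2]; B <- d[3]; C <- d[4]
  dh <- C %/% num_heads
  N <- H * W
  Kb <- num_heads * B
  cs <- .rope_cos_sin(rope, H, W)
  phiQ <- ag_elu1(ag_rope(.tok_heads(Q, num_heads), cs$cosA, cs$sinA))
  phiK <- ag_elu1(ag_rope(.tok_heads(K, num_heads), cs$cosA, cs$sinA))
  Vt <- .tok_heads(V, num_heads)
  KtV <- ag_bmm(ag_btranspose(phiK), Vt)                  # (dh, dh, Kb)
  term1 <- ag_bmm(phiQ, KtV)                              # (N, dh, Kb)
  onesN <- ag_const(array(1 / N, c(1L, N, Kb)))
  Kbar <- ag_bmm(onesN, phiK)                             # (1, dh, Kb)
  Vbar <- ag_bmm(onesN, Vt)
  z <- ag_bmm(phiQ, ag_btranspose(Kbar))                  # (N, 1, Kb)
  zfull <- ag_bmm(z, ag_const(array(1, c(1L, dh, Kb))))
  vbarfull <- ag_bmm(ag_const(array(1, c(N, 1L, Kb))), Vbar)
  w <- ag_add_const(ag_recip(ag_add_const(zfull, epsilon)), 1)
  out <- ag_sub(ag_mul(term1, w), ag_mul(zfull, vbarfull))
  .untok_heads(out, H, W, B, C, num_heads)
}

# Full AIFI-MALA block on a grid node; `p` holds node-wrapped parameters.
nn_aifi_mala <- function(x, p, cfg) {
  C <- cfg$embed_dim
  qkvo <- ag_conv1x1(x, p$wqkvo, p$bqkvo)
  Q <- ag_slice_ch(qkvo, seq_len(C))
  K <- ag_slice_ch(qkvo, C + seq_len(C))
  V <- ag_slice_ch(qkvo, 2L * C + seq_len(C))
  O <- ag_slice_ch(qkvo, 3L * C + seq_len(C))
  core <- nn_mala_core(Q, K, V, cfg$num_heads, cfg$rope, cfg$epsilon)
  lpe <- ag_dwconv2d(V, p$dw)
  Y <- ag_conv1x1(ag_mul(ag_add(core, lpe), O), p$wproj, p$bproj)
  ffn <- ag_conv1x1(ag_gelu(ag_conv1x1(Y, p$ffn_w1, p$ffn_b1)),
                    p$ffn_w2, p$ffn_b2)
  inner <- nn_ln_grid(ag_add(Y, ffn), p$ln1_g, p$ln1_b)
  nn_ln_grid(ag_add(x, inner), p$ln2_g, p$ln2_b)
}

.wrap_params <- function(p) .wrap_tree(p)

.check_grid_channels <- function(x, C, what) {
  d <- dim(x)
  ch <- if (length(d) == 4L) d[2] else if (length(d) == 3L) d[1] else 1L
  if (ch != C) {
    stop(what, ": expected ", C, " channels, got ", ch)
  }
  invisible(NULL)
}

#' Fused Q/K/V/O projection
#'
#' One pointwise (1x1) linear map produces all four tensors at once.
#' @param X feature grid, (B, C, H, W) or (C, H, W)
#' @param params a [mala_params()] list
#' @return list with elements Q, K, V, O, each shaped like `X`
#' @export
qkvo_project <- function(X, params) {
  .check_grid_channels(X, params$embed_dim, "qkvo_project")
  d <- dim(X)
  xn <- ag_const(.to_hwbc(X))
  y <- ag_value(ag_conv1x1(xn, params$wqkvo, params$bqkvo))
  C <- params$embed_dim
  pick <- function(i) .to_orig(y[, , , (i - 1L) * C + seq_len(C), drop = FALSE], d)
  list(Q = pick(1L), K = pick(2L), V = pick(3L), O = pick(4L))
}

#' Magnitude-aware linear attention core
#'
#' Applies rotary encoding to Q and K, the positive kernel map, and the
#' magnitude correction that restores query-norm sensitivity. Never builds
#' an N x N attention matrix: all intermediates are N x d or d x d per head.
#'
#' @param Q,K,V feature grids of identical shape, (B, C, H, W) or (C, H, W)
#' @param rope an `axial_rope`; heads are inferred as C / rope$head_dim
#' @param epsilon stability constant
#' @return grid of the same shape as `V`
#' @export
mala_core <- function(Q, K, V, rope, epsilon = 1e-6) {
  if (!all(is.finite(Q)) || !all(is.finite(K)) || !all(is.finite(V))) {
    stop("mala_core: non-finite values in Q/K/V input")
  }
  stopifnot(identical(dim(Q), dim(K)), identical(dim(Q), dim(V)))
  d <- dim(Q)
  qh <- .to_hwbc(Q); kh <- .to_hwbc(K); vh <- .to_hwbc(V)
  C <- dim(qh)[4]
  if (C %% rope$head_dim != 0) {
    stop("channel count ", C, " not a multiple of head_dim ", rope$head_dim)
  }
  nh <- C %/% rope$head_dim
  out <- ag_value(nn_mala_core(ag_const(qh), ag_const(kh), ag_const(vh),
                               nh, rope, epsilon))
  .to_orig(out, d)
}

#' Depthwise local positional enhancement
#'
#' 5x5 depthwise convolution of V (padding 2, zero bias): a locally
#' learnable positional perturbation with no cross-channel mixing.
#' @param V feature grid
#' @param params a [mala_params()] list (uses `params$dw`)
#' @return grid shaped like `V`
#' @export
dw_lpe <- function(V, params) {
  d <- dim(V)
  out <- ag_value(ag_dwconv2d(ag_const(.to_hwbc(V)), params$dw))
  .to_orig(out, d)
}

#' Gated fusion and output projection
#'
#' Elementwise `(core + lpe) * O`, then a pointwise projection back to C
#' channels.
#' @param core_out,lpe_out,O grids of identical shape
#' @param params a [mala_params()] list
#' @return grid shaped like the inputs
#' @export
mala_fuse <- function(core_out, lpe_out, O, params) {
  stopifnot(identical(dim(core_out), dim(lpe_out)),
            identical(dim(core_out), dim(O)))
  d <- dim(core_out)
  fused <- (.to_hwbc(core_out) + .to_hwbc(lpe_out)) * .to_hwbc(O)
  out <- ag_value(ag_conv1x1(ag_const(fused), params$wproj, params$bproj))
  .to_orig(out, d)
}

#' Full AIFI-MALA block
#'
#' Projection, magnitude-aware attention, local enhancement, output gate,
#' and the post-norm feed-forward update
#' \eqn{Y' = LN(X + LN\{Y + W_2\,\mathrm{GELU}(W_1 Y)\})}, where layer
#' normalisation acts over the channel axis at each spatial position.
#'
#' @param X feature grid, (B, C, H, W) or (C, H, W)
#' @param params a [mala_params()] list
#' @return grid shaped like `X`
#' @export
aifi_mala_block <- function(X, params) {
  .check_grid_channels(X, params$embed_dim, "aifi_mala_block")
  d <- dim(X)
  p <- .wrap_params(params)
  out <- ag_value(nn_aifi_mala(ag_const(.to_hwbc(X)), p, params))
  .to_orig(out, d)
}

# Softmax-attention baseline (the conventional AIFI block) ------------------

#' Parameters for the baseline softmax-attention intra-scale block
#' @inheritParams mala_params
#' @return named list of arrays plus configuration fields
#' @export
mhsa_params <- function(embed_dim, num_heads = 4L, ffn_ratio = 4L) {
  C <- as.integer(embed_dim)
  if (C %% num_heads != 0) stop("embed_dim must be divisible by num_heads")
  hid <- as.integer(ffn_ratio * C)
  list(embed_dim = C, num_heads = as.integer(num_heads), ffn_ratio = ffn_ratio,
       wqkv = .init_lin(C, 3L * C), bqkv = .zeros(3L * C),
       wproj = .init_lin(C, C), bproj = .zeros(C),
       ffn_w1 = .init_lin(C, hid), ffn_b1 = .zeros(hid),
       ffn_w2 = .init_lin(hid, C), ffn_b2 = .zeros(C),
       ln1_g = .ones(C), ln1_b = .zeros(C),
       ln2_g = .ones(C), ln2_b = .zeros(C))
}

# Multi-head softmax self-attention over all positions of a grid node, with
# fixed sine-cosine positional terms added to the Q/K path (DETR convention).
nn_aifi_mhsa <- function(x, p, cfg) {
  d <- dim(ag_value(x))
  H <- d[1]; W <- d[2]; B <- d[3]; C <- d[4]
  nh <- cfg$num_heads
  dh <- C %/% nh
  pos <- sincos_embed_2d(H, W, C)
  posg <- ag_const(aperm(array(pos, c(H * W, C, B)), c(1L, 3L, 2L)) |>
                     array(dim = c(H, W, B, C)))
  xq <- ag_add(x, posg)
  qkvp <- ag_conv1x1(xq, p$wqkv, p$bqkv)
  Q <- .tok_heads(ag_slice_ch(qkvp, seq_len(C)), nh)
  K <- .tok_heads(ag_slice_ch(qkvp, C + seq_len(C)), nh)
  qkvx <- ag_conv1x1(x, p$wqkv, p$bqkv)
  V <- .tok_heads(ag_slice_ch(qkvx, 2L * C + seq_len(C)), nh)
  A <- ag_softmax_rows(ag_scale(ag_bmm(Q, ag_btranspose(K)), 1 / sqrt(dh)))
  out <- .untok_heads(ag_bmm(A, V), H, W, B, C, nh)
  Y <- ag_conv1x1(out, p$wproj, p$bproj)
  ffn <- ag_conv1x1(ag_gelu(ag_conv1x1(Y, p$ffn_w1, p$ffn_b1)),
                    p$ffn_w2, p$ffn_b2)
  inner <- nn_ln_grid(ag_add(Y, ffn), p$ln1_g, p$ln1_b)
  nn_ln_grid(ag_add(x, inner), p$ln2_g, p$ln2_b)
}
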