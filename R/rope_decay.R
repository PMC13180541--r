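# Positional geometry shared by the attention operators: two-dimensional
# axial rotary encoding and Manhattan-distance decay masks.

#' Construct axial rotary-encoding frequencies
#'
#' Builds the per-axis frequency vectors for two-dimensional rotary position
#' encoding. Channels of each attention head are split in half: the first
#' half is rotated by angles proportional to the row index, the second half
#' by the column index. Within each half, consecutive channel pairs are
#' rotated as complex numbers. Frequencies follow the standard inverse-power
#' spacing \eqn{\omega_i = \mathrm{base}^{-2i/(d/2)}} for
#' \eqn{i = 0, \dots, d/4 - 1}, so they are strictly positive and strictly
#' decreasing, and the rotation at position (0, 0) is the identity.
#'
#' @param head_dim channels per attention head; must be divisible by 4
#' @param base frequency base (default 10000)
#' @return an object of class `axial_rope` with fields `head_dim`, `freq_h`,
#'   `freq_w`, `base`
#' @export
build_axial_frequencies <- function(head_dim, base = 10000) {
  if (head_dim %% 4 != 0) {
    stop("head_dim must be divisible by 4, got ", head_dim)
  }
  q <- head_dim %/% 4L
  freqs <- base^(-2 * (seq_len(q) - 1) / (head_dim / 2))
  structure(list(head_dim = as.integer(head_dim),
                 freq_h = freqs, freq_w = freqs, base = base),
            class = "axial_rope")
}

# Per-token angle matrix (N x head_dim/2) for an H x W grid in the internal
# token order (row index fastest), positions 0-based.
.rope_angles <- function(rope, H, W) {
  h <- rep(seq_len(H) - 1L, W)
  w <- rep(seq_len(W) - 1L, each = H)
  cbind(outer(h, rope$freq_h), outer(w, rope$freq_w))
}

# cos/sin matrices expanded to full head_dim (each angle drives one
# channel pair).
.rope_cos_sin <- function(rope, H, W) {
  ang <- .rope_angles(rope, H, W)
  idx <- rep(seq_len(ncol(ang)), each = 2L)
  list(cosA = cos(ang)[, idx, drop = FALSE],
       sinA = sin(ang)[, idx, drop = FALSE])
}

# In-pair channel shift: (a, b) -> (-b, a), along dim 2 of (N, d[, K]).
.rope_shift <- function(x) {
  d <- dim(x)
  dd <- d[2]
  odd <- seq(1L, dd, 2L)
  even <- odd + 1L
  y <- x
  if (length(d) == 2L) {
    y[, odd] <- -x[, even]
    y[, even] <- x[, odd]
  } else {
    y[, odd, ] <- -x[, even, ]
    y[, even, ] <- x[, odd, ]
  }
  y
}

# Tape op: rotate token channels; x is (N, d) or (N, d, K); cosA/sinA (N, d)
# recycle over K (column-major layout makes the recycling exact).
ag_rope <- function(x, cosA, sinA) {
  x <- as_node(x)
  xv <- x$v
  cv <- as.vector(cosA); sv <- as.vector(sinA)
  y <- xv * cv + .rope_shift(xv) * sv
  .ag_new(y, list(x), function(g) {
    # gradient is the inverse rotation (by -theta)
    list(g * cv + .rope_shift(g) * (-sv))
  })
}

#' Rotate a feature grid with two-dimensional axial rotary encoding
#'
#' Applies the pairwise-channel complex rotation
#' \eqn{(a, b) \mapsto (a\cos\theta - b\sin\theta,\; a\sin\theta + b\cos\theta)}
#' at every spatial position, with angles \eqn{h\,\omega_h} on the first half
#' of the head channels and \eqn{w\,\omega_w} on the second half. The map is
#' norm-preserving per channel pair and makes rotated inner products depend
#' only on the relative offset between positions.
#'
#' @param t array of shape (head_dim, H, W) or (B, head_dim, H, W)
#' @param rope an `axial_rope` object; `rope$head_dim` must equal the
#'   channel count of `t`
#' @return array of the same shape as `t`
#' @export
rope2d_rotate <- function(t, rope) {
  d <- dim(t)
  x <- .to_hwbc(t)
  dh <- dim(x)
  if (dh[4] != rope$head_dim) {
    stop("channel count ", dh[4], " does not match head_dim ", rope$head_dim)
  }
  cs <- .rope_cos_sin(rope, dh[1], dh[2])
  out <- ag_value(.untok_heads(ag_rope(.tok_heads(ag_const(x), 1L),
                                       cs$cosA, cs$sinA),
                               dh[1], dh[2], dh[3], dh[4], 1L))
  .to_orig(out, d)
}

#' Manhattan-distance decay specification
#'
#' Builds the spatial decay matrix \eqn{D[n, m] = \gamma^{|x_n - x_m| +
#' |y_n - y_m|}} over an H x W grid (row-major flattening, n = r*W + c),
#' together with its one-dimensional axis factors \eqn{\gamma^{|i-j|}}.
#' D is symmetric with unit diagonal and factorises exactly as
#' `d_row[r1, r2] * d_col[c1, c2]`.
#'
#' @param gamma decay rate in (0, 1]
#' @param H,W grid size
#' @return an object of class `decay_spec` with fields `gamma`, `H`, `W`,
#'   `D`, `d_row`, `d_col`
#' @export
manhattan_decay <- function(gamma, H, W) {
  if (!(gamma > 0 && gamma <= 1)) {
    stop("gamma must lie in (0, 1], got ", gamma)
  }
  if (H < 1 || W < 1) stop("grid dimensions must be >= 1")
  d_row <- gamma^abs(outer(seq_len(H), seq_len(H), `-`))
  d_col <- gamma^abs(outer(seq_len(W), seq_len(W), `-`))
  # row-major position flattening: n = r*W + c (r, c 0-based)
  r <- rep(seq_len(H), each = W)
  cc <- rep(seq_len(W), H)
  D <- d_row[r, r, drop = FALSE] * d_col[cc, cc, drop = FALSE]
  structure(list(gamma = gamma, H = as.integer(H), W = as.integer(W),
                 D = D, d_row = d_row, d_col = d_col),
            class = "decay_spec")
}

#' Write a decay matrix as plain text (debugging aid)
#' @param spec a `decay_spec`
#' @param path output file
#' @export
write_decay_matrix <- function(spec, path) {
  utils::write.table(spec$D, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Per-head decay schedule gamma_i = 1 - 2^(-5-i), the retention-literature
# convention; used as the default wherever a head count is known.
decay_schedule <- function(num_heads) {
  1 - 2^(-5 - (seq_len(num_heads) - 1))
}
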