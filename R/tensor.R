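# Layout helpers and parameter initialisation.
#
# Public functions speak the (batch, channel, height, width) convention of
# detection frameworks; internally feature maps are (H, W, C, B) so that
# column-major BLAS reshapes stay cheap.

# Accepts (H, W) matrix, (C, H, W) or (B, C, H, W) arrays -> internal
# layout (H, W, B, C).
.to_hwbc <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) {
    x <- array(x, c(dim(as.matrix(x)), 1L, 1L))
    return(x)
  }
  if (length(d) == 3L) return(aperm(array(x, c(1L, d)), c(3L, 4L, 1L, 2L)))
  if (length(d) == 4L) return(aperm(x, c(3L, 4L, 1L, 2L)))
  stop("expected a 2-, 3- or 4-dimensional array")
}

# Inverse of .to_hwbc, returning the same rank as the input had.
.to_orig <- function(y, orig_dim) {
  nd <- if (is.null(orig_dim)) 2L else length(orig_dim)
  if (nd <= 2L) return(y[, , 1L, 1L])
  z <- aperm(y, c(3L, 4L, 1L, 2L))   # self-inverse permutation -> (B, C, H, W)
  if (nd == 3L) return(array(z[1L, , , ], dim(z)[2:4]))
  z
}

# Kaiming-style initialisers (draw from the current RNG stream).
.init_conv <- function(kh, kw, cin, cout, gain = 2) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(gain / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

.init_dw <- function(k, c) {
  array(stats::rnorm(k * k * c, sd = sqrt(2 / (k * k))), c(k, k, c))
}

.init_lin <- function(cin, cout) {
  lim <- 1 / sqrt(cin)
  matrix(stats::runif(cin * cout, -lim, lim), cin, cout)
}

.zeros <- function(...) array(0, c(...))
.ones <- function(...) array(1, c(...))

# Fixed 2D sine-cosine positional embedding for an H x W grid, D channels.
# Token order matches the internal flattening (h fastest).
sincos_embed_2d <- function(H, W, D, temperature = 10000) {
  stopifnot(D %% 4 == 0)
  q <- D %/% 4L
  omega <- temperature^(-(seq_len(q) - 1) / q)
  h <- rep(seq_len(H) - 1L, W)
  w <- rep(seq_len(W) - 1L, each = H)
  ah <- outer(h, omega)
  aw <- outer(w, omega)
  cbind(sin(aw), cos(aw), sin(ah), cos(ah))
}

# Box geometry helpers (plain arrays; differentiable variants live in loss.R)

#' Convert normalized center-size boxes to corner form
#'
#' @param b matrix with columns cx, cy, w, h
#' @return matrix with columns x1, y1, x2, y2 (same units)
#' @export
box_cxcywh_to_xyxy <- function(b) {
  b <- matrix(b, ncol = 4L)
  cbind(b[, 1] - b[, 3] / 2, b[, 2] - b[, 4] / 2,
        b[, 1] + b[, 3] / 2, b[, 2] + b[, 4] / 2)
}

#' Convert corner boxes to center-size form
#' @param b matrix with columns x1, y1, x2, y2
#' @return matrix with columns cx, cy, w, h
#' @export
box_xyxy_to_cxcywh <- function(b) {
  b <- matrix(b, ncol = 4L)
  cbind((b[, 1] + b[, 3]) / 2, (b[, 2] + b[, 4]) / 2,
        b[, 3] - b[, 1], b[, 4] - b[, 2])
}
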