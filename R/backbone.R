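# Backbones: CSP-MambaOut (gated-CNN blocks inside cross-stage-partial
# stages) and a ResNet18-style baseline for the ablation grid. Both emit
# pyramid features S3/S4/S5 at strides 8/16/32.

#' Parameters of one gated-CNN block
#'
#' The block computes
#' \eqn{y = x + \sigma(W_g\,\mathrm{Norm}(x)) \circ \mathrm{conv}(W_f\,\mathrm{Norm}(x))}
#' with logistic gate \eqn{\sigma}, Hadamard product \eqn{\circ}, layer
#' normalisation over channels, and a depthwise convolution as `conv`
#' (kernel size `kernel`, default 7). With `expand_ratio = 1` (default) the
#' equation holds verbatim; a ratio above 1 widens the two branches and adds
#' a pointwise output projection to restore the residual width.
#'
#' @param channels input/output channel count
#' @param kernel depthwise kernel size
#' @param expand_ratio hidden-width multiplier
#' @return named list of arrays plus configuration fields
#' @export
gated_block_params <- function(channels, kernel = 7L, expand_ratio = 1) {
  C <- as.integer(channels)
  h <- as.integer(round(expand_ratio * C))
  p <- list(channels = C, kernel = as.integer(kernel), hidden = h,
            ln_g = .ones(C), ln_b = .zeros(C),
            wg = .init_lin(C, h), bg = .zeros(h),
            wf = .init_lin(C, h), bf = .zeros(h),
            dw = .init_dw(as.integer(kernel), h))
  if (h != C) {
    p$wo <- .init_lin(h, C)
    p$bo <- .zeros(C)
  }
  p
}

nn_gated_block <- function(x, p, cfg) {
  t <- nn_ln_grid(x, p$ln_g, p$ln_b)
  gate <- ag_sigmoid(ag_conv1x1(t, p$wg, p$bg))
  feat <- ag_dwconv2d(ag_conv1x1(t, p$wf, p$bf), p$dw)
  branch <- ag_mul(gate, feat)
  if (!is.null(p$wo)) branch <- ag_conv1x1(branch, p$wo, p$bo)
  ag_add(x, branch)
}

#' Apply one gated-CNN block to a feature grid
#'
#' @param x feature grid, (B, C, H, W) or (C, H, W)
#' @param params a [gated_block_params()] list
#' @return grid shaped like `x`
#' @export
gated_cnn_block <- function(x, params) {
  .check_grid_channels(x, params$channels, "gated_cnn_block")
  d <- dim(x)
  p <- .wrap_tree(params)
  .to_orig(ag_value(nn_gated_block(ag_const(.to_hwbc(x)), p, params)), d)
}

#' Parameters of one cross-stage-partial stage
#'
#' Entry 3x3 convolution (optionally strided) to `out_ch`, channel split in
#' half, `num_blocks` gated-CNN blocks on the main half, concatenation with
#' the untouched residual half, and a pointwise fuse convolution.
#'
#' @param in_ch,out_ch stage channel counts (`out_ch` must be even)
#' @param num_blocks gated blocks on the main branch
#' @param stride entry-convolution stride (2 to downsample)
#' @param kernel depthwise kernel of the gated blocks
#' @return nested list of arrays plus configuration fields
#' @export
csp_stage_params <- function(in_ch, out_ch, num_blocks, stride = 1L,
                             kernel = 7L) {
  if (out_ch %% 2 != 0) {
    stop("csp stage with split ratio 0.5 needs an even out_ch, got ", out_ch)
  }
  half <- out_ch %/% 2L
  list(in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
       num_blocks = as.integer(num_blocks), stride = as.integer(stride),
       entry_w = .init_conv(3L, 3L, in_ch, out_ch), entry_b = .zeros(out_ch),
       blocks = lapply(seq_len(num_blocks),
                       function(i) gated_block_params(half, kernel)),
       fuse_w = .init_lin(out_ch, out_ch), fuse_b = .zeros(out_ch))
}

nn_csp_stage <- function(x, p, cfg, tap = NULL) {
  half <- cfg$out_ch %/% 2L
  y <- ag_silu(ag_conv2d(x, p$entry_w, p$entry_b,
                         stride = cfg$stride, pad = 1L))
  res <- ag_slice_ch(y, seq_len(half))
  main <- ag_slice_ch(y, half + seq_len(half))
  for (i in seq_len(cfg$num_blocks)) {
    main <- nn_gated_block(main, p$blocks[[i]], cfg$blocks[[i]])
  }
  if (!is.null(tap)) {
    tap$residual_pre_concat <- ag_value(res)
  }
  ag_silu(ag_conv1x1(ag_concat_ch(res, main), p$fuse_w, p$fuse_b))
}

#' Run one cross-stage-partial stage
#'
#' @param x feature grid, (B, C, H, W) or (C, H, W)
#' @param stage_config a [csp_stage_params()] list
#' @return grid with `out_ch` channels, spatially downsampled by `stride`
#' @export
csp_stage <- function(x, stage_config) {
  .check_grid_channels(x, stage_config$in_ch, "csp_stage")
  d <- dim(x)
  p <- .wrap_tree(stage_config)
  out <- ag_value(nn_csp_stage(ag_const(.to_hwbc(x)), p, stage_config))
  .to_orig(out, d)
}

# ResNet basic block ---------------------------------------------------------

.bn_params <- function(C) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- rep(0, C)
  st$running_var <- rep(1, C)
  list(g = .ones(C), b = .zeros(C), state = st)
}

basic_block_params <- function(in_ch, out_ch, stride = 1L) {
  p <- list(in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
            stride = as.integer(stride),
            w1 = .init_conv(3L, 3L, in_ch, out_ch), bn1 = .bn_params(out_ch),
            w2 = .init_conv(3L, 3L, out_ch, out_ch), bn2 = .bn_params(out_ch))
  if (stride != 1L || in_ch != out_ch) {
    p$wd <- .init_conv(1L, 1L, in_ch, out_ch)
    p$bnd <- .bn_params(out_ch)
  }
  p
}

nn_basic_block <- function(x, p, cfg, training) {
  bn <- function(z, pp, cc) ag_batchnorm(z, pp$g, pp$b, cc$state, training)
  h <- ag_relu(bn(ag_conv2d(x, p$w1, NULL, stride = cfg$stride, pad = 1L),
                  p$bn1, cfg$bn1))
  h <- bn(ag_conv2d(h, p$w2, NULL, stride = 1L, pad = 1L), p$bn2, cfg$bn2)
  sc <- if (!is.null(p$wd)) {
    bn(ag_conv2d(x, p$wd, NULL, stride = cfg$stride, pad = 0L), p$bnd, cfg$bnd)
  } else {
    x
  }
  ag_relu(ag_add(h, sc))
}

# Backbone assembly -----------------------------------------------------------

#' Construct backbone parameters
#'
#' `cspmambaout`: stem of two strided 3x3 convolutions (overall stride 4)
#' followed by four cross-stage-partial stages with strides (1, 2, 2, 2);
#' S3/S4/S5 tap the last three stages. `resnet18`: the standard
#' two-convolution residual basic-block layout with depths (2, 2, 2, 2) and
#' widths (64, 128, 256, 512) unless overridden.
#'
#' @param variant "cspmambaout" or "resnet18"
#' @param widths per-stage channel widths (length 4)
#' @param depths per-stage block counts (length 4)
#' @param kernel depthwise kernel size of the gated blocks
#' @return nested parameter list with class `backbone_params`
#' @export
backbone_params <- function(variant = c("cspmambaout", "resnet18"),
                            widths = NULL, depths = NULL, kernel = 7L) {
  variant <- match.arg(variant)
  if (variant == "cspmambaout") {
    if (is.null(widths)) widths <- c(64L, 128L, 256L, 512L)
    if (is.null(depths)) depths <- c(2L, 2L, 6L, 2L)
    s0 <- widths[1]
    p <- list(variant = variant, widths = widths, depths = depths,
              stem1_w = .init_conv(3L, 3L, 3L, s0 %/% 2L),
              stem1_b = .zeros(s0 %/% 2L),
              stem2_w = .init_conv(3L, 3L, s0 %/% 2L, s0),
              stem2_b = .zeros(s0),
              stages = list(
                csp_stage_params(s0, widths[1], depths[1], 1L, kernel),
                csp_stage_params(widths[1], widths[2], depths[2], 2L, kernel),
                csp_stage_params(widths[2], widths[3], depths[3], 2L, kernel),
                csp_stage_params(widths[3], widths[4], depths[4], 2L, kernel)))
  } else {
    if (is.null(widths)) widths <- c(64L, 128L, 256L, 512L)
    if (is.null(depths)) depths <- c(2L, 2L, 2L, 2L)
    s0 <- widths[1]
    mk_layer <- function(in_ch, out_ch, n, stride) {
      lapply(seq_len(n), function(i) {
        basic_block_params(if (i == 1L) in_ch else out_ch, out_ch,
                           if (i == 1L) stride else 1L)
      })
    }
    p <- list(variant = variant, widths = widths, depths = depths,
              stem1_w = .init_conv(3L, 3L, 3L, s0), stem1_b = .zeros(s0),
              stem2_w = .init_conv(3L, 3L, s0, s0), stem2_b = .zeros(s0),
              layers = list(
                mk_layer(s0, widths[1], depths[1], 1L),
                mk_layer(widths[1], widths[2], depths[2], 2L),
                mk_layer(widths[2], widths[3], depths[3], 2L),
                mk_layer(widths[3], widths[4], depths[4], 2L)))
  }
  class(p) <- c("backbone_params", "list")
  p
}

nn_backbone <- function(x, p, cfg, training = FALSE) {
  if (cfg$variant == "cspmambaout") {
    h <- ag_silu(ag_conv2d(x, p$stem1_w, p$stem1_b, stride = 2L, pad = 1L))
    h <- ag_silu(ag_conv2d(h, p$stem2_w, p$stem2_b, stride = 2L, pad = 1L))
    outs <- list()
    for (i in 1:4) {
      h <- nn_csp_stage(h, p$stages[[i]], cfg$stages[[i]])
      outs[[i]] <- h
    }
  } else {
    h <- ag_relu(ag_conv2d(x, p$stem1_w, p$stem1_b, stride = 2L, pad = 1L))
    h <- ag_relu(ag_conv2d(h, p$stem2_w, p$stem2_b, stride = 2L, pad = 1L))
    outs <- list()
    for (i in 1:4) {
      for (j in seq_along(p$layers[[i]])) {
        h <- nn_basic_block(h, p$layers[[i]][[j]], cfg$layers[[i]][[j]],
                            training)
      }
      outs[[i]] <- h
    }
  }
  list(S3 = outs[[2]], S4 = outs[[3]], S5 = outs[[4]])
}

#' Run a backbone forward pass
#'
#' @param image (B, 3, H, W) or (3, H, W) array; H and W divisible by 32
#' @param config a [backbone_params()] list
#' @return list with S3, S4, S5 grids at strides 8, 16, 32 (same batch
#'   convention as the input)
#' @export
backbone_forward <- function(image, config) {
  d <- dim(image)
  x <- .to_hwbc(image)
  dh <- dim(x)
  if (dh[1] %% 32 != 0 || dh[2] %% 32 != 0) {
    stop("input side must be divisible by 32, got ", dh[1], "x", dh[2])
  }
  if (dh[4] != 3L) stop("backbone expects 3 input channels")
  tree <- .wrap_tree(config)
  outs <- ag_no_grad(nn_backbone(ag_const(x), tree, config))
  lapply(outs, function(o) .to_orig(ag_value(o), d))
}

# Configuration fields that must never become trainable leaves.
.cfg_fields <- c("variant", "widths", "depths", "in_ch", "out_ch",
                 "num_blocks", "stride", "channels", "kernel", "hidden",
                 "embed_dim", "num_heads", "epsilon", "ffn_ratio", "gamma",
                 "gammas", "num_classes", "num_queries", "hidden_dim",
                 "decoder_layers", "image_size", "seed", "n_ret", "depth")

# Recursively wrap numeric leaves of a nested parameter list as tape
# leaves; unnamed sub-lists (block stacks, decoder layers) recurse by index.
.wrap_tree <- function(p) {
  if (is.numeric(p)) return(ag_param(p))
  if (inherits(p, "axial_rope") || inherits(p, "decay_spec") ||
      is.environment(p)) return(p)
  if (is.list(p)) {
    out <- p
    nms <- names(p)
    for (i in seq_along(p)) {
      nm <- if (!is.null(nms)) nms[i] else ""
      out[[i]] <- if (nzchar(nm) && nm %in% .cfg_fields) {
        p[[i]]
      } else {
        .wrap_tree(p[[i]])
      }
    }
    return(out)
  }
  p
}

# Flatten the node tree into a named list of leaf nodes for the optimizer.
.collect_leaves <- function(tree, prefix = "") {
  out <- list()
  nms <- names(tree)
  for (i in seq_along(tree)) {
    el <- tree[[i]]
    nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (inherits(el, "ag_node")) {
      out[[key]] <- el
    } else if (is.list(el) && !inherits(el, "axial_rope")) {
      out <- c(out, .collect_leaves(el, key))
    }
  }
  out
}
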