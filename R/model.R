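# Detector assembly: backbone x intra-scale block x aggregation block (the
# 2^3 ablation grid), hybrid encoder with top-down/bottom-up cross-scale
# fusion, objectness-based query selection, a multi-head cross-attention
# decoder, and class/box prediction heads. NMS-free set prediction.

#' Detector configuration
#'
#' The three architectural toggles span the ablation grid: backbone
#' (`cspmambaout` vs `resnet18`), intra-scale block on S5 (`aifi_mala` vs
#' `aifi_mhsa`) and cross-scale aggregation (`retblockc3` vs `repc3`). The
#' full improved model is (cspmambaout, aifi_mala, retblockc3); the full
#' baseline is (resnet18, aifi_mhsa, repc3).
#'
#' @param backbone one of "cspmambaout", "resnet18"
#' @param intra_scale one of "aifi_mala", "aifi_mhsa"
#' @param aggregation one of "retblockc3", "repc3"
#' @param hidden_dim encoder/decoder width (head_dim must be divisible by 4)
#' @param num_heads attention heads
#' @param num_queries decoder object queries
#' @param decoder_layers decoder depth
#' @param num_classes detection classes
#' @param image_size nominal square input side (divisible by 32)
#' @param seed initialisation seed
#' @param widths,depths backbone stage widths/depths (NULL = variant default)
#' @param n_ret RetBlocks per RetBlockC3
#' @param repc3_depth units per RepC3 stack
#' @param epsilon stability constant of the magnitude-aware attention
#' @return object of class `model_config`
#' @export
model_config <- function(backbone = c("cspmambaout", "resnet18"),
                         intra_scale = c("aifi_mala", "aifi_mhsa"),
                         aggregation = c("retblockc3", "repc3"),
                         hidden_dim = 256L, num_heads = 8L,
                         num_queries = 300L, decoder_layers = 3L,
                         num_classes = 4L, image_size = 640L, seed = 0L,
                         widths = NULL, depths = NULL, n_ret = 3L,
                         repc3_depth = 3L, epsilon = 1e-6) {
  backbone <- match.arg(backbone)
  intra_scale <- match.arg(intra_scale)
  aggregation <- match.arg(aggregation)
  D <- as.integer(hidden_dim)
  if (D %% num_heads != 0 || (D %/% num_heads) %% 4 != 0) {
    stop("hidden_dim / num_heads must be an integer divisible by 4")
  }
  if (image_size %% 32 != 0) stop("image_size must be divisible by 32")
  structure(list(backbone = backbone, intra_scale = intra_scale,
                 aggregation = aggregation, hidden_dim = D,
                 num_heads = as.integer(num_heads),
                 num_queries = as.integer(num_queries),
                 decoder_layers = as.integer(decoder_layers),
                 num_classes = as.integer(num_classes),
                 image_size = as.integer(image_size), seed = as.integer(seed),
                 widths = widths, depths = depths, n_ret = as.integer(n_ret),
                 repc3_depth = as.integer(repc3_depth), epsilon = epsilon),
            class = "model_config")
}

.agg_params <- function(kind, in_ch, out_ch, cfg) {
  if (kind == "retblockc3") {
    retblockc3_params(in_ch, out_ch, n_ret = cfg$n_ret,
                      num_heads = cfg$num_heads)
  } else {
    list(entry_w = .init_lin(in_ch, out_ch), entry_b = .zeros(out_ch),
         rep = repc3_params(out_ch, cfg$repc3_depth))
  }
}

nn_agg <- function(x, p, cfg_p, kind, training) {
  if (kind == "retblockc3") {
    nn_retblockc3(x, p, cfg_p)
  } else {
    nn_repc3(ag_silu(ag_conv1x1(x, p$entry_w, p$entry_b)),
             p$rep, cfg_p$rep, training)
  }
}

.dec_layer_params <- function(D, ffn_hid) {
  list(ln1_g = .ones(D), ln1_b = .zeros(D),
       wqkv = .init_lin(D, 3L * D), bqkv = .zeros(3L * D),
       wo = .init_lin(D, D), bo = .zeros(D),
       ln2_g = .ones(D), ln2_b = .zeros(D),
       cq_w = .init_lin(D, D), cq_b = .zeros(D),
       ck_w = .init_lin(D, D), ck_b = .zeros(D),
       cv_w = .init_lin(D, D), cv_b = .zeros(D),
       co_w = .init_lin(D, D), co_b = .zeros(D),
       ln3_g = .ones(D), ln3_b = .zeros(D),
       ffn_w1 = .init_lin(D, ffn_hid), ffn_b1 = .zeros(ffn_hid),
       ffn_w2 = .init_lin(ffn_hid, D), ffn_b2 = .zeros(D))
}

#' Build a detector
#'
#' Instantiates all parameters for the configured variant. The same
#' (config, seed) pair always produces identical initial parameters.
#'
#' @param config a [model_config()]
#' @return object of class `detr_model` holding parameter nodes, the plain
#'   parameter arrays (for configuration lookups), and the config
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  set.seed(config$seed)
  D <- config$hidden_dim
  nc <- config$num_classes
  bb <- backbone_params(config$backbone, config$widths, config$depths)
  wS <- bb$widths
  arrays <- list(
    backbone = bb,
    proj3_w = .init_lin(wS[2], D), proj3_b = .zeros(D),
    proj4_w = .init_lin(wS[3], D), proj4_b = .zeros(D),
    proj5_w = .init_lin(wS[4], D), proj5_b = .zeros(D),
    aifi = if (config$intra_scale == "aifi_mala") {
      mala_params(D, config$num_heads, config$epsilon)
    } else {
      mhsa_params(D, config$num_heads)
    },
    agg_f4 = .agg_params(config$aggregation, 2L * D, D, config),
    agg_f3 = .agg_params(config$aggregation, 2L * D, D, config),
    agg_n4 = .agg_params(config$aggregation, 2L * D, D, config),
    agg_n5 = .agg_params(config$aggregation, 2L * D, D, config),
    down1_w = .init_conv(3L, 3L, D, D), down1_b = .zeros(D),
    down2_w = .init_conv(3L, 3L, D, D), down2_b = .zeros(D),
    level_emb = matrix(stats::rnorm(3L * D, sd = 0.02), 3L, D),
    enc_cls_w = .init_lin(D, nc), enc_cls_b = rep(-4, nc),
    enc_box_w1 = .init_lin(D, D), enc_box_b1 = .zeros(D),
    enc_box_w2 = .zeros(D, 4L), enc_box_b2 = .zeros(4L),
    qproj_w = .init_lin(D, D), qproj_b = .zeros(D),
    dec = lapply(seq_len(config$decoder_layers),
                 function(i) .dec_layer_params(D, 4L * D)),
    lnf_g = .ones(D), lnf_b = .zeros(D),
    cls_w = .init_lin(D, nc), cls_b = rep(-4, nc),
    box_w1 = .init_lin(D, D), box_b1 = .zeros(D),
    box_w2 = .zeros(D, 4L), box_b2 = .zeros(4L))
  tree <- .wrap_tree(arrays)
  params <- .collect_leaves(tree)
  structure(list(config = config, arrays = arrays, tree = tree,
                 params = params),
            class = "detr_model")
}

# Layer norm over channels of token node (N, B, D); free reshapes.
nn_ln_tokens <- function(x, g, b) {
  d <- dim(ag_value(x))
  xm <- ag_reshape(x, c(d[1] * d[2], d[3]))
  ag_reshape(ag_layernorm_cols(xm, g, b), d)
}

# Pointwise linear map of token node (N, B, D) -> (N, B, M).
nn_linear_tokens <- function(x, w, b = NULL) {
  d <- dim(ag_value(x))
  M <- ncol(if (inherits(w, "ag_node")) w$v else w)
  xm <- ag_reshape(x, c(d[1] * d[2], d[3]))
  ym <- ag_matmul(xm, w)
  if (!is.null(b)) ym <- ag_add_colvec(ym, b)
  ag_reshape(ym, c(d[1], d[2], M))
}

# Fold a token node (n, B, D) into per-head slices (n, dh, nh*B).
.tok_heads_nbd <- function(x, nh) {
  d <- dim(ag_value(x))
  dh <- d[3] %/% nh
  ag_reshape(ag_aperm(ag_reshape(x, c(d[1], d[2], dh, nh)),
                      c(1L, 3L, 4L, 2L)), c(d[1], dh, nh * d[2]))
}

.untok_heads_nbd <- function(x, n, B, D, nh) {
  dh <- D %/% nh
  ag_reshape(ag_aperm(ag_reshape(x, c(n, dh, nh, B)), c(1L, 4L, 2L, 3L)),
             c(n, B, D))
}

# Batched multi-head softmax attention on token nodes.
# q (nq, B, D), k/v (nk, B, D) -> (nq, B, D)
nn_mh_attention <- function(q, k, v, num_heads) {
  dq <- dim(ag_value(q)); dk <- dim(ag_value(k))
  D <- dq[3]; B <- dq[2]
  dh <- D %/% num_heads
  Q <- .tok_heads_nbd(q, num_heads)
  K <- .tok_heads_nbd(k, num_heads)
  V <- .tok_heads_nbd(v, num_heads)
  A <- ag_softmax_rows(ag_scale(ag_bmm(Q, ag_btranspose(K)), 1 / sqrt(dh)))
  .untok_heads_nbd(ag_bmm(A, V), dq[1], B, D, num_heads)
}

.inv_sigmoid <- function(p, eps = 1e-5) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

# Sine-cosine embedding of box centers (n x 4 cxcywh) -> (n, D).
.box_pos_embed <- function(refs, D) {
  q <- D %/% 4L
  omega <- 10000^(-(seq_len(q) - 1) / q)
  acx <- outer(refs[, 1] * 2 * pi, omega)
  acy <- outer(refs[, 2] * 2 * pi, omega)
  cbind(sin(acx), cos(acx), sin(acy), cos(acy))
}

#' Select decoder queries from encoder tokens
#'
#' Top-K tokens by objectness score, deterministic tie-break by token index.
#'
#' @param encoder_tokens (N x D) token features
#' @param scores_head length-N objectness scores
#' @param num_queries K
#' @return list with `indices` (K) and `queries` (K x D)
#' @export
select_queries <- function(encoder_tokens, scores_head, num_queries) {
  N <- nrow(encoder_tokens)
  if (N < num_queries) {
    stop("token count ", N, " is smaller than num_queries ", num_queries)
  }
  idx <- order(-scores_head)[seq_len(num_queries)]
  list(indices = idx, queries = encoder_tokens[idx, , drop = FALSE])
}

# Full forward pass. x: (H, W, 3, B) plain array (internal layout).
# Returns nodes for encoder and decoder outputs plus selection bookkeeping.
nn_model_forward <- function(model, x, training = FALSE, hooks = NULL) {
  cfg <- model$config
  p <- model$tree
  a <- model$arrays
  D <- cfg$hidden_dim
  nc <- cfg$num_classes
  B <- dim(x)[3]
  img <- dim(x)[1]

  feats <- nn_backbone(ag_const(x), p$backbone, a$backbone, training)
  S3 <- ag_conv1x1(feats$S3, p$proj3_w, p$proj3_b)
  S4 <- ag_conv1x1(feats$S4, p$proj4_w, p$proj4_b)
  S5 <- ag_conv1x1(feats$S5, p$proj5_w, p$proj5_b)

  P5 <- if (cfg$intra_scale == "aifi_mala") {
    nn_aifi_mala(S5, p$aifi, a$aifi)
  } else {
    nn_aifi_mhsa(S5, p$aifi, a$aifi)
  }

  kind <- cfg$aggregation
  F4 <- nn_agg(ag_concat_ch(ag_upsample2x(P5), S4), p$agg_f4, a$agg_f4,
               kind, training)
  F3 <- nn_agg(ag_concat_ch(ag_upsample2x(F4), S3), p$agg_f3, a$agg_f3,
               kind, training)
  D3 <- ag_silu(ag_conv2d(F3, p$down1_w, p$down1_b, stride = 2L, pad = 1L))
  N4 <- nn_agg(ag_concat_ch(D3, F4), p$agg_n4, a$agg_n4, kind, training)
  D4 <- ag_silu(ag_conv2d(N4, p$down2_w, p$down2_b, stride = 2L, pad = 1L))
  N5 <- nn_agg(ag_concat_ch(D4, P5), p$agg_n5, a$agg_n5, kind, training)

  if (!is.null(hooks)) {
    for (nm in c("F3", "N4", "N5")) {
      nd <- switch(nm, F3 = F3, N4 = N4, N5 = N5)
      nd$keep_grad <- TRUE
      hooks[[paste0("ccfm.", tolower(nm))]] <- nd
    }
  }

  levels <- list(F3, N4, N5)
  strides <- c(8L, 16L, 32L)
  toks <- list()
  pos_list <- list()
  anchors <- NULL
  for (l in 1:3) {
    dl <- dim(ag_value(levels[[l]]))
    H <- dl[1]; W <- dl[2]
    tk <- ag_reshape(levels[[l]], c(H * W, B, D))
    tk <- ag_add_rowvec3(tk, ag_take_rows(p$level_emb, l))
    toks[[l]] <- tk
    pos_list[[l]] <- sincos_embed_2d(H, W, D)
    s <- strides[l]
    hh <- rep(seq_len(H) - 0.5, W)
    ww <- rep(seq_len(W) - 0.5, each = H)
    wh <- min(max(4 * s / img, 0.05), 0.95)
    anchors <- rbind(anchors, cbind(ww * s / img, hh * s / img, wh, wh))
  }
  mem <- ag_concat_rows(toks)
  mempos <- do.call(rbind, pos_list)
  N <- nrow(anchors)

  enc_logits <- nn_linear_tokens(mem, p$enc_cls_w, p$enc_cls_b)  # (N, B, nc)
  eh <- ag_gelu(nn_linear_tokens(mem, p$enc_box_w1, p$enc_box_b1))
  enc_delta <- nn_linear_tokens(eh, p$enc_box_w2, p$enc_box_b2)  # (N, B, 4)
  anchor_logit <- .inv_sigmoid(anchors)
  al_nb4 <- array(0, c(N, B, 4L))
  for (j in 1:4) al_nb4[, , j] <- anchor_logit[, j]
  enc_boxes <- ag_sigmoid(ag_add(enc_delta, ag_const(al_nb4)))

  # query selection: top-K by max-class objectness (deterministic tie-break)
  elv <- ag_value(enc_logits)
  nq <- cfg$num_queries
  if (N < nq) stop("token count ", N, " < num_queries ", nq)
  sel <- matrix(0L, nq, B)
  refs <- array(0, c(nq, B, 4L))
  qlist <- vector("list", B)
  ebv <- ag_value(enc_boxes)
  for (b in seq_len(B)) {
    pm <- matrix(elv[, b, ], N)
    sc <- pm[cbind(seq_len(N), max.col(pm, ties.method = "first"))]
    idx <- order(-sc)[seq_len(nq)]
    sel[, b] <- idx
    refs[, b, ] <- ebv[idx, b, ]
    qlist[[b]] <- ag_take_rows(ag_slice_batch(mem, b), idx)
  }
  tgt <- nn_linear_tokens(ag_stack_batch(qlist), p$qproj_w, p$qproj_b)

  qpos <- array(0, c(nq, B, D))
  for (b in seq_len(B)) qpos[, b, ] <- .box_pos_embed(matrix(refs[, b, ], nq),
                                                      D)
  qpos <- ag_const(qpos)
  memkpos <- ag_const(aperm(array(mempos, c(N, D, B)), c(1L, 3L, 2L)))
  memk <- ag_add(mem, memkpos)

  nh <- cfg$num_heads
  for (li in seq_len(cfg$decoder_layers)) {
    lp <- p$dec[[li]]
    t1 <- nn_ln_tokens(tgt, lp$ln1_g, lp$ln1_b)
    qk <- ag_add(t1, qpos)
    qkv_q <- nn_linear_tokens(qk, lp$wqkv, lp$bqkv)
    qkv_v <- nn_linear_tokens(t1, lp$wqkv, lp$bqkv)
    Qs <- ag_slice3_ch(qkv_q, seq_len(D))
    Ks <- ag_slice3_ch(qkv_q, D + seq_len(D))
    Vs <- ag_slice3_ch(qkv_v, 2L * D + seq_len(D))
    sa <- nn_mh_attention(Qs, Ks, Vs, nh)
    tgt <- ag_add(tgt, nn_linear_tokens(sa, lp$wo, lp$bo))
    t2 <- nn_ln_tokens(tgt, lp$ln2_g, lp$ln2_b)
    Qc <- nn_linear_tokens(ag_add(t2, qpos), lp$cq_w, lp$cq_b)
    Kc <- nn_linear_tokens(memk, lp$ck_w, lp$ck_b)
    Vc <- nn_linear_tokens(mem, lp$cv_w, lp$cv_b)
    ca <- nn_mh_attention(Qc, Kc, Vc, nh)
    tgt <- ag_add(tgt, nn_linear_tokens(ca, lp$co_w, lp$co_b))
    t3 <- nn_ln_tokens(tgt, lp$ln3_g, lp$ln3_b)
    ffn <- nn_linear_tokens(ag_gelu(nn_linear_tokens(t3, lp$ffn_w1,
                                                     lp$ffn_b1)),
                            lp$ffn_w2, lp$ffn_b2)
    tgt <- ag_add(tgt, ffn)
  }
  hs <- nn_ln_tokens(tgt, p$lnf_g, p$lnf_b)
  dec_logits <- nn_linear_tokens(hs, p$cls_w, p$cls_b)
  bh <- ag_gelu(nn_linear_tokens(hs, p$box_w1, p$box_b1))
  dec_delta <- nn_linear_tokens(bh, p$box_w2, p$box_b2)
  dec_boxes <- ag_sigmoid(ag_add(dec_delta, ag_const(.inv_sigmoid(refs))))

  list(dec_logits = dec_logits, dec_boxes = dec_boxes,
       enc_logits = enc_logits, enc_boxes = enc_boxes,
       sel = sel, refs = refs, anchors = anchors)
}

# Channel slice of a token node (N, B, D) along dim 3.
ag_slice3_ch <- function(x, idx) {
  x <- as_node(x)
  d <- dim(x$v)
  .ag_new(x$v[, , idx, drop = FALSE], list(x), function(g) {
    gg <- array(0, d)
    gg[, , idx] <- g
    list(gg)
  })
}

# Convert a batch of image_samples to the internal (S, S, B, 3) array,
# replicating grayscale to three channels.
.batch_images <- function(samples) {
  S <- nrow(samples[[1]]$image)
  B <- length(samples)
  x <- array(0, c(S, S, B, 3L))
  for (b in seq_len(B)) {
    # image matrices are (row = y, col = x); internal layout is (H, W)
    x[, , b, 1L] <- samples[[b]]$image
    x[, , b, 2L] <- samples[[b]]$image
    x[, , b, 3L] <- samples[[b]]$image
  }
  x
}

#' Run detection on images
#'
#' Per query, the score is the maximum class probability (sigmoid); all
#' queries above `score_threshold` are returned sorted by descending score.
#' No non-maximum suppression is applied.
#'
#' @param model a [build_model()] detector
#' @param images list of `image_sample` objects (or matrices in [0, 1])
#' @param score_threshold minimum score to keep a detection
#' @return list of detection sets, each with `boxes` (pixel xyxy, clipped),
#'   `scores`, `classes` (0-based)
#' @export
predict_detections <- function(model, images, score_threshold = 0.25) {
  if (inherits(images, "image_sample")) images <- list(images)
  images <- lapply(images, function(im) {
    if (is.matrix(im)) structure(list(image = im), class = "image_sample")
    else im
  })
  S <- nrow(images[[1]]$image)
  out <- vector("list", length(images))
  bs <- 8L
  i <- 1L
  while (i <= length(images)) {
    j <- min(i + bs - 1L, length(images))
    x <- .batch_images(images[i:j])
    fw <- ag_no_grad(nn_model_forward(model, x, training = FALSE))
    lg <- ag_value(fw$dec_logits)
    bx <- ag_value(fw$dec_boxes)
    for (b in seq_len(j - i + 1L)) {
      prob <- 1 / (1 + exp(-matrix(lg[, b, ], dim(lg)[1])))
      cls_i <- max.col(prob, ties.method = "first")
      scores <- prob[cbind(seq_len(nrow(prob)), cls_i)]
      cls <- cls_i - 1L
      keep <- which(scores >= score_threshold)
      keep <- keep[order(-scores[keep])]
      xy <- box_cxcywh_to_xyxy(matrix(bx[, b, ], dim(bx)[1])[keep, ,
                                                             drop = FALSE]) * S
      xy[, c(1, 3)] <- pmin(pmax(xy[, c(1, 3)], 0), S)
      xy[, c(2, 4)] <- pmin(pmax(xy[, c(2, 4)], 0), S)
      out[[i + b - 1L]] <- list(boxes = xy, scores = scores[keep],
                                classes = cls[keep])
    }
    i <- j + 1L
  }
  out
}
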