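# Set-prediction training: AdamW, Hungarian-matched detection loss on the
# decoder output plus an auxiliary loss on the encoder proposals (this is
# what makes top-K objectness selection "IoU-aware": the proposal boxes and
# scores are trained with the same matched GIoU/focal objective), early
# stopping on validation mAP@50, horizontal-flip augmentation only.

#' Training configuration
#'
#' Defaults follow the detection-transformer recipe on which the package is
#' modelled: batch size 8, 100 epochs, AdamW, early-stop patience 10,
#' seed 0. The learning rate (1e-4) and weight decay (1e-4) are package
#' defaults.
#'
#' @param epochs maximum epochs
#' @param batch_size images per step
#' @param lr AdamW learning rate
#' @param weight_decay decoupled weight decay
#' @param patience epochs without validation-mAP@50 improvement before stop
#' @param seed training seed (shuffling, augmentation)
#' @param flip_prob horizontal-flip probability
#' @param val_fraction fraction of the dataset held out for validation when
#'   no explicit validation set is given
#' @param lambda detection loss weights (cls, l1, giou)
#' @param enc_loss_weight weight of the auxiliary encoder-proposal loss
#' @param out_dir optional run directory for checkpoint/log/config
#' @param verbose print per-epoch progress
#' @return a `train_config` list
#' @export
train_config <- function(epochs = 100L, batch_size = 8L, lr = 1e-4,
                         weight_decay = 1e-4, patience = 10L, seed = 0L,
                         flip_prob = 0.5, val_fraction = 0.15,
                         lambda = c(cls = 2, l1 = 5, giou = 2),
                         enc_loss_weight = 1, out_dir = NULL,
                         verbose = FALSE) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay, patience = as.integer(patience),
                 seed = as.integer(seed), flip_prob = flip_prob,
                 val_fraction = val_fraction, lambda = lambda,
                 enc_loss_weight = enc_loss_weight, out_dir = out_dir,
                 verbose = verbose),
            class = "train_config")
}

# Ground truth of a sample in normalized cxcywh plus classes.
.gt_of <- function(sample) {
  b <- sample$boxes
  if (is.null(b) || nrow(b) == 0L) {
    list(boxes = matrix(0, 0L, 4L), classes = integer(0))
  } else {
    list(boxes = matrix(b[, 2:5], ncol = 4L), classes = as.integer(b[, 1]))
  }
}

# Ground truth in pixel xyxy (for evaluation).
.gt_pixels <- function(sample) {
  S <- nrow(sample$image)
  g <- .gt_of(sample)
  list(boxes = box_cxcywh_to_xyxy(g$boxes) * S, classes = g$classes)
}

.flip_sample <- function(sample) {
  img <- sample$image[, rev(seq_len(ncol(sample$image))), drop = FALSE]
  b <- sample$boxes
  if (nrow(b) > 0L) b[, 2] <- 1 - b[, 2]
  structure(list(image = img, boxes = b, class_id = sample$class_id,
                 meta = sample$meta), class = "image_sample")
}

# One training step on a batch; returns the scalar loss value.
.train_step <- function(model, batch, opt, tc) {
  x <- .batch_images(batch)
  fw <- nn_model_forward(model, x, training = TRUE)
  B <- length(batch)
  loss <- NULL
  for (b in seq_len(B)) {
    gt <- .gt_of(batch[[b]])
    dl <- ag_slice_batch(fw$dec_logits, b)
    db <- ag_slice_batch(fw$dec_boxes, b)
    as_dec <- hungarian_match(ag_value(db), ag_value(dl), gt,
                              weights = unname(tc$lambda))
    li <- nn_detection_loss(dl, db, gt, as_dec, tc$lambda)$total
    el <- ag_slice_batch(fw$enc_logits, b)
    eb <- ag_slice_batch(fw$enc_boxes, b)
    as_enc <- hungarian_match(ag_value(eb), ag_value(el), gt,
                              weights = unname(tc$lambda))
    le <- nn_detection_loss(el, eb, gt, as_enc, tc$lambda)$total
    term <- ag_add(li, ag_scale(le, tc$enc_loss_weight))
    loss <- if (is.null(loss)) term else ag_add(loss, term)
  }
  loss <- ag_scale(loss, 1 / B)
  ag_backward(loss)
  ag_value(loss)
}

#' Evaluate a detector on labelled samples
#'
#' @param model a detector
#' @param samples list of `image_sample` objects with boxes
#' @param score_threshold operating point for precision/recall
#' @return an `eval_result` (see [evaluate()])
#' @export
evaluate_model <- function(model, samples, score_threshold = 0.25) {
  dets <- predict_detections(model, samples, score_threshold = 0.001)
  gts <- lapply(samples, .gt_pixels)
  evaluate(dets, gts, classes = 0:(model$config$num_classes - 1L),
           score_thr = score_threshold)
}

#' Train a detector
#'
#' Standard loop with shuffled minibatches, horizontal-flip augmentation,
#' AdamW updates, and early stopping on validation mAP@50. When
#' `tc$out_dir` is set, the resolved configuration, a per-epoch plain-text
#' metric log and the best checkpoint are written there.
#'
#' @param model a [build_model()] detector (modified in place and returned)
#' @param dataset non-empty list of `image_sample` objects
#' @param tc a [train_config()]
#' @param val_data optional explicit validation set; otherwise
#'   `val_fraction` of `dataset` is held out
#' @return list with `model`, `log` (data frame), `best_mAP50`, `epochs_run`
#' @export
train_model <- function(model, dataset, tc = train_config(),
                        val_data = NULL) {
  if (length(dataset) == 0L) stop("empty training dataset")
  set.seed(tc$seed)
  if (is.null(val_data)) {
    nval <- max(1L, round(tc$val_fraction * length(dataset)))
    vi <- sample.int(length(dataset), nval)
    val_data <- dataset[vi]
    dataset <- dataset[-vi]
  }
  if (!is.null(tc$out_dir)) {
    dir.create(tc$out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(c(unclass(tc)[!vapply(tc, is.null, TRUE)],
                       list(model = unclass(model$config)[
                         !vapply(model$config, is.null, TRUE)])),
                     file.path(tc$out_dir, "config.yaml"))
  }
  opt <- adamw_init(model$params)
  best <- -Inf
  best_state <- NULL
  wait <- 0L
  log <- data.frame()
  epochs_run <- 0L
  for (ep in seq_len(tc$epochs)) {
    ord <- sample.int(length(dataset))
    flips <- stats::runif(length(dataset)) < tc$flip_prob
    ep_loss <- 0
    nb <- 0L
    i <- 1L
    while (i <= length(ord)) {
      j <- min(i + tc$batch_size - 1L, length(ord))
      batch <- lapply(seq(i, j), function(k) {
        s <- dataset[[ord[k]]]
        if (flips[ord[k]]) .flip_sample(s) else s
      })
      ep_loss <- ep_loss + .train_step(model, batch, opt, tc)
      opt <- adamw_step(model$params, opt, lr = tc$lr,
                        weight_decay = tc$weight_decay)
      nb <- nb + 1L
      i <- j + 1L
    }
    ev <- evaluate_model(model, val_data)
    m50 <- ev$mAP50
    epochs_run <- ep
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / nb,
                                 val_mAP50 = m50))
    if (tc$verbose) {
      message(sprintf("epoch %3d  loss %.4f  val mAP@50 %.4f",
                      ep, ep_loss / nb, m50))
    }
    if (m50 > best) {
      best <- m50
      wait <- 0L
      best_state <- lapply(model$params, function(p) p$v)
    } else {
      wait <- wait + 1L
      if (wait >= tc$patience) break
    }
  }
  if (!is.null(best_state)) {
    for (nm in names(best_state)) model$params[[nm]]$v <- best_state[[nm]]
  }
  if (!is.null(tc$out_dir)) {
    utils::write.table(log, file.path(tc$out_dir, "metrics.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    save_checkpoint(model, file.path(tc$out_dir, "checkpoint.rds"))
  }
  list(model = model, log = log, best_mAP50 = best, epochs_run = epochs_run)
}

#' Save model parameters and configuration
#' @param model a detector
#' @param path destination file (RDS)
#' @export
save_checkpoint <- function(model, path) {
  bns <- .collect_bn(model$arrays)
  saveRDS(list(config = model$config,
               values = lapply(model$params, function(p) p$v),
               bn = lapply(bns, function(e) list(m = e$running_mean,
                                                 v = e$running_var))),
          path)
  invisible(path)
}

# Named list of batch-norm state environments in a parameter tree.
.collect_bn <- function(tree, prefix = "") {
  out <- list()
  nms <- names(tree)
  for (i in seq_along(tree)) {
    el <- tree[[i]]
    nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.environment(el) && !is.null(el$running_mean)) {
      out[[key]] <- el
    } else if (is.list(el) && !inherits(el, "axial_rope")) {
      out <- c(out, .collect_bn(el, key))
    }
  }
  out
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path checkpoint file
#' @return a detector with restored parameters
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config)
  for (nm in names(ck$values)) model$params[[nm]]$v <- ck$values[[nm]]
  if (!is.null(ck$bn)) {
    bns <- .collect_bn(model$arrays)
    for (nm in names(ck$bn)) {
      bns[[nm]]$running_mean <- ck$bn[[nm]]$m
      bns[[nm]]$running_var <- ck$bn[[nm]]$v
    }
  }
  model
}
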