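# Grad-CAM for the detector: the top fraction of detections by confidence
# defines the backpropagation objective (classification logits plus box
# regression outputs jointly); channel weights are spatial gradient means.

#' Gradient-weighted class activation maps
#'
#' Selects the `ceil(top_fraction * num_queries)` highest-confidence
#' detections, backpropagates the scalar objective
#' sum(max class logit + sum of box regression outputs), and for each
#' target module weights each activation channel by the spatial mean of its
#' gradient, sums over channels, rectifies, min-max normalises to [0, 1]
#' (an all-zero map stays zero) and upsamples to the image size.
#'
#' @param model a [build_model()] detector
#' @param image an `image_sample` or an S x S matrix in [0, 1]
#' @param target_modules named activation hooks; available:
#'   "ccfm.f3", "ccfm.n4", "ccfm.n5" (cross-scale fusion outputs)
#' @param top_fraction fraction of queries used as targets (default 0.02)
#' @return named list of S x S heatmap matrices in [0, 1]
#' @export
grad_cam <- function(model, image,
                     target_modules = c("ccfm.f3", "ccfm.n4", "ccfm.n5"),
                     top_fraction = 0.02) {
  if (is.matrix(image)) {
    image <- structure(list(image = image), class = "image_sample")
  }
  S <- nrow(image$image)
  hooks <- new.env(parent = emptyenv())
  x <- .batch_images(list(image))
  fw <- nn_model_forward(model, x, training = FALSE, hooks = hooks)
  for (tm in target_modules) {
    if (is.null(hooks[[tm]])) {
      stop("no stored activation for target module '", tm, "'; available: ",
           paste(ls(hooks), collapse = ", "))
    }
  }
  lg <- ag_slice_batch(fw$dec_logits, 1L)
  bx <- ag_slice_batch(fw$dec_boxes, 1L)
  prob <- 1 / (1 + exp(-ag_value(lg)))
  conf <- apply(prob, 1L, max)
  k <- ceiling(top_fraction * model$config$num_queries)
  idx <- order(-conf)[seq_len(k)]
  objective <- ag_add(ag_sum(ag_rowmax(ag_take_rows(lg, idx))),
                      ag_sum(ag_take_rows(bx, idx)))
  ag_backward(objective)
  out <- list()
  for (tm in target_modules) {
    nd <- hooks[[tm]]
    A <- ag_value(nd)                       # (H, W, 1, C)
    d <- dim(A)
    G <- nd$g
    if (is.null(G)) G <- array(0, d)
    Am <- matrix(A, d[1] * d[2], d[4])
    Gm <- matrix(G, d[1] * d[2], d[4])
    w <- colMeans(Gm)
    cam <- matrix(pmax(Am %*% w, 0), d[1], d[2])
    if (max(cam) > 0) cam <- (cam - min(cam)) / (max(cam) - min(cam))
    up <- EBImage::resize(cam, w = S, h = S)
    out[[tm]] <- pmin(pmax(up, 0), 1)
  }
  out
}

#' Save heatmaps as PNG files, optionally overlaid on the image
#' @param cams named list from [grad_cam()]
#' @param dir output directory
#' @param image optional background image matrix for a 50/50 overlay
#' @export
write_heatmaps <- function(cams, dir, image = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cams)) {
    cam <- cams[[nm]]
    if (!is.null(image)) cam <- 0.5 * cam + 0.5 * image
    png::writePNG(pmin(pmax(cam, 0), 1),
                  file.path(dir, paste0(gsub("[^a-z0-9]+", "_", nm), ".png")))
  }
  invisible(dir)
}
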