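# Detection metrics: IoU, COCO-style greedy matching, 101-point
# interpolated average precision, and the full per-class evaluation with
# precision/recall at IoU 0.50 and mAP over the 0.50-0.95 threshold grid.

#' Intersection over union of two boxes
#'
#' Boxes are corner-form (x1, y1, x2, y2) with the half-open pixel
#' convention; x2 > x1 and y2 > y1 are required.
#'
#' @param a,b numeric length-4 vectors
#' @return scalar in [0, 1]
#' @export
box_iou <- function(a, b) {
  if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2]) {
    stop("degenerate box: x2 > x1 and y2 > y1 are required")
  }
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

# Pairwise IoU matrix between n x 4 and m x 4 corner-form boxes.
box_iou_matrix <- function(A, B) {
  A <- matrix(A, ncol = 4L); B <- matrix(B, ncol = 4L)
  n <- nrow(A); m <- nrow(B)
  if (n == 0L || m == 0L) return(matrix(0, n, m))
  iw <- outer(A[, 3], B[, 3], pmin) - outer(A[, 1], B[, 1], pmax)
  ih <- outer(A[, 4], B[, 4], pmin) - outer(A[, 2], B[, 2], pmax)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  areaA <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2])
  areaB <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  inter / (outer(areaA, areaB, `+`) - inter)
}

#' Greedy matching of detections to ground truth (COCO convention)
#'
#' Detections are visited in descending score order; each matches the
#' highest-IoU not-yet-matched ground-truth box of the same class with IoU
#' at or above the threshold. One match per ground-truth box.
#'
#' @param dets list with `boxes` (n x 4 xyxy), `scores`, `classes`
#'   (score-sorted descending)
#' @param gts list with `boxes` (m x 4 xyxy), `classes`
#' @param iou_thr IoU threshold
#' @return list with logical `tp` per detection and integer `fn` count
#' @export
match_detections <- function(dets, gts, iou_thr) {
  nb <- if (is.null(dets$boxes)) 0L else nrow(matrix(dets$boxes, ncol = 4L))
  mg <- if (is.null(gts$boxes)) 0L else nrow(matrix(gts$boxes, ncol = 4L))
  tp <- logical(nb)
  if (nb == 0L) return(list(tp = tp, fn = mg))
  if (mg == 0L) return(list(tp = tp, fn = 0L))
  if (is.unsorted(rev(dets$scores))) {
    stop("detections must be sorted by descending score")
  }
  iou <- box_iou_matrix(matrix(dets$boxes, ncol = 4L),
                        matrix(gts$boxes, ncol = 4L))
  taken <- logical(mg)
  for (i in seq_len(nb)) {
    cand <- which(!taken & gts$classes == dets$classes[i] &
                    iou[i, ] >= iou_thr)
    if (length(cand) > 0L) {
      j <- cand[which.max(iou[i, cand])]
      taken[j] <- TRUE
      tp[i] <- TRUE
    }
  }
  list(tp = tp, fn = sum(!taken))
}

#' 101-point interpolated average precision
#'
#' Area under the precision-recall curve, COCO convention: precision is
#' evaluated on the recall grid 0.00, 0.01, ..., 1.00 as the maximum
#' precision at any recall at or to the right of each grid point. With
#' `num_gt = 0` and no detections the AP is undefined (NA, excluded from
#' means); with detections but no ground truth it is 0.
#'
#' @param flags logical TP flag per detection, score-descending order
#' @param scores detection scores (only the ordering matters)
#' @param num_gt number of ground-truth boxes
#' @return AP in [0, 1], or NA_real_
#' @export
average_precision <- function(flags, scores, num_gt) {
  if (num_gt < 0) stop("num_gt must be >= 0")
  if (num_gt == 0L) {
    return(if (length(flags) == 0L) NA_real_ else 0)
  }
  if (length(flags) == 0L) return(0)
  o <- order(scores, decreasing = TRUE)
  flags <- flags[o]
  tp <- cumsum(flags)
  fp <- cumsum(!flags)
  rec <- tp / num_gt
  prec <- tp / (tp + fp)
  # max precision to the right of each point
  pr_interp <- rev(cummax(rev(prec)))
  grid <- seq(0, 1, by = 0.01)
  # for each grid recall, first detection index with rec >= g
  idx <- findInterval(grid, rec, left.open = TRUE) + 1L
  pg <- ifelse(idx <= length(rec), pr_interp[pmin(idx, length(rec))], 0)
  mean(pg)
}

#' Evaluate detections against ground truth
#'
#' Computes per-class average precision at IoU thresholds 0.50 to 0.95 in
#' steps of 0.05, mAP@50 (mean over classes at 0.50), mAP@50-95 (mean over
#' classes and all ten thresholds), and precision/recall at IoU 0.50 using
#' all detections with score at or above `score_thr`.
#'
#' @param dets list (one element per image) of lists with `boxes`
#'   (n x 4 xyxy pixels), `scores`, `classes` (0-based class ids)
#' @param gts list (one element per image) of lists with `boxes`, `classes`
#' @param classes integer vector of class ids (0-based)
#' @param score_thr operating score threshold for P/R (default 0.25)
#' @return object of class `eval_result`: per-class AP matrix, mAP50,
#'   mAP50_95, precision, recall, TP/FP/FN counts
#' @export
evaluate <- function(dets, gts, classes, score_thr = 0.25) {
  stopifnot(length(dets) == length(gts))
  thresholds <- seq(0.50, 0.95, by = 0.05)
  all_cls <- unlist(lapply(c(dets, gts), function(x) x$classes))
  if (length(all_cls) > 0 && any(!(all_cls %in% classes))) {
    stop("class id outside the declared class set: ",
         paste(setdiff(all_cls, classes), collapse = ", "))
  }
  ap <- matrix(NA_real_, length(classes), length(thresholds),
               dimnames = list(paste0("class", classes),
                               sprintf("iou%.2f", thresholds)))
  as_box_mat <- function(b) {
    if (is.null(b) || length(b) == 0L) matrix(0, 0L, 4L) else matrix(b, ncol = 4L)
  }
  tpc <- fpc <- fnc <- 0L
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    # pool detections of this class over all images
    for (ti in seq_along(thresholds)) {
      thr <- thresholds[ti]
      flags <- logical(0)
      scores <- numeric(0)
      ngt <- 0L
      for (im in seq_along(dets)) {
        d <- dets[[im]]; g <- gts[[im]]
        sel <- which(d$classes == cl)
        sel <- sel[order(d$scores[sel], decreasing = TRUE)]
        gsel <- which(g$classes == cl)
        dd <- list(boxes = as_box_mat(d$boxes)[sel, , drop = FALSE],
                   scores = d$scores[sel], classes = d$classes[sel])
        gg <- list(boxes = as_box_mat(g$boxes)[gsel, , drop = FALSE],
                   classes = g$classes[gsel])
        mm <- match_detections(dd, gg, thr)
        flags <- c(flags, mm$tp)
        scores <- c(scores, dd$scores)
        ngt <- ngt + length(gsel)
      }
      ap[ci, ti] <- average_precision(flags, scores, ngt)
    }
    # P/R at IoU 0.50 on score-thresholded detections only
    for (im in seq_along(dets)) {
      d <- dets[[im]]; g <- gts[[im]]
      sel <- which(d$classes == cl & d$scores >= score_thr)
      sel <- sel[order(d$scores[sel], decreasing = TRUE)]
      gsel <- which(g$classes == cl)
      dd <- list(boxes = as_box_mat(d$boxes)[sel, , drop = FALSE],
                 scores = d$scores[sel], classes = d$classes[sel])
      gg <- list(boxes = as_box_mat(g$boxes)[gsel, , drop = FALSE],
                 classes = g$classes[gsel])
      mm <- match_detections(dd, gg, 0.50)
      tpc <- tpc + sum(mm$tp)
      fpc <- fpc + sum(!mm$tp)
      fnc <- fnc + mm$fn
    }
  }
  mAP50 <- mean(ap[, 1], na.rm = TRUE)
  mAP50_95 <- mean(ap, na.rm = TRUE)
  precision <- if (tpc + fpc > 0) tpc / (tpc + fpc) else NA_real_
  recall <- if (tpc + fnc > 0) tpc / (tpc + fnc) else NA_real_
  structure(list(ap = ap, mAP50 = mAP50, mAP50_95 = mAP50_95,
                 precision = precision, recall = recall,
                 tp = tpc, fp = fpc, fn = fnc,
                 thresholds = thresholds, classes = classes,
                 score_thr = score_thr),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("Detection evaluation\n")
  cat(sprintf("  mAP@50    : %.4f\n", x$mAP50))
  cat(sprintf("  mAP@50-95 : %.4f\n", x$mAP50_95))
  cat(sprintf("  P / R (IoU 0.50, score >= %.2f): %.4f / %.4f\n",
              x$score_thr, x$precision, x$recall))
  cat("  per-class AP@50:\n")
  for (i in seq_len(nrow(x$ap))) {
    cat(sprintf("    %-8s %.4f\n", rownames(x$ap)[i], x$ap[i, 1]))
  }
  invisible(x)
}

#' Write an evaluation report as a machine-readable table
#' @param res an `eval_result`
#' @param path TSV output path
#' @export
write_eval_report <- function(res, path) {
  df <- data.frame(class = rownames(res$ap), res$ap, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
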