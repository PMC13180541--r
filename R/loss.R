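# Set-prediction training machinery: Hungarian matching and the detection
# loss (focal classification + L1 + generalised IoU on matched pairs).

# Differentiable column extraction: (n, 4) node -> (n, 1) node.
.ag_col4 <- function(x, j) {
  e <- matrix(0, 4L, 1L)
  e[j, 1L] <- 1
  ag_matmul(x, ag_const(e))
}

# Generalised IoU between two (n, 4) cxcywh box nodes -> (n, 1) node.
nn_giou <- function(p, g) {
  px1 <- ag_sub(.ag_col4(p, 1L), ag_scale(.ag_col4(p, 3L), 0.5))
  px2 <- ag_add(.ag_col4(p, 1L), ag_scale(.ag_col4(p, 3L), 0.5))
  py1 <- ag_sub(.ag_col4(p, 2L), ag_scale(.ag_col4(p, 4L), 0.5))
  py2 <- ag_add(.ag_col4(p, 2L), ag_scale(.ag_col4(p, 4L), 0.5))
  gx1 <- ag_sub(.ag_col4(g, 1L), ag_scale(.ag_col4(g, 3L), 0.5))
  gx2 <- ag_add(.ag_col4(g, 1L), ag_scale(.ag_col4(g, 3L), 0.5))
  gy1 <- ag_sub(.ag_col4(g, 2L), ag_scale(.ag_col4(g, 4L), 0.5))
  gy2 <- ag_add(.ag_col4(g, 2L), ag_scale(.ag_col4(g, 4L), 0.5))
  iw <- ag_relu(ag_sub(ag_pmin2(px2, gx2), ag_pmax2(px1, gx1)))
  ih <- ag_relu(ag_sub(ag_pmin2(py2, gy2), ag_pmax2(py1, gy1)))
  inter <- ag_mul(iw, ih)
  pa <- ag_mul(ag_sub(px2, px1), ag_sub(py2, py1))
  ga <- ag_mul(ag_sub(gx2, gx1), ag_sub(gy2, gy1))
  union <- ag_sub(ag_add(pa, ga), inter)
  # clamping only guards true degeneracy (zero-area boxes); for valid boxes
  # the ratio is exact, so perfect matches give GIoU = 1 exactly
  iou <- ag_mul(inter, ag_recip(ag_clamp(union, 1e-12, Inf)))
  cw <- ag_sub(ag_pmax2(px2, gx2), ag_pmin2(px1, gx1))
  ch <- ag_sub(ag_pmax2(py2, gy2), ag_pmin2(py1, gy1))
  ca <- ag_mul(cw, ch)
  ag_sub(iou, ag_mul(ag_sub(ca, union),
                     ag_recip(ag_clamp(ca, 1e-12, Inf))))
}

# Plain-array GIoU (used for matching costs).
.giou_matrix <- function(P, G) {
  # P (n, 4), G (m, 4), both cxcywh -> n x m GIoU
  Px <- box_cxcywh_to_xyxy(P); Gx <- box_cxcywh_to_xyxy(G)
  n <- nrow(Px); m <- nrow(Gx)
  iw <- pmax(outer(Px[, 3], Gx[, 3], pmin) - outer(Px[, 1], Gx[, 1], pmax), 0)
  ih <- pmax(outer(Px[, 4], Gx[, 4], pmin) - outer(Px[, 2], Gx[, 2], pmax), 0)
  inter <- iw * ih
  pa <- (Px[, 3] - Px[, 1]) * (Px[, 4] - Px[, 2])
  ga <- (Gx[, 3] - Gx[, 1]) * (Gx[, 4] - Gx[, 2])
  union <- outer(pa, ga, `+`) - inter
  iou <- inter / pmax(union, 1e-12)
  cw <- outer(Px[, 3], Gx[, 3], pmax) - outer(Px[, 1], Gx[, 1], pmin)
  ch <- outer(Px[, 4], Gx[, 4], pmax) - outer(Px[, 2], Gx[, 2], pmin)
  ca <- cw * ch
  iou - (ca - union) / pmax(ca, 1e-12)
}

#' One-to-one matching of predictions to ground truth
#'
#' Minimises the set-prediction cost
#' \eqn{\lambda_{cls}(-p_{c_j}) + \lambda_{L1}\|b_i - b_j\|_1 +
#' \lambda_{giou}(1 - \mathrm{GIoU}(b_i, b_j))} over one-to-one assignments;
#' unmatched queries are background.
#'
#' @param pred_boxes (num_queries x 4) normalized cxcywh
#' @param pred_logits (num_queries x num_classes) raw logits (sigmoid scores)
#' @param gt list with `boxes` (m x 4 normalized cxcywh) and `classes`
#'   (0-based ids)
#' @param weights cost weights (class, L1, giou); defaults (2, 5, 2)
#' @return integer vector of length num_queries: index of the matched
#'   ground-truth box, or 0 for background
#' @export
hungarian_match <- function(pred_boxes, pred_logits, gt,
                            weights = c(2, 5, 2)) {
  nq <- nrow(pred_boxes)
  m <- if (is.null(gt$boxes) || length(gt$boxes) == 0L) 0L else
    nrow(matrix(gt$boxes, ncol = 4L))
  if (m == 0L) return(integer(nq))
  G <- matrix(gt$boxes, ncol = 4L)
  prob <- 1 / (1 + exp(-pred_logits))
  cls_cost <- -prob[, gt$classes + 1L, drop = FALSE]
  l1_cost <- matrix(0, nq, m)
  for (j in seq_len(m)) {
    l1_cost[, j] <- rowSums(abs(pred_boxes - matrix(G[j, ], nq, 4L,
                                                    byrow = TRUE)))
  }
  giou_cost <- 1 - .giou_matrix(pred_boxes, G)
  cost <- weights[1] * cls_cost + weights[2] * l1_cost +
    weights[3] * giou_cost
  if (any(!is.finite(cost))) stop("non-finite matching costs")
  solve_assignment(cost)
}

# Focal binary cross-entropy on a logits node with a constant target
# matrix; returns the summed loss node.
nn_focal_bce <- function(logits, targets, alpha = 0.25, gamma = 2) {
  p <- ag_clamp(ag_sigmoid(logits), 1e-7, 1 - 1e-7)
  q <- ag_add_const(ag_neg(p), 1)             # 1 - p
  pos <- ag_mul(ag_mul(ag_pow_const(q, gamma), ag_log(p)),
                ag_const(targets * alpha))
  neg <- ag_mul(ag_mul(ag_pow_const(p, gamma), ag_log(q)),
                ag_const((1 - targets) * (1 - alpha)))
  ag_neg(ag_add(ag_sum(pos), ag_sum(neg)))
}

# Node-level detection loss for one image. logits (nq, nc) node, boxes
# (nq, 4) node, gt plain, assignment integer vector.
nn_detection_loss <- function(logits, boxes, gt, assignment,
                              lambda = c(cls = 2, l1 = 5, giou = 2),
                              focal_alpha = 0.25, focal_gamma = 2) {
  nq <- nrow(ag_value(logits))
  nc <- ncol(ag_value(logits))
  matched <- which(assignment > 0L)
  norm <- max(1, length(matched))
  targets <- matrix(0, nq, nc)
  if (length(matched) > 0L) {
    targets[cbind(matched, gt$classes[assignment[matched]] + 1L)] <- 1
  }
  cls <- ag_scale(nn_focal_bce(logits, targets, focal_alpha, focal_gamma),
                  1 / norm)
  if (length(matched) > 0L) {
    pb <- ag_take_rows(boxes, matched)
    gb <- ag_const(matrix(gt$boxes, ncol = 4L)[assignment[matched], ,
                                               drop = FALSE])
    l1 <- ag_scale(ag_sum(ag_abs(ag_sub(pb, gb))), 1 / norm)
    gi <- ag_scale(ag_sum(ag_add_const(ag_neg(nn_giou(pb, gb)), 1)), 1 / norm)
  } else {
    l1 <- ag_const(0)
    gi <- ag_const(0)
  }
  total <- ag_add(ag_add(ag_scale(cls, lambda[["cls"]]),
                         ag_scale(l1, lambda[["l1"]])),
                  ag_scale(gi, lambda[["giou"]]))
  list(total = total, cls = cls, l1 = l1, giou = gi)
}

#' Detection loss for one image
#'
#' Focal-style binary cross-entropy over classes (background negatives
#' included), plus L1 and (1 - GIoU) terms on matched pairs, each
#' normalised by the number of matches. The returned total satisfies
#' `total == sum(lambda * components)` exactly.
#'
#' @param preds list with `logits` (num_queries x num_classes) and `boxes`
#'   (num_queries x 4 normalized cxcywh)
#' @param gt list with `boxes`, `classes`
#' @param assignment integer vector from [hungarian_match()]
#' @param lambda named loss weights (cls, l1, giou)
#' @return list with `total` and `components` (cls, l1, giou)
#' @export
detection_loss <- function(preds, gt, assignment,
                           lambda = c(cls = 2, l1 = 5, giou = 2)) {
  out <- nn_detection_loss(ag_const(preds$logits), ag_const(preds$boxes),
                           gt, assignment, lambda)
  list(total = ag_value(out$total),
       components = c(cls = ag_value(out$cls), l1 = ag_value(out$l1),
                      giou = ag_value(out$giou)))
}
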