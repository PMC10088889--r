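#' Pixel confusion counts
#'
#' @param pred_binary,target binary matrices of identical shape.
#' @return a list with integer counts `tp`, `fp`, `tn`, `fn` summing to the
#'   pixel count.
#' @export
confusion <- function(pred_binary, target) {
  assert_binary_mask(pred_binary, "pred_binary")
  assert_binary_mask(target, "target")
  check_shapes(pred_binary, target)
  tp <- sum(pred_binary == 1 & target == 1)
  fp <- sum(pred_binary == 1 & target == 0)
  tn <- sum(pred_binary == 0 & target == 0)
  fn <- sum(pred_binary == 0 & target == 1)
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Dice coefficient from confusion counts
#'
#' `2*tp / (2*tp + fp + fn)`; defined as 1 when prediction and target are both
#' empty (a correctly empty prediction is perfect, not undefined).
#'
#' @param c confusion counts from [confusion()].
#' @return value in \[0, 1\].
#' @export
dice_coefficient <- function(c) {
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0) return(1)
  2 * c$tp / den
}

#' Precision (positive predictive value)
#'
#' `tp / (tp + fp)`; `NA` when nothing is predicted positive, so that
#' aggregate means are taken over defined cases only.
#'
#' @inheritParams dice_coefficient
#' @return value in \[0, 1\] or `NA`.
#' @export
precision <- function(c) {
  den <- c$tp + c$fp
  if (den == 0) return(NA_real_)
  c$tp / den
}

#' Specificity (true negative rate)
#'
#' `tn / (tn + fp)`; `NA` when the target has no background.
#'
#' @inheritParams dice_coefficient
#' @return value in \[0, 1\] or `NA`.
#' @export
specificity <- function(c) {
  den <- c$tn + c$fp
  if (den == 0) return(NA_real_)
  c$tn / den
}

#' Pixel accuracy
#'
#' `(tp + tn) / (tp + fp + tn + fn)`.
#'
#' @inheritParams dice_coefficient
#' @return value in \[0, 1\].
#' @export
pixel_accuracy <- function(c) {
  (c$tp + c$tn) / (c$tp + c$fp + c$tn + c$fn)
}

#' Per-case IoU and class-averaged mIoU
#'
#' Foreground IoU per case is `tp / (tp + fp + fn)`; mIoU averages the
#' foreground IoU and the background IoU `tn / (tn + fp + fn)` over the two
#' classes, then over cases.
#'
#' @param cases list of confusion-count lists.
#' @return list with numeric vector `iou` (per case, foreground) and scalar
#'   `miou`.
#' @export
iou_and_miou <- function(cases) {
  if (length(cases) == 0L) stop("no cases supplied")
  fg <- vapply(cases, function(c) {
    den <- c$tp + c$fp + c$fn
    if (den == 0) 1 else c$tp / den
  }, numeric(1))
  bg <- vapply(cases, function(c) {
    den <- c$tn + c$fp + c$fn
    if (den == 0) 1 else c$tn / den
  }, numeric(1))
  list(iou = fg, miou = mean((fg + bg) / 2))
}

#' Hausdorff distance between two boundary point sets
#'
#' `h(A,B) = max over a in A of min over b in B of ||a - b||`;
#' `H(A,B) = max(h(A,B), h(B,A))`. Computed on boundary point sets in pixel
#' units; `H = 0` exactly when the two sets are equal.
#'
#' @param a,b non-empty data.frames with `row`/`col` columns (pixel
#'   coordinates), as from [extract_boundary()].
#' @return list with `h_ab`, `h_ba` and the symmetric `H`.
#' @export
hausdorff <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("degenerate boundary: Hausdorff distance needs two non-empty point sets")
  }
  d2 <- outer(a$row, b$row, "-")^2 + outer(a$col, b$col, "-")^2
  h_ab <- sqrt(max(apply(d2, 1, min)))
  h_ba <- sqrt(max(apply(d2, 2, min)))
  list(h_ab = h_ab, h_ba = h_ba, H = max(h_ab, h_ba))
}

#' Evaluate one predicted case against its ground truth
#'
#' Thresholds the probability map, computes all region metrics and the
#' Hausdorff distance between the extracted boundaries. When either boundary
#' is degenerate (empty prediction or target) the Hausdorff distance is
#' recorded as `NA`.
#'
#' @param pred probability matrix.
#' @param target binary ground-truth matrix.
#' @param threshold binarization threshold in (0,1), default 0.5.
#' @param case_id optional identifier carried into the report row.
#' @return one-row data.frame with columns `case`, `dice`, `precision`,
#'   `specificity`, `iou`, `pa`, `hausdorff`.
#' @export
evaluate_case <- function(pred, target, threshold = 0.5, case_id = NA) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0,1)")
  check_shapes(pred, target)
  pb <- 1 * (pred >= threshold)
  cc <- confusion(pb, target)
  hd <- NA_real_
  ba <- extract_boundary(pb)
  bb <- extract_boundary(target)
  if (nrow(ba) > 0L && nrow(bb) > 0L) hd <- hausdorff(ba, bb)$H
  data.frame(case = case_id,
             dice = dice_coefficient(cc),
             precision = precision(cc),
             specificity = specificity(cc),
             iou = iou_and_miou(list(cc))$iou,
             pa = pixel_accuracy(cc),
             hausdorff = hd)
}

#' Evaluate a batch of cases
#'
#' @param preds list of probability matrices.
#' @param targets list of binary matrices.
#' @param threshold binarization threshold.
#' @param case_ids optional identifiers.
#' @return list with per-case data.frame `cases`, scalar `miou`, and a named
#'   vector `means` of column means over defined cases.
#' @export
evaluate_batch <- function(preds, targets, threshold = 0.5, case_ids = NULL) {
  stopifnot(length(preds) == length(targets))
  if (is.null(case_ids)) case_ids <- seq_along(preds)
  rows <- mapply(function(p, t, id) evaluate_case(p, t, threshold, id),
                 preds, targets, case_ids, SIMPLIFY = FALSE)
  cases <- do.call(rbind, rows)
  ccs <- mapply(function(p, t) confusion(1 * (p >= threshold), t),
                preds, targets, SIMPLIFY = FALSE)
  mi <- iou_and_miou(ccs)
  means <- colMeans(cases[, -1, drop = FALSE], na.rm = TRUE)
  list(cases = cases, miou = mi$miou, means = means)
}
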