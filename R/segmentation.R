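# Segmentation and annotation agreement metrics --------------------------
#
# Pixel coordinates are 0-based; a box (x0, y0, w, h) covers the half-open
# region [x0, x0 + w) x [y0, y0 + h), so its area is exactly w * h.

#' Construct a bounding box
#'
#' @param x0,y0 0-based top-left pixel coordinates.
#' @param w,h Positive integer width and height in pixels.
#' @return A list of class `bbox`.
#' @export
bbox <- function(x0, y0, w, h) {
  if (w < 1 || h < 1) rlang::abort("box width and height must be >= 1.")
  structure(list(x0 = x0, y0 = y0, w = w, h = h), class = "bbox")
}

#' Intersection-over-union of two bounding boxes
#'
#' `|a intersect b| / |a union b|` on half-open pixel areas; 0 for disjoint
#' boxes.
#'
#' @param a,b [bbox()] objects (plain lists with `x0`, `y0`, `w`, `h` are
#'   accepted).
#' @return IoU in \[0, 1\].
#' @examples
#' bbox_iou(bbox(0, 0, 2, 2), bbox(1, 1, 2, 2))  # 1/7
#' @export
bbox_iou <- function(a, b) {
  for (box in list(a, b)) {
    if (box$w < 1 || box$h < 1) rlang::abort("zero-area box.")
  }
  ix <- max(0, min(a$x0 + a$w, b$x0 + b$w) - max(a$x0, b$x0))
  iy <- max(0, min(a$y0 + a$h, b$y0 + b$h) - max(a$y0, b$y0))
  inter <- ix * iy
  union <- a$w * a$h + b$w * b$h - inter
  inter / union
}

check_mask_pair <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) {
    rlang::abort("masks must have identical shapes.")
  }
  if (sum(pred) + sum(gt) == 0) {
    rlang::abort("metric undefined: both masks are empty.")
  }
}

#' Dice coefficient of two binary masks
#'
#' `2|pred intersect gt| / (|pred| + |gt|)` over foreground pixels.
#'
#' @param pred,gt Binary (0/1) matrices of identical shape, not both empty.
#' @return Dice in \[0, 1\].
#' @export
mask_dice <- function(pred, gt) {
  check_mask_pair(pred, gt)
  2 * sum(pred == 1 & gt == 1) / (sum(pred) + sum(gt))
}

#' Intersection-over-union (Jaccard) of two binary masks
#'
#' `|pred intersect gt| / |pred union gt|`; related to Dice by
#' `Dice = 2 * IoU / (1 + IoU)`.
#'
#' @inheritParams mask_dice
#' @return IoU in \[0, 1\].
#' @export
mask_iou <- function(pred, gt) {
  check_mask_pair(pred, gt)
  inter <- sum(pred == 1 & gt == 1)
  inter / (sum(pred) + sum(gt) - inter)
}

#' Cohen's kappa between two binary annotations
#'
#' Chance-corrected pixelwise agreement `kappa = (po - pe) / (1 - pe)` with
#' observed agreement `po` and expected agreement `pe` from the marginal
#' label frequencies of each annotator. Two identical constant masks (where
#' `pe = 1`) are defined as perfect agreement, `kappa = 1`.
#'
#' @param a,b Binary matrices of identical shape with at least one pixel.
#' @return A tibble with `po`, `pe`, `kappa`.
#' @export
cohens_kappa <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    rlang::abort("masks must have identical shapes.")
  }
  n <- length(a)
  if (n < 1) rlang::abort("masks must contain at least one pixel.")
  po <- mean(a == b)
  pa <- mean(a == 1); pb <- mean(b == 1)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  tibble::tibble(po = po, pe = pe, kappa = kappa)
}

#' Precision/recall-based IoU proxy
#'
#' The detector-level proxy `(precision + recall) / 2`. This is a proxy
#' score, not geometric overlap, and is deliberately kept separate from
#' [bbox_iou()]/[mask_iou()].
#'
#' @param precision,recall Values in \[0, 1\].
#' @return Value in \[0, 1\].
#' @export
iou_from_pr <- function(precision, recall) {
  if (any(c(precision, recall) < 0 | c(precision, recall) > 1)) {
    rlang::abort("precision and recall must lie in [0, 1].")
  }
  (precision + recall) / 2
}

#' mAP-based IoU proxies
#'
#' `iou_50()` is the identity on mAP at IoU threshold 0.5; `iou_avg()` is
#' the mean of mAP@50 and mAP@50:95. Proxy scores, not geometric overlap.
#'
#' @param map50,map50_95 Values in \[0, 1\].
#' @return Value in \[0, 1\].
#' @export
iou_avg <- function(map50, map50_95) {
  if (any(c(map50, map50_95) < 0 | c(map50, map50_95) > 1)) {
    rlang::abort("mAP values must lie in [0, 1].")
  }
  (map50 + map50_95) / 2
}

#' @rdname iou_avg
#' @export
iou_50 <- function(map50) {
  if (any(map50 < 0 | map50 > 1)) rlang::abort("mAP values must lie in [0, 1].")
  map50
}

#' Per-image agreement table for mask pairs
#'
#' Computes Dice, IoU and Cohen's kappa for each (prediction, ground-truth)
#' mask pair.
#'
#' @param pairs Named list of lists with elements `pred` and `gt` (binary
#'   matrices); names identify the images.
#' @return A tibble with columns `name`, `dice`, `iou`, `kappa`.
#' @export
segmentation_metrics_table <- function(pairs) {
  purrr::imap_dfr(pairs, function(p, nm) {
    tibble::tibble(name = nm,
                   dice = mask_dice(p$pred, p$gt),
                   iou = mask_iou(p$pred, p$gt),
                   kappa = cohens_kappa(p$pred, p$gt)$kappa)
  })
}
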