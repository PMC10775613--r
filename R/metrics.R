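#' Intersection over union of two binary masks
#'
#' `IoU = |S intersect G| / |S union G|`. Identical masks give 1, disjoint
#' masks 0. Undefined (an error) when both masks are empty.
#'
#' @param pred_mask,true_mask logical (or 0/1) matrices of the same shape.
#' @return Scalar in `[0, 1]`.
#' @export
iou <- function(pred_mask, true_mask) {
  if (!identical(dim(pred_mask), dim(true_mask)))
    stop("masks have different shapes", call. = FALSE)
  p <- pred_mask != 0
  g <- true_mask != 0
  u <- sum(p | g)
  if (u == 0L)
    stop("IoU is undefined when both masks are empty", call. = FALSE)
  sum(p & g) / u
}

#' Overlap error between two binary masks
#'
#' `E = 1 - IoU`: 0 for identical masks, 1 for disjoint masks.
#'
#' @inheritParams iou
#' @return Scalar in `[0, 1]`.
#' @export
overlap_error <- function(pred_mask, true_mask) {
  1 - iou(pred_mask, true_mask)
}
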