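#' Classical baseline extraction methods
#'
#' Comparison harness: applies Otsu thresholding and Roberts/Sobel edge
#' detection (standard library operators) per frame, post-processes each into
#' a best-effort corneal mask, and scores the overlap error against ground
#' truth. Otsu masks keep the largest bright component; edge maps are
#' thresholded (Otsu on the gradient magnitude), dilated, hole-filled, eroded
#' back, and reduced to their largest component.
#'
#' @param video a `"cornea_video"`.
#' @param truth a `"cornea_truth"`.
#' @param methods subset of `c("otsu", "roberts", "sobel")`.
#' @return A data frame with one row per method: `method`, `mean_E`, `std_E`,
#'   `n_frames`, `n_failed`; per-frame errors in attribute `"per_frame"`.
#' @export
run_baselines <- function(video, truth,
                          methods = c("otsu", "roberts", "sobel")) {
  stopifnot(inherits(video, "cornea_video"))
  methods <- match.arg(methods, several.ok = TRUE)
  per <- list()
  rows <- lapply(methods, function(meth) {
    E <- vapply(seq_len(video$n_frames), function(t) {
      mask <- tryCatch(baseline_mask(video$frames[[t]], meth),
                       error = function(e) NULL)
      if (is.null(mask) || !any(mask)) return(1)
      overlap_error(mask, truth$masks[[t]])
    }, numeric(1))
    per[[meth]] <<- E
    data.frame(method = meth, mean_E = mean(E), std_E = sd(E),
               n_frames = video$n_frames, n_failed = sum(E >= 1))
  })
  out <- do.call(rbind, rows)
  attr(out, "per_frame") <- per
  out
}

baseline_mask <- function(frame, method) {
  h <- nrow(frame); w <- ncol(frame)
  if (method == "otsu") {
    th <- EBImage::otsu(EBImage::Image(frame), range = c(0, 1))
    bw <- frame > th
  } else {
    g <- if (method == "roberts") roberts_magnitude(frame) else
      sobel_magnitude(frame)
    th <- EBImage::otsu(EBImage::Image(g / max(g)), range = c(0, 1))
    bw <- (g / max(g)) > th
    brush <- EBImage::makeBrush(5L, shape = "disc")
    img <- EBImage::dilate(EBImage::Image(bw * 1), brush)
    img <- EBImage::fillHull(img)
    img <- EBImage::erode(img, brush)
    bw <- as.matrix(img) > 0
  }
  cc <- cpp_connected_components(as.integer(bw), h, w)
  if (cc$ncomp == 0L) return(matrix(FALSE, h, w))
  sizes <- tabulate(cc$comp, nbins = cc$ncomp)
  matrix(cc$comp == which.max(sizes), h, w)
}

roberts_magnitude <- function(f) {
  h <- nrow(f); w <- ncol(f)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[-h, -w] <- f[-h, -w] - f[-1L, -1L]
  gy[-h, -w] <- f[-h, -1L] - f[-1L, -w]
  sqrt(gx^2 + gy^2)
}

sobel_magnitude <- function(f) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3L, 3L)
  gx <- as.matrix(EBImage::filter2(EBImage::Image(f), kx))
  gy <- as.matrix(EBImage::filter2(EBImage::Image(f), t(kx)))
  sqrt(gx^2 + gy^2)
}
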