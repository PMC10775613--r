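#' Process a corneal deformation video end to end
#'
#' For each frame: SLIC pre-grouping, unsupervised FCN training, corneal
#' region selection by shape factor, and contour extraction. With
#' `warm_start = TRUE` (the shared model), frame 1 trains from a cold random
#' initialisation with the first-frame epoch budget and every later frame is
#' initialised from the previous frame's trained parameters with the smaller
#' warm budget. With `warm_start = FALSE` every frame is cold-started (with a
#' frame-specific seed), which serves as the random-initialisation control.
#'
#' Frames where no corneal region is found are marked failed and the pipeline
#' continues; an error is raised only if every frame fails.
#'
#' @param video a `"cornea_video"`.
#' @param cfg a [train_config()].
#' @param K,m,n_iter,smooth_sigma SLIC parameters (see [pregroup()]).
#' @param warm_start share model parameters across frames (default `TRUE`).
#' @param truth optional `"cornea_truth"`; if supplied the result is
#'   evaluated against it (see [evaluate_video()]).
#' @param verbose print per-frame progress.
#' @return An object of class `"video_result"`: list with `frames` (a data
#'   frame with one row per frame: `frame`, `failed`, `loss`, `epochs_used`,
#'   `epochs_to_threshold`, `n_labels`), `masks`, `contours`, `final_state`,
#'   and (after evaluation) per-frame `E`/`iou` columns plus a `summary`.
#' @export
process_video <- function(video, cfg = train_config(), K = 2400L, m = 10,
                          n_iter = 10L, smooth_sigma = 0.5, warm_start = TRUE, truth = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(video, "cornea_video"))
  n <- video$n_frames
  if (n < 1L) stop("video has no frames", call. = FALSE)
  masks <- vector("list", n)
  contours <- vector("list", n)
  rows <- vector("list", n)
  state <- NULL
  for (t in seq_len(n)) {
    frame <- video$frames[[t]]
    part <- pregroup(frame, K = K, m = m, n_iter = n_iter,
                     smooth_sigma = smooth_sigma)
    tr <- if (warm_start && t > 1L && !is.null(state)) {
      train_frame(frame, part, init = state, cfg = cfg)
    } else {
      train_frame(frame, part, init = NULL, cfg = cfg,
                  seed = cfg$seed + (t - 1L))
    }
    state <- tr$state
    failed <- FALSE
    sel <- tryCatch({
      regs <- connected_regions(tr$labels)
      select_corneal_region(regs, C_target = cfg$C_target)
    }, error = function(e) NULL)
    if (is.null(sel) || tr$collapsed) {
      failed <- TRUE
    } else {
      masks[[t]] <- region_mask(sel)
      contours[[t]] <- extract_contour(masks[[t]])
    }
    rows[[t]] <- data.frame(
      frame = t, failed = failed,
      loss = if (length(tr$loss_history)) tr$loss_history[length(tr$loss_history)] else NA_real_,
      epochs_used = tr$epochs_used,
      epochs_to_threshold = tr$epochs_to_threshold,
      n_labels = length(unique(as.vector(tr$labels))))
    if (verbose)
      message(sprintf("frame %d/%d: epochs=%d loss=%.4f%s", t, n,
                      tr$epochs_used, rows[[t]]$loss,
                      if (failed) " FAILED" else ""))
  }
  frames <- do.call(rbind, rows)
  if (all(frames$failed))
    stop("corneal region extraction failed on every frame", call. = FALSE)
  res <- structure(list(frames = frames, masks = masks, contours = contours,
                        final_state = state, warm_start = warm_start,
                        config = cfg),
                   class = "video_result")
  if (!is.null(truth)) res <- evaluate_video(res, truth)
  res
}

#' Evaluate a video result against ground truth
#'
#' Adds per-frame overlap error `E = 1 - IoU` (failed frames score `E = 1`)
#' and a summary with `mean_E`, `std_E` and `mean_IoU = 1 - mean_E`, computed
#' over all frames.
#'
#' @param result a `"video_result"`.
#' @param truth a `"cornea_truth"` with one mask per frame.
#' @return The augmented `"video_result"`.
#' @export
evaluate_video <- function(result, truth) {
  stopifnot(inherits(result, "video_result"))
  n <- nrow(result$frames)
  if (length(truth$masks) != n)
    stop("ground truth frame count does not match the result", call. = FALSE)
  E <- vapply(seq_len(n), function(t) {
    if (result$frames$failed[t]) return(1)
    overlap_error(result$masks[[t]], truth$masks[[t]])
  }, numeric(1))
  result$frames$E <- E
  result$frames$iou <- 1 - E
  result$summary <- list(mean_E = mean(E), std_E = sd(E),
                         mean_IoU = 1 - mean(E), n_frames = n,
                         n_failed = sum(result$frames$failed))
  result
}

#' @export
print.video_result <- function(x, ...) {
  cat(sprintf("<video_result> %d frames, %d failed, %s\n",
              nrow(x$frames), sum(x$frames$failed),
              if (x$warm_start) "shared model" else "cold start"))
  if (!is.null(x$summary))
    cat(sprintf("  mean E = %.4f (sd %.4f), mean IoU = %.4f\n",
                x$summary$mean_E, x$summary$std_E, x$summary$mean_IoU))
  invisible(x)
}

#' Per-frame results as a data frame
#'
#' @param x a `"video_result"`.
#' @param row.names,optional,... passed on for S3 compatibility (unused).
#' @return The per-frame data frame.
#' @export
as.data.frame.video_result <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  x$frames
}

#' Overlay extracted contours on a frame
#'
#' @param video a `"cornea_video"`.
#' @param result a `"video_result"`.
#' @param frame frame index to display.
#' @export
plot_contour_overlay <- function(video, result, frame = 1L) {
  f <- video$frames[[frame]]
  graphics::image(t(f)[, nrow(f):1], col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, asp = nrow(f) / ncol(f))
  ct <- result$contours[[frame]]
  if (!is.null(ct)) {
    graphics::points((ct[, "col"] - 1) / (ncol(f) - 1),
                     1 - (ct[, "row"] - 1) / (nrow(f) - 1),
                     col = "red", pch = ".", cex = 2)
  }
  invisible(NULL)
}
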