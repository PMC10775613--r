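#' Configuration for synthetic corneal deformation videos
#'
#' Describes a synthetic Scheimpflug-like corneal deformation sequence: a
#' bright crescent-shaped corneal band on a dark background whose apex is
#' depressed and recovers over the sequence (emulating the air-puff
#' applanation/rebound cycle), contaminated by additive Gaussian noise and
#' spurious bright blob artifacts.
#'
#' @param height,width frame size in pixels.
#' @param n_frames number of frames in the sequence.
#' @param band_thickness vertical thickness of the corneal band, pixels. The
#'   default (scaled from 22 px at 150 px height) puts the band's shape factor
#'   near the corneal prior `C = 10` used downstream.
#' @param apex_depression_max maximum downward apex displacement, pixels,
#'   reached mid-sequence; 0 at the first and last frame.
#' @param noise_sigma standard deviation of additive Gaussian intensity noise,
#'   on the `[0, 1]` intensity scale.
#' @param n_blob_artifacts number of spurious bright disk artifacts per frame,
#'   placed uniformly at random away from the band.
#' @param blob_intensity intensity of the blob artifacts in `[0, 1]`.
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration.
#'
#' @return An object of class `"synthetic_config"`.
#' @seealso [generate_video()]
#' @export
synthetic_config <- function(height = 150L, width = 576L, n_frames = 139L,
                             band_thickness = round(22 * height / 150),
                             apex_depression_max = round(25 * height / 150),
                             noise_sigma = 0.05, n_blob_artifacts = 5L,
                             blob_intensity = 0.8, seed = 1L) {
  cfg <- list(height = as.integer(height), width = as.integer(width),
              n_frames = as.integer(n_frames),
              band_thickness = as.integer(band_thickness),
              apex_depression_max = as.integer(apex_depression_max),
              noise_sigma = as.numeric(noise_sigma),
              n_blob_artifacts = as.integer(n_blob_artifacts),
              blob_intensity = as.numeric(blob_intensity),
              seed = as.integer(seed))
  if (cfg$height < 1L || cfg$width < 1L || cfg$n_frames < 1L)
    stop("height, width and n_frames must all be >= 1", call. = FALSE)
  if (cfg$noise_sigma < 0)
    stop("noise_sigma must be >= 0", call. = FALSE)
  if (cfg$apex_depression_max >= cfg$height - cfg$band_thickness)
    stop("apex_depression_max must be < height - band_thickness", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

# per-column top edge of the band at frame t (1-based), fractional rows
band_top_profile <- function(cfg, t) {
  w <- cfg$width; h <- cfg$height
  cx <- (w + 1) / 2
  half <- max((w - 1) / 2, 1)
  apex_y <- 0.2 * h
  sag <- 0.4 * h
  xs <- (seq_len(w) - cx) / half
  depth <- if (cfg$n_frames == 1L) 0 else
    cfg$apex_depression_max * sin(pi * (t - 1) / (cfg$n_frames - 1))^2
  bump <- exp(-((seq_len(w) - cx)^2) / (2 * (w / 6)^2))
  apex_y + sag * xs^2 + depth * bump
}

band_mask_at <- function(cfg, t) {
  top <- band_top_profile(cfg, t)
  if (any(top + cfg$band_thickness > cfg$height))
    stop("invalid geometry: corneal band leaves the frame", call. = FALSE)
  rows <- seq_len(cfg$height)
  # band occupies rows in [top, top + thickness)
  vapply(seq_len(cfg$width), function(c) {
    rows >= top[c] & rows < top[c] + cfg$band_thickness
  }, logical(cfg$height))
}

#' Generate a synthetic corneal deformation video with ground truth
#'
#' Renders `cfg$n_frames` grayscale frames in `[0, 1]`: a bright corneal band
#' (intensity 0.85) delimited by two vertically offset parabolic arcs on a dark
#' background (intensity 0.10), with a raised-cosine apex depression over time,
#' plus additive Gaussian noise and bright disk artifacts. Ground-truth masks
#' contain the band only (never the artifacts).
#'
#' @param cfg a [synthetic_config()].
#' @return A list with components `video` (class `"cornea_video"`: list of
#'   `height x width` frame matrices plus dimensions) and `truth` (class
#'   `"cornea_truth"`: per-frame logical `masks` and ordered boundary
#'   `contours` as two-column row/col matrices).
#' @export
generate_video <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  h <- cfg$height; w <- cfg$width; n <- cfg$n_frames
  local_seed(cfg$seed, {
    frames <- vector("list", n)
    masks <- vector("list", n)
    contours <- vector("list", n)
    for (t in seq_len(n)) {
      mask <- band_mask_at(cfg, t)
      frame <- matrix(0.10, h, w)
      frame[mask] <- 0.85
      # bright blob artifacts, kept off the band by a safety margin
      if (cfg$n_blob_artifacts > 0L) {
        dil <- dilate_mask(mask, 10L)
        for (b in seq_len(cfg$n_blob_artifacts)) {
          for (try in 1:50) {
            r0 <- runif(1, 1, h); c0 <- runif(1, 1, w)
            rad <- runif(1, 3, 6)
            rr <- pmax(1, floor(r0 - rad)):pmin(h, ceiling(r0 + rad))
            cc <- pmax(1, floor(c0 - rad)):pmin(w, ceiling(c0 + rad))
            blob <- outer(rr, cc, function(r, c) (r - r0)^2 + (c - c0)^2 <= rad^2)
            if (!any(blob & dil[rr, cc])) {
              sub <- frame[rr, cc]
              sub[blob] <- pmax(sub[blob], cfg$blob_intensity)
              frame[rr, cc] <- sub
              break
            }
          }
        }
      }
      if (cfg$noise_sigma > 0)
        frame <- frame + matrix(rnorm(h * w, 0, cfg$noise_sigma), h, w)
      frames[[t]] <- pmin(pmax(frame, 0), 1)
      masks[[t]] <- mask
      contours[[t]] <- extract_contour(mask)
    }
    video <- structure(list(frames = frames, height = h, width = w,
                            n_frames = n), class = "cornea_video")
    truth <- structure(list(masks = masks, contours = contours),
                       class = "cornea_truth")
    list(video = video, truth = truth)
  })
}

# crude square dilation used only to keep artifacts away from the band
dilate_mask <- function(mask, margin) {
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  for (dr in -margin:margin) {
    rs <- seq_len(h) + dr
    ok <- rs >= 1 & rs <= h
    if (!any(ok)) next
    out[ok, ] <- out[ok, ] | mask[rs[ok], ]
  }
  m2 <- out
  for (dc in -margin:margin) {
    cs <- seq_len(w) + dc
    ok <- cs >= 1 & cs <= w
    if (!any(ok)) next
    out[, ok] <- out[, ok] | m2[, cs[ok]]
  }
  out
}

#' Write a video (and optional ground truth) to a directory of PNG files
#'
#' Frames are written as `frame_0000.png`, `frame_0001.png`, ... (0-based
#' index), masks as `mask_0000.png` (0/255), and a `meta.json` sidecar records
#' the generating configuration including its seed.
#'
#' @param video a `"cornea_video"`.
#' @param path output directory (created if missing).
#' @param truth optional `"cornea_truth"` with per-frame masks.
#' @param cfg optional [synthetic_config()] stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_video <- function(video, path, truth = NULL, cfg = NULL) {
  stopifnot(inherits(video, "cornea_video"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory: ", path, call. = FALSE)
  for (t in seq_len(video$n_frames)) {
    png::writePNG(video$frames[[t]],
                  file.path(path, sprintf("frame_%04d.png", t - 1L)))
    if (!is.null(truth))
      png::writePNG(matrix(as.numeric(truth$masks[[t]]), video$height),
                    file.path(path, sprintf("mask_%04d.png", t - 1L)))
  }
  meta <- list(height = video$height, width = video$width,
               n_frames = video$n_frames)
  if (!is.null(cfg)) meta$config <- unclass(cfg)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a video (and masks, if present) from a directory written by write_video
#'
#' @param path directory containing `frame_%04d.png` files.
#' @return A list with `video`, `truth` (or `NULL`) and `meta`.
#' @export
read_video <- function(path) {
  files <- sort(list.files(path, pattern = "^frame_\\d{4}\\.png$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no frames found in ", path, call. = FALSE)
  frames <- lapply(files, function(f) {
    x <- png::readPNG(f)
    if (length(dim(x)) == 3L) x <- x[, , 1L]
    x
  })
  h <- nrow(frames[[1L]]); w <- ncol(frames[[1L]])
  video <- structure(list(frames = frames, height = h, width = w,
                          n_frames = length(frames)), class = "cornea_video")
  mfiles <- sort(list.files(path, pattern = "^mask_\\d{4}\\.png$",
                            full.names = TRUE))
  truth <- NULL
  if (length(mfiles) == length(files)) {
    masks <- lapply(mfiles, function(f) {
      x <- png::readPNG(f)
      if (length(dim(x)) == 3L) x <- x[, , 1L]
      x > 0.5
    })
    truth <- structure(list(masks = masks,
                            contours = lapply(masks, extract_contour)),
                       class = "cornea_truth")
  }
  meta_file <- file.path(path, "meta.json")
  meta <- if (file.exists(meta_file)) jsonlite::read_json(meta_file) else NULL
  list(video = video, truth = truth, meta = meta)
}
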