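#' Connected regions of a label map with shape statistics
#'
#' Finds 8-connected components of each label value, drops components below a
#' minimum area, and computes for each survivor its area `S` (pixel count),
#' perimeter `L` (Moore-trace path length, diagonal steps weighted `sqrt(2)`),
#' shape factor `Fs = L^2 / (4 * pi * S)`, and the fraction of the top frame
#' border it occupies (used to suppress background regions from corneal
#' candidacy).
#'
#' @param lm `height x width` integer label matrix.
#' @param min_area minimum component area in pixels; defaults to 50 px at
#'   576x150 resolution, scaled proportionally with frame area.
#' @return A data frame with columns `label`, `component_id`, `area_S`,
#'   `perimeter_L`, `shape_factor_Fs`, `top_border_frac`; the component-id
#'   map is attached as attribute `"component_map"`. Zero rows if no
#'   component survives.
#' @export
connected_regions <- function(lm, min_area = NULL) {
  if (length(lm) == 0L) stop("label map is empty", call. = FALSE)
  h <- nrow(lm); w <- ncol(lm)
  if (is.null(min_area)) min_area <- max(1L, round(50 * h * w / (576 * 150)))
  cc <- cpp_label_components(as.integer(lm), h, w)
  comp_map <- matrix(cc$comp, h, w)
  sizes <- tabulate(cc$comp, nbins = cc$ncomp)
  keep <- which(sizes >= min_area)
  rows <- lapply(keep, function(id) {
    mask <- comp_map == id
    tr <- cpp_trace_contour(as.integer(mask), h, w)
    data.frame(label = cc$label[id], component_id = id,
               area_S = sizes[id], perimeter_L = tr$perimeter,
               shape_factor_Fs = tr$perimeter^2 / (4 * pi * sizes[id]),
               top_border_frac = sum(mask[1L, ]) / w)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), component_id = integer(0),
               area_S = integer(0), perimeter_L = numeric(0),
               shape_factor_Fs = numeric(0), top_border_frac = numeric(0))
  attr(out, "component_map") <- comp_map
  out
}

#' Shape factor of a binary region
#'
#' `Fs = L^2 / (4 * pi * S)` with `L` the Moore-trace perimeter and `S` the
#' pixel area. `Fs` is 1 for a disk (up to discretisation) and grows with
#' elongation; the corneal band is designed around `Fs ~ 10`.
#'
#' @param mask logical (or 0/1) matrix with a single connected component.
#' @return Scalar shape factor.
#' @export
shape_factor <- function(mask) {
  mask <- mask != 0
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  h <- nrow(mask); w <- ncol(mask)
  cc <- cpp_connected_components(as.integer(mask), h, w)
  if (cc$ncomp != 1L)
    stop("mask must contain a single connected component", call. = FALSE)
  tr <- cpp_trace_contour(as.integer(mask), h, w)
  tr$perimeter^2 / (4 * pi * sum(mask))
}

#' Select the corneal region by its shape factor
#'
#' Among candidate regions, returns the one whose shape factor is closest to
#' the corneal constant `C_target`; ties break towards the larger area.
#' Components occupying 60% or more of the top frame border are excluded
#' first (they are background, whose shape factor can accidentally approach
#' `C`).
#'
#' @param regions data frame from [connected_regions()].
#' @param C_target corneal shape-factor constant (default 10).
#' @return The selected one-row region (with the `"component_map"` attribute
#'   of `regions` carried over).
#' @export
select_corneal_region <- function(regions, C_target = 10) {
  if (nrow(regions) == 0L)
    stop("no candidate regions to select from", call. = FALSE)
  cand <- regions[regions$top_border_frac < 0.6, , drop = FALSE]
  if (nrow(cand) == 0L)
    stop("no corneal candidate region (all touch the top border)",
         call. = FALSE)
  d <- abs(cand$shape_factor_Fs - C_target)
  best <- cand[order(d, -cand$area_S), , drop = FALSE][1L, , drop = FALSE]
  attr(best, "component_map") <- attr(regions, "component_map")
  best
}

#' Extract the ordered boundary contour of a region
#'
#' Moore-neighbour tracing, clockwise from the topmost-then-leftmost boundary
#' pixel. Every returned pixel lies in the mask and has a background
#' 4-neighbour or touches the frame edge; consecutive points (and the
#' first/last pair) are 8-connected.
#'
#' @param mask logical (or 0/1) matrix with a single connected component.
#' @return Two-column integer matrix of (row, col) boundary coordinates with
#'   attribute `"perimeter"` (trace path length).
#' @export
extract_contour <- function(mask) {
  mask <- mask != 0
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  tr <- cpp_trace_contour(as.integer(mask), nrow(mask), ncol(mask))
  pts <- tr$points + 1L  # to 1-based coordinates
  colnames(pts) <- c("row", "col")
  structure(pts, perimeter = tr$perimeter)
}

# logical mask of one selected region
region_mask <- function(region) {
  cm <- attr(region, "component_map")
  cm == region$component_id
}
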