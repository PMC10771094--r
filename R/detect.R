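#' Background subtraction by running robust statistics
#'
#' Models the stationary background of a frame stack with a per-pixel running
#' median over a temporal window and flags pixels exceeding the background by
#' `k_sigma` robust standard deviations (1.4826 x MAD). The running median is
#' block-updated: background statistics are recomputed at anchors spaced half
#' a window apart and each frame is thresholded against its nearest anchor.
#'
#' @param stack A [render_frames()] / [read_frame_stack()] frame stack.
#' @param window Temporal window length in frames (shrinks, with a warning,
#'   for stacks shorter than the window).
#' @param k_sigma Threshold in robust standard deviations.
#' @return Object of class `fg_masks`: logical array (height x width x n)
#'   plus the camera and frame bookkeeping of the stack.
#' @export
background_subtract <- function(stack, window = 151, k_sigma = 5) {
  stopifnot(inherits(stack, "frame_stack"), window >= 3)
  d <- dim(stack$frames)
  h <- d[1]; w <- d[2]; n <- d[3]
  if (n < window) {
    warn(sprintf("stack has %d frames < window %d; window shrunk", n, window))
    window <- n
  }
  hw <- max(1L, window %/% 2L)
  anchors <- unique(pmin(seq(1L, n, by = hw) + hw %/% 2L, n))
  assign_anchor <- anchors[
    apply(abs(outer(seq_len(n), anchors, "-")), 1, which.min)]

  masks <- array(FALSE, dim = d)
  flat <- matrix(stack$frames, h * w, n)
  anchor_ids <- unique(assign_anchor)
  bg <- matrix(0, h * w, length(anchor_ids))
  for (ai in seq_along(anchor_ids)) {
    a <- anchor_ids[ai]
    blk <- flat[, max(1L, a - hw):min(n, a + hw), drop = FALSE]
    st <- .row_median_mad(blk)
    bg[, ai] <- st$median
    thr <- st$median + k_sigma * 1.4826 * pmax(st$mad, 1e-9)
    for (t in which(assign_anchor == a)) {
      masks[, , t] <- flat[, t] > thr
    }
  }
  structure(list(masks = masks, background = bg,
                 frame_anchor = match(assign_anchor, anchor_ids),
                 camera = stack$camera, fps = stack$fps,
                 start_frame = stack$start_frame),
            class = "fg_masks")
}

# 8-connectivity labeling of foreground pixels via union-find; rows/cols are
# 1-based pixel indices within one frame.
label_components8 <- function(rows, cols, h) {
  n <- length(rows)
  if (n == 0L) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  key <- cols * (h + 2L) + rows
  for (off in list(c(1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L))) {
    j <- match((cols + off[2]) * (h + 2L) + (rows + off[1]), key)
    for (i in which(!is.na(j))) {
      a <- find(i); b <- find(j[i])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Extract blob detections from foreground masks
#'
#' Connected components (8-connectivity) of each frame's foreground mask,
#' filtered to `[min_area, max_area]` pixels. Centroids are intensity
#' weighted over the component using the raw frame; coordinates are 0-based.
#'
#' @param masks A [background_subtract()] result.
#' @param stack The frame stack the masks came from.
#' @param min_area,max_area Component area bounds in pixels.
#' @return Detections tibble: `camera`, `frame`, `x_px`, `y_px`, `area_px`,
#'   `peak_intensity`.
#' @export
extract_detections <- function(masks, stack, min_area = 3, max_area = 500) {
  stopifnot(inherits(masks, "fg_masks"), min_area > 0, max_area >= min_area)
  d <- dim(masks$masks)
  h <- d[1]; n <- d[3]
  out <- vector("list", n)
  for (t in seq_len(n)) {
    idx <- which(masks$masks[, , t])
    if (!length(idx)) next
    rows <- ((idx - 1L) %% h) + 1L
    cols <- ((idx - 1L) %/% h) + 1L
    lab <- label_components8(rows, cols, h)
    raw <- as.numeric(stack$frames[, , t][idx])
    # weights are background-subtracted so the centroid tracks the blob
    # kernel rather than the (uniform) background under the component
    bg_t <- if (is.null(masks$background)) 0 else
      masks$background[idx, masks$frame_anchor[t]]
    inten <- pmax(raw - bg_t, 1e-6)
    comp <- lapply(split(seq_along(idx), lab), function(ii) {
      area <- length(ii)
      if (area < min_area || area > max_area) return(NULL)
      wgt <- inten[ii]
      tibble(
        camera = masks$camera$index,
        frame = masks$start_frame + t - 1L,
        x_px = sum((cols[ii] - 1) * wgt) / sum(wgt),
        y_px = sum((rows[ii] - 1) * wgt) / sum(wgt),
        area_px = area,
        peak_intensity = max(raw[ii])
      )
    })
    out[[t]] <- bind_rows(comp)
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(camera = integer(), frame = integer(), x_px = numeric(),
                  y_px = numeric(), area_px = integer(),
                  peak_intensity = numeric())
  }
  res
}

#' Spatiotemporal neighbor filter for detections
#'
#' Keeps a detection at frame `t` only if some detection in frame `t - 1` or
#' `t + 1` of the same camera lies within `radius_px` (Euclidean distance in
#' pixels). The test runs in a single pass against the original detection
#' set, so members of a continuous track survive while isolated spurious
#' detections are removed; the filter is deliberately not iterated to a
#' fixed point.
#'
#' @param detections Detections tibble (one or more cameras).
#' @param radius_px Neighborhood radius in pixels.
#' @param keep_all If `TRUE`, return all rows with a logical `kept` column
#'   instead of dropping.
#' @return Filtered detections tibble (or flagged, with `keep_all`).
#' @export
neighbor_filter <- function(detections, radius_px = 30, keep_all = FALSE) {
  stopifnot(radius_px > 0)
  if (nrow(detections) == 0) {
    return(if (keep_all) mutate(detections, kept = logical(0)) else detections)
  }
  kept <- rep(FALSE, nrow(detections))
  for (rows_cam in split(seq_len(nrow(detections)), detections$camera)) {
    det <- detections[rows_cam, ]
    by_frame <- split(seq_along(rows_cam), det$frame)
    frame_keys <- as.integer(names(by_frame))
    for (g in seq_along(by_frame)) {
      ii <- by_frame[[g]]
      prev <- match(frame_keys[g] - 1L, frame_keys)
      nxt <- match(frame_keys[g] + 1L, frame_keys)
      cand <- c(if (!is.na(prev)) by_frame[[prev]],
                if (!is.na(nxt)) by_frame[[nxt]])
      if (!length(cand)) next
      dx <- outer(det$x_px[ii], det$x_px[cand], "-")
      dy <- outer(det$y_px[ii], det$y_px[cand], "-")
      ok <- rowSums(dx * dx + dy * dy <= radius_px^2) > 0
      kept[rows_cam[ii[ok]]] <- TRUE
    }
  }
  if (keep_all) mutate(detections, kept = kept) else detections[kept, ]
}
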