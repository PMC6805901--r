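# The "pretest": accumulate all frame-to-frame change into one activity
# map, then segment the bright (moving) areas into labeled regions of
# interest for masked, per-cell evaluation.

#' Accumulated activity map
#'
#' Sums the absolute per-pixel differences of every consecutive frame pair,
#' producing a single image that is bright wherever movement concentrated
#' over the whole recording. The raw sums are kept alongside an 8-bit
#' display rescale (min to 0, max to 255) on which the user-facing
#' `lower_threshold` operates.
#'
#' @param stack a [frame_stack()].
#' @return an object of class `activity_map` with `grid` (numeric matrix of
#'   raw accumulated differences) and `display` (integer matrix, 0--255).
#' @export
build_activity_map <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  grid <- matrix(0, stack$height, stack$width)
  prev <- stack$frames[[1L]]
  for (i in 2:stack$n_frames) {
    cur <- stack$frames[[i]]
    grid <- grid + abs(cur - prev)
    prev <- cur
  }
  rng <- range(grid)
  display <- if (rng[2L] > rng[1L]) {
    floor((grid - rng[1L]) / (rng[2L] - rng[1L]) * 255)
  } else {
    matrix(0, stack$height, stack$width)
  }
  storage.mode(display) <- "integer"
  structure(list(grid = grid, display = display), class = "activity_map")
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged with a union-find over label pairs.
label8 <- function(bin) {
  lab <- EBImage::bwlabel(bin)
  lab <- matrix(as.integer(lab), nrow(bin), ncol(bin))
  k <- max(lab)
  if (k < 2L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  a <- lab[-h, -w]; b <- lab[-1L, -1L]   # down-right diagonal
  c_ <- lab[-1L, -w]; d <- lab[-h, -1L]  # up-right diagonal
  pairs <- rbind(
    cbind(as.vector(a), as.vector(b)),
    cbind(as.vector(c_), as.vector(d))
  )
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L & pairs[, 1L] != pairs[, 2L], ,
                 drop = FALSE]
  parent <- seq_len(k)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1L]); rb <- find(pairs[i, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(k), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

#' Detect contracting regions on an activity map
#'
#' Binarizes the 8-bit display map above `lower_threshold`, fills interior
#' holes (a pulsing disc moves only at its rim, but the whole cell should
#' count), labels connected components with 8-connectivity, and discards
#' components smaller than `cellsize` pixels. Survivors are relabeled 1..k
#' in order of decreasing area so region ids are stable across runs.
#'
#' @param map an [build_activity_map()] result.
#' @param lower_threshold 8-bit cutoff (0--255) on the display map.
#' @param cellsize minimum component area in pixels ("particle size").
#' @return an object of class `roi_set`: `label_image` (integer matrix,
#'   0 = background) and `rois`, a list with per region `id`, `area`,
#'   `mask` (logical matrix), `outline` (ordered boundary pixels, columns
#'   row/col, 1-based), `bounding_box` and `centroid`.
#' @export
detect_rois <- function(map, lower_threshold, cellsize) {
  stopifnot(inherits(map, "activity_map"),
            lower_threshold >= 0, lower_threshold <= 255, cellsize >= 1)
  bin <- map$display > lower_threshold
  storage.mode(bin) <- "integer"
  if (!any(bin == 1L)) {
    warning("no pixels above lower_threshold; empty ROI set", call. = FALSE)
    return(empty_roi_set(map))
  }
  bin <- EBImage::fillHull(bin)
  bin <- matrix(as.integer(bin), nrow(map$display), ncol(map$display))
  lab <- label8(bin)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= cellsize)
  if (length(keep) == 0L) {
    warning("no component reaches cellsize = ", cellsize,
            "; empty ROI set (evaluation requires unmasked mode)", call. = FALSE)
    return(empty_roi_set(map))
  }
  keep <- keep[order(areas[keep], decreasing = TRUE)]
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  label_image <- lab
  label_image[lab > 0L] <- relab[lab[lab > 0L]]

  contours <- EBImage::ocontour(label_image)
  rois <- lapply(seq_along(keep), function(i) {
    mask <- label_image == i
    idx <- which(mask, arr.ind = TRUE)
    outline <- contours[[as.character(i)]]
    if (is.null(outline)) outline <- contours[[i]]
    outline <- outline + 1L  # ocontour is 0-based
    colnames(outline) <- c("row", "col")
    list(
      id = i,
      area = nrow(idx),
      mask = mask,
      outline = outline,
      bounding_box = c(row_min = min(idx[, 1L]), row_max = max(idx[, 1L]),
                       col_min = min(idx[, 2L]), col_max = max(idx[, 2L])),
      centroid = c(row = mean(idx[, 1L]), col = mean(idx[, 2L]))
    )
  })
  structure(list(label_image = label_image, rois = rois), class = "roi_set")
}

empty_roi_set <- function(map) {
  structure(list(
    label_image = matrix(0L, nrow(map$display), ncol(map$display)),
    rois = list()
  ), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d region(s)\n", length(x$rois)))
  for (r in x$rois) {
    cat(sprintf("  #%d: %d px, bbox rows %d-%d cols %d-%d\n", r$id, r$area,
                r$bounding_box[1L], r$bounding_box[2L],
                r$bounding_box[3L], r$bounding_box[4L]))
  }
  invisible(x)
}

# 3 x 5 bitmap digits for overlay numerals
digit_font <- function() {
  rows <- c(
    "111101101101111", "010110010010111", "111001111100111",
    "111001111001111", "101101111001001", "111100111001111",
    "111100111101111", "111001001010010", "111101111101111",
    "111101111001111"
  )
  lapply(rows, function(s) {
    matrix(as.integer(strsplit(s, "")[[1]]) == 1L, nrow = 5, byrow = TRUE)
  })
}

draw_label <- function(img_r, img_g, img_b, text, row0, col0, scale = 2L) {
  font <- digit_font()
  digits <- as.integer(strsplit(text, "")[[1]])
  col <- col0
  h <- nrow(img_r); w <- ncol(img_r)
  for (d in digits) {
    glyph <- font[[d + 1L]]
    for (gr in 1:5) for (gc in 1:3) {
      if (!glyph[gr, gc]) next
      rr <- row0 + (gr - 1L) * scale + seq_len(scale) - 1L
      cc <- col + (gc - 1L) * scale + seq_len(scale) - 1L
      rr <- rr[rr >= 1L & rr <= h]; cc <- cc[cc >= 1L & cc <= w]
      img_r[rr, cc] <- 255L; img_g[rr, cc] <- 255L; img_b[rr, cc] <- 0L
    }
    col <- col + 4L * scale
  }
  list(img_r, img_g, img_b)
}

#' Render a region overlay
#'
#' Copies one grayscale frame to RGB and draws each region's outline in
#' yellow with its id rendered near the region centroid, mirroring the
#' per-cell outline-and-number display used for visual quality control.
#'
#' @param frame integer matrix (one frame of a stack).
#' @param rois a [detect_rois()] result.
#' @return integer array `height x width x 3`, values 0--255.
#' @export
render_overlay <- function(frame, rois) {
  stopifnot(is.matrix(frame), inherits(rois, "roi_set"))
  if (length(rois$rois) > 0 &&
      !identical(dim(frame), dim(rois$label_image))) {
    stop("frame and ROI geometry differ", call. = FALSE)
  }
  r <- frame; g <- frame; b <- frame
  for (roi in rois$rois) {
    idx <- cbind(roi$outline[, 1L], roi$outline[, 2L])
    r[idx] <- 255L; g[idx] <- 255L; b[idx] <- 0L
    lab <- draw_label(r, g, b, as.character(roi$id),
                      row0 = as.integer(round(roi$centroid[1L])) - 5L,
                      col0 = as.integer(round(roi$centroid[2L])) - 3L)
    r <- lab[[1L]]; g <- lab[[2L]]; b <- lab[[3L]]
  }
  out <- array(0L, dim = c(nrow(frame), ncol(frame), 3L))
  out[, , 1L] <- r; out[, , 2L] <- g; out[, , 3L] <- b
  out
}
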