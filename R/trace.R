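# Speed and amplitude: the two primary frame-differencing signals.
#
# Both are means of absolute per-pixel intensity differences, so they live
# on the 0..255 intensity scale regardless of frame size. Masked evaluation
# divides by the mask's pixel count, not the frame's, which is what makes a
# masked trace independent of the field of view around the cell. All
# arithmetic is double precision after differencing; nothing is re-quantized
# to 8 bit.

#' Per-frame movement speed
#'
#' `speed[n]` is the mean absolute per-pixel difference between frame `n`
#' and frame `n - 1` — high values mean fast movement into frame `n`.
#' `speed[1] = 0` by convention (no predecessor), keeping the series the
#' same length as the stack.
#'
#' @param stack a [frame_stack()].
#' @param mask optional logical matrix restricting evaluation to a region.
#' @return numeric vector of length `n_frames`, values in \[0, 255\].
#' @export
compute_speed <- function(stack, mask = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  mask <- check_mask(stack, mask)
  n <- stack$n_frames
  out <- numeric(n)
  prev <- stack$frames[[1L]]
  for (i in 2:n) {
    cur <- stack$frames[[i]]
    d <- abs(cur - prev)
    out[i] <- if (is.null(mask)) mean(d) else mean(d[mask])
    prev <- cur
  }
  out
}

#' Per-frame contraction amplitude
#'
#' `amplitude[n]` is the mean absolute per-pixel difference between frame
#' `n` and a fixed reference frame (normally one from the resting phase), so
#' it measures deviation from rest. It is zero at the reference frame
#' itself.
#'
#' @param stack a [frame_stack()].
#' @param ref_frame 1-based reference frame index.
#' @param mask optional logical matrix restricting evaluation to a region.
#' @return numeric vector of length `n_frames`, values in \[0, 255\].
#' @export
compute_amplitude <- function(stack, ref_frame = 1, mask = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  mask <- check_mask(stack, mask)
  if (ref_frame < 1 || ref_frame > stack$n_frames || ref_frame != round(ref_frame)) {
    stop("ref_frame must be an integer in [1, ", stack$n_frames, "]", call. = FALSE)
  }
  ref <- stack$frames[[ref_frame]]
  vapply(stack$frames, function(f) {
    d <- abs(f - ref)
    if (is.null(mask)) mean(d) else mean(d[mask])
  }, numeric(1))
}

#' Automatic reference-frame selection
#'
#' Picks a frame from the longest quiet stretch of the recording: frames
#' whose speed falls at or below the 10th percentile of the speed series
#' are marked quiet, and the center of the longest run of consecutive quiet
#' frames is returned (ties broken toward the earliest run, even-length
#' runs toward the earlier center). For a beating cell this lands inside
#' the diastolic rest phase; for a recording with no rest phase some valid
#' frame is still returned.
#'
#' @param stack a [frame_stack()].
#' @param mask optional logical matrix restricting the speed computation.
#' @return a 1-based frame index.
#' @export
auto_reference <- function(stack, mask = NULL) {
  stopifnot(inherits(stack, "frame_stack"), stack$n_frames >= 3)
  speed <- compute_speed(stack, mask)
  # speed[1] is a convention, not a measurement; judge quietness on 2..n
  s <- speed[-1L]
  quiet <- c(FALSE, s <= stats::quantile(s, 0.10, names = FALSE))
  quiet[1L] <- quiet[2L]  # frame 1 joins the run that frame 2 starts
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) == 0L) return(1L)
  best <- runs[which.max(r$lengths[runs])]  # which.max takes the earliest tie
  start <- starts[best]
  as.integer(start + (r$lengths[best] - 1L) %/% 2L)
}

#' Compute a full trace for one region
#'
#' Bundles [compute_speed()], [compute_amplitude()] and (optionally)
#' [auto_reference()] into the `contraction_trace` record consumed by the
#' beat-detection and reporting stages.
#'
#' @param stack a [frame_stack()].
#' @param ref_frame 1-based frame index, or `"auto"` to select a
#'   resting-phase frame automatically.
#' @param mask optional logical matrix; when given the trace is "masked".
#' @param roi_id region label for bookkeeping (0 = whole frame).
#' @return an object of class `contraction_trace`: `roi_id`, `amplitude`,
#'   `speed`, `fps`, `ref_frame`, `masked`, `pixel_count`.
#' @export
compute_trace <- function(stack, ref_frame = "auto", mask = NULL, roi_id = 0L) {
  stopifnot(inherits(stack, "frame_stack"))
  mask <- check_mask(stack, mask)
  if (identical(ref_frame, "auto")) {
    ref_frame <- auto_reference(stack, mask)
  }
  structure(list(
    roi_id      = as.integer(roi_id),
    amplitude   = compute_amplitude(stack, ref_frame, mask),
    speed       = compute_speed(stack, mask),
    fps         = stack$fps,
    ref_frame   = as.integer(ref_frame),
    masked      = !is.null(mask),
    pixel_count = if (is.null(mask)) stack$height * stack$width else sum(mask)
  ), class = "contraction_trace")
}

#' @export
print.contraction_trace <- function(x, ...) {
  cat(sprintf(
    "<contraction_trace> roi %d (%s, %d px), %d frames @ %.6g fps, ref frame %d\n  amplitude range [%.4g, %.4g]\n",
    x$roi_id, if (x$masked) "masked" else "unmasked", x$pixel_count,
    length(x$amplitude), x$fps, x$ref_frame,
    min(x$amplitude), max(x$amplitude)
  ))
  invisible(x)
}
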