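#' Construct a frame stack
#'
#' A `frame_stack` is the canonical in-memory representation of a recording:
#' an ordered sequence of 8-bit grayscale frames sharing one geometry, plus
#' the acquisition frame rate. All downstream computations (speed, amplitude,
#' activity map, region detection) operate on this container. Frames are
#' numbered 1-based, and frame `n` is assigned the time `(n - 1) / fps`
#' seconds, so frame 1 sits at t = 0.
#'
#' @param frames list of integer matrices (rows = height, cols = width) with
#'   values in 0--255, or a 3-d integer array `height x width x n_frames`.
#' @param fps frames per second; must be a single positive number.
#' @param source optional provenance string (file path or generator call).
#' @return an object of class `frame_stack` with elements `frames` (list of
#'   integer matrices), `width`, `height`, `n_frames`, `fps`, `source`.
#' @examples
#' fs <- frame_stack(list(matrix(0L, 4, 4), matrix(255L, 4, 4)), fps = 50)
#' fs$n_frames
#' @export
frame_stack <- function(frames, fps, source = "in-memory") {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  }
  if (!is.list(frames) || length(frames) < 2L) {
    stop("a frame stack needs at least 2 frames", call. = FALSE)
  }
  frames <- lapply(frames, function(f) {
    if (!is.matrix(f)) stop("every frame must be a matrix", call. = FALSE)
    storage.mode(f) <- "integer"
    f
  })
  d <- dim(frames[[1L]])
  ok <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(ok)) stop("all frames must share the same geometry", call. = FALSE)
  rng <- range(vapply(frames, range, integer(2)))
  if (rng[1L] < 0L || rng[2L] > 255L) {
    stop("pixel values must lie in [0, 255] (8-bit grayscale)", call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop("fps must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      frames   = frames,
      width    = d[2L],
      height   = d[1L],
      n_frames = length(frames),
      fps      = as.numeric(fps),
      source   = as.character(source)
    ),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf(
    "<frame_stack> %d frames, %d x %d px, %.6g fps (%.3f s)\n  source: %s\n",
    x$n_frames, x$width, x$height, x$fps, (x$n_frames - 1) / x$fps, x$source
  ))
  invisible(x)
}

#' Frame times in seconds
#'
#' @param stack a `frame_stack`.
#' @return numeric vector of length `n_frames`; frame 1 maps to 0.
#' @export
frame_times <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  (seq_len(stack$n_frames) - 1) / stack$fps
}

# internal: check a logical mask against a stack's geometry
check_mask <- function(stack, mask) {
  if (is.null(mask)) return(NULL)
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("mask must be a logical matrix", call. = FALSE)
  }
  if (nrow(mask) != stack$height || ncol(mask) != stack$width) {
    stop("mask geometry does not match the frame stack", call. = FALSE)
  }
  if (!any(mask)) stop("mask is empty: no pixels to evaluate", call. = FALSE)
  mask
}
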