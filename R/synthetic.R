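# Deterministic synthetic recordings: three analytic test patterns whose
# speed/amplitude values are known in closed form, plus a parameterized
# beating-cell scene with ground truth for end-to-end validation.

#' Alternating black/white test video
#'
#' Frames alternate between all-white (255) and all-black (0), starting
#' white. Every transition flips every pixel, the maximum possible change in
#' 8-bit grayscale, so the unmasked speed is 255 at every transition and the
#' amplitude against frame 1 alternates 0/255.
#'
#' @param n_frames number of frames (>= 2).
#' @param width,height geometry in pixels.
#' @param fps frames per second.
#' @return a [frame_stack()].
#' @export
gen_alternating <- function(n_frames, width = 100, height = 100, fps = 50) {
  stopifnot(n_frames >= 2)
  frames <- lapply(seq_len(n_frames), function(n) {
    matrix(if (n %% 2L == 1L) 255L else 0L, height, width)
  })
  frame_stack(frames, fps = fps, source = sprintf("gen_alternating(%d)", n_frames))
}

#' Moving-bar test video
#'
#' A 100 x 500 px black bar on a white 500 x 500 px background, translating
#' exactly one pixel per frame. Each transition inverts 500 pixels at the
#' bar's leading edge and 500 at its trailing edge, so the expected speed is
#' (1000 / 250000) * 255 = 1.02 per transition; against frame 1 the
#' amplitude climbs by the same 1.02 per frame until the bar has cleared its
#' starting position (frame 101), then plateaus at (100000 / 250000) * 255
#' = 102.
#'
#' @param n_frames number of frames (2--400, so the bar stays in frame).
#' @param fps frames per second.
#' @return a 500 x 500 [frame_stack()].
#' @export
gen_moving_bar <- function(n_frames, fps = 50) {
  stopifnot(n_frames >= 2)
  if (n_frames > 400) {
    stop("n_frames must be <= 400: the bar would leave the 500-px frame",
         call. = FALSE)
  }
  frames <- lapply(seq_len(n_frames), function(n) {
    m <- matrix(255L, 500L, 500L)
    offset <- n - 1L
    m[, (offset + 1L):(offset + 100L)] <- 0L
    m
  })
  frame_stack(frames, fps = fps, source = sprintf("gen_moving_bar(%d)", n_frames))
}

#' Uniform-intensity stack following a frame-indexed function
#'
#' Every pixel of frame `n` holds `floor(clamp(f(n), 0, 255))`, matching the
#' 8-bit quantization of scientific image writers (negative values clamp to
#' zero, fractional intensities are rounded down). Because all pixels agree,
#' speed equals `|amplitude[n] - amplitude[n - 1]|` exactly when the
#' reference frame sits at the function's minimum — the discrete analogue of
#' "speed is the absolute first derivative of the amplitude".
#'
#' @param f function of the 1-based frame index returning an intensity.
#' @param n_frames number of frames.
#' @param width,height geometry in pixels.
#' @param fps frames per second.
#' @return a [frame_stack()].
#' @export
gen_uniform_function <- function(f, n_frames, width = 50, height = 50, fps = 50) {
  stopifnot(is.function(f), n_frames >= 2)
  frames <- lapply(seq_len(n_frames), function(n) {
    v <- floor(max(0, min(255, f(n))))
    matrix(as.integer(v), height, width)
  })
  frame_stack(frames, fps = fps, source = sprintf("gen_uniform_function(%d)", n_frames))
}

# ---- beating-cell scenes --------------------------------------------------

#' Specify one synthetic contracting cell
#'
#' The cell is a filled disc whose radius follows a piecewise-linear pulse:
#' from `rest_radius` it shrinks linearly over `rise_time` to
#' `rest_radius * (1 - contraction_fraction)` (peak contraction), relaxes
#' linearly back over `fall_time`, and rests for the remainder of each
#' `period`. A per-beat amplitude schedule scales the contraction depth of
#' successive beats, emulating arrhythmic recordings with very different
#' local amplitudes. The linear pulse (rather than a sinusoid) keeps every
#' threshold-crossing frame hand-computable.
#'
#' @param center `(x, y)` pixel coordinates of the disc center.
#' @param rest_radius resting radius in pixels.
#' @param contraction_fraction radius shrink at peak, in (0, 1).
#' @param period beat period in seconds.
#' @param rise_time,fall_time contraction and relaxation durations in
#'   seconds; their sum must not exceed `period`.
#' @param phase delay of the first beat in seconds.
#' @param beat_amplitude_schedule optional vector of per-beat scale factors
#'   in (0, 1], recycled over beats.
#' @param intensity_cell,intensity_bg 8-bit intensities of cell and
#'   background.
#' @return an object of class `cell_spec`.
#' @export
cell_spec <- function(center, rest_radius, contraction_fraction = 0.4,
                      period = 1, rise_time = 0.2, fall_time = 0.3,
                      phase = 0, beat_amplitude_schedule = NULL,
                      intensity_cell = 60, intensity_bg = 200) {
  stopifnot(length(center) == 2L, rest_radius >= 1,
            contraction_fraction > 0, contraction_fraction < 1,
            period > 0, rise_time > 0, fall_time > 0, phase >= 0)
  if (rise_time + fall_time > period) {
    stop("rise_time + fall_time must not exceed the period", call. = FALSE)
  }
  if (rest_radius * (1 - contraction_fraction) < 1) {
    stop("peak-contracted radius falls below 1 px", call. = FALSE)
  }
  if (!is.null(beat_amplitude_schedule) &&
      (any(beat_amplitude_schedule <= 0) || any(beat_amplitude_schedule > 1))) {
    stop("beat_amplitude_schedule factors must lie in (0, 1]", call. = FALSE)
  }
  structure(list(
    center = as.numeric(center), rest_radius = rest_radius,
    contraction_fraction = contraction_fraction, period = period,
    rise_time = rise_time, fall_time = fall_time, phase = phase,
    beat_amplitude_schedule = beat_amplitude_schedule,
    intensity_cell = intensity_cell, intensity_bg = intensity_bg
  ), class = "cell_spec")
}

#' Specify a synthetic recording of beating cells
#'
#' @param width,height geometry in pixels.
#' @param fps frames per second.
#' @param duration recording length in seconds (`fps * duration >= 2`).
#' @param cells list of [cell_spec()] objects; resting discs must lie fully
#'   inside the frame.
#' @param drift_rate global additive illumination drift in intensity units
#'   per second (applied before noise and clamping); emulates changing
#'   illumination, a typical cause of baseline-shifted amplitudes.
#' @param noise_sd standard deviation of i.i.d. Gaussian pixel noise,
#'   intensity units.
#' @param seed integer seed; the rendered stack is bit-identical for equal
#'   seeds.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(width, height, fps, duration, cells,
                       drift_rate = 0, noise_sd = 0, seed = 1) {
  if (inherits(cells, "cell_spec")) cells <- list(cells)
  stopifnot(length(cells) >= 1L, fps > 0, duration > 0)
  if (round(fps * duration) < 2) stop("scene must span at least 2 frames", call. = FALSE)
  for (cl in cells) {
    cx <- cl$center[1L]; cy <- cl$center[2L]; r <- cl$rest_radius
    if (cx - r < 1 || cx + r > width || cy - r < 1 || cy + r > height) {
      stop("a cell's resting disc extends outside the frame", call. = FALSE)
    }
  }
  structure(list(
    width = width, height = height, fps = fps, duration = duration,
    cells = cells, drift_rate = drift_rate, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "scene_spec")
}

# pulse height in [0, 1] for one cell at time t (vectorized over t)
cell_pulse <- function(cell, t) {
  tt <- t - cell$phase
  out <- numeric(length(t))
  active <- tt >= 0
  k <- floor(tt[active] / cell$period)
  u <- tt[active] - k * cell$period
  p <- ifelse(u < cell$rise_time, u / cell$rise_time,
         ifelse(u < cell$rise_time + cell$fall_time,
                1 - (u - cell$rise_time) / cell$fall_time, 0))
  if (!is.null(cell$beat_amplitude_schedule)) {
    sched <- cell$beat_amplitude_schedule
    p <- p * sched[(k %% length(sched)) + 1L]
  }
  out[active] <- p
  out
}

# frames at which each beat reaches peak contraction, within n_frames
cell_beat_frames <- function(cell, fps, n_frames) {
  peaks <- integer(0)
  k <- 0
  repeat {
    t_peak <- cell$phase + k * cell$period + cell$rise_time
    fr <- round(t_peak * fps) + 1
    if (fr > n_frames) break
    peaks <- c(peaks, as.integer(fr))
    k <- k + 1
  }
  peaks
}

# run code with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Render a synthetic beating-cell recording
#'
#' Cells are drawn as filled discs (a pixel belongs to a cell when its
#' center lies within the current radius), the global illumination drift
#' `drift_rate * t` is added to every pixel, Gaussian noise is added, and
#' the result is clamped to \[0, 255\] and floored to integers. Rendering is
#' deterministic given the scene seed.
#'
#' @param spec a [scene_spec()].
#' @return a list with `stack` (the [frame_stack()]) and `truth`, which
#'   holds per cell the 1-based frame indices of peak contraction
#'   (`beat_frames`), the resting-disc mask (`rest_mask`) and the annulus
#'   actually swept by the rim (`motion_mask`).
#' @export
gen_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  n_frames <- as.integer(round(spec$fps * spec$duration))
  h <- spec$height; w <- spec$width
  t <- (seq_len(n_frames) - 1) / spec$fps
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)

  # flag overlapping resting discs (allowed, but the ROI stage may merge them)
  if (length(spec$cells) > 1L) {
    for (i in seq_along(spec$cells)[-1L]) {
      for (j in seq_len(i - 1L)) {
        a <- spec$cells[[i]]; b <- spec$cells[[j]]
        d <- sqrt(sum((a$center - b$center)^2))
        if (d < a$rest_radius + b$rest_radius) {
          warning("cells ", j, " and ", i, " overlap at rest", call. = FALSE)
        }
      }
    }
  }

  dist2 <- lapply(spec$cells, function(cl) {
    (xs - cl$center[1L])^2 + (ys - cl$center[2L])^2
  })

  frames <- with_local_seed(spec$seed, {
    lapply(seq_len(n_frames), function(n) {
      bg <- spec$cells[[1L]]$intensity_bg
      img <- matrix(as.numeric(bg), h, w)
      for (ci in seq_along(spec$cells)) {
        cl <- spec$cells[[ci]]
        r <- cl$rest_radius * (1 - cl$contraction_fraction * cell_pulse(cl, t[n]))
        inside <- dist2[[ci]] <= r^2
        img[inside] <- cl$intensity_cell
      }
      img <- img + spec$drift_rate * t[n]
      if (spec$noise_sd > 0) {
        img <- img + matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
      }
      img <- floor(pmin(pmax(img, 0), 255))
      storage.mode(img) <- "integer"
      img
    })
  })

  truth <- lapply(seq_along(spec$cells), function(ci) {
    cl <- spec$cells[[ci]]
    r_rest <- cl$rest_radius
    r_min <- cl$rest_radius * (1 - cl$contraction_fraction)
    list(
      beat_frames = cell_beat_frames(cl, spec$fps, n_frames),
      rest_mask   = dist2[[ci]] <= r_rest^2,
      motion_mask = dist2[[ci]] <= r_rest^2 & dist2[[ci]] > r_min^2
    )
  })

  list(
    stack = frame_stack(frames, fps = spec$fps,
                        source = sprintf("gen_scene(seed=%d)", spec$seed)),
    truth = truth
  )
}
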