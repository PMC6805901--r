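# Independent oracles used across tests. These deliberately avoid the
# package's own scan/labeling code paths: the extrema oracle maximizes over
# all alternating sequences by memoized recursion, the crossing oracle is a
# naive linear scan, and the component oracle is a BFS flood fill.

# Maximum number of committable extrema: alternating max/min sequences
# (starting with a maximum) in which every adjacent excursion is >= eps and
# the final extremum is confirmed by a later opposite move >= eps.
oracle_extrema_counts <- function(x, detection) {
  rng <- range(x)
  if (rng[2L] == rng[1L]) return(c(maxima = 0L, minima = 0L))
  eps <- (rng[2L] - rng[1L]) / detection
  n <- length(x)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  # best event count starting at frame >= pos, next event of `kind`,
  # previous committed value `prev` (NA for the opening maximum)
  best <- function(pos, kind, prev) {
    key <- paste(pos, kind, prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- 0L
    for (f in pos:n) {
      v <- x[f]
      if (kind == "max") {
        if (!is.na(prev) && v - prev < eps) next
        if (f < n && any(x[(f + 1L):n] <= v - eps)) {
          out <- max(out, 1L + best(f + 1L, "min", v))
        }
      } else {
        if (prev - v < eps) next
        if (f < n && any(x[(f + 1L):n] >= v + eps)) {
          out <- max(out, 1L + best(f + 1L, "max", v))
        }
      }
    }
    memo[[key]] <- out
    out
  }
  total <- best(1L, "max", NA_real_)
  # events alternate starting with a maximum
  c(maxima = as.integer(ceiling(total / 2)), minima = as.integer(floor(total / 2)))
}

# first-crossing arithmetic for one beat window, written as a bare loop
oracle_crossings <- function(amplitude, m, M, win_end, threshold, fps) {
  f_up <- NA_integer_
  for (f in (m + 1L):M) {
    if (amplitude[f] >= threshold) { f_up <- f; break }
  }
  f_dn <- NA_integer_
  if (M < win_end) {
    for (f in (M + 1L):win_end) {
      if (amplitude[f] < threshold) { f_dn <- f; break }
    }
  }
  list(
    systole = if (is.na(f_up)) NA_real_ else (M - f_up) / fps,
    diastole = if (is.na(f_dn)) NA_real_ else (f_dn - M) / fps
  )
}

# 8-connected components of a logical matrix by BFS; returns component sizes
oracle_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  sizes <- integer(0)
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(queue)) {
      p <- queue[1L]; queue <- queue[-1L]
      size <- size + 1L
      r <- (p - 1L) %% h + 1L; c_ <- (p - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c_ + dc
        if (rr < 1L || rr > h || cc < 1L || cc > w) next
        q <- (cc - 1L) * h + rr
        if (mask[q] && !seen[q]) {
          seen[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# a trace with peaks of given prominences separated by returns to baseline
peaks_trace <- function(heights, gap = 3L) {
  out <- numeric(0)
  for (h in heights) {
    out <- c(out, rep(0, gap), seq(0, h, length.out = 4L)[-1L],
             rev(seq(0, h, length.out = 4L))[-1L])
  }
  c(out, rep(0, gap))
}

# baseline-drift scene: a large cell (local amplitude ~18 units) under a
# slow illumination ramp, so per-beat thresholds stay trackable while
# thresholds frozen at beat 1 are overtaken by the rising baseline
drift_scene <- function(duration = 6, fps = 100, drift_rate = 0.8, seed = 1) {
  cell <- cell_spec(center = c(80, 80), rest_radius = 40,
                    contraction_fraction = 0.4, period = 1,
                    rise_time = 0.2, fall_time = 0.3, phase = 0.1)
  gen_scene(scene_spec(160, 160, fps, duration, list(cell),
                       drift_rate = drift_rate, seed = seed))
}

# standard single-cell test scene: zero noise, hand-checkable timing
basic_scene <- function(duration = 3, fps = 100, drift_rate = 0, noise_sd = 0,
                        seed = 1, phase = 0.1, n_cells = 1, width = 120,
                        height = 120, schedule = NULL) {
  cells <- lapply(seq_len(n_cells), function(i) {
    cell_spec(center = c(width * i / (n_cells + 1), height / 2),
              rest_radius = min(width / (n_cells + 1), height) / 3,
              contraction_fraction = 0.4, period = 1,
              rise_time = 0.2, fall_time = 0.3, phase = phase,
              beat_amplitude_schedule = schedule)
  })
  gen_scene(scene_spec(width, height, fps, duration, cells,
                       drift_rate = drift_rate, noise_sd = noise_sd,
                       seed = seed))
}
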