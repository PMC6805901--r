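# Beat detection and timing decomposition on an amplitude trace.
#
# The sensitivity parameter `detection` sets the minimum excursion an
# extremum must have to be recognized: epsilon = (global max - global min)
# / detection. A detection of 5 therefore picks up peaks of about 20% of
# the trace's full range; raising detection recognizes ever smaller peaks.
# Thresholds are *dynamic*: the 10/20/50/90% levels are recomputed for
# every single beat from its own local minimum and maximum, which is what
# lets the method track amplitudes whose baseline drifts (changing
# illumination) or whose local peak heights differ wildly (arrhythmia) —
# conditions under which thresholds frozen at the start of a recording lose
# the signal entirely.

#' Detect alternating maxima and minima with a sensitivity parameter
#'
#' A single forward scan maintains a candidate extremum, starting in the
#' seeking-maximum state at the first sample. A maximum is committed when
#' the trace falls at least `epsilon = range / detection` below the running
#' candidate high; a minimum when it rises at least `epsilon` above the
#' candidate low; the states alternate. Plateaus resolve to their earliest
#' frame and a trailing uncommitted candidate is discarded, so every
#' reported extremum is confirmed by a full excursion on both sides (except
#' the leading maximum, which may open the series).
#'
#' @param amplitude numeric trace (length >= 3).
#' @param detection sensitivity, > 0; larger values accept smaller peaks.
#' @return a data frame of class `extrema_list` with columns `frame`
#'   (1-based), `kind` (`"minimum"`/`"maximum"`), `value`. A flat trace
#'   yields zero rows.
#' @export
detect_extrema <- function(amplitude, detection) {
  stopifnot(is.numeric(amplitude), length(amplitude) >= 3,
            is.numeric(detection), length(detection) == 1L, detection > 0)
  rng <- range(amplitude)
  empty <- data.frame(frame = integer(0), kind = character(0), value = numeric(0))
  if (rng[2L] == rng[1L]) return(structure(empty, class = c("extrema_list", "data.frame")))
  eps <- (rng[2L] - rng[1L]) / detection

  frames <- integer(0); kinds <- character(0); values <- numeric(0)
  seeking_max <- TRUE
  cand_val <- amplitude[1L]; cand_frame <- 1L
  for (i in 2:length(amplitude)) {
    x <- amplitude[i]
    if (seeking_max) {
      if (x > cand_val) {           # strict: plateaus keep the earliest frame
        cand_val <- x; cand_frame <- i
      } else if (cand_val - x >= eps) {
        frames <- c(frames, cand_frame); kinds <- c(kinds, "maximum")
        values <- c(values, cand_val)
        seeking_max <- FALSE; cand_val <- x; cand_frame <- i
      }
    } else {
      if (x < cand_val) {
        cand_val <- x; cand_frame <- i
      } else if (x - cand_val >= eps) {
        frames <- c(frames, cand_frame); kinds <- c(kinds, "minimum")
        values <- c(values, cand_val)
        seeking_max <- TRUE; cand_val <- x; cand_frame <- i
      }
    }
  }
  structure(
    data.frame(frame = frames, kind = kinds, value = values),
    class = c("extrema_list", "data.frame")
  )
}

# beats are the (minimum -> next maximum) pairs of an extrema list;
# returns a data frame with one row per pair
beat_pairs <- function(extrema) {
  n <- nrow(extrema)
  if (n < 2L) {
    return(data.frame(min_frame = integer(0), max_frame = integer(0),
                      local_min = numeric(0), local_max = numeric(0)))
  }
  i_min <- which(extrema$kind == "minimum" &
                   c(extrema$kind[-1L], "") == "maximum")
  data.frame(
    min_frame = extrema$frame[i_min],
    max_frame = extrema$frame[i_min + 1L],
    local_min = extrema$value[i_min],
    local_max = extrema$value[i_min + 1L]
  )
}

#' Per-beat dynamic thresholds
#'
#' For every minimum-to-maximum pair the threshold at level `l` is
#' `local_min + l * (local_max - local_min)`, recomputed for every single
#' recognized contraction. A degenerate beat (local min equal to local max)
#' gets all thresholds at that shared value and is flagged.
#'
#' @param amplitude numeric trace (used only for validation; thresholds
#'   derive from the extrema values).
#' @param extrema a [detect_extrema()] result.
#' @param levels threshold fractions, default `c(0.10, 0.20, 0.50, 0.90)`.
#' @return data frame with one row per beat: `beat_index`, `min_frame`,
#'   `max_frame`, `local_min`, `local_max`, `degenerate`, and one
#'   `threshold_<pct>` column per level.
#' @export
compute_thresholds <- function(amplitude, extrema,
                               levels = c(0.10, 0.20, 0.50, 0.90)) {
  stopifnot(inherits(extrema, "extrema_list") || is.data.frame(extrema),
            all(levels > 0), all(levels < 1))
  pairs <- beat_pairs(extrema)
  out <- data.frame(
    beat_index = seq_len(nrow(pairs)),
    pairs,
    degenerate = pairs$local_max == pairs$local_min
  )
  for (l in levels) {
    out[[sprintf("threshold_%g", l * 100)]] <-
      pairs$local_min + l * (pairs$local_max - pairs$local_min)
  }
  out
}

level_col <- function(prefix, l) sprintf("%s_%g", prefix, l * 100)

#' Decompose beats into systolic, diastolic and overall peak times
#'
#' For each beat (minimum m -> maximum M -> next minimum), and each
#' threshold level: the systole (contraction time) runs from the first
#' frame after m whose amplitude reaches the threshold (`>=`) up to M; the
#' diastole (relaxation time) runs from M to the first later frame whose
#' amplitude falls below the threshold (`<`), searched up to the next
#' minimum (or the end of the trace). If the amplitude never falls back
#' below the threshold the diastole is left `NA` (incomplete) rather than
#' guessed. The overall peak time is systole + diastole. Crossings are
#' reported at frame resolution — no sub-frame interpolation.
#'
#' With `static = TRUE` the thresholds of the *first* beat are frozen and
#' applied to all later beats (the naive fixed-threshold strategy); this
#' exists to demonstrate why dynamic per-beat thresholds are needed under
#' baseline drift, and is never used by the standard pipeline.
#'
#' @param amplitude numeric trace.
#' @param fps frames per second (> 0).
#' @param extrema a [detect_extrema()] result.
#' @param levels threshold fractions, default `c(0.10, 0.20, 0.50, 0.90)`.
#' @param static freeze beat-1 thresholds for all beats (comparison mode).
#' @return data frame of class `beat_table`, one row per beat, with frames,
#'   extremum values, `local_max_amplitude`, per-level `threshold_*`,
#'   `systole_*`, `diastole_*`, `peak_time_*` (seconds), `beat_time`,
#'   `time_since_previous` and `contractions_so_far`.
#' @export
compute_beats <- function(amplitude, fps, extrema,
                          levels = c(0.10, 0.20, 0.50, 0.90),
                          static = FALSE) {
  stopifnot(is.numeric(fps), fps > 0)
  thr <- compute_thresholds(amplitude, extrema, levels)
  n_beats <- nrow(thr)
  all_max_frames <- extrema$frame[extrema$kind == "maximum"]
  min_frames_all <- extrema$frame[extrema$kind == "minimum"]
  n <- length(amplitude)

  for (l in levels) {
    thr[[level_col("systole", l)]] <- rep(NA_real_, n_beats)
    thr[[level_col("diastole", l)]] <- rep(NA_real_, n_beats)
    thr[[level_col("peak_time", l)]] <- rep(NA_real_, n_beats)
  }
  thr$beat_time <- rep(NA_real_, n_beats)
  thr$time_since_previous <- rep(NA_real_, n_beats)
  thr$contractions_so_far <- rep(NA_integer_, n_beats)

  for (b in seq_len(n_beats)) {
    m <- thr$min_frame[b]; M <- thr$max_frame[b]
    # diastolic search window ends at the next committed minimum, else EOT
    next_min <- min_frames_all[min_frames_all > M]
    win_end <- if (length(next_min)) next_min[1L] else n
    for (l in levels) {
      t_level <- if (static) thr[[sprintf("threshold_%g", l * 100)]][1L]
                 else        thr[[sprintf("threshold_%g", l * 100)]][b]
      up <- which(amplitude[(m + 1L):M] >= t_level)
      if (length(up)) {
        f_up <- m + up[1L]
        thr[[level_col("systole", l)]][b] <- (M - f_up) / fps
      }
      if (M < win_end) {
        dn <- which(amplitude[(M + 1L):win_end] < t_level)
        if (length(dn)) {
          f_dn <- M + dn[1L]
          thr[[level_col("diastole", l)]][b] <- (f_dn - M) / fps
        }
      }
      thr[[level_col("peak_time", l)]][b] <-
        thr[[level_col("systole", l)]][b] + thr[[level_col("diastole", l)]][b]
    }
    later_max <- all_max_frames[all_max_frames > M]
    if (length(later_max)) thr$beat_time[b] <- (later_max[1L] - M) / fps
    earlier_max <- all_max_frames[all_max_frames < M]
    if (length(earlier_max)) {
      thr$time_since_previous[b] <- (M - max(earlier_max)) / fps
    }
    thr$contractions_so_far[b] <- sum(all_max_frames <= M)
  }
  thr$local_max_amplitude <- thr$local_max - thr$local_min
  class(thr) <- c("beat_table", "data.frame")
  thr
}

#' Summary statistics over a beat table
#'
#' Mean, SD and n of beat time, local maximal amplitude and the per-level
#' systole/diastole/peak times. Incomplete (NA) entries — beats cut off by
#' the trace boundary or whose relaxation never recrossed the threshold —
#' are excluded.
#'
#' @param beats a [compute_beats()] result.
#' @param levels the threshold fractions used to build it.
#' @return data frame with columns `parameter`, `mean`, `sd`, `n`.
#' @export
summarize_beats <- function(beats, levels = c(0.10, 0.20, 0.50, 0.90)) {
  params <- c("beat_time", "local_max_amplitude",
              unlist(lapply(levels, function(l) {
                c(level_col("systole", l), level_col("diastole", l),
                  level_col("peak_time", l))
              })))
  params <- params[params %in% names(beats)]
  do.call(rbind, lapply(params, function(p) {
    v <- beats[[p]]
    v <- v[!is.na(v)]
    data.frame(parameter = p,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n = length(v))
  }))
}
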