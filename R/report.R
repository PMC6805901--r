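# Tabular output and re-analysis.
#
# Two files are written per run: a full "Results <timestamp>.txt" holding
# the settings, a frame-level table, a beat-level table and summary
# statistics for every region — enough to retrace the whole experiment —
# and a compact "Amplitudes only <timestamp>.txt" holding just the
# amplitude columns at full precision, from which the beat-detection stage
# can be re-run with different detection/levels settings in real time,
# without touching the video again.

PKG_VERSION <- function() as.character(utils::packageVersion("myobeat"))

#' Analysis settings
#'
#' The complete set of user parameters of a run; embedded verbatim in every
#' output file so any result can be retraced.
#'
#' @param lower_threshold 8-bit cutoff (0--255) binarizing the activity map
#'   during the pretest.
#' @param cellsize minimum region area in pixels.
#' @param detection extremum sensitivity (> 0); the minimum excursion is
#'   the trace range divided by this value.
#' @param ref_frame 1-based reference frame, or `"auto"`.
#' @param fps frames per second; `NULL` takes the stack's rate.
#' @param levels threshold fractions for the beat decomposition.
#' @param masked restrict evaluation to detected regions?
#' @param provenance free-text provenance string.
#' @return an object of class `myo_settings`.
#' @export
myo_settings <- function(lower_threshold = 50, cellsize = 100, detection = 5,
                         ref_frame = "auto", fps = NULL,
                         levels = c(0.10, 0.20, 0.50, 0.90),
                         masked = FALSE, provenance = "") {
  stopifnot(lower_threshold >= 0, lower_threshold <= 255, cellsize >= 1,
            detection > 0, all(levels > 0), all(levels < 1))
  if (!identical(ref_frame, "auto")) {
    stopifnot(is.numeric(ref_frame), length(ref_frame) == 1L, ref_frame >= 1)
  }
  structure(list(
    lower_threshold = lower_threshold, cellsize = cellsize,
    detection = detection, ref_frame = ref_frame, fps = fps,
    levels = levels, masked = isTRUE(masked),
    provenance = as.character(provenance)
  ), class = "myo_settings")
}

#' Run the full evaluation pipeline on a frame stack
#'
#' Unmasked mode evaluates the whole frame as region 0. Masked mode runs
#' the pretest first (activity map, thresholding, size filter) unless a
#' region set is supplied, then evaluates each detected region through its
#' own mask. Each region gets a trace, an extrema list, a beat table and
#' summary statistics.
#'
#' @param stack a [frame_stack()].
#' @param settings a [myo_settings()].
#' @param rois optional pre-computed [detect_rois()] result (masked mode).
#' @return an object of class `result_bundle`: `settings` (with `fps` and
#'   resolved `ref_frame` filled in per region), `rois`, and `per_roi`, a
#'   named list of `trace`, `extrema`, `beats`, `summary` per region.
#' @export
evaluate_stack <- function(stack, settings = myo_settings(), rois = NULL) {
  stopifnot(inherits(stack, "frame_stack"), inherits(settings, "myo_settings"))
  if (is.null(settings$fps)) settings$fps <- stack$fps
  masks <- list()
  if (settings$masked) {
    if (is.null(rois)) {
      map <- build_activity_map(stack)
      rois <- detect_rois(map, settings$lower_threshold, settings$cellsize)
    }
    if (length(rois$rois) == 0L) {
      warning("masked evaluation requested but no regions detected; ",
              "falling back to unmasked whole-frame evaluation", call. = FALSE)
      settings$masked <- FALSE
    } else {
      masks <- lapply(rois$rois, function(r) r$mask)
      names(masks) <- vapply(rois$rois, function(r) as.character(r$id), character(1))
    }
  }
  if (!settings$masked) {
    masks <- list("0" = NULL)
    rois <- NULL
  }
  per_roi <- lapply(names(masks), function(id) {
    trace <- compute_trace(stack, ref_frame = settings$ref_frame,
                           mask = masks[[id]], roi_id = as.integer(id))
    extrema <- detect_extrema(trace$amplitude, settings$detection)
    beats <- compute_beats(trace$amplitude, settings$fps, extrema,
                           levels = settings$levels)
    list(trace = trace, extrema = extrema, beats = beats,
         summary = summarize_beats(beats, settings$levels))
  })
  names(per_roi) <- names(masks)
  structure(list(settings = settings, rois = rois, per_roi = per_roi),
            class = "result_bundle")
}

# ---- serialization helpers ------------------------------------------------

fmt6 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}
fmt_full <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

settings_lines <- function(s) {
  c("[settings]",
    paste("lower_threshold", s$lower_threshold, sep = "\t"),
    paste("cellsize", s$cellsize, sep = "\t"),
    paste("detection", fmt_full(s$detection), sep = "\t"),
    paste("ref_frame", s$ref_frame, sep = "\t"),
    paste("fps", fmt_full(s$fps), sep = "\t"),
    paste("levels", paste(s$levels, collapse = ","), sep = "\t"),
    paste("masked", s$masked, sep = "\t"),
    paste("provenance", s$provenance, sep = "\t"))
}

parse_settings <- function(lines) {
  kv <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, function(x) if (length(x) > 1L) x[2L] else "", character(1))
  get <- function(k) vals[match(k, keys)]
  rf <- get("ref_frame")
  myo_settings(
    lower_threshold = as.numeric(get("lower_threshold")),
    cellsize = as.numeric(get("cellsize")),
    detection = as.numeric(get("detection")),
    ref_frame = if (identical(rf, "auto")) "auto" else as.numeric(rf),
    fps = as.numeric(get("fps")),
    levels = as.numeric(strsplit(get("levels"), ",", fixed = TRUE)[[1L]]),
    masked = identical(get("masked"), "TRUE"),
    provenance = get("provenance")
  )
}

# frame-level table for one region: the per-frame parameters
frame_table <- function(roi_res) {
  trace <- roi_res$trace
  n <- length(trace$amplitude)
  frames <- seq_len(n)
  max_frames <- roi_res$extrema$frame[roi_res$extrema$kind == "maximum"]
  min_frames <- roi_res$extrema$frame[roi_res$extrema$kind == "minimum"]
  last_max <- vapply(frames, function(f) {
    prior <- max_frames[max_frames <= f]
    if (length(prior)) max(prior) else NA_integer_
  }, numeric(1))
  data.frame(
    frame = frames,
    time_s = (frames - 1) / trace$fps,
    amplitude = trace$amplitude,
    speed = trace$speed,
    is_maximum = frames %in% max_frames,
    is_minimum = frames %in% min_frames,
    time_since_last_contraction = (frames - last_max) / trace$fps,
    contractions_so_far = vapply(frames, function(f) sum(max_frames <= f), integer(1))
  )
}

write_table_block <- function(df, con, fmt = fmt6) {
  writeLines(paste(names(df), collapse = "\t"), con)
  cols <- lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) fmt(col) else as.character(col)
  })
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
}

read_table_block <- function(lines) {
  con <- textConnection(lines)
  on.exit(close(con))
  utils::read.delim(con, header = TRUE, sep = "\t", na.strings = "NA",
                    stringsAsFactors = FALSE)
}

default_timestamp <- function() format(Sys.time(), "%Y-%m-%dT%H-%M-%S")

# ---- writers --------------------------------------------------------------

#' Write the full results file
#'
#' One tab-separated UTF-8 text file holding, for every region: the
#' settings block, a frame-level table (frame, time, amplitude, speed,
#' extremum flags, time since last contraction, running contraction count),
#' a beat-level table (every [compute_beats()] column) and the summary
#' statistics. Floating-point values carry 6 significant digits with a
#' decimal point. The file alone suffices to reconstruct the settings and
#' re-derive every beat metric from its amplitude column.
#'
#' @param bundle a [evaluate_stack()] result.
#' @param out_dir output directory (created if missing).
#' @param timestamp file-name timestamp; defaults to the current time, pass
#'   a fixed string for reproducible file names.
#' @return the file path, invisibly.
#' @export
write_results <- function(bundle, out_dir, timestamp = NULL) {
  stopifnot(inherits(bundle, "result_bundle"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(timestamp)) timestamp <- default_timestamp()
  path <- file.path(out_dir, sprintf("Results %s.txt", timestamp))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# myobeat results", paste0("# version: ", PKG_VERSION())), con)
  writeLines(settings_lines(bundle$settings), con)
  for (id in names(bundle$per_roi)) {
    res <- bundle$per_roi[[id]]
    writeLines(sprintf("[roi %s frames]", id), con)
    write_table_block(frame_table(res), con)
    writeLines(sprintf("[roi %s beats]", id), con)
    write_table_block(as.data.frame(res$beats), con)
    writeLines(sprintf("[roi %s summary]", id), con)
    write_table_block(res$summary, con)
  }
  writeLines("[end]", con)
  invisible(path)
}

#' Write the amplitudes-only file
#'
#' A compact tab-separated file: frame, time, then one amplitude column per
#' region, at full floating-point precision, with the image-stage settings
#' recorded in the header. [reanalyze()] reruns the beat-detection stage on
#' this file with different `detection`/`levels` — in real time, without
#' re-evaluating the video.
#'
#' @inheritParams write_results
#' @return the file path, invisibly.
#' @export
write_amplitudes <- function(bundle, out_dir, timestamp = NULL) {
  stopifnot(inherits(bundle, "result_bundle"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(timestamp)) timestamp <- default_timestamp()
  path <- file.path(out_dir, sprintf("Amplitudes only %s.txt", timestamp))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# myobeat amplitudes", paste0("# version: ", PKG_VERSION())), con)
  writeLines(settings_lines(bundle$settings), con)
  ids <- names(bundle$per_roi)
  amps <- lapply(ids, function(id) bundle$per_roi[[id]]$trace$amplitude)
  n <- length(amps[[1L]])
  df <- data.frame(frame = seq_len(n),
                   time_s = (seq_len(n) - 1) / bundle$settings$fps)
  for (i in seq_along(ids)) df[[paste0("amplitude_roi_", ids[i])]] <- amps[[i]]
  writeLines("[amplitudes]", con)
  write_table_block(df, con, fmt = fmt_full)
  invisible(path)
}

# split a results/amplitudes file into named sections
read_sections <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  heads <- grep("^\\[.*\\]$", lines)
  if (length(heads) == 0L) stop("malformed file (no sections): ", path, call. = FALSE)
  sections <- list()
  for (i in seq_along(heads)) {
    name <- sub("^\\[(.*)\\]$", "\\1", lines[heads[i]])
    end <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    body <- if (heads[i] + 1L <= end) lines[(heads[i] + 1L):end] else character(0)
    sections[[name]] <- body[nzchar(body)]
  }
  sections
}

#' Read a results file back into a bundle
#'
#' Parses a file written by [write_results()] into settings, frame tables,
#' beat tables and summaries (at the file's printed precision).
#'
#' @param path a "Results *.txt" file.
#' @return a list of class `parsed_results` with `settings` and `per_roi`
#'   (per region: `frames`, `beats`, `summary`).
#' @export
read_results <- function(path) {
  sections <- read_sections(path)
  if (is.null(sections$settings)) stop("malformed results file: no settings block",
                                       call. = FALSE)
  settings <- parse_settings(sections$settings)
  roi_ids <- unique(sub("^roi (\\S+) .*$", "\\1",
                        grep("^roi ", names(sections), value = TRUE)))
  per_roi <- lapply(roi_ids, function(id) {
    list(frames = read_table_block(sections[[sprintf("roi %s frames", id)]]),
         beats = read_table_block(sections[[sprintf("roi %s beats", id)]]),
         summary = read_table_block(sections[[sprintf("roi %s summary", id)]]))
  })
  names(per_roi) <- roi_ids
  structure(list(settings = settings, per_roi = per_roi),
            class = "parsed_results")
}

#' Re-run beat detection from an amplitudes-only file
#'
#' Applies the events stage (extrema detection, dynamic thresholds, beat
#' decomposition) to stored amplitude columns. Only `detection` and
#' `levels` may differ from the stored settings: the amplitude trace was
#' produced under the image-stage settings (`lower_threshold`, `cellsize`,
#' `ref_frame`, `fps`, `masked`), so changing those requires a full re-run
#' on the video and is refused with an explanatory error.
#'
#' @param amplitudes_file an "Amplitudes only *.txt" file.
#' @param new_settings optional [myo_settings()]; fields left at their
#'   defaults inherit the stored values.
#' @param detection,levels convenience overrides, equivalent to setting
#'   them in `new_settings`.
#' @return a `result_bundle` whose traces carry the stored amplitudes
#'   (speed columns are not stored and come back as `NA`).
#' @export
reanalyze <- function(amplitudes_file, new_settings = NULL,
                      detection = NULL, levels = NULL) {
  sections <- read_sections(amplitudes_file)
  if (is.null(sections$settings) || is.null(sections$amplitudes)) {
    stop("malformed amplitudes file: ", amplitudes_file, call. = FALSE)
  }
  stored <- parse_settings(sections$settings)
  if (!is.null(new_settings)) {
    stopifnot(inherits(new_settings, "myo_settings"))
    fixed <- c("lower_threshold", "cellsize", "ref_frame", "masked")
    for (f in fixed) {
      if (!identical(new_settings[[f]], stored[[f]])) {
        stop("cannot change ", f, " during re-analysis: the stored amplitudes ",
             "were computed under the original image-stage settings; ",
             "a full re-run on the video is required", call. = FALSE)
      }
    }
    if (!is.null(new_settings$fps) && !identical(new_settings$fps, stored$fps)) {
      stop("cannot change fps during re-analysis: the stored amplitudes ",
           "were computed under the original image-stage settings; ",
           "a full re-run on the video is required", call. = FALSE)
    }
    stored$detection <- new_settings$detection
    stored$levels <- new_settings$levels
  }
  if (!is.null(detection)) stored$detection <- detection
  if (!is.null(levels)) stored$levels <- levels

  tab <- read_table_block(sections$amplitudes)
  amp_cols <- grep("^amplitude_roi_", names(tab), value = TRUE)
  if (length(amp_cols) == 0L) {
    stop("malformed amplitudes file: no amplitude columns (line ",
         "'", paste(names(tab), collapse = "\t"), "')", call. = FALSE)
  }
  per_roi <- lapply(amp_cols, function(cn) {
    id <- sub("^amplitude_roi_", "", cn)
    amp <- tab[[cn]]
    trace <- structure(list(
      roi_id = as.integer(id), amplitude = amp,
      speed = rep(NA_real_, length(amp)), fps = stored$fps,
      ref_frame = if (identical(stored$ref_frame, "auto")) NA_integer_
                  else as.integer(stored$ref_frame),
      masked = stored$masked, pixel_count = NA_integer_
    ), class = "contraction_trace")
    extrema <- detect_extrema(amp, stored$detection)
    beats <- compute_beats(amp, stored$fps, extrema, levels = stored$levels)
    list(trace = trace, extrema = extrema, beats = beats,
         summary = summarize_beats(beats, stored$levels))
  })
  names(per_roi) <- sub("^amplitude_roi_", "", amp_cols)
  structure(list(settings = stored, rois = NULL, per_roi = per_roi),
            class = "result_bundle")
}

#' Plot a region's amplitude trace
#'
#' Amplitude over time with maxima/minima markers and the per-beat dynamic
#' threshold segments. The rendering is fixed-style with no timestamps, so
#' the same bundle always produces the same image.
#'
#' @param bundle a `result_bundle`.
#' @param roi_id region id (`0` for whole frame).
#' @param file output PNG path.
#' @param width,height image size in pixels.
#' @return the file path, invisibly.
#' @export
plot_trace <- function(bundle, roi_id, file, width = 900, height = 400) {
  stopifnot(inherits(bundle, "result_bundle"))
  res <- bundle$per_roi[[as.character(roi_id)]]
  if (is.null(res)) stop("no region with id ", roi_id, call. = FALSE)
  amp <- res$trace$amplitude
  t <- (seq_along(amp) - 1) / res$trace$fps
  grDevices::png(file, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 2, 1))
  graphics::plot(t, amp, type = "l", lwd = 1.5, xlab = "time [s]",
                 ylab = "amplitude [a.u.]",
                 main = sprintf("region %s", roi_id))
  ex <- res$extrema
  if (nrow(ex) > 0) {
    mx <- ex[ex$kind == "maximum", ]
    mn <- ex[ex$kind == "minimum", ]
    graphics::points((mx$frame - 1) / res$trace$fps, mx$value, pch = 24,
                     bg = "red", cex = 0.9)
    graphics::points((mn$frame - 1) / res$trace$fps, mn$value, pch = 25,
                     bg = "blue", cex = 0.9)
  }
  beats <- res$beats
  thr_cols <- grep("^threshold_", names(beats), value = TRUE)
  if (nrow(beats) > 0) {
    for (b in seq_len(nrow(beats))) {
      x0 <- (beats$min_frame[b] - 1) / res$trace$fps
      x1 <- (beats$max_frame[b] - 1) / res$trace$fps
      for (tc in thr_cols) {
        graphics::segments(x0, beats[[tc]][b], x1, beats[[tc]][b],
                           col = "grey55", lty = 2)
      }
    }
  }
  invisible(file)
}
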