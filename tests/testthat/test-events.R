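test_that("sensitivity scan finds exactly the peaks above the excursion floor", {
  # peaks of prominence 100, 30, 5 on a range-100 trace; detection 5 -> eps 20
  trace <- peaks_trace(c(100, 30, 5))
  ex <- detect_extrema(trace, detection = 5)
  expect_identical(sum(ex$kind == "maximum"), 2L)
  oracle <- oracle_extrema_counts(trace, 5)
  expect_identical(sum(ex$kind == "maximum"), oracle[["maxima"]])
  expect_identical(sum(ex$kind == "minimum"), oracle[["minima"]])
})

test_that("monotone and flat traces yield no interior extrema", {
  expect_identical(nrow(detect_extrema(seq(0, 100, by = 5), 5)), 0L)
  expect_identical(nrow(detect_extrema(rep(3, 10), 5)), 0L)
})

test_that("raising detection recovers progressively smaller decaying peaks", {
  trace <- peaks_trace(c(100, 40, 12, 4, 1.6))
  counts <- vapply(c(1, 5, 20, 80), function(d) {
    sum(detect_extrema(trace, d)$kind == "maximum")
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
  for (i in seq_along(counts)) {
    expect_identical(counts[i],
                     oracle_extrema_counts(trace, c(1, 5, 20, 80)[i])[["maxima"]])
  }
  # the sweep's top recovers every peak
  expect_identical(counts[4], 5L)
})

test_that("scan agrees with the exhaustive alternating-excursion oracle", {
  set.seed(902)
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    trace <- as.numeric(sample(0:12, n, replace = TRUE))
    detection <- sample(c(2, 3, 5, 8, 15), 1)
    ex <- detect_extrema(trace, detection)
    oracle <- oracle_extrema_counts(trace, detection)
    expect_identical(sum(ex$kind == "maximum"), oracle[["maxima"]])
    expect_identical(sum(ex$kind == "minimum"), oracle[["minima"]])
    if (nrow(ex) > 1) {
      # invariants: alternation, increasing frames, maxima above neighbors
      expect_true(all(ex$kind[-1] != ex$kind[-nrow(ex)]))
      expect_true(all(diff(ex$frame) > 0))
      mx <- which(ex$kind == "maximum")
      for (i in mx) {
        if (i > 1) expect_gt(ex$value[i], ex$value[i - 1])
        if (i < nrow(ex)) expect_gt(ex$value[i], ex$value[i + 1])
      }
    }
  }
})

test_that("plateau extrema resolve to their earliest frame", {
  trace <- c(0, 10, 10, 10, 0, 0, 10, 0)
  ex <- detect_extrema(trace, 5)
  expect_identical(ex$frame[ex$kind == "maximum"][1], 2L)
  expect_identical(ex$frame[ex$kind == "minimum"][1], 5L)
})

test_that("per-beat thresholds follow min + level * local range", {
  # direct arithmetic check on a hand-built extrema list
  ex <- structure(data.frame(frame = c(2L, 4L, 6L),
                             kind = c("maximum", "minimum", "maximum"),
                             value = c(60, 10, 110)),
                  class = c("extrema_list", "data.frame"))
  thr <- compute_thresholds(numeric(7), ex)
  expect_identical(nrow(thr), 1L)
  expect_equal(unlist(thr[1, c("threshold_10", "threshold_20",
                               "threshold_50", "threshold_90")],
                      use.names = FALSE),
               c(20, 30, 60, 100))

  ex$value <- c(100, 0, 255)
  thr2 <- compute_thresholds(numeric(7), ex)
  expect_equal(unlist(thr2[1, c("threshold_10", "threshold_20",
                                "threshold_50", "threshold_90")],
                      use.names = FALSE),
               c(25.5, 51, 127.5, 229.5))

  ex$value <- c(50, 40, 40)  # degenerate: min equals max
  thr3 <- compute_thresholds(numeric(7), ex)
  expect_true(thr3$degenerate[1])
  expect_equal(thr3$threshold_50[1], 40)
})

test_that("beat decomposition matches first-crossing arithmetic on a triangle", {
  # baseline 0, peak 100: 10 frames up, 20 frames down, fps 100
  pulse <- c(rep(0, 5), seq(0, 100, length.out = 11),
             seq(100, 0, length.out = 21)[-1], rep(0, 5))
  trace <- c(pulse, pulse)  # two identical beats
  ex <- detect_extrema(trace, 10)
  beats <- compute_beats(trace, fps = 100, ex)
  expect_identical(nrow(beats), 1L)  # second peak has no committed closing rise
  b <- beats[1, ]
  for (l in c(0.10, 0.20, 0.50, 0.90)) {
    thr <- b[[sprintf("threshold_%g", l * 100)]]
    o <- oracle_crossings(trace, b$min_frame, b$max_frame,
                          length(trace), thr, 100)
    expect_equal(b[[sprintf("systole_%g", l * 100)]], o$systole)
    expect_equal(b[[sprintf("diastole_%g", l * 100)]], o$diastole)
    expect_equal(b[[sprintf("peak_time_%g", l * 100)]], o$systole + o$diastole)
  }
})

test_that("beat time spans successive maxima and counts accumulate", {
  trace <- rep(0, 300)
  for (at in c(45L, 145L, 245L)) trace[at + 0:10] <- c(1:5, 6, 5:1) * 20
  ex <- detect_extrema(trace, 5)
  beats <- compute_beats(trace, fps = 100, ex)
  # maxima at frames 50, 150, 250 -> beat time 1.0 s
  expect_identical(ex$frame[ex$kind == "maximum"], c(50L, 150L, 250L))
  expect_equal(beats$beat_time[1], 1.0)
  expect_equal(beats$time_since_previous[1], 1.0)
  expect_identical(beats$contractions_so_far[nrow(beats)], 3L)
})

test_that("a single maximum with monotone decline yields no complete beat", {
  trace <- c(0, 100, seq(99, 0, length.out = 30))
  ex <- detect_extrema(trace, 5)
  expect_identical(sum(ex$kind == "maximum"), 1L)
  beats <- compute_beats(trace, 100, ex)
  expect_identical(nrow(beats), 0L)
})

test_that("systole and diastole shrink as the threshold level rises", {
  sc <- basic_scene(duration = 4)
  tr <- compute_trace(sc$stack, ref_frame = "auto")
  beats <- compute_beats(tr$amplitude, sc$stack$fps,
                         detect_extrema(tr$amplitude, 5))
  expect_gt(nrow(beats), 0L)
  for (b in seq_len(nrow(beats))) {
    sys <- unlist(beats[b, paste0("systole_", c(90, 50, 20, 10))])
    dia <- unlist(beats[b, paste0("diastole_", c(90, 50, 20, 10))])
    expect_true(all(diff(sys[!is.na(sys)]) >= 0))
    expect_true(all(diff(dia[!is.na(dia)]) >= 0))
    expect_true(all(stats::na.omit(unlist(beats[b, grepl("^(systole|diastole)", names(beats))])) >= 0))
  }
})

test_that("editing the trace after a beat's closing minimum leaves earlier beats unchanged", {
  sc <- basic_scene(duration = 4)
  tr <- compute_trace(sc$stack, ref_frame = "auto")
  amp <- tr$amplitude
  ex <- detect_extrema(amp, 5)
  beats <- compute_beats(amp, sc$stack$fps, ex)
  stopifnot(nrow(beats) >= 2)
  closing_min <- min(ex$frame[ex$kind == "minimum" & ex$frame > beats$max_frame[2]])
  amp2 <- amp
  amp2[(closing_min + 1):length(amp2)] <- amp[closing_min]  # flatten the tail
  beats2 <- compute_beats(amp2, sc$stack$fps, detect_extrema(amp2, 5))
  cols <- setdiff(names(beats), c("beat_time", "time_since_previous"))
  expect_equal(as.data.frame(beats2)[1, cols], as.data.frame(beats)[1, cols])
})

test_that("frozen thresholds lose a drifting amplitude that dynamic ones track", {
  sc <- drift_scene()
  tr <- compute_trace(sc$stack, ref_frame = 1)
  ex <- detect_extrema(tr$amplitude, 5)
  dynamic <- compute_beats(tr$amplitude, sc$stack$fps, ex)
  static <- compute_beats(tr$amplitude, sc$stack$fps, ex, static = TRUE)
  dyn_vals <- unlist(dynamic[, grepl("^(systole|diastole)_", names(dynamic))])
  expect_false(anyNA(dyn_vals))
  expect_true(anyNA(unlist(static[, grepl("^diastole_", names(static))])))
})
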