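bundle_for <- function(stack, ...) {
  evaluate_stack(stack, myo_settings(...))
}

test_that("results file stores the alternating amplitude exactly and round-trips", {
  st <- gen_alternating(10, 20, 20)
  b <- bundle_for(st, ref_frame = 1, detection = 5)
  dir <- withr::local_tempdir()
  path <- write_results(b, dir, timestamp = "fixed")
  expect_identical(basename(path), "Results fixed.txt")

  parsed <- read_results(path)
  expect_identical(as.numeric(parsed$per_roi[["0"]]$frames$amplitude),
                   rep(c(0, 255), 5))
  expect_identical(parsed$settings$detection, 5)
  expect_identical(parsed$settings$ref_frame, 1)
  expect_false(parsed$settings$masked)
})

test_that("results round-trip field-for-field at printed precision", {
  sc <- basic_scene()
  b <- bundle_for(sc$stack, detection = 5, masked = TRUE,
                  lower_threshold = 20, cellsize = 50)
  dir <- withr::local_tempdir()
  parsed <- read_results(write_results(b, dir, timestamp = "t"))
  expect_setequal(names(parsed$per_roi), names(b$per_roi))
  for (id in names(b$per_roi)) {
    got <- parsed$per_roi[[id]]
    expect_equal(got$frames$amplitude, b$per_roi[[id]]$trace$amplitude,
                 tolerance = 1e-5)
    expect_equal(got$frames$speed, b$per_roi[[id]]$trace$speed,
                 tolerance = 1e-5)
    want_beats <- as.data.frame(b$per_roi[[id]]$beats)
    got_beats <- got$beats
    got_beats$kind <- NULL
    expect_identical(got_beats$min_frame, want_beats$min_frame)
    expect_identical(got_beats$max_frame, want_beats$max_frame)
    num_cols <- names(want_beats)[vapply(want_beats, is.numeric, logical(1))]
    for (cn in num_cols) {
      expect_equal(got_beats[[cn]], want_beats[[cn]], tolerance = 1e-5)
    }
  }
})

test_that("full retracement: beat metrics re-derive from the stored amplitude", {
  sc <- basic_scene()
  b <- bundle_for(sc$stack, detection = 5)
  dir <- withr::local_tempdir()
  parsed <- read_results(write_results(b, dir, timestamp = "t"))
  s <- parsed$settings
  amp <- parsed$per_roi[["0"]]$frames$amplitude
  beats <- compute_beats(amp, s$fps, detect_extrema(amp, s$detection), s$levels)
  stored <- parsed$per_roi[["0"]]$beats
  expect_identical(beats$max_frame, stored$max_frame)
  expect_equal(beats$systole_50, stored$systole_50, tolerance = 1e-5)
  expect_equal(beats$diastole_50, stored$diastole_50, tolerance = 1e-5)
})

test_that("amplitudes file has one column per region and one row per frame", {
  sc <- basic_scene(n_cells = 2, width = 240, height = 120)
  b <- bundle_for(sc$stack, detection = 5, masked = TRUE,
                  lower_threshold = 20, cellsize = 50)
  dir <- withr::local_tempdir()
  path <- write_amplitudes(b, dir, timestamp = "t")
  tab_lines <- readLines(path)
  header <- tab_lines[grep("^frame\t", tab_lines)]
  expect_identical(strsplit(header, "\t")[[1]],
                   c("frame", "time_s", "amplitude_roi_1", "amplitude_roi_2"))
  n_data <- length(tab_lines) - grep("^frame\t", tab_lines)
  expect_identical(n_data, sc$stack$n_frames)
})

test_that("reanalysis with unchanged settings reproduces beats bit-exactly", {
  sc <- basic_scene()
  b <- bundle_for(sc$stack, detection = 5)
  dir <- withr::local_tempdir()
  path <- write_amplitudes(b, dir, timestamp = "t")
  again <- reanalyze(path)
  expect_identical(as.data.frame(again$per_roi[["0"]]$beats),
                   as.data.frame(b$per_roi[["0"]]$beats))
  expect_identical(again$per_roi[["0"]]$trace$amplitude,
                   b$per_roi[["0"]]$trace$amplitude)
})

test_that("raising detection during reanalysis recovers smaller peaks", {
  # decaying-amplitude beats: low detection misses the small ones
  sc <- basic_scene(duration = 5, schedule = c(1, 0.45, 0.2, 0.09, 0.04))
  b <- bundle_for(sc$stack, detection = 2)
  dir <- withr::local_tempdir()
  path <- write_amplitudes(b, dir, timestamp = "t")
  amp <- b$per_roi[["0"]]$trace$amplitude
  for (d in c(2, 5, 20, 80)) {
    again <- reanalyze(path, detection = d)
    got <- sum(again$per_roi[["0"]]$extrema$kind == "maximum")
    expect_identical(got, oracle_extrema_counts(amp, d)[["maxima"]])
  }
})

test_that("image-stage settings cannot change during reanalysis", {
  sc <- basic_scene()
  b <- bundle_for(sc$stack, detection = 5)
  dir <- withr::local_tempdir()
  path <- write_amplitudes(b, dir, timestamp = "t")
  stored <- b$settings
  changed <- stored
  changed$lower_threshold <- 99
  expect_error(reanalyze(path, new_settings = changed), "full re-run")
  changed2 <- stored
  changed2$fps <- 42
  expect_error(reanalyze(path, new_settings = changed2), "full re-run")
  # same image-stage settings with new detection: accepted
  ok <- stored
  ok$detection <- 20
  expect_identical(reanalyze(path, new_settings = ok)$settings$detection, 20)
})

test_that("malformed amplitude files raise parse errors naming the problem", {
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("no sections here", "just text"), bad)
  expect_error(reanalyze(bad), "malformed|sections")
  bad2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("[settings]", "fps\t10", "levels\t0.5", "detection\t5",
               "lower_threshold\t0", "cellsize\t1", "ref_frame\t1",
               "masked\tFALSE", "provenance\t", "[amplitudes]",
               "frame\ttime_s\twrong_column", "1\t0\t0"), bad2)
  expect_error(reanalyze(bad2), "no amplitude columns")
})

test_that("trace plots are deterministic and render one marker per beat", {
  sc <- basic_scene()
  b <- bundle_for(sc$stack, detection = 5)
  expect_identical(sum(b$per_roi[["0"]]$extrema$kind == "maximum"), 3L)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.png"); f2 <- file.path(dir, "b.png")
  plot_trace(b, 0, f1)
  plot_trace(b, 0, f2)
  expect_identical(png::readPNG(f1), png::readPNG(f2))
  # flat trace renders without markers or error
  flat <- evaluate_stack(
    frame_stack(replicate(5, matrix(3L, 8, 8), simplify = FALSE), fps = 10),
    myo_settings(ref_frame = 1)
  )
  f3 <- file.path(dir, "flat.png")
  plot_trace(flat, 0, f3)
  expect_true(file.exists(f3))
  expect_error(plot_trace(b, 7, file.path(dir, "x.png")), "no region")
})

test_that("summary statistics skip incomplete beats", {
  sc <- basic_scene(duration = 4)
  b <- bundle_for(sc$stack, detection = 5)
  sm <- b$per_roi[["0"]]$summary
  bt <- sm[sm$parameter == "beat_time", ]
  beats <- b$per_roi[["0"]]$beats
  expect_identical(bt$n, sum(!is.na(beats$beat_time)))
  expect_equal(bt$mean, mean(beats$beat_time, na.rm = TRUE))
})
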