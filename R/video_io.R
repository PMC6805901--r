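# ---- grayscale conversion -------------------------------------------------

# ITU-R BT.601 luma, rounded half-up, clamped to [0, 255].
# Fixed weights keep results reproducible across decoders.
luma601 <- function(r, g, b) {
  v <- floor(0.299 * r + 0.587 * g + 0.114 * b + 0.5)
  v[v < 0] <- 0
  v[v > 255] <- 255
  v
}

# accepts a numeric array in [0,1] (as returned by png/tiff readers) with
# 2 dims (gray) or 3 dims (RGB/RGBA); returns an integer matrix 0..255
plane_to_gray <- function(x) {
  if (length(dim(x)) == 2L || is.null(dim(x))) {
    m <- floor(as.matrix(x) * 255 + 0.5)
  } else {
    m <- luma601(x[, , 1L] * 255, x[, , 2L] * 255, x[, , 3L] * 255)
  }
  storage.mode(m) <- "integer"
  m
}

# ---- natural sort ---------------------------------------------------------

# "frame2" < "frame10": every digit run is zero-padded before ordering
natural_order <- function(paths) {
  keys <- gsub("(\\d+)", "~\\1~", basename(paths))
  keys <- vapply(strsplit(keys, "~"), function(parts) {
    parts <- vapply(parts, function(p) {
      if (grepl("^\\d+$", p)) sprintf("%020d", as.numeric(p)) else p
    }, character(1))
    paste(parts, collapse = "")
  }, character(1))
  order(keys, paths)
}

# ---- AVI (RIFF) -----------------------------------------------------------

fourcc <- function(s) writeBin(charToRaw(s), raw(), size = 1)
u32 <- function(...) writeBin(as.integer(c(...)), raw(), size = 4, endian = "little")
u16 <- function(...) writeBin(as.integer(c(...)), raw(), size = 2, endian = "little")

riff_chunk <- function(id, payload) {
  pad <- if (length(payload) %% 2L == 1L) as.raw(0L) else raw(0)
  c(fourcc(id), u32(length(payload)), payload, pad)
}
riff_list <- function(type, payload) riff_chunk("LIST", c(fourcc(type), payload))

# 8-bit bottom-up DIB with rows padded to 4-byte boundaries
frame_to_dib <- function(m) {
  h <- nrow(m); w <- ncol(m)
  stride <- 4L * ((w + 3L) %/% 4L)
  out <- matrix(as.raw(0L), nrow = stride, ncol = h)
  # DIB stores the bottom image row first
  out[seq_len(w), ] <- matrix(as.raw(t(m[h:1, , drop = FALSE])), nrow = w)
  as.vector(out)
}

write_avi_uncompressed <- function(stack, path) {
  w <- stack$width; h <- stack$height; n <- stack$n_frames
  stride <- 4L * ((w + 3L) %/% 4L)
  frame_bytes <- stride * h
  rate <- as.integer(round(stack$fps * 1000))
  avih <- c(
    u32(round(1e6 / stack$fps)),          # microseconds per frame
    u32(frame_bytes * as.integer(round(stack$fps))), # max bytes/sec (advisory)
    u32(0), u32(16),                      # padding, flags (AVIF_HASINDEX)
    u32(n), u32(0), u32(1),               # total frames, initial frames, streams
    u32(frame_bytes), u32(w), u32(h),
    u32(0, 0, 0, 0)
  )
  strh <- c(
    fourcc("vids"), fourcc("DIB "),
    u32(0), u16(0, 0), u32(0),
    u32(1000), u32(rate),                 # scale, rate: fps = rate / scale
    u32(0), u32(n), u32(frame_bytes),
    u32(-1), u32(0),
    u16(0, 0, w, h)
  )
  palette <- as.raw(as.vector(rbind(0:255, 0:255, 0:255, rep(0L, 256))))
  strf <- c(
    u32(40), u32(w), u32(h), u16(1), u16(8),
    u32(0),                               # BI_RGB, uncompressed
    u32(frame_bytes), u32(0), u32(0), u32(256), u32(0),
    palette
  )
  hdrl <- riff_list("hdrl", c(
    riff_chunk("avih", avih),
    riff_list("strl", c(riff_chunk("strh", strh), riff_chunk("strf", strf)))
  ))
  movi_frames <- lapply(stack$frames, function(m) riff_chunk("00db", frame_to_dib(m)))
  movi <- riff_list("movi", do.call(c, movi_frames))
  # idx1: one entry per frame, offsets relative to the start of 'movi' data
  offs <- cumsum(c(4L, head(vapply(movi_frames, length, integer(1)), -1L)))
  idx <- do.call(c, lapply(seq_len(n), function(i) {
    c(fourcc("00db"), u32(16L), u32(offs[i]), u32(frame_bytes))
  }))
  body <- c(fourcc("AVI "), hdrl, movi, riff_chunk("idx1", idx))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(fourcc("RIFF"), u32(length(body)), body), con)
  invisible(path)
}

read_u32 <- function(raw, off) {
  sum(as.numeric(raw[off + 0:3]) * c(1, 256, 65536, 16777216))
}
read_fourcc <- function(raw, off) rawToChar(raw[off + 0:3])

read_avi <- function(path) {
  bytes <- readBin(path, raw(), file.info(path)$size)
  if (length(bytes) < 12L || read_fourcc(bytes, 1L) != "RIFF" ||
      read_fourcc(bytes, 9L) != "AVI ") {
    stop("not a RIFF/AVI file: ", path, call. = FALSE)
  }
  env <- new.env(parent = emptyenv())
  env$frames <- list(); env$scale <- NA_real_; env$rate <- NA_real_
  env$bitcount <- NA_integer_; env$compression <- NA_real_
  env$palette <- NULL; env$width <- NA_integer_; env$height <- NA_integer_

  walk <- function(off, end) {
    while (off + 8L <= end + 1L) {
      id <- read_fourcc(bytes, off)
      size <- read_u32(bytes, off + 4L)
      data_off <- off + 8L
      if (id %in% c("RIFF", "LIST")) {
        walk(data_off + 4L, data_off + size - 1L)
      } else if (id == "strh") {
        typ <- read_fourcc(bytes, data_off)
        if (typ == "vids") {
          env$scale <- read_u32(bytes, data_off + 20L)
          env$rate <- read_u32(bytes, data_off + 24L)
        }
      } else if (id == "strf" && is.na(env$bitcount)) {
        env$width <- read_u32(bytes, data_off + 4L)
        env$height <- read_u32(bytes, data_off + 8L)
        env$bitcount <- read_u32(bytes, data_off + 14L) %% 65536
        env$compression <- read_u32(bytes, data_off + 16L)
        n_col <- read_u32(bytes, data_off + 32L)
        if (env$bitcount == 8) {
          if (n_col == 0) n_col <- 256
          pal <- bytes[data_off + 40L + seq_len(4L * n_col) - 1L]
          pal <- matrix(as.integer(pal), nrow = 4L)  # B, G, R, reserved
          env$palette <- luma601(pal[3L, ], pal[2L, ], pal[1L, ])
        }
      } else if (grepl("^[0-9]{2}d[bc]$", id)) {
        env$frames[[length(env$frames) + 1L]] <- bytes[data_off + seq_len(size) - 1L]
      }
      off <- data_off + size + (size %% 2L)
    }
  }
  walk(13L, length(bytes))

  if (is.na(env$compression) || !env$compression %in% c(0)) {
    stop("unsupported AVI codec (only uncompressed 'DIB ' video is readable): ",
         path, call. = FALSE)
  }
  w <- env$width; h <- env$height
  decode <- function(buf) {
    if (env$bitcount == 8) {
      stride <- 4L * ((w + 3L) %/% 4L)
      px <- matrix(as.integer(buf[seq_len(stride * h)]), nrow = stride)
      m <- t(px[seq_len(w), , drop = FALSE])[, , drop = FALSE]
      m <- matrix(env$palette[m + 1L], nrow = h, ncol = w, byrow = FALSE)
      m[h:1, , drop = FALSE]
    } else if (env$bitcount == 24) {
      stride <- 4L * ((3L * w + 3L) %/% 4L)
      px <- matrix(as.integer(buf[seq_len(stride * h)]), nrow = stride)
      b <- t(px[seq(1L, 3L * w, by = 3L), , drop = FALSE])
      g <- t(px[seq(2L, 3L * w, by = 3L), , drop = FALSE])
      r <- t(px[seq(3L, 3L * w, by = 3L), , drop = FALSE])
      m <- luma601(r, g, b)
      m[h:1, , drop = FALSE]
    } else {
      stop("unsupported AVI bit depth: ", env$bitcount, call. = FALSE)
    }
  }
  frames <- lapply(env$frames, decode)
  fps <- if (!is.na(env$rate) && !is.na(env$scale) && env$scale > 0) {
    env$rate / env$scale
  } else {
    NA_real_
  }
  list(frames = frames, fps = fps)
}

# ---- public readers / writers --------------------------------------------

#' Read a video or image stack as 8-bit grayscale frames
#'
#' Accepts an uncompressed AVI file, a multi-page TIFF, a directory, or a
#' glob of numbered PNG/TIFF frames (ordered by natural sort, so `frame2`
#' precedes `frame10`). Color input is converted with fixed ITU-R BT.601
#' luma weights (0.299, 0.587, 0.114), rounded half-up and clamped, so the
#' same file yields the same pixels everywhere.
#'
#' The frame rate comes from AVI metadata when present; `fps_override`
#' always wins. Image sequences and TIFF stacks carry no rate, so the
#' override is mandatory for them — the rate is never silently defaulted.
#'
#' @param path file, directory, or glob pattern.
#' @param fps_override frames per second; overrides any container metadata.
#' @return a [frame_stack()].
#' @export
read_stack <- function(path, fps_override = NULL) {
  if (!is.null(fps_override)) {
    stopifnot(is.numeric(fps_override), length(fps_override) == 1L, fps_override > 0)
  }
  files <- NULL
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L) stop("no PNG/TIFF frames found in ", path, call. = FALSE)
  } else if (grepl("[*?]", path)) {
    files <- Sys.glob(path)
    if (length(files) == 0L) stop("no files match ", path, call. = FALSE)
  } else if (!file.exists(path)) {
    stop("cannot read input: ", path, " does not exist", call. = FALSE)
  }

  if (!is.null(files)) {
    files <- files[natural_order(files)]
    frames <- lapply(files, function(f) {
      ext <- tolower(tools::file_ext(f))
      img <- if (ext == "png") png::readPNG(f) else tiff::readTIFF(f)
      plane_to_gray(img)
    })
    fps <- NA_real_
    src <- path
  } else {
    ext <- tolower(tools::file_ext(path))
    if (ext == "avi") {
      avi <- read_avi(path)
      frames <- avi$frames
      fps <- avi$fps
    } else if (ext %in% c("tif", "tiff")) {
      pages <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      frames <- lapply(pages, plane_to_gray)
      fps <- NA_real_
    } else {
      stop("unsupported input format: ", path, call. = FALSE)
    }
    src <- path
  }

  if (length(frames) < 2L) {
    stop("degenerate input: ", src, " holds fewer than 2 frames", call. = FALSE)
  }
  if (!is.null(fps_override)) fps <- fps_override
  if (is.na(fps)) {
    stop("frame rate unknown for ", src,
         ": the container carries no fps metadata; pass fps_override",
         call. = FALSE)
  }
  frame_stack(frames, fps = fps, source = src)
}

#' Write a frame stack to disk
#'
#' `.avi` paths get an uncompressed 8-bit AVI (bit-exact round trip through
#' [read_stack()]); `.tif`/`.tiff` paths a multi-page TIFF; any other path is
#' treated as a directory that receives numbered single-frame TIFFs.
#'
#' @param stack a [frame_stack()].
#' @param path output file or directory.
#' @param codec `"uncompressed"` (the only codec this package encodes;
#'   lossy MJPEG files can be read by downstream tools but are not written).
#' @return the path, invisibly.
#' @export
write_stack <- function(stack, path, codec = c("uncompressed", "mjpeg")) {
  stopifnot(inherits(stack, "frame_stack"))
  codec <- match.arg(codec)
  if (codec == "mjpeg") {
    stop("MJPEG encoding is not provided; use codec = \"uncompressed\"",
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "avi") {
    write_avi_uncompressed(stack, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(lapply(stack$frames, function(m) m / 255), path,
                    bits.per.sample = 8L)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (i in seq_len(stack$n_frames)) {
      tiff::writeTIFF(stack$frames[[i]] / 255,
                      file.path(path, sprintf("frame_%05d.tif", i)),
                      bits.per.sample = 8L)
    }
  }
  invisible(path)
}
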