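#' Construct a thermal frame sequence
#'
#' A `thermal_sequence` is an ordered stack of single-channel thermal frames
#' in raw sensor counts (16-bit range), together with its sampling rate.
#' Intensities are kept as integers on the signal path; no rescaling or 8-bit
#' conversion is ever applied before signal extraction.
#'
#' @param frames list of 2-D matrices, all with identical dimensions; values
#'   are dimensionless sensor counts.
#' @param fps sampling rate in frames per second (> 0).
#' @param timestamps optional vector of frame times in seconds; when omitted,
#'   frame `i` is stamped `(i-1)/fps`. Supplied timestamps must be strictly
#'   increasing with constant spacing `1/fps` (tolerance 1e-9 s).
#' @return An object of class `thermal_sequence` with elements `frames`,
#'   `fps`, `timestamps`, `height`, `width`.
#' @seealso [read_thermal_stack()], [generate_scene()]
#' @export
thermal_sequence <- function(frames, fps, timestamps = NULL) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("'frames' must be a list of at least 2 frames")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("'fps' must be a single positive number")
  dims <- dim(frames[[1L]])
  if (is.null(dims) || length(dims) != 2L)
    stop("frames must be 2-D matrices")
  for (i in seq_along(frames)) {
    di <- dim(frames[[i]])
    if (is.null(di) || !identical(as.integer(di), as.integer(dims)))
      stop(sprintf("frame %d has dimensions %s, expected %dx%d",
                   i, paste(di, collapse = "x"), dims[1L], dims[2L]))
  }
  n <- length(frames)
  if (is.null(timestamps)) {
    timestamps <- (seq_len(n) - 1) / fps
  } else {
    if (length(timestamps) != n)
      stop("'timestamps' must have one entry per frame")
    dt <- diff(timestamps)
    if (any(dt <= 0) || any(abs(dt - 1 / fps) > 1e-9))
      stop("'timestamps' must be strictly increasing with spacing 1/fps (tol 1e-9 s)")
  }
  structure(
    list(frames = frames, fps = fps, timestamps = timestamps,
         height = as.integer(dims[1L]), width = as.integer(dims[2L])),
    class = "thermal_sequence")
}

#' @export
print.thermal_sequence <- function(x, ...) {
  cat(sprintf("thermal_sequence: %d frames of %dx%d px @ %.3g fps (%.2f s)\n",
              length(x$frames), x$width, x$height, x$fps,
              length(x$frames) / x$fps))
  invisible(x)
}

#' @export
length.thermal_sequence <- function(x) length(x$frames)

#' Construct a face bounding box
#'
#' Boxes use 0-based pixel coordinates with half-open extents: the box covers
#' columns `[x, x+w)` and rows `[y, y+h)`. The minimum size `w >= 4`,
#' `h >= 6` guarantees every cell of the default 4x6 grid is at least one
#' pixel.
#'
#' @param x,y top-left corner, 0-based pixels.
#' @param w,h box width and height in pixels.
#' @param frame_index 0-based index of the frame the box applies to, or
#'   `"all"` for a static box.
#' @return An object of class `face_box`.
#' @export
face_box <- function(x, y, w, h, frame_index = "all") {
  for (v in list(x = x, y = y, w = w, h = h)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v != round(v))
      stop("box coordinates must be single finite integers")
  }
  if (x < 0 || y < 0) stop("box corner must satisfy x >= 0, y >= 0")
  if (w < 4 || h < 6)
    stop(sprintf("box too small (w=%d, h=%d): need w >= 4 and h >= 6", w, h))
  if (!identical(frame_index, "all")) {
    if (!is.numeric(frame_index) || frame_index != round(frame_index) ||
        frame_index < 0)
      stop("'frame_index' must be \"all\" or a nonnegative integer")
    frame_index <- as.integer(frame_index)
  }
  structure(list(x = as.integer(x), y = as.integer(y),
                 w = as.integer(w), h = as.integer(h),
                 frame_index = frame_index),
            class = "face_box")
}

#' @export
print.face_box <- function(x, ...) {
  cat(sprintf("face_box: %dx%d at (%d,%d), frame %s\n",
              x$w, x$h, x$x, x$y, as.character(x$frame_index)))
  invisible(x)
}

# check a box against the frame extents of a sequence
validate_box_in_frame <- function(box, width, height, what = "box") {
  if (box$x + box$w > width || box$y + box$h > height)
    stop(sprintf("%s (%d,%d,%d,%d) exceeds frame extents %dx%d",
                 what, box$x, box$y, box$w, box$h, width, height))
  invisible(box)
}

#' Read a thermal frame stack
#'
#' Supported containers: a multi-page TIFF (uint16), a directory of 16-bit
#' (or 8-bit) grayscale PNGs ordered lexicographically, or a raw binary array
#' with a plain-text sidecar header (see Details). Pixel counts are preserved
#' bit-exactly as integers; PNG intensities, which decode as normalised
#' values, are mapped onto the 16-bit range `0..65535` (an 8-bit PNG value
#' `v` becomes `v * 257`).
#'
#' @details The raw container is a little-endian array at `<path>` with a
#' sidecar `<path>.hdr` containing `key=value` lines for `dtype` (only
#' `uint16`), `height`, `width`, `n_frames`. Frames are stored one after
#' another in row-major (C) order.
#'
#' @param path file or directory path.
#' @param fps sampling rate in frames/second; required, container metadata is
#'   never trusted.
#' @return A [thermal_sequence()].
#' @export
read_thermal_stack <- function(path, fps) {
  if (!file.exists(path))
    stop(sprintf("cannot read thermal stack: '%s' does not exist", path))
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("'fps' must be a single positive number")
  frames <-
    if (dir.exists(path)) {
      files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
      if (length(files) == 0L)
        stop(sprintf("no PNG frames found in directory '%s'", path))
      lapply(files, function(f) {
        img <- png::readPNG(f)
        if (length(dim(img)) == 3L) img <- img[, , 1L]  # grayscale channel
        matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
      })
    } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
      pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      lapply(pages, function(m) {
        if (length(dim(m)) == 3L) m <- m[, , 1L]
        storage.mode(m) <- "integer"
        m
      })
    } else {
      read_raw_stack(path)
    }
  thermal_sequence(frames, fps = fps)
}

read_raw_stack <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path))
    stop(sprintf("raw stack '%s' has no sidecar header '%s'", path, hdr_path))
  lines <- readLines(hdr_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  hdr <- stats::setNames(trimws(vapply(kv, `[`, "", 2L)),
                         trimws(vapply(kv, `[`, "", 1L)))
  for (key in c("dtype", "height", "width", "n_frames"))
    if (is.na(hdr[key]))
      stop(sprintf("sidecar header '%s' is missing field '%s'", hdr_path, key))
  if (hdr[["dtype"]] != "uint16")
    stop(sprintf("unsupported raw dtype '%s' (only uint16)", hdr[["dtype"]]))
  h <- as.integer(hdr[["height"]]); w <- as.integer(hdr[["width"]])
  nf <- as.integer(hdr[["n_frames"]])
  con <- file(path, "rb"); on.exit(close(con))
  vals <- readBin(con, what = "integer", n = h * w * nf, size = 2L,
                  signed = FALSE, endian = "little")
  if (length(vals) != h * w * nf)
    stop(sprintf("raw stack '%s' truncated: expected %d values, got %d",
                 path, h * w * nf, length(vals)))
  lapply(seq_len(nf), function(k) {
    # row-major on disk -> fill the matrix by row
    matrix(vals[((k - 1L) * h * w + 1L):(k * h * w)], nrow = h, ncol = w,
           byrow = TRUE)
  })
}

#' Write a thermal frame stack
#'
#' Writes the sequence as a multi-page 16-bit TIFF (`format = "tiff"`) or a
#' raw uint16 array with sidecar header (`format = "raw"`). An additional
#' `"png8"` format exports 8-bit PNGs for visualisation only; it quantises
#' and must never feed the signal path.
#'
#' @param seq a [thermal_sequence()].
#' @param path output file (or directory for `"png8"`).
#' @param format one of `"tiff"`, `"raw"`, `"png8"`.
#' @return `path`, invisibly.
#' @export
write_thermal_stack <- function(seq, path, format = c("tiff", "raw", "png8")) {
  format <- match.arg(format)
  stopifnot(inherits(seq, "thermal_sequence"))
  rng <- range(vapply(seq$frames, range, numeric(2)))
  if (rng[1L] < 0 || rng[2L] > 65535)
    stop("pixel values outside the uint16 range [0, 65535] cannot be written")
  if (format == "tiff") {
    tiff::writeTIFF(lapply(seq$frames, function(m) m / 65535), path,
                    bits.per.sample = 16L, compression = "none")
  } else if (format == "raw") {
    con <- file(path, "wb")
    for (m in seq$frames)  # row-major on disk
      writeBin(as.integer(t(m)), con, size = 2L, endian = "little")
    close(con)
    writeLines(c("dtype=uint16",
                 sprintf("height=%d", seq$height),
                 sprintf("width=%d", seq$width),
                 sprintf("n_frames=%d", length(seq$frames))),
               paste0(path, ".hdr"))
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (i in seq_along(seq$frames))
      png::writePNG(seq$frames[[i]] / 65535,
                    file.path(path, sprintf("frame_%05d.png", i - 1L)))
  }
  invisible(path)
}

#' Read face bounding boxes
#'
#' Accepts a CSV with header `frame_index,x,y,w,h` or a JSON list of records
#' with the same fields. A single record with `frame_index = "all"` denotes a
#' static box used for every frame. Order is preserved; checks against a
#' particular sequence's extents are deferred to signal extraction.
#'
#' @param path CSV (`.csv`) or JSON (`.json`) file.
#' @return A list of [face_box()] objects.
#' @export
read_boxes <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read boxes: '%s' does not exist", path))
  recs <-
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      df <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
      lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
    } else {
      df <- utils::read.csv(path, colClasses = c(frame_index = "character"))
      need <- c("frame_index", "x", "y", "w", "h")
      if (!all(need %in% names(df)))
        stop(sprintf("box CSV '%s' must have header %s", path,
                     paste(need, collapse = ",")))
      lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
    }
  boxes <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    fi <- r$frame_index
    if (!identical(fi, "all")) {
      fi <- suppressWarnings(as.numeric(fi))
      if (is.na(fi))
        stop(sprintf("malformed box record at line %d of '%s'", i + 1L, path))
    }
    box <- tryCatch(face_box(r$x, r$y, r$w, r$h, frame_index = fi),
                    error = function(e)
                      stop(sprintf("invalid box at line %d of '%s': %s",
                                   i + 1L, path, conditionMessage(e)),
                           call. = FALSE))
    boxes[[i]] <- box
  }
  boxes
}

#' Write face bounding boxes to CSV
#'
#' @param boxes list of [face_box()] objects (or a single one).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_boxes <- function(boxes, path) {
  if (inherits(boxes, "face_box")) boxes <- list(boxes)
  df <- data.frame(
    frame_index = vapply(boxes, function(b) as.character(b$frame_index), ""),
    x = vapply(boxes, `[[`, 0L, "x"), y = vapply(boxes, `[[`, 0L, "y"),
    w = vapply(boxes, `[[`, 0L, "w"), h = vapply(boxes, `[[`, 0L, "h"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Face-detector provider contract
#'
#' The core pipeline never depends on a trained detector: any function that
#' maps a [thermal_sequence()] to a single static [face_box()] or a list of
#' per-frame boxes satisfies the provider contract. `static_detector()` wraps
#' a fixed box as such a provider; detector output from external models is
#' supplied through [read_boxes()] files instead.
#'
#' @param box a [face_box()].
#' @return A function `(seq) -> face_box`.
#' @export
static_detector <- function(box) {
  stopifnot(inherits(box, "face_box"))
  function(seq) box
}

# resolve user-supplied boxes (face_box, list of face_box, or provider
# function) into either one static box or one box per frame
resolve_boxes <- function(seq, boxes) {
  if (is.function(boxes)) boxes <- boxes(seq)
  if (inherits(boxes, "face_box")) return(list(static = boxes))
  stopifnot(is.list(boxes), all(vapply(boxes, inherits, TRUE, "face_box")))
  if (length(boxes) == 1L && identical(boxes[[1L]]$frame_index, "all"))
    return(list(static = boxes[[1L]]))
  if (length(boxes) != length(seq$frames))
    stop(sprintf("need one box per frame (%d), got %d",
                 length(seq$frames), length(boxes)))
  ord <- vapply(boxes, function(b)
    if (identical(b$frame_index, "all")) NA_integer_ else b$frame_index, 0L)
  if (!anyNA(ord)) boxes <- boxes[order(ord)]
  list(per_frame = boxes)
}
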