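#' Split a face box into the subregion grid
#'
#' The face box is tiled exactly by `n_cols` x `n_rows` cells (default 4
#' columns by 6 rows, matching the roughly 1:2 aspect ratio of a face).
#' Integer division remainders are distributed one pixel per column from the
#' left and one per row from the top, so the geometry is deterministic.
#' Cells are indexed row-major from the top-left, `k = 0..n_cols*n_rows-1`.
#'
#' @param box a [face_box()].
#' @param n_cols,n_rows grid shape; the transposed 6x4 grid is available for
#'   sensitivity checks.
#' @return An object of class `roi_grid` with elements `parent`, `n_cols`,
#'   `n_rows` and `cells` (a list of cell boxes `x,y,w,h`, 0-based half-open
#'   like their parent).
#' @export
split_grid <- function(box, n_cols = 4L, n_rows = 6L) {
  stopifnot(inherits(box, "face_box"))
  n_cols <- as.integer(n_cols); n_rows <- as.integer(n_rows)
  if (n_cols < 1L || n_rows < 1L) stop("grid shape must be at least 1x1")
  if (box$w < n_cols || box$h < n_rows)
    stop(sprintf("box %dx%d too small for a %dx%d grid",
                 box$w, box$h, n_cols, n_rows))
  widths  <- (box$w %/% n_cols) + (seq_len(n_cols) <= box$w %% n_cols)
  heights <- (box$h %/% n_rows) + (seq_len(n_rows) <= box$h %% n_rows)
  xs <- box$x + c(0L, cumsum(widths))[seq_len(n_cols)]
  ys <- box$y + c(0L, cumsum(heights))[seq_len(n_rows)]
  cells <- vector("list", n_cols * n_rows)
  for (r in seq_len(n_rows)) {
    for (cc in seq_len(n_cols)) {
      k <- (r - 1L) * n_cols + cc  # 1-based position of 0-based index k-1
      cells[[k]] <- list(x = as.integer(xs[cc]), y = as.integer(ys[r]),
                         w = as.integer(widths[cc]), h = as.integer(heights[r]))
    }
  }
  structure(list(parent = box, n_cols = n_cols, n_rows = n_rows,
                 cells = cells),
            class = "roi_grid")
}

#' @export
print.roi_grid <- function(x, ...) {
  cat(sprintf("roi_grid: %d cols x %d rows over %dx%d box at (%d,%d)\n",
              x$n_cols, x$n_rows, x$parent$w, x$parent$h,
              x$parent$x, x$parent$y))
  invisible(x)
}

# mean intensity of one cell in one frame; cell is 0-based half-open
cell_mean <- function(frame, cell) {
  mean(frame[(cell$y + 1L):(cell$y + cell$h),
             (cell$x + 1L):(cell$x + cell$w), drop = FALSE])
}

#' Extract the mean-intensity signal of one subregion
#'
#' For each frame `t`, the signal value is the arithmetic mean of the raw
#' pixel counts inside the cell, computed in double precision with no
#' quantisation:
#' `S(t) = (1/(w*h)) * sum_{i,j} I(i, j, t)`.
#'
#' @param seq a [thermal_sequence()].
#' @param cell a cell from [split_grid()] (or any list with 0-based `x`,
#'   `y`, `w`, `h`).
#' @param roi_index optional 0-based grid index stored on the trace.
#' @return An object of class `signal_trace` with `values` (one per frame),
#'   `fps` and `roi_index`.
#' @export
extract_signal <- function(seq, cell, roi_index = NA_integer_) {
  stopifnot(inherits(seq, "thermal_sequence"))
  if (cell$x < 0 || cell$y < 0 ||
      cell$x + cell$w > seq$width || cell$y + cell$h > seq$height)
    stop(sprintf("cell (%d,%d,%d,%d) out of bounds for %dx%d frames (frame 1)",
                 cell$x, cell$y, cell$w, cell$h, seq$width, seq$height))
  values <- vapply(seq$frames, cell_mean, numeric(1), cell = cell)
  signal_trace(values, fps = seq$fps, roi_index = roi_index)
}

#' Construct a signal trace
#'
#' @param values per-frame signal values (sensor counts).
#' @param fps sampling rate, frames/second.
#' @param roi_index optional 0-based grid index.
#' @return An object of class `signal_trace`.
#' @export
signal_trace <- function(values, fps, roi_index = NA_integer_) {
  stopifnot(is.numeric(values), length(values) >= 2L, fps > 0)
  structure(list(values = as.numeric(values), fps = fps,
                 roi_index = as.integer(roi_index)),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("signal_trace: %d samples @ %.3g fps%s, mean %.2f counts\n",
              length(x$values), x$fps,
              if (is.na(x$roi_index)) "" else sprintf(" (roi %d)", x$roi_index),
              mean(x$values)))
  invisible(x)
}

#' Extract all grid signals of a sequence
#'
#' Splits the face box into the grid and extracts every cell's mean-intensity
#' trace. With per-frame boxes (from per-frame detection) the grid is
#' re-derived from each frame's own box and the k-th cell is matched by
#' index, not by pixel position, so small box jitter does not break the
#' traces.
#'
#' @param seq a [thermal_sequence()].
#' @param boxes a [face_box()], a list of per-frame boxes, or a detector
#'   provider function (see [static_detector()]).
#' @param n_cols,n_rows grid shape, default 4x6.
#' @return An object of class `roi_signals`: a list with `values` (matrix,
#'   frames x cells, column `k+1` holding roi index `k`), `fps`, `grid` (the
#'   first frame's grid) and `n_cells`.
#' @export
extract_grid_signals <- function(seq, boxes, n_cols = 4L, n_rows = 6L) {
  stopifnot(inherits(seq, "thermal_sequence"))
  res <- resolve_boxes(seq, boxes)
  n <- length(seq$frames)
  n_cells <- as.integer(n_cols) * as.integer(n_rows)
  values <- matrix(NA_real_, n, n_cells)
  if (!is.null(res$static)) {
    validate_box_in_frame(res$static, seq$width, seq$height, "face box")
    grid <- split_grid(res$static, n_cols, n_rows)
    for (t in seq_len(n))
      for (k in seq_len(n_cells))
        values[t, k] <- cell_mean(seq$frames[[t]], grid$cells[[k]])
  } else {
    grid <- NULL
    for (t in seq_len(n)) {
      bt <- res$per_frame[[t]]
      tryCatch(validate_box_in_frame(bt, seq$width, seq$height),
               error = function(e)
                 stop(sprintf("frame %d: %s", t, conditionMessage(e)),
                      call. = FALSE))
      gt <- split_grid(bt, n_cols, n_rows)
      if (is.null(grid)) grid <- gt
      for (k in seq_len(n_cells))
        values[t, k] <- cell_mean(seq$frames[[t]], gt$cells[[k]])
    }
  }
  colnames(values) <- sprintf("roi_%02d", seq_len(n_cells) - 1L)
  structure(list(values = values, fps = seq$fps, grid = grid,
                 n_cells = n_cells),
            class = "roi_signals")
}

#' @export
print.roi_signals <- function(x, ...) {
  cat(sprintf("roi_signals: %d frames x %d cells @ %.3g fps\n",
              nrow(x$values), x$n_cells, x$fps))
  invisible(x)
}

# pull cell k (0-based) out of a roi_signals object as a signal_trace
trace_of <- function(signals, k) {
  signal_trace(signals$values[, k + 1L], fps = signals$fps, roi_index = k)
}

#' Write grid traces to CSV
#'
#' Columns: `t_seconds`, then `roi_00 ... roi_NN`.
#'
#' @param signals a `roi_signals` object from [extract_grid_signals()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(signals, path) {
  stopifnot(inherits(signals, "roi_signals"))
  df <- data.frame(t_seconds = (seq_len(nrow(signals$values)) - 1) / signals$fps)
  df <- cbind(df, as.data.frame(signals$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
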