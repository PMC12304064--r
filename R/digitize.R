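#' Extract the ECG trace from a snapshot as a per-column waveform
#'
#' Classifies pixels by Euclidean RGB distance to the trace color and
#' reduces each column's foreground to its intensity-weighted centroid
#' row. Because the renderer anti-aliases the trace vertically, the
#' centroid recovers the sub-pixel trace position on clean renders. Grid
#' pixels are suppressed first (any pixel closer to the grid color than
#' to the trace color is ignored). Columns with no foreground are masked
#' invalid and never interpolated across - gap handling is an explicit
#' caller choice.
#'
#' With `trace_color_hint = "auto"` the background is estimated as the
#' modal pixel color and the trace color as the mean color of the pixels
#' most distant from it; the trace must then be the dominant
#' high-contrast foreground.
#'
#' @param snapshot a `monitor_snapshot`, an RGB array in `[0, 1]`, or a
#'   PNG path.
#' @param trace_color_hint `"auto"` or an RGB triple in `[0, 1]`. For a
#'   `monitor_snapshot` the style's own colors are used unless a hint is
#'   given explicitly.
#' @param background_color optional RGB triple; estimated when NULL.
#' @param grid_color optional RGB triple of grid lines to suppress.
#' @return an object of class `extracted_trace`: `y_per_column`
#'   (sub-pixel rows, NA where invalid), `valid_mask`, `width`, `height`,
#'   and `foreground_threshold`, the decision rule actually used
#'   (recorded for provenance).
#' @export
extract_trace <- function(snapshot, trace_color_hint = "auto",
                          background_color = NULL, grid_color = NULL) {
  from_style <- inherits(snapshot, "monitor_snapshot")
  if (from_style && identical(trace_color_hint, "auto")) {
    trace_color_hint <- snapshot$style$trace_color
    if (is.null(background_color)) background_color <- snapshot$style$background_color
    if (is.null(grid_color) && isTRUE(snapshot$style$grid$enabled)) {
      grid_color <- snapshot$style$grid$color
    }
  }
  pixels <- snapshot_pixels(snapshot)
  height <- dim(pixels)[1]; width <- dim(pixels)[2]
  if (height == 0L || width == 0L) abort("image is empty")

  r <- pixels[, , 1]; g <- pixels[, , 2]; b <- pixels[, , 3]

  if (is.null(background_color)) {
    # modal color over coarse bins
    key <- paste(round(r, 1), round(g, 1), round(b, 1))
    mode_key <- names(which.max(table(key)))
    sel <- key == mode_key
    background_color <- c(mean(r[sel]), mean(g[sel]), mean(b[sel]))
  }
  d_bg <- sqrt((r - background_color[1])^2 +
               (g - background_color[2])^2 +
               (b - background_color[3])^2)
  if (max(d_bg) < 0.1) {
    abort("no trace found: the image is blank (uniform background, no foreground pixels)")
  }

  if (identical(trace_color_hint, "auto")) {
    cut <- stats::quantile(d_bg, 0.99)
    sel <- d_bg >= max(cut, 0.5 * max(d_bg))
    trace_color <- c(mean(r[sel]), mean(g[sel]), mean(b[sel]))
  } else {
    trace_color <- trace_color_hint
  }
  contrast <- sqrt(sum((trace_color - background_color)^2))
  if (contrast < 0.1) abort("trace and background colors are indistinguishable")

  d_tr <- sqrt((r - trace_color[1])^2 +
               (g - trace_color[2])^2 +
               (b - trace_color[3])^2)
  # coverage estimate: 1 on pure trace, 0 at/beyond background distance
  w <- pmax(1 - d_tr / contrast, 0)  # matrix first: pmax keeps its dims
  if (!is.null(grid_color)) {
    d_gr <- sqrt((r - grid_color[1])^2 +
                 (g - grid_color[2])^2 +
                 (b - grid_color[3])^2)
    w[d_gr < d_tr] <- 0
  }

  col_max <- apply(w, 2, max)
  if (all(col_max < 0.5)) {
    abort("no trace found: foreground pixels exist but none match the trace color hint (color hint mismatch?)")
  }
  w[w < 0.02] <- 0  # drop the noise floor before the centroid
  valid <- col_max >= 0.5
  rows0 <- 0:(height - 1L)  # 0-based row convention
  num <- colSums(w * rows0)
  den <- colSums(w)
  y <- ifelse(valid & den > 0, num / den, NA_real_)

  structure(
    list(
      y_per_column = y,
      valid_mask = valid & den > 0,
      width = width,
      height = height,
      foreground_threshold = list(
        rule = "euclidean RGB distance; coverage = 1 - d/contrast; column valid iff max coverage >= 0.5",
        trace_color = trace_color,
        background_color = background_color,
        grid_color = grid_color,
        contrast = contrast
      )
    ),
    class = "extracted_trace"
  )
}

#' Convert an extracted trace to a calibrated signal
#'
#' Maps pixel coordinates back to physical units using the rendering
#' calibration: time of column x is `x / px_per_second` (left-edge
#' convention) and amplitude is `(baseline_row - y) / px_per_mV` mV.
#' Invalid columns are kept as rows with `valid = FALSE` and NA
#' amplitude, so gaps stay visible.
#'
#' @param trace an [extract_trace()] result.
#' @param style a [snapshot_style()], or any list providing
#'   `px_per_second`, `px_per_mV` and `baseline_row` (e.g. a truth
#'   sidecar from [read_truth_json()]).
#' @return a data frame with columns `column`, `time_s`, `amplitude_mV`,
#'   `valid`.
#' @export
trace_to_signal <- function(trace, style) {
  stopifnot(inherits(trace, "extracted_trace"))
  pps <- style$px_per_second; ppmv <- style$px_per_mV
  base <- style$baseline_row
  check_number(pps, "px_per_second", positive = TRUE)
  check_number(base, "baseline_row")
  if (!is.numeric(ppmv) || length(ppmv) != 1L || ppmv == 0) {
    abort("`px_per_mV` must be a single nonzero number")
  }
  cols <- 0:(trace$width - 1L)
  data.frame(
    column = cols,
    time_s = cols / pps,
    amplitude_mV = (base - trace$y_per_column) / ppmv,
    valid = trace$valid_mask
  )
}
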