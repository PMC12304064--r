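#' Snapshot rendering style
#'
#' Describes how a synthetic ECG is drawn as a raster image. The image
#' origin is top-left: column x maps to time `x / px_per_second` (left
#' edge convention, 0-based), and amplitude maps to row
#' `baseline_row - mV * px_per_mV` (y grows downward).
#'
#' Two presets exist. `mode = "monitor"` (default) is a dark background
#' with a bright green trace at 200 px/s and 100 px/mV, loosely modeled
#' on a bedside monitor display. `mode = "paper"` is a white background
#' with a black trace and a pale red grid whose spacing equals 1 mm of
#' standard 25 mm/s ECG paper, i.e. 40 ms per division.
#'
#' @param mode `"monitor"` or `"paper"`; presets may be overridden by the
#'   other arguments.
#' @param px_per_second horizontal scale, pixels per second (> 0).
#' @param px_per_mV vertical scale, pixels per mV (> 0).
#' @param image_height image height in pixels.
#' @param baseline_row 0-based row of the 0 mV baseline.
#' @param trace_color,background_color RGB triples in `[0, 1]`.
#' @param grid list with `enabled`, `spacing_px`, `color`; when NULL a
#'   mode-appropriate default is used (no grid on monitor; 40 ms grid on
#'   paper).
#' @param line_thickness trace thickness in pixels (>= 1).
#' @param pixel_noise_sd standard deviation of additive per-pixel
#'   luminance noise, on the `[0, 1]` intensity scale (0 = clean).
#' @param max_width_px widest image the renderer will produce.
#' @return an object of class `snapshot_style`.
#' @export
snapshot_style <- function(mode = c("monitor", "paper"),
                           px_per_second = 200,
                           px_per_mV = 100,
                           image_height = 200L,
                           baseline_row = 140,
                           trace_color = NULL,
                           background_color = NULL,
                           grid = NULL,
                           line_thickness = 1,
                           pixel_noise_sd = 0,
                           max_width_px = 20000L) {
  mode <- match.arg(mode)
  if (is.null(trace_color)) {
    trace_color <- if (mode == "monitor") c(0, 1, 0) else c(0, 0, 0)
  }
  if (is.null(background_color)) {
    background_color <- if (mode == "monitor") c(0, 0, 0) else c(1, 1, 1)
  }
  if (is.null(grid)) {
    grid <- if (mode == "paper") {
      # 1 mm on 25 mm/s paper is 40 ms
      list(enabled = TRUE, spacing_px = 0.040 * px_per_second,
           color = c(1, 0.75, 0.75))
    } else {
      list(enabled = FALSE, spacing_px = 0.040 * px_per_second,
           color = c(0.2, 0.2, 0.2))
    }
  }
  check_number(px_per_second, "px_per_second", positive = TRUE)
  check_number(px_per_mV, "px_per_mV", positive = TRUE)
  check_number(line_thickness, "line_thickness", positive = TRUE)
  check_number(pixel_noise_sd, "pixel_noise_sd", nonneg = TRUE)
  if (line_thickness < 1) abort("`line_thickness` must be >= 1")
  if (baseline_row < 0 || baseline_row >= image_height) {
    abort("`baseline_row` must lie within [0, image_height)")
  }
  structure(
    list(
      mode = mode,
      px_per_second = px_per_second, px_per_mV = px_per_mV,
      image_height = as.integer(image_height),
      baseline_row = baseline_row,
      trace_color = trace_color, background_color = background_color,
      grid = grid,
      line_thickness = line_thickness,
      pixel_noise_sd = pixel_noise_sd,
      max_width_px = as.integer(max_width_px)
    ),
    class = "snapshot_style"
  )
}

#' Render a synthetic ECG as a monitor-style snapshot
#'
#' Draws the signal as a connected polyline. Ground-truth fiducial pixel
#' positions are recorded as sub-pixel floats (`time * px_per_second`)
#' *before* rasterization, so marker placement error and pixel
#' quantization can be studied separately.
#'
#' Rasterization: each column gets a vertical band of the trace color
#' covering the curve's extent over that column's time window, padded by
#' half the line thickness, with anti-aliased (partial-coverage) ends -
#' much as a monitor pixel integrates the sweeping beam. Neighboring
#' bands overlap on steep QRS slopes, so the line stays connected, and on
#' flat or straight stretches the intensity-weighted column centroid is
#' exactly the sub-pixel trace position. The grid (when enabled) is drawn
#' beneath the trace; pixel noise is added last.
#'
#' @param ecg a [synthesize_ecg()] result.
#' @param style a [snapshot_style()].
#' @return an object of class `monitor_snapshot`: `pixels` (height x
#'   width x 3 array in `[0, 1]`), `style`, `hr_bpm`, `true_qt_ms`, and
#'   `truth`, a data frame of sub-pixel fiducial columns
#'   (`x_q_onset_px`, `x_t_end_px`) per rendered beat.
#' @export
render_snapshot <- function(ecg, style = snapshot_style()) {
  stopifnot(inherits(ecg, "synthetic_ecg"), inherits(style, "snapshot_style"))
  duration_s <- ecg$time_s[length(ecg$time_s)]
  width <- as.integer(ceiling(duration_s * style$px_per_second))
  if (width > style$max_width_px) {
    abort(sprintf(
      "signal of %.3g s at %g px/s needs %d columns, above the configured maximum width of %d px",
      duration_s, style$px_per_second, width, style$max_width_px
    ))
  }
  height <- style$image_height

  # Per-column trace position (sub-pixel row): column x covers times
  # [x - 0.5, x + 0.5] / px_per_second around its nominal time x / px_per_second.
  # The curve is supersampled across that window so each column draws the
  # full vertical extent the continuous trace sweeps through it - the way a
  # monitor pixel integrates the sweeping beam - keeping steep QRS slopes
  # connected and the column centroid on the curve.
  col_time <- (0:(width - 1L)) / style$px_per_second
  mv <- stats::approx(ecg$time_s, ecg$samples, xout = col_time, rule = 2)$y
  yf <- style$baseline_row - mv * style$px_per_mV
  sub_offsets <- seq(-0.5, 0.5, length.out = 5L) / style$px_per_second
  y_lo <- rep(Inf, width); y_hi <- rep(-Inf, width)
  for (off in sub_offsets) {
    mv_k <- stats::approx(ecg$time_s, ecg$samples, xout = col_time + off,
                          rule = 2)$y
    y_k <- style$baseline_row - mv_k * style$px_per_mV
    y_lo <- pmin(y_lo, y_k); y_hi <- pmax(y_hi, y_k)
  }

  bg <- style$background_color
  pixels <- array(rep(bg, each = height * width), dim = c(height, width, 3L))

  if (isTRUE(style$grid$enabled)) {
    sp <- style$grid$spacing_px
    gcols <- unique(pmin(width - 1L, as.integer(round(seq(0, width - 1, by = sp)))))
    grows <- unique(pmin(height - 1L, as.integer(round(seq(0, height - 1, by = sp)))))
    for (ch in 1:3) {
      pixels[, gcols + 1L, ch] <- style$grid$color[ch]
      pixels[grows + 1L, , ch] <- style$grid$color[ch]
    }
  }

  th <- style$line_thickness
  tc <- style$trace_color
  # Vertical band per column: the curve's extent over the column window,
  # padded by half the line thickness, anti-aliased at both ends. On flat
  # or straight stretches the intensity-weighted centroid of the band is
  # exactly the sub-pixel trace position.
  for (x in seq_len(width)) {
    band_lo <- y_lo[x] - th / 2
    band_hi <- y_hi[x] + th / 2
    rows <- floor(band_lo - 0.5):ceiling(band_hi + 0.5)
    # pixel row r covers [r - 0.5, r + 0.5]; coverage = overlap with the band
    cov <- pmin(rows + 0.5, band_hi) - pmax(rows - 0.5, band_lo)
    keep <- cov > 0 & rows >= 0 & rows <= height - 1L
    rows <- rows[keep]; cov <- pmin(1, cov[keep])
    if (length(rows)) {
      for (ch in 1:3) {
        idx <- cbind(rows + 1L, x, ch)
        pixels[idx] <- pixels[idx] * (1 - cov) + tc[ch] * cov
      }
    }
  }

  if (style$pixel_noise_sd > 0) {
    noise <- matrix(stats::rnorm(height * width, sd = style$pixel_noise_sd),
                    nrow = height)
    for (ch in 1:3) pixels[, , ch] <- pixels[, , ch] + noise
    pixels[pixels < 0] <- 0
    pixels[pixels > 1] <- 1
  }

  truth <- data.frame(
    x_q_onset_px = ecg$fiducials$q_onset_s * style$px_per_second,
    x_t_end_px = ecg$fiducials$t_end_s * style$px_per_second
  )
  structure(
    list(
      pixels = pixels,
      style = style,
      truth = truth,
      hr_bpm = ecg$hr_bpm,
      true_qt_ms = ecg$true_qt_ms,
      width = width,
      height = height
    ),
    class = "monitor_snapshot"
  )
}

#' Write a snapshot image as PNG
#'
#' @param snapshot a `monitor_snapshot`.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
write_snapshot_png <- function(snapshot, path) {
  stopifnot(inherits(snapshot, "monitor_snapshot"))
  png::writePNG(snapshot$pixels, target = path)
  invisible(path)
}

#' Write the ground-truth sidecar for a snapshot
#'
#' JSON with the displayed heart rate, the true QT, the rendering
#' calibration, and the sub-pixel fiducial columns of every rendered
#' beat. Full float precision is kept so a write/read round trip is
#' lossless.
#'
#' @param snapshot a `monitor_snapshot`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_truth_json <- function(snapshot, path) {
  stopifnot(inherits(snapshot, "monitor_snapshot"))
  obj <- list(
    hr_bpm = snapshot$hr_bpm,
    true_qt_ms = snapshot$true_qt_ms,
    px_per_second = snapshot$style$px_per_second,
    px_per_mV = snapshot$style$px_per_mV,
    baseline_row = snapshot$style$baseline_row,
    image_height = snapshot$style$image_height,
    mode = snapshot$style$mode,
    trace_color = snapshot$style$trace_color,
    background_color = snapshot$style$background_color,
    fiducials = snapshot$truth
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a ground-truth sidecar
#'
#' @param path JSON path written by [write_truth_json()].
#' @return a list mirroring the sidecar fields; `fiducials` is a data
#'   frame.
#' @export
read_truth_json <- function(path) {
  if (!file.exists(path)) abort(sprintf("truth sidecar not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$fiducials <- as.data.frame(obj$fiducials)
  obj
}
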