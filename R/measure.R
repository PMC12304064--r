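#' RR interval from displayed heart rate
#'
#' The RR interval (time between successive beats) follows from the heart
#' rate shown on the monitor as RR = 60000 / HR milliseconds. No rounding
#' is applied.
#'
#' @param hr_bpm heart rate in beats per minute; must be > 0. Monitors
#'   display integers but any positive value is accepted.
#' @return RR interval in milliseconds.
#' @export
#' @examples
#' rr_from_hr(60)   # 1000 ms
#' rr_from_hr(75)   # 800 ms
rr_from_hr <- function(hr_bpm) {
  check_number(hr_bpm, "hr_bpm", positive = TRUE)
  60000 / hr_bpm
}

#' Bazett heart-rate correction
#'
#' Corrects a QT interval to a heart rate of 60 beats/min:
#' QTc = QT / sqrt(RR / 1000), with RR in milliseconds. At RR = 1000 ms
#' (HR 60) the correction is the identity.
#'
#' @param qt_ms QT interval in ms (>= 0).
#' @param rr_ms RR interval in ms (> 0).
#' @return QTc in milliseconds.
#' @export
#' @examples
#' bazett_qtc(400, 1000)  # 400
#' bazett_qtc(300, 250)   # 600
bazett_qtc <- function(qt_ms, rr_ms) {
  check_number(qt_ms, "qt_ms", nonneg = TRUE)
  check_number(rr_ms, "rr_ms", positive = TRUE)
  qt_ms / sqrt(rr_ms / 1000)
}

#' Construct a marker triplet
#'
#' The three slider positions placed on a snapshot: the onsets of two
#' neighboring Q waves and the end of the T wave in between. Coordinates
#' are sub-pixel column positions (0-based, x increasing with time).
#'
#' @param x_q1_px column of the first Q-wave onset.
#' @param x_q2_px column of the next beat's Q-wave onset; must exceed
#'   `x_q1_px` (the Q-Q span calibrates one RR interval).
#' @param x_t_px column of the T-wave end; must exceed `x_q1_px`. A T end
#'   beyond `x_q2_px` is allowed (flagged downstream), since a long QT at
#'   a high heart rate can push the T end past the next Q onset.
#' @return an object of class `marker_triplet`.
#' @export
marker_triplet <- function(x_q1_px, x_q2_px, x_t_px) {
  check_number(x_q1_px, "x_q1_px")
  check_number(x_q2_px, "x_q2_px")
  check_number(x_t_px, "x_t_px")
  if (x_q2_px <= x_q1_px) {
    abort(sprintf(
      "calibration error: x_q2_px (%g) must be > x_q1_px (%g); the two Q markers must span a positive RR interval",
      x_q2_px, x_q1_px
    ))
  }
  if (x_t_px <= x_q1_px) {
    abort(sprintf(
      "marker-order error: x_t_px (%g) must be > x_q1_px (%g); the T-end marker lies after the first Q onset",
      x_t_px, x_q1_px
    ))
  }
  structure(
    list(x_q1_px = x_q1_px, x_q2_px = x_q2_px, x_t_px = x_t_px),
    class = "marker_triplet"
  )
}

#' Measure QT and QTc from a marker triplet and heart rate
#'
#' The measurement core. The two Q-onset markers span exactly one RR
#' interval, and the displayed heart rate gives that interval in
#' milliseconds (RR = 60000/HR), which fixes the pixel-to-time scale
#' `px_per_ms = (x_q2 - x_q1) / RR`. The QT interval is then the Q1-to-T
#' pixel span divided by that scale; equivalently
#' `QT = RR * (x_t - x_q1) / (x_q2 - x_q1)` - the image resolution cancels.
#' QTc applies Bazett's correction.
#'
#' A single cardiac cycle is measured; no multi-beat averaging is
#' performed.
#'
#' @param markers a [marker_triplet()] (a plain list with the same fields
#'   is accepted).
#' @param hr_bpm displayed heart rate in beats/min (> 0).
#' @return an object of class `qt_measurement`: a list with `qt_ms`,
#'   `qtc_ms`, `rr_ms`, `hr_bpm`, `px_per_ms` and a character vector
#'   `warnings` (contains `"t_end_beyond_next_q"` when the T marker lies
#'   past the second Q marker).
#' @export
#' @examples
#' m <- measure_qt(marker_triplet(100, 600, 300), hr_bpm = 60)
#' m$qt_ms   # 400
#' m$qtc_ms  # 400 (identity correction at HR 60)
measure_qt <- function(markers, hr_bpm) {
  if (!inherits(markers, "marker_triplet")) {
    markers <- marker_triplet(markers$x_q1_px, markers$x_q2_px, markers$x_t_px)
  }
  rr_ms <- rr_from_hr(hr_bpm)
  px_per_ms <- (markers$x_q2_px - markers$x_q1_px) / rr_ms
  qt_ms <- (markers$x_t_px - markers$x_q1_px) / px_per_ms
  warnings <- character(0)
  if (markers$x_t_px > markers$x_q2_px) {
    warnings <- c(warnings, "t_end_beyond_next_q")
  }
  structure(
    list(
      qt_ms = qt_ms,
      qtc_ms = bazett_qtc(qt_ms, rr_ms),
      rr_ms = rr_ms,
      hr_bpm = hr_bpm,
      px_per_ms = px_per_ms,
      markers = markers,
      warnings = warnings
    ),
    class = "qt_measurement"
  )
}

#' Measure QT and QTc from a snapshot image
#'
#' Identical arithmetic to [measure_qt()]: the image does not enter the
#' computation (calibration comes entirely from the markers and the heart
#' rate). The image is validated - all markers must fall inside its width
#' - and attached as provenance.
#'
#' @param snapshot a `monitor_snapshot`, an RGB array, or a path to a PNG.
#' @param markers a [marker_triplet()].
#' @param hr_bpm displayed heart rate in beats/min.
#' @return a `qt_measurement` with `provenance` recording the image width.
#' @export
measure_from_snapshot <- function(snapshot, markers, hr_bpm) {
  pixels <- snapshot_pixels(snapshot)
  width <- dim(pixels)[2]
  if (!inherits(markers, "marker_triplet")) {
    markers <- marker_triplet(markers$x_q1_px, markers$x_q2_px, markers$x_t_px)
  }
  for (nm in c("x_q1_px", "x_q2_px", "x_t_px")) {
    x <- markers[[nm]]
    if (x < 0 || x >= width) {
      abort(sprintf(
        "marker out of bounds: %s = %g lies outside the image (width %d, valid range [0, %d))",
        nm, x, width, width
      ))
    }
  }
  m <- measure_qt(markers, hr_bpm)
  m$provenance <- list(source = "snapshot", image_width = width,
                       image_height = dim(pixels)[1])
  m
}

# accept a monitor_snapshot, an RGB array, or a PNG path
snapshot_pixels <- function(snapshot) {
  if (inherits(snapshot, "monitor_snapshot")) return(snapshot$pixels)
  if (is.character(snapshot) && length(snapshot) == 1L) {
    if (!file.exists(snapshot)) abort(sprintf("image file not found: %s", snapshot))
    img <- png::readPNG(snapshot)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
    return(img[, , 1:3, drop = FALSE])
  }
  if (is.array(snapshot) && length(dim(snapshot)) == 3L) return(snapshot)
  abort("`snapshot` must be a monitor_snapshot, an RGB array, or a PNG path")
}

#' @export
print.qt_measurement <- function(x, ...) {
  cat("QT measurement (single cycle)\n")
  cat(sprintf("  QT  : %d ms\n", as.integer(round_half_away(x$qt_ms))))
  cat(sprintf("  QTc : %d ms (Bazett)\n", as.integer(round_half_away(x$qtc_ms))))
  cat(sprintf("  RR  : %d ms   HR: %g bpm\n",
              as.integer(round_half_away(x$rr_ms)), x$hr_bpm))
  cat(sprintf("  scale: %.4f px/ms\n", x$px_per_ms))
  if (length(x$warnings)) {
    cat("  warnings:", paste(x$warnings, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a measurement to a JSON-ready list
#'
#' Times are reported at 0.1 ms resolution; the calibration scale keeps
#' full precision.
#'
#' @param m a `qt_measurement`.
#' @return a named list suitable for `jsonlite::toJSON(auto_unbox = TRUE)`.
#' @export
measurement_record <- function(m) {
  stopifnot(inherits(m, "qt_measurement"))
  list(
    qt_ms = round_half_away(m$qt_ms, 1),
    qtc_ms = round_half_away(m$qtc_ms, 1),
    rr_ms = round_half_away(m$rr_ms, 1),
    hr_bpm = m$hr_bpm,
    px_per_ms = m$px_per_ms,
    warnings = m$warnings
  )
}
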