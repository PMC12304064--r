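#' Synthesize a constant-rate single-lead ECG with known fiducials
#'
#' Repeats a beat template at a constant heart rate and records the exact
#' Q-onset and T-end time of every beat. Consecutive Q onsets are spaced
#' exactly `60 / hr_bpm` seconds; for every beat,
#' `t_end - q_onset == true_qt_ms / 1000` seconds to machine precision
#' (the T-end fiducial is stored as Q onset plus the template QT, not
#' re-derived from segment sums). The baseline between beats is flat zero mV.
#'
#' @param template a [build_beat_template()] result.
#' @param hr_bpm heart rate in beats/min (> 0).
#' @param n_beats number of beats (>= 2: two Q onsets are needed for
#'   pixel-to-time calibration downstream).
#' @param sample_rate sampling rate in Hz.
#' @return an object of class `synthetic_ecg`: `samples` (mV), `time_s`,
#'   `sample_rate`, `hr_bpm`, `true_qt_ms`, and `fiducials`, a data frame
#'   with one row per beat (`q_onset_s`, `t_end_s`).
#' @export
#' @examples
#' ecg <- synthesize_ecg(build_beat_template(400), hr_bpm = 60, n_beats = 3)
#' diff(ecg$fiducials$q_onset_s)  # 1 1
synthesize_ecg <- function(template, hr_bpm, n_beats = 3L,
                           sample_rate = 500) {
  stopifnot(inherits(template, "beat_template"))
  check_number(hr_bpm, "hr_bpm", positive = TRUE)
  check_number(sample_rate, "sample_rate", positive = TRUE)
  if (!is.numeric(n_beats) || n_beats < 2) {
    abort("`n_beats` must be >= 2: two Q onsets are required for calibration")
  }
  n_beats <- as.integer(n_beats)
  rr_ms <- rr_from_hr(hr_bpm)
  if (template$t_end_ms >= rr_ms) {
    abort(sprintf(
      "beat template (%g ms to T end) does not fit within the RR interval (%g ms) at %g beats/min",
      template$t_end_ms, rr_ms, hr_bpm
    ))
  }
  rr_s <- rr_ms / 1000
  duration_s <- n_beats * rr_s
  n_samples <- floor(duration_s * sample_rate) + 1L
  time_s <- (seq_len(n_samples) - 1L) / sample_rate
  # beat-local time; every beat is an identical copy of the template
  tau_ms <- (time_s - floor(time_s / rr_s) * rr_s) * 1000
  samples <- beat_waveform(template, tau_ms)

  k <- 0:(n_beats - 1L)
  q_onset_s <- k * rr_s + template$q_onset_ms / 1000
  fiducials <- data.frame(
    q_onset_s = q_onset_s,
    t_end_s = q_onset_s + template$qt_ms / 1000
  )
  structure(
    list(
      sample_rate = sample_rate,
      time_s = time_s,
      samples = samples,
      hr_bpm = hr_bpm,
      rr_ms = rr_ms,
      true_qt_ms = template$qt_ms,
      fiducials = fiducials,
      template = template
    ),
    class = "synthetic_ecg"
  )
}
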