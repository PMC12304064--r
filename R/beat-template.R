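#' Build a single-beat morphology template with an exact QT interval
#'
#' The beat is piecewise-analytic so that the Q-wave onset and T-wave end
#' are crisp segment boundaries rather than tails of smooth bumps: the P
#' and T waves are raised-cosine lobes, the Q/R/S deflections are
#' triangles, and the PQ and ST segments are flat baseline. The QT
#' interval is enforced exactly by construction: the ST segment absorbs
#' whatever duration is left after the QRS complex and the T wave, so
#' `t_end_ms - q_onset_ms == qt_ms` to the last bit.
#'
#' Default durations and amplitudes are ordinary adult lead-II values.
#' The P + PQ lead-in is 120 ms (PR interval at the lower normal bound),
#' chosen so that templates with physiologic QT still fit within one RR
#' interval at heart rates up to ~140 beats/min.
#'
#' @param qt_ms target QT interval in ms. Must be at least the combined
#'   duration of the QRS deflections and the T wave (270 ms under
#'   defaults); shorter values are rejected with the minimum named.
#' @param p_duration,p_height P-wave duration (ms) and height (mV).
#' @param pq_segment flat PQ segment duration (ms).
#' @param q_dip,r_wave,s_dip lists with `duration` (ms) and `depth` or
#'   `height` (mV) for the Q, R and S deflections.
#' @param t_wave list with `duration` (ms) and `height` (mV).
#' @return an object of class `beat_template` with fields including
#'   `q_onset_ms`, `t_end_ms`, `st_segment` and `qt_ms`.
#' @export
#' @examples
#' tpl <- build_beat_template(400)
#' tpl$t_end_ms - tpl$q_onset_ms  # exactly 400
build_beat_template <- function(qt_ms,
                                p_duration = 80, p_height = 0.15,
                                pq_segment = 40,
                                q_dip = list(duration = 20, depth = 0.10),
                                r_wave = list(duration = 40, height = 1.00),
                                s_dip = list(duration = 30, depth = 0.20),
                                t_wave = list(duration = 180, height = 0.30)) {
  check_number(qt_ms, "qt_ms", positive = TRUE)
  for (nm in c("p_duration", "pq_segment")) {
    check_number(get(nm), nm, positive = TRUE)
  }
  segs <- list(q_dip = q_dip, r_wave = r_wave, s_dip = s_dip, t_wave = t_wave)
  for (nm in names(segs)) {
    check_number(segs[[nm]]$duration, paste0(nm, "$duration"), positive = TRUE)
  }
  qrs_t <- q_dip$duration + r_wave$duration + s_dip$duration + t_wave$duration
  if (qt_ms < qrs_t) {
    abort(sprintf(
      "qt_ms = %g is too short: the QRS complex plus T wave alone last %g ms, the minimum QT this morphology supports",
      qt_ms, qrs_t
    ))
  }
  st_segment <- qt_ms - qrs_t
  q_onset_ms <- p_duration + pq_segment
  structure(
    list(
      p_duration = p_duration, p_height = p_height,
      pq_segment = pq_segment,
      q_dip = q_dip, r_wave = r_wave, s_dip = s_dip,
      st_segment = st_segment, t_wave = t_wave,
      q_onset_ms = q_onset_ms,
      t_end_ms = q_onset_ms + qt_ms,
      qt_ms = qt_ms
    ),
    class = "beat_template"
  )
}

# raised-cosine lobe on u in [0, 1], peak at u = 0.5, zero at both ends
raised_cosine <- function(u, height) height * 0.5 * (1 - cos(2 * pi * u))

# triangular deflection on u in [0, 1], apex at u = 0.5
triangle <- function(u, peak) peak * (1 - abs(2 * u - 1))

#' Evaluate the template waveform
#'
#' Amplitude in mV at times `t_ms` measured from the beat start (P-wave
#' onset). Zero (flat baseline) outside wave segments and beyond the
#' T-wave end.
#'
#' @param template a `beat_template`.
#' @param t_ms numeric vector of times in ms from beat start.
#' @return amplitudes in mV, same length as `t_ms`.
#' @export
beat_waveform <- function(template, t_ms) {
  tp <- template
  b0 <- 0
  b1 <- b0 + tp$p_duration                 # P wave
  b2 <- b1 + tp$pq_segment                 # PQ segment (flat)
  b3 <- b2 + tp$q_dip$duration             # Q
  b4 <- b3 + tp$r_wave$duration            # R
  b5 <- b4 + tp$s_dip$duration             # S
  b6 <- b5 + tp$st_segment                 # ST segment (flat)
  b7 <- b6 + tp$t_wave$duration            # T wave; b7 == t_end_ms

  y <- numeric(length(t_ms))
  piece <- function(lo, hi) t_ms >= lo & t_ms < hi
  i <- piece(b0, b1)
  y[i] <- raised_cosine((t_ms[i] - b0) / tp$p_duration, tp$p_height)
  i <- piece(b2, b3)
  y[i] <- triangle((t_ms[i] - b2) / tp$q_dip$duration, -tp$q_dip$depth)
  i <- piece(b3, b4)
  y[i] <- triangle((t_ms[i] - b3) / tp$r_wave$duration, tp$r_wave$height)
  i <- piece(b4, b5)
  y[i] <- triangle((t_ms[i] - b4) / tp$s_dip$duration, -tp$s_dip$depth)
  i <- piece(b6, b7)
  y[i] <- raised_cosine((t_ms[i] - b6) / tp$t_wave$duration, tp$t_wave$height)
  y
}
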