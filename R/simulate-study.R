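#' Observer model for manual slider placement
#'
#' Simulates a human placing the three sliders on a snapshot. Independent
#' Gaussian noise (SD in pixels) is added to every marker. The systematic
#' `placement_bias` is applied to the T-end marker only: a bias common to
#' all three markers would cancel exactly by the translation invariance
#' of the ratio calibration, so only the T-end bias can produce a
#' systematic QT offset - a positive value means the T end is habitually
#' marked late, a negative value early.
#'
#' @param placement_noise_sd per-marker placement noise SD in pixels
#'   (>= 0).
#' @param placement_bias systematic T-end marker offset in pixels.
#' @return an object of class `observer_model`.
#' @export
observer_model <- function(placement_noise_sd = 0, placement_bias = 0) {
  check_number(placement_noise_sd, "placement_noise_sd", nonneg = TRUE)
  check_number(placement_bias, "placement_bias")
  structure(
    list(placement_noise_sd = placement_noise_sd,
         placement_bias = placement_bias),
    class = "observer_model"
  )
}

#' Simulate a paired QT/QTc method-comparison study
#'
#' Emulates a bedside validation study: for each simulated subject an ECG
#' with a known QT and a constant integer heart rate is synthesized and
#' rendered as a snapshot; the observer model perturbs the true fiducial
#' pixel positions to produce the three slider placements; the test QT
#' and QTc come from [measure_qt()] on those markers. The reference QT is
#' the generator's true QT and the reference QTc is its exact Bazett
#' correction, standing in for careful manual measurement from a 12-lead
#' printout.
#'
#' Heart rate is drawn as an integer (monitors display integers),
#' truncated to 40-140 beats/min by redrawing; QT is drawn from a normal
#' distribution truncated by redrawing to at least 280 ms and to fit the
#' beat template within the RR interval with a 5 ms margin. The default
#' observer (noise 3.3 px, T-end bias -2.8 px at the default 0.2 px/ms
#' scale) yields a QT difference distribution of roughly 14 +/- 20 ms,
#' typical of marker-based snapshot measurement against a manual
#' reference.
#'
#' All randomness flows from `seed`; a fixed seed reproduces the paired
#' series exactly.
#'
#' @param n_subjects number of subjects (>= 2); one measurement pair per
#'   subject.
#' @param qt_mean_ms,qt_sd_ms QT distribution across subjects (ms).
#' @param hr_mean_bpm,hr_sd_bpm heart-rate distribution (beats/min).
#' @param style a [snapshot_style()].
#' @param observer an [observer_model()].
#' @param seed integer RNG seed.
#' @param n_beats beats rendered per snapshot.
#' @param sample_rate waveform sampling rate (Hz).
#' @return a data frame with columns `id`, `test_qt_ms`, `ref_qt_ms`,
#'   `test_qtc_ms`, `ref_qtc_ms` (one row per subject) and attributes
#'   `hr_bpm`, `px_per_ms` (per subject) and `config`.
#' @export
simulate_study <- function(n_subjects,
                           qt_mean_ms = 385, qt_sd_ms = 45,
                           hr_mean_bpm = 70, hr_sd_bpm = 12,
                           style = snapshot_style(),
                           observer = observer_model(placement_noise_sd = 3.3,
                                                     placement_bias = -2.8),
                           seed = 1L,
                           n_beats = 3L,
                           sample_rate = 500) {
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    abort("`n_subjects` must be >= 2")
  }
  check_number(qt_sd_ms, "qt_sd_ms", nonneg = TRUE)
  check_number(hr_sd_bpm, "hr_sd_bpm", nonneg = TRUE)
  stopifnot(inherits(style, "snapshot_style"), inherits(observer, "observer_model"))
  n_subjects <- as.integer(n_subjects)
  set.seed(as.integer(seed))

  lead_in_ms <- 120  # default P + PQ duration of build_beat_template
  draw_subject <- function() {
    for (try in 1:1000) {
      hr <- round(stats::rnorm(1, hr_mean_bpm, hr_sd_bpm))
      if (hr < 40 || hr > 140) next
      rr <- 60000 / hr
      qt_max <- rr - lead_in_ms - 5
      if (qt_max < 280) next
      qt <- stats::rnorm(1, qt_mean_ms, qt_sd_ms)
      if (qt < 280 || qt > qt_max) next
      return(list(hr = hr, qt = qt, rr = rr))
    }
    abort("could not draw a physiologic (QT, HR) pair; check the distribution parameters")
  }

  out <- data.frame(
    id = seq_len(n_subjects),
    test_qt_ms = numeric(n_subjects), ref_qt_ms = numeric(n_subjects),
    test_qtc_ms = numeric(n_subjects), ref_qtc_ms = numeric(n_subjects)
  )
  hr_used <- integer(n_subjects)
  ppm_used <- numeric(n_subjects)

  for (i in seq_len(n_subjects)) {
    s <- draw_subject()
    tpl <- build_beat_template(s$qt)
    ecg <- synthesize_ecg(tpl, s$hr, n_beats = n_beats, sample_rate = sample_rate)
    snap <- render_snapshot(ecg, style)
    truth <- snap$truth

    repeat {
      e <- stats::rnorm(3, sd = observer$placement_noise_sd)
      xq1 <- truth$x_q_onset_px[1] + e[1]
      xq2 <- truth$x_q_onset_px[2] + e[2]
      xt <- truth$x_t_end_px[1] + observer$placement_bias + e[3]
      if (xq2 > xq1 && xt > xq1) break  # re-place degenerate sliders
    }
    m <- measure_qt(marker_triplet(xq1, xq2, xt), s$hr)

    out$test_qt_ms[i] <- m$qt_ms
    out$test_qtc_ms[i] <- m$qtc_ms
    out$ref_qt_ms[i] <- s$qt
    out$ref_qtc_ms[i] <- bazett_qtc(s$qt, s$rr)
    hr_used[i] <- s$hr
    ppm_used[i] <- m$px_per_ms
  }

  attr(out, "hr_bpm") <- hr_used
  attr(out, "px_per_ms") <- ppm_used
  attr(out, "config") <- list(
    n_subjects = n_subjects,
    qt_mean_ms = qt_mean_ms, qt_sd_ms = qt_sd_ms,
    hr_mean_bpm = hr_mean_bpm, hr_sd_bpm = hr_sd_bpm,
    placement_noise_sd = observer$placement_noise_sd,
    placement_bias = observer$placement_bias,
    px_per_second = style$px_per_second,
    n_beats = n_beats, sample_rate = sample_rate,
    seed = as.integer(seed)
  )
  out
}
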