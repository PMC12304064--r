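test_that("beat template encodes the requested QT exactly and deterministically", {
  for (qt in c(300, 400, 487.25)) {
    tpl <- build_beat_template(qt)
    expect_identical(tpl$t_end_ms - tpl$q_onset_ms, qt)
    expect_gt(tpl$st_segment, -1e-12)
  }
  expect_identical(build_beat_template(400), build_beat_template(400))
  # QRS + T alone exceed a 10 ms QT under defaults; the error names the minimum
  expect_error(build_beat_template(10), "270")
  expect_error(build_beat_template(-5), "> 0")
})

test_that("waveform is flat baseline outside the wave segments", {
  tpl <- build_beat_template(400)
  # PQ segment, ST segment, and beyond the T end are all 0 mV
  expect_equal(beat_waveform(tpl, tpl$p_duration + tpl$pq_segment / 2), 0)
  st_mid <- tpl$q_onset_ms + tpl$q_dip$duration + tpl$r_wave$duration +
    tpl$s_dip$duration + tpl$st_segment / 2
  expect_equal(beat_waveform(tpl, st_mid), 0)
  expect_equal(beat_waveform(tpl, tpl$t_end_ms + c(0, 10, 50)), c(0, 0, 0))
  # R apex reaches the configured height
  r_apex <- tpl$q_onset_ms + tpl$q_dip$duration + tpl$r_wave$duration / 2
  expect_equal(beat_waveform(tpl, r_apex), tpl$r_wave$height)
})

test_that("synthesized beats are spaced at exactly 60/HR with QT conserved per beat", {
  ecg <- synthesize_ecg(build_beat_template(400), hr_bpm = 60, n_beats = 5)
  expect_equal(nrow(ecg$fiducials), 5)
  expect_equal(diff(ecg$fiducials$q_onset_s), rep(1, 4))
  expect_equal(ecg$fiducials$q_onset_s[5] - ecg$fiducials$q_onset_s[1], 4)
  ecg2 <- synthesize_ecg(build_beat_template(300), hr_bpm = 120, n_beats = 2)
  expect_equal(diff(ecg2$fiducials$q_onset_s), 0.5)
  # fiducial conservation to machine precision
  for (hr in c(47, 60, 93, 125)) {
    e <- synthesize_ecg(build_beat_template(340), hr, n_beats = 4)
    expect_equal(e$fiducials$t_end_s - e$fiducials$q_onset_s,
                 rep(0.340, 4), tolerance = 1e-13)
  }
})

test_that("synthesis rejects impossible inputs", {
  tpl <- build_beat_template(500)  # 620 ms to T end
  expect_error(synthesize_ecg(tpl, hr_bpm = 120), "does not fit")
  expect_error(synthesize_ecg(tpl, hr_bpm = 60, n_beats = 1), "n_beats")
  expect_error(synthesize_ecg(tpl, hr_bpm = 0), "> 0")
})

test_that("rendered truth fiducials are time times px_per_second, before rasterization", {
  ecg <- synthesize_ecg(build_beat_template(400), 60, n_beats = 3)
  snap <- render_snapshot(ecg, snapshot_style(px_per_second = 200))
  expect_equal(snap$truth$x_q_onset_px, ecg$fiducials$q_onset_s * 200)
  expect_equal(snap$truth$x_t_end_px, ecg$fiducials$t_end_s * 200)
  expect_true(all(diff(unlist(t(snap$truth))) > 0))
  expect_gte(snap$width, ceiling(max(ecg$time_s) * 200))
  # rendering linearity: doubling the sweep speed doubles every truth x
  snap2 <- render_snapshot(ecg, snapshot_style(px_per_second = 400))
  expect_equal(snap2$truth$x_q_onset_px, 2 * snap$truth$x_q_onset_px)
  expect_equal(snap2$truth$x_t_end_px, 2 * snap$truth$x_t_end_px)
})

test_that("a zero-amplitude signal renders on the baseline row only", {
  ecg <- synthesize_ecg(build_beat_template(400), 72, n_beats = 2)
  ecg$samples[] <- 0
  style <- snapshot_style(image_height = 80L, baseline_row = 40)
  snap <- render_snapshot(ecg, style)
  on_rows <- which(apply(snap$pixels[, , 2], 1, max) > 0.05) - 1L
  expect_true(all(abs(on_rows - 40) <= style$line_thickness))
})

test_that("rendering rejects images wider than the configured maximum", {
  ecg <- synthesize_ecg(build_beat_template(400), 60, n_beats = 3)
  expect_error(
    render_snapshot(ecg, snapshot_style(max_width_px = 100L)),
    "maximum width"
  )
})

test_that("identical seeds reproduce snapshots and paired series bit-identically", {
  style <- snapshot_style(pixel_noise_sd = 0.03)
  ecg <- synthesize_ecg(build_beat_template(380), 75, n_beats = 2)
  set.seed(99); a <- render_snapshot(ecg, style)
  set.seed(99); b <- render_snapshot(ecg, style)
  expect_identical(a$pixels, b$pixels)
  s1 <- simulate_study(8, seed = 5)
  s2 <- simulate_study(8, seed = 5)
  expect_identical(s1, s2)
  expect_equal(nrow(simulate_study(12, seed = 1)), 12)
})

test_that("an exact observer reproduces the true QT for every subject", {
  s <- simulate_study(10, seed = 21,
                      observer = observer_model(placement_noise_sd = 0,
                                                placement_bias = 0))
  expect_equal(s$test_qt_ms, s$ref_qt_ms, tolerance = 1e-10)
  expect_equal(s$test_qtc_ms, s$ref_qtc_ms, tolerance = 1e-10)
})

test_that("a pure T-marker bias shifts every difference by -bias/px_per_ms", {
  b <- 4.5
  s <- simulate_study(15, seed = 8,
                      observer = observer_model(placement_noise_sd = 0,
                                                placement_bias = b))
  d <- s$ref_qt_ms - s$test_qt_ms
  expect_equal(d, -b / attr(s, "px_per_ms"), tolerance = 1e-9)
})

test_that("degenerate study distributions are rejected", {
  expect_error(simulate_study(1), ">= 2")
  expect_error(simulate_study(10, qt_sd_ms = -1), ">= 0")
  expect_error(simulate_study(10, hr_mean_bpm = 500, hr_sd_bpm = 0),
               "physiologic")
})
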