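# shared fixtures and independent oracles

# canonical rendered snapshot with known QT/HR
make_snapshot <- function(qt_ms = 400, hr_bpm = 72, n_beats = 3,
                          style = snapshot_style()) {
  ecg <- synthesize_ecg(build_beat_template(qt_ms), hr_bpm, n_beats = n_beats)
  list(ecg = ecg, snap = render_snapshot(ecg, style))
}

# truth fiducials of beat k (1-based) as a marker triplet: Q onsets of
# beats k and k+1, T end of beat k
truth_markers <- function(snap, beat = 1) {
  tr <- snap$truth
  marker_triplet(tr$x_q_onset_px[beat], tr$x_q_onset_px[beat + 1],
                 tr$x_t_end_px[beat])
}

# draw a (hr, qt) pair satisfying the template-fits-in-RR constraint
draw_valid_hr_qt <- function() {
  repeat {
    hr <- round(stats::runif(1, 40, 140))
    qt_max <- min(500, 60000 / hr - 125)
    if (qt_max >= 300) break
  }
  c(hr = hr, qt = stats::runif(1, 300, qt_max))
}

# brute-force statistics via explicit sums, independent of the package path
brute_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}
brute_sd <- function(x) {
  m <- brute_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  sqrt(s / (length(x) - 1))
}
brute_pearson <- function(x, y) {
  mx <- brute_mean(x); my <- brute_mean(y)
  sxy <- sxx <- syy <- 0
  for (i in seq_along(x)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}
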