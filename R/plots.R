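#' Bland-Altman plot with confidence bands
#'
#' Differences (reference minus test) against pair means, with the bias
#' as a bold line, the 95% limits of agreement as dashed lines, and the
#' 95% confidence interval of each as a shaded band.
#'
#' @param pairs a [paired_series()].
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(pairs) {
  stopifnot(inherits(pairs, "paired_series"))
  ba <- bland_altman(pairs)
  df <- data.frame(
    mean_ms = (pairs$test_ms + pairs$ref_ms) / 2,
    diff_ms = differences(pairs)
  )
  bands <- data.frame(
    lo = c(ba$ci_bias[1], ba$ci_loa_low[1], ba$ci_loa_high[1]),
    hi = c(ba$ci_bias[2], ba$ci_loa_low[2], ba$ci_loa_high[2])
  )
  lab <- toupper(pairs$metric_name)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_ms, y = .data$diff_ms)) +
    ggplot2::geom_rect(
      data = bands, inherit.aes = FALSE,
      ggplot2::aes(xmin = -Inf, xmax = Inf, ymin = .data$lo, ymax = .data$hi),
      fill = "grey70", alpha = 0.4
    ) +
    ggplot2::geom_hline(yintercept = ba$bias_ms, linewidth = 1) +
    ggplot2::geom_hline(yintercept = c(ba$loa_low_ms, ba$loa_high_ms),
                        linetype = "dashed") +
    ggplot2::geom_point(shape = 1) +
    ggplot2::labs(
      x = sprintf("Mean of test and reference %s (ms)", lab),
      y = sprintf("Reference minus test %s (ms)", lab),
      title = sprintf("Bland-Altman: %s, bias %d ms, 95%%-LOA %d to %d ms",
                      lab,
                      as.integer(round_half_away(ba$bias_ms)),
                      as.integer(round_half_away(ba$loa_low_ms)),
                      as.integer(round_half_away(ba$loa_high_ms)))
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of test against reference values
#'
#' Test-method values against reference values with the identity line;
#' the Pearson correlation is shown in the title.
#'
#' @param pairs a [paired_series()].
#' @return a ggplot object.
#' @export
plot_agreement_scatter <- function(pairs) {
  stopifnot(inherits(pairs, "paired_series"))
  r <- tryCatch(pearson_agreement(pairs)$r, error = function(e) NA_real_)
  df <- data.frame(test_ms = pairs$test_ms, ref_ms = pairs$ref_ms)
  lab <- toupper(pairs$metric_name)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ref_ms, y = .data$test_ms)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(shape = 1) +
    ggplot2::labs(
      x = sprintf("Reference %s (ms)", lab),
      y = sprintf("Test %s (ms)", lab),
      title = if (is.finite(r)) sprintf("%s: r = %.2f", lab, r) else lab
    ) +
    ggplot2::theme_minimal()
}
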