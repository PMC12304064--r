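#' Construct a paired test/reference series
#'
#' Holds one metric (QT or QTc) measured on the same subjects by a test
#' method and a reference method.
#'
#' @param test_ms test-method values in ms.
#' @param ref_ms reference-method values in ms; same length.
#' @param ids optional subject labels (defaults to 1..n).
#' @param metric `"qt"` or `"qtc"`.
#' @return an object of class `paired_series`.
#' @export
paired_series <- function(test_ms, ref_ms, ids = NULL,
                          metric = c("qt", "qtc")) {
  metric <- match.arg(metric)
  if (length(test_ms) != length(ref_ms)) {
    abort(sprintf("length mismatch: %d test values vs %d reference values",
                  length(test_ms), length(ref_ms)))
  }
  n <- length(test_ms)
  if (n < 2) abort("at least 2 measurement pairs are required")
  if (is.null(ids)) ids <- seq_len(n)
  if (length(ids) != n) abort("`ids` must match the number of pairs")
  if (!all(is.finite(test_ms)) || !all(is.finite(ref_ms))) {
    abort("all values must be finite")
  }
  if (any(test_ms <= 0) || any(ref_ms <= 0)) {
    abort("all interval values must be > 0 ms")
  }
  structure(
    list(ids = ids, test_ms = as.numeric(test_ms),
         ref_ms = as.numeric(ref_ms), metric_name = metric),
    class = "paired_series"
  )
}

#' Paired differences, reference minus test
#'
#' The sign convention used throughout: a test method that underestimates
#' the reference gives positive differences; one that overestimates gives
#' negative differences.
#'
#' @param pairs a [paired_series()].
#' @return numeric vector of `ref - test`, order preserved.
#' @export
differences <- function(pairs) {
  stopifnot(inherits(pairs, "paired_series"))
  pairs$ref_ms - pairs$test_ms
}

# bias/SD/LOA/CI arithmetic shared by bland_altman() and loa_from_summary()
ba_core <- function(bias, sd, n) {
  z <- 1.96
  loa_low <- bias - z * sd
  loa_high <- bias + z * sd
  se_bias <- sd / sqrt(n)
  se_loa <- sd * sqrt(3 / n)  # classic normal-approximation SE of a LOA
  list(
    n = n, bias_ms = bias, sd_ms = sd,
    loa_low_ms = loa_low, loa_high_ms = loa_high,
    ci_bias = c(bias - z * se_bias, bias + z * se_bias),
    ci_loa_low = c(loa_low - z * se_loa, loa_low + z * se_loa),
    ci_loa_high = c(loa_high - z * se_loa, loa_high + z * se_loa)
  )
}

#' Bland-Altman analysis of a paired series
#'
#' Computes the mean of the differences (bias, reference minus test), the
#' sample SD of the differences (n - 1 denominator), the 95% limits of
#' agreement `bias +/- 1.96 SD`, and 95% confidence intervals: for the
#' bias via the standard error `SD / sqrt(n)`, and for each limit of
#' agreement via the classic normal-approximation standard error
#' `SD * sqrt(3 / n)`, both with z = 1.96.
#'
#' @param pairs a [paired_series()].
#' @return a list of class `bland_altman` with `n`, `bias_ms`, `sd_ms`,
#'   `loa_low_ms`, `loa_high_ms`, `ci_bias`, `ci_loa_low`, `ci_loa_high`.
#' @export
#' @examples
#' p <- paired_series(test_ms = c(390, 380, 370), ref_ms = c(400, 400, 400))
#' bland_altman(p)$bias_ms  # 20
bland_altman <- function(pairs) {
  d <- differences(pairs)
  n <- length(d)
  if (n < 2) abort("Bland-Altman needs at least 2 pairs (SD undefined otherwise)")
  structure(ba_core(mean(d), stats::sd(d), n), class = "bland_altman")
}

#' Limits of agreement from summary statistics
#'
#' The same LOA/CI arithmetic as [bland_altman()], driven by a published
#' bias, SD and sample size instead of raw pairs - useful for checking a
#' reported agreement table.
#'
#' @param bias_ms mean of the differences in ms.
#' @param sd_ms SD of the differences in ms (>= 0).
#' @param n number of pairs (>= 2).
#' @return a list of class `bland_altman` (see [bland_altman()]).
#' @export
#' @examples
#' # bias 13 ms, SD 15 ms, n 57 -> LOA (-16.4, 42.4), rounding to (-16, 42)
#' loa_from_summary(13, 15, 57)
loa_from_summary <- function(bias_ms, sd_ms, n) {
  check_number(bias_ms, "bias_ms")
  check_number(sd_ms, "sd_ms", nonneg = TRUE)
  if (!is.numeric(n) || n < 2) abort("`n` must be >= 2")
  structure(ba_core(bias_ms, sd_ms, as.integer(n)), class = "bland_altman")
}

#' Grade the agreement of each measurement pair
#'
#' Absolute differences are binned into three clinically motivated
#' grades: excellent (< 20 ms), acceptable (20 to < 40 ms), unacceptable
#' (>= 40 ms). The bins are half-open, `[0, 20)`, `[20, 40)`, `[40,
#' Inf)`, so every pair lands in exactly one grade; percentages are
#' `100 * count / n` rounded half away from zero (they can sum to 99 or
#' 101 for that reason).
#'
#' @param pairs a [paired_series()].
#' @return a list with `counts` and `pct`, each a named vector
#'   (`excellent`, `acceptable`, `unacceptable`).
#' @export
grade_agreement <- function(pairs) {
  d <- abs(differences(pairs))
  n <- length(d)
  counts <- c(
    excellent = sum(d < 20),
    acceptable = sum(d >= 20 & d < 40),
    unacceptable = sum(d >= 40)
  )
  list(counts = counts, pct = round_half_away(100 * counts / n))
}

#' Clinical acceptability of a method comparison
#'
#' A test method is clinically acceptable when the mean of the
#' differences and their SD are each at most 20 ms (the "20 +/- 20 ms"
#' criterion); the bias is judged by magnitude.
#'
#' @param bias_ms mean of the differences in ms.
#' @param sd_ms SD of the differences in ms (>= 0).
#' @return logical.
#' @export
#' @examples
#' clinical_acceptability(13, 15)  # TRUE
#' clinical_acceptability(21, 5)   # FALSE
clinical_acceptability <- function(bias_ms, sd_ms) {
  check_number(bias_ms, "bias_ms")
  check_number(sd_ms, "sd_ms", nonneg = TRUE)
  abs(bias_ms) <= 20 && sd_ms <= 20
}

#' Pearson correlation between test and reference series
#'
#' Standard product-moment correlation with the two-sided p-value from
#' the t transform on n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param pairs a [paired_series()].
#' @return a list with `r` and `p_value`.
#' @export
pearson_agreement <- function(pairs) {
  stopifnot(inherits(pairs, "paired_series"))
  for (side in c("test_ms", "ref_ms")) {
    if (stats::sd(pairs[[side]]) == 0) {
      abort(sprintf("correlation undefined: the %s series is constant", side))
    }
  }
  if (length(pairs$test_ms) < 3) abort("at least 3 pairs are needed for a p-value")
  ct <- stats::cor.test(pairs$test_ms, pairs$ref_ms, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Full method-comparison report
#'
#' Aggregates the Bland-Altman analysis, Pearson correlation, agreement
#' grading and the clinical-acceptability verdict into one record, the
#' shape of a published agreement table. Printed values are rounded half
#' away from zero to integer ms; the stored fields keep full precision.
#'
#' @param pairs a [paired_series()].
#' @return an object of class `agreement_report`.
#' @export
agreement_report <- function(pairs) {
  stopifnot(inherits(pairs, "paired_series"))
  ba <- bland_altman(pairs)
  gr <- grade_agreement(pairs)
  r <- if (length(pairs$test_ms) >= 3 &&
           stats::sd(pairs$test_ms) > 0 && stats::sd(pairs$ref_ms) > 0) {
    pearson_agreement(pairs)
  } else {
    list(r = NA_real_, p_value = NA_real_)
  }
  structure(
    list(
      metric_name = pairs$metric_name,
      n = ba$n,
      bias_ms = ba$bias_ms, sd_ms = ba$sd_ms,
      loa_low_ms = ba$loa_low_ms, loa_high_ms = ba$loa_high_ms,
      ci_bias = ba$ci_bias,
      ci_loa_low = ba$ci_loa_low, ci_loa_high = ba$ci_loa_high,
      pearson_r = r$r, pearson_p = r$p_value,
      grade_counts = gr$counts, grade_pct = gr$pct,
      clinically_acceptable = clinical_acceptability(ba$bias_ms, ba$sd_ms)
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  fmt_ci <- function(v) sprintf("(%d to %d)",
                                as.integer(round_half_away(v[1])),
                                as.integer(round_half_away(v[2])))
  cat(sprintf("Method comparison: %s, n = %d pairs\n",
              toupper(x$metric_name), x$n))
  cat(sprintf("  Mean of the differences (95%%-CI), ms : %d %s\n",
              as.integer(round_half_away(x$bias_ms)), fmt_ci(x$ci_bias)))
  cat(sprintf("  SD of the differences, ms            : %d\n",
              as.integer(round_half_away(x$sd_ms))))
  cat(sprintf("  Lower limit of agreement (95%%-CI), ms: %d %s\n",
              as.integer(round_half_away(x$loa_low_ms)), fmt_ci(x$ci_loa_low)))
  cat(sprintf("  Upper limit of agreement (95%%-CI), ms: %d %s\n",
              as.integer(round_half_away(x$loa_high_ms)), fmt_ci(x$ci_loa_high)))
  if (is.finite(x$pearson_r)) {
    cat(sprintf("  Pearson r = %.2f (P %s)\n", x$pearson_r,
                if (x$pearson_p < 0.001) "< 0.001" else sprintf("= %.3f", x$pearson_p)))
  }
  cat(sprintf("  Agreement grades: %d%% excellent, %d%% acceptable, %d%% unacceptable\n",
              x$grade_pct[["excellent"]], x$grade_pct[["acceptable"]],
              x$grade_pct[["unacceptable"]]))
  cat(sprintf("  Clinically acceptable (|bias| <= 20 and SD <= 20 ms): %s\n",
              if (x$clinically_acceptable) "yes" else "no"))
  invisible(x)
}
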