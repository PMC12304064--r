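test_that("differences follow the reference-minus-test sign convention", {
  p <- paired_series(test_ms = c(390, 400, 410), ref_ms = c(400, 400, 400))
  expect_equal(differences(p), c(10, 0, -10))
  same <- paired_series(test_ms = c(400, 380), ref_ms = c(400, 380))
  expect_equal(differences(same), c(0, 0))
  expect_error(paired_series(test_ms = c(1, 2), ref_ms = c(1, 2, 3)),
               "length mismatch")
})

test_that("Bland-Altman matches hand-computed summaries", {
  # d = 10, 20, 30: bias 20, sd 10, LOA 20 -/+ 19.6
  p <- paired_series(test_ms = c(390, 380, 370), ref_ms = c(400, 400, 400))
  ba <- bland_altman(p)
  expect_equal(ba$bias_ms, 20)
  expect_equal(ba$sd_ms, 10)
  expect_equal(ba$loa_low_ms, 0.4)
  expect_equal(ba$loa_high_ms, 39.6)
  ident <- bland_altman(paired_series(test_ms = c(400, 410), ref_ms = c(400, 410)))
  expect_equal(ident$bias_ms, 0)
  expect_equal(ident$sd_ms, 0)
  expect_equal(c(ident$loa_low_ms, ident$loa_high_ms), c(0, 0))
})

test_that("a published QTc agreement row closes under integer rounding", {
  # bias 13 ms, SD 15 ms, n 57 pairs
  ba <- loa_from_summary(13, 15, 57)
  expect_equal(round_half_away(c(ba$loa_low_ms, ba$loa_high_ms)), c(-16, 42))
  expect_equal(round_half_away(ba$ci_bias), c(9, 17))
})

test_that("agreement grading partitions pairs at the documented 20/40 ms boundaries", {
  ref <- rep(400, 7)
  test <- ref - c(10, -10, 25, -25, 45, 40, 20)  # |d|: 10 10 25 25 45 40 20
  g <- grade_agreement(paired_series(test, ref))
  expect_equal(unname(g$counts), c(2, 3, 2))  # 20 -> acceptable, 40 -> unacceptable
  expect_equal(sum(g$counts), 7)
  set.seed(41)
  for (i in 1:10) {
    n <- sample(3:60, 1)
    d <- rnorm(n, 10, 30)
    g <- grade_agreement(paired_series(400 - d, rep(400, n)))
    expect_equal(sum(g$counts), n)
    expect_lte(abs(sum(g$pct) - 100), 1)
  }
})

test_that("clinical acceptability applies the 20 +/- 20 ms criterion", {
  expect_true(clinical_acceptability(14, 20))
  expect_true(clinical_acceptability(13, 15))
  expect_true(clinical_acceptability(-20, 20))
  expect_false(clinical_acceptability(21, 5))
  expect_false(clinical_acceptability(0, 20.5))
})

test_that("Pearson correlation matches hand computation and handles edge cases", {
  p <- paired_series(test_ms = c(1, 2, 3), ref_ms = c(1, 2, 4))
  expect_equal(round(pearson_agreement(p)$r, 4), 0.982)
  exact <- paired_series(test_ms = c(300, 350, 400), ref_ms = c(300, 350, 400))
  expect_equal(pearson_agreement(exact)$r, 1)
  neg <- paired_series(test_ms = c(300, 350, 400), ref_ms = c(500, 450, 400))
  expect_equal(pearson_agreement(neg)$r, -1)
  const <- paired_series(test_ms = c(400, 400, 400), ref_ms = c(390, 410, 420))
  expect_error(pearson_agreement(const), "test_ms")
})

test_that("bias, SD and r agree with explicit-sum oracles to 1e-10", {
  set.seed(57)
  for (i in 1:50) {
    n <- sample(5:80, 1)
    ref <- runif(n, 320, 480)
    test <- ref - rnorm(n, 10, 20)
    test[test <= 0] <- 1
    p <- paired_series(test, ref)
    ba <- bland_altman(p)
    d <- ref - test
    expect_equal(ba$bias_ms, brute_mean(d), tolerance = 1e-10)
    expect_equal(ba$sd_ms, brute_sd(d), tolerance = 1e-10)
    expect_equal(pearson_agreement(p)$r, brute_pearson(test, ref),
                 tolerance = 1e-10)
  }
})

test_that("shifting every test value shifts the bias and nothing else", {
  set.seed(73)
  ref <- runif(30, 350, 450)
  test <- ref - rnorm(30, 5, 15)
  c0 <- bland_altman(paired_series(test, ref))
  shift <- 12.5
  c1 <- bland_altman(paired_series(test + shift, ref))
  expect_equal(c1$bias_ms, c0$bias_ms - shift)
  expect_equal(c1$sd_ms, c0$sd_ms)
  expect_equal(pearson_agreement(paired_series(test + shift, ref))$r,
               pearson_agreement(paired_series(test, ref))$r)
})

test_that("about 95 percent of normal differences fall inside the computed LOA", {
  set.seed(101)
  n <- 10000
  d <- rnorm(n, 13, 15)
  p <- paired_series(test_ms = 400 - d, ref_ms = rep(400, n))
  ba <- bland_altman(p)
  coverage <- mean(d >= ba$loa_low_ms & d <= ba$loa_high_ms)
  expect_gte(coverage, 0.94)
  expect_lte(coverage, 0.96)
})

test_that("the full report is internally consistent", {
  set.seed(7)
  study <- simulate_study(20, seed = 7)
  p <- paired_series(study$test_qt_ms, study$ref_qt_ms)
  rep <- agreement_report(p)
  expect_equal(rep$loa_low_ms, rep$bias_ms - 1.96 * rep$sd_ms)
  expect_equal(rep$loa_high_ms, rep$bias_ms + 1.96 * rep$sd_ms)
  expect_equal(sum(rep$grade_counts), rep$n)
  expect_true(rep$pearson_r >= -1 && rep$pearson_r <= 1)
  expect_identical(rep$clinically_acceptable,
                   clinical_acceptability(rep$bias_ms, rep$sd_ms))
  # perfect agreement collapses everything
  perf <- agreement_report(paired_series(study$ref_qt_ms, study$ref_qt_ms))
  expect_equal(perf$bias_ms, 0)
  expect_equal(perf$sd_ms, 0)
  expect_equal(unname(perf$grade_pct[["excellent"]]), 100)
  expect_true(perf$clinically_acceptable)
  expect_output(print(rep), "Mean of the differences")
})

test_that("agreement plots build without error", {
  study <- simulate_study(12, seed = 2)
  p <- paired_series(study$test_qtc_ms, study$ref_qtc_ms, metric = "qtc")
  expect_s3_class(plot_bland_altman(p), "ggplot")
  expect_s3_class(plot_agreement_scatter(p), "ggplot")
})
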