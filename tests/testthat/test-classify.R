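test_that("GAPDH-normalised ratios follow the printed arithmetic", {
  expect_equal(ct_ratio(25, 40), 62.5)
  expect_equal(ct_ratio(25, 25), 100)
  expect_equal(ct_ratio(26, 20), 130)
  expect_equal(round(ct_ratio(25, 45), 1), 55.6)
  expect_equal(round(ct_ratio(25, 28), 1), 89.3)
  expect_equal(ct_ratio(25, 40, scale = 1) * 100, ct_ratio(25, 40, scale = 100))
  expect_error(ct_ratio(25, 0), "denominator")
  expect_error(ct_ratio(NA_real_, 20), "finite")
})

test_that("the EBV rule maps ratios to blood/uncertain/LCL with inclusive boundaries", {
  expect_identical(classify_ebv(62.5), "blood")
  expect_identical(classify_ebv(130), "LCL")
  expect_identical(classify_ebv(91), "uncertain")
  expect_identical(classify_ebv(110), "uncertain")
  expect_identical(classify_ebv(c(90.99, 110.01)), c("blood", "LCL"))
})

test_that("the TCR-gamma rule mirrors the EBV rule", {
  expect_identical(classify_tcrg(100), "blood")
  expect_identical(classify_tcrg(55.6), "LCL")
  expect_identical(classify_tcrg(80), "uncertain")
  expect_identical(classify_tcrg(70), "uncertain")
})

test_that("the TCR-beta Tm rule reads 'over the cutoff' strictly and treats no peak as LCL", {
  expect_identical(classify_tcrb(90.2), "blood")
  expect_identical(classify_tcrb(89.5), "LCL")
  expect_identical(classify_tcrb(NA_real_), "LCL")
})

test_that("per-assay labels move monotonically as the target Ct decreases", {
  # more EBV (earlier Ct) pushes blood -> uncertain -> LCL
  labels <- classify_ebv(ct_ratio(25, seq(40, 18, by = -0.5)))
  expect_identical(rle(labels)$values, c("blood", "uncertain", "LCL"))
  # more TCR-gamma (earlier Ct) pushes LCL -> uncertain -> blood
  labels <- classify_tcrg(ct_ratio(25, seq(45, 25, by = -0.5)))
  expect_identical(rle(labels)$values, c("LCL", "uncertain", "blood"))
})

test_that("combine_calls matches brute-force enumeration of all 27 label triples", {
  grid <- expand.grid(ebv = c("blood", "LCL", "uncertain"),
                      tcrg = c("blood", "LCL", "uncertain"),
                      tcrb = c("blood", "LCL", "uncertain"),
                      stringsAsFactors = FALSE)
  got <- combine_calls(grid$ebv, grid$tcrg, grid$tcrb)
  expected <- vapply(seq_len(nrow(grid)), function(i) {
    reference_combine(grid$ebv[i], grid$tcrg[i], grid$tcrb[i])
  }, character(1))
  expect_identical(got$combined, expected)
  expect_true(all(got$votes_blood + got$votes_lcl <= 3))
  expect_identical(got$combined == "blood", got$votes_blood >= 2)
  # a lone blood positive among discordant tests stays uncertain
  expect_identical(combine_calls("blood", "LCL", "uncertain")$combined,
                   "uncertain")
  expect_error(combine_calls("blood", "plasma", "LCL"), "labels")
})

test_that("classify_samples composes the per-assay rules on hand-built panels", {
  out <- classify_samples(fixture_panels())
  expect_identical(out$combined,
                   c("blood", "LCL", "uncertain", "blood"))
  expect_identical(out$votes_blood, c(3L, 0L, 1L, 3L))
  expect_identical(out$votes_lcl, c(0L, 3L, 1L, 0L))
  expect_equal(out$ebv_ratio[1], 62.5)
  expect_equal(round(out$tcrg_ratio[2], 1), 55.6)
})

test_that("classify_samples handles empty input and unclassifiable samples", {
  empty <- classify_samples(fixture_panels()[0, ])
  expect_equal(nrow(empty), 0)
  broken <- fixture_panels()
  broken$ct_gapdh[2] <- NA_real_
  expect_warning(out <- classify_samples(broken), "lcl1")
  expect_identical(out$combined[2], "unclassifiable")
  expect_identical(out$combined[-2], c("blood", "uncertain", "blood"))
})

test_that("threshold configuration validates its ordering", {
  expect_error(threshold_config(ebv_lower = 120), "ebv_lower")
  expect_error(threshold_config(tcrg_lower = 90, tcrg_upper = 80),
               "tcrg_lower")
})

test_that("TCR-gamma threshold calibration places the band inside the class gap", {
  withr::with_seed(21, {
    d <- tibble::tibble(
      tcrg_ratio = c(runif(60, 50, 62), runif(60, 82, 95)),
      tissue = rep(c("LCL", "blood"), each = 60)
    )
  })
  fit <- calibrate_tcrg_thresholds(d)
  expect_gt(fit$tcrg_lower, max(d$tcrg_ratio[d$tissue == "LCL"]))
  expect_lt(fit$tcrg_upper, min(d$tcrg_ratio[d$tissue == "blood"]))
  expect_lt(fit$tcrg_lower, fit$tcrg_upper)
  cfg <- threshold_config(tcrg_lower = fit$tcrg_lower,
                          tcrg_upper = fit$tcrg_upper)
  labels <- classify_tcrg(d$tcrg_ratio, cfg)
  expect_identical(labels, d$tissue)
  expect_error(calibrate_tcrg_thresholds(d[d$tissue == "blood", ]), "both")
})
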