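test_that("metric identities hold against an independent recount on random cohorts", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      n <- 60
      d <- tibble::tibble(
        tissue = sample(c("blood", "LCL"), n, replace = TRUE),
        combined = sample(c("blood", "LCL", "uncertain"), n, replace = TRUE)
      )
      ev <- evaluate_binary(d)
      ref <- reference_binary_metrics(d$tissue, d$combined)
      expect_equal(ev$tp, ref$tp)
      expect_equal(ev$fp, ref$fp)
      expect_equal(ev$tn, ref$tn)
      expect_equal(ev$fn, ref$fn)
      expect_equal(ev$sensitivity, ref$sens)
      expect_equal(ev$specificity, ref$spec)
      expect_equal(ev$accuracy, ref$acc)
      expect_equal(ev$n, n)
      # shuffling sample order changes nothing
      ev2 <- evaluate_binary(d[sample(n), ])
      expect_equal(glance(ev2), glance(ev))
    }
  })
})

test_that("a perfect classifier scores 100% everywhere", {
  d <- tibble::tibble(tissue = rep(c("blood", "LCL"), each = 10))
  d$combined <- d$tissue
  ev <- evaluate_binary(d)
  expect_equal(ev$sensitivity, 100)
  expect_equal(ev$specificity, 100)
  expect_equal(ev$ppv, 100)
  expect_equal(ev$npv, 100)
  expect_equal(ev$accuracy, 1)
})

test_that("zero-denominator metrics are undefined, not zero", {
  # nothing called blood: PPV has no positive calls to condition on
  ev <- binary_eval(tp = 0, fp = 0, tn = 5, fn = 5)
  expect_true(is.na(ev$ppv))
  expect_equal(ev$specificity, 100)
  # no LCL at all: specificity undefined
  ev2 <- binary_eval(tp = 5, fp = 0, tn = 0, fn = 0)
  expect_true(is.na(ev2$specificity))
  expect_true(is.na(ev2$npv))
})

test_that("evaluate_binary rejects malformed truth", {
  d <- tibble::tibble(tissue = c("blood", "uncertain"),
                      combined = c("blood", "LCL"))
  expect_error(evaluate_binary(d), "blood")
})

test_that("tidy and glance expose display rounding and full precision", {
  ev <- binary_eval(tp = 450, fn = 7, tn = 316, fp = 0)
  td <- tidy(ev)
  expect_identical(td$metric,
                   c("sensitivity", "specificity", "ppv", "npv", "accuracy"))
  expect_equal(td$display[td$metric == "npv"], 97.8)
  expect_equal(td$value[td$metric == "npv"], 100 * 316 / 323)
  gl <- glance(ev)
  expect_equal(gl$n, 773)
})

test_that("concordance cross-tabulates and summarises annotation agreement", {
  d <- tibble::tibble(
    annotation = c("blood", "blood", "LCL", "LCL", "unknown", "unknown"),
    combined = c("blood", "uncertain", "LCL", "LCL", "blood", "uncertain")
  )
  cc <- concordance(d)
  expect_equal(cc$n_annotated, 4)
  expect_equal(cc$overall_concordance, 100 * 3 / 4)
  expect_equal(cc$identified_rate, 50)
  expect_equal(cc$n_uncertain, 2)
  expect_equal(sum(cc$counts), 6)
  expect_equal(unname(rowSums(cc$counts)), c(2, 2, 2))
})

test_that("degenerate concordance inputs give undefined rates, not errors", {
  all_unknown <- tibble::tibble(annotation = rep("unknown", 4),
                                combined = c("blood", "LCL", "LCL", "blood"))
  cc <- concordance(all_unknown)
  expect_true(is.na(cc$overall_concordance))
  expect_equal(cc$identified_rate, 100)

  perfect <- tibble::tibble(annotation = c("blood", "LCL"),
                            combined = c("blood", "LCL"))
  cc2 <- concordance(perfect)
  expect_equal(cc2$overall_concordance, 100)
  expect_equal(unname(cc2$row_rate[c("blood", "LCL")]), c(100, 100))
})

test_that("reconstructed combined-test counts are internally consistent", {
  # with 457 blood / 316 LCL, sensitivity 98.5% and specificity 100%
  # imply this confusion matrix, whose NPV and accuracy follow
  ev <- binary_eval(tp = 450, fn = 7, tn = 316, fp = 0)
  expect_equal(round(ev$sensitivity, 1), 98.5)
  expect_equal(round(ev$npv, 1), 97.8)
  expect_equal(round(ev$accuracy, 3), 0.991)
})
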