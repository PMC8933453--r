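test_that("the age model reproduces its printed coefficients arithmetically", {
  p <- function(e, k, t) {
    predict_age(tibble::tibble(elovl2_cpg5 = e, klf14_cpg2 = k,
                               trim59_cpg5 = t))$predicted_age
  }
  expect_equal(p(0, 0, 0), -20.372)
  expect_equal(p(60, 20, 40), 92.488)
  expect_equal(p(100, 100, 100), 306.428)
})

test_that("the age model is affine: convex combinations commute with prediction", {
  withr::with_seed(41, {
    for (rep in 1:5) {
      x <- runif(3, 0, 100)
      y <- runif(3, 0, 100)
      a <- runif(1)
      mix <- a * x + (1 - a) * y
      p <- function(v) {
        predict_age(tibble::tibble(elovl2_cpg5 = v[1], klf14_cpg2 = v[2],
                                   trim59_cpg5 = v[3]))$predicted_age
      }
      expect_equal(p(mix), a * p(x) + (1 - a) * p(y), tolerance = 1e-10)
    }
  })
})

test_that("out-of-range methylation is rejected", {
  expect_error(predict_age(tibble::tibble(
    elovl2_cpg5 = 101, klf14_cpg2 = 10, trim59_cpg5 = 10
  )), "0, 100")
  expect_error(predict_age(tibble::tibble(
    elovl2_cpg5 = -1, klf14_cpg2 = 10, trim59_cpg5 = 10
  )), "0, 100")
})

test_that("MAD and Pearson R behave on hand-computable cases", {
  exact <- tibble::tibble(tissue = "blood", chronological_age = c(20, 40, 60),
                          predicted_age = c(20, 40, 60))
  ev <- evaluate_age(exact)
  expect_equal(ev$mad, 0)
  expect_equal(ev$pearson_r, 1)

  shifted <- tibble::tibble(tissue = "blood", chronological_age = c(30, 50),
                            predicted_age = c(35, 55))
  ev2 <- evaluate_age(shifted)
  expect_equal(ev2$mad, 5)
  expect_equal(ev2$pearson_r, 1)

  single <- tibble::tibble(tissue = "blood", chronological_age = 30,
                           predicted_age = 31)
  expect_true(is.na(evaluate_age(single)$pearson_r))
})

test_that("default methylation noise propagates to roughly four years of blood error", {
  cfg <- cohort_config(n_blood = 200, n_lcl = 0, seed = 77)
  ev <- evaluate_age(predict_age(simulate_cohort(cfg)$methylation))
  expect_gt(ev$mad, 3)
  expect_lt(ev$mad, 6)
})

test_that("the clock degrades in LCLs: higher MAD, lower correlation than blood", {
  cfg <- cohort_config(n_blood = 60, n_lcl = 60, seed = 13)
  ev <- evaluate_age(predict_age(simulate_cohort(cfg)$methylation))
  blood <- ev[ev$group == "blood", ]
  lcl <- ev[ev$group == "LCL", ]
  expect_lt(blood$mad, lcl$mad)
  expect_gt(blood$pearson_r, lcl$pearson_r)
  expect_gt(blood$pearson_r, 0.7)
  expect_lt(lcl$pearson_r, 0.6)
})

test_that("age_eval tidiers return per-group and pooled summaries", {
  cfg <- cohort_config(n_blood = 20, n_lcl = 20, seed = 4)
  ev <- evaluate_age(predict_age(simulate_cohort(cfg)$methylation))
  td <- tidy(ev)
  expect_identical(names(td), c("group", "n", "mad", "pearson_r"))
  expect_equal(nrow(td), 2)
  gl <- glance(ev)
  expect_equal(gl$n, 40)
  expect_equal(gl$n_groups, 2)
})
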