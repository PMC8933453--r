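test_that("an empty configuration yields an empty cohort", {
  cohort <- simulate_cohort(cohort_config(n_blood = 0, n_lcl = 0))
  expect_equal(nrow(cohort$truth), 0)
  expect_equal(nrow(cohort$curves), 0)
  expect_equal(nrow(cohort$methylation), 0)
})

test_that("the same configuration reproduces the identical cohort", {
  cfg <- cohort_config(n_blood = 4, n_lcl = 4, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$curves, b$curves)
  expect_identical(a$methylation, b$methylation)
  c <- simulate_cohort(cohort_config(n_blood = 4, n_lcl = 4, seed = 100))
  expect_false(identical(a$curves, c$curves))
})

test_that("ground truth respects the tissue-specific marker supports", {
  cohort <- simulate_cohort(cohort_config(n_blood = 40, n_lcl = 40, seed = 5))
  tr <- cohort$truth
  lcl <- tr[tr$tissue == "LCL", ]
  blood <- tr[tr$tissue == "blood", ]
  expect_true(all(lcl$ebv_copies_per_genome >= 2 &
                    lcl$ebv_copies_per_genome <= 500))
  expect_true(all(lcl$t_cell_fraction == 0))
  expect_true(all(blood$ebv_copies_per_genome <= 0.01))
  expect_true(all(blood$t_cell_fraction >= 0.05 &
                    blood$t_cell_fraction <= 0.4))
  # the no-amplification path is exercised: most blood samples carry no EBV
  expect_gt(mean(blood$ebv_copies_per_genome == 0), 0.5)
})

test_that("generated curves reproduce the copy-number arithmetic of the truth", {
  # noiseless single blood sample with fixed T-cell fraction 0.2:
  # GAPDH template = 2/genome, TCR-gamma template = 0.2/genome, so
  # delta-Ct = log2(2 / 0.2) = log2(10)
  cfg <- cohort_config(
    n_blood = 1, n_lcl = 0, seed = 1, genomes_cv = 0,
    t_cell_range = c(0.2, 0.2), fluor_noise_sd = 0, ct_jitter_sd = 0
  )
  panel <- call_panels(simulate_cohort(cfg)$curves)
  expect_false(panel$tcrg_imputed)
  expect_lt(abs((panel$ct_tcrg - panel$ct_gapdh) - log2(10)), 0.1)

  # noiseless single LCL at 100 EBV copies/genome: far more EBV targets
  # than the 2 GAPDH alleles, so Ct_EBV < Ct_GAPDH and the ratio > 100
  cfg2 <- cohort_config(
    n_blood = 0, n_lcl = 1, seed = 1, genomes_cv = 0,
    lcl_ebv_range = c(100, 100), fluor_noise_sd = 0, ct_jitter_sd = 0
  )
  panel2 <- call_panels(simulate_cohort(cfg2)$curves)
  expect_lt(panel2$ct_ebv, panel2$ct_gapdh)
  expect_gt(ct_ratio(panel2$ct_gapdh, panel2$ct_ebv), 100)
})

test_that("blood melts carry a specific product above 89.5 C and LCL melts never do", {
  cohort <- simulate_cohort(cohort_config(n_blood = 15, n_lcl = 15, seed = 8))
  panels <- call_panels(cohort$curves)
  panels <- dplyr::left_join(panels, cohort$truth[, c("sample_id", "tissue")],
                             by = "sample_id")
  expect_true(all(panels$tcrb_max_tm[panels$tissue == "blood"] > 89.5))
  lcl_tm <- panels$tcrb_max_tm[panels$tissue == "LCL"]
  expect_true(all(is.na(lcl_tm) | lcl_tm < 89.5))
})

test_that("noise-free blood methylation inverts the age model exactly", {
  cfg <- cohort_config(n_blood = 10, n_lcl = 0, seed = 3, meth_noise_sd = 0)
  meth <- simulate_cohort(cfg)$methylation
  pred <- predict_age(meth)
  expect_equal(pred$predicted_age, pred$chronological_age, tolerance = 1e-10)
})

test_that("cohort sizes and sample ids line up across tables", {
  cohort <- simulate_cohort(cohort_config(n_blood = 5, n_lcl = 3, seed = 2))
  expect_equal(nrow(cohort$truth), 8)
  expect_equal(sum(cohort$truth$tissue == "blood"), 5)
  expect_setequal(unique(cohort$curves$sample_id), cohort$truth$sample_id)
  expect_identical(cohort$methylation$sample_id, cohort$truth$sample_id)
  # per sample: 3 amplification runs of 50 cycles + one 151-point melt
  expect_equal(nrow(cohort$curves), 8 * (3 * 50 + 151))
})

test_that("invalid cohort configurations are rejected by field name", {
  expect_error(cohort_config(n_blood = -1), "n_blood")
  expect_error(cohort_config(t_cell_range = c(0, 0.4)), "t_cell_range")
  expect_error(cohort_config(lcl_ebv_range = c(500, 2)), "lcl_ebv_range")
  expect_error(cohort_config(lcl_methylation = 2), "unused argument")
  expect_error(simulate_cohort(list(n_blood = 1)), "cohort_config")
})
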