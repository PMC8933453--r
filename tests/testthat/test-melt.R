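test_that("a single product's Tm is recovered within one acquisition step", {
  oracle <- dense_melt_peaks(data.frame(tm = 90, fraction = 0.8))
  expect_equal(oracle, 90, tolerance = 1e-2)
  pk <- extract_tm_peaks(simulate_melt(data.frame(tm = 90, fraction = 0.8)))
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$tm - 90), 0.2)
})

test_that("no products means no peak", {
  melt <- simulate_melt(data.frame(tm = numeric(), fraction = numeric()))
  pk <- extract_tm_peaks(melt)
  expect_equal(nrow(pk), 0)
  expect_true(is.na(max_tm(pk)))
})

test_that("two separated products both appear and the hotter one is max_tm", {
  prods <- data.frame(tm = c(87, 90.5), fraction = c(0.3, 0.7))
  oracle <- dense_melt_peaks(prods)
  expect_equal(length(oracle), 2)
  pk <- extract_tm_peaks(simulate_melt(prods))
  expect_equal(nrow(pk), 2)
  expect_lt(max(abs(sort(pk$tm) - sort(oracle))), 0.2)
  expect_lt(abs(max_tm(pk) - 90.5), 0.2)
})

test_that("a product melting exactly at the decision cutoff is located there", {
  pk <- extract_tm_peaks(simulate_melt(data.frame(tm = 89.5, fraction = 0.6)))
  expect_lt(abs(max_tm(pk) - 89.5), 0.2)
})

test_that("a blood-like dimer + specific-product melt yields two peaks above and below the cutoff", {
  prods <- data.frame(tm = c(84, 90.2), fraction = c(0.2, 0.6))
  pk <- extract_tm_peaks(simulate_melt(prods))
  expect_equal(nrow(pk), 2)
  expect_gt(max_tm(pk), 89.5)
  expect_lt(min(pk$tm), 89.5)
  expect_equal(pk$tm, sort(pk$tm)) # ascending order contract
})

test_that("off-grid melting temperatures are recovered within the grid bound", {
  withr::with_seed(9, {
    for (tm in runif(8, 80, 92)) {
      pk <- extract_tm_peaks(simulate_melt(data.frame(tm = tm, fraction = 0.6)))
      expect_lt(abs(pk$tm[which.max(pk$prominence)] - tm), 0.2,
                label = sprintf("|tm error| at %.3f C", tm))
    }
  })
})

test_that("smoothed and unsmoothed melt-peak calling agree on noiseless curves", {
  melt <- simulate_melt(data.frame(tm = 88.3, fraction = 0.6))
  a <- extract_tm_peaks(melt, window = 1)
  b <- extract_tm_peaks(melt, window = 9)
  expect_lt(abs(max_tm(a) - max_tm(b)), 0.05)
})

test_that("a featureless monotone decay has no peak", {
  decay <- tibble::tibble(temperature = seq(65, 95, 0.2))
  decay$fluorescence <- 10 - 0.05 * (decay$temperature - 65)
  expect_equal(nrow(extract_tm_peaks(decay)), 0)
})

test_that("melt simulation rejects invalid products and short curves error", {
  expect_error(simulate_melt(data.frame(tm = 60, fraction = 0.5)), "window")
  expect_error(simulate_melt(data.frame(tm = 96, fraction = 0.5)), "window")
  expect_error(simulate_melt(data.frame(tm = c(80, 85), fraction = c(0.6, 0.6))),
               "fraction")
  short <- tibble::tibble(temperature = seq(65, 65.6, 0.2),
                          fluorescence = c(4, 3, 2, 1))
  expect_error(extract_tm_peaks(short), "points")
})
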