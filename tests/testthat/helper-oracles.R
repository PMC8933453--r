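# Independent oracles used across the suite.

# Analytic position of the second-derivative maximum of the saturating
# amplification model: the noiseless curve is logistic with slope log(E)
# and inflection c0 = log_E(K / N); curvature peaks ln(2 + sqrt(3)) / k
# cycles before the inflection.
analytic_sdm <- function(template_copies, efficiency = 2,
                         half_max_copies = 1.5e12) {
  c0 <- (log(half_max_copies) - log(template_copies)) / log(efficiency)
  c0 - log(2 + sqrt(3)) / log(efficiency)
}

# Dense-grid oracle for melt peaks: render the noiseless melt model on a
# millikelvin-scale grid and locate the local maxima of -dF/dT directly.
dense_melt_peaks <- function(products, step = 0.001) {
  curve <- simulate_melt(products, noise_sd = 0, temp_step = step)
  d <- -diff(curve$fluorescence) / step
  mids <- (head(curve$temperature, -1) + tail(curve$temperature, -1)) / 2
  n <- length(d)
  idx <- which(d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n]) + 1
  # ignore tiny background ripples
  idx <- idx[d[idx] > 0.1]
  mids[idx]
}

# Reference 2-of-3 voting rule, written directly from its verbal
# definition, for brute-force comparison with combine_calls().
reference_combine <- function(ebv, tcrg, tcrb) {
  votes <- c(ebv, tcrg, tcrb)
  if (sum(votes == "blood") >= 2) "blood"
  else if (sum(votes == "LCL") >= 2) "LCL"
  else "uncertain"
}

# Independent recount of binary metrics from raw label pairs.
reference_binary_metrics <- function(truth, call) {
  pos <- call == "blood"
  tp <- sum(pos & truth == "blood"); fp <- sum(pos & truth == "LCL")
  tn <- sum(!pos & truth == "LCL"); fn <- sum(!pos & truth == "blood")
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sens = 100 * tp / (tp + fn), spec = 100 * tn / (tn + fp),
       acc = (tp + tn) / length(truth))
}

# Small deterministic blood/LCL panel table with hand-derivable labels.
fixture_panels <- function() {
  tibble::tibble(
    sample_id = c("blood1", "lcl1", "uncertain1", "blood2"),
    ct_gapdh = c(25, 25, 25, 26),
    ct_ebv = c(40, 20, 25.5, 40),    # ratios 62.5, 125, 98.04, 65
    ct_tcrg = c(28, 45, 30, 29),     # ratios 89.3, 55.6, 83.3, 89.7
    tcrb_max_tm = c(90.2, 84.0, NA, 91.0)
  )
}
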