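#' Simulate a real-time PCR amplification curve
#'
#' Generates per-cycle fluorescence for one reaction under a saturating
#' exponential-growth model.  Starting from `template_copies` molecules the
#' product grows by a factor `efficiency` per cycle until it approaches the
#' reaction's saturation copy number, so the noiseless fluorescence is a
#' logistic sigmoid in cycle number,
#' \deqn{F(c) = b + P \cdot \mathrm{logit}^{-1}\{\log(E)\,(c - c_0)\},\qquad
#'       c_0 = \log_E(K / N),}
#' with `N` template copies, per-cycle efficiency `E`, plateau `P`, baseline
#' `b` and half-saturation copy number `K`.  Multiplying the template by a
#' factor `f` shifts the inflection cycle left by exactly \eqn{\log_E f},
#' which is what makes GAPDH-normalised Ct ratios meaningful.  Zero template
#' yields a baseline-only trace.
#'
#' @param template_copies Number of target molecules in the reaction
#'   (non-negative; need not be an integer).
#' @param efficiency Per-cycle amplification factor in (1, 2]; 2 is perfect
#'   doubling.
#' @param plateau Fluorescence rise amplitude at saturation (arbitrary
#'   units).
#' @param baseline Background fluorescence added to every cycle.
#' @param half_max_copies Product copy number at which fluorescence reaches
#'   half the plateau.  The default (1.5e12) places the Ct of a 10 ng
#'   genomic input (~6000 single-copy targets) near cycle 26.
#' @param noise_sd Standard deviation of i.i.d. Gaussian fluorescence noise
#'   (same units as `plateau`); 0 for a noiseless curve.
#' @param n_cycles Number of PCR cycles (curve covers cycles 1..`n_cycles`).
#' @param sample_id,assay Identifiers carried into the output table.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#'
#' @return A tibble with columns `sample_id`, `assay`, `cycle`,
#'   `fluorescence` — one row per cycle.
#' @seealso [call_ct()] to recover the quantification cycle,
#'   [simulate_melt()] for post-PCR melting curves.
#' @examples
#' curve <- simulate_amplification(6000, sample_id = "S1", assay = "GAPDH")
#' call_ct(curve)
#' @export
simulate_amplification <- function(template_copies,
                                   efficiency = 2,
                                   plateau = 10,
                                   baseline = 0.5,
                                   half_max_copies = 1.5e12,
                                   noise_sd = 0,
                                   n_cycles = 50,
                                   sample_id = "sample",
                                   assay = "assay",
                                   seed = NULL) {
  check_number(template_copies, "template_copies", min = 0)
  check_number(efficiency, "efficiency", min = 1, max = 2, allow_min = FALSE)
  check_number(plateau, "plateau", min = 0, allow_min = FALSE)
  check_number(baseline, "baseline", min = 0)
  check_number(half_max_copies, "half_max_copies", min = 0, allow_min = FALSE)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(n_cycles, "n_cycles", min = 5)

  cycles <- seq_len(n_cycles)
  if (template_copies == 0) {
    signal <- rep(0, n_cycles)
  } else {
    # logistic in cycle with slope log(efficiency); computed on the log scale
    # so extreme copy numbers cannot overflow
    c0 <- (log(half_max_copies) - log(template_copies)) / log(efficiency)
    signal <- plogis(log(efficiency) * (cycles - c0))
  }
  fluor <- baseline + plateau * signal
  if (noise_sd > 0) {
    fluor <- withr::with_seed(
      seed %||% sample.int(.Machine$integer.max, 1),
      fluor + rnorm(n_cycles, sd = noise_sd)
    )
  }
  tibble(
    sample_id = sample_id, assay = assay,
    cycle = cycles, fluorescence = fluor
  )
}

#' Simulate a post-PCR melting curve
#'
#' Produces fluorescence versus temperature for a pool of double-stranded
#' products read with a saturating intercalating dye.  Each product
#' contributes a two-state melt transition — a logistic drop in
#' fluorescence centred at its melting temperature — weighted by its
#' fraction of the pool, on top of a slowly decaying background.  The
#' negative derivative \eqn{-dF/dT} of the noiseless curve then peaks at
#' each product's Tm, which is how instrument software presents melt peaks.
#'
#' @param products A data frame (or tibble) with columns `tm` (degrees C,
#'   strictly inside the acquisition window) and `fraction` (non-negative,
#'   summing to at most 1), one row per distinct product.  An empty frame
#'   gives a featureless background-only curve.
#' @param noise_sd Gaussian fluorescence noise standard deviation.
#' @param temp_min,temp_max,temp_step Acquisition grid in degrees C
#'   (defaults 65 to 95 in 0.2 steps, the usual post-amplification ramp).
#' @param amplitude Fluorescence drop of a fraction-1 product across its
#'   melt transition.
#' @param transition_width Width parameter of each melt transition in
#'   degrees C (logistic scale parameter).
#' @param baseline Residual fluorescence after all products have melted.
#' @param drift_slope Linear background drift per degree C (background
#'   fluorescence decays as temperature rises).
#' @param sample_id,assay Identifiers carried into the output table.
#' @param seed Optional integer seed for the noise stream.
#'
#' @return A tibble with columns `sample_id`, `assay`, `temperature`,
#'   `fluorescence`.
#' @seealso [extract_tm_peaks()]
#' @examples
#' melt <- simulate_melt(data.frame(tm = 90, fraction = 0.8))
#' extract_tm_peaks(melt)
#' @export
simulate_melt <- function(products,
                          noise_sd = 0,
                          temp_min = 65,
                          temp_max = 95,
                          temp_step = 0.2,
                          amplitude = 10,
                          transition_width = 0.35,
                          baseline = 0.5,
                          drift_slope = 0.02,
                          sample_id = "sample",
                          assay = "TCRB",
                          seed = NULL) {
  products <- as_tibble(products)
  if (nrow(products) > 0) {
    if (!all(c("tm", "fraction") %in% names(products))) {
      stop_config("`products` must have columns `tm` and `fraction`")
    }
    if (any(!is.finite(products$tm)) ||
        any(products$tm <= temp_min) || any(products$tm >= temp_max)) {
      stop_config(sprintf(
        "product `tm` values must lie strictly inside the acquisition window (%g, %g) degrees C",
        temp_min, temp_max
      ))
    }
    if (any(products$fraction < 0) || sum(products$fraction) > 1 + 1e-9) {
      stop_config("product `fraction`s must be non-negative and sum to at most 1")
    }
  }
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(transition_width, "transition_width", min = 0, allow_min = FALSE)

  temps <- seq(temp_min, temp_max, by = temp_step)
  fluor <- baseline + drift_slope * (temp_max - temps)
  for (i in seq_len(nrow(products))) {
    fluor <- fluor + products$fraction[i] * amplitude *
      plogis((products$tm[i] - temps) / transition_width)
  }
  if (noise_sd > 0) {
    fluor <- withr::with_seed(
      seed %||% sample.int(.Machine$integer.max, 1),
      fluor + rnorm(length(temps), sd = noise_sd)
    )
  }
  tibble(
    sample_id = sample_id, assay = assay,
    temperature = temps, fluorescence = fluor
  )
}
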