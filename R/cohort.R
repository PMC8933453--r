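#' Configuration for the synthetic blood/LCL cohort generator
#'
#' Bundles every tunable of [simulate_cohort()] with validated defaults.
#' The defaults are chosen so a default cohort shows the signal structure
#' the assay panel was designed around: LCL samples carry a high episomal
#' EBV load (log-uniform between 2 and 500 genome copies per diploid
#' genome) and, being B-cell derived, no rearranged TCR; blood samples are
#' mostly EBV-free (90% give no EBV amplification at all, the rest trace
#' loads below 0.01 copies/genome) and contain a T-cell fraction between
#' 5% and 40% carrying rearranged TCR-gamma/beta.  TCR-beta melting curves
#' show a specific product above 89.5 degrees C only in blood; LCL
#' reactions melt only primer dimers and non-specific products below it.
#' Blood methylation at the three clock CpGs follows the affine age model
#' exactly (plus noise); LCL methylation is decorrelated from age and
#' shifted by a per-sample passage effect.
#'
#' @param n_blood,n_lcl Number of blood and LCL samples to generate.
#' @param seed Integer seed; the same configuration always reproduces the
#'   same cohort byte for byte.
#' @param genomes_per_reaction Nominal diploid genome equivalents per
#'   reaction (10 ng of human DNA is about 3000).
#' @param genomes_cv Lognormal coefficient of variation of the realised
#'   input amount per sample.
#' @param lcl_ebv_range,blood_ebv_range Support (copies per diploid
#'   genome, log-uniform) of the EBV load in LCL samples, and of the trace
#'   load in the minority of blood samples that carry any.
#' @param blood_ebv_zero_prob Probability that a blood sample has no EBV at
#'   all (exercising the no-amplification/imputation path).
#' @param t_cell_range Uniform support of the blood T-cell fraction.
#' @param age_range Uniform support of donor chronological age (years).
#' @param efficiency,plateau,half_max_copies Amplification model settings
#'   shared by the GAPDH/EBV/TCRG assays (see
#'   [simulate_amplification()]).
#' @param fluor_noise_sd Gaussian fluorescence noise on every curve
#'   (amplification and melt), in plateau units.
#' @param ct_jitter_sd Between-reaction Ct jitter in cycles, applied as a
#'   lognormal factor on effective template copies.
#' @param blood_tm_range Support of the specific TCR-beta product Tm in
#'   blood (drawn uniformly; strictly above the 89.5 cutoff).
#' @param dimer_tm_range Support of primer-dimer / non-specific product Tm
#'   (below the cutoff).
#' @param blood_dimer_prob Probability a blood reaction also shows a
#'   primer-dimer peak next to its specific product.
#' @param lcl_extra_peak_prob Probability an LCL reaction shows a second
#'   non-specific peak.
#' @param meth_noise_sd Per-CpG methylation measurement noise (percentage
#'   points).  The default 2.6 propagates through the clock coefficients to
#'   roughly 4 years of age error in blood.
#' @param lcl_decorrelation Mixing weight in \[0, 1\] replacing LCL
#'   methylation with an age-independent draw (0 = blood-like, 1 = fully
#'   decorrelated).
#' @param passage_effect_range Uniform support of the per-sample LCL
#'   methylation shift (percentage points added to every CpG).
#' @param n_cycles Cycles per amplification run.
#'
#' @return A validated list of class `"cohort_config"`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_blood = 500,
                          n_lcl = 500,
                          seed = 1L,
                          genomes_per_reaction = 3000,
                          genomes_cv = 0.05,
                          lcl_ebv_range = c(2, 500),
                          blood_ebv_range = c(0.001, 0.01),
                          blood_ebv_zero_prob = 0.9,
                          t_cell_range = c(0.05, 0.4),
                          age_range = c(19, 79),
                          efficiency = 2,
                          plateau = 10,
                          half_max_copies = 1.5e12,
                          fluor_noise_sd = 0.05,
                          ct_jitter_sd = 0.15,
                          blood_tm_range = c(90, 91.5),
                          dimer_tm_range = c(82, 86),
                          blood_dimer_prob = 0.5,
                          lcl_extra_peak_prob = 0.5,
                          meth_noise_sd = 2.6,
                          lcl_decorrelation = 0.8,
                          passage_effect_range = c(2, 8),
                          n_cycles = 50) {
  check_number(n_blood, "n_blood", min = 0)
  check_number(n_lcl, "n_lcl", min = 0)
  check_number(seed, "seed")
  check_number(genomes_per_reaction, "genomes_per_reaction", min = 0, allow_min = FALSE)
  check_number(genomes_cv, "genomes_cv", min = 0)
  check_range <- function(r, name, lo = -Inf, hi = Inf) {
    if (!is.numeric(r) || length(r) != 2 || any(!is.finite(r)) ||
        r[1] > r[2] || r[1] < lo || r[2] > hi) {
      stop_config(sprintf("`%s` must be a finite increasing pair within [%g, %g]",
                          name, lo, hi))
    }
  }
  check_range(lcl_ebv_range, "lcl_ebv_range", lo = 0)
  check_range(blood_ebv_range, "blood_ebv_range", lo = 0)
  check_number(blood_ebv_zero_prob, "blood_ebv_zero_prob", min = 0, max = 1)
  check_range(t_cell_range, "t_cell_range", lo = 0, hi = 1)
  if (n_blood > 0 && t_cell_range[1] <= 0) {
    stop_config("`t_cell_range` must be strictly positive: blood carries rearranged TCR")
  }
  check_range(age_range, "age_range", lo = 0)
  check_number(efficiency, "efficiency", min = 1, max = 2, allow_min = FALSE)
  check_number(fluor_noise_sd, "fluor_noise_sd", min = 0)
  check_number(ct_jitter_sd, "ct_jitter_sd", min = 0)
  check_range(blood_tm_range, "blood_tm_range", lo = 65, hi = 95)
  check_range(dimer_tm_range, "dimer_tm_range", lo = 65, hi = 95)
  check_number(blood_dimer_prob, "blood_dimer_prob", min = 0, max = 1)
  check_number(lcl_extra_peak_prob, "lcl_extra_peak_prob", min = 0, max = 1)
  check_number(meth_noise_sd, "meth_noise_sd", min = 0)
  check_number(lcl_decorrelation, "lcl_decorrelation", min = 0, max = 1)
  check_range(passage_effect_range, "passage_effect_range", lo = 0)
  check_number(n_cycles, "n_cycles", min = 10)

  structure(
    list(
      n_blood = as.integer(n_blood), n_lcl = as.integer(n_lcl),
      seed = as.integer(seed),
      genomes_per_reaction = genomes_per_reaction, genomes_cv = genomes_cv,
      lcl_ebv_range = lcl_ebv_range, blood_ebv_range = blood_ebv_range,
      blood_ebv_zero_prob = blood_ebv_zero_prob,
      t_cell_range = t_cell_range, age_range = age_range,
      efficiency = efficiency, plateau = plateau,
      half_max_copies = half_max_copies,
      fluor_noise_sd = fluor_noise_sd, ct_jitter_sd = ct_jitter_sd,
      blood_tm_range = blood_tm_range, dimer_tm_range = dimer_tm_range,
      blood_dimer_prob = blood_dimer_prob,
      lcl_extra_peak_prob = lcl_extra_peak_prob,
      meth_noise_sd = meth_noise_sd, lcl_decorrelation = lcl_decorrelation,
      passage_effect_range = passage_effect_range,
      n_cycles = as.integer(n_cycles)
    ),
    class = "cohort_config"
  )
}

#' Generate a ground-truth-labelled synthetic blood/LCL cohort
#'
#' Draws per-sample ground truth (tissue, input amount, EBV load, T-cell
#' fraction, age, passage effect), then renders for every sample the raw
#' signals the real assay panel would measure: GAPDH, EBV and TCR-gamma
#' amplification curves (template copies implied by the truth: 2 GAPDH
#' alleles per genome, `ebv_copies_per_genome` EBV targets, one rearranged
#' TCR-gamma target per T cell), a TCR-beta melting curve, and a
#' three-CpG methylation profile.  Blood methylation is the analytic
#' inverse of the age model plus noise; LCL methylation is decorrelated
#' from age and shifted by the passage effect.
#'
#' Randomness is fully determined by `config$seed`: four per-stage streams
#' (truth, amplification, melt, methylation) are derived from it, so the
#' same configuration reproduces the identical cohort.
#'
#' @param config A [cohort_config()].
#' @return A list of class `"origin_cohort"` with tibbles
#'   \describe{
#'     \item{`truth`}{one row per sample: `sample_id`, `tissue`,
#'       `diploid_genomes_per_reaction`, `ebv_copies_per_genome`,
#'       `t_cell_fraction`, `chronological_age`, `passage_effect`.}
#'     \item{`curves`}{long table of every raw signal: `sample_id`,
#'       `assay`, `x_kind` (`"cycle"` or `"temperature_C"`), `x`,
#'       `fluorescence`.}
#'     \item{`methylation`}{`sample_id`, `elovl2_cpg5`, `klf14_cpg2`,
#'       `trim59_cpg5`, `chronological_age`, `tissue`.}
#'   }
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_blood = 3, n_lcl = 3, seed = 7))
#' cohort$truth
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    stop_config("`config` must be created by cohort_config()")
  }
  n <- config$n_blood + config$n_lcl
  empty <- list(
    truth = tibble(
      sample_id = character(), tissue = character(),
      diploid_genomes_per_reaction = numeric(),
      ebv_copies_per_genome = numeric(), t_cell_fraction = numeric(),
      chronological_age = numeric(), passage_effect = numeric()
    ),
    curves = tibble(sample_id = character(), assay = character(),
                    x_kind = character(), x = numeric(),
                    fluorescence = numeric()),
    methylation = tibble(sample_id = character(), elovl2_cpg5 = numeric(),
                         klf14_cpg2 = numeric(), trim59_cpg5 = numeric(),
                         chronological_age = numeric(), tissue = character())
  )
  if (n == 0) return(structure(c(empty, list(config = config)),
                               class = "origin_cohort"))

  truth <- withr::with_seed(derive_seed(config$seed, 1), draw_truth(config))
  curves <- withr::with_seed(derive_seed(config$seed, 2),
                             draw_amplification(truth, config))
  melts <- withr::with_seed(derive_seed(config$seed, 3),
                            draw_melts(truth, config))
  methylation <- withr::with_seed(derive_seed(config$seed, 4),
                                  draw_methylation(truth, config))

  structure(
    list(truth = truth,
         curves = bind_rows(curves, melts),
         methylation = methylation,
         config = config),
    class = "origin_cohort"
  )
}

#' @export
print.origin_cohort <- function(x, ...) {
  cat(sprintf(
    "<origin_cohort> %d samples (%d blood, %d LCL), %d raw signal points\n",
    nrow(x$truth), sum(x$truth$tissue == "blood"),
    sum(x$truth$tissue == "LCL"), nrow(x$curves)
  ))
  invisible(x)
}

# --- internal draw stages ----------------------------------------------------

runif_log <- function(n, range) {
  exp(runif(n, log(range[1]), log(range[2])))
}

draw_truth <- function(cfg) {
  n <- cfg$n_blood + cfg$n_lcl
  tissue <- rep(c("blood", "LCL"), c(cfg$n_blood, cfg$n_lcl))
  genomes <- cfg$genomes_per_reaction *
    exp(rnorm(n, sd = sqrt(log(1 + cfg$genomes_cv^2))))
  ebv <- numeric(n)
  tcell <- numeric(n)
  is_blood <- tissue == "blood"
  nb <- sum(is_blood)
  if (nb > 0) {
    has_trace <- runif(nb) >= cfg$blood_ebv_zero_prob
    trace <- runif_log(nb, cfg$blood_ebv_range)
    ebv[is_blood] <- ifelse(has_trace, trace, 0)
    tcell[is_blood] <- runif(nb, cfg$t_cell_range[1], cfg$t_cell_range[2])
  }
  if (n - nb > 0) {
    ebv[!is_blood] <- runif_log(n - nb, cfg$lcl_ebv_range)
  }
  age <- runif(n, cfg$age_range[1], cfg$age_range[2])
  passage <- ifelse(is_blood, 0,
                    runif(n, cfg$passage_effect_range[1],
                          cfg$passage_effect_range[2]))
  tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    tissue = tissue,
    diploid_genomes_per_reaction = genomes,
    ebv_copies_per_genome = ebv,
    t_cell_fraction = tcell,
    chronological_age = age,
    passage_effect = passage
  )
}

draw_amplification <- function(truth, cfg) {
  per_sample <- function(i) {
    g <- truth$diploid_genomes_per_reaction[i]
    copies <- c(
      GAPDH = g * 2, # two alleles per diploid genome
      EBV = g * truth$ebv_copies_per_genome[i],
      TCRG = g * truth$t_cell_fraction[i]
    )
    purrr::map(names(copies), function(a) {
      jitter <- if (cfg$ct_jitter_sd > 0) {
        cfg$efficiency^rnorm(1, sd = cfg$ct_jitter_sd)
      } else 1
      simulate_amplification(
        template_copies = copies[[a]] * jitter,
        efficiency = cfg$efficiency, plateau = cfg$plateau,
        half_max_copies = cfg$half_max_copies,
        noise_sd = cfg$fluor_noise_sd, n_cycles = cfg$n_cycles,
        sample_id = truth$sample_id[i], assay = a
      )
    })
  }
  purrr::map(seq_len(nrow(truth)), per_sample) |>
    purrr::flatten() |>
    bind_rows() |>
    mutate(x_kind = "cycle") |>
    rename(x = "cycle") |>
    select("sample_id", "assay", "x_kind", "x", "fluorescence")
}

draw_melts <- function(truth, cfg) {
  per_sample <- function(i) {
    if (truth$tissue[i] == "blood") {
      prods <- tibble(tm = runif(1, cfg$blood_tm_range[1], cfg$blood_tm_range[2]),
                      fraction = runif(1, 0.5, 0.8))
      if (runif(1) < cfg$blood_dimer_prob) {
        prods <- bind_rows(prods, tibble(
          tm = runif(1, cfg$dimer_tm_range[1], cfg$dimer_tm_range[2]),
          fraction = runif(1, 0.1, 0.2)
        ))
      }
    } else {
      n_peaks <- 1 + (runif(1) < cfg$lcl_extra_peak_prob)
      tms <- runif(n_peaks, cfg$dimer_tm_range[1], cfg$dimer_tm_range[2])
      # keep non-specific peaks resolvable on the 0.2 C grid
      if (n_peaks == 2 && abs(diff(tms)) < 1.5) tms[2] <- tms[1] + 1.5
      prods <- tibble(tm = pmin(tms, 89),
                      fraction = runif(n_peaks, 0.15, 0.35))
    }
    simulate_melt(prods, noise_sd = cfg$fluor_noise_sd,
                  sample_id = truth$sample_id[i], assay = "TCRB")
  }
  purrr::map(seq_len(nrow(truth)), per_sample) |>
    bind_rows() |>
    mutate(x_kind = "temperature_C") |>
    rename(x = "temperature") |>
    select("sample_id", "assay", "x_kind", "x", "fluorescence")
}

draw_methylation <- function(truth, cfg) {
  n <- nrow(truth)
  base <- clock_baseline()
  dir <- clock_direction()
  m <- matrix(0, nrow = n, ncol = 3)
  for (j in seq_along(base)) {
    m[, j] <- base[j] + truth$chronological_age * dir[j]
  }
  is_lcl <- truth$tissue == "LCL"
  if (any(is_lcl)) {
    lambda <- cfg$lcl_decorrelation
    for (j in seq_along(base)) {
      decor <- runif(sum(is_lcl), base[j], base[j] + 100 * dir[j])
      m[is_lcl, j] <- (1 - lambda) * m[is_lcl, j] + lambda * decor +
        truth$passage_effect[is_lcl]
    }
  }
  if (cfg$meth_noise_sd > 0) {
    m <- m + matrix(rnorm(n * 3, sd = cfg$meth_noise_sd), nrow = n)
  }
  m <- pmin(pmax(m, 0), 100)
  tibble(
    sample_id = truth$sample_id,
    elovl2_cpg5 = m[, 1], klf14_cpg2 = m[, 2], trim59_cpg5 = m[, 3],
    chronological_age = truth$chronological_age,
    tissue = truth$tissue
  )
}
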