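#' Run the full tissue-of-origin pipeline on a synthetic cohort
#'
#' Chains every stage end to end: simulate a labelled cohort, call Cts and
#' melting peaks from the raw curves, impute no-amplification sentinels,
#' classify each sample with the three assays and the two-of-three vote,
#' evaluate the per-assay and combined calls against the ground truth, and
#' run the methylation age model per tissue group.
#'
#' @param config A [cohort_config()] describing the cohort.
#' @param thresholds A [threshold_config()].
#' @param min_amplitude,min_prominence Signal-calling criteria passed to
#'   [call_panels()].
#' @return A list of class `"origin_pipeline"`:
#'   \describe{
#'     \item{`cohort`}{the simulated `"origin_cohort"`.}
#'     \item{`panels`}{per-sample called values.}
#'     \item{`calls`}{per-sample classification joined with the truth.}
#'     \item{`evaluation`}{named list of `"binary_eval"` objects for the
#'       `ebv`, `tcrg`, `tcrb` tests alone and `combined`.}
#'     \item{`age`}{an `"age_eval"` per-tissue summary.}
#'   }
#' @examples
#' \donttest{
#' res <- run_origin_pipeline(cohort_config(n_blood = 50, n_lcl = 50, seed = 1))
#' res$evaluation$combined
#' res$age
#' }
#' @export
run_origin_pipeline <- function(config = cohort_config(),
                                thresholds = threshold_config(),
                                min_amplitude = 0.5,
                                min_prominence = 0.5) {
  cohort <- simulate_cohort(config)
  panels <- call_panels(cohort$curves, min_amplitude = min_amplitude,
                        min_prominence = min_prominence)
  calls <- classify_samples(panels, thresholds) |>
    left_join(select(cohort$truth, "sample_id", "tissue",
                     "chronological_age"),
              by = "sample_id")
  evaluation <- list(
    ebv = evaluate_binary(calls, truth = tissue, estimate = ebv_call),
    tcrg = evaluate_binary(calls, truth = tissue, estimate = tcrg_call),
    tcrb = evaluate_binary(calls, truth = tissue, estimate = tcrb_call),
    combined = evaluate_binary(calls, truth = tissue, estimate = combined)
  )
  age <- evaluate_age(predict_age(cohort$methylation))
  structure(
    list(cohort = cohort, panels = panels, calls = calls,
         evaluation = evaluation, age = age),
    class = "origin_pipeline"
  )
}

#' @export
print.origin_pipeline <- function(x, ...) {
  print(x$cohort)
  counts <- table(factor(x$calls$combined,
                         levels = c(.call_levels, "unclassifiable")))
  cat(sprintf("  combined calls: %s\n",
              paste(sprintf("%s %d", names(counts), counts), collapse = ", ")))
  cat("\nCombined test vs ground truth:\n")
  print(x$evaluation$combined)
  cat("\n")
  print(x$age)
  invisible(x)
}
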