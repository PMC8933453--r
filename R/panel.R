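#' Build per-sample assay panels from raw curve tables
#'
#' Reduces the long table of raw signals to one row of called values per
#' sample: Cts for GAPDH, EBV and TCR-gamma via the
#' second-derivative-maximum caller, and the highest TCR-beta melting
#' temperature via melt-peak extraction.  Reactions with no amplification
#' are imputed at the panel's conventional sentinel Cts — 40 cycles for
#' EBV and 45 for TCR-gamma — so that the downstream ratio tests remain
#' computable; the imputation is flagged.  GAPDH is the amplifiability
#' control: a sample whose GAPDH reaction fails is reported with
#' `ct_gapdh = NA` and cannot be classified.
#'
#' @param curves Long-format curve table with columns `sample_id`,
#'   `assay` (`"GAPDH"`, `"EBV"`, `"TCRG"` amplification and `"TCRB"`
#'   melt), `x_kind` (`"cycle"` or `"temperature_C"`), `x`,
#'   `fluorescence` — the schema written by [simulate_cohort()] /
#'   [write_cohort()].
#' @param min_amplitude Amplification-call amplitude criterion passed to
#'   [call_ct()].
#' @param min_prominence Melt-peak prominence criterion passed to
#'   [extract_tm_peaks()].
#' @return A tibble with one row per sample: `sample_id`, `ct_gapdh`,
#'   `ct_ebv`, `ebv_imputed`, `ct_tcrg`, `tcrg_imputed`, `tcrb_max_tm`
#'   (`NA` when no peak), `tcrb_no_peak`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_blood = 2, n_lcl = 2, seed = 3))
#' call_panels(cohort$curves)
#' @export
call_panels <- function(curves, min_amplitude = 0.5, min_prominence = 0.5) {
  curves <- as_tibble(curves)
  needed <- c("sample_id", "assay", "x_kind", "x", "fluorescence")
  if (!all(needed %in% names(curves))) {
    stop_input(sprintf("`curves` must have columns %s",
                       paste(needed, collapse = ", ")))
  }
  ids <- unique(curves$sample_id)
  if (length(ids) == 0) {
    return(tibble(
      sample_id = character(), ct_gapdh = numeric(), ct_ebv = numeric(),
      ebv_imputed = logical(), ct_tcrg = numeric(), tcrg_imputed = logical(),
      tcrb_max_tm = numeric(), tcrb_no_peak = logical()
    ))
  }

  one_ct <- function(sub) {
    if (nrow(sub) == 0) return(NA_real_)
    res <- call_ct(rename(sub, cycle = "x"), min_amplitude = min_amplitude)
    res$ct
  }
  one_sample <- function(id) {
    s <- curves[curves$sample_id == id, ]
    ct_g <- one_ct(s[s$assay == "GAPDH" & s$x_kind == "cycle", ])
    ct_e <- one_ct(s[s$assay == "EBV" & s$x_kind == "cycle", ])
    ct_t <- one_ct(s[s$assay == "TCRG" & s$x_kind == "cycle", ])
    melt <- s[s$assay == "TCRB" & s$x_kind == "temperature_C", ]
    tm <- if (nrow(melt)) {
      max_tm(extract_tm_peaks(rename(melt, temperature = "x"),
                              min_prominence = min_prominence))
    } else NA_real_
    tibble(
      sample_id = id,
      ct_gapdh = ct_g,
      ct_ebv = if_else(is.na(ct_e), .imputed_ct[["EBV"]], ct_e),
      ebv_imputed = is.na(ct_e),
      ct_tcrg = if_else(is.na(ct_t), .imputed_ct[["TCRG"]], ct_t),
      tcrg_imputed = is.na(ct_t),
      tcrb_max_tm = tm,
      tcrb_no_peak = is.na(tm)
    )
  }
  purrr::map(ids, one_sample) |> bind_rows()
}
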