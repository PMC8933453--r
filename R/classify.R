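#' Decision thresholds for the tissue-of-origin tests
#'
#' The three assays are scored against fixed empirical thresholds.  EBV
#' and TCR-gamma use GAPDH-normalised Ct ratios on a x100 scale (see
#' [ct_ratio()]); each has a pair of thresholds delimiting an abstention
#' band, so every sample maps to blood, LCL or uncertain.  TCR-beta uses a
#' single cutoff on the highest melting temperature: a specific rearranged
#' product melts above it, primer dimers and non-specific products below.
#'
#' Default orientation of the rules:
#' \itemize{
#'   \item EBV ratio below `ebv_lower` (91) means blood (little or no EBV,
#'     so a late or imputed EBV Ct deflates the ratio); above `ebv_upper`
#'     (110) means LCL (high episomal load, early EBV Ct); between, the
#'     call is withheld.
#'   \item TCR-gamma mirrors this: a ratio above `tcrg_upper` (80) means
#'     blood (rearranged TCR-gamma amplifies, an earlier Ct inflates the
#'     ratio); below `tcrg_lower` (70) means LCL.
#'   \item TCR-beta highest Tm strictly above `tcrb_tm_cutoff` (89.5
#'     degrees C) means blood; at or below (or no peak at all) means LCL.
#' }
#' The EBV pair and the Tm cutoff are the published operating points of
#' the assay panel; the TCR-gamma pair is not published and the default
#' was calibrated on the synthetic generator (see
#' [calibrate_tcrg_thresholds()] to refit it on labelled data).
#' Boundary values fall in the abstention band for the ratio tests and on
#' the LCL side for the Tm test.
#'
#' @param ebv_lower,ebv_upper EBV ratio thresholds (blood below, LCL
#'   above).
#' @param tcrg_lower,tcrg_upper TCR-gamma ratio thresholds (LCL below,
#'   blood above).
#' @param tcrb_tm_cutoff TCR-beta melting-temperature cutoff in degrees C.
#' @param ratio_scale Multiplier applied to the raw Ct ratio (default 100,
#'   the scale on which the EBV thresholds are expressed).
#' @return A validated list of class `"threshold_config"`.
#' @export
threshold_config <- function(ebv_lower = 91, ebv_upper = 110,
                             tcrg_lower = 70, tcrg_upper = 80,
                             tcrb_tm_cutoff = 89.5, ratio_scale = 100) {
  check_number(ebv_lower, "ebv_lower", min = 0, allow_min = FALSE)
  check_number(ebv_upper, "ebv_upper", min = 0, allow_min = FALSE)
  check_number(tcrg_lower, "tcrg_lower", min = 0, allow_min = FALSE)
  check_number(tcrg_upper, "tcrg_upper", min = 0, allow_min = FALSE)
  check_number(tcrb_tm_cutoff, "tcrb_tm_cutoff", min = 0, allow_min = FALSE)
  check_number(ratio_scale, "ratio_scale", min = 0, allow_min = FALSE)
  if (ebv_lower >= ebv_upper) stop_config("`ebv_lower` must be < `ebv_upper`")
  if (tcrg_lower >= tcrg_upper) stop_config("`tcrg_lower` must be < `tcrg_upper`")
  structure(
    list(ebv_lower = ebv_lower, ebv_upper = ebv_upper,
         tcrg_lower = tcrg_lower, tcrg_upper = tcrg_upper,
         tcrb_tm_cutoff = tcrb_tm_cutoff, ratio_scale = ratio_scale),
    class = "threshold_config"
  )
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("Tissue-of-origin thresholds\n")
  cat(sprintf("  EBV ratio      : blood < %g, LCL > %g (x%g scale)\n",
              x$ebv_lower, x$ebv_upper, x$ratio_scale))
  cat(sprintf("  TCR-gamma ratio: LCL < %g, blood > %g\n",
              x$tcrg_lower, x$tcrg_upper))
  cat(sprintf("  TCR-beta Tm    : blood > %g degrees C\n", x$tcrb_tm_cutoff))
  invisible(x)
}

#' GAPDH-normalised Ct ratio
#'
#' Scores a target assay against the single-copy GAPDH control as
#' `scale * ct_gapdh / ct_target`.  With GAPDH in the numerator, an
#' abundant target (early Ct) inflates the ratio above `scale` and an
#' absent target (late or imputed Ct) deflates it, which is the
#' orientation on which the EBV thresholds 91/110 are expressed.
#'
#' @param ct_gapdh,ct_target Numeric Ct vectors (cycles), recycled to a
#'   common length.
#' @param scale Ratio multiplier (default 100).
#' @return Numeric vector of ratios.
#' @examples
#' ct_ratio(25, 40) # EBV imputed at 40 -> 62.5, well below 91 -> blood
#' @export
ct_ratio <- function(ct_gapdh, ct_target, scale = 100) {
  if (any(!is.finite(ct_gapdh)) || any(!is.finite(ct_target))) {
    stop_input("Ct values must be finite")
  }
  if (any(ct_target == 0)) stop_input("target Ct of 0 is not a valid denominator")
  scale * ct_gapdh / ct_target
}

#' Per-assay three-way tissue calls
#'
#' Apply one assay's decision rule to its score, yielding `"blood"`,
#' `"LCL"` or `"uncertain"` per sample.  All three are vectorised.
#'
#' `classify_ebv()`: ratio strictly below `ebv_lower` is blood, strictly
#' above `ebv_upper` is LCL, the closed interval in between abstains.
#' `classify_tcrg()`: the mirror rule (above `tcrg_upper` is blood, below
#' `tcrg_lower` is LCL).  `classify_tcrb()`: highest Tm strictly above the
#' cutoff is blood; at or below the cutoff, or no peak at all (`NA`), is
#' LCL.
#'
#' @param ratio Numeric vector of [ct_ratio()] scores.
#' @param max_tm Numeric vector of highest melting temperatures; `NA`
#'   means no melting peak.
#' @param thresholds A [threshold_config()].
#' @return Character vector of labels.
#' @examples
#' classify_ebv(c(62.5, 100, 130))
#' classify_tcrb(c(90.2, 89.5, NA))
#' @export
classify_ebv <- function(ratio, thresholds = threshold_config()) {
  if (any(!is.finite(ratio))) stop_input("`ratio` must be finite")
  dplyr::case_when(
    ratio < thresholds$ebv_lower ~ "blood",
    ratio > thresholds$ebv_upper ~ "LCL",
    TRUE ~ "uncertain"
  )
}

#' @rdname classify_ebv
#' @export
classify_tcrg <- function(ratio, thresholds = threshold_config()) {
  if (any(!is.finite(ratio))) stop_input("`ratio` must be finite")
  dplyr::case_when(
    ratio > thresholds$tcrg_upper ~ "blood",
    ratio < thresholds$tcrg_lower ~ "LCL",
    TRUE ~ "uncertain"
  )
}

#' @rdname classify_ebv
#' @export
classify_tcrb <- function(max_tm, thresholds = threshold_config()) {
  dplyr::case_when(
    is.na(max_tm) ~ "LCL",
    max_tm > thresholds$tcrb_tm_cutoff ~ "blood",
    TRUE ~ "LCL"
  )
}

#' Combine three per-assay calls by two-of-three vote
#'
#' A sample is called blood when at least two of the three assays vote
#' blood; symmetrically it is called LCL when at least two vote LCL; any
#' other vote pattern (discordant singletons and abstentions) leaves the
#' sample uncertain.  Requiring two concordant positive tests is what
#' drives false-positive blood calls to zero: a single spurious assay
#' cannot flip the combined call.
#'
#' @param ebv,tcrg,tcrb Character vectors of per-assay labels
#'   (`"blood"`, `"LCL"` or `"uncertain"`), recycled to a common length.
#' @return A tibble with columns `votes_blood`, `votes_lcl`, `combined`.
#' @examples
#' combine_calls("blood", "blood", "LCL")     # blood
#' combine_calls("blood", "LCL", "uncertain") # uncertain
#' @export
combine_calls <- function(ebv, tcrg, tcrb) {
  len <- max(length(ebv), length(tcrg), length(tcrb))
  labels <- list(ebv = rep_len(ebv, len), tcrg = rep_len(tcrg, len),
                 tcrb = rep_len(tcrb, len))
  bad <- !unlist(labels) %in% .call_levels
  if (any(bad)) {
    stop_input(sprintf("labels must be one of %s",
                       paste(.call_levels, collapse = ", ")))
  }
  votes_blood <- (labels$ebv == "blood") + (labels$tcrg == "blood") +
    (labels$tcrb == "blood")
  votes_lcl <- (labels$ebv == "LCL") + (labels$tcrg == "LCL") +
    (labels$tcrb == "LCL")
  tibble(
    votes_blood = as.integer(votes_blood),
    votes_lcl = as.integer(votes_lcl),
    combined = dplyr::case_when(
      votes_blood >= 2 ~ "blood",
      votes_lcl >= 2 ~ "LCL",
      TRUE ~ "uncertain"
    )
  )
}

#' Classify an assay-panel table into tissue-of-origin calls
#'
#' Takes per-sample called values — GAPDH, EBV and TCR-gamma Cts (with
#' no-amplification values already imputed, see [call_panels()]) and the
#' highest TCR-beta melting temperature — computes the two GAPDH-normalised
#' ratios, applies the three per-assay rules and the two-of-three vote.
#'
#' Samples whose GAPDH Ct is missing cannot be normalised and are returned
#' with `NA` scores and an `"unclassifiable"` combined label (a warning
#' lists them); all other samples are still processed.
#'
#' @param panels A data frame with columns `sample_id`, `ct_gapdh`,
#'   `ct_ebv`, `ct_tcrg`, `tcrb_max_tm` (as produced by [call_panels()];
#'   extra columns are ignored).
#' @param thresholds A [threshold_config()].
#' @return A tibble with one row per panel: `sample_id`, `ebv_ratio`,
#'   `tcrg_ratio`, `tcrb_max_tm`, `ebv_call`, `tcrg_call`, `tcrb_call`,
#'   `votes_blood`, `votes_lcl`, `combined`.
#' @examples
#' classify_samples(data.frame(
#'   sample_id = "S1", ct_gapdh = 25, ct_ebv = 40, ct_tcrg = 28,
#'   tcrb_max_tm = 90.2
#' ))
#' @export
classify_samples <- function(panels, thresholds = threshold_config()) {
  panels <- as_tibble(panels)
  needed <- c("sample_id", "ct_gapdh", "ct_ebv", "ct_tcrg", "tcrb_max_tm")
  missing_cols <- setdiff(needed, names(panels))
  if (length(missing_cols)) {
    stop_input(sprintf("`panels` is missing columns: %s",
                       paste(missing_cols, collapse = ", ")))
  }
  if (nrow(panels) == 0) {
    return(tibble(
      sample_id = character(), ebv_ratio = numeric(), tcrg_ratio = numeric(),
      tcrb_max_tm = numeric(), ebv_call = character(),
      tcrg_call = character(), tcrb_call = character(),
      votes_blood = integer(), votes_lcl = integer(), combined = character()
    ))
  }
  ok <- is.finite(panels$ct_gapdh) & is.finite(panels$ct_ebv) &
    is.finite(panels$ct_tcrg)
  if (any(!ok)) {
    warn(sprintf(
      "%d sample(s) lack a usable GAPDH/EBV/TCR-gamma Ct and are unclassifiable: %s",
      sum(!ok), paste(utils::head(panels$sample_id[!ok], 5), collapse = ", ")
    ))
  }
  out <- tibble(
    sample_id = panels$sample_id,
    ebv_ratio = NA_real_, tcrg_ratio = NA_real_,
    tcrb_max_tm = panels$tcrb_max_tm,
    ebv_call = NA_character_, tcrg_call = NA_character_,
    tcrb_call = NA_character_,
    votes_blood = NA_integer_, votes_lcl = NA_integer_,
    combined = "unclassifiable"
  )
  if (any(ok)) {
    p <- panels[ok, ]
    ebv_ratio <- ct_ratio(p$ct_gapdh, p$ct_ebv, thresholds$ratio_scale)
    tcrg_ratio <- ct_ratio(p$ct_gapdh, p$ct_tcrg, thresholds$ratio_scale)
    ebv_call <- classify_ebv(ebv_ratio, thresholds)
    tcrg_call <- classify_tcrg(tcrg_ratio, thresholds)
    tcrb_call <- classify_tcrb(p$tcrb_max_tm, thresholds)
    votes <- combine_calls(ebv_call, tcrg_call, tcrb_call)
    out[ok, c("ebv_ratio", "tcrg_ratio")] <- tibble(ebv_ratio, tcrg_ratio)
    out[ok, c("ebv_call", "tcrg_call", "tcrb_call")] <-
      tibble(ebv_call, tcrg_call, tcrb_call)
    out[ok, c("votes_blood", "votes_lcl", "combined")] <- votes
  }
  out
}

#' Calibrate the unpublished TCR-gamma ratio thresholds from labelled data
#'
#' The TCR-gamma rule needs a lower (LCL) and upper (blood) ratio
#' threshold, but no published operating point exists for them.  Given a
#' labelled calibration cohort this helper chooses the single cut
#' maximising accuracy of the two-way rule and then places the abstention
#' band inside the empirical gap between the classes: the band spans the
#' middle half of the interval between the highest LCL ratio and the
#' lowest blood ratio below/above that cut.  If the classes overlap the
#' band collapses to a narrow interval around the optimal cut.
#'
#' @param data A data frame of labelled calibration samples.
#' @param ratio,tissue Columns holding the TCR-gamma ratio and the true
#'   tissue (`"blood"`/`"LCL"`), tidy-eval.
#' @return A list with `tcrg_lower` and `tcrg_upper`, ready to splice into
#'   [threshold_config()].
#' @export
calibrate_tcrg_thresholds <- function(data, ratio = tcrg_ratio,
                                      tissue = tissue) {
  data <- as_tibble(data)
  r <- dplyr::pull(data, {{ ratio }})
  tt <- dplyr::pull(data, {{ tissue }})
  if (!all(tt %in% .tissue_levels)) {
    stop_input("`tissue` must contain only blood/LCL labels")
  }
  if (length(unique(tt)) < 2) {
    stop_input("calibration needs both blood and LCL samples")
  }
  cuts <- sort(unique(r))
  cuts <- (utils::head(cuts, -1) + utils::tail(cuts, -1)) / 2
  acc <- vapply(cuts, function(cc) {
    mean((r > cc & tt == "blood") | (r < cc & tt == "LCL"))
  }, numeric(1))
  cut <- cuts[which.max(acc)]
  lcl_top <- suppressWarnings(max(r[tt == "LCL" & r < cut]))
  blood_bot <- suppressWarnings(min(r[tt == "blood" & r > cut]))
  if (is.finite(lcl_top) && is.finite(blood_bot) && lcl_top < blood_bot) {
    gap <- blood_bot - lcl_top
    list(tcrg_lower = lcl_top + 0.25 * gap,
         tcrg_upper = blood_bot - 0.25 * gap)
  } else {
    list(tcrg_lower = cut - 0.5, tcrg_upper = cut + 0.5)
  }
}
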