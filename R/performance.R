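#' Diagnostic performance of blood calls against known tissue
#'
#' Scores the three-way calls as a binary diagnostic test for blood under
#' the convention used throughout this panel: a call of `"blood"` is a
#' positive result, while `"LCL"` and `"uncertain"` (and any
#' unclassifiable sample) are negative — abstaining on a true blood
#' sample therefore costs sensitivity, and an uncertain call on an LCL
#' sample still counts as a correct negative.  Truth must be two-way
#' (blood or LCL).
#'
#' Metrics follow the standard definitions: sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), PPV = TP/(TP+FP), NPV = TN/(TN+FN) (all as
#' percentages), accuracy = (TP+TN)/n (a proportion).  A metric whose
#' denominator is zero is reported as `NA` (undefined), not as 0.
#'
#' @param data A data frame holding one row per evaluated sample.
#' @param truth,estimate Columns with the true tissue (`"blood"`/`"LCL"`)
#'   and the test's call (tidy-eval; defaults `tissue` and `combined`).
#' @return An object of class `"binary_eval"`: a list with the confusion
#'   counts (`tp`, `fp`, `tn`, `fn`) and full-precision metrics.  Use
#'   [tidy()] for a per-metric tibble with display rounding (percentages
#'   to 1 decimal, accuracy to 3), [glance()] for a one-row summary, and
#'   `print()` for a report-style line.
#' @examples
#' calls <- data.frame(
#'   tissue = c("blood", "blood", "LCL", "LCL"),
#'   combined = c("blood", "uncertain", "LCL", "LCL")
#' )
#' evaluate_binary(calls)
#' @export
evaluate_binary <- function(data, truth = tissue, estimate = combined) {
  data <- as_tibble(data)
  tr <- dplyr::pull(data, {{ truth }})
  est <- dplyr::pull(data, {{ estimate }})
  if (length(tr) != length(est)) stop_input("truth and estimate lengths differ")
  if (!all(tr %in% .tissue_levels)) {
    stop_input("truth labels must be 'blood' or 'LCL' only")
  }
  positive <- est == "blood" & !is.na(est)
  binary_eval(
    tp = sum(positive & tr == "blood"),
    fp = sum(positive & tr == "LCL"),
    tn = sum(!positive & tr == "LCL"),
    fn = sum(!positive & tr == "blood")
  )
}

#' Construct a diagnostic evaluation from confusion-matrix counts
#'
#' Builds the same object as [evaluate_binary()] directly from
#' true/false-positive/negative counts, for use when only a published
#' confusion matrix (not per-sample labels) is available.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A `"binary_eval"` object; see [evaluate_binary()].
#' @examples
#' binary_eval(tp = 450, fn = 7, tn = 316, fp = 0)
#' @export
binary_eval <- function(tp, fp, tn, fn) {
  for (nm in c("tp", "fp", "tn", "fn")) {
    check_number(get(nm), nm, min = 0)
  }
  ratio_or_na <- function(num, den) if (den > 0) num / den else NA_real_
  structure(
    list(
      tp = tp, fp = fp, tn = tn, fn = fn,
      n = tp + fp + tn + fn,
      sensitivity = 100 * ratio_or_na(tp, tp + fn),
      specificity = 100 * ratio_or_na(tn, tn + fp),
      ppv = 100 * ratio_or_na(tp, tp + fp),
      npv = 100 * ratio_or_na(tn, tn + fn),
      accuracy = ratio_or_na(tp + tn, tp + fp + tn + fn)
    ),
    class = "binary_eval"
  )
}

#' @export
print.binary_eval <- function(x, ...) {
  fmt_pct <- function(v) if (is.na(v)) "  NA " else sprintf("%5.1f", v)
  cat("Tissue-of-origin test evaluation (blood = positive)\n")
  cat(sprintf("  n = %d  (TP %d, FP %d, TN %d, FN %d)\n",
              x$n, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf(
    "  Sensitivity %s%%  Specificity %s%%  PPV %s%%  NPV %s%%  Accuracy %s\n",
    fmt_pct(x$sensitivity), fmt_pct(x$specificity), fmt_pct(x$ppv),
    fmt_pct(x$npv), if (is.na(x$accuracy)) "NA" else sprintf("%.3f", x$accuracy)
  ))
  invisible(x)
}

#' Tidiers for tissueorigin result objects
#'
#' [tidy()] returns per-component rows; [glance()] returns a one-row
#' summary.  For `binary_eval`, `tidy()` carries both the full-precision
#' value and the conventional display rounding (percentages to 1 decimal
#' place, accuracy to 3).
#'
#' @param x A `binary_eval`, `origin_concordance` or `age_eval` object.
#' @param ... Unused.
#' @name tissueorigin-tidiers
#' @method tidy binary_eval
#' @export
tidy.binary_eval <- function(x, ...) {
  metrics <- c("sensitivity", "specificity", "ppv", "npv", "accuracy")
  value <- unlist(x[metrics], use.names = FALSE)
  tibble(
    metric = metrics,
    value = value,
    display = mapply(round, value, c(1, 1, 1, 1, 3)),
    unit = c(rep("percent", 4), "proportion")
  )
}

#' @rdname tissueorigin-tidiers
#' @method glance binary_eval
#' @export
glance.binary_eval <- function(x, ...) {
  as_tibble(x[c("tp", "fp", "tn", "fn", "n", "sensitivity", "specificity",
                "ppv", "npv", "accuracy")])
}

#' Concordance between test calls and database annotation
#'
#' Cross-tabulates the combined tissue-of-origin calls against a recorded
#' annotation that may itself be missing or uncertain, the situation of a
#' legacy biobank whose records need verifying.  Annotation classes are
#' `"blood"`, `"LCL"` and `"unknown"`; calls are `"blood"`, `"LCL"` and
#' `"uncertain"`.
#'
#' Summaries reported:
#' \itemize{
#'   \item per-row rates: for annotated rows the fraction of calls that
#'     agree with the record; for the unknown row the fraction still
#'     uncertain after testing;
#'   \item overall concordance: agreeing calls over all annotated samples;
#'   \item identified rate: unknown-annotation samples resolved to blood
#'     or LCL;
#'   \item the count and rate of samples left uncertain overall.
#' }
#'
#' @param data A data frame with one row per sample.
#' @param annotation,estimate Columns with the recorded origin
#'   (`"blood"`/`"LCL"`/`"unknown"`) and the test call (tidy-eval;
#'   defaults `annotation`, `combined`).
#' @return An object of class `"origin_concordance"` wrapping the 3x3
#'   count table and the summary rates; `tidy()` gives the long cell
#'   table, `glance()` the one-row summary.
#' @examples
#' d <- data.frame(
#'   annotation = c("blood", "blood", "LCL", "unknown"),
#'   combined = c("blood", "uncertain", "LCL", "blood")
#' )
#' concordance(d)
#' @export
concordance <- function(data, annotation = annotation, estimate = combined) {
  data <- as_tibble(data)
  ann <- dplyr::pull(data, {{ annotation }})
  est <- dplyr::pull(data, {{ estimate }})
  if (length(ann) != length(est)) {
    stop_input("annotation and estimate lengths differ")
  }
  ann[is.na(ann) | ann %in% c("uncertain", "missing")] <- "unknown"
  if (!all(ann %in% c(.tissue_levels, "unknown"))) {
    stop_input("annotations must be 'blood', 'LCL' or 'unknown'/missing")
  }
  est[is.na(est) | est == "unclassifiable"] <- "uncertain"
  if (!all(est %in% .call_levels)) {
    stop_input("calls must be 'blood', 'LCL' or 'uncertain'")
  }
  ann <- factor(ann, levels = c("blood", "LCL", "unknown"))
  est <- factor(est, levels = .call_levels)
  counts <- table(annotation = ann, call = est)

  row_n <- rowSums(counts)
  rate_or_na <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  row_rate <- c(
    blood = rate_or_na(counts["blood", "blood"], row_n[["blood"]]),
    LCL = rate_or_na(counts["LCL", "LCL"], row_n[["LCL"]]),
    unknown = rate_or_na(counts["unknown", "uncertain"], row_n[["unknown"]])
  )
  n_annotated <- row_n[["blood"]] + row_n[["LCL"]]
  structure(
    list(
      counts = counts,
      n_total = length(ann),
      n_annotated = n_annotated,
      n_unknown = row_n[["unknown"]],
      row_rate = row_rate,
      overall_concordance = rate_or_na(
        counts["blood", "blood"] + counts["LCL", "LCL"], n_annotated
      ),
      identified_rate = rate_or_na(
        counts["unknown", "blood"] + counts["unknown", "LCL"],
        row_n[["unknown"]]
      ),
      n_uncertain = sum(counts[, "uncertain"]),
      uncertain_rate = rate_or_na(sum(counts[, "uncertain"]), length(ann))
    ),
    class = "origin_concordance"
  )
}

#' @export
print.origin_concordance <- function(x, ...) {
  cat("Concordance between recorded origin and tissue-of-origin calls\n")
  print(x$counts)
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", v)
  cat(sprintf("  Overall concordance (annotated, n = %d): %s\n",
              x$n_annotated, fmt(x$overall_concordance)))
  cat(sprintf("  Identified among unknown (n = %d): %s\n",
              x$n_unknown, fmt(x$identified_rate)))
  cat(sprintf("  Still uncertain: %d / %d (%s)\n",
              x$n_uncertain, x$n_total, fmt(x$uncertain_rate)))
  invisible(x)
}

#' @rdname tissueorigin-tidiers
#' @method tidy origin_concordance
#' @export
tidy.origin_concordance <- function(x, ...) {
  as_tibble(as.data.frame(x$counts, responseName = "n")) |>
    mutate(annotation = as.character(.data$annotation),
           call = as.character(.data$call))
}

#' @rdname tissueorigin-tidiers
#' @method glance origin_concordance
#' @export
glance.origin_concordance <- function(x, ...) {
  tibble(
    n_total = x$n_total,
    n_annotated = x$n_annotated,
    n_unknown = x$n_unknown,
    overall_concordance = x$overall_concordance,
    identified_rate = x$identified_rate,
    n_uncertain = x$n_uncertain,
    uncertain_rate = x$uncertain_rate
  )
}
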