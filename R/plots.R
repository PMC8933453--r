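#' Marker-distribution histograms with decision thresholds
#'
#' Draws the three score distributions the classifier operates on — EBV
#' ratio, TCR-gamma ratio and highest TCR-beta Tm — as faceted
#' histograms with the decision thresholds overlaid, optionally filled by
#' a grouping column (e.g. true or recorded tissue).  On a well-separated
#' cohort each panel shows the characteristic bimodal split between the
#' blood and LCL modes.
#'
#' @param calls Output of [classify_samples()] (optionally joined with a
#'   truth/annotation column).
#' @param thresholds The [threshold_config()] used for classification.
#' @param fill Optional tidy-eval column to colour the histograms by.
#' @param bins Histogram bin count per facet.
#' @return A ggplot object.
#' @export
plot_marker_distributions <- function(calls, thresholds = threshold_config(),
                                      fill = NULL, bins = 60) {
  calls <- as_tibble(calls)
  long <- tidyr::pivot_longer(
    calls,
    cols = c("ebv_ratio", "tcrg_ratio", "tcrb_max_tm"),
    names_to = "marker", values_to = "score"
  ) |>
    mutate(marker = factor(.data$marker,
                           levels = c("ebv_ratio", "tcrg_ratio", "tcrb_max_tm"),
                           labels = c("Ct GAPDH / Ct EBV (x100)",
                                      "Ct GAPDH / Ct TCR-gamma (x100)",
                                      "TCR-beta max Tm (deg C)"))) |>
    filter(is.finite(.data$score))
  cuts <- tibble(
    marker = factor(rep(levels(long$marker), c(2, 2, 1)),
                    levels = levels(long$marker)),
    cut = c(thresholds$ebv_lower, thresholds$ebv_upper,
            thresholds$tcrg_lower, thresholds$tcrg_upper,
            thresholds$tcrb_tm_cutoff)
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$score, fill = {{ fill }})) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.8, position = "identity") +
    ggplot2::geom_vline(data = cuts, ggplot2::aes(xintercept = .data$cut),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~marker, scales = "free") +
    ggplot2::labs(x = NULL, y = "samples") +
    ggplot2::theme_minimal()
  p
}

#' Plot raw amplification or melting curves
#'
#' @param curves Long curve table (columns `sample_id`, `assay`,
#'   `x_kind`, `x`, `fluorescence`).
#' @param kind `"cycle"` for amplification runs or `"temperature_C"` for
#'   melting runs.
#' @return A ggplot object, one line per sample faceted by assay.
#' @export
plot_curves <- function(curves, kind = c("cycle", "temperature_C")) {
  kind <- match.arg(kind)
  d <- filter(as_tibble(curves), .data$x_kind == kind)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$fluorescence,
                                  group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~assay, scales = "free_y") +
    ggplot2::labs(
      x = if (kind == "cycle") "PCR cycle" else "temperature (deg C)",
      y = "fluorescence (a.u.)"
    ) +
    ggplot2::theme_minimal()
}

#' Predicted versus chronological age, per tissue group
#'
#' The scatter used to judge an epigenetic clock: predicted age against
#' chronological age with the identity line, annotated per group with n,
#' MAD and Pearson R.  Blood points hug the identity line; LCL points
#' scatter away from it.
#'
#' @param object An `"age_eval"` from [evaluate_age()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot age_eval
#' @export
autoplot.age_eval <- function(object, ...) {
  d <- attr(object, "data")
  lab <- vapply(seq_len(nrow(object)), function(i) {
    sprintf("%s: n=%d, MAD=%.1f, R=%s", object$group[i], object$n[i],
            object$mad[i],
            ifelse(is.na(object$pearson_r[i]), "NA",
                   sprintf("%.2f", object$pearson_r[i])))
  }, character(1))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$predicted,
                                  colour = .data$group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "chronological age (years)",
                  y = "predicted age (years)",
                  colour = NULL, subtitle = paste(lab, collapse = "   ")) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix tile plot for a diagnostic evaluation
#'
#' @param object A `"binary_eval"` from [evaluate_binary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot binary_eval
#' @export
autoplot.binary_eval <- function(object, ...) {
  d <- tibble(
    truth = factor(c("blood", "blood", "LCL", "LCL"),
                   levels = c("blood", "LCL")),
    call = factor(c("positive", "negative", "positive", "negative"),
                  levels = c("positive", "negative")),
    n = c(object$tp, object$fn, object$fp, object$tn)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$call, y = .data$truth)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$n), colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "grey95", high = "steelblue") +
    ggplot2::labs(x = "test result", y = "true tissue", fill = "n") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
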