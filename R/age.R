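#' Coefficients of the three-CpG methylation age model
#'
#' The age predictor is an affine model on percent methylation at three
#' age-correlated CpG sites:
#' \deqn{\widehat{\mathrm{age}} = -20.372 + 0.830\,\mathrm{ELOVL2}_{CpG5}
#'   + 1.723\,\mathrm{KLF14}_{CpG2} + 0.715\,\mathrm{TRIM59}_{CpG5}.}
#'
#' @return A named numeric vector with elements `intercept`,
#'   `elovl2_cpg5`, `klf14_cpg2`, `trim59_cpg5`.
#' @export
age_model_coefficients <- function() {
  c(intercept = -20.372,
    elovl2_cpg5 = 0.830, klf14_cpg2 = 1.723, trim59_cpg5 = 0.715)
}

# Generator-side inverse of the clock.  The model maps three methylation
# values to one age, so its inverse is under-determined; the generator
# fixes one loading direction (per-year methylation gain at each CpG,
# ELOVL2-dominated as in blood) normalised so predicted age advances one
# year per year, and a baseline with predicted age exactly 0.
clock_direction <- function() {
  cf <- age_model_coefficients()[-1]
  d <- c(0.9, 0.15, 0.3)
  d / sum(cf * d)
}

clock_baseline <- function() {
  cf <- age_model_coefficients()
  b <- c(elovl2_cpg5 = 7, klf14_cpg2 = NA_real_, trim59_cpg5 = 6)
  # solve the KLF14 baseline so the model's prediction at age 0 is 0
  b["klf14_cpg2"] <- (-cf["intercept"] - cf["elovl2_cpg5"] * b["elovl2_cpg5"] -
                        cf["trim59_cpg5"] * b["trim59_cpg5"]) / cf["klf14_cpg2"]
  unname(b)
}

#' Predict chronological age from three-CpG methylation
#'
#' Applies the affine methylation clock (see [age_model_coefficients()])
#' to every row.  Predictions are not clamped: values below 0 or above the
#' human lifespan are reported as-is, since deviations from chronological
#' age are themselves the quantity of interest (they flag disturbed
#' methylomes such as cultured cell lines).
#'
#' @param data A data frame with percent-methylation columns (values in
#'   \[0, 100\]).
#' @param elovl2,klf14,trim59 Columns holding methylation at ELOVL2 CpG 5,
#'   KLF14 CpG 2 and TRIM59 CpG 5 (tidy-eval; defaults match the
#'   generator's output names).
#' @return `data` as a tibble with a `predicted_age` column appended.
#' @examples
#' predict_age(data.frame(elovl2_cpg5 = 60, klf14_cpg2 = 20, trim59_cpg5 = 40))
#' @export
predict_age <- function(data, elovl2 = elovl2_cpg5, klf14 = klf14_cpg2,
                        trim59 = trim59_cpg5) {
  data <- as_tibble(data)
  e <- dplyr::pull(data, {{ elovl2 }})
  k <- dplyr::pull(data, {{ klf14 }})
  t <- dplyr::pull(data, {{ trim59 }})
  vals <- c(e, k, t)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 100)) {
    stop_input("methylation values must be finite percentages in [0, 100]")
  }
  cf <- age_model_coefficients()
  mutate(data, predicted_age = cf[["intercept"]] +
           cf[["elovl2_cpg5"]] * e + cf[["klf14_cpg2"]] * k +
           cf[["trim59_cpg5"]] * t)
}

#' Evaluate age predictions per tissue group
#'
#' Summarises prediction quality the way epigenetic-clock validations are
#' reported: the mean absolute deviation (MAD) of predicted from
#' chronological age, in years, and the Pearson correlation between the
#' two, computed separately for each tissue group.  In an intact blood
#' methylome the clock tracks age closely (low MAD, high R); in LCLs the
#' methylome is disturbed by immortalisation and culture, so MAD inflates
#' and R collapses.
#'
#' @param data A data frame of predictions, e.g. the output of
#'   [predict_age()].
#' @param age,predicted,group Columns holding chronological age, predicted
#'   age and the grouping label (tidy-eval; defaults
#'   `chronological_age`, `predicted_age`, `tissue`).
#' @return A tibble of class `"age_eval"` with one row per group:
#'   `group`, `n`, `mad` (years) and `pearson_r` (`NA` when a group has
#'   fewer than two samples or no age variance).  The evaluated data are
#'   kept as an attribute so [autoplot.age_eval()] can draw the
#'   predicted-versus-chronological scatter.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_blood = 30, n_lcl = 30, seed = 2))
#' evaluate_age(predict_age(cohort$methylation))
#' @export
evaluate_age <- function(data, age = chronological_age,
                         predicted = predicted_age, group = tissue) {
  data <- as_tibble(data)
  df <- tibble(
    group = dplyr::pull(data, {{ group }}),
    age = dplyr::pull(data, {{ age }}),
    predicted = dplyr::pull(data, {{ predicted }})
  )
  if (any(!is.finite(df$age)) || any(!is.finite(df$predicted))) {
    stop_input("ages and predictions must be finite")
  }
  out <- df |>
    group_by(.data$group) |>
    summarise(
      n = n(),
      mad = mean(abs(.data$predicted - .data$age)),
      pearson_r = if (n() >= 2 && stats::sd(.data$age) > 0 &&
                      stats::sd(.data$predicted) > 0) {
        cor(.data$predicted, .data$age)
      } else NA_real_,
      .groups = "drop"
    )
  structure(out, data = df, class = c("age_eval", class(out)))
}

#' @export
print.age_eval <- function(x, ...) {
  cat("Methylation age-prediction evaluation\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-9s n = %3d  MAD = %5.1f y  R = %s\n",
                x$group[i], x$n[i], x$mad[i],
                ifelse(is.na(x$pearson_r[i]), "NA",
                       sprintf("%.2f", x$pearson_r[i]))))
  }
  invisible(x)
}

#' @rdname tissueorigin-tidiers
#' @method tidy age_eval
#' @export
tidy.age_eval <- function(x, ...) {
  as_tibble(unclass(x)[c("group", "n", "mad", "pearson_r")])
}

#' @rdname tissueorigin-tidiers
#' @method glance age_eval
#' @export
glance.age_eval <- function(x, ...) {
  d <- attr(x, "data")
  tibble(
    n = nrow(d),
    n_groups = nrow(x),
    mad = mean(abs(d$predicted - d$age)),
    pearson_r = if (nrow(d) >= 2 && stats::sd(d$age) > 0 &&
                    stats::sd(d$predicted) > 0) cor(d$predicted, d$age)
                else NA_real_
  )
}
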