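#' Call the quantification cycle (Ct) by the second-derivative-maximum method
#'
#' Locates the PCR cycle at which the amplification curve's curvature
#' peaks.  The caller fits a 4-parameter logistic
#' \eqn{F(c) = b + P\,\mathrm{logit}^{-1}\{k (c - c_0)\}} to the trace
#' (Levenberg-Marquardt least squares, initialised from the discrete
#' second difference of a Savitzky-Golay-smoothed copy) and returns the
#' analytic curvature maximum of the fit,
#' \eqn{C_t = c_0 - \ln(2 + \sqrt 3)/k}.  Fitting the whole sigmoid is how
#' established qPCR analysis software computes the second-derivative
#' maximum: it uses every point of the curve, so calls stay stable to
#' within a few hundredths of a cycle under percent-level fluorescence
#' noise where direct numerical differentiation scatters by a cycle or
#' more.  If the fit fails to converge, the caller falls back to the
#' discrete second difference refined by local quadratic interpolation
#' (earlier cycle wins a tied discrete maximum).  The method is
#' threshold-free, so curves on different fluorescence scales are called
#' consistently.
#'
#' A curve is declared `"no_amplification"` when its rise amplitude
#' (maximum smoothed fluorescence minus the early-cycle baseline) is below
#' `min_amplitude`, or when no positive curvature maximum occurs before the
#' last three cycles (a late drift rather than true amplification).
#'
#' @param curve A tibble as returned by [simulate_amplification()] (columns
#'   `cycle` and `fluorescence`, unit-spaced cycles, one curve).  Columns
#'   `sample_id`/`assay` are carried through when present.
#' @param min_amplitude Minimum fluorescence rise (same units as the curve)
#'   for the reaction to count as amplified.  Default 0.5, i.e. 5% of the
#'   simulator's default plateau.
#' @param window,poly_order Savitzky-Golay smoothing window length (odd)
#'   and polynomial order used for the initialisation/fallback path.  The
#'   defaults (5, 2) preserve locally quadratic signal exactly.
#'
#' @return A one-row tibble with columns `sample_id`, `assay`, `ct`
#'   (numeric, or `NA` when not amplified) and `called_by`
#'   (`"second_derivative_max"` or `"no_amplification"`).
#' @examples
#' call_ct(simulate_amplification(3000))
#' call_ct(simulate_amplification(0)) # no template -> no amplification
#' @export
call_ct <- function(curve, min_amplitude = 0.5, window = 5, poly_order = 2) {
  curve <- as_tibble(curve)
  if (!all(c("cycle", "fluorescence") %in% names(curve))) {
    stop_input("`curve` must have columns `cycle` and `fluorescence`")
  }
  n <- nrow(curve)
  if (n < max(window, 7)) {
    stop_input(sprintf("amplification curve has %d points; need at least %d", n, max(window, 7)))
  }
  curve <- arrange(curve, .data$cycle)
  if (any(abs(diff(curve$cycle) - 1) > 1e-8)) {
    stop_input("`cycle` must be unit-spaced")
  }
  if (any(!is.finite(curve$fluorescence))) {
    stop_input("`fluorescence` must be finite")
  }
  check_number(min_amplitude, "min_amplitude", min = 0, allow_min = FALSE)

  sid <- col_or_na(curve, "sample_id")
  asy <- col_or_na(curve, "assay")
  no_amp <- tibble(sample_id = sid, assay = asy, ct = NA_real_,
                   called_by = "no_amplification")

  y <- smooth_sgolay(curve$fluorescence, window, poly_order)
  baseline <- median(y[seq_len(min(5, n))])
  if (max(y) - baseline < min_amplitude) return(no_amp)

  # discrete second derivative: d2[i] sits at cycle[i + 1]
  d2 <- diff(y, differences = 2)
  # only maxima before the final three cycles count as real amplification
  at_cycle <- curve$cycle[seq_along(d2) + 1]
  eligible <- which(at_cycle <= curve$cycle[n] - 3)
  if (length(eligible) == 0 || max(d2[eligible]) <= 0) return(no_amp)
  i <- eligible[which.max(d2[eligible])] # which.max takes the earliest tie

  ct <- fit_logistic_sdm(curve$cycle, curve$fluorescence, y,
                         c0_init = at_cycle[i])
  if (is.na(ct)) { # fall back to the discrete estimate
    ct <- at_cycle[i] + quad_refine_offset(d2, i)
  }
  # calls in the final three cycles are late drift, not amplification
  if (ct <= curve$cycle[1] || ct > curve$cycle[n] - 3) return(no_amp)
  tibble(sample_id = sid, assay = asy, ct = ct,
         called_by = "second_derivative_max")
}

# Fit the 4-parameter logistic and return the analytic position of its
# second-derivative maximum, c0 - ln(2 + sqrt(3))/k; NA when the fit does
# not converge to a usable optimum.
fit_logistic_sdm <- function(x, y, y_smooth, c0_init) {
  b0 <- min(y_smooth)
  amp0 <- max(y_smooth) - b0
  # max slope of a logistic is amp * k / 4
  k0 <- max(0.2, min(1.5, 4 * max(diff(y_smooth)) / amp0))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + amp * plogis(k * (x - c0)),
      data = list(x = x, y = y),
      start = list(b = b0, amp = amp0, k = k0, c0 = c0_init + 2),
      lower = c(b = -Inf, amp = 0, k = 1e-3, c0 = min(x) - 10),
      upper = c(b = Inf, amp = Inf, k = 10, c0 = max(x) + 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NA_real_)
  cf <- stats::coef(fit)
  if (!all(is.finite(cf)) || cf[["k"]] <= 0 || cf[["amp"]] <= 0) {
    return(NA_real_)
  }
  cf[["c0"]] - log(2 + sqrt(3)) / cf[["k"]]
}

#' Extract melting-peak temperatures from a melting curve
#'
#' Computes the negative first derivative of fluorescence with respect to
#' temperature on a Savitzky-Golay-smoothed curve and reports every local
#' maximum whose topographic prominence is at least `min_prominence`.  Peak
#' positions are refined by local quadratic interpolation, so a product
#' melting between two acquisition points is still located to well within
#' the 0.2 degree C step.  The highest-temperature peak is the one used by
#' the TCR-beta tissue-of-origin rule (specific product versus primer
#' dimer).
#'
#' @param curve A tibble as returned by [simulate_melt()] (columns
#'   `temperature`, `fluorescence`; constant temperature spacing).
#' @param min_prominence Minimum peak prominence on the \eqn{-dF/dT} scale.
#'   The default 0.5 sits well below the derivative peak of the faintest
#'   real product (a ~10% primer-dimer fraction) but above what
#'   sub-percent fluorescence noise produces after smoothing.
#' @param window,poly_order Savitzky-Golay smoothing parameters (defaults
#'   9, 2).
#'
#' @return A tibble with one row per detected peak, columns `sample_id`,
#'   `assay`, `tm` (degrees C, ascending) and `prominence`.  Zero rows mean
#'   no peak (e.g. a featureless primer-free reaction).
#' @seealso [max_tm()] for the highest peak, [classify_tcrb()] for the rule
#'   applied to it.
#' @examples
#' melt <- simulate_melt(data.frame(tm = c(84, 90.2), fraction = c(0.3, 0.6)))
#' extract_tm_peaks(melt)
#' @export
extract_tm_peaks <- function(curve, min_prominence = 0.5,
                             window = 9, poly_order = 2) {
  curve <- as_tibble(curve)
  if (!all(c("temperature", "fluorescence") %in% names(curve))) {
    stop_input("`curve` must have columns `temperature` and `fluorescence`")
  }
  n <- nrow(curve)
  if (n < 5) stop_input("melting curve needs at least 5 acquisition points")
  curve <- arrange(curve, .data$temperature)
  steps <- diff(curve$temperature)
  h <- steps[1]
  if (any(abs(steps - h) > 1e-6)) {
    stop_input("`temperature` must have constant spacing")
  }
  if (any(!is.finite(curve$fluorescence))) {
    stop_input("`fluorescence` must be finite")
  }
  check_number(min_prominence, "min_prominence", min = 0, allow_min = FALSE)

  sid <- col_or_na(curve, "sample_id")
  asy <- col_or_na(curve, "assay")

  y <- smooth_sgolay(curve$fluorescence, min(window, n - (1 - n %% 2)), poly_order)
  # negative central first derivative at interior points
  d <- (y[seq_len(n - 2)] - y[3:n]) / (2 * h)
  temps <- curve$temperature[2:(n - 1)]

  idx <- local_maxima(d)
  if (length(idx)) {
    prom <- vapply(idx, function(i) peak_prominence(d, i), numeric(1))
    keep <- prom >= min_prominence
    idx <- idx[keep]
    prom <- prom[keep]
  }
  if (!length(idx)) {
    return(tibble(sample_id = character(), assay = character(),
                  tm = numeric(), prominence = numeric()))
  }
  tm <- vapply(idx, function(i) temps[i] + h * quad_refine_offset(d, i), numeric(1))
  tm <- pmin(pmax(tm, curve$temperature[1]), curve$temperature[n])
  tibble(sample_id = sid, assay = asy, tm = tm, prominence = prom) |>
    arrange(.data$tm)
}

#' Highest melting temperature of a peak table
#'
#' @param peaks A peak tibble from [extract_tm_peaks()].
#' @return The largest `tm`, or `NA` when there is no peak.
#' @export
max_tm <- function(peaks) {
  if (nrow(peaks) == 0) NA_real_ else max(peaks$tm)
}

# --- internal signal helpers -------------------------------------------------

col_or_na <- function(df, nm) {
  if (nm %in% names(df)) df[[nm]][1] else NA_character_
}

# Savitzky-Golay smoothing; degrades gracefully to the identity when the
# series is too short for the requested window.
smooth_sgolay <- function(y, window, poly_order) {
  window <- as.integer(window)
  if (window %% 2 == 0) window <- window + 1L
  if (length(y) < window || window < poly_order + 2) return(y)
  as.numeric(signal::sgolayfilt(y, p = poly_order, n = window))
}

# Indices of strict local maxima; plateaus credit their first point.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  which(
    x[2:(n - 1)] > x[3:n] & x[2:(n - 1)] >= x[1:(n - 2)] &
      # drop plateau continuations: require a strict rise somewhere on the left
      vapply(2:(n - 1), function(i) {
        j <- i - 1
        while (j >= 1 && x[j] == x[i]) j <- j - 1
        j >= 1 && x[j] < x[i]
      }, logical(1))
  ) + 1L
}

# Topographic prominence of peak i: on each side, walk to the nearest point
# higher than the peak (or the series end) and take the minimum in between;
# prominence is peak height minus the higher of the two side minima.
peak_prominence <- function(x, i) {
  h <- x[i]
  left <- x[seq_len(i - 1)]
  higher_l <- which(left > h)
  left_min <- min(left[seq.int(from = if (length(higher_l)) max(higher_l) else 1,
                               to = i - 1)])
  right <- x[seq.int(i + 1, length(x))]
  higher_r <- which(right > h)
  right_min <- min(right[seq_len(if (length(higher_r)) min(higher_r) else length(right))])
  h - max(left_min, right_min)
}

# Sub-grid refinement: vertex offset (in grid units, within [-1, 1]) of the
# parabola through points (i-1, i, i+1); 0 at series boundaries or when the
# three points are collinear.
quad_refine_offset <- function(x, i) {
  if (i <= 1 || i >= length(x)) return(0)
  denom <- x[i - 1] - 2 * x[i] + x[i + 1]
  if (denom >= 0) return(0) # not locally concave; leave at grid point
  off <- 0.5 * (x[i - 1] - x[i + 1]) / denom
  max(-1, min(1, off))
}
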