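#' Centile differences between two reference curves
#'
#' Evaluates `new - old` at one percent level over an age grid and flags
#' ages where the absolute difference exceeds the noticeability threshold
#' (0.5 cm for height, 0.3 kg/m2 for BMI — differences below these are
#' within measurement noise and daily physiological variation and are not
#' clinically noticeable).  Grids reaching outside either curve's span are
#' truncated to the common span with a message.
#'
#' @param curve_new,curve_old [lms_curve] objects for the same measure.
#' @param level percent level to compare.
#' @param ages evaluation grid (default 0.1-y steps over the common span).
#' @param threshold noticeability threshold in measure units; default by
#'   measure (0.5 for height, 0.3 for bmi), required for other measures.
#' @return data frame of class `difference_series`: `age`, `level`,
#'   `delta`, `flagged`.
#' @export
percentile_difference <- function(curve_new, curve_old, level, ages = NULL,
                                  threshold = NULL) {
  stopifnot(inherits(curve_new, "lms_curve"), inherits(curve_old, "lms_curve"))
  if (is.null(threshold)) {
    measure <- curve_new$measure
    threshold <- switch(as.character(measure), height = 0.5, bmi = 0.3,
                        stop("no default threshold for measure `", measure,
                             "`; supply `threshold`", call. = FALSE))
  }
  lo <- max(min(curve_new$age), min(curve_old$age))
  hi <- min(max(curve_new$age), max(curve_old$age))
  if (lo >= hi) stop("curve spans do not overlap", call. = FALSE)
  if (is.null(ages)) ages <- seq(lo, hi, by = 0.1)
  if (any(ages < lo | ages > hi)) {
    message(sprintf("grid truncated to the common span [%g, %g]", lo, hi))
    ages <- ages[ages >= lo & ages <= hi]
  }
  delta <- curve_quantile(curve_new, ages, level) -
    curve_quantile(curve_old, ages, level)
  structure(data.frame(age = ages, level = level, delta = delta,
                       flagged = abs(delta) > threshold),
            threshold = threshold,
            class = c("difference_series", "data.frame"))
}

#' Convert a BMI difference into a weight difference
#'
#' At fixed height, `BMI = weight / (height/100)^2`, so a BMI difference
#' maps to `delta_weight = delta_bmi * (height/100)^2` kilograms.  At the
#' median height of a 10-year-old girl (141 cm) a difference of 1 kg/m2
#' is very nearly 2 kg.
#'
#' @param delta_bmi BMI difference(s) in kg/m2.
#' @param height_cm height(s) in cm, positive.
#' @return weight difference(s) in kg.
#' @examples
#' bmi_weight_equivalence(1, 141)     # ~2 kg
#' bmi_weight_equivalence(0.3, 149.4) # ~0.67 kg
#' @export
bmi_weight_equivalence <- function(delta_bmi, height_cm) {
  .check_pos(height_cm, "height_cm")
  delta_bmi * (height_cm / 100)^2
}
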