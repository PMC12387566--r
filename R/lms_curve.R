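#' An age-indexed LMS reference curve
#'
#' An `lms_curve` holds `(mu, sigma, nu)` on an ordered age grid together
#' with a shape-preserving interpolation rule, so that z-scores, CDF values
#' and centiles can be evaluated at any age inside the grid span.
#'
#' Each parameter is interpolated separately with a monotone-safe cubic
#' Hermite spline (Fritsch-Carlson, `stats::splinefun(method = "monoH.FC")`).
#' This reproduces the tabulated parameter values exactly at the knots and
#' cannot overshoot between sparse adult rows, at the cost of a slightly
#' less smooth second derivative than a natural cubic spline.  Evaluation
#' outside the grid span is an error, never an extrapolation.
#'
#' @param age strictly increasing vector of decimal ages (years).
#' @param mu,sigma,nu parameter vectors of the same length as `age`.
#' @param sex `"F"` or `"M"` (optional metadata).
#' @param measure `"height"`, `"weight"` or `"bmi"` (optional metadata).
#' @return an object of class `lms_curve`.
#' @export
lms_curve <- function(age, mu, sigma, nu, sex = NA_character_,
                      measure = NA_character_) {
  age <- as.numeric(age)
  if (length(age) < 2 || any(diff(age) <= 0))
    stop("`age` must be strictly increasing with length >= 2", call. = FALSE)
  stopifnot(length(mu) == length(age), length(sigma) == length(age),
            length(nu) == length(age))
  .check_pos(mu, "mu"); .check_pos(sigma, "sigma")
  structure(list(age = age, mu = as.numeric(mu), sigma = as.numeric(sigma),
                 nu = as.numeric(nu), sex = sex, measure = measure),
            class = "lms_curve")
}

#' @export
print.lms_curve <- function(x, ...) {
  cat(sprintf("<lms_curve> %s %s: %d knots, ages %.2f-%.2f y\n",
              ifelse(is.na(x$sex), "?", x$sex),
              ifelse(is.na(x$measure), "?", x$measure),
              length(x$age), min(x$age), max(x$age)))
  invisible(x)
}

#' @export
range.lms_curve <- function(..., na.rm = FALSE) {
  x <- list(...)[[1]]
  range(x$age)
}

.curve_check_age <- function(curve, age) {
  if (any(age < min(curve$age) - 1e-9 | age > max(curve$age) + 1e-9))
    stop(sprintf("age outside the curve span [%g, %g]; extrapolation is not supported",
                 min(curve$age), max(curve$age)), call. = FALSE)
  pmin(pmax(age, min(curve$age)), max(curve$age))
}

.curve_interp <- function(curve, age, what) {
  f <- stats::splinefun(curve$age, curve[[what]], method = "monoH.FC")
  f(age)
}

#' Evaluate LMS parameters along a curve
#'
#' @param curve an [lms_curve].
#' @param age vector of ages inside the curve span.
#' @return data frame with columns `age`, `mu`, `sigma`, `nu`.
#' @export
curve_params <- function(curve, age) {
  stopifnot(inherits(curve, "lms_curve"))
  age <- .curve_check_age(curve, age)
  st <- attr(curve, "stitch")
  if (!is.null(st))   # stitched curves evaluate their blend analytically
    return(.stitch_params(st$c1, st$c2, st$join, st$halfwidth, age))
  data.frame(age = age,
             mu = .curve_interp(curve, age, "mu"),
             sigma = pmax(.curve_interp(curve, age, "sigma"), 1e-6),
             nu = .curve_interp(curve, age, "nu"))
}

#' Centiles, CDF values and z-scores along an LMS curve
#'
#' `curve_quantile` returns the measurement at a percent level,
#' `curve_cdf` the probability below a measurement, and `curve_zscore`
#' the standard-normal deviate of a measurement, all at given ages.
#' Arguments are recycled to a common length.
#'
#' @param curve an [lms_curve].
#' @param age ages inside the curve span.
#' @param level percent level(s) in (0, 100).
#' @param y measurement value(s), positive.
#' @return a numeric vector.
#' @export
curve_quantile <- function(curve, age, level) {
  n <- max(length(age), length(level))
  p <- curve_params(curve, rep_len(age, n))
  qBCCGo(rep_len(level, n) / 100, p$mu, p$sigma, p$nu)
}

#' @rdname curve_quantile
#' @export
curve_cdf <- function(curve, age, y) {
  n <- max(length(age), length(y))
  p <- curve_params(curve, rep_len(age, n))
  pBCCGo(rep_len(y, n), p$mu, p$sigma, p$nu)
}

#' @rdname curve_quantile
#' @export
curve_zscore <- function(curve, age, y) {
  n <- max(length(age), length(y))
  p <- curve_params(curve, rep_len(age, n))
  zBCCGo(rep_len(y, n), p$mu, p$sigma, p$nu)
}

#' Export a centile table from an LMS curve
#'
#' Produces the conventional wide layout of published growth tables:
#' one row per age, one column per percent level.
#'
#' @param curve an [lms_curve].
#' @param ages ages at which to tabulate (inside the span).
#' @param levels percent levels, default the classical seven.
#' @param digits rounding applied to the values (default 1, as printed
#'   references do); use `NA` for no rounding.
#' @return data frame with column `age` then one `p<level>` column each.
#' @export
centile_table <- function(curve, ages, levels = c(3, 10, 25, 50, 75, 90, 97),
                          digits = 1) {
  vals <- vapply(levels, function(lv) curve_quantile(curve, ages, lv),
                 numeric(length(ages)))
  vals <- matrix(vals, nrow = length(ages))
  if (!is.na(digits)) vals <- round(vals, digits)
  out <- data.frame(age = ages, vals)
  names(out) <- c("age", paste0("p", levels))
  out
}
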