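#' Count records inside and outside an extreme centile band, by group
#'
#' Computes each record's BMI-for-age (or height-for-age) percentile under
#' a reference model and splits the sample into the rows "below the band"
#' and "inside the band" (percentile at or above the band's lower level),
#' by a grouping column — the contingency table behind the question
#' whether a collection region is over-represented among the heaviest
#' children.  The two rows are disjoint by construction.
#'
#' @param records canonical record data frame.
#' @param model an `lms_fit` or [lms_curve].
#' @param band percent band, default `c(97, 100)`.
#' @param age_range ages retained, default the model span.
#' @param by grouping column name (default `"region"`).
#' @return a 2 x K integer matrix with rows `outside`, `band`; empty
#'   groups are retained as zero columns with a warning.
#' @export
band_counts <- function(records, model, band = c(97, 100),
                        age_range = NULL, by = "region") {
  crv <- .as_curve(model)
  span <- range(crv$age)
  if (is.null(age_range)) age_range <- span
  stopifnot(length(band) == 2, band[1] < band[2],
            band[1] >= 0, band[2] <= 100)
  rec <- records[records$age_years >= max(age_range[1], span[1]) &
                   records$age_years <= min(age_range[2], span[2]), ]
  y <- switch(crv$measure,
              height = rec$height_cm, weight = rec$weight_kg,
              bmi = rec$weight_kg / (rec$height_cm / 100)^2,
              stop("model curve carries no known measure", call. = FALSE))
  pct <- 100 * curve_cdf(crv, rec$age_years, y)
  inside <- if (band[1] <= 0) pct <= band[2]
  else pct >= band[1] & (band[2] >= 100 | pct <= band[2])
  g <- factor(rec[[by]])
  tab <- rbind(outside = table(g[!inside]), band = table(g[inside]))
  if (any(colSums(tab) == 0))
    warning("empty group column(s) retained as zeros: ",
            paste(colnames(tab)[colSums(tab) == 0], collapse = ", "))
  tab
}

#' Pearson chi-square test with adjusted standardized residuals
#'
#' Tests independence of the two factors of a counts table (no continuity
#' correction) and reports the adjusted standardized residual of each
#' cell,
#' \deqn{r = (O - E) / \sqrt{E (1 - n_{row}/N)(1 - n_{col}/N)},}
#' whose magnitude beyond about 2 indicates over- or under-representation.
#' The statistic, p-value, expected counts and residuals are delegated to
#' [stats::chisq.test()] (whose `stdres` component is exactly the adjusted
#' form above); small-expected-count approximation warnings are
#' propagated.
#'
#' @param tab a counts matrix (non-negative, positive grand total).
#' @return object of class `contingency_result`: list with `observed`,
#'   `expected`, `statistic`, `df`, `p.value`, `stdres`.
#' @examples
#' tab <- rbind(outside = c(2346, 971, 373), band = c(50, 38, 14))
#' contingency_test(tab)   # X2 = 9.07, band residuals -3.0 / 2.5 / 1.2
#' @export
contingency_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || sum(tab) <= 0)
    stop("counts must be non-negative with a positive total", call. = FALSE)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(E == 0))
    stop("zero expected count: merge sparse rows/columns before testing",
         call. = FALSE)
  ct <- stats::chisq.test(tab, correct = FALSE)
  structure(list(observed = tab, expected = ct$expected,
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p.value = ct$p.value,
                 stdres = ct$stdres),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, digits = 4, ...) {
  cat(sprintf("<contingency_result> X-squared = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  cat("adjusted standardized residuals:\n")
  print(round(x$stdres, 1))
  invisible(x)
}

#' Null calibration of the representation test
#'
#' Simulates contingency tables under independent margins (each record
#' lands in a group with probability `col_probs` and inside the band with
#' probability `band_prob`, independently), applies the Pearson test, and
#' reports the fraction of replicates rejected at `alpha`.  With
#' adequately filled cells the rate should match the nominal level.
#'
#' @param reps number of replicates.
#' @param n records per replicate.
#' @param band_prob probability of the band row.
#' @param col_probs group probabilities (sum to 1).
#' @param alpha nominal level.
#' @return the empirical rejection rate (scalar).
#' @export
null_rejection_rate <- function(reps = 10000, n = 500, band_prob = 0.1,
                                col_probs = c(0.5, 0.3, 0.2), alpha = 0.05) {
  stopifnot(abs(sum(col_probs) - 1) < 1e-9, band_prob > 0, band_prob < 1)
  K <- length(col_probs)
  cellp <- as.vector(outer(c(1 - band_prob, band_prob), col_probs))
  M <- stats::rmultinom(reps, n, cellp)          # (2K) x reps, row-major pairs
  O <- array(M, dim = c(2, K, reps))
  rowt <- apply(O, c(1, 3), sum)                  # 2 x reps
  colt <- apply(O, c(2, 3), sum)                  # K x reps
  X2 <- numeric(reps)
  ok <- rep(TRUE, reps)
  for (i in 1:2) for (j in 1:K) {
    E <- rowt[i, ] * colt[j, ] / n
    ok <- ok & E > 0
    X2 <- X2 + ifelse(E > 0, (O[i, j, ] - E)^2 / E, 0)
  }
  p <- stats::pchisq(X2[ok], df = K - 1, lower.tail = FALSE)
  mean(p < alpha)
}
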