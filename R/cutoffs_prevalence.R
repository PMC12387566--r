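#' Derive overweight and obesity cut-offs by the IOTF pass-through method
#'
#' The IOTF convention defines childhood overweight and obesity by the
#' centile curves of a BMI reference that pass through 25 and 30 kg/m2 at
#' age 18: the percentile level at which each anchor BMI sits at 18 is
#' carried through all ages as an age-varying BMI cut-off curve.
#'
#' @param bmi_curve an [lms_curve] for BMI whose span includes the anchor
#'   age.
#' @param anchor_age anchor age in years (18 by convention).
#' @param anchors named anchor BMI values (`overweight = 25, obese = 30`).
#' @return object of class `iotf_cutoffs`: list with `sex`, `anchor_age`,
#'   `anchors`, `levels` (derived percent levels) and `curve` (the
#'   underlying reference).
#' @examples
#' cuts <- derive_iotf_cutoffs(reference_curve("F", "bmi"))
#' cuts$levels            # c(overweight = 84.3, obese = 97.1), about
#' cutoff_bmi(cuts, 10)   # age-10 cut-off BMIs
#' @export
derive_iotf_cutoffs <- function(bmi_curve, anchor_age = 18,
                                anchors = c(overweight = 25, obese = 30)) {
  stopifnot(inherits(bmi_curve, "lms_curve"))
  span <- range(bmi_curve$age)
  if (anchor_age < span[1] || anchor_age > span[2])
    stop(sprintf("anchor age %g lies outside the model window [%g, %g]",
                 anchor_age, span[1], span[2]), call. = FALSE)
  stopifnot(all(c("overweight", "obese") %in% names(anchors)),
            anchors[["obese"]] > anchors[["overweight"]])
  levels <- 100 * curve_cdf(bmi_curve, anchor_age, anchors)
  names(levels) <- names(anchors)
  structure(list(sex = bmi_curve$sex, anchor_age = anchor_age,
                 anchors = anchors, levels = levels, curve = bmi_curve),
            class = "iotf_cutoffs")
}

#' @export
print.iotf_cutoffs <- function(x, ...) {
  cat(sprintf("<iotf_cutoffs> sex %s: BMI %g/%g at age %g sit at the %.1f / %.1f percentiles\n",
              ifelse(is.na(x$sex), "?", x$sex), x$anchors[["overweight"]],
              x$anchors[["obese"]], x$anchor_age,
              x$levels[["overweight"]], x$levels[["obese"]]))
  invisible(x)
}

#' Age-varying cut-off BMI values
#'
#' @param cutoffs an [derive_iotf_cutoffs()] object.
#' @param age ages inside the reference span.
#' @param which `"overweight"`, `"obese"` or both.
#' @return matrix (ages x categories) of cut-off BMI values in kg/m2.
#' @export
cutoff_bmi <- function(cutoffs, age, which = c("overweight", "obese")) {
  stopifnot(inherits(cutoffs, "iotf_cutoffs"))
  which <- match.arg(which, several.ok = TRUE)
  out <- vapply(which,
                function(w) curve_quantile(cutoffs$curve, age,
                                           cutoffs$levels[[w]]),
                numeric(length(age)))
  matrix(out, nrow = length(age), dimnames = list(NULL, which))
}

#' Classify records as normal / overweight / obese
#'
#' A record is obese when its BMI is at or above the obesity cut-off curve
#' at its age, else overweight when at or above the overweight curve, else
#' normal (a BMI exactly on a cut-off classifies into the heavier
#' category).  Records younger than `min_age` (2 y, the convention of
#' prevalence reporting) or beyond the reference span are excluded and
#' reported via the `excluded` attribute.
#'
#' @param records canonical record data frame.
#' @param cutoffs an [derive_iotf_cutoffs()] object.
#' @param min_age minimum age retained (default 2 y).
#' @return the eligible records with added columns `bmi` and `status`
#'   (factor normal < overweight < obese); attribute `excluded` counts
#'   the dropped records by reason.
#' @export
classify_weight_status <- function(records, cutoffs, min_age = 2) {
  stopifnot(inherits(cutoffs, "iotf_cutoffs"))
  span <- range(cutoffs$curve$age)
  under <- records$age_years < max(min_age, span[1])
  over <- records$age_years > span[2]
  keep <- !under & !over
  rec <- records[keep, , drop = FALSE]
  rec$bmi <- rec$weight_kg / (rec$height_cm / 100)^2
  cb <- cutoff_bmi(cutoffs, rec$age_years)
  rec$status <- factor(ifelse(rec$bmi >= cb[, "obese"], "obese",
                              ifelse(rec$bmi >= cb[, "overweight"],
                                     "overweight", "normal")),
                       levels = c("normal", "overweight", "obese"),
                       ordered = TRUE)
  rownames(rec) <- NULL
  attr(rec, "excluded") <- c(under_age = sum(under), beyond_span = sum(over))
  rec
}

#' Prevalence of overweight and obesity by parental origin
#'
#' Tabulates, per origin group, the number of classified records, the
#' overweight percentage (including obesity, the usual reporting
#' convention) and the obesity percentage, plus a `total` row over all
#' origin-known records.  Records with unknown origin are excluded and
#' counted in the `excluded_unknown` attribute.
#'
#' @param records canonical record data frame (one sex).
#' @param cutoffs an [derive_iotf_cutoffs()] object.
#' @param digits rounding of the rates in percent (default 1).
#' @return data frame `origin`, `n`, `overweight`, `obese` with a final
#'   `total` row.
#' @export
prevalence_by_group <- function(records, cutoffs, digits = 1) {
  cl <- classify_weight_status(records, cutoffs)
  unknown <- cl$origin == "unknown"
  cl <- cl[!unknown, , drop = FALSE]
  groups <- sort(unique(cl$origin))
  rate <- function(sel) {
    n <- sum(sel)
    if (n == 0) return(c(n = 0, overweight = NA_real_, obese = NA_real_))
    c(n = n,
      overweight = round(100 * mean(cl$status[sel] >= "overweight"), digits),
      obese = round(100 * mean(cl$status[sel] == "obese"), digits))
  }
  rows <- t(vapply(groups, function(g) rate(cl$origin == g), numeric(3)))
  out <- data.frame(origin = c(groups, "total"),
                    rbind(rows, rate(rep(TRUE, nrow(cl)))),
                    row.names = NULL)
  attr(out, "excluded_unknown") <- sum(unknown)
  out
}

#' n-weighted aggregation of group prevalence rates
#'
#' @param n group sizes, positive.
#' @param rates group rates in percent.
#' @param digits rounding (default 1, matching published tables).
#' @return the n-weighted mean rate.
#' @examples
#' prev <- load_prevalence_reference()
#' g <- prev[prev$sex == "F", ]
#' aggregate_prevalence(g$n, g$overweight)   # 13.1
#' @export
aggregate_prevalence <- function(n, rates, digits = 1) {
  if (length(n) != length(rates))
    stop("`n` and `rates` must have the same length", call. = FALSE)
  if (any(n <= 0)) stop("group sizes must be positive", call. = FALSE)
  if (any(rates < 0 | rates > 100))
    stop("rates must be percentages in [0, 100]", call. = FALSE)
  round(sum(n * rates) / sum(n), digits)
}

#' Burden shares by parental origin
#'
#' For origin-known records at ages >= 2 y, returns each group's share of
#' the total sample, of all overweight (including obesity) cases, and of
#' all obesity cases — the quantities behind "group X makes up a% of the
#' cohort but b% of the obesity cases".  Each share column sums to 100.
#'
#' @param records canonical record data frame (one sex).
#' @param cutoffs an [derive_iotf_cutoffs()] object.
#' @return data frame `origin`, `total_share`, `overweight_share`,
#'   `obese_share` (percent).  If no record is obese the obese column is
#'   `NA` with a message.
#' @export
burden_share <- function(records, cutoffs) {
  cl <- classify_weight_status(records, cutoffs)
  cl <- cl[cl$origin != "unknown", , drop = FALSE]
  groups <- sort(unique(cl$origin))
  share <- function(sel) {
    if (!sum(sel)) return(rep(NA_real_, length(groups)))
    100 * vapply(groups, function(g) sum(sel & cl$origin == g), 0) / sum(sel)
  }
  ow <- cl$status >= "overweight"
  ob <- cl$status == "obese"
  if (!any(ob)) message("no obese records: obese shares undefined")
  data.frame(origin = groups,
             total_share = share(rep(TRUE, nrow(cl))),
             overweight_share = share(ow),
             obese_share = share(ob), row.names = NULL)
}
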