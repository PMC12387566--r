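#' Sex- and age-specific cleaning quantiles
#'
#' Computes the quartiles (P25, P50, P75) of height and weight per sex and
#' age bin, the inputs of the robust outlier filters.  Bins are half-year
#' wide up to age 2 and one-year wide after; bins with fewer than `min_n`
#' records are merged with the following bin (the last bin merges
#' backwards) until every bin is large enough.  Quantiles use the standard
#' linear interpolation of order statistics (`type = 7`); the filter bounds
#' depend on this convention, so it is fixed rather than configurable.
#'
#' @param records canonical record data frame.
#' @param min_n minimum records per bin (default 20).
#' @return data frame of class `cleaning_quantiles`: one row per sex x bin
#'   with columns `sex`, `age_lo`, `age_hi`, `n`, and
#'   `<measure>_p25/_p50/_p75` for height and weight.
#' @export
empirical_quantiles <- function(records, min_n = 20) {
  if (!nrow(records)) stop("no records", call. = FALSE)
  out <- list()
  for (sx in sort(unique(records$sex))) {
    r <- records[records$sex == sx, ]
    top <- max(r$age_years) + 1e-9
    breaks <- unique(c(seq(0, 2, by = 0.5),
                       seq(3, max(3, ceiling(top)), by = 1)))
    if (max(breaks) < top) breaks <- c(breaks, top)
    # merge sparse bins forward
    repeat {
      cnt <- table(cut(r$age_years, breaks, right = FALSE,
                       include.lowest = TRUE))
      small <- which(cnt < min_n)
      if (!length(small) || length(breaks) <= 2) break
      i <- small[1]
      drop <- if (i == length(cnt)) i else i + 1
      breaks <- breaks[-drop]
    }
    bin <- cut(r$age_years, breaks, right = FALSE, include.lowest = TRUE)
    for (b in levels(bin)) {
      sel <- bin == b
      i <- match(b, levels(bin))
      qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75),
                                        type = 7, names = FALSE)
      qh <- qs(r$height_cm[sel]); qw <- qs(r$weight_kg[sel])
      if (any(diff(qh) <= 0) || any(diff(qw) <= 0))
        stop(sprintf("degenerate quartiles in bin %s (sex %s): P25 < P50 < P75 must hold",
                     b, sx), call. = FALSE)
      out[[length(out) + 1]] <- data.frame(
        sex = sx, age_lo = breaks[i], age_hi = breaks[i + 1], n = sum(sel),
        height_p25 = qh[1], height_p50 = qh[2], height_p75 = qh[3],
        weight_p25 = qw[1], weight_p50 = qw[2], weight_p75 = qw[3])
    }
  }
  structure(do.call(rbind, out),
            class = c("cleaning_quantiles", "data.frame"))
}

.match_bin <- function(records, q) {
  idx <- rep(NA_integer_, nrow(records))
  for (i in seq_len(nrow(q))) {
    hit <- records$sex == q$sex[i] &
      records$age_years >= q$age_lo[i] - 1e-9 &
      (records$age_years < q$age_hi[i] |
         (i == nrow(q) | (i < nrow(q) && q$sex[i + 1] != q$sex[i])) &
         records$age_years <= q$age_hi[i] + 1e-9)
    idx[hit & is.na(idx)] <- i
  }
  if (anyNA(idx))
    stop(sprintf("%d record(s) fall outside the cleaning-quantile bins (first age %.3g)",
                 sum(is.na(idx)), records$age_years[which(is.na(idx))[1]]),
         call. = FALSE)
  idx
}

.outlier_bounds <- function(q, measure) {
  if (measure == "height") {
    lower <- q$height_p25 - 4.5 * (q$height_p50 - q$height_p25)
    upper <- q$height_p75 + 4.5 * (q$height_p75 - q$height_p50)
  } else {
    lower <- q$weight_p25 - 5 * (q$weight_p50 - q$weight_p25)^0.75
    upper <- q$weight_p75 + 9 * (q$weight_p75 - q$weight_p50)
  }
  data.frame(lower = lower, upper = upper)
}

.flag_outliers <- function(records, q, measure) {
  col <- if (measure == "height") "height_cm" else "weight_kg"
  idx <- .match_bin(records, q)
  b <- .outlier_bounds(q, measure)[idx, ]
  # "outside the interval" is read strictly: boundary values are kept
  out <- records[[col]] < b$lower | records[[col]] > b$upper
  excl <- records[out, , drop = FALSE]
  if (nrow(excl)) {
    excl$reason <- paste0(measure, "_outlier")
    excl$bin <- sprintf("[%g,%g)", q$age_lo[idx[out]], q$age_hi[idx[out]])
    excl$lower <- b$lower[out]
    excl$upper <- b$upper[out]
  } else {
    excl$reason <- character(); excl$bin <- character()
    excl$lower <- numeric(); excl$upper <- numeric()
  }
  rownames(excl) <- NULL
  kept <- records[!out, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, excluded = excl)
}

#' Robust percentile-based outlier filters
#'
#' A record is excluded when its measurement lies strictly outside the
#' sex- and age-specific interval
#' * height: `[P25 - 4.5 (P50 - P25), P75 + 4.5 (P75 - P50)]`
#' * weight: `[P25 - 5 (P50 - P25)^0.75, P75 + 9 (P75 - P50)]`
#'
#' The asymmetric weight bounds reflect the right skew of weight: the upper
#' arm is wider, and the lower arm grows sub-linearly with the lower
#' quartile spread.  Both intervals sit roughly four or more robust SDs
#' from the median, so under clean data well under 0.5% of records are
#' touched.  The filters are single-pass: bounds come from the supplied
#' quantiles and are not recomputed after exclusions.
#'
#' @param records canonical record data frame.
#' @param q a [empirical_quantiles()] table covering every record's bin.
#' @return list with `kept` and `excluded` (the latter annotated with
#'   `reason`, `bin`, `lower`, `upper`).
#' @export
flag_height_outliers <- function(records, q) .flag_outliers(records, q, "height")

#' @rdname flag_height_outliers
#' @export
flag_weight_outliers <- function(records, q) .flag_outliers(records, q, "weight")

#' Duplicate removal and input-error flagging
#'
#' Collapses byte-identical duplicate rows and flags the classical input
#' errors:
#' * swap candidates: weight exceeding height-in-cm (numerically impossible
#'   for a true child record), or height below 30 cm past age 2;
#' * decimal candidates: a value far outside its robust bin interval
#'   (beyond twice the upper bound or below half the lower bound) that a
#'   single x10 or /10 correction brings back inside.
#'
#' Flagging is conservative by design so that clean records are essentially
#' never touched; correction is opt-in via `repair = TRUE` (decimal slips
#' are rescaled, swaps are swapped back), otherwise candidates are only
#' reported.
#'
#' @param records canonical record data frame.
#' @param q optional [empirical_quantiles()] table; computed from the
#'   deduplicated records when missing.
#' @param repair apply the inferred corrections?
#' @return list with `records` (deduplicated, repaired if requested) and
#'   `report` (data frame `record_id`, `action`, `detail`).
#' @export
dedupe_and_repair <- function(records, q = NULL, repair = FALSE) {
  report <- list()
  dup <- duplicated(records)
  if (any(dup))
    report[[length(report) + 1]] <-
      data.frame(record_id = records$record_id[dup],
                 action = "duplicate_removed",
                 detail = "byte-identical row collapsed")
  records <- records[!dup, , drop = FALSE]
  rownames(records) <- NULL
  if (is.null(q)) q <- empirical_quantiles(records)
  idx <- .match_bin(records, q)
  bh <- .outlier_bounds(q, "height")[idx, ]
  bw <- .outlier_bounds(q, "weight")[idx, ]

  dec_fix <- function(x, lower, upper) {
    # factor restoring a far-out value into its plausible interval
    f <- rep(NA_real_, length(x))
    f[x > 2 * upper & x / 10 >= lower & x / 10 <= upper] <- 0.1
    f[x < lower / 2 & x * 10 >= lower & x * 10 <= upper] <- 10
    f
  }
  # a swap explains the record if exchanging the two values puts both back
  # inside their plausible intervals; checked before the decimal rule since
  # a /10 height slip also violates the weight < height ordering
  swap <- records$weight_kg > records$height_cm &
    records$weight_kg >= bh$lower & records$weight_kg <= bh$upper &
    records$height_cm >= bw$lower & records$height_cm <= bw$upper
  fh <- dec_fix(records$height_cm, bh$lower, bh$upper)
  fw <- dec_fix(records$weight_kg, bw$lower, bw$upper)
  deci <- !swap & (!is.na(fh) | !is.na(fw))
  # residual impossibilities that neither rule can repair: flag only
  odd <- !swap & !deci & (records$weight_kg > records$height_cm |
                            (records$height_cm < 30 & records$age_years > 2))
  if (any(deci)) {
    which_m <- ifelse(!is.na(fh), "height_cm", "weight_kg")[deci]
    fac <- ifelse(!is.na(fh), fh, fw)[deci]
    report[[length(report) + 1]] <-
      data.frame(record_id = records$record_id[deci],
                 action = "decimal_candidate",
                 detail = sprintf("%s x%g restores plausibility", which_m, fac))
    if (repair) {
      i <- which(deci)
      for (j in seq_along(i))
        records[i[j], which_m[j]] <- records[i[j], which_m[j]] * fac[j]
    }
  }
  if (any(swap)) {
    report[[length(report) + 1]] <-
      data.frame(record_id = records$record_id[swap],
                 action = "swap_candidate",
                 detail = "exchanging height and weight restores plausibility")
    if (repair) {
      h <- records$height_cm[swap]
      records$height_cm[swap] <- records$weight_kg[swap]
      records$weight_kg[swap] <- h
    }
  }
  if (any(odd)) {
    report[[length(report) + 1]] <-
      data.frame(record_id = records$record_id[odd],
                 action = "implausible_candidate",
                 detail = "weight/height ordering physiologically impossible")
  }
  report <- if (length(report)) do.call(rbind, report)
  else data.frame(record_id = character(), action = character(),
                  detail = character())
  rownames(report) <- NULL
  list(records = records, report = report)
}

#' Full cleaning pass
#'
#' Runs the complete cleaning pipeline in the order duplicates / input-error
#' candidates, then the height and weight outlier filters.  Swap and
#' decimal candidates are repaired when `repair = TRUE` and excluded
#' otherwise.  The outlier bounds are computed once, after deduplication,
#' and applied in a single pass.
#'
#' @param records canonical record data frame.
#' @param min_n minimum bin size for [empirical_quantiles()].
#' @param repair repair flagged swap/decimal candidates instead of
#'   excluding them?
#' @return list with `records` (clean cohort) and `report` (one row per
#'   action: `record_id`, `action`, `detail`).
#' @export
clean_cohort <- function(records, min_n = 20, repair = FALSE) {
  dr <- dedupe_and_repair(records, repair = repair)
  rec <- dr$records
  report <- dr$report
  if (!repair) {
    bad <- rec$record_id %in%
      report$record_id[report$action != "duplicate_removed"]
    rec <- rec[!bad, , drop = FALSE]
    rownames(rec) <- NULL
  }
  q <- empirical_quantiles(rec, min_n = min_n)
  fh <- flag_height_outliers(rec, q)
  fw <- flag_weight_outliers(fh$kept, q)
  add <- function(excl) {
    if (!nrow(excl)) return(NULL)
    data.frame(record_id = excl$record_id,
               action = paste0(excl$reason, "_excluded"),
               detail = sprintf("bin %s, interval [%.2f, %.2f]",
                                excl$bin, excl$lower, excl$upper))
  }
  report <- rbind(report, add(fh$excluded), add(fw$excluded))
  rownames(report) <- NULL
  list(records = fw$kept, report = report)
}
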