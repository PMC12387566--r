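#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure of a national
#' cross-sectional growth survey: the age-group x sex x data-source case
#' counts of the published sampling table, the collection-region shares and
#' per-region parental-origin mix, height and BMI marginals that follow the
#' packaged reference curves, origin-specific BMI shifts calibrated to the
#' published prevalence table, and the coarser rounding of military records.
#'
#' Heights and BMIs are drawn as a bivariate-normal z-score pair mapped
#' through the reference LMS curves, so the empirical centiles of a large
#' unshifted cohort match the reference tables by construction.  Parental
#' origin acts on the BMI z-score only (location shift `delta` and scale
#' `scale`), not on height, mirroring the finding that migration background
#' is associated with BMI but not height differences.
#'
#' @param n target total number of records (allocated over sex, age-group
#'   and source strata proportionally to the published sampling table).
#' @param sex sexes to include, subset of `c("F", "M")`.
#' @param seed integer seed; the cohort is a pure function of the config.
#' @param height_bmi_cor correlation between the height and BMI z-scores.
#'   The survey reports no joint law; 0.1 (weakly positive) is a free
#'   parameter of the generator.
#' @param sigma_scale multiplier on the reference `sigma` curves (0 gives a
#'   degenerate cohort sitting exactly on the medians).
#' @param origin_effects `NULL` for the calibrated defaults (see
#'   [default_origin_effects()]), or a data frame with columns
#'   `origin`, `sex`, `delta`, `scale`.
#' @param strata stratum plan; defaults to the published sampling table
#'   ([load_age_strata()]).
#' @param region_shares named shares for prospective records over
#'   `c(german, romande, ticino)`; defaults to the published region totals.
#' @param origin_mix per-region origin mix; defaults to the published
#'   origin-by-region table.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n = 10000, sex = c("F", "M"), seed = 1,
                          height_bmi_cor = 0.1, sigma_scale = 1,
                          origin_effects = NULL, strata = load_age_strata(),
                          region_shares = NULL, origin_mix = load_origin_mix()) {
  sex <- match.arg(sex, c("F", "M"), several.ok = TRUE)
  if (n < 1) stop("`n` must be positive", call. = FALSE)
  if (abs(height_bmi_cor) > 1) stop("`height_bmi_cor` must be in [-1, 1]",
                                    call. = FALSE)
  if (sigma_scale < 0) stop("`sigma_scale` must be >= 0", call. = FALSE)
  if (is.null(region_shares)) {
    tot <- colSums(origin_mix[, c("german", "romande", "ticino")])
    region_shares <- tot / sum(tot)
  }
  if (abs(sum(region_shares) - 1) > 1e-9)
    stop("`region_shares` must sum to 1", call. = FALSE)
  structure(list(n = n, sex = sex, seed = seed,
                 height_bmi_cor = height_bmi_cor, sigma_scale = sigma_scale,
                 origin_effects = origin_effects, strata = strata,
                 region_shares = region_shares, origin_mix = origin_mix),
            class = "cohort_config")
}

#' Calibrated parental-origin effects on the BMI z-score
#'
#' For each origin group the published overweight (including obesity) and
#' obesity rates pin down a two-parameter normal model for the group's BMI
#' z-score, `z ~ delta + scale * N(0, 1)`: with cut-off z-levels `z_ow`,
#' `z_ob` (from the reference BMI curve at age 18, see
#' [derive_iotf_cutoffs()]) and published rates `p_ow > p_ob`,
#' `scale = (z_ob - z_ow) / (qnorm(1 - p_ob) - qnorm(1 - p_ow))` and
#' `delta = z_ow - scale * qnorm(1 - p_ow)`.  The group-wise prevalences of
#' a cohort generated with these defaults therefore match the published
#' table in expectation; no tuning is involved.
#'
#' @param sexes sexes to include.
#' @return data frame with columns `origin`, `sex`, `delta`, `scale`.
#' @export
default_origin_effects <- function(sexes = c("F", "M")) {
  prev <- load_prevalence_reference()
  out <- list()
  for (sx in sexes) {
    cuts <- derive_iotf_cutoffs(reference_curve(sx, "bmi"))
    z_ow <- stats::qnorm(cuts$levels[["overweight"]] / 100)
    z_ob <- stats::qnorm(cuts$levels[["obese"]] / 100)
    p <- prev[prev$sex == sx, ]
    q1 <- stats::qnorm(1 - p$overweight / 100)
    q2 <- stats::qnorm(1 - p$obese / 100)
    sc <- (z_ob - z_ow) / (q2 - q1)
    de <- z_ow - sc * q1
    # the published table pools other/mixed parents into one row
    grp <- data.frame(origin = p$origin, sex = sx, delta = de, scale = sc,
                      stringsAsFactors = FALSE)
    om <- grp[grp$origin == "other_mixed", ]
    if (nrow(om)) {
      grp <- grp[grp$origin != "other_mixed", ]
      grp <- rbind(grp,
                   transform(om, origin = "other_both"),
                   transform(om, origin = "mixed_non_swiss"))
    }
    grp <- rbind(grp, data.frame(origin = "unknown", sex = sx,
                                 delta = 0, scale = 1))
    out[[sx]] <- grp
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Null origin effects
#'
#' A zero-shift, unit-scale effects table: every origin group draws its
#' BMI z-score straight from the reference distribution.  Use this for
#' parameter-recovery experiments, where the cohort must follow the
#' reference curves exactly.
#'
#' @param sexes sexes to include.
#' @return data frame with columns `origin`, `sex`, `delta`, `scale`.
#' @export
no_origin_effects <- function(sexes = c("F", "M")) {
  groups <- c(unique(load_origin_mix()$origin))
  expand <- expand.grid(origin = groups, sex = sexes,
                        stringsAsFactors = FALSE)
  data.frame(expand, delta = 0, scale = 1)
}

# z-score clamped inside the finite Box-Cox support bound 1 + nu*sigma*z > 0
.clamp_z <- function(z, sigma, nu) {
  bound <- 0.995 / pmax(abs(nu) * sigma, 1e-12)
  neg <- nu < -.nu_eps
  pos <- nu > .nu_eps
  z[neg] <- pmin(z[neg], bound[neg])
  z[pos] <- pmax(z[pos], -bound[pos])
  z
}

.curve_span <- function(curve) range(curve$age)

#' Generate a synthetic anthropometric cohort
#'
#' Draws records per the stratum plan, maps z-scores through the packaged
#' reference curves, back-solves weight from BMI and height, applies
#' origin-specific BMI shifts, and rounds military records to whole
#' centimetres and kilograms.  Output is deterministic given the config.
#'
#' Ages are uniform within each stratum, except that birth-registry records
#' concentrate in the first 0.1 y (the newborn spike of real collections).
#' Ages beyond a reference curve's printed span are evaluated at the span
#' boundary.
#'
#' @param config a [cohort_config()].
#' @return data frame with columns `record_id`, `sex`, `age_years`,
#'   `height_cm`, `weight_kg`, `region`, `source`, `origin`.
#' @examples
#' head(sample_cohort(cohort_config(n = 200, seed = 7)))
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  strata <- config$strata[config$strata$sex %in% config$sex, ]
  if (!nrow(strata)) stop("empty stratum plan", call. = FALSE)
  src_counts <- as.matrix(strata[, c("practice", "school", "retrospective")])
  tot <- sum(src_counts)
  if (tot == 0) stop("empty stratum plan", call. = FALSE)
  set.seed(config$seed)

  eff <- config$origin_effects
  if (is.null(eff)) eff <- default_origin_effects(config$sex)

  rows <- list()
  for (i in seq_len(nrow(strata))) {
    st <- strata[i, ]
    for (src in c("practice", "school", "retrospective")) {
      k <- round(st[[src]] / tot * config$n)
      if (k == 0) next
      if (src == "retrospective") {
        source_lab <- "retrospective"
        retro <- st$retro_source
      } else {
        source_lab <- src
        retro <- NA_character_
      }
      age <- if (identical(retro, "birth"))
        stats::runif(k, 0, 0.1)
      else
        stats::runif(k, st$age_lo, st$age_hi)
      rows[[length(rows) + 1]] <-
        data.frame(sex = st$sex, age_years = age, source = source_lab,
                   retro_source = retro, stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, rows)
  n <- nrow(rec)

  # region: prospective by published shares; school-medical retrospective
  # came from French-speaking communities; births/military are national
  rec$region <- "national"
  pro <- rec$source != "retrospective"
  rec$region[pro] <- sample(names(config$region_shares), sum(pro),
                            replace = TRUE, prob = config$region_shares)
  rec$region[!pro & rec$retro_source == "school_medical"] <- "romande"

  # origin: known only for prospective records, mix depends on region
  rec$origin <- "unknown"
  mix <- config$origin_mix[config$origin_mix$origin != "unknown", ]
  for (rg in c("german", "romande", "ticino")) {
    idx <- which(pro & rec$region == rg)
    if (length(idx))
      rec$origin[idx] <- sample(mix$origin, length(idx), replace = TRUE,
                                prob = mix[[rg]] / sum(mix[[rg]]))
  }

  z_h <- stats::rnorm(n)
  z_b <- config$height_bmi_cor * z_h +
    sqrt(1 - config$height_bmi_cor^2) * stats::rnorm(n)
  ekey <- paste(rec$origin, rec$sex)
  m <- match(ekey, paste(eff$origin, eff$sex))
  if (anyNA(m))
    stop("origin_effects table misses groups: ",
         paste(unique(ekey[is.na(m)]), collapse = ", "), call. = FALSE)
  z_b <- eff$delta[m] + eff$scale[m] * z_b

  rec$height_cm <- NA_real_
  rec$weight_kg <- NA_real_
  for (sx in unique(rec$sex)) {
    hc <- reference_curve(sx, "height")
    bc <- reference_curve(sx, "bmi")
    idx <- which(rec$sex == sx)
    age_h <- pmin(pmax(rec$age_years[idx], .curve_span(hc)[1]), .curve_span(hc)[2])
    age_b <- pmin(pmax(rec$age_years[idx], .curve_span(bc)[1]), .curve_span(bc)[2])
    ph <- curve_params(hc, age_h)
    pb <- curve_params(bc, age_b)
    ph$sigma <- pmax(ph$sigma * config$sigma_scale, 1e-9)
    pb$sigma <- pmax(pb$sigma * config$sigma_scale, 1e-9)
    # truncate z at the bounds of observed anthropometry: the Box-Cox tail
    # with nu < 0 explodes far outside the data range the reference was
    # built on.  Applied after the origin shift, so group-wise prevalences
    # (thresholds at |z| < 2.3) are exactly preserved.
    zh <- .clamp_z(pmax(pmin(z_h[idx], 3.5), -3.5), ph$sigma, ph$nu)
    zb <- .clamp_z(pmax(pmin(z_b[idx], 3), -3), pb$sigma, pb$nu)
    h <- qBCCGo(stats::pnorm(zh), ph$mu, ph$sigma, ph$nu)
    bmi <- qBCCGo(stats::pnorm(zb), pb$mu, pb$sigma, pb$nu)
    rec$height_cm[idx] <- h
    rec$weight_kg[idx] <- bmi * (h / 100)^2
  }

  mil <- !is.na(rec$retro_source) & rec$retro_source == "military"
  rec$height_cm <- ifelse(mil, round(rec$height_cm), round(rec$height_cm, 1))
  rec$weight_kg <- ifelse(mil, round(rec$weight_kg), round(rec$weight_kg, 1))
  rec$weight_kg <- pmax(rec$weight_kg, 0.1)

  rec$record_id <- sprintf("r%07d", seq_len(nrow(rec)))
  rec$retro_source <- NULL
  rec[, c("record_id", "sex", "age_years", "height_cm", "weight_kg",
          "region", "source", "origin")]
}

#' Inject known flaws into a cohort
#'
#' Simulates the classical anthropometric input errors so that the cleaning
#' stage can be validated against ground truth: exact duplicate rows,
#' height/weight swaps, and decimal-place slips (x10 or /10 on one
#' measure).  Each record receives at most one of swap/decimal; duplication
#' is drawn independently.  Every injected flaw is returned in a ledger.
#'
#' @param records canonical record data frame.
#' @param duplicate_rate,swap_rate,decimal_rate per-record probabilities.
#' @param seed optional seed (otherwise the current RNG stream is used).
#' @return list with `records` (flawed cohort, duplicates appended at the
#'   end) and `ledger` (data frame `record_id`, `kind`, `detail`).
#' @export
inject_errors <- function(records, duplicate_rate = 0, swap_rate = 0,
                          decimal_rate = 0, seed = NULL) {
  rates <- c(duplicate_rate, swap_rate, decimal_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]", call. = FALSE)
  if (swap_rate + decimal_rate > 1)
    stop("swap_rate + decimal_rate must be <= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(records)
  ledger <- list()

  u <- stats::runif(n)
  swap <- u < swap_rate
  deci <- !swap & u < swap_rate + decimal_rate
  if (any(swap)) {
    h <- records$height_cm[swap]
    records$height_cm[swap] <- records$weight_kg[swap]
    records$weight_kg[swap] <- h
    ledger[[length(ledger) + 1]] <-
      data.frame(record_id = records$record_id[swap], kind = "swap",
                 detail = "height and weight exchanged")
  }
  if (any(deci)) {
    which_m <- sample(c("height_cm", "weight_kg"), sum(deci), replace = TRUE)
    fac <- sample(c(10, 0.1), sum(deci), replace = TRUE)
    idx <- which(deci)
    for (j in seq_along(idx))
      records[idx[j], which_m[j]] <- records[idx[j], which_m[j]] * fac[j]
    ledger[[length(ledger) + 1]] <-
      data.frame(record_id = records$record_id[idx], kind = "decimal",
                 detail = sprintf("%s x%g", which_m, fac))
  }
  dup <- stats::runif(n) < duplicate_rate
  if (any(dup)) {
    records <- rbind(records, records[dup, ])
    rownames(records) <- NULL
    ledger[[length(ledger) + 1]] <-
      data.frame(record_id = records$record_id[which(dup)], kind = "duplicate",
                 detail = "exact copy appended")
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger)
  else data.frame(record_id = character(), kind = character(),
                  detail = character())
  rownames(ledger) <- NULL
  list(records = records, ledger = ledger)
}
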