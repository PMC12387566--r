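#' Packaged smoothed reference tables
#'
#' The package ships the smoothed centile tables of a national growth
#' reference for height and BMI (girls to 18 y, boys to 20 y; BMI from 2 y)
#' at the seven classical levels 3/10/25/50/75/90/97, transcribed cell for
#' cell from the published tables, plus the published contingency and
#' prevalence tables used by the downstream analyses.
#'
#' `load_reference()` returns a `quantile_table`: a data frame with one row
#' per age and columns `age`, `p3` ... `p97`, with `sex`, `measure` and
#' `levels` attributes.  Weight centiles were not published in tabular form;
#' requesting them is an error pointing the user at [fit_lms()] instead.
#'
#' @param sex `"F"` or `"M"`.
#' @param measure `"height"` or `"bmi"`.
#' @return a data frame of class `quantile_table`.
#' @examples
#' tab <- load_reference("F", "height")
#' tab[tab$age == 10, "p50"]   # 141.0 cm
#' @export
load_reference <- function(sex = c("F", "M"), measure = c("height", "bmi", "weight")) {
  sex <- match.arg(sex)
  measure <- match.arg(measure)
  if (measure == "weight")
    stop("weight centiles are not printed in the packaged reference; ",
         "fit a weight model from records with fit_lms() instead",
         call. = FALSE)
  all <- .load_fixture(paste0("reference_", measure, ".csv"))
  tab <- all[all$sex == sex, -1, drop = FALSE]
  rownames(tab) <- NULL
  validate_quantile_table(tab)
  structure(tab, sex = sex, measure = measure,
            levels = c(3, 10, 25, 50, 75, 90, 97),
            class = c("quantile_table", "data.frame"))
}

.load_fixture <- function(name) {
  path <- system.file("extdata", name, package = "growthlms", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Validate a quantile table
#'
#' Checks the wide centile-table layout: an `age` column plus `p<level>`
#' columns, rows strictly increasing across levels, ages strictly
#' increasing.
#'
#' @param tab a data frame in the wide layout of [load_reference()].
#' @return `tab`, invisibly; errors describe the offending row.
#' @export
validate_quantile_table <- function(tab) {
  pc <- grep("^p[0-9.]+$", names(tab), value = TRUE)
  if (!"age" %in% names(tab) || length(pc) < 3)
    stop("quantile table needs an `age` column and >= 3 `p<level>` columns",
         call. = FALSE)
  if (any(diff(tab$age) <= 0))
    stop("quantile table ages must be strictly increasing", call. = FALSE)
  vals <- as.matrix(tab[pc])
  bad <- which(apply(vals, 1, function(r) any(diff(r) <= 0)))
  if (length(bad))
    stop(sprintf("quantile table row for age %g is not strictly increasing across levels",
                 tab$age[bad[1]]), call. = FALSE)
  invisible(tab)
}

.table_levels <- function(tab) {
  lv <- attr(tab, "levels")
  if (!is.null(lv)) return(lv)
  as.numeric(sub("^p", "", grep("^p[0-9.]+$", names(tab), value = TRUE)))
}

#' Convert a printed centile table into an LMS curve
#'
#' For every age row an LMS triplet is recovered from the printed centiles
#' with [fit_lms_point()]; the per-age triplets are then interpolated across
#' age (see [lms_curve]).
#'
#' Printed cells carry up to 0.05 units of rounding noise each (tables are
#' printed to 0.1), and the least-squares triplet can occasionally leave a
#' single cell just past its rounding radius while under-using the slack at
#' the others.  With `polish = TRUE` (the default) each row's triplet is
#' therefore refined from the least-squares solution to the minimax
#' (Chebyshev) solution, which equalises the worst-case cell error; the
#' reconstructed curve then reproduces every printed cell to within the
#' 0.05-unit rounding radius.
#'
#' @param tab a `quantile_table` (see [load_reference()]).
#' @param polish refine each row fit from least-squares to minimax?
#' @return an [lms_curve].
#' @examples
#' crv <- table_to_lms_curve(load_reference("F", "height"))
#' curve_quantile(crv, 10, 50)   # 141.0 +/- 0.05
#' @export
table_to_lms_curve <- function(tab, polish = TRUE) {
  validate_quantile_table(tab)
  levels <- .table_levels(tab)
  pc <- paste0("p", levels)
  pts <- lapply(seq_len(nrow(tab)), function(i) {
    vals <- as.numeric(tab[i, pc])
    pt <- tryCatch(fit_lms_point(levels, vals, age = tab$age[i]),
                   error = function(e)
                     stop(sprintf("LMS fit failed for age row %g: %s",
                                  tab$age[i], conditionMessage(e)),
                          call. = FALSE))
    if (polish) pt <- .minimax_polish(pt, levels, vals)
    pt
  })
  lms_curve(age = vapply(pts, `[[`, 0, "age"),
            mu = vapply(pts, `[[`, 0, "mu"),
            sigma = vapply(pts, `[[`, 0, "sigma"),
            nu = vapply(pts, `[[`, 0, "nu"),
            sex = attr(tab, "sex") %||% NA_character_,
            measure = attr(tab, "measure") %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Chebyshev refinement of a row fit: minimise the worst-case cell error,
# starting from the least-squares triplet
.minimax_polish <- function(pt, levels, values) {
  zq <- stats::qnorm(levels / 100)
  obj <- function(par) {
    mu <- exp(par[1]); s <- exp(par[2]); nu <- par[3]
    if (abs(nu) < .nu_eps) {
      pred <- mu * exp(s * zq)
    } else {
      a <- 1 + nu * s * zq
      if (any(a <= 0)) return(1e10)
      pred <- mu * a^(1 / nu)
    }
    max(abs(pred - values))
  }
  par <- c(log(pt$mu), log(pt$sigma), pt$nu)
  for (k in 1:2)
    par <- stats::optim(par, obj, control = list(maxit = 5000,
                                                 reltol = 1e-14))$par
  out <- lms_point(pt$age, exp(par[1]), exp(par[2]), par[3])
  attr(out, "max_abs_err") <- obj(par)
  out
}

# curve cache: per-row quantile fits are deterministic, no need to redo them
.ref_cache <- new.env(parent = emptyenv())

#' Reference LMS curve for a sex and measure
#'
#' Convenience wrapper: [load_reference()] + [table_to_lms_curve()], cached
#' for the session (the reconstruction is deterministic).
#'
#' @inheritParams load_reference
#' @return an [lms_curve].
#' @export
reference_curve <- function(sex = c("F", "M"), measure = c("height", "bmi")) {
  sex <- match.arg(sex); measure <- match.arg(measure)
  key <- paste(sex, measure, sep = ".")
  if (is.null(.ref_cache[[key]]))
    .ref_cache[[key]] <- table_to_lms_curve(load_reference(sex, measure))
  .ref_cache[[key]]
}

#' Published study tables
#'
#' Loaders for the remaining published tables bundled as fixtures:
#' * `load_age_strata()`: case counts per sex, 2-year age group and data
#'   source (pediatric practice / school / retrospective), with the
#'   retrospective source class (birth registry, school medical service,
#'   military recruits).
#' * `load_origin_mix()`: parental-origin counts overall and per collection
#'   region; origin is unknown for all retrospective records.
#' * `load_region_band_counts()`: girls aged 8-15 per collection region,
#'   all BMI percentiles versus the 97th-100th percentile band.
#' * `load_prevalence_reference()`: published IOTF-based overweight
#'   (including obesity) and obesity rates per parental-origin group and
#'   sex (ages >= 2 y).  The published table pools children with parents
#'   from other regions and from two different non-Swiss regions into one
#'   `other_mixed` row.
#' @return a data frame.
#' @name study_tables
NULL

#' @rdname study_tables
#' @export
load_age_strata <- function() .load_fixture("age_strata.csv")

#' @rdname study_tables
#' @export
load_origin_mix <- function() .load_fixture("origin_by_region.csv")

#' @rdname study_tables
#' @export
load_region_band_counts <- function() .load_fixture("region_band_counts.csv")

#' @rdname study_tables
#' @export
load_prevalence_reference <- function() .load_fixture("prevalence_by_origin.csv")
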