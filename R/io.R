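.record_cols <- c("record_id", "sex", "age_years", "height_cm", "weight_kg",
                  "region", "source", "origin")
.region_levels <- c("german", "romande", "ticino", "national")
.source_levels <- c("practice", "school", "retrospective")
.origin_levels <- c("swiss_both", "north_central_eu_both", "ita_spa_por_both",
                    "balkan_both", "turkey_both", "other_both",
                    "mixed_non_swiss", "swiss_one", "unknown")

#' Read and write the canonical record CSV
#'
#' The canonical record file is a comma-separated, dot-decimal, UTF-8 CSV
#' with a header and exactly the columns `record_id, sex, age_years,
#' height_cm, weight_kg, region, source, origin`.  `read_records`
#' validates the schema and the categorical labels, reporting offending
#' row numbers; `write_records` writes the same layout back (round-trip
#' safe).
#'
#' @param path file path.
#' @param records canonical record data frame.
#' @return `read_records` the validated data frame; `write_records` the
#'   path, invisibly.
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(record_id = "character"))
  if (!identical(names(rec), .record_cols))
    stop("unexpected columns: expected exactly ",
         paste(.record_cols, collapse = ", "), call. = FALSE)
  bad_row <- function(ok, what) {
    if (all(ok)) return(invisible())
    stop(sprintf("%s invalid in row(s) %s", what,
                 paste(utils::head(which(!ok), 5), collapse = ", ")),
         call. = FALSE)
  }
  bad_row(rec$sex %in% c("F", "M"), "sex")
  bad_row(is.finite(rec$age_years) & rec$age_years >= 0, "age_years")
  bad_row(is.finite(rec$height_cm) & rec$height_cm > 0, "height_cm")
  bad_row(is.finite(rec$weight_kg) & rec$weight_kg > 0, "weight_kg")
  bad_row(rec$region %in% .region_levels, "region")
  bad_row(rec$source %in% .source_levels, "source")
  bad_row(rec$origin %in% .origin_levels, "origin")
  bad_row(rec$origin == "unknown" | rec$source != "retrospective",
          "origin (retrospective records must have origin = unknown)")
  rec
}

#' @rdname read_records
#' @export
write_records <- function(records, path) {
  stopifnot(all(.record_cols %in% names(records)))
  utils::write.csv(records[.record_cols], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize fitted models and cut-off sets to JSON
#'
#' A fitted model round-trips through a JSON document holding the config
#' and the age-grid parameter table; a cut-off set stores the anchor
#' definition, the derived levels and the reference grid.
#'
#' @param fit an `lms_fit` or [lms_curve].
#' @param cutoffs an `iotf_cutoffs` object.
#' @param path file path.
#' @return readers return the reconstructed object; writers the path,
#'   invisibly.
#' @export
model_to_json <- function(fit, path) {
  crv <- .as_curve(fit)
  doc <- list(type = "lms_curve",
              sex = crv$sex, measure = crv$measure,
              grid = list(age = crv$age, mu = crv$mu, sigma = crv$sigma,
                          nu = crv$nu))
  if (inherits(fit, "lms_fit")) {
    cfg <- fit$config
    doc$config <- cfg[setdiff(names(cfg), "join")]
    doc$deviance <- fit$deviance
    doc$converged <- fit$converged
    doc$n <- fit$n
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  lms_curve(doc$grid$age, doc$grid$mu, doc$grid$sigma, doc$grid$nu,
            sex = doc$sex %||% NA_character_,
            measure = doc$measure %||% NA_character_)
}

#' @rdname model_to_json
#' @export
cutoffs_to_json <- function(cutoffs, path) {
  stopifnot(inherits(cutoffs, "iotf_cutoffs"))
  crv <- cutoffs$curve
  jsonlite::write_json(
    list(type = "iotf_cutoffs", sex = cutoffs$sex,
         anchor_age = cutoffs$anchor_age,
         anchors = as.list(cutoffs$anchors),
         levels = as.list(cutoffs$levels),
         grid = list(age = crv$age, mu = crv$mu, sigma = crv$sigma,
                     nu = crv$nu)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_to_json
#' @export
cutoffs_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  crv <- lms_curve(doc$grid$age, doc$grid$mu, doc$grid$sigma, doc$grid$nu,
                   sex = doc$sex %||% NA_character_, measure = "bmi")
  derive_iotf_cutoffs(crv, anchor_age = doc$anchor_age,
                      anchors = unlist(doc$anchors))
}

#' Run the simulate / clean / fit / tabulate pipeline
#'
#' End-to-end demonstration pipeline over the package's stages: generate a
#' synthetic cohort, clean it, fit a two-part height reference per the
#' standard windows (infant model below 2 y, childhood model above 0.25 y,
#' joined at 1.2 y), and export the centile table, the cleaned records and
#' a manifest (config echo, package version, seed, stage timings).  All
#' outputs are deterministic given the seed.
#'
#' @param output_dir directory for the artifacts (created if missing).
#' @param n cohort size.
#' @param seed integer seed.
#' @param sex sex to fit.
#' @param ages tabulated ages of the exported centile table.
#' @return (invisibly) list with the cleaned records, the stitched curve,
#'   the centile table and the manifest.
#' @export
run_growth_pipeline <- function(output_dir, n = 30000, seed = 1, sex = "F",
                                ages = 0:18) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[3]
  cfg <- cohort_config(n = n, sex = sex, seed = seed)
  cohort <- sample_cohort(cfg)
  t_sim <- proc.time()[3]
  cleaned <- clean_cohort(cohort)
  write_records(cleaned$records, file.path(output_dir, "records_clean.csv"))
  t_clean <- proc.time()[3]
  m1 <- fit_lms(cleaned$records,
                fit_config("height", sex, age_range = c(0, 2),
                           lambda_age = 0.5, age_offset = 0.01))
  m2 <- fit_lms(cleaned$records,
                fit_config("height", sex,
                           age_range = c(0.25, max(ages))))
  m2 <- enforce_monotone_median(m2, cleaned$records)
  curve <- stitch_models(m1, m2, join = 1.2)
  t_fit <- proc.time()[3]
  tab <- centile_table(curve, ages)
  utils::write.csv(tab, file.path(output_dir, "centiles_height.csv"),
                   row.names = FALSE)
  model_to_json(curve, file.path(output_dir, "height_model.json"))
  manifest <- list(
    package = "growthlms",
    version = as.character(utils::packageVersion("growthlms")),
    seed = seed, n = n, sex = sex,
    n_clean = nrow(cleaned$records),
    n_excluded = nrow(cleaned$report),
    timings_s = list(simulate = round(t_sim - t0, 2),
                     clean = round(t_clean - t_sim, 2),
                     fit = round(t_fit - t_clean, 2)))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(records = cleaned$records, curve = curve, table = tab,
                 manifest = manifest))
}
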