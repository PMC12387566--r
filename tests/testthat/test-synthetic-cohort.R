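test_that("cohorts are reproducible and structurally valid", {
  cfg <- cohort_config(n = 2000, seed = 31)
  a <- sample_cohort(cfg)
  b <- sample_cohort(cohort_config(n = 2000, seed = 31))
  expect_identical(a, b)
  # written CSVs are byte-identical too
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  write_records(a, fa); write_records(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
  # origin is unknown exactly for retrospective records
  expect_true(all((a$origin == "unknown") == (a$source == "retrospective")))
  expect_true(all(a$height_cm > 0 & a$weight_kg > 0))
  expect_error(sample_cohort(cohort_config(n = 2000,
                                           strata = load_age_strata()[0, ])),
               "empty stratum plan")
})

test_that("a zero-variance config collapses onto the median curves", {
  coh <- sample_cohort(cohort_config(n = 500, sex = "F", seed = 5,
                                     sigma_scale = 0))
  hc <- reference_curve("F", "height")
  sel <- coh$age_years <= 18 & coh$source != "retrospective"
  med <- curve_quantile(hc, coh$age_years[sel], 50)
  expect_lt(max(abs(coh$height_cm[sel] - med)), 0.051)  # 0.1-unit rounding
})

test_that("unshifted cohorts match the reference marginals", {
  coh <- sample_cohort(cohort_config(n = 50000, sex = "F", seed = 12,
                                     origin_effects = no_origin_effects("F")))
  hc <- reference_curve("F", "height")
  # empirical median height at age 10, age-detrended within the window
  sel <- abs(coh$age_years - 10) <= 0.25
  adj <- coh$height_cm[sel] -
    curve_quantile(hc, coh$age_years[sel], 50) + 141.0
  expect_equal(median(adj), 141.0, tolerance = 0.4)
  # per-age-bin probability transform is uniform (KS)
  sel2 <- coh$age_years >= 8 & coh$age_years < 10
  u <- curve_cdf(hc, coh$age_years[sel2], coh$height_cm[sel2])
  expect_gt(length(u), 2000)
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("calibrated origin effects reproduce the published group rates", {
  # force every prospective record into one origin group for a clean read
  mix <- load_origin_mix()
  mix[, c("overall", "german", "romande", "ticino")] <- 0
  mix[mix$origin == "balkan_both", c("german", "romande", "ticino")] <- 1
  coh <- sample_cohort(cohort_config(n = 14000, sex = "M", seed = 21,
                                     origin_mix = mix))
  cuts <- derive_iotf_cutoffs(reference_curve("M", "bmi"))
  prev <- prevalence_by_group(coh, cuts)
  grp <- prev[prev$origin == "balkan_both", ]
  expect_gt(grp$n, 5000)
  expect_equal(grp$obese, 8.5, tolerance = 1.5)       # published 8.5
  expect_equal(grp$overweight, 27.2, tolerance = 2.5) # published 27.2
})

test_that("error injection is exhaustive, ledgered and inert at rate zero", {
  coh <- sample_cohort(cohort_config(n = 10000, seed = 9))
  expect_identical(inject_errors(coh)$records, coh)
  inj <- inject_errors(coh, duplicate_rate = 0.01, seed = 101)
  ndup <- sum(inj$ledger$kind == "duplicate")
  expect_equal(nrow(inj$records), nrow(coh) + ndup)
  expect_true(abs(ndup - 100) <= 30)  # binomial(10000, 0.01)
  swapped <- inject_errors(coh, swap_rate = 1, seed = 102)
  expect_true(all(swapped$records$weight_kg > swapped$records$height_cm))
  expect_error(inject_errors(coh, swap_rate = 1.5), "\\[0, 1\\]")
})
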