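test_that("cut-off derivation passes through the anchors", {
  # a model whose age-18 parameters put BMI 25 exactly at the 90th centile
  mu <- 25 / (1 + 0.1 * qnorm(0.9))
  crv <- constant_curve(mu, 0.1, 1, lo = 2, hi = 20)
  cuts <- derive_iotf_cutoffs(crv)
  expect_equal(unname(cuts$levels["overweight"]), 90, tolerance = 1e-9)
  # pass-through identity at the anchor age, for reference models too
  for (sx in c("F", "M")) {
    cc <- derive_iotf_cutoffs(reference_curve(sx, "bmi"))
    cb <- cutoff_bmi(cc, 18)
    expect_equal(unname(cb[, "overweight"]), 25, tolerance = 0.001)
    expect_equal(unname(cb[, "obese"]), 30, tolerance = 0.001)
    expect_gt(cc$levels[["obese"]], cc$levels[["overweight"]])
  }
  short <- constant_curve(16, 0.1, -1, lo = 2, hi = 10)
  expect_error(derive_iotf_cutoffs(short), "outside the model window")
})

test_that("classification respects boundaries, age limits and ground truth", {
  crv <- reference_curve("F", "bmi")
  cuts <- derive_iotf_cutoffs(crv)
  cb <- cutoff_bmi(cuts, c(6, 6))
  rec <- make_records(age = c(6, 6, 6, 1.5, 25),
                      height = 100,
                      weight = c(cb[1, "overweight"], cb[1, "obese"], 12,
                                 15, 20))
  cl <- classify_weight_status(rec, cuts)
  expect_equal(as.character(cl$status), c("overweight", "obese", "normal"))
  expect_equal(unname(attr(cl, "excluded")["under_age"]), 1)
  expect_equal(unname(attr(cl, "excluded")["beyond_span"]), 1)
  # agreement with the percentile route on a synthetic cohort
  coh <- sample_cohort(cohort_config(n = 5000, sex = "F", seed = 51))
  cl2 <- classify_weight_status(coh, cuts)
  pct <- 100 * curve_cdf(crv, cl2$age_years, cl2$bmi)
  expect_identical(cl2$status == "obese", pct >= cuts$levels[["obese"]])
  expect_identical(cl2$status >= "overweight",
                   pct >= cuts$levels[["overweight"]])
})

test_that("prevalence tables aggregate consistently and monotonely", {
  cuts <- derive_iotf_cutoffs(reference_curve("F", "bmi"))
  coh <- sample_cohort(cohort_config(n = 12000, sex = "F", seed = 52))
  prev <- prevalence_by_group(coh, cuts)
  grp <- prev[prev$origin != "total", ]
  tot <- prev[prev$origin == "total", ]
  expect_true(all(grp$obese <= grp$overweight))
  # the total row is the n-weighted mean of its group rows
  expect_equal(tot$overweight,
               aggregate_prevalence(grp$n, grp$overweight), tolerance = 0.051)
  expect_equal(tot$n, sum(grp$n))
  # duplication of the whole cohort leaves rates unchanged
  prev2 <- prevalence_by_group(rbind(coh, coh), cuts)
  expect_equal(prev2$overweight, prev$overweight)
  # raising every BMI never decreases any prevalence
  heavier <- coh
  heavier$weight_kg <- (coh$weight_kg / (coh$height_cm / 100)^2 + 1) *
    (coh$height_cm / 100)^2
  prev3 <- prevalence_by_group(heavier, cuts)
  expect_true(all(prev3$overweight >= prev$overweight))
  expect_true(all(prev3$obese >= prev$obese))
  # single-group input: total equals the group
  one <- coh[coh$origin == "swiss_both", ]
  p1 <- prevalence_by_group(one, cuts)
  expect_equal(p1$overweight[1], p1$overweight[2])
})

test_that("n-weighted aggregation reproduces the published totals", {
  prev <- load_prevalence_reference()
  g <- prev[prev$sex == "F", ]
  expect_equal(aggregate_prevalence(g$n, g$overweight), 13.1)
  expect_equal(aggregate_prevalence(g$n, g$obese), 2.8)
  b <- prev[prev$sex == "M", ]
  expect_equal(aggregate_prevalence(b$n, b$overweight), 14.0)
  expect_equal(aggregate_prevalence(b$n, b$obese), 3.0)
  expect_equal(aggregate_prevalence(500, 12.3), 12.3)
  expect_error(aggregate_prevalence(c(1, 2), 5), "same length")
})

test_that("burden shares expose group enrichment in the heavy categories", {
  cuts <- derive_iotf_cutoffs(reference_curve("F", "bmi"))
  # uniform risk: the three distributions coincide up to sampling error
  coh0 <- sample_cohort(cohort_config(n = 30000, sex = "F", seed = 53,
                                      origin_effects = no_origin_effects("F")))
  bs0 <- burden_share(coh0, cuts)
  expect_equal(sum(bs0$total_share), 100, tolerance = 0.1)
  expect_equal(sum(bs0$obese_share), 100, tolerance = 0.1)
  expect_lt(max(abs(bs0$overweight_share - bs0$total_share)), 5)
  # calibrated shifts concentrate obesity in the southern-origin groups
  coh <- sample_cohort(cohort_config(n = 30000, sex = "F", seed = 54))
  bs <- burden_share(coh, cuts)
  south <- bs$origin %in% c("ita_spa_por_both", "balkan_both")
  expect_gt(sum(bs$obese_share[south]), 35 - 1e-9)
  expect_lt(sum(bs$obese_share[south]), 43 + 1e-9)
  expect_gt(sum(bs$obese_share[south]), sum(bs$total_share[south]))
  # a cohort where only one group can be obese owns 100% of that share
  slim <- coh0
  slim$weight_kg <- 14 * (slim$height_cm / 100)^2
  heavy <- slim$origin == "turkey_both" & slim$age_years >= 3 &
    slim$age_years <= 17
  slim$weight_kg[heavy] <- 35 * (slim$height_cm[heavy] / 100)^2
  bs1 <- burden_share(slim, cuts)
  expect_equal(bs1$obese_share[bs1$origin == "turkey_both"], 100)
})
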