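test_that("bin quartiles follow the linear-interpolation rule", {
  rec <- make_records(age = rep(5.5, 100), height = 1:100, weight = 1:100)
  q <- empirical_quantiles(rec)
  expect_equal(nrow(q), 1)
  expect_equal(q$height_p25, 25.75)
  expect_equal(q$height_p50, 50.5)
  expect_equal(q$height_p75, 75.25)
  # permutation invariance
  q2 <- empirical_quantiles(rec[sample(nrow(rec)), ])
  expect_equal(q2$weight_p25, q$weight_p25)
  # degenerate bins are refused by name
  flat <- make_records(age = rep(5.5, 50), height = 100, weight = 20)
  expect_error(empirical_quantiles(flat), "degenerate quartiles")
  expect_error(empirical_quantiles(rec[0, ]), "no records")
})

test_that("height filter applies the printed interval formula strictly", {
  q <- structure(data.frame(sex = "F", age_lo = 5, age_hi = 6, n = 50,
                            height_p25 = 100, height_p50 = 105,
                            height_p75 = 110, weight_p25 = 15,
                            weight_p50 = 17, weight_p75 = 20),
                 class = c("cleaning_quantiles", "data.frame"))
  # interval [100 - 4.5*5, 110 + 4.5*5] = [77.5, 132.5]
  rec <- make_records(age = rep(5.5, 4), height = c(77.4, 77.5, 132.5, 132.6),
                      weight = 18)
  fl <- flag_height_outliers(rec, q)
  expect_equal(nrow(fl$kept), 2)        # boundary values are kept
  expect_setequal(fl$excluded$height_cm, c(77.4, 132.6))
  expect_equal(fl$excluded$lower, c(77.5, 77.5))
  # a record on the median is always kept
  expect_equal(nrow(flag_height_outliers(
    make_records(5.5, 105, 18), q)$excluded), 0)
  # interval widens as the lower quartile spread grows
  q2 <- q; q2$height_p25 <- 95
  expect_lt(flag_height_outliers(rec, q2)$excluded$lower[1], 77.5)
  # missing bin coverage is an error, not a pass-through
  expect_error(flag_height_outliers(make_records(9.5, 130, 30), q),
               "outside the cleaning-quantile bins")
})

test_that("weight filter applies the asymmetric printed bounds", {
  q <- structure(data.frame(sex = "F", age_lo = 3, age_hi = 4, n = 50,
                            height_p25 = 95, height_p50 = 98,
                            height_p75 = 101, weight_p25 = 15,
                            weight_p50 = 17, weight_p75 = 20),
                 class = c("cleaning_quantiles", "data.frame"))
  # [15 - 5*2^0.75, 20 + 9*3] = [6.591, 47.0]
  rec <- make_records(age = rep(3.5, 4), height = 98,
                      weight = c(6.5, 6.6, 47.0, 47.1))
  fl <- flag_weight_outliers(rec, q)
  expect_setequal(fl$excluded$weight_kg, c(6.5, 47.1))
  expect_equal(fl$excluded$lower[1], 15 - 5 * 2^0.75)
  expect_equal(fl$excluded$upper[1], 47)
})

test_that("duplicates collapse and injected flaws are recovered", {
  coh <- sample_cohort(cohort_config(n = 10000, seed = 17))
  inj <- inject_errors(coh, duplicate_rate = 0.005, swap_rate = 0.005,
                       decimal_rate = 0.005, seed = 18)
  dr <- dedupe_and_repair(inj$records)
  injected <- unique(inj$ledger$record_id)
  flagged <- unique(dr$report$record_id)
  expect_gte(mean(injected %in% flagged), 0.95)          # sensitivity
  false_flags <- setdiff(flagged, injected)
  expect_lte(length(false_flags) / nrow(coh), 0.001)     # specificity
  # two byte-identical rows: one kept, one reported
  two <- make_records(c(5.5, 5.5), c(110, 110), c(19, 19))
  two$record_id <- "same"
  dd <- dedupe_and_repair(rbind(two, make_records(rep(5.4, 30),
                                                  100 + 1:30, 15 + 1:30)))
  expect_equal(sum(dd$report$action == "duplicate_removed"), 1)
  # opt-in repair restores swapped values
  rep1 <- dedupe_and_repair(inj$records, repair = TRUE)
  swaps <- inj$ledger$record_id[inj$ledger$kind == "swap"]
  fixed <- rep1$records[match(swaps, rep1$records$record_id), ]
  orig <- coh[match(swaps, coh$record_id), ]
  expect_equal(fixed$height_cm, orig$height_cm)
})

test_that("the full pass is idempotent, order-invariant and light-touch", {
  coh <- sample_cohort(cohort_config(n = 10000, seed = 23))
  cl <- clean_cohort(coh)
  expect_lt(nrow(cl$report) / nrow(coh), 0.005)   # bounds sit ~4 robust SD out
  cl2 <- clean_cohort(cl$records)
  expect_equal(nrow(cl2$report), 0)
  expect_identical(cl2$records, cl$records)
  perm <- coh[sample(nrow(coh)), ]
  clp <- clean_cohort(perm)
  expect_setequal(clp$records$record_id, cl$records$record_id)
})
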