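test_that("band counts split records at the percentile band", {
  crv <- reference_curve("F", "bmi")
  coh <- sample_cohort(cohort_config(n = 25000, sex = "F", seed = 61,
                                     origin_effects = no_origin_effects("F")))
  coh$region <- "german"
  tab <- band_counts(coh, crv, band = c(97, 100), age_range = c(2, 18))
  n <- sum(tab)
  # ~3% binomial mass lands in the band
  expect_lt(abs(tab["band", "german"] / n - 0.03), 0.005)
  # the whole range puts everyone in the band row
  all_band <- band_counts(coh, crv, band = c(0, 100), age_range = c(2, 18))
  expect_equal(unname(all_band["outside", "german"]), 0)
  # permuting labels permutes columns identically
  coh2 <- sample_cohort(cohort_config(n = 5000, sex = "F", seed = 62))
  t1 <- band_counts(coh2, crv, age_range = c(8, 16))
  coh3 <- coh2
  coh3$region <- chartr("gr", "rg", coh3$region)  # german <-> romande initials
  map <- c(german = "rerman", romande = "gomande", ticino = "ticino")
  coh3$region <- unname(map[coh2$region])
  t2 <- band_counts(coh3, crv, age_range = c(8, 16))
  expect_equal(unname(t1[, "german"]), unname(t2[, "rerman"]))
  expect_equal(unname(t1[, "romande"]), unname(t2[, "gomande"]))
})

test_that("the Pearson test matches closed forms and the printed table", {
  # proportional rows: perfect independence
  prop <- rbind(c(10, 20, 30), c(1, 2, 3))
  r0 <- suppressWarnings(contingency_test(prop))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_true(all(abs(r0$stdres) < 1e-6))
  # published regional table: statistic, df, residuals
  counts <- load_region_band_counts()
  tab <- rbind(outside = counts$all_percentiles, band = counts$band_97_100)
  colnames(tab) <- counts$region
  res <- contingency_test(tab)
  expect_equal(res$statistic, 9.0664, tolerance = 1e-4)
  expect_equal(res$df, 2)
  expect_equal(round(res$p.value, 3), 0.011)
  expect_equal(unname(round(res$stdres["band", ], 1)), c(-3.0, 2.5, 1.2))
  # 2x2 closed form N(ad - bc)^2 / (r1 r2 c1 c2)
  t22 <- rbind(c(10, 20), c(20, 10))
  expect_equal(contingency_test(t22)$statistic,
               60 * (100 - 400)^2 / (30 * 30 * 30 * 30))
  # the spec's residual formula, computed independently
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  adj <- (tab - E) / sqrt(E * (1 - rowSums(tab) / sum(tab)) %o%
                            (1 - colSums(tab) / sum(tab)))
  expect_equal(unname(res$stdres), unname(adj), tolerance = 1e-12)
  expect_error(contingency_test(rbind(c(0, 0), c(1, 2))), "merge")
  expect_error(contingency_test(rbind(c(-1, 2), c(1, 2))), "non-negative")
})

test_that("residual and scale identities hold for 2 x K tables", {
  set.seed(63)
  for (rep in 1:20) {
    tab <- matrix(rpois(6, lambda = 40) + 1, nrow = 2)
    res <- contingency_test(tab)
    # column residuals are equal in magnitude, opposite in sign
    expect_equal(res$stdres[1, ], -res$stdres[2, ], tolerance = 1e-9)
    # scaling counts by c scales X2 by c and residuals by sqrt(c)
    res4 <- contingency_test(tab * 4)
    expect_equal(res4$statistic, 4 * res$statistic, tolerance = 1e-9)
    expect_equal(res4$stdres, 2 * res$stdres, tolerance = 1e-9)
  }
})

test_that("the test holds its nominal level under an independent-margins null", {
  set.seed(64)
  rate <- null_rejection_rate(reps = 4000, n = 500)
  expect_lt(abs(rate - 0.05), 0.015)
})
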