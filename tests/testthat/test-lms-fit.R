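test_that("the age transform is a normalised power law", {
  expect_equal(transform_age(c(1, 4, 9), lambda = 1, span = 9), c(1, 4, 9) / 9)
  expect_equal(transform_age(c(1, 4, 9), lambda = 0.5, span = 9),
               c(1 / 3, 2 / 3, 1))
  set.seed(1)
  a <- sort(runif(50, 0.1, 20))
  for (lam in c(0.3, 1, 2.5))
    expect_true(all(diff(transform_age(a, lam)) > 0))
  expect_error(transform_age(0, offset = 0), "positive")
})

test_that("constant-parameter data are recovered under heavy penalties", {
  rec <- constant_param_records(5000, mu = 16, sigma = 0.12, nu = -0.8,
                                seed = 41)
  fit <- fit_lms(rec, fit_config("weight", "F", age_range = c(2, 18),
                                 regime = "rigid"))
  expect_true(fit$converged)
  p <- curve_params(fit$curve, seq(3, 17, 1))
  expect_lt(max(abs(p$mu / 16 - 1)), 0.02)
  expect_lt(max(abs(p$sigma / 0.12 - 1)), 0.02)
  expect_lt(max(abs(p$nu + 0.8)), 0.15)
  # penalized deviance is non-increasing across outer iterations
  expect_true(all(diff(fit$trace) <= 1e-6))
  expect_error(fit_lms(rec[1:50, ], fit_config("weight", "F", c(2, 18))),
               ">= 200 required")
})

test_that("a reference-drawn cohort is recovered across the age window", {
  coh <- sample_cohort(cohort_config(n = 20000, sex = "F", seed = 43,
                                     origin_effects = no_origin_effects("F")))
  fit <- fit_lms(coh, fit_config("bmi", "F", age_range = c(2, 18)))
  truth <- reference_curve("F", "bmi")
  ages <- seq(3, 17, 0.2)
  rel <- abs(curve_quantile(fit$curve, ages, 50) /
               curve_quantile(truth, ages, 50) - 1)
  expect_lt(max(rel), 0.015)
})

test_that("monotone enforcement projects dips and leaves monotone fits alone", {
  fake_fit <- function(curve) {
    structure(list(curve = curve,
                   config = fit_config("height", "F",
                                       age_range = range(curve$age)),
                   deviance = NA_real_, trace = NA_real_, iterations = 0L,
                   converged = TRUE, n = 0L),
              class = "lms_fit")
  }
  ages <- seq(2, 18, length.out = 161)
  up <- lms_curve(ages, mu = 80 + 5 * ages, sigma = rep(0.04, 161),
                  nu = rep(1, 161), sex = "F", measure = "height")
  out <- enforce_monotone_median(fake_fit(up))
  expect_equal(attr(out, "monotone_adjustment"), 0)
  expect_equal(out$curve$mu, up$mu)
  # an artificial dip in the median is projected away
  dip_mu <- 80 + 5 * ages - 8 * exp(-((ages - 10) / 0.8)^2)
  dip <- lms_curve(ages, mu = dip_mu, sigma = rep(0.04, 161),
                   nu = rep(1, 161), sex = "F", measure = "height")
  mono <- enforce_monotone_median(fake_fit(dip))
  grid <- seq(2, 18, 0.05)
  expect_true(all(diff(curve_params(mono$curve, grid)$mu) >= -1e-9))
  expect_gt(attr(mono, "monotone_adjustment"), 0)
  # the projection agrees with an independent pool-adjacent-violators oracle
  mu_in <- curve_params(dip, grid)$mu
  expect_equal(curve_params(mono$curve, grid)$mu, pava_oracle(mu_in),
               tolerance = 1e-6)
  # the constrained centiles are monotone too
  for (lv in c(3, 50, 97))
    expect_true(all(diff(curve_quantile(mono$curve, grid, lv)) >= -1e-9))
})

test_that("stitching cross-fades on the log scale and keeps centiles continuous", {
  c80 <- constant_curve(80, 0.04, 1, lo = 0, hi = 2, measure = "height")
  c82 <- constant_curve(82, 0.04, 1, lo = 0.25, hi = 18, measure = "height")
  st <- stitch_models(c80, c82, join = 1.2, halfwidth = 0.3)
  expect_equal(curve_quantile(st, 1.2, 50), sqrt(80 * 82), tolerance = 1e-9)
  expect_equal(curve_quantile(st, 0.5, 50), 80)   # below the blend
  expect_equal(curve_quantile(st, 5, 50), 82)     # above the blend
  # identical part-models stitch to themselves
  same <- stitch_models(c82, c82, join = 1.2)
  ages <- seq(0.3, 17.9, 0.05)
  expect_lt(max(abs(curve_quantile(same, ages, 97) -
                      curve_quantile(c82, ages, 97))), 1e-9)
  # no jumps anywhere across the blend, and grid refinement changes nothing
  fine <- stitch_models(c80, c82, join = 1.2, step = 0.005)
  probe <- seq(0.85, 1.55, 0.001)
  med <- curve_quantile(st, probe, 50)
  expect_lt(max(abs(diff(med))), 0.02)  # continuous at 0.001-y resolution
  expect_lt(max(abs(curve_quantile(fine, probe, 50) - med)), 1e-6)
  expect_error(stitch_models(c80, c82, join = 10), "do not overlap")
})

test_that("worm-plot statistics flag scale misfit and pass calibrated data", {
  crv <- constant_curve(16, 0.12, -0.8, lo = 2, hi = 18)
  set.seed(46)
  age <- runif(6000, 2, 18)
  ok <- make_records(age, height = 100,
                     weight = qBCCGo(pnorm(rnorm(6000)), 16, 0.12, -0.8))
  ok$weight_kg <- ok$weight_kg * (ok$height_cm / 100)^2  # bmi == weight here
  ws <- worm_plot_stats(ok, crv, breaks = c(2, 7, 12, 18))
  expect_equal(nrow(ws), 3)
  expect_true(all(abs(ws$intercept) < 0.05))
  expect_true(all(abs(ws$slope) < 0.05))
  expect_false(any(ws$flagged))
  # variance inflated by 1.3: positive slope, flagged
  bad <- ok
  bad$weight_kg <- qBCCGo(pnorm(rnorm(6000, sd = 1.3)), 16, 0.12, -0.8)
  wb <- worm_plot_stats(bad, crv, breaks = c(2, 7, 12, 18))
  expect_true(all(wb$slope > 0.1))
  expect_true(all(wb$flagged))
  # sparse groups are skipped with a notice
  expect_message(worm_plot_stats(ok[1:40, ], crv, breaks = c(2, 7, 12, 18)),
                 "skipped")
})

test_that("median velocity matches finite differences of the reference", {
  flat <- constant_curve(100, 0.04, 1, lo = 0, hi = 10, measure = "height")
  expect_lt(max(abs(median_velocity(flat)$velocity)), 1e-9)
  lin <- lms_curve(c(0, 5, 10), mu = 100 + 2 * c(0, 5, 10),
                   sigma = rep(0.04, 3), nu = rep(1, 3), measure = "height")
  v <- median_velocity(lin)
  expect_equal(v$velocity, rep(2, nrow(v)), tolerance = 1e-9)
  # girls' height velocity at 6.5 y ~ (117.1 - 110.3) cm/y from printed medians
  ref <- median_velocity(reference_curve("F", "height"), step = 0.5)
  expect_equal(ref$velocity[which.min(abs(ref$age - 6.5))], 6.8,
               tolerance = 0.5)
})
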