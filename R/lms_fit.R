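#' Configuration of a penalized LMS fit
#'
#' The fit estimates age-varying `(mu, sigma, nu)` by penalized maximum
#' likelihood under the Box-Cox Cole-Green distribution.  `log mu` and
#' `log sigma` are modelled as P-splines (cubic B-spline basis on the
#' transformed age with a quadratic second-difference penalty); `nu` is
#' modelled on the identity scale with a much stiffer penalty, keeping the
#' skewness curve near-linear in age as standard LMS practice recommends.
#'
#' Two penalty regimes are offered: `"adaptive"` (penalties grow with
#' `n / log n`, the default, appropriate for the tens of thousands of
#' records of a reference study) and `"rigid"` (ten-fold stiffer, for a
#' deliberately conservative preparatory fit).
#'
#' @param measure `"height"`, `"weight"` or `"bmi"`.
#' @param sex `"F"` or `"M"` (metadata carried to the fitted curve).
#' @param age_range fitting window `(lower, upper)` in years.
#' @param lambda_age exponent of the age transform, see [transform_age()];
#'   values below 1 stretch infancy, where growth is fastest.
#' @param age_offset offset added to age before transforming (allows a
#'   window starting at birth with `lambda_age < 1`).
#' @param n_segments number of B-spline segments (basis size is
#'   `n_segments + 3`).
#' @param penalties named vector `c(mu=, sigma=, nu=)` of penalty weights,
#'   or `NULL` for the regime defaults.
#' @param regime `"adaptive"` or `"rigid"`.
#' @param monotone enforce a non-decreasing median after fitting? (default:
#'   only for height; BMI references are legitimately non-monotone).
#' @param max_iter,tol outer-iteration cap and convergence tolerance on the
#'   relative change of the penalized deviance.
#' @param join optional `list(age =, halfwidth =)` stitching specification,
#'   carried as metadata for [stitch_models()].
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(measure = c("height", "weight", "bmi"),
                       sex = c("F", "M"), age_range,
                       lambda_age = 1, age_offset = 0, n_segments = 12,
                       penalties = NULL, regime = c("adaptive", "rigid"),
                       monotone = NULL, max_iter = 50, tol = 1e-7,
                       join = NULL) {
  measure <- match.arg(measure); sex <- match.arg(sex)
  regime <- match.arg(regime)
  stopifnot(length(age_range) == 2, age_range[1] < age_range[2],
            tol > 0, max_iter >= 1, n_segments >= 3, lambda_age > 0)
  if (!is.null(penalties)) {
    stopifnot(all(c("mu", "sigma", "nu") %in% names(penalties)),
              all(penalties >= 0))
  }
  if (is.null(monotone)) monotone <- measure == "height"
  structure(list(measure = measure, sex = sex, age_range = age_range,
                 lambda_age = lambda_age, age_offset = age_offset,
                 n_segments = n_segments, penalties = penalties,
                 regime = regime, monotone = monotone,
                 max_iter = max_iter, tol = tol, join = join),
            class = "fit_config")
}

#' Power transform of age
#'
#' `t* = ((age + offset) / span) ^ lambda`, strictly increasing for any
#' `lambda > 0`.  Sub-unity exponents expand the infant end of the age
#' axis, giving the spline basis more resolution where growth velocity is
#' highest.
#'
#' @param age decimal ages.
#' @param lambda exponent, > 0.
#' @param offset shift, must keep `age + offset > 0`.
#' @param span normalising span (default `max(age + offset)`).
#' @return transformed ages.
#' @export
transform_age <- function(age, lambda = 1, offset = 0, span = NULL) {
  x <- age + offset
  if (any(x <= 0))
    stop("age + offset must be positive for the power transform",
         call. = FALSE)
  if (is.null(span)) span <- max(x)
  (x / span)^lambda
}

# equally spaced cubic B-spline basis (classical P-spline setup)
.bbase <- function(x, xl = 0, xr = 1, ndx = 12, deg = 3) {
  dx <- (xr - xl) / ndx
  knots <- seq(xl - deg * dx, xr + deg * dx, by = dx)
  splines::splineDesign(knots, pmin(pmax(x, xl), xr), ord = deg + 1,
                        outer.ok = TRUE)
}

.loglik_bccgo <- function(y, mu, sigma, nu) {
  sum(dBCCGo(y, mu, sigma, nu, log = TRUE))
}

.default_penalties <- function(regime, n) {
  base <- c(mu = 2, sigma = 100, nu = 2000) * n / 1000
  if (regime == "rigid") base <- base * 10
  base
}

# per-parameter penalty matrices.  The rigid regime adds a first-difference
# penalty on the shape parameters: a D2 penalty leaves their linear-in-age
# component free, and sigma and nu carry so little likelihood information
# that this component chases sampling noise; the conservative preparatory
# regime shrinks them toward constants instead, as classic LMS practice
# does for the skewness curve.
.penalty_matrices <- function(K, lam, regime) {
  D2 <- diff(diag(K), differences = 2)
  D1 <- diff(diag(K), differences = 1)
  P2 <- crossprod(D2); P1 <- crossprod(D1)
  lam1 <- if (regime == "rigid") c(mu = 0, sigma = 5, nu = 5) * lam else
    c(mu = 0, sigma = 0, nu = 0)
  list(mu = lam[["mu"]] * P2 + lam1[["mu"]] * P1,
       sigma = lam[["sigma"]] * P2 + lam1[["sigma"]] * P1,
       nu = lam[["nu"]] * P2 + lam1[["nu"]] * P1)
}

#' Fit an age-varying LMS model by penalized maximum likelihood
#'
#' Maximises `sum log f_BCCGo(y_i; mu(t_i), sigma(t_i), nu(t_i))` minus
#' second-difference penalties on the spline coefficients of each
#' parameter, by parameter-wise Fisher scoring (the RS backfitting scheme):
#' each parameter in turn is updated by a penalized weighted least-squares
#' step built from the score and (approximate) expected information of its
#' predictor, with step-halving whenever a step fails to decrease the
#' penalized deviance.  Per-observation quantities, with
#' `u = (y/mu)^nu` and `z` the LMS z-score:
#' * `d l / d log mu  = z u / sigma - nu`, weight `1/sigma^2 + 2 nu^2`
#' * `d l / d log sigma = z^2 - 1`, weight `2`
#' * `d l / d nu` evaluated exactly, weight `7 sigma^2 / 4`
#'
#' The sigma and nu weights are the leading small-sigma terms of the
#' expected information, accurate for growth data where `sigma` is a few
#' percent.  Cross-derivatives between parameters are ignored, as in
#' standard GAMLSS backfitting.
#'
#' @param records canonical record data frame (the measure is taken from
#'   `height_cm`, `weight_kg`, or their BMI ratio per `config$measure`).
#' @param config a [fit_config()].
#' @return object of class `lms_fit`: list with `curve` (an [lms_curve] on
#'   a fine grid over the window), `config`, `deviance` (final penalized
#'   deviance), `trace`, `iterations`, `converged`, `n`.
#' @export
fit_lms <- function(records, config) {
  stopifnot(inherits(config, "fit_config"))
  win <- config$age_range
  rec <- records[records$age_years >= win[1] & records$age_years <= win[2], ]
  if (nrow(rec) < 200)
    stop(sprintf("only %d records in the fitting window [%g, %g]; >= 200 required",
                 nrow(rec), win[1], win[2]), call. = FALSE)
  y <- switch(config$measure,
              height = rec$height_cm,
              weight = rec$weight_kg,
              bmi = rec$weight_kg / (rec$height_cm / 100)^2)
  .check_pos(y, config$measure)
  age <- rec$age_years
  n <- length(y)

  span <- win[2] + config$age_offset
  tfun <- function(a) transform_age(a, config$lambda_age, config$age_offset,
                                    span = span)
  t_lo <- tfun(win[1]); t_hi <- tfun(win[2])
  u01 <- (tfun(age) - t_lo) / (t_hi - t_lo)
  B <- .bbase(u01, 0, 1, config$n_segments)
  K <- ncol(B)
  lam <- config$penalties %||% .default_penalties(config$regime, n)
  Pl <- .penalty_matrices(K, lam, config$regime)
  P <- Pl$mu / max(lam[["mu"]], 1e-12)   # unit D2 form for the mu init

  # initial values: smoothed log-median, then a constant-parameter ML fit
  # for (sigma, nu) given that median -- nu carries little likelihood
  # information, so a poor start would stall the outer loop early
  a_mu <- solve(crossprod(B) + lam["mu"] * P + 1e-8 * diag(K),
                crossprod(B, log(y)))
  eta_mu <- drop(B %*% a_mu)
  s0 <- max(stats::sd(log(y) - eta_mu), 1e-3)
  mu0 <- exp(eta_mu)
  init <- stats::optim(c(log(s0), 1), function(par)
    -.loglik_bccgo(y, mu0, exp(min(max(par[1], -9), 0.7)),
                   min(max(par[2], -6), 6)),
    control = list(maxit = 200))
  a_sig <- rep(min(max(init$par[1], -9), 0.7), K)
  a_nu <- rep(min(max(init$par[2], -6), 6), K)

  pen_dev <- function(am, as_, an) {
    mu <- exp(drop(B %*% am)); sg <- exp(drop(B %*% as_))
    nu <- drop(B %*% an)
    -2 * .loglik_bccgo(y, mu, sg, nu) +
      sum(am * (Pl$mu %*% am)) +
      sum(as_ * (Pl$sigma %*% as_)) +
      sum(an * (Pl$nu %*% an))
  }

  dev <- pen_dev(a_mu, a_sig, a_nu)
  trace <- dev
  converged <- FALSE
  it <- 0
  for (it in seq_len(config$max_iter)) {
    for (par in c("mu", "sigma", "nu")) {
      mu <- exp(drop(B %*% a_mu))
      sg <- pmin(pmax(exp(drop(B %*% a_sig)), 1e-5), 2)
      nu <- pmin(pmax(drop(B %*% a_nu), -6), 6)
      z <- zBCCGo(y, mu, sg, nu)
      if (par == "mu") {
        uu <- 1 + nu * sg * z                      # (y/mu)^nu, exactly
        score <- z * uu / sg - nu
        w <- 1 / sg^2 + 2 * nu^2
        a_old <- a_mu; eta <- drop(B %*% a_mu)
      } else if (par == "sigma") {
        score <- z^2 - 1
        w <- rep(2, n)
        a_old <- a_sig; eta <- drop(B %*% a_sig)
      } else {
        l <- log(y / mu)
        dz <- ifelse(abs(nu) < .nu_eps,
                     l^2 / (2 * sg),
                     (l * (1 + nu * sg * z)) / (nu * sg) - z / nu)
        score <- -z * dz + l
        w <- pmax(7 * sg^2 / 4, 1e-8)
        a_old <- a_nu; eta <- drop(B %*% a_nu)
      }
      lhs <- crossprod(B * w, B) + Pl[[par]] + 1e-10 * diag(K)
      rhs <- crossprod(B, w * eta + score)
      a_new <- tryCatch(drop(solve(lhs, rhs)),
                        error = function(e)
                          stop(sprintf("singular basis while updating `%s`", par),
                               call. = FALSE))
      # step-halving towards the old coefficients if the step overshoots
      step <- 1
      repeat {
        a_try <- a_old + step * (a_new - a_old)
        d_try <- switch(par,
                        mu = pen_dev(a_try, a_sig, a_nu),
                        sigma = pen_dev(a_mu, a_try, a_nu),
                        nu = pen_dev(a_mu, a_sig, a_try))
        if (is.finite(d_try) && d_try <= dev + 1e-10) break
        step <- step / 2
        if (step < 1e-4) { a_try <- a_old; d_try <- dev; break }
      }
      dev <- d_try
      if (par == "mu") a_mu <- a_try
      else if (par == "sigma") a_sig <- a_try
      else a_nu <- a_try
    }
    trace <- c(trace, dev)
    last <- trace[length(trace) - 1]
    if (abs(last - dev) < config$tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      break
    }
  }

  grid_age <- seq(win[1], win[2], length.out = 161)
  gu <- (tfun(grid_age) - t_lo) / (t_hi - t_lo)
  Bg <- .bbase(gu, 0, 1, config$n_segments)
  curve <- lms_curve(grid_age,
                     mu = exp(drop(Bg %*% a_mu)),
                     sigma = pmin(pmax(exp(drop(Bg %*% a_sig)), 1e-5), 2),
                     nu = pmin(pmax(drop(Bg %*% a_nu), -6), 6),
                     sex = config$sex, measure = config$measure)
  structure(list(curve = curve, config = config,
                 coefficients = list(mu = drop(a_mu), sigma = drop(a_sig),
                                     nu = drop(a_nu)),
                 deviance = dev, trace = trace, iterations = it,
                 converged = converged, n = n),
            class = "lms_fit")
}

#' @export
print.lms_fit <- function(x, ...) {
  cat(sprintf("<lms_fit> %s %s on [%g, %g] y: n = %d, penalized deviance %.2f, %s in %d iterations\n",
              x$config$sex, x$config$measure, x$config$age_range[1],
              x$config$age_range[2], x$n, x$deviance,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

.as_curve <- function(x) {
  if (inherits(x, "lms_fit")) x$curve
  else if (inherits(x, "lms_curve")) x
  else stop("expected an `lms_fit` or `lms_curve`", call. = FALSE)
}

#' Enforce a non-decreasing median curve
#'
#' Projects the fitted median onto the nearest (least-squares) non-
#' decreasing curve via isotonic regression on a fine age grid, leaving
#' already-monotone fits untouched.  When `records` are supplied, `sigma`
#' and `nu` are refitted conditional on the constrained median, so the
#' scale and skewness adapt to the projection.  Intended for height
#' references; BMI references are legitimately non-monotone and should
#' bypass this step.
#'
#' @param fit an `lms_fit`.
#' @param records optional records for the conditional refit of
#'   `sigma`/`nu`.
#' @param step grid resolution in years for the monotonicity check.
#' @return the (possibly) modified `lms_fit`, with attribute
#'   `monotone_adjustment` (max absolute change of the median, in measure
#'   units).
#' @export
enforce_monotone_median <- function(fit, records = NULL, step = 0.05) {
  stopifnot(inherits(fit, "lms_fit"))
  crv <- fit$curve
  grid <- seq(min(crv$age), max(crv$age), by = step)
  if (grid[length(grid)] < max(crv$age)) grid <- c(grid, max(crv$age))
  p <- curve_params(crv, grid)
  if (all(diff(p$mu) >= 0)) {
    attr(fit, "monotone_adjustment") <- 0
    return(fit)
  }
  iso <- stats::isoreg(grid, p$mu)
  adj <- max(abs(iso$yf - p$mu))
  new_curve <- lms_curve(grid, mu = iso$yf,
                         sigma = p$sigma, nu = p$nu,
                         sex = crv$sex, measure = crv$measure)
  fit$curve <- new_curve
  if (!is.null(records)) {
    refit <- .refit_scale_shape(records, fit)
    fit$curve <- refit$curve
    fit$deviance <- refit$deviance
  }
  attr(fit, "monotone_adjustment") <- adj
  fit
}

# conditional sigma/nu refit with mu(t) held fixed
.refit_scale_shape <- function(records, fit) {
  cfg <- fit$config
  win <- cfg$age_range
  rec <- records[records$age_years >= win[1] & records$age_years <= win[2], ]
  y <- switch(cfg$measure,
              height = rec$height_cm, weight = rec$weight_kg,
              bmi = rec$weight_kg / (rec$height_cm / 100)^2)
  age <- rec$age_years
  n <- length(y)
  mu <- curve_params(fit$curve, age)$mu

  span <- win[2] + cfg$age_offset
  tfun <- function(a) transform_age(a, cfg$lambda_age, cfg$age_offset, span)
  u01 <- (tfun(age) - tfun(win[1])) / (tfun(win[2]) - tfun(win[1]))
  B <- .bbase(u01, 0, 1, cfg$n_segments)
  K <- ncol(B)
  lam <- cfg$penalties %||% .default_penalties(cfg$regime, n)
  Pl <- .penalty_matrices(K, lam, cfg$regime)
  a_sig <- rep(log(max(stats::sd(log(y / mu)), 1e-3)), K)
  a_nu <- rep(1, K)
  dev <- Inf
  for (it in 1:30) {
    for (par in c("sigma", "nu")) {
      sg <- pmin(pmax(exp(drop(B %*% a_sig)), 1e-5), 2)
      nu <- pmin(pmax(drop(B %*% a_nu), -6), 6)
      z <- zBCCGo(y, mu, sg, nu)
      if (par == "sigma") {
        score <- z^2 - 1; w <- rep(2, n)
        eta <- drop(B %*% a_sig)
      } else {
        l <- log(y / mu)
        dz <- ifelse(abs(nu) < .nu_eps, l^2 / (2 * sg),
                     (l * (1 + nu * sg * z)) / (nu * sg) - z / nu)
        score <- -z * dz + l; w <- pmax(7 * sg^2 / 4, 1e-8)
        eta <- drop(B %*% a_nu)
      }
      a_new <- drop(solve(crossprod(B * w, B) + Pl[[par]] + 1e-10 * diag(K),
                          crossprod(B, w * eta + score)))
      if (par == "sigma") a_sig <- a_new else a_nu <- a_new
    }
    sg <- pmin(pmax(exp(drop(B %*% a_sig)), 1e-5), 2)
    nu <- pmin(pmax(drop(B %*% a_nu), -6), 6)
    d_new <- -2 * .loglik_bccgo(y, mu, sg, nu) +
      sum(a_sig * (Pl$sigma %*% a_sig)) + sum(a_nu * (Pl$nu %*% a_nu))
    if (is.finite(dev) && abs(dev - d_new) < 1e-6 * (abs(d_new) + 0.1)) break
    dev <- d_new
  }
  grid <- fit$curve$age
  gu <- (tfun(grid) - tfun(win[1])) / (tfun(win[2]) - tfun(win[1]))
  Bg <- .bbase(gu, 0, 1, cfg$n_segments)
  list(curve = lms_curve(grid, mu = fit$curve$mu,
                         sigma = pmin(pmax(exp(drop(Bg %*% a_sig)), 1e-5), 2),
                         nu = pmin(pmax(drop(Bg %*% a_nu), -6), 6),
                         sex = fit$curve$sex, measure = fit$curve$measure),
       deviance = dev)
}

#' Join two part-models into one reference curve
#'
#' Growth references often need different smoothness in infancy and
#' childhood; the standard remedy is two overlapping part-models joined at
#' a stated age.  Here the two fits are cross-faded parameter-wise — a
#' linear blend of `(log mu, log sigma, nu)` over
#' `[join - halfwidth, join + halfwidth]` — which keeps every centile
#' continuous across the join and exactly equal to the respective
#' part-model outside the blend window.  At the join age the blended
#' median is the geometric mean of the two part medians.
#'
#' @param m1,m2 `lms_fit` or [lms_curve] objects; `m1` rules below the
#'   join, `m2` above.
#' @param join join age in years.
#' @param halfwidth half-width of the blend window (default 0.3 y).
#' @param step grid resolution of the stitched curve.
#' @return an [lms_curve] spanning both windows.
#' @export
stitch_models <- function(m1, m2, join, halfwidth = 0.3, step = 0.02) {
  c1 <- .as_curve(m1); c2 <- .as_curve(m2)
  s1 <- range(c1$age); s2 <- range(c2$age)
  if (s1[2] < join + halfwidth || s2[1] > join - halfwidth)
    stop(sprintf("part-models do not overlap the blend window [%g, %g]",
                 join - halfwidth, join + halfwidth), call. = FALSE)
  grid <- sort(unique(c(seq(s1[1], s2[2], by = step), join - halfwidth,
                        join, join + halfwidth, s2[2])))
  p <- .stitch_params(c1, c2, join, halfwidth, grid)
  out <- lms_curve(grid, mu = p$mu, sigma = p$sigma, nu = p$nu,
                   sex = c1$sex, measure = c1$measure)
  # keep the part-models so evaluation is exact, independent of the grid
  attr(out, "stitch") <- list(c1 = c1, c2 = c2, join = join,
                              halfwidth = halfwidth)
  out
}

.stitch_params <- function(c1, c2, join, halfwidth, age) {
  s1 <- range(c1$age); s2 <- range(c2$age)
  w <- pmin(pmax((age - (join - halfwidth)) / (2 * halfwidth), 0), 1)
  lo <- age <= join + halfwidth
  hi <- age >= join - halfwidth
  n <- length(age)
  full1 <- full2 <- list(mu = numeric(n), sigma = numeric(n),
                         nu = numeric(n))
  p1 <- curve_params(c1, pmin(age[lo], s1[2]))
  p2 <- curve_params(c2, pmax(age[hi], s2[1]))
  for (f in c("mu", "sigma", "nu")) {
    full1[[f]][lo] <- p1[[f]]
    full2[[f]][hi] <- p2[[f]]
  }
  blend <- function(f, logscale) {
    v1 <- full1[[f]]; v2 <- full2[[f]]
    v1[!lo] <- v2[!lo]; v2[!hi] <- v1[!hi]
    if (logscale) exp((1 - w) * log(v1) + w * log(v2))
    else (1 - w) * v1 + w * v2
  }
  data.frame(age = age, mu = blend("mu", TRUE),
             sigma = blend("sigma", TRUE), nu = blend("nu", FALSE))
}

#' Worm-plot summary statistics
#'
#' Detrended QQ diagnostics of model residuals by age group: within each
#' group the ordered z-scores are compared to the expected normal order
#' statistics and the deviation is regressed on the theoretical quantile
#' with a quadratic term.  A well-calibrated model gives coefficients near
#' zero; the intercept picks up location misfit, the slope scale misfit
#' (positive slope = residual variance above 1), the curvature skewness
#' misfit.  Groups are flagged when |intercept| or |slope| exceeds 0.10.
#'
#' @param records canonical record data frame.
#' @param model an `lms_fit` or [lms_curve].
#' @param breaks age-group boundaries partitioning the window.
#' @param min_n groups smaller than this are skipped with a message.
#' @return data frame: `group`, `n`, `intercept`, `slope`, `curvature`,
#'   `flagged`.
#' @export
worm_plot_stats <- function(records, model, breaks, min_n = 30) {
  crv <- .as_curve(model)
  span <- range(crv$age)
  rec <- records[records$age_years >= span[1] & records$age_years <= span[2], ]
  y <- switch(crv$measure,
              height = rec$height_cm, weight = rec$weight_kg,
              bmi = rec$weight_kg / (rec$height_cm / 100)^2,
              stop("model curve carries no known measure", call. = FALSE))
  z <- curve_zscore(crv, rec$age_years, y)
  grp <- cut(rec$age_years, breaks, right = FALSE, include.lowest = TRUE)
  out <- list()
  for (g in levels(grp)) {
    zi <- z[grp == g & !is.na(grp)]
    if (length(zi) < min_n) {
      message(sprintf("worm_plot_stats: group %s has %d < %d records, skipped",
                      g, length(zi), min_n))
      next
    }
    xq <- stats::qnorm(stats::ppoints(length(zi)))
    dev <- sort(zi) - xq
    co <- stats::coef(stats::lm(dev ~ xq + I(xq^2)))
    out[[length(out) + 1]] <-
      data.frame(group = g, n = length(zi), intercept = co[1], slope = co[2],
                 curvature = co[3],
                 flagged = abs(co[1]) > 0.10 || abs(co[2]) > 0.10)
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(group = character(), n = integer(), intercept = numeric(),
                  slope = numeric(), curvature = numeric(),
                  flagged = logical())
  rownames(res) <- NULL
  res
}

#' Median velocity curve
#'
#' Central finite differences of the median with respect to age, used to
#' screen fitted curves for unrealistic wiggles: an accepted height fit
#' should have non-negative velocity with a single (pubertal) local
#' maximum after early childhood.
#'
#' @param curve an [lms_curve] or `lms_fit`.
#' @param step finite-difference step in years.
#' @return data frame `age`, `velocity` (measure units per year) on the
#'   interior grid `[min + step, max - step]`.
#' @export
median_velocity <- function(curve, step = 0.1) {
  crv <- .as_curve(curve)
  stopifnot(step > 0, 2 * step < diff(range(crv$age)))
  ages <- seq(min(crv$age) + step, max(crv$age) - step, by = step / 2)
  mu_p <- curve_params(crv, ages + step)$mu
  mu_m <- curve_params(crv, ages - step)$mu
  data.frame(age = ages, velocity = (mu_p - mu_m) / (2 * step))
}
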