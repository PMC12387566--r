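#' The Box-Cox Cole-Green (LMS) distribution
#'
#' The LMS method summarises an age-varying, positively skewed measurement
#' distribution by three parameters: the median `mu`, the coefficient of
#' variation `sigma`, and the Box-Cox power `nu` that removes skewness.  A
#' measurement `y` maps to a standard-normal deviate
#' \deqn{z = \frac{(y/\mu)^\nu - 1}{\nu\,\sigma} \quad (\nu \ne 0), \qquad
#'       z = \frac{\log(y/\mu)}{\sigma} \quad (\nu = 0),}
#' so centiles of the reference are `mu * (1 + nu * sigma * z_alpha)^(1/nu)`.
#' The `nu = 0` log form is the continuous limit of the power form; it is
#' taken whenever `|nu| < 1e-8`.
#'
#' The distribution is formally truncated below at `y = 0`; as in standard
#' LMS practice the truncation mass `Phi(-1/(sigma * |nu|))` is ignored here.
#' For growth data (`sigma` well below `1/|nu|`) that mass is far below
#' 1e-10 and the resulting error in `pBCCGo`/`qBCCGo` is negligible.
#'
#' @param y,q vector of positive measurements.
#' @param p vector of probabilities in (0, 1).
#' @param mu median parameter(s), > 0.
#' @param sigma coefficient of variation, > 0.
#' @param nu Box-Cox power (skewness); `nu = 1` is normal, `nu < 1` right skew.
#' @param log logical; return the log-density?
#' @return `zBCCGo` the z-score, `pBCCGo` the CDF, `qBCCGo` the quantile,
#'   `dBCCGo` the density, each vectorised over its arguments.
#' @examples
#' zBCCGo(110, mu = 100, sigma = 0.05, nu = 1)   # 2
#' pBCCGo(110, mu = 100, sigma = 0.05, nu = 1)   # pnorm(2)
#' qBCCGo(0.5, mu = 21.4, sigma = 0.13, nu = -1.2)
#' @name bccgo
NULL

.nu_eps <- 1e-8

.check_pos <- function(x, what) {
  if (any(!is.finite(x) | x <= 0))
    stop(sprintf("`%s` must be positive and finite", what), call. = FALSE)
  invisible(x)
}

#' @rdname bccgo
#' @export
zBCCGo <- function(y, mu, sigma, nu) {
  .check_pos(y, "y"); .check_pos(mu, "mu"); .check_pos(sigma, "sigma")
  n <- max(length(y), length(mu), length(sigma), length(nu))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  l <- log(y / mu)
  z <- l / sigma                      # nu = 0 branch
  pw <- abs(nu) >= .nu_eps
  z[pw] <- (exp(nu[pw] * l[pw]) - 1) / (nu[pw] * sigma[pw])
  z
}

#' @rdname bccgo
#' @export
pBCCGo <- function(q, mu, sigma, nu) {
  stats::pnorm(zBCCGo(q, mu, sigma, nu))
}

#' @rdname bccgo
#' @export
qBCCGo <- function(p, mu, sigma, nu) {
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  .check_pos(mu, "mu"); .check_pos(sigma, "sigma")
  n <- max(length(p), length(mu), length(sigma), length(nu))
  p <- rep_len(p, n); mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  z <- stats::qnorm(p)
  out <- mu * exp(sigma * z)
  pw <- abs(nu) >= .nu_eps
  if (any(pw)) {
    a <- 1 + nu[pw] * sigma[pw] * z[pw]
    # below the truncation point the quantile is pinned just above zero
    a[a <= 0] <- .Machine$double.eps
    out[pw] <- mu[pw] * a^(1 / nu[pw])
  }
  out
}

#' @rdname bccgo
#' @export
dBCCGo <- function(y, mu, sigma, nu, log = FALSE) {
  z <- zBCCGo(y, mu, sigma, nu)
  n <- length(z)
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  ld <- stats::dnorm(z, log = TRUE) + nu * log(y / mu) - log(y) - log(sigma)
  if (log) ld else exp(ld)
}

#' A single LMS reference point
#'
#' Bundles an age with its `(mu, sigma, nu)` triplet.  `mu` carries the units
#' of the measure (cm, kg or kg/m2); `sigma` and `nu` are dimensionless.
#'
#' @param age decimal age in years (>= 0); `NA` for an age-free triplet.
#' @param mu,sigma,nu distribution parameters, see [bccgo].
#' @return an object of class `lms_point`.
#' @export
lms_point <- function(age = NA_real_, mu, sigma, nu) {
  stopifnot(length(mu) == 1, length(sigma) == 1, length(nu) == 1)
  .check_pos(mu, "mu"); .check_pos(sigma, "sigma")
  if (!is.na(age) && age < 0) stop("`age` must be >= 0", call. = FALSE)
  structure(list(age = as.numeric(age), mu = as.numeric(mu),
                 sigma = as.numeric(sigma), nu = as.numeric(nu)),
            class = "lms_point")
}

#' @export
print.lms_point <- function(x, ...) {
  cat(sprintf("<lms_point> age %s: mu = %.4g, sigma = %.4g, nu = %.4g\n",
              ifelse(is.na(x$age), "-", format(x$age)), x$mu, x$sigma, x$nu))
  invisible(x)
}

#' @export
format.lms_point <- function(x, ...) {
  sprintf("lms_point(age = %s, mu = %g, sigma = %g, nu = %g)",
          format(x$age), x$mu, x$sigma, x$nu)
}

#' Fit an LMS triplet to a set of printed quantiles
#'
#' Recovers `(mu, sigma, nu)` from a handful of tabulated centiles by
#' least squares on the quantile scale: the fitted triplet minimises
#' `sum((qBCCGo(level/100) - value)^2)`.  Published growth tables print
#' smoothed centiles rather than distribution parameters; this inversion
#' turns a printed table row back into a usable reference distribution.
#'
#' Optimisation runs unconstrained in `(log mu, log sigma, nu)` with
#' multi-start over `nu` in {-2, -1, 0, 1} to avoid local minima.
#'
#' @param levels percent levels in (0, 100), at least 3 distinct values.
#' @param values measurements at those levels, strictly increasing.
#' @param age optional age attached to the returned point.
#' @return an [lms_point] with attributes `sse` (residual sum of squares)
#'   and `converged` (logical).
#' @examples
#' p <- fit_lms_point(c(3, 10, 25, 50, 75, 90, 97),
#'                    qBCCGo(c(3, 10, 25, 50, 75, 90, 97) / 100,
#'                           mu = 21.4, sigma = 0.13, nu = -1.2))
#' unlist(p[c("mu", "sigma", "nu")])
#' @export
fit_lms_point <- function(levels, values, age = NA_real_) {
  if (length(levels) != length(values) || length(unique(levels)) < 3)
    stop("need >= 3 distinct levels with matching values", call. = FALSE)
  if (any(levels <= 0 | levels >= 100))
    stop("`levels` must lie strictly inside (0, 100)", call. = FALSE)
  ord <- order(levels)
  levels <- levels[ord]; values <- values[ord]
  if (any(diff(values) <= 0))
    stop("`values` must be strictly increasing with level", call. = FALSE)
  .check_pos(values, "values")

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
    sum((pred - values)^2)
  }
  mu0 <- values[which.min(abs(levels - 50))]
  s0 <- max((values[length(values)] - values[1]) /
              (diff(range(zq)) * mu0), 1e-4)
  best <- NULL
  for (nu0 in c(-2, -1, 0, 1)) {
    fit <- stats::optim(c(log(mu0), log(s0), nu0), obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish with mu profiled out (it enters the prediction linearly): the
  # remaining 2-d problem converges to machine precision, which matters
  # when the values were generated exactly from a triplet
  shape_fn <- function(s, nu) {
    if (abs(nu) < .nu_eps) return(exp(s * zq))
    a <- 1 + nu * s * zq
    if (any(a <= 0)) return(NULL)
    a^(1 / nu)
  }
  obj2 <- function(par) {
    g <- shape_fn(exp(par[1]), par[2])
    if (is.null(g)) return(1e10)
    mu <- sum(g * values) / sum(g * g)
    sum((mu * g - values)^2)
  }
  p2 <- best$par[2:3]
  for (k in 1:3)
    p2 <- stats::optim(p2, obj2, control = list(maxit = 5000,
                                                reltol = 1e-16))$par
  if (obj2(p2) <= best$value + 1e-15) {
    g <- shape_fn(exp(p2[1]), p2[2])
    best <- list(par = c(log(sum(g * values) / sum(g * g)), p2),
                 value = obj2(p2), convergence = 0L)
  }
  if (!is.finite(best$value) || best$value >= 1e10)
    stop("LMS quantile fit failed to converge to a valid triplet",
         call. = FALSE)
  out <- lms_point(age, exp(best$par[1]), exp(best$par[2]), best$par[3])
  attr(out, "sse") <- best$value
  attr(out, "converged") <- best$convergence == 0
  out
}
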