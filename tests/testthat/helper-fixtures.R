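# shared fixture builders; everything is generated in code at test time

# a flat LMS curve with constant parameters over [lo, hi]
constant_curve <- function(mu, sigma, nu, lo = 0, hi = 20,
                           measure = "bmi", sex = "F") {
  lms_curve(c(lo, (lo + hi) / 2, hi), rep(mu, 3), rep(sigma, 3), rep(nu, 3),
            sex = sex, measure = measure)
}

# minimal canonical records from raw vectors
make_records <- function(age, height, weight, sex = "F", region = "german",
                         source = "practice", origin = "swiss_both") {
  n <- length(age)
  data.frame(record_id = sprintf("t%06d", seq_len(n)), sex = sex,
             age_years = age, height_cm = height, weight_kg = weight,
             region = region, source = source, origin = origin,
             stringsAsFactors = FALSE)
}

# cohort drawn from a constant-parameter weight model (for fit tests)
constant_param_records <- function(n, mu, sigma, nu, age_lo = 2, age_hi = 18,
                                   seed = 1) {
  set.seed(seed)
  age <- runif(n, age_lo, age_hi)
  y <- qBCCGo(pnorm(rnorm(n)), mu, sigma, nu)
  make_records(age, height = 100, weight = y)
}

# independent pool-adjacent-violators oracle for the monotone projection
pava_oracle <- function(y) {
  n <- length(y)
  val <- as.numeric(y); w <- rep(1, n)
  i <- 1
  while (i < length(val)) {
    if (val[i] > val[i + 1] + 1e-12) {
      merged <- (w[i] * val[i] + w[i + 1] * val[i + 1]) / (w[i] + w[i + 1])
      val <- c(val[seq_len(i - 1)], merged, val[-seq_len(i + 1)])
      w <- c(w[seq_len(i - 1)], w[i] + w[i + 1], w[-seq_len(i + 1)])
      i <- max(i - 1, 1)
    } else i <- i + 1
  }
  rep(val, w)
}
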