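# Small fixtures built in code, shared across test files.

# three-subject outcome set used in the estimator hand examples
toy_outcomes <- function() {
  tibble::tibble(time = c(1, 2, 3), event = c(1, 0, 1))
}

# a cohort with one strong binary susceptibility variable: carriers are
# mostly susceptible, non-carriers mostly cured
separating_cohort <- function(n = 100, seed = 5) {
  generate_cure_cohort(n, signal_spec("g", "binary", alpha = 3, beta = 0),
                       theta0 = 0.05, horizon = 3, seed = seed)
}

# two-group cohort simulated under the null (alpha = beta = 0)
null_two_group <- function(n = 60, seed = 1) {
  w <- rep(c(0, 1), each = n / 2)
  d <- simulate_cure_outcomes(cure_model(1), w = w, censor_time = 2,
                              seed = seed)
  d$w <- w
  d
}

# random small survival dataset with a moderate planted group effect,
# for the score-vs-gradient oracle
random_scored_dataset <- function(seed, n = 25) {
  withr::with_seed(seed, {
    w <- stats::rbinom(n, 1, 0.5)
    d <- simulate_cure_outcomes(cure_model(1, alpha = 0.8, beta = 0.8),
                                w = w, censor_time = 2)
    d$w <- w
    d
  })
}

# Independent oracle for the score vector: numerical central-difference
# gradient of the discretised profile likelihood, with the plug-ins (and
# the predictable hazard-ratio factor) held fixed.
numeric_score_gradient <- function(d, membership, h = 1e-5) {
  ne <- null_estimates(d)
  tj <- ne$event_times
  d_lambda <- diff(c(0, ne$cumhaz))
  h0_minus <- c(0, ne$h0[-length(ne$h0)])
  w <- as.numeric(membership)
  loglik <- function(a, b) {
    tot <- 0
    for (j in seq_along(tj)) {
      at <- d$time >= tj[j]
      mu <- exp(a * w + b * w - h0_minus[j] * (exp(b * w) - 1)) *
        d_lambda[j]
      dn <- d$event == 1 & d$time == tj[j]
      tot <- tot + sum(log(mu[at & dn])) - sum(mu[at])
    }
    tot
  }
  c((loglik(h, 0) - loglik(-h, 0)) / (2 * h),
    (loglik(0, h) - loglik(0, -h)) / (2 * h))
}

# brute-force Harrell C by explicit pair enumeration
brute_force_c <- function(time, event, risk) {
  conc <- disc <- tied <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      first <- (time[i] < time[j] && event[i] == 1) ||
        (time[i] == time[j] && event[i] == 1 && event[j] == 0)
      if (!first) next
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] < risk[j]) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  (conc + 0.5 * tied) / (conc + disc + tied)
}
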