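#' Bounded-cumulative-hazard (promotion-time) cure model
#'
#' Population survival model for a cohort that mixes susceptible
#' ("immune-reactive") and non-susceptible ("immune-tolerant") subjects.
#' Each subject carries a latent Poisson number `N` of competent B-cell
#' clones with mean `theta(w) = theta0 * exp(alpha * w)`; each clone has an
#' i.i.d. activation time with distribution
#' `F(t | w) = 1 - exp(-H0(t) * exp(beta * w))`, and the observed event time
#' is the first activation.  Subjects with `N = 0` never experience the
#' event, so the population survival function is improper:
#'
#' \deqn{S(t | w) = \exp\{-\theta(w)\,[1 - e^{-H_0(t) e^{\beta w}}]\}}
#'
#' with tail defect (cured fraction) `S(Inf | w) = exp(-theta(w)) > 0`.  The
#' cumulative hazard `-log S` is bounded by `theta(w)`.  `alpha` shifts the
#' cured fraction between the two groups coded by `w`; `beta` shifts the
#' event dynamics among the susceptible, which makes the hazard ratio
#' time-varying unless `beta = 0`.
#'
#' @param theta0 Positive baseline mean number of competent clones; the
#'   baseline cured fraction is `exp(-theta0)`.
#' @param alpha Log-effect of `w` on the clone mean (cured fraction).
#' @param beta Log-effect of `w` on the clone activation dynamics.
#' @param h0 Baseline pseudo-cumulative hazard, a [weibull_hazard()] or
#'   [step_hazard()].
#' @return An object of class `cure_model`.
#' @examples
#' m <- cure_model(theta0 = log(2), alpha = log(2), beta = 0)
#' cure_fraction(m, w = 0)  # 0.5
#' cure_fraction(m, w = 1)  # 0.25
#' @export
cure_model <- function(theta0, alpha = 0, beta = 0, h0 = weibull_hazard()) {
  stopifnot(is.numeric(theta0), length(theta0) == 1, is.finite(theta0),
            theta0 > 0,
            is.numeric(alpha), length(alpha) == 1, is.finite(alpha),
            is.numeric(beta), length(beta) == 1, is.finite(beta),
            inherits(h0, "baseline_hazard"))
  structure(list(theta0 = theta0, alpha = alpha, beta = beta, h0 = h0),
            class = "cure_model")
}

#' @export
print.cure_model <- function(x, ...) {
  cat(sprintf(
    "<cure_model> theta0 = %g, alpha = %g, beta = %g (baseline cure %.3f)\n",
    x$theta0, x$alpha, x$beta, exp(-x$theta0)))
  print(x$h0)
  invisible(x)
}

#' Population survival function of the cure model
#'
#' @param model A [cure_model()].
#' @param t Nonnegative times (vectorised).
#' @param w Covariate value(s) for the binary/continuous contrast; recycled
#'   against `t`.
#' @return `S(t | w)` in `(0, 1]`, nonincreasing in `t`, with limit
#'   `exp(-theta(w)) > 0`.
#' @export
population_survival <- function(model, t, w = 0) {
  stopifnot(inherits(model, "cure_model"), is.numeric(t), is.numeric(w))
  if (any(t < 0, na.rm = TRUE)) stop("population_survival: t must be >= 0")
  theta <- model$theta0 * exp(model$alpha * w)
  exp(-theta * (1 - exp(-hazard_at(model$h0, t) * exp(model$beta * w))))
}

#' Hazard ratio between the two groups of a binary split
#'
#' Instantaneous rate ratio `lambda(t, w = 1) / lambda(t, w = 0)`:
#' `exp(alpha) * exp(beta) * exp(-H0(t) * (exp(beta) - 1))`.  Equal to
#' `exp(alpha + beta)` at `t = 0` and constant only when `beta = 0`
#' (non-proportional hazards otherwise).
#'
#' @inheritParams population_survival
#' @export
hazard_ratio <- function(model, t) {
  stopifnot(inherits(model, "cure_model"), is.numeric(t))
  if (any(t < 0, na.rm = TRUE)) stop("hazard_ratio: t must be >= 0")
  exp(model$alpha + model$beta) *
    exp(-hazard_at(model$h0, t) * (exp(model$beta) - 1))
}

#' Cured (immune-tolerant) fraction
#'
#' The tail defect `S(Inf | w) = exp(-theta0 * exp(alpha * w))`.
#'
#' @inheritParams population_survival
#' @export
cure_fraction <- function(model, w = 0) {
  stopifnot(inherits(model, "cure_model"), is.numeric(w))
  exp(-model$theta0 * exp(model$alpha * w))
}

# Core mechanistic simulator shared by the user-facing wrappers: per-subject
# clone mean `theta` and log dynamic multiplier `log_dyn` (H(t|i) =
# H0(t) * exp(log_dyn_i)).  N = 0 subjects are cured and exit censored.
simulate_promotion_times <- function(theta, log_dyn, h0, censor_time,
                                     latent = FALSE) {
  n <- length(theta)
  stopifnot(length(log_dyn) == n)
  censor_time <- rep_len(censor_time, n)
  if (any(censor_time <= 0)) stop("censor_time must be positive")
  n_clones <- stats::rpois(n, theta)
  t_event <- rep(Inf, n)
  idx <- which(n_clones > 0)
  if (length(idx)) {
    # min of N i.i.d. activation times has cumulative hazard N*exp(ld)*H0(t)
    e <- stats::rexp(length(idx))
    t_event[idx] <- hazard_inverse(
      h0, e / (n_clones[idx] * exp(log_dyn[idx])))
  }
  out <- tibble::tibble(
    time  = pmin(t_event, censor_time),
    event = as.integer(is.finite(t_event) & t_event <= censor_time)
  )
  if (latent) out$n_clones <- n_clones
  out
}

#' Simulate outcomes from the Poisson-clone mechanism
#'
#' Draws, for each subject, a Poisson number of competent clones with mean
#' `theta(w)`; subjects with zero clones are immune-tolerant and leave the
#' study censored at `censor_time`, the rest experience the event at the
#' first clone activation time (inverse-transform through `H0`), censored
#' administratively at `censor_time`.
#'
#' @inheritParams population_survival
#' @param w Covariate value per subject (length gives the cohort size unless
#'   `n` is supplied).
#' @param censor_time Positive censoring horizon (scalar or per subject);
#'   `Inf` disables censoring, in which case cured subjects keep `time = Inf`
#'   and `event = 0`.
#' @param n Optional number of subjects when `w` is scalar.
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @param latent If `TRUE`, also return the latent clone count `n_clones`
#'   (test oracles only; never feed it to a predictor).
#' @return A tibble with columns `time`, `event` (and `n_clones` if
#'   requested).
#' @export
simulate_cure_outcomes <- function(model, w = 0, censor_time = Inf, n = NULL,
                                   seed = NULL, latent = FALSE) {
  stopifnot(inherits(model, "cure_model"))
  if (!is.null(n)) w <- rep_len(w, n)
  draw <- function() {
    simulate_promotion_times(
      theta = model$theta0 * exp(model$alpha * w),
      log_dyn = model$beta * w,
      h0 = model$h0, censor_time = censor_time, latent = latent)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
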