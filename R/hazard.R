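#' Baseline pseudo-cumulative hazard functions
#'
#' The improper survival model used throughout this package is driven by a
#' baseline pseudo-cumulative hazard `H0(t)`: a nondecreasing function with
#' `H0(0) = 0`.  Two representations are supported: a Weibull-type parametric
#' family `H0(t) = (t / scale)^shape`, which increases from zero to infinity
#' and can be inverted in closed form (required for simulation), and a
#' nondecreasing right-continuous step function given as `(time, value)`
#' pairs, which is what nonparametric plug-in estimation produces.
#'
#' @param shape,scale Positive Weibull parameters; `shape = 1, scale = 1`
#'   gives exponential clone activation times, the simulation default.
#' @return An object of class `baseline_hazard`.
#' @examples
#' h <- weibull_hazard(shape = 2, scale = 3)
#' hazard_at(h, c(0, 3))   # 0 and 1
#' @export
weibull_hazard <- function(shape = 1, scale = 1) {
  stopifnot(is.numeric(shape), length(shape) == 1, shape > 0,
            is.numeric(scale), length(scale) == 1, scale > 0)
  structure(list(shape = shape, scale = scale),
            class = c("weibull_hazard", "baseline_hazard"))
}

#' @rdname weibull_hazard
#' @param time,value Numeric vectors defining a nondecreasing step function:
#'   `H0(t)` equals the last `value` whose `time` is `<= t`, and 0 before the
#'   first jump.
#' @export
step_hazard <- function(time, value) {
  stopifnot(is.numeric(time), is.numeric(value), length(time) == length(value))
  if (length(time) == 0) {
    return(structure(list(time = numeric(0), value = numeric(0)),
                     class = c("step_hazard", "baseline_hazard")))
  }
  o <- order(time)
  time <- time[o]; value <- value[o]
  if (any(time < 0)) stop("step_hazard: jump times must be nonnegative")
  if (any(value < 0) || is.unsorted(value)) {
    stop("step_hazard: values must be nonnegative and nondecreasing")
  }
  structure(list(time = time, value = value),
            class = c("step_hazard", "baseline_hazard"))
}

#' Evaluate a baseline hazard
#'
#' @param h0 A [weibull_hazard()] or [step_hazard()] object.
#' @param t Nonnegative evaluation times; negative times are a domain error.
#' @return `H0(t)`, same length as `t`.
#' @export
hazard_at <- function(h0, t) {
  stopifnot(inherits(h0, "baseline_hazard"), is.numeric(t))
  if (any(t < 0, na.rm = TRUE)) stop("hazard_at: t must be nonnegative")
  UseMethod("hazard_at")
}

#' @export
hazard_at.weibull_hazard <- function(h0, t) (t / h0$scale)^h0$shape

#' @export
hazard_at.step_hazard <- function(h0, t) {
  idx <- findInterval(t, h0$time)
  c(0, h0$value)[idx + 1L]
}

#' Invert a baseline hazard
#'
#' Returns the smallest `t` with `H0(t) >= u`.  Only parametric hazards are
#' invertible; inversion of a step hazard is refused because simulated event
#' times would then be concentrated on the observed jump times.
#'
#' @inheritParams hazard_at
#' @param u Nonnegative hazard levels.
#' @export
hazard_inverse <- function(h0, u) {
  stopifnot(inherits(h0, "baseline_hazard"), is.numeric(u))
  if (any(u < 0, na.rm = TRUE)) stop("hazard_inverse: u must be nonnegative")
  UseMethod("hazard_inverse")
}

#' @export
hazard_inverse.weibull_hazard <- function(h0, u) h0$scale * u^(1 / h0$shape)

#' @export
hazard_inverse.step_hazard <- function(h0, u) {
  stop("hazard_inverse: a step-function baseline cannot be inverted; ",
       "use a parametric (e.g. weibull_hazard) baseline for simulation")
}

#' @export
print.baseline_hazard <- function(x, ...) {
  if (inherits(x, "weibull_hazard")) {
    cat(sprintf("<weibull_hazard> H0(t) = (t/%g)^%g\n", x$scale, x$shape))
  } else {
    cat(sprintf("<step_hazard> %d jumps, H0(max) = %g\n",
                length(x$time), if (length(x$value)) max(x$value) else 0))
  }
  invisible(x)
}
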