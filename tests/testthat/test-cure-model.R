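test_that("baseline hazards evaluate, invert and validate their domain", {
  h <- weibull_hazard(shape = 2, scale = 3)
  expect_equal(hazard_at(h, c(0, 3, 6)), c(0, 1, 4))
  expect_equal(hazard_inverse(h, hazard_at(h, 1.7)), 1.7)
  expect_error(hazard_at(h, -1), "nonnegative")
  expect_error(weibull_hazard(shape = -1), "shape")

  s <- step_hazard(time = c(1, 2), value = c(0.5, 1.5))
  expect_equal(hazard_at(s, c(0, 1, 1.5, 2, 10)), c(0, 0.5, 0.5, 1.5, 1.5))
  expect_error(step_hazard(c(1, 2), c(1, 0.5)), "nondecreasing")
  expect_error(hazard_inverse(s, 0.3), "parametric")
})

test_that("population survival matches the closed form and its oracle", {
  m0 <- cure_model(theta0 = 1)
  expect_equal(population_survival(m0, 0, 0), 1)
  # tail defect: S(inf) = exp(-theta(w))
  expect_equal(population_survival(m0, 1e9, 0), exp(-1), tolerance = 1e-12)

  # numeric-integration oracle for S(1 | w = 1) at theta0 = .5, alpha = ln 2
  m <- cure_model(0.5, alpha = log(2), beta = 0)
  lam <- function(t) 1 * exp(-t)   # theta(w=1) * h0 * exp(-H0(t)), theta = 1
  s_oracle <- exp(-stats::integrate(lam, 0, 1)$value)
  expect_equal(population_survival(m, 1, w = 1), s_oracle, tolerance = 1e-9)
  expect_equal(population_survival(m, 1, w = 1), exp(-(1 - exp(-1))),
               tolerance = 1e-12)
  expect_error(population_survival(m, -0.1), ">= 0")
})

test_that("hazard ratio follows the bounded-hazard form and its limits", {
  expect_equal(hazard_ratio(cure_model(1), c(0, 1, 7)), c(1, 1, 1))
  # beta = 0 collapses to constant exp(alpha)
  m <- cure_model(1, alpha = 0.2, beta = 0)
  expect_equal(hazard_ratio(m, c(0, 5, 50)), rep(exp(0.2), 3))
  # closed form at t = 1
  m2 <- cure_model(1, alpha = 0.5, beta = 0.3)
  expect_equal(hazard_ratio(m2, 1), exp(0.8) * exp(-(exp(0.3) - 1)),
               tolerance = 1e-12)
  # finite-difference oracle: ratio of dLambda/dt from population_survival
  t <- seq(0.1, 5, length.out = 25)
  eps <- 1e-5
  num <- function(w) {
    (-log(population_survival(m2, t + eps, w)) +
       log(population_survival(m2, t - eps, w))) / (2 * eps)
  }
  expect_equal(hazard_ratio(m2, t), num(1) / num(0), tolerance = 1e-4)
})

test_that("cure fraction is the survival limit and lower-bounds S", {
  expect_equal(cure_fraction(cure_model(log(2))), 0.5)
  expect_equal(cure_fraction(cure_model(log(2), alpha = log(2)), w = 1),
               0.25)
  m <- cure_model(0.3, alpha = -0.1)
  expect_equal(cure_fraction(m, 2), population_survival(m, 1e6, 2),
               tolerance = 1e-6)
  # cure bound: S(t | w) >= exp(-theta(w)) everywhere
  t <- seq(0, 50, length.out = 200)
  for (w in c(-1, 0, 2)) {
    expect_true(all(population_survival(m, t, w) >= cure_fraction(m, w)))
  }
})

test_that("the Poisson-clone simulator matches the closed-form law", {
  # theta ~ 0 means (almost) nobody is susceptible
  o <- simulate_cure_outcomes(cure_model(1e-9), n = 1e4, censor_time = 1,
                              seed = 1)
  expect_equal(sum(o$event), 0)

  # event-free fraction at theta0 = ln 2 converges to the 50% cure fraction
  o2 <- simulate_cure_outcomes(cure_model(log(2)), n = 1e5, seed = 1)
  expect_equal(mean(o2$event == 0), 0.5, tolerance = 0.01)

  # marginal consistency: empirical survival vs closed form, sup over grid
  m <- cure_model(0.8, alpha = 0.4, beta = 0.6, h0 = weibull_hazard(1.3, 2))
  o3 <- simulate_cure_outcomes(m, w = 1, n = 1e5, seed = 2)
  grid <- seq(0, 8, length.out = 50)
  emp <- vapply(grid, function(t) mean(o3$time > t), 0)
  expect_lt(max(abs(emp - population_survival(m, grid, 1))), 0.01)

  # latent clone counts agree with the cure mechanism: N = 0 iff cured
  o4 <- simulate_cure_outcomes(cure_model(log(2)), n = 2000, seed = 3,
                               latent = TRUE)
  expect_true(all(o4$event[o4$n_clones == 0] == 0))
  expect_equal(mean(o4$n_clones == 0), 0.5, tolerance = 0.05)

  # reproducibility and administrative censoring
  a <- simulate_cure_outcomes(m, n = 50, censor_time = 2, seed = 9)
  b <- simulate_cure_outcomes(m, n = 50, censor_time = 2, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$time <= 2))
  expect_error(simulate_cure_outcomes(m, n = 5, censor_time = 0), "positive")
})
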