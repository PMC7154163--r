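test_that("Nelson-Aalen estimator reproduces hand-computed values", {
  one <- tibble::tibble(time = 1, event = 1)
  na1 <- nelson_aalen(one)
  expect_equal(chf_at(na1, c(0.5, 1, 2)), c(0, 1, 1))

  na <- nelson_aalen(toy_outcomes())
  expect_equal(chf_at(na, 1), 1 / 3)
  expect_equal(chf_at(na, 3), 1 / 3 + 1)
  expect_true(all(diff(na$cumhaz) >= 0))

  cens <- tibble::tibble(time = c(1, 2, 3), event = c(0, 0, 0))
  expect_equal(chf_at(nelson_aalen(cens), c(1, 5)), c(0, 0))
})

test_that("null plug-ins give theta0_hat, clamped finite H0_hat", {
  ne <- null_estimates(toy_outcomes())
  expect_equal(ne$theta0_hat, 4 / 3)
  expect_equal(h0_hat_at(ne, 1), -log(0.75))
  # at the largest event time Lambda/theta0 = 1 exactly -> clamped finite
  expect_equal(h0_hat_at(ne, 3), -log(1e-6))
  expect_true(all(is.finite(ne$h0)))
  expect_true(all(diff(ne$h0) >= 0))

  # single event: theta0_hat = d/Y of that one jump
  single <- tibble::tibble(time = c(2, 3), event = c(1, 0))
  ne1 <- null_estimates(single)
  expect_equal(ne1$theta0_hat, 0.5)
  expect_equal(length(ne1$event_times), 1)

  expect_error(null_estimates(tibble::tibble(time = 1:3, event = c(0, 0, 0))),
               "no events")
})

test_that("score statistic reproduces the two-subject hand computation", {
  d <- tibble::tibble(time = c(1, 2), event = c(1, 1))
  s <- score_split_statistic(d, membership = c(1, 0))
  # t = 1: d1 = 1, Y1 = 1, Y = 2 -> O - E = 1/2; t = 2 contributes 0
  expect_equal(unname(s$u["alpha"]), 0.5)
  # predictable beta weight at the first event time is 1 - H0_hat(0) = 1
  expect_equal(unname(s$u["beta"]), 0.5)
  expect_equal(s$v["alpha", "alpha"], 0.25)
  # V is rank one here; generalized inverse gives exactly 1
  expect_equal(s$statistic, 1)
  expect_equal(s$df_used, 1L)
})

test_that("mirror data and label swaps behave symmetrically", {
  # two groups with identical outcome multisets -> U = 0, statistic = 0
  d <- tibble::tibble(time = rep(c(1, 2, 3, 4), 2),
                      event = rep(c(1, 0, 1, 1), 2),
                      g = rep(c(0, 1), each = 4))
  s <- score_split_statistic(d, d$g)
  expect_equal(unname(s$u), c(0, 0))
  expect_equal(s$statistic, 0)

  # label symmetry: swapping groups negates U, preserves the statistic
  d2 <- null_two_group(seed = 11)
  s1 <- score_split_statistic(d2, d2$w)
  s2 <- score_split_statistic(d2, 1 - d2$w)
  expect_equal(unname(s1$u), -unname(s2$u), tolerance = 1e-12)
  expect_equal(s1$statistic, s2$statistic, tolerance = 1e-12)
  expect_equal(logrank_statistic(d2, d2$w), logrank_statistic(d2, 1 - d2$w),
               tolerance = 1e-12)

  expect_error(score_split_statistic(d2, rep(1, nrow(d2))), "one side")
})

test_that("score vector equals the numerical likelihood gradient", {
  # score-as-gradient oracle across random small datasets
  for (seed in 1:20) {
    d <- random_scored_dataset(seed)
    if (sum(d$event) < 2) next
    s <- score_split_statistic(d, d$w)
    g <- numeric_score_gradient(d, d$w)
    expect_lt(max(abs(g - unname(s$u))) / max(abs(s$u)), 1e-3)
  }
})

test_that("alpha component and chi-square match the survival package", {
  skip_if_not_installed("survival")
  for (seed in c(2, 13, 77)) {
    d <- random_scored_dataset(seed, n = 50)
    if (length(unique(d$w)) < 2 || sum(d$event) < 2) next
    sd <- survival::survdiff(survival::Surv(time, event) ~ w, data = d)
    s <- score_split_statistic(d, d$w)
    expect_equal(unname(s$u["alpha"]), (sd$obs - sd$exp)[2],
                 tolerance = 1e-8)
    expect_equal(logrank_statistic(d, d$w), unname(sd$chisq),
                 tolerance = 1e-8)
  }
})

test_that("candidate enumeration follows the variable-kind rules", {
  co <- as_cohort(
    tibble::tibble(
      time = c(1, 2, 3, 4, 5, 6, 7, 8),
      event = c(1, 1, 0, 1, 0, 1, 1, 0),
      b = c(0, 1, 0, 1, 0, 1, 0, 1),
      snp = c(0, 1, 2, 0, 1, 2, 0, 1),
      x = c(1, 2, 3, 4, 1, 2, 3, 4),
      dis = c("cd", "uc", "ms", "ra", "cd", "uc", "ms", "ra")),
    kinds = c(b = "binary", snp = "genotype012", x = "continuous",
              dis = "categorical"))
  cand <- enumerate_candidates(co, min_node_size = 1)
  expect_equal(sum(cand$variable == "b"), 1)
  # genotype: dominant and recessive partitions
  expect_equal(cand$value[cand$variable == "snp"], c(0.5, 1.5))
  # continuous midpoints between distinct values {1,2,3,4}
  expect_equal(cand$value[cand$variable == "x"], c(1.5, 2.5, 3.5))
  # unordered categorical: one-vs-rest per level
  expect_equal(sum(cand$variable == "dis"), 4)
  # candidate-count accounting: b + 2g + cL at the root
  expect_equal(nrow(cand), 1 + 2 * 1 + 4 + 3)

  # child-size filtering drops candidates
  cand2 <- enumerate_candidates(co, min_node_size = 3)
  expect_true(all(cand2$variable %in% c("b", "snp", "x")))
  expect_false(1.5 %in% cand2$value[cand2$variable == "snp"])

  # quartile mode restricts continuous cuts
  co2 <- as_cohort(
    tibble::tibble(time = 1:20, event = rep(1, 20), x = as.numeric(1:20)),
    kinds = c(x = "continuous"))
  cq <- enumerate_candidates(co2, min_node_size = 1, quartiles = TRUE)
  expect_lte(nrow(cq), 3)
})

test_that("best_split finds the separator and breaks ties deterministically", {
  co <- separating_cohort()
  bs <- best_split(co, criterion = "logrank", min_node_size = 15)
  expect_equal(bs$variable, "g")
  expect_gt(bs$statistic, qchisq(0.999, 1))

  # duplicated variable -> bit-identical statistics; first column wins
  d <- tibble::as_tibble(co)
  d$a_copy <- d$g
  co2 <- as_cohort(d[, c("time", "event", "g", "a_copy")],
                   kinds = c(g = "binary", a_copy = "binary"))
  bs2 <- best_split(co2, criterion = "score", min_node_size = 15)
  expect_equal(bs2$variable, "g")

  # empty admissible set -> NULL
  tiny <- as_cohort(tibble::tibble(time = c(1, 2), event = c(1, 1),
                                   g = c(0, 1)), kinds = c(g = "binary"))
  expect_null(best_split(tiny, min_node_size = 15))
})

test_that("engine statistics agree with the scalar implementations", {
  co <- separating_cohort(n = 80, seed = 21)
  d <- tibble::as_tibble(co)
  for (crit in c("logrank", "score")) {
    bs <- best_split(co, criterion = crit, min_node_size = 5)
    memb <- d$g > bs$value
    ref <- if (crit == "logrank") {
      logrank_statistic(d, memb)
    } else {
      score_split_statistic(d, memb)$statistic
    }
    expect_equal(bs$statistic, ref, tolerance = 1e-10)
  }
})
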