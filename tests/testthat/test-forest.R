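make_forest_cohort <- function(n = 120, seed = 1) {
  generate_cure_cohort(
    n, signal_spec(c("g", "z"), c("binary", "continuous"),
                   alpha = c(1.5, 0.5)),
    theta0 = 0.4, horizon = 3, n_noise = 8, seed = seed)
}

test_that("subspace sizing, defaults and config echo", {
  co <- make_forest_cohort()
  f <- rsf_fit(co, n_trees = 10, fraction = 0.25, criterion = "logrank",
               min_node_size = 10, seed = 2)
  # m = 10 predictors, fraction 0.25 -> ceil(2.5) = 3 per tree
  expect_true(all(vapply(f$trees, function(t) length(t$subspace), 0L) == 3))
  expect_equal(formals(rsf_fit)$n_trees, 500)
  expect_equal(glance(f)$p_star, 3)
  expect_equal(glance(f)$criterion, "logrank")
  expect_error(rsf_fit(co[1:10, ], n_trees = 2), "min_node_size")
})

test_that("seed determinism and subspace(1) = bagging equivalence", {
  co <- make_forest_cohort()
  f1 <- rsf_fit(co, n_trees = 25, mode = "subspace", fraction = 1,
                criterion = "logrank", min_node_size = 10, seed = 7)
  f2 <- rsf_fit(co, n_trees = 25, mode = "bagging",
                criterion = "logrank", min_node_size = 10, seed = 7)
  f3 <- rsf_fit(co, n_trees = 25, mode = "subspace", fraction = 1,
                criterion = "logrank", min_node_size = 10, seed = 7)
  expect_identical(f1$trees, f3$trees)
  expect_identical(f1$inbag_count, f3$inbag_count)
  # bit-identical trees and predictions across the two modes
  expect_identical(f1$trees, f2$trees)
  expect_identical(predict_ensemble_chf(f1, co), predict_ensemble_chf(f2, co))
})

test_that("ensemble prediction is the pointwise mean over trees", {
  co <- make_forest_cohort()
  f <- rsf_fit(co, n_trees = 7, fraction = 0.5, criterion = "logrank",
               min_node_size = 10, seed = 3)
  sub <- co[sample(nrow(co), 10), ]
  X <- cureforest:::forest_feature_matrix(f, sub)
  brute <- Reduce(`+`, lapply(f$trees, function(t) {
    cureforest:::tree_chf_matrix(t, X)
  })) / f$n_trees
  expect_equal(unname(predict_ensemble_chf(f, sub)), brute,
               tolerance = 1e-12)
  # single-tree forest predicts exactly that tree
  f1 <- rsf_fit(co, n_trees = 1, fraction = 1, criterion = "logrank",
                min_node_size = 10, seed = 4)
  expect_equal(unname(predict_ensemble_chf(f1, sub)),
               cureforest:::tree_chf_matrix(f1$trees[[1]], X))
})

test_that("out-of-bag predictions use only excluding trees", {
  co <- make_forest_cohort()
  f <- rsf_fit(co, n_trees = 30, fraction = 0.5, criterion = "logrank",
               min_node_size = 10, seed = 5)
  op <- oob_predict(f)
  X <- cureforest:::forest_feature_matrix(f, co)
  # OOB validity + brute-force recomputation per subject
  for (i in seq_len(nrow(co))) {
    oob_trees <- which(f$inbag_count[i, ] == 0L)
    expect_equal(op$n_trees_oob[i], length(oob_trees))
    for (b in oob_trees) expect_false(i %in% f$trees[[b]]$boot)
    if (length(oob_trees)) {
      brute <- Reduce(`+`, lapply(f$trees[oob_trees], function(t) {
        cureforest:::tree_chf_matrix(t, X[i, , drop = FALSE])
      })) / length(oob_trees)
      expect_equal(unname(attr(op, "chf")[i, ]), drop(brute),
                   tolerance = 1e-12)
    } else {
      expect_true(is.na(op$mortality[i]))
    }
  }
  # B = 1: in-bag subjects missing, the rest get that tree's prediction
  f1 <- rsf_fit(co, n_trees = 1, fraction = 1, criterion = "logrank",
                min_node_size = 10, seed = 6)
  op1 <- oob_predict(f1)
  inbag <- unique(f1$trees[[1]]$boot)
  expect_true(all(is.na(op1$mortality[inbag])))
  expect_true(all(!is.na(op1$mortality[-inbag])))
  # cohort mismatch is refused
  expect_error(oob_predict(f, co[-1, ]), "match")
})

test_that("per-tree OOB fraction is near (1 - 1/n)^n", {
  co <- make_forest_cohort(n = 200, seed = 8)
  f <- rsf_fit(co, n_trees = 60, fraction = 0.25, criterion = "logrank",
               min_node_size = 20, seed = 9)
  frac <- mean(colSums(f$inbag_count == 0L)) / nrow(co)
  expect_equal(frac, (1 - 1 / 200)^200, tolerance = 0.015)
})

test_that("mortality is a monotone, order-preserving risk summary", {
  expect_equal(mortality(rep(0, 10)), 0)
  expect_equal(mortality(rep(1, 10)), 10)
  f <- cumsum(runif(20)); g <- f * 0.7
  expect_gte(mortality(f), mortality(g))
  expect_error(mortality(c(1, 0.5)), "nondecreasing")
  m <- rbind(f, g)
  expect_equal(mortality(m), c(f = sum(f), g = sum(g)))
})

test_that("JSON serialisation round-trips a forest exactly", {
  co <- make_forest_cohort(n = 60, seed = 10)
  f <- rsf_fit(co, n_trees = 5, fraction = 0.5, criterion = "score",
               min_node_size = 8, seed = 11)
  path <- withr::local_tempfile(fileext = ".json")
  write_forest_json(f, path)
  f2 <- read_forest_json(path)
  expect_equal(f2$trees, f$trees)
  expect_identical(predict_ensemble_chf(f2, co), predict_ensemble_chf(f, co))
  expect_equal(f2$config, f$config)
})
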