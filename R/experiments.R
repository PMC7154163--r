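#' Out-of-bag error versus subsampling fraction
#'
#' Fits one subspace forest per feature fraction on the same cohort and
#' records each fit's out-of-bag error rate (`1 - C`).  Optional comparison
#' arms add the classical per-node-mtry forest and the bagging forest.
#' Per-run seeds are derived deterministically from `seed`, so the sweep is
#' reproducible end to end.
#'
#' @param data A [as_cohort()] cohort.
#' @param fractions Feature fractions in `(0, 1]`, strictly increasing.
#'   The default grid covers 1% to 100% with extra resolution around the
#'   20-25% region where sparse-signal benchmarks bottom out.
#' @param n_trees Trees per forest.
#' @param criterion Split criterion for every arm.
#' @param min_node_size,quartiles,epsilon Passed to [rsf_fit()].
#' @param include_classical,include_bagging Add the comparison arms.
#' @param seed Optional integer base seed.
#' @return A tibble of class `rsf_sweep`: `arm`, `fraction`, `oob_error`,
#'   `n_trees`, `seed`, `n_excluded`.
#' @export
run_subsample_sweep <- function(data,
                                fractions = c(0.01, 0.05, 0.10, 0.20, 0.25,
                                              0.50, 0.75, 1.00),
                                n_trees = 500,
                                criterion = c("logrank", "score"),
                                min_node_size = 15, quartiles = FALSE,
                                epsilon = 1e-6,
                                include_classical = FALSE,
                                include_bagging = FALSE, seed = NULL) {
  stopifnot(inherits(data, "cure_cohort"), length(fractions) >= 1,
            all(fractions > 0), all(fractions <= 1),
            !is.unsorted(fractions, strictly = TRUE))
  criterion <- match.arg(criterion)
  arms <- tibble::tibble(arm = "subspace", fraction = fractions)
  if (include_classical) {
    arms <- dplyr::bind_rows(arms,
      tibble::tibble(arm = "classical", fraction = NA_real_))
  }
  if (include_bagging) {
    arms <- dplyr::bind_rows(arms,
      tibble::tibble(arm = "bagging", fraction = 1))
  }
  run_seeds <- derive_seeds(seed, nrow(arms))
  res <- purrr::pmap(list(arms$arm, arms$fraction, seq_len(nrow(arms))),
    function(arm, frac, i) {
      s <- if (is.null(run_seeds)) NULL else run_seeds[i]
      f <- rsf_fit(data, n_trees = n_trees, mode = arm,
                   fraction = if (is.na(frac)) 1 else frac,
                   criterion = criterion, min_node_size = min_node_size,
                   quartiles = quartiles, epsilon = epsilon, seed = s)
      err <- oob_error(f)
      tibble::tibble(arm = arm, fraction = frac,
                     oob_error = err$error_rate, n_trees = n_trees,
                     seed = s %||% NA_integer_,
                     n_excluded = err$n_excluded)
    })
  out <- dplyr::bind_rows(res)
  class(out) <- c("rsf_sweep", class(out))
  out
}

#' Export per-subject predicted risk curves
#'
#' The per-subject predicted cumulative distribution function of the event,
#' `CDF(t) = 1 - exp(-CHF(t))` on the forest's time grid, from either the
#' out-of-bag estimator (internal, unbiased) or the full ensemble applied
#' to `newdata`.  A horizon-risk column and a high/low-risk flag at
#' `threshold` are included: subjects whose predicted event probability at
#' the horizon exceeds 50% are the natural high-risk group.
#'
#' @param forest A fitted [rsf_fit()] forest.
#' @param newdata Data for ensemble prediction when `oob = FALSE`;
#'   defaults to the training cohort.
#' @param oob Use the out-of-bag estimator (training subjects only).
#' @param horizon Time at which the risk column is read off; defaults to
#'   the end of the forest's time grid (the administrative window).
#' @param threshold High-risk cut on the horizon risk (default 0.5).
#' @return A long tibble: `id`, `time`, `cdf`, plus per-subject
#'   `risk_at_horizon` and `high_risk`.  Subjects without an OOB
#'   prediction carry `NA` curves.
#' @export
export_predicted_cdf <- function(forest, newdata = NULL, oob = TRUE,
                                 horizon = NULL, threshold = 0.5) {
  stopifnot(inherits(forest, "cure_rsf"))
  horizon <- horizon %||% max(forest$time_grid)
  if (oob) {
    op <- oob_predict(forest)
    chf <- attr(op, "chf")
    ids <- op$id
  } else {
    newdata <- newdata %||% forest$data
    chf <- predict_ensemble_chf(forest, newdata)
    ids <- if (inherits(newdata, "cure_cohort")) cohort_ids(newdata) else
      seq_len(nrow(newdata))
  }
  grid <- c(0, forest$time_grid)           # CDF(0) = 0 row for every subject
  cdf <- cbind(0, 1 - exp(-chf))
  cdf[is.na(chf[, 1]), 1] <- NA            # keep missing-OOB subjects NA
  gi <- findInterval(horizon, grid)
  risk <- cdf[, max(gi, 1)]
  out <- chf_long(cdf, grid, value_name = "cdf")
  out$id <- rep(ids, each = length(grid))
  out$risk_at_horizon <- rep(risk, each = length(grid))
  out$high_risk <- out$risk_at_horizon > threshold
  dplyr::relocate(out, "id")[, c("id", "time", "cdf", "risk_at_horizon",
                                 "high_risk")]
}
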