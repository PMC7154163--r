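#' Harrell's concordance index
#'
#' Probability that, in a randomly selected permissible pair, the subject
#' who fails first carries the higher predicted risk.  A pair `(i, j)` is
#' permissible when `t_i < t_j` with subject `i` an event, or `t_i = t_j`
#' with exactly one of the two an event (the event-bearer fails first);
#' pairs of events at the same time, and pairs whose earlier time is
#' censored, are not comparable.  Tied risks are credited 1/2.  The
#' reported error rate is `1 - C`: 0.5 is random guessing, 0 is perfect
#' ranking.
#'
#' @param time Follow-up times.
#' @param event 0/1 event indicators.
#' @param risk Predicted risk scores (higher = fails earlier), e.g.
#'   [mortality()] of a predicted cumulative hazard.
#' @return An object of class `concordance_result`: `c_index`,
#'   `error_rate`, `n_permissible`, `n_concordant`, `n_discordant`,
#'   `n_tied_risk`.
#' @examples
#' concordance_index(c(1, 2, 3), c(1, 1, 0), c(3, 1, 2))$c_index  # 2/3
#' @export
concordance_index <- function(time, event, risk) {
  stopifnot(is.numeric(time), is.numeric(risk),
            length(time) == length(event), length(time) == length(risk),
            all(event %in% c(0, 1)))
  if (anyNA(time) || anyNA(event) || anyNA(risk)) {
    stop("concordance_index: missing values in time/event/risk")
  }
  n <- length(time)
  # pair (i, j): i fails first.  Work on the upper triangle both ways via
  # outer comparisons; n here is at most a cohort, so O(n^2) is fine.
  ti <- matrix(time, n, n)
  ei <- matrix(event, n, n)
  ri <- matrix(risk, n, n)
  tj <- t(ti); ej <- t(ei); rj <- t(ri)
  first <- (ti < tj & ei == 1) | (ti == tj & ei == 1 & ej == 0)
  conc <- sum(first & ri > rj)
  disc <- sum(first & ri < rj)
  tied <- sum(first & ri == rj)
  perm <- conc + disc + tied
  if (perm == 0) stop("concordance_index: no permissible pairs")
  c_index <- (conc + 0.5 * tied) / perm
  structure(list(c_index = c_index, error_rate = 1 - c_index,
                 n_permissible = perm, n_concordant = conc,
                 n_discordant = disc, n_tied_risk = tied),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "<concordance_result> C = %.4f (error %.4f), %d permissible pairs (%d concordant, %d discordant, %d tied risks)\n",
    x$c_index, x$error_rate, x$n_permissible, x$n_concordant,
    x$n_discordant, x$n_tied_risk))
  invisible(x)
}

#' Out-of-bag prediction error of a forest
#'
#' Computes [oob_predict()] mortalities, drops subjects that were never
#' out-of-bag (their count is reported), and returns the
#' [concordance_index()] of the rest against the observed outcomes.  The
#' quantity usually reported is `error_rate = 1 - C`.
#'
#' @inheritParams oob_predict
#' @return A `concordance_result` with an extra field `n_excluded`.
#' @export
oob_error <- function(forest, data = NULL) {
  data <- data %||% forest$data
  op <- oob_predict(forest, data)
  keep <- !is.na(op$mortality)
  if (!any(keep)) stop("oob_error: every subject lacks an OOB prediction")
  res <- concordance_index(cohort_time(data)[keep],
                           cohort_event(data)[keep],
                           op$mortality[keep])
  res$n_excluded <- sum(!keep)
  res
}
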