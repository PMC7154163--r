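#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted forest
#'
#' One row per tree: subspace size, leaf count, in-bag unique subjects.
#'
#' @param x A [rsf_fit()] forest.
#' @param ... Unused.
#' @export
tidy.cure_rsf <- function(x, ...) {
  tibble::tibble(
    tree = seq_len(x$n_trees),
    n_features = vapply(x$trees, function(t) length(t$subspace), 0L),
    n_leaves = vapply(x$trees, function(t) t$n_leaves, 0L),
    n_inbag_unique = colSums(x$inbag_count > 0L))
}

#' @rdname tidy.cure_rsf
#' @export
glance.cure_rsf <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(
    n = nrow(x$data), m = length(x$feature_names),
    n_trees = x$n_trees, mode = cfg$mode,
    fraction = if (cfg$mode == "subspace") cfg$fraction else NA_real_,
    p_star = cfg$p_star, mtry = cfg$mtry %||% NA_integer_,
    criterion = cfg$criterion, min_node_size = cfg$min_node_size,
    n_events = sum(cohort_event(x$data)))
}

#' Tidy a concordance result
#'
#' @param x A [concordance_index()] result.
#' @param ... Unused.
#' @export
tidy.concordance_result <- function(x, ...) {
  tibble::tibble(c_index = x$c_index, error_rate = x$error_rate,
                 n_permissible = x$n_permissible,
                 n_concordant = x$n_concordant,
                 n_discordant = x$n_discordant,
                 n_tied_risk = x$n_tied_risk,
                 n_excluded = x$n_excluded %||% 0L)
}

#' Tidy a score-test result
#'
#' One row per score component plus the joint statistic in `glance` form.
#'
#' @param x A [score_split_statistic()] result.
#' @param ... Unused.
#' @export
tidy.score_result <- function(x, ...) {
  tibble::tibble(component = c("alpha", "beta"),
                 score = unname(x$u),
                 variance = unname(diag(x$v)))
}

#' @rdname tidy.score_result
#' @export
glance.score_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df_used = x$df_used,
                 p_value = stats::pchisq(x$statistic, df = max(x$df_used, 1),
                                         lower.tail = FALSE))
}

#' Flat evaluation report
#'
#' Key-value export of a concordance result, writable with
#' [write_config()] or [jsonlite::write_json()].
#'
#' @param x A `concordance_result`.
#' @export
evaluation_report <- function(x) {
  stopifnot(inherits(x, "concordance_result"))
  list(c_index = x$c_index, error_rate = x$error_rate,
       n_permissible = x$n_permissible, n_concordant = x$n_concordant,
       n_discordant = x$n_discordant, n_tied_risk = x$n_tied_risk,
       n_excluded = x$n_excluded %||% 0L)
}
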