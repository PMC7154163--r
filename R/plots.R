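#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an error-rate sweep
#'
#' Out-of-bag error rate against the feature-subsampling fraction, with
#' horizontal reference lines for any classical / bagging arms.
#'
#' @param object A [run_subsample_sweep()] result.
#' @param ... Unused.
#' @export
autoplot.rsf_sweep <- function(object, ...) {
  sub <- dplyr::filter(object, .data$arm == "subspace")
  p <- ggplot2::ggplot(sub,
         ggplot2::aes(x = .data$fraction, y = .data$oob_error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "feature subsampling fraction",
                  y = "out-of-bag error rate (1 - C)") +
    ggplot2::theme_minimal()
  ref <- dplyr::filter(object, .data$arm != "subspace")
  if (nrow(ref)) {
    p <- p + ggplot2::geom_hline(
      data = ref,
      ggplot2::aes(yintercept = .data$oob_error, linetype = .data$arm)) +
      ggplot2::labs(linetype = NULL)
  }
  p
}

#' Plot per-subject predicted risk curves
#'
#' One predicted event CDF per subject, coloured by the high/low-risk flag
#' at the horizon.
#'
#' @param object A [export_predicted_cdf()] table.
#' @param alpha Line transparency.
#' @param ... Unused.
#' @export
plot_predicted_cdf <- function(object, alpha = 0.25, ...) {
  stopifnot(all(c("id", "time", "cdf", "high_risk") %in% names(object)))
  ggplot2::ggplot(dplyr::filter(object, !is.na(.data$cdf)),
    ggplot2::aes(x = .data$time, y = .data$cdf, group = .data$id,
                 colour = .data$high_risk)) +
    ggplot2::geom_step(alpha = alpha) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time", y = "predicted event probability",
                  colour = "high risk") +
    ggplot2::theme_minimal()
}

#' Plot a cure model's survival curves
#'
#' Population survival for `w = 0` and `w = 1`, with the two cure
#' fractions as horizontal asymptotes.
#'
#' @param object A [cure_model()].
#' @param t_max Right end of the time axis.
#' @param ... Unused.
#' @export
autoplot.cure_model <- function(object, t_max = 5, ...) {
  grid <- seq(0, t_max, length.out = 200)
  d <- dplyr::bind_rows(
    tibble::tibble(t = grid, w = "w = 0",
                   S = population_survival(object, grid, 0)),
    tibble::tibble(t = grid, w = "w = 1",
                   S = population_survival(object, grid, 1)))
  asym <- tibble::tibble(w = c("w = 0", "w = 1"),
                         S = c(cure_fraction(object, 0),
                               cure_fraction(object, 1)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$S,
                                  colour = .data$w)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = asym,
      ggplot2::aes(yintercept = .data$S, colour = .data$w),
      linetype = "dashed", alpha = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time", y = "population survival S(t | w)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
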