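#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-trait consistency test results
#'
#' Shows, per trait, the observed consistency index as a standardized
#' distance below (or above) the random-pairing expectation: the expectation
#' sits at zero with a two-standard-deviation band, and the point marks
#' (observed - expected) / SD. Points far below zero indicate traits on
#' which partner sets are much more alike than random pairing predicts.
#'
#' @param object A `consistency_tbl` from [consistency_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.consistency_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(
      z = ifelse(.data$expected_sd > 0,
                 (.data$observed_delta - .data$expected_delta) /
                   .data$expected_sd, 0),
      trait = stats::reorder(.data$trait, .data$z))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$trait)) +
    ggplot2::annotate("rect", xmin = -2, xmax = 2, ymin = -Inf, ymax = Inf,
                      alpha = 0.15) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "standardized consistency index (observed - expected, in null SDs)",
      y = NULL,
      title = "Mate-choice consistency by trait",
      subtitle = "shaded band: ±2 SD of the random-pairing null") +
    ggplot2::theme_minimal()
}

#' Plot the cumulative effect size accumulation
#'
#' Bars show each trait's unique contribution in inclusion order; the line
#' tracks the running total up to the maximal cumulative effect size.
#'
#' @param object A `cumulative_result` from [cumulative_effect()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.cumulative_result <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(trait = factor(.data$trait, levels = .data$trait))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$unique_contribution),
                      fill = "grey55") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_pct, group = 1)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative_pct)) +
    ggplot2::labs(x = NULL, y = "partners to relocate (%)",
                  title = sprintf("Maximal cumulative effect size: %.2f%%",
                                  attr(object, "total_pct"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot father-exclusion permutation tests
#'
#' Shows, per trait, the change in the consistency index when true fathers
#' are excluded (point) against the change when randomly relabelled
#' "fathers" are excluded (zero line with a two-SD band), standardized by
#' the null SD. Points far below zero mark traits where fathers are
#' exceptional members of the partner sets.
#'
#' @param object A `father_exclusion_tbl` from [father_exclusion_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.father_exclusion_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(
      z = ifelse(.data$expected_change_sd > 0,
                 (.data$observed_change - .data$expected_change_mean) /
                   .data$expected_change_sd, 0),
      trait = stats::reorder(.data$trait, .data$z))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$trait)) +
    ggplot2::annotate("rect", xmin = -2, xmax = 2, ymin = -Inf, ymax = Inf,
                      alpha = 0.15) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "standardized change in consistency index when fathers are excluded",
      y = NULL,
      title = "Father exceptionality by trait",
      subtitle = "below zero: fathers exceptional; above: fathers typical") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.mate_choice_analysis <- function(object, ...) {
  autoplot.consistency_tbl(object$consistency, ...)
}
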