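#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a mate-choice analysis into one row per trait
#'
#' Merges the consistency test, relocation effect size and association
#' measures into a single per-trait tibble (the customary wide results
#' table).
#'
#' @param x A `mate_choice_analysis` from [run_mate_choice_analysis()].
#' @param ... Unused.
#' @return A tibble with one row per trait.
#' @exportS3Method
tidy.mate_choice_analysis <- function(x, ...) {
  out <- tibble::as_tibble(x$consistency)
  if (!is.null(x$effect)) {
    out <- dplyr::left_join(out,
                            dplyr::select(tibble::as_tibble(x$effect),
                                          "trait", "effect_pct", "ci_lo",
                                          "ci_hi"),
                            by = "trait")
  }
  if (!is.null(x$association)) {
    out <- dplyr::left_join(out,
                            dplyr::select(tibble::as_tibble(x$association),
                                          "trait", "icc_pct", "icc_label",
                                          "pearson_r"),
                            by = "trait")
  }
  out
}

#' One-row summary of a mate-choice analysis
#'
#' @inheritParams tidy.mate_choice_analysis
#' @return A one-row tibble: cohort sizes, number of traits, traits
#'   significant after BH adjustment, median effect size, and the maximal
#'   cumulative effect size when computed.
#' @exportS3Method
glance.mate_choice_analysis <- function(x, ...) {
  m <- x$manifest
  tibble::tibble(
    n_respondents = m$n_respondents,
    n_partners = m$n_partners,
    n_traits = length(m$traits),
    n_consistent = sum(x$consistency$p_adj < m$alpha),
    median_effect_pct = if (!is.null(x$effect)) {
      stats::median(x$effect$effect_pct)
    } else NA_real_,
    cumulative_pct = if (!is.null(x$cumulative)) {
      attr(x$cumulative, "total_pct")
    } else NA_real_,
    n_perm = m$n_perm,
    seed = m$seed %||% NA_integer_)
}

#' @rdname glance.cumulative_result
#' @exportS3Method
tidy.trait_correlations <- function(x, ...) x$pairs

#' Summaries for shared and cumulative effect results
#'
#' @param x A `cumulative_result` or `trait_correlations` object.
#' @param ... Unused.
#' @return `glance.cumulative_result()`: a one-row tibble with `total_pct`
#'   and `n_traits`; `tidy.trait_correlations()`: the long per-pair tibble.
#' @exportS3Method
glance.cumulative_result <- function(x, ...) {
  tibble::tibble(total_pct = attr(x, "total_pct"), n_traits = nrow(x))
}

#' @rdname glance.cumulative_result
#' @exportS3Method
tidy.null_distribution <- function(x, ...) {
  tibble::tibble(sample = x$samples)
}
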