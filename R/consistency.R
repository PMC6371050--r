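#' Per-respondent mean pairwise difference
#'
#' The building block of the consistency index: the mean absolute difference
#' over all unordered pairs of one respondent's partner values on a trait.
#' For partners scoring 5, 10, 7 and 14 the six pairwise differences are
#' 5, 2, 9, 3, 4 and 7, so the respondent's value is 5.
#'
#' @param values Numeric vector of at least two non-missing trait values.
#' @return A non-negative number.
#' @export
#' @examples
#' respondent_mean_pairwise_diff(c(5, 10, 7, 14))  # 5
#' respondent_mean_pairwise_diff(c(11, 13))        # 2
respondent_mean_pairwise_diff <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    stop("need at least 2 non-missing values", call. = FALSE)
  }
  mean_abs_pairdiff(values)
}

#' Population consistency index
#'
#' The consistency index of a trait is the unweighted mean, across informative
#' respondents, of each respondent's mean absolute pairwise difference among
#' her partners' values. Every respondent contributes equally regardless of
#' how many partners she listed. Lower values mean more similar partners,
#' i.e. more consistent mate choice.
#'
#' @param cohort A `mate_cohort` tibble (see [cohort_table()]).
#' @param trait Name of a registered trait column.
#' @return A non-negative number.
#' @export
population_delta <- function(cohort, trait) {
  slots <- informative_slots(cohort, trait)
  if (is.null(slots)) {
    stop("no informative respondent for trait '", trait, "'", call. = FALSE)
  }
  slots_delta(slots$values, slots$group, slots$sizes)
}

#' Permutation null distribution of the consistency index
#'
#' Reassigns the informative partners' trait values across respondents
#' uniformly at random, preserving the number of partners each respondent
#' reported, and recomputes the consistency index for each random pairing.
#' Performed per trait on that trait's informative subset.
#'
#' @inheritParams population_delta
#' @param n_perm Number of random pairings (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `null_distribution`: a list with `samples`,
#'   `mean`, `sd`, `n_perm`, `seed`, `trait`, and the informative counts
#'   `n_respondents` and `n_partners`.
#' @export
permutation_null <- function(cohort, trait, n_perm = 10000L, seed = NULL) {
  if (n_perm < 1L) stop("n_perm must be at least 1", call. = FALSE)
  slots <- informative_slots(cohort, trait)
  if (is.null(slots) || slots$n_groups < 2L) {
    stop("need at least 2 informative respondents for trait '", trait, "'",
         call. = FALSE)
  }
  samples <- with_seed_if(seed, {
    vapply(seq_len(n_perm), function(i) {
      v <- slots$values[sample.int(slots$n_slots)]
      slots_delta(v, slots$group, slots$sizes)
    }, numeric(1))
  })
  new_null_distribution(samples, seed = seed, trait = trait,
                        n_respondents = slots$n_groups,
                        n_partners = slots$n_slots)
}

new_null_distribution <- function(samples, seed = NULL, trait = NA_character_,
                                  n_respondents = NA_integer_,
                                  n_partners = NA_integer_) {
  structure(list(samples = samples, mean = mean(samples), sd = stats::sd(samples),
                 n_perm = length(samples), seed = seed, trait = trait,
                 n_respondents = n_respondents, n_partners = n_partners),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Permutation null", if (!is.na(x$trait)) paste0("for '", x$trait, "'"),
      "\n  n_perm =", x$n_perm,
      " mean =", signif(x$mean, 4), " sd =", signif(x$sd, 4), "\n")
  invisible(x)
}

#' One-tailed permutation p-value for mate-choice consistency
#'
#' The p-value is the proportion of random-pairing consistency indices that
#' fall strictly below the observed index: small values indicate partners
#' more alike than random pairing predicts. A degenerate null with zero
#' spread (e.g. a constant trait) yields p = 1, carrying no evidence of
#' consistency.
#'
#' @param observed Observed consistency index (see [population_delta()]).
#' @param null A `null_distribution` from [permutation_null()].
#' @return A p-value in \[0, 1\].
#' @export
consistency_test <- function(observed, null) {
  stopifnot(inherits(null, "null_distribution"))
  if (null$n_perm < 1L) stop("empty null distribution", call. = FALSE)
  if (null$sd == 0) return(1)
  mean(null$samples < observed)
}

#' Per-trait consistency test table
#'
#' Runs the observed consistency index, its permutation null and the
#' one-tailed test for each requested trait, and adjusts the p-values with
#' the Benjamini-Hochberg procedure across traits.
#'
#' @inheritParams permutation_null
#' @param traits Character vector of traits; defaults to every registered
#'   trait present in the cohort.
#' @param seed Optional master seed; per-trait seeds are derived from it.
#' @return A tibble of class `consistency_tbl` with one row per trait:
#'   `trait`, `observed_delta`, `expected_delta`, `expected_sd`, `p`,
#'   `p_adj`, `n_respondents_informative`, `n_partners_informative`.
#' @export
consistency_table <- function(cohort, traits = NULL, n_perm = 10000L,
                              seed = NULL) {
  traits <- traits %||% intersect(trait_registry(cohort)$trait, names(cohort))
  seeds <- if (is.null(seed)) rep(list(NULL), length(traits))
           else as.list(derive_seeds(seed, length(traits)))
  rows <- purrr::map2_dfr(traits, seeds, function(tr, s) {
    obs <- population_delta(cohort, tr)
    null <- permutation_null(cohort, tr, n_perm = n_perm, seed = s)
    tibble::tibble(
      trait = tr,
      observed_delta = obs,
      expected_delta = null$mean,
      expected_sd = null$sd,
      p = consistency_test(obs, null),
      n_respondents_informative = null$n_respondents,
      n_partners_informative = null$n_partners)
  })
  rows <- dplyr::mutate(rows, p_adj = bh_adjust(.data$p), .after = "p")
  structure(rows, class = c("consistency_tbl", class(rows)))
}
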