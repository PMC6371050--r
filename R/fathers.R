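#' Change in consistency when fathers are excluded
#'
#' Computes the consistency index for the full partner set and again after
#' removing every partner flagged as a father of the respondent's child(ren);
#' respondents left with fewer than two informative partners drop out of the
#' restricted average. A negative change means partner sets look more
#' consistent without fathers, i.e. fathers are exceptional within their
#' sets; a positive change means fathers are especially typical.
#'
#' @inheritParams population_delta
#' @return The restricted-minus-full difference in the consistency index.
#' @export
father_exclusion_change <- function(cohort, trait) {
  prep <- father_trait_prep(cohort, trait)
  obs <- exclusion_delta(prep, prep$father) - prep$delta_full
  if (is.na(obs)) {
    stop("no respondent remains informative for '", trait,
         "' after father exclusion", call. = FALSE)
  }
  obs
}

# Per-trait structures shared by the observed change and the permutations.
father_trait_prep <- function(cohort, trait) {
  if (!trait %in% names(cohort)) {
    stop("trait '", trait, "' is not a column of the cohort", call. = FALSE)
  }
  data <- tibble::as_tibble(cohort)[, c("respondent_id", "is_father", trait)]
  data <- data[order(data$respondent_id), ]
  group <- match(data$respondent_id, unique(data$respondent_id))
  values <- as.numeric(data[[trait]])
  father <- as.logical(data$is_father)
  if (!any(father)) {
    stop("cohort flags no fathers", call. = FALSE)
  }
  ok <- !is.na(values)
  cnt <- tabulate(group[ok], nbins = max(group))
  informative <- which(cnt >= 2L)
  if (length(informative) < 1L) {
    stop("no informative respondent for trait '", trait, "'", call. = FALSE)
  }
  keep <- ok & cnt[group] >= 2L
  delta_full <- slots_delta(values[keep], group[keep],
                            tabulate(group[keep], nbins = max(group)))
  list(values = values, group = group, father = father,
       delta_full = delta_full, n_slots = length(values))
}

# Restricted consistency index when rows flagged in `excl` are removed.
exclusion_delta <- function(prep, excl) {
  keep <- !excl & !is.na(prep$values)
  if (!any(keep)) return(NA_real_)
  g <- prep$group[keep]
  cnt <- tabulate(g, nbins = max(prep$group))
  keep2 <- cnt[g] >= 2L
  if (!any(keep2)) return(NA_real_)
  slots_delta(prep$values[keep][keep2], g[keep2],
              tabulate(g[keep2], nbins = max(prep$group)))
}

#' Permutation test of father exceptionality
#'
#' Compares the observed change in the consistency index after excluding
#' fathers against the change when, within every respondent's partner set,
#' the same number of partners is relabelled as "fathers" uniformly at
#' random and excluded. A change below the null expectation marks fathers as
#' exceptional individuals within their partner sets; a change above it
#' marks them as especially typical. The two-tailed p-value doubles the
#' smaller tail fraction and is capped at 1.
#'
#' @inheritParams permutation_null
#' @return A one-row tibble of class `father_exclusion_row`: `trait`,
#'   `observed_change`, `expected_change_mean`, `expected_change_sd`, `p`,
#'   with the permutation samples in `attr(, "samples")`.
#' @export
father_exclusion_test <- function(cohort, trait, n_perm = 10000L,
                                  seed = NULL) {
  if (n_perm < 1L) stop("n_perm must be at least 1", call. = FALSE)
  prep <- father_trait_prep(cohort, trait)
  observed <- exclusion_delta(prep, prep$father) - prep$delta_full
  if (is.na(observed)) {
    stop("no respondent remains informative for '", trait,
         "' after father exclusion", call. = FALSE)
  }
  samples <- with_seed_if(seed, {
    vapply(seq_len(n_perm), function(i) {
      # ordering by (group, uniform key) permutes rows within each
      # respondent block, so flags are reassigned within respondents while
      # per-respondent father counts are preserved exactly
      fp <- prep$father[order(prep$group, runif(prep$n_slots))]
      exclusion_delta(prep, fp) - prep$delta_full
    }, numeric(1))
  })
  samples <- samples[!is.na(samples)]
  p <- min(1, 2 * min(mean(samples <= observed), mean(samples >= observed)))
  out <- tibble::tibble(trait = trait, observed_change = observed,
                        expected_change_mean = mean(samples),
                        expected_change_sd = stats::sd(samples),
                        p = p, n_perm = length(samples))
  structure(out, samples = samples,
            class = c("father_exclusion_row", class(out)))
}

#' Father exclusion table across traits
#'
#' Runs [father_exclusion_test()] per trait and BH-adjusts the p-values
#' across the trait family.
#'
#' @inheritParams consistency_table
#' @return A tibble of class `father_exclusion_tbl` with one row per trait.
#' @export
father_exclusion_table <- function(cohort, traits = NULL, n_perm = 10000L,
                                   seed = NULL) {
  traits <- traits %||% intersect(trait_registry(cohort)$trait, names(cohort))
  seeds <- if (is.null(seed)) rep(list(NULL), length(traits))
           else as.list(derive_seeds(seed, length(traits)))
  rows <- purrr::map2_dfr(traits, seeds, function(tr, s) {
    father_exclusion_test(cohort, tr, n_perm = n_perm, seed = s)
  })
  rows <- dplyr::mutate(rows, p_adj = bh_adjust(.data$p), .after = "p")
  structure(rows, class = c("father_exclusion_tbl", class(rows)))
}

#' Father versus non-father group contrasts
#'
#' `group_mean_model()` tests equality of father and non-father group means
#' for one trait with a mixed-effect model: trait value on a father
#' indicator, respondent identity as a random intercept. The intercept is
#' the non-father mean; the father effect is the adjusted group difference.
#' `group_variance_model()` is the mixed-model analogue of Levene's test for
#' equality of group variances: the response is the absolute deviation of
#' each value from its own (father or non-father) global group mean, fed
#' through the same model. P-values use Satterthwaite degrees of freedom.
#'
#' @inheritParams population_delta
#' @return A one-row tibble: `trait`, `model` ("mean" or "variance"),
#'   `intercept_nonfather`, `effect_father`, `se`, `p`, `note` (`NA` unless
#'   the fit is degenerate, in which case estimates are `NA` and `note`
#'   explains why).
#' @export
group_mean_model <- function(cohort, trait) {
  fit_father_model(cohort, trait, transform = identity, model = "mean")
}

#' @rdname group_mean_model
#' @export
group_variance_model <- function(cohort, trait) {
  fit_father_model(cohort, trait, model = "variance",
                   transform = function(df) {
                     df$value <- levene_response(df$value, df$is_father)
                     df
                   })
}

# absolute deviation from the global mean of the father / non-father group
levene_response <- function(value, is_father) {
  mu <- tapply(value, is_father, mean)
  as.numeric(abs(value - mu[as.character(is_father)]))
}

fit_father_model <- function(cohort, trait, transform, model) {
  if (!trait %in% names(cohort)) {
    stop("trait '", trait, "' is not a column of the cohort", call. = FALSE)
  }
  df <- data.frame(value = as.numeric(cohort[[trait]]),
                   is_father = as.logical(cohort$is_father),
                   respondent_id = factor(cohort$respondent_id))
  df <- df[!is.na(df$value), ]
  empty_row <- function(note) {
    tibble::tibble(trait = trait, model = model,
                   intercept_nonfather = NA_real_, effect_father = NA_real_,
                   se = NA_real_, p = NA_real_, note = note)
  }
  if (length(unique(df$is_father)) < 2L) {
    return(empty_row("one of the father/non-father groups is empty"))
  }
  if (model == "variance" && any(table(df$is_father) < 2L)) {
    return(empty_row("group of size < 2; variance contrast inestimable"))
  }
  df <- transform(df)
  if (stats::sd(df$value) == 0) {
    return(empty_row("constant response; inestimable"))
  }
  fit <- tryCatch(
    lmerTest::lmer(value ~ is_father + (1 | respondent_id), data = df),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(empty_row("mixed model failed to converge"))
  }
  cf <- stats::coef(summary(fit))
  tibble::tibble(trait = trait, model = model,
                 intercept_nonfather = cf["(Intercept)", "Estimate"],
                 effect_father = cf["is_fatherTRUE", "Estimate"],
                 se = cf["is_fatherTRUE", "Std. Error"],
                 p = cf["is_fatherTRUE", "Pr(>|t|)"],
                 note = NA_character_)
}

#' Father group model table across traits
#'
#' Runs the mean and variance contrasts for every trait; p-values are
#' BH-adjusted separately within the mean family and the variance family.
#'
#' @inheritParams consistency_table
#' @return A tibble of class `father_model_tbl`, two rows per trait.
#' @export
father_model_table <- function(cohort, traits = NULL) {
  traits <- traits %||% intersect(trait_registry(cohort)$trait, names(cohort))
  rows <- dplyr::bind_rows(
    purrr::map_dfr(traits, function(tr) group_mean_model(cohort, tr)),
    purrr::map_dfr(traits, function(tr) group_variance_model(cohort, tr)))
  rows <- rows |>
    dplyr::group_by(.data$model) |>
    dplyr::mutate(p_adj = {
      adj <- rep(NA_real_, dplyr::n())
      ok <- !is.na(.data$p)
      adj[ok] <- bh_adjust(.data$p[ok])
      adj
    }, .after = "p") |>
    dplyr::ungroup()
  structure(rows, class = c("father_model_tbl", class(rows)))
}
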