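#' Run the full mate-choice consistency analysis
#'
#' Orchestrates every stage over one cohort: per-trait permutation nulls and
#' consistency tests, stepwise relocation effect sizes, intraclass and
#' double-entry correlation measures with their equivalence summary,
#' pairwise shared effect sizes accumulated into the maximal cumulative
#' effect size, and the father-exclusion and father group-model contrasts.
#' All randomness derives from one master seed, so an identical cohort,
#' configuration and seed reproduce identical results.
#'
#' @inheritParams consistency_table
#' @param n_perm Random pairings per permutation null (default 10000).
#' @param n_effect_runs Stepwise runs per trait (default 10000).
#' @param n_resid_runs Residual runs per direction per trait pair
#'   (default 1000).
#' @param alpha Significance level used for flags.
#' @param run_shared Compute the pairwise shared-effect table and cumulative
#'   effect size. This is the most expensive stage (quadratic in traits);
#'   disable for quick looks.
#' @param out_dir Optional directory; when given, result tables are written
#'   there via [write_results_tables()].
#' @param verbose Print stage progress to stderr.
#' @return An object of class `mate_choice_analysis`: a list with tibbles
#'   `consistency`, `effect`, `association`, `equivalence`,
#'   `father_exclusion`, `father_models`, objects `shared`
#'   (`shared_effect_table`) and `cumulative` (`cumulative_result`) when
#'   `run_shared` is `TRUE`, plus `manifest` (seeds and counts). Use
#'   [tidy()] for the merged per-trait table and [glance()] for a one-row
#'   summary.
#' @export
run_mate_choice_analysis <- function(cohort, traits = NULL,
                                     n_perm = 10000L,
                                     n_effect_runs = 10000L,
                                     n_resid_runs = 1000L,
                                     seed = NULL, alpha = 0.05,
                                     run_shared = TRUE,
                                     out_dir = NULL, verbose = FALSE) {
  stopifnot(n_perm >= 1L, n_effect_runs >= 1L, n_resid_runs >= 1L)
  traits <- traits %||% intersect(trait_registry(cohort)$trait, names(cohort))
  say <- function(...) if (verbose) message("[mateperm] ", ...)
  stage_seeds <- if (is.null(seed)) rep(list(NULL), 4L)
                 else as.list(derive_seeds(seed, 4L))

  say("consistency: ", length(traits), " traits, n_perm = ", n_perm)
  trait_seeds <- if (is.null(seed)) rep(list(NULL), length(traits))
                 else as.list(derive_seeds(stage_seeds[[1]], length(traits)))
  nulls <- rlang::set_names(
    purrr::map2(traits, trait_seeds, function(tr, s) {
      permutation_null(cohort, tr, n_perm = n_perm, seed = s)
    }), traits)
  consistency <- purrr::map_dfr(traits, function(tr) {
    null <- nulls[[tr]]
    obs <- population_delta(cohort, tr)
    tibble::tibble(trait = tr, observed_delta = obs,
                   expected_delta = null$mean, expected_sd = null$sd,
                   p = consistency_test(obs, null),
                   n_respondents_informative = null$n_respondents,
                   n_partners_informative = null$n_partners)
  })
  consistency <- dplyr::mutate(consistency, p_adj = bh_adjust(.data$p),
                               .after = "p")
  consistency <- structure(consistency,
                           class = c("consistency_tbl", class(consistency)))

  say("stepwise effect sizes: n_runs = ", n_effect_runs)
  effect <- effect_size_table(cohort, traits, n_runs = n_effect_runs,
                              seed = stage_seeds[[2]], nulls = nulls)

  say("association measures")
  association <- association_table(cohort, traits)
  eq_rows <- dplyr::left_join(
    dplyr::select(effect, "trait", "effect_pct"),
    dplyr::select(association, "trait", "icc_pct", "pearson_r"),
    by = "trait")
  equivalence <- if (nrow(eq_rows) >= 3L) {
    tryCatch(measure_equivalence(eq_rows), error = function(e) NULL)
  }

  shared <- NULL
  cumulative <- NULL
  if (run_shared && length(traits) >= 2L) {
    say("shared effects: ", choose(length(traits), 2), " pairs, n_runs = ",
        n_resid_runs, " per direction")
    shared <- shared_effect_table(cohort, traits, n_perm = n_perm,
                                  n_runs = n_resid_runs,
                                  n_simple_runs = n_resid_runs,
                                  seed = stage_seeds[[3]])
    # reuse the main-stage simple effect sizes (higher run count)
    shared$simple <- rlang::set_names(effect$effect_pct, effect$trait)[shared$traits]
    diag(shared$shared) <- shared$simple
    shared$shared <- pmin(shared$shared, outer(shared$simple, shared$simple, pmin))
    cumulative <- cumulative_effect(shared)
  }

  father_exclusion <- NULL
  father_models <- NULL
  if (any(as.logical(cohort$is_father))) {
    say("father contrasts")
    father_exclusion <- father_exclusion_table(cohort, traits,
                                               n_perm = n_perm,
                                               seed = stage_seeds[[4]])
    father_models <- father_model_table(cohort, traits)
  }

  manifest <- list(
    package = "mateperm",
    version = as.character(utils::packageVersion("mateperm")),
    seed = seed, n_perm = n_perm, n_effect_runs = n_effect_runs,
    n_resid_runs = n_resid_runs, alpha = alpha, traits = traits,
    n_respondents = length(unique(cohort$respondent_id)),
    n_partners = nrow(cohort))

  result <- structure(list(consistency = consistency, effect = effect,
                           association = association,
                           equivalence = equivalence, shared = shared,
                           cumulative = cumulative,
                           father_exclusion = father_exclusion,
                           father_models = father_models,
                           manifest = manifest),
                      class = "mate_choice_analysis")
  if (!is.null(out_dir)) write_results_tables(result, out_dir)
  result
}

#' @export
print.mate_choice_analysis <- function(x, ...) {
  m <- x$manifest
  cat("Mate-choice consistency analysis\n")
  cat("  cohort: ", m$n_respondents, " respondents, ", m$n_partners,
      " partners, ", length(m$traits), " traits\n", sep = "")
  cat("  traits with adjusted consistency p < ", m$alpha, ": ",
      sum(x$consistency$p_adj < m$alpha), " / ",
      nrow(x$consistency), "\n", sep = "")
  if (!is.null(x$cumulative)) {
    cat("  maximal cumulative effect size: ",
        sprintf("%.2f%%", attr(x$cumulative, "total_pct")), "\n", sep = "")
  }
  invisible(x)
}

#' Cumulative effect size from a ready-made shared-effect table
#'
#' Bypasses all resampling: reads a shared-effect CSV (diagonal = simple
#' effect sizes, lower triangle = pairwise shared effect sizes; see
#' [read_shared_table()]) — for example one assembled from published
#' values — and accumulates it into the maximal cumulative effect size.
#'
#' @param table_path Path to the CSV, or a `shared_effect_table` object.
#' @param order Optional explicit inclusion order (see [cumulative_effect()]).
#' @param ... Passed on to [cumulative_effect()] (e.g. `fix_inconsistent`).
#' @return A `cumulative_result` tibble.
#' @export
run_cumulative_from_table <- function(table_path, order = NULL, ...) {
  table <- if (inherits(table_path, "shared_effect_table")) table_path
           else read_shared_table(table_path)
  cumulative_effect(table, order = order, ...)
}

#' Write the analysis result tables
#'
#' Writes the customary presentation tables as CSV with fixed column order:
#' `table1_consistency.csv` (consistency test, effect size and association
#' measures merged per trait), `table2_shared_effects.csv` (diagonal simple
#' effects, lower triangle shared effects, upper triangle correlations),
#' `table3_father_exclusion.csv`, `table4_father_models.csv`,
#' `equivalence.csv`, `cumulative.csv` and a `manifest.yaml`. P-values are
#' stored at full precision; a separate `p_display` column carries the
#' presentation string (e.g. `<0.001`). Empty stages produce header-only
#' files.
#'
#' @param results A `mate_choice_analysis`, or a named list with any of the
#'   elements `consistency`, `effect`, `association`, `equivalence`,
#'   `shared`, `cumulative`, `father_exclusion`, `father_models`,
#'   `manifest`.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the character vector of files written.
#' @export
write_results_tables <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("cannot create output directory '", out_dir, "'", call. = FALSE)
    }
  }
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path, na = "")
    files <<- c(files, path)
  }

  t1_template <- tibble::tibble(
    trait = character(), observed_delta = numeric(),
    expected_delta = numeric(), expected_sd = numeric(), p = numeric(),
    p_adj = numeric(), p_display = character(), effect_pct = numeric(),
    ci_lo = numeric(), ci_hi = numeric(), icc_pct = numeric(),
    pearson_r = numeric(), n_respondents_informative = integer(),
    n_partners_informative = integer())
  t1 <- results$consistency
  if (!is.null(t1)) {
    t1 <- tibble::as_tibble(t1)
    if (!is.null(results$effect)) {
      t1 <- dplyr::left_join(t1, dplyr::select(tibble::as_tibble(results$effect),
                                               "trait", "effect_pct",
                                               "ci_lo", "ci_hi"),
                             by = "trait")
    }
    if (!is.null(results$association)) {
      t1 <- dplyr::left_join(t1,
                             dplyr::select(tibble::as_tibble(results$association),
                                           "trait", "icc_pct", "pearson_r"),
                             by = "trait")
    }
    t1$p_display <- format_p(t1$p)
    t1 <- fill_schema(t1, t1_template)
  } else {
    t1 <- t1_template
  }
  emit(t1, "table1_consistency.csv")

  if (!is.null(results$shared)) {
    path <- file.path(out_dir, "table2_shared_effects.csv")
    write_shared_table(results$shared, path)
    files <- c(files, path)
  }

  t3_template <- tibble::tibble(
    trait = character(), observed_change = numeric(),
    expected_change_mean = numeric(), expected_change_sd = numeric(),
    p = numeric(), p_adj = numeric(), p_display = character(),
    n_perm = integer())
  t3 <- results$father_exclusion
  if (!is.null(t3)) {
    t3 <- tibble::as_tibble(t3)
    t3$p_display <- format_p(t3$p)
    t3 <- fill_schema(t3, t3_template)
  } else {
    t3 <- t3_template
  }
  emit(t3, "table3_father_exclusion.csv")

  t4_template <- tibble::tibble(
    trait = character(), model = character(),
    intercept_nonfather = numeric(), effect_father = numeric(),
    se = numeric(), p = numeric(), p_adj = numeric(),
    p_display = character(), note = character())
  t4 <- results$father_models
  if (!is.null(t4)) {
    t4 <- tibble::as_tibble(t4)
    t4$p_display <- format_p(t4$p)
    t4 <- fill_schema(t4, t4_template)
  } else {
    t4 <- t4_template
  }
  emit(t4, "table4_father_models.csv")

  if (!is.null(results$equivalence)) {
    emit(tibble::as_tibble(results$equivalence), "equivalence.csv")
  }
  if (!is.null(results$cumulative)) {
    cum <- tibble::as_tibble(results$cumulative)
    cum$total_pct <- attr(results$cumulative, "total_pct")
    emit(cum, "cumulative.csv")
  }
  if (!is.null(results$manifest)) {
    yaml::write_yaml(results$manifest, file.path(out_dir, "manifest.yaml"))
    files <- c(files, file.path(out_dir, "manifest.yaml"))
  }
  invisible(files)
}

fill_schema <- function(df, template) {
  for (nm in setdiff(names(template), names(df))) {
    df[[nm]] <- template[[nm]][rep(NA_integer_, nrow(df))]
  }
  df[, names(template)]
}

# Presentation-layer p-value strings; full-precision numbers stay in `p`.
format_p <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "<0.001",
    TRUE ~ sprintf("%.3f", p))
}
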