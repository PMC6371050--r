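#' Stepwise randomization effect sizes
#'
#' The effect size of consistent mate choice on a trait is expressed as the
#' proportion of partners that must change respondents before the consistency
#' index rises to the level expected under random pairing. Starting from the
#' observed data, two partners of different respondents are drawn uniformly
#' at random and exchanged; each exchange relocates two partners. The index
#' is elevated gradually: a proposed exchange that would not raise it is
#' discarded (and not counted), so every counted relocation moves the
#' configuration toward random-pairing diversity. The climb stops the first
#' time the consistency index reaches the target, and the proportion of
#' relocated partners (out of all informative partners) is recorded. The
#' proportion is bounded by about 50%: relocating more than half of the
#' partners starts to restore the original configuration.
#'
#' @name stepwise
NULL

# One stepwise randomization phase over a values matrix (rows = partner
# slots, cols = traits). Proposes uniform random swaps of whole partner rows
# between different respondents and accepts a proposal only if it raises the
# consistency index of column `active` (the index is elevated gradually, so
# moves that would lower it again are discarded and do not count); stops at
# the first accepted swap that lifts the index to `target`. Relies on the
# caller for RNG state. Returns the final matrix and the number of accepted
# swaps.
stepwise_phase <- function(V, group, sizes, idx_by_group, active, target,
                           max_swaps = Inf) {
  n_groups <- length(idx_by_group)
  group_delta <- unname(vapply(idx_by_group,
                               function(ix) mean_abs_pairdiff(V[ix, active]),
                               numeric(1)))
  delta <- mean(group_delta)
  nswaps <- 0L
  n_slots <- nrow(V)
  stall <- 0L
  max_stall <- max(10000L, 200L * n_slots)
  # tolerance guards against float drift in the incrementally tracked index
  # when the target is exactly attainable
  tol <- 1e-9 * max(1, abs(target))
  while (delta < target - tol) {
    if (nswaps >= max_swaps) {
      stop("stepwise randomization did not reach the target after ",
           max_swaps, " swaps", call. = FALSE)
    }
    i <- sample.int(n_slots, 1L)
    repeat {
      j <- sample.int(n_slots, 1L)
      if (group[j] != group[i]) break
    }
    ga <- group[i]; gb <- group[j]
    tmp <- V[i, ]
    V[i, ] <- V[j, ]
    V[j, ] <- tmp
    gd_a <- mean_abs_pairdiff(V[idx_by_group[[ga]], active])
    gd_b <- mean_abs_pairdiff(V[idx_by_group[[gb]], active])
    new_delta <- delta +
      (gd_a - group_delta[ga] + gd_b - group_delta[gb]) / n_groups
    if (new_delta > delta) {
      group_delta[ga] <- gd_a
      group_delta[gb] <- gd_b
      delta <- new_delta
      nswaps <- nswaps + 1L
      stall <- 0L
    } else {
      # revert: this relocation would not elevate the index
      tmp <- V[i, ]
      V[i, ] <- V[j, ]
      V[j, ] <- tmp
      stall <- stall + 1L
      if (stall >= max_stall) {
        stop("stepwise randomization stalled below the target (no ",
             "elevating relocation found in ", max_stall, " proposals)",
             call. = FALSE)
      }
    }
  }
  list(V = V, nswaps = nswaps, delta = delta)
}

slots_matrix <- function(slots) {
  V <- matrix(slots$values, ncol = 1)
  idx_by_group <- split(seq_len(slots$n_slots), slots$group)
  list(V = V, group = slots$group, sizes = slots$sizes,
       idx_by_group = idx_by_group)
}

#' @rdname stepwise
#' @inheritParams population_delta
#' @param target_delta Consistency-index level at which to stop, usually the
#'   mean of the trait's permutation null. If the observed index already
#'   meets it, no partners need to be switched and the run returns 0.
#' @param seed Optional integer seed.
#' @param max_swaps Safety cap on the number of swaps in one run.
#' @return `stepwise_run()` returns a single percentage: 100 x (2 x swaps) /
#'   (number of informative partners).
#' @export
stepwise_run <- function(cohort, trait, target_delta, seed = NULL,
                         max_swaps = Inf) {
  slots <- informative_slots(cohort, trait)
  if (is.null(slots) || slots$n_groups < 2L) {
    stop("need at least 2 informative respondents for trait '", trait, "'",
         call. = FALSE)
  }
  sm <- slots_matrix(slots)
  res <- with_seed_if(seed,
    stepwise_phase(sm$V, sm$group, sm$sizes, sm$idx_by_group, 1L,
                   target_delta, max_swaps))
  100 * (2 * res$nswaps) / slots$n_slots
}

#' @rdname stepwise
#' @param null A `null_distribution` for `trait` (see [permutation_null()]);
#'   its mean is the stopping target.
#' @param n_runs Number of independent stepwise runs (default 10000).
#' @return `stepwise_effect_size()` returns a one-row tibble of class
#'   `effect_size_estimate`: `trait`, `effect_pct` (mean over runs), `ci_lo`,
#'   `ci_hi` (2.5 and 97.5 percentiles over runs), `n_runs`.
#' @export
#' @examples
#' coh <- toy_eye_color_cohort(6)
#' population_delta(coh, "eye_color")  # 0: perfectly consistent
stepwise_effect_size <- function(cohort, trait, null, n_runs = 10000L,
                                 seed = NULL, max_swaps = Inf) {
  stopifnot(inherits(null, "null_distribution"))
  if (n_runs < 1L) stop("n_runs must be at least 1", call. = FALSE)
  slots <- informative_slots(cohort, trait)
  if (is.null(slots) || slots$n_groups < 2L) {
    stop("need at least 2 informative respondents for trait '", trait, "'",
         call. = FALSE)
  }
  sm <- slots_matrix(slots)
  target <- null$mean
  runs <- with_seed_if(seed, {
    vapply(seq_len(n_runs), function(i) {
      res <- stepwise_phase(sm$V, sm$group, sm$sizes, sm$idx_by_group, 1L,
                            target, max_swaps)
      100 * (2 * res$nswaps) / slots$n_slots
    }, numeric(1))
  })
  out <- tibble::tibble(
    trait = trait,
    effect_pct = mean(runs),
    ci_lo = unname(stats::quantile(runs, 0.025)),
    ci_hi = unname(stats::quantile(runs, 0.975)),
    n_runs = as.integer(n_runs))
  structure(out, runs = runs,
            class = c("effect_size_estimate", class(out)))
}

#' Per-trait effect size table
#'
#' Convenience wrapper computing, for each trait, the permutation null and
#' the stepwise relocation effect size against that null's mean.
#'
#' @inheritParams consistency_table
#' @param n_runs Stepwise runs per trait.
#' @param nulls Optional named list of precomputed `null_distribution`
#'   objects (names = traits), e.g. from a previous [consistency_table()]
#'   stage; missing entries are computed.
#' @return A tibble with one `effect_size_estimate` row per trait.
#' @export
effect_size_table <- function(cohort, traits = NULL, n_perm = 10000L,
                              n_runs = 10000L, seed = NULL, nulls = NULL) {
  traits <- traits %||% intersect(trait_registry(cohort)$trait, names(cohort))
  seeds <- if (is.null(seed)) rep(list(NULL), 2L * length(traits))
           else as.list(derive_seeds(seed, 2L * length(traits)))
  purrr::imap_dfr(rlang::set_names(traits), function(tr, nm) {
    k <- 2L * (match(tr, traits) - 1L)
    null <- nulls[[tr]] %||%
      permutation_null(cohort, tr, n_perm = n_perm, seed = seeds[[k + 1L]])
    stepwise_effect_size(cohort, tr, null, n_runs = n_runs,
                         seed = seeds[[k + 2L]])
  })
}

#' Minimal relocation to the maximal-consistency-index configuration
#'
#' Helper for two-level traits where every respondent lists exactly two
#' partners with identical values (e.g. the all-brown/all-blue eye-colour
#' toy cohort). The maximal consistency index is attained when every
#' respondent holds one partner of each value; the minimal way there pairs
#' respondents of opposite values and exchanges one partner per pair. The
#' result is the proportion of partners relocated, as a percentage.
#'
#' @inheritParams population_delta
#' @return A percentage of all partners.
#' @export
#' @examples
#' minimal_relocation_to_max(toy_eye_color_cohort(100), "eye_color")  # 50
minimal_relocation_to_max <- function(cohort, trait) {
  slots <- informative_slots(cohort, trait)
  if (is.null(slots)) stop("no informative respondents", call. = FALSE)
  if (any(slots$sizes[unique(slots$group)] != 2L)) {
    stop("helper requires exactly two partners per respondent", call. = FALSE)
  }
  vals <- split(slots$values, slots$group)
  pure <- vapply(vals, function(v) v[1] == v[2], logical(1))
  levels <- unique(slots$values)
  if (length(levels) != 2L) {
    stop("helper requires a two-level trait", call. = FALSE)
  }
  pure_by_level <- table(factor(vapply(vals[pure], `[`, numeric(1), 1),
                                levels = levels))
  if (pure_by_level[1] != pure_by_level[2]) {
    stop("pure respondents are unbalanced across the two values; the fully ",
         "mixed configuration is unreachable", call. = FALSE)
  }
  n_swaps <- sum(pure) / 2
  100 * (2 * n_swaps) / slots$n_slots
}
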