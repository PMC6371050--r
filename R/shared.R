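#' Residual effect size of one trait after eliminating another
#'
#' The residual effect size of trait `b` given trait `a` is the proportion of
#' partners that still must be switched to remove consistency in `b` after
#' consistency in `a` has already been randomized away. Each run first swaps
#' whole partners (both trait values travel together) until the consistency
#' index of `a` reaches its random-pairing expectation, then continues
#' swapping from that configuration until `b` reaches its own expectation;
#' only the second-phase relocations count. Both traits are analysed on their
#' common informative subset: partners with both values present, respondents
#' with at least two such partners.
#'
#' @inheritParams population_delta
#' @param a,b Trait names; `a` is eliminated first, the residual is for `b`.
#' @param nulls Optional named list of `null_distribution` objects for `a`
#'   and `b`. They must describe the common informative subset; when `NULL`
#'   (recommended) both nulls are computed on that subset with `n_perm`
#'   random pairings.
#' @param n_runs Number of two-phase runs to average (default 1000).
#' @param n_perm Random pairings used for internally computed nulls.
#' @param seed Optional integer seed.
#' @param max_swaps Safety cap per phase.
#' @return A one-row tibble: `a`, `b`, `residual_pct` (mean over runs),
#'   `simple_a_pct`, `simple_b_pct` (single-trait effect sizes on the common
#'   subset, averaged over the same runs), `n_runs`.
#' @export
residual_effect_size <- function(cohort, a, b, nulls = NULL, n_runs = 1000L,
                                 n_perm = 1000L, seed = NULL,
                                 max_swaps = Inf) {
  if (n_runs < 1L) stop("n_runs must be at least 1", call. = FALSE)
  sm <- pairwise_slots(cohort, a, b)
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL)
           else as.list(derive_seeds(seed, 3L))
  target_a <- pair_null_mean(sm, 1L, nulls[[a]], n_perm, seeds[[1]])
  target_b <- pair_null_mean(sm, 2L, nulls[[b]], n_perm, seeds[[2]])
  runs <- with_seed_if(seeds[[3]], {
    vapply(seq_len(n_runs), function(i) {
      ph_a <- stepwise_phase(sm$V, sm$group, sm$sizes, sm$idx_by_group, 1L,
                             target_a, max_swaps)
      ph_b <- stepwise_phase(ph_a$V, sm$group, sm$sizes, sm$idx_by_group, 2L,
                             target_b, max_swaps)
      100 * (2 * ph_b$nswaps) / nrow(sm$V)
    }, numeric(1))
  })
  tibble::tibble(a = a, b = b, residual_pct = mean(runs),
                 n_runs = as.integer(n_runs))
}

# Common informative subset of two traits as a two-column slots matrix.
pairwise_slots <- function(cohort, a, b) {
  for (tr in c(a, b)) {
    if (!tr %in% names(cohort)) {
      stop("trait '", tr, "' is not a column of the cohort", call. = FALSE)
    }
  }
  keep <- !is.na(cohort[[a]]) & !is.na(cohort[[b]])
  sub <- cohort[keep, c("respondent_id", a, b)]
  sub <- sub[order(sub$respondent_id), ]
  counts <- table(sub$respondent_id)
  sub <- sub[sub$respondent_id %in% names(counts)[counts >= 2L], ]
  if (nrow(sub) == 0L) {
    stop("no common informative partners for '", a, "' and '", b, "'",
         call. = FALSE)
  }
  group <- match(sub$respondent_id, unique(sub$respondent_id))
  if (max(group) < 2L) {
    stop("need at least 2 informative respondents for the pair ('",
         a, "', '", b, "')", call. = FALSE)
  }
  V <- cbind(as.numeric(sub[[a]]), as.numeric(sub[[b]]))
  list(V = V, group = group, sizes = tabulate(group),
       idx_by_group = split(seq_len(nrow(V)), group))
}

pair_null_mean <- function(sm, col, null, n_perm, seed) {
  if (!is.null(null)) {
    stopifnot(inherits(null, "null_distribution"))
    return(null$mean)
  }
  vals <- sm$V[, col]
  samples <- with_seed_if(seed, {
    vapply(seq_len(n_perm), function(i) {
      slots_delta(vals[sample.int(length(vals))], sm$group, sm$sizes)
    }, numeric(1))
  })
  mean(samples)
}

#' Shared effect size of two traits
#'
#' Two traits' relocation effect sizes overlap when randomizing partners for
#' one also removes consistency in the other. Writing the union of the two
#' effects as one simple effect plus the other's residual, the shared part is
#' the amount by which the sum of simple effects exceeds the union. With
#' simple effects 16% and 11% and residuals 6% (second after first) and 11%
#' (first after second), the union is 22% either way and the shared effect
#' is 5%.
#'
#' @param e_a,e_b Simple effect sizes (%) of the two traits.
#' @param resid_b_given_a Residual effect (%) of the second trait after the
#'   first is eliminated.
#' @param resid_a_given_b Residual effect (%) of the first after the second.
#' @return A one-row tibble with `shared` (clamped below at 0) and `union`
#'   (the mean of the two directed union estimates).
#' @export
#' @examples
#' shared_effect(16, 11, 6, 11)  # shared 5, union 22
shared_effect <- function(e_a, e_b, resid_b_given_a, resid_a_given_b) {
  inputs <- c(e_a, e_b, resid_b_given_a, resid_a_given_b)
  if (any(inputs < 0)) stop("effect sizes must be non-negative", call. = FALSE)
  union <- mean(c(e_a + resid_b_given_a, e_b + resid_a_given_b))
  shared <- max(0, e_a + e_b - union)
  tibble::tibble(shared = shared, union = union)
}

#' Apportion a third trait's overlap with a two-trait union
#'
#' Estimating third-order intersections by permutation is computationally
#' prohibitive, so the overlap of a third trait C with the union of A and B
#' is split proportionally: the segments (A ∩ C) ∖ B, (B ∩ C) ∖ A and
#' A ∩ B ∩ C are assumed to stand in the same proportion as A ∖ B, B ∖ A and
#' A ∩ B, scaled so that their sum — with the triple intersection counted
#' twice, once inside A ∩ C and once inside B ∩ C — equals
#' `shared_ac + shared_bc`.
#'
#' @param e_a,e_b,e_c Simple effect sizes (%).
#' @param shared_ab,shared_ac,shared_bc Pairwise shared effect sizes (%);
#'   each must not exceed the smaller of its two simple effects.
#' @return A one-row tibble: `ac_not_b`, `bc_not_a`, `abc`, `unique_c`
#'   (= `e_c` minus C's total overlap, floored at 0), and `union_abc`.
#'   Negative apportionment weights (possible only with inconsistent inputs)
#'   are clamped to zero and the remaining weights renormalized.
#' @export
#' @examples
#' apportion_higher_order(20, 15, 10, 10, 4, 3)
#' # ac_not_b 2, bc_not_a 1, abc 2, unique_c 5, union_abc 30
apportion_higher_order <- function(e_a, e_b, e_c, shared_ab, shared_ac,
                                   shared_bc) {
  if (shared_ab > min(e_a, e_b) + 1e-9 || shared_ac > min(e_a, e_c) + 1e-9 ||
      shared_bc > min(e_b, e_c) + 1e-9) {
    stop("each shared effect must not exceed its simple effects",
         call. = FALSE)
  }
  w <- pmax(0, c(e_a - shared_ab, e_b - shared_ab, shared_ab))
  target <- shared_ac + shared_bc
  if (sum(w) == 0) {
    if (target > 1e-9) {
      stop("cannot apportion a positive overlap over an empty A-B union",
           call. = FALSE)
    }
    seg <- c(0, 0, 0)
  } else {
    w <- w / sum(w)
    seg <- target / (w[1] + w[2] + 2 * w[3]) * w
  }
  unique_c <- max(0, e_c - sum(seg))
  tibble::tibble(ac_not_b = seg[1], bc_not_a = seg[2], abc = seg[3],
                 unique_c = unique_c,
                 union_abc = e_a + (e_b - shared_ab) + unique_c)
}

#' Shared-effect table for a set of traits
#'
#' Computes, for every trait pair, the directed residual effect sizes and
#' from them the symmetric shared effect size, alongside simple effect sizes
#' and partner-level Pearson correlations. This is the input to
#' [cumulative_effect()].
#'
#' @inheritParams consistency_table
#' @param simple Optional named numeric vector of simple effect sizes (%);
#'   when `NULL` they are computed with [effect_size_table()] using
#'   `n_simple_runs` runs per trait.
#' @param n_runs Residual runs per direction per pair (default 1000).
#' @param n_simple_runs Stepwise runs per trait for simple effects.
#' @param n_perm Random pairings per permutation null.
#' @return An object of class `shared_effect_table`: a list with `traits`,
#'   `simple` (named %), `shared` (symmetric matrix, diagonal = simple,
#'   pairwise values clamped into \[0, min of the two simple effects\]),
#'   `resid` (directed matrix, entry \[b, a\] = residual of b given a),
#'   `corr` and `corr_p_adj` (partner-level Pearson correlations and their
#'   jointly BH-adjusted p-values).
#' @export
shared_effect_table <- function(cohort, traits = NULL, n_perm = 1000L,
                                n_runs = 1000L, n_simple_runs = n_runs,
                                seed = NULL) {
  traits <- traits %||% intersect(trait_registry(cohort)$trait, names(cohort))
  k <- length(traits)
  if (k < 2L) stop("need at least 2 traits", call. = FALSE)
  seeds <- if (is.null(seed)) rep(list(NULL), k * k + 1L)
           else as.list(derive_seeds(seed, k * k + 1L))
  est <- effect_size_table(cohort, traits, n_perm = n_perm,
                           n_runs = n_simple_runs, seed = seeds[[k * k + 1L]])
  simple <- rlang::set_names(est$effect_pct, est$trait)

  resid <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  shared <- matrix(0, k, k, dimnames = list(traits, traits))
  diag(shared) <- simple[traits]
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      a <- traits[i]; b <- traits[j]
      r_ba <- residual_effect_size(cohort, a, b, n_runs = n_runs,
                                   n_perm = n_perm,
                                   seed = seeds[[(i - 1L) * k + j]])
      r_ab <- residual_effect_size(cohort, b, a, n_runs = n_runs,
                                   n_perm = n_perm,
                                   seed = seeds[[(j - 1L) * k + i]])
      resid[b, a] <- r_ba$residual_pct
      resid[a, b] <- r_ab$residual_pct
      se <- shared_effect(simple[[a]], simple[[b]],
                          resid[b, a], resid[a, b])
      shared[a, b] <- shared[b, a] <-
        min(max(0, se$shared), simple[[a]], simple[[b]])
    }
  }
  tc <- trait_correlations(cohort, traits)
  new_shared_effect_table(traits, simple[traits], shared, resid,
                          corr = tc$r, corr_p_adj = tc$p_adj)
}

new_shared_effect_table <- function(traits, simple, shared, resid = NULL,
                                    corr = NULL, corr_p_adj = NULL) {
  stopifnot(isTRUE(all.equal(shared, t(shared), tolerance = 1e-8)))
  structure(list(traits = traits, simple = simple, shared = shared,
                 resid = resid, corr = corr, corr_p_adj = corr_p_adj),
            class = "shared_effect_table")
}

#' @export
print.shared_effect_table <- function(x, ...) {
  cat("Shared-effect table over", length(x$traits), "traits\n")
  cat("  simple effects (%):\n")
  print(round(x$simple, 2))
  invisible(x)
}

#' Read and write shared-effect tables as CSV
#'
#' The CSV mirrors the customary presentation: first column `trait`, then one
#' column per trait; simple effect sizes (%) on the diagonal, pairwise shared
#' effect sizes (%) in the lower triangle, and (optionally) partner-level
#' Pearson correlations in the upper triangle. A table written by
#' `write_shared_table()` — or assembled by hand from published values — can
#' be read back and fed straight into [cumulative_effect()].
#'
#' @param x A `shared_effect_table`.
#' @param path CSV path.
#' @return `read_shared_table()` returns a `shared_effect_table` (with
#'   `corr` populated from the upper triangle when present);
#'   `write_shared_table()` returns `path` invisibly.
#' @export
write_shared_table <- function(x, path) {
  stopifnot(inherits(x, "shared_effect_table"))
  k <- length(x$traits)
  m <- matrix(NA_real_, k, k, dimnames = list(x$traits, x$traits))
  m[lower.tri(m)] <- x$shared[lower.tri(x$shared)]
  diag(m) <- x$simple
  if (!is.null(x$corr)) m[upper.tri(m)] <- x$corr[upper.tri(x$corr)]
  out <- tibble::as_tibble(as.data.frame(m), rownames = "trait")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_shared_table
#' @export
read_shared_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  traits <- raw$trait
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- traits
  if (!identical(colnames(m), traits)) {
    stop("shared table rows and columns must list the same traits in the ",
         "same order", call. = FALSE)
  }
  simple <- rlang::set_names(as.numeric(diag(m)), traits)
  shared <- matrix(0, length(traits), length(traits),
                   dimnames = list(traits, traits))
  shared[lower.tri(shared)] <- m[lower.tri(m)]
  shared <- shared + t(shared)
  diag(shared) <- simple
  corr <- NULL
  if (any(!is.na(m[upper.tri(m)]))) {
    corr <- matrix(NA_real_, length(traits), length(traits),
                   dimnames = list(traits, traits))
    corr[upper.tri(corr)] <- m[upper.tri(m)]
    corr[lower.tri(corr)] <- t(corr)[lower.tri(corr)]
    diag(corr) <- 1
  }
  new_shared_effect_table(traits, simple, shared, corr = corr)
}

#' Maximal cumulative effect size
#'
#' Accumulates per-trait relocation effect sizes into the proportion of
#' partners that must be switched to remove consistency on all traits
#' simultaneously. Traits are added one at a time; each remaining trait's
#' unique contribution to the running union is estimated by splitting its
#' pairwise shared effects with the already-included traits across the
#' union's disjoint segments, in proportion to segment sizes, with a segment
#' covered by m included traits counted m times (the pairwise generalization
#' of the three-variable proportional apportionment). A contribution that
#' grows from one step to the next signals accumulated apportionment error,
#' so each candidate's contribution is capped at the minimum value computed
#' for it in earlier steps, and floored at zero.
#'
#' @param table A `shared_effect_table` (computed by [shared_effect_table()],
#'   or read from CSV with [read_shared_table()]).
#' @param order Optional character vector fixing the inclusion order. By
#'   default the trait with the largest simple effect is taken first and each
#'   subsequent step adds the trait with the largest unique contribution,
#'   ties broken by trait name.
#' @param fix_inconsistent A shared effect larger than one of its two simple
#'   effects is set-algebraically impossible, yet tables assembled from
#'   independently resampled (or rounded, published) estimates can carry
#'   such excesses. With `FALSE` (default) they are an error; with `TRUE`
#'   the offending shared values are clamped to the smaller simple effect,
#'   with a message.
#' @return A tibble of class `cumulative_result` with one row per inclusion
#'   step: `step`, `trait`, `unique_contribution` (%), `cumulative_pct`.
#'   The grand total is `attr(, "total_pct")` and is also reported by
#'   [glance.cumulative_result()].
#' @export
cumulative_effect <- function(table, order = NULL, fix_inconsistent = FALSE) {
  stopifnot(inherits(table, "shared_effect_table"))
  traits <- table$traits
  simple <- table$simple[traits]
  shared <- table$shared[traits, traits, drop = FALSE]
  cap <- outer(simple, simple, pmin)
  bad <- which(shared > cap + 1e-6, arr.ind = TRUE)
  bad <- bad[bad[, 1] != bad[, 2], , drop = FALSE]
  if (nrow(bad) > 0L) {
    if (!fix_inconsistent) {
      stop("inconsistent table: shared effect exceeds a simple effect for ",
           paste(unique(traits[bad[, 1]]), collapse = ", "),
           "; rerun with fix_inconsistent = TRUE to clamp", call. = FALSE)
    }
    message("clamping ", nrow(bad) / 2, " shared effect(s) that exceed a ",
            "simple effect")
    shared <- pmin(shared, cap)
  }
  if (!is.null(order)) {
    if (!setequal(order, traits)) {
      stop("'order' must be a permutation of the table's traits",
           call. = FALSE)
    }
  }

  # Disjoint segments of the running union: sizes[i] with labels[[i]] the
  # set of included traits covering segment i.
  seg_size <- numeric(0)
  seg_mult <- integer(0)
  seg_cover <- list()   # per segment, character vector of covering traits
  included <- character(0)
  remaining <- sort(traits)
  run_min <- rlang::set_names(rep(Inf, length(traits)), traits)
  rows <- list()

  candidate_overlap <- function(tr) {
    target <- sum(shared[tr, included])
    if (length(seg_size) == 0L || sum(seg_size) == 0) {
      return(list(overlap = 0, x = numeric(length(seg_size))))
    }
    denom <- sum(seg_mult * seg_size)
    s <- if (denom > 0) min(target / denom, 1) else 0
    x <- s * seg_size
    list(overlap = sum(x), x = x)
  }

  step <- 0L
  while (length(remaining) > 0L) {
    step <- step + 1L
    if (step == 1L) {
      pick <- if (!is.null(order)) order[1L] else {
        cand <- remaining[simple[remaining] == max(simple[remaining])]
        sort(cand)[1L]
      }
      contrib_raw <- unname(simple[pick])
      ov <- list(overlap = 0, x = numeric(0))
    } else {
      raw <- vapply(remaining, function(tr) {
        unname(simple[tr]) - candidate_overlap(tr)$overlap
      }, numeric(1))
      eff <- rlang::set_names(
        pmax(0, pmin(unname(raw), unname(run_min[remaining]))), remaining)
      run_min[remaining] <- pmin(run_min[remaining], raw)
      pick <- if (!is.null(order)) order[step] else {
        cand <- remaining[eff == max(eff)]
        sort(cand)[1L]
      }
      contrib_raw <- unname(eff[[pick]])
      ov <- candidate_overlap(pick)
    }
    contrib <- max(0, contrib_raw)

    # Split the union's segments into covered / uncovered parts; scale the
    # raw proportional pieces so the total overlap equals simple - contrib.
    overlap_eff <- max(0, unname(simple[pick]) - contrib)
    x <- ov$x
    if (length(x) > 0L) {
      tot_raw <- sum(x)
      x <- if (tot_raw > 0) x * (overlap_eff / tot_raw)
           else if (sum(seg_size) > 0) seg_size * (overlap_eff / sum(seg_size))
           else x
      x <- pmin(x, seg_size)
    }
    new_size <- c(seg_size - x, x, contrib)
    new_cover <- c(seg_cover,
                   lapply(seg_cover, function(cv) c(cv, pick)),
                   list(pick))
    keep <- new_size > 1e-12
    seg_size <- new_size[keep]
    seg_cover <- new_cover[keep]
    seg_mult <- lengths(seg_cover)

    included <- c(included, pick)
    remaining <- setdiff(remaining, pick)
    rows[[step]] <- tibble::tibble(step = step, trait = pick,
                                   unique_contribution = contrib)
  }
  out <- dplyr::bind_rows(rows)
  out$cumulative_pct <- cumsum(out$unique_contribution)
  total <- sum(out$unique_contribution)
  structure(out, total_pct = total,
            class = c("cumulative_result", class(out)))
}

#' @export
print.cumulative_result <- function(x, ...) {
  cat("Maximal cumulative effect size:",
      sprintf("%.2f%%", attr(x, "total_pct")), "\n")
  NextMethod()
}
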