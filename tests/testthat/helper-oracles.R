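# Independent brute-force oracles; intentionally naive and written without
# reusing package internals, so they can cross-check the fast paths.

# consistency index by the definition: explicit double loop over respondents
# and over all unordered partner pairs
oracle_delta <- function(cohort, trait) {
  per_resp <- c()
  for (id in unique(cohort$respondent_id)) {
    v <- cohort[[trait]][cohort$respondent_id == id]
    v <- v[!is.na(v)]
    if (length(v) < 2) next
    acc <- c()
    for (j in seq_along(v)) {
      for (k in seq_along(v)) {
        if (j < k) acc <- c(acc, abs(v[j] - v[k]))
      }
    }
    per_resp <- c(per_resp, mean(acc))
  }
  mean(per_resp)
}

# all permutations of 1..n (n <= 8), recursively
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

# exact null distribution of the consistency index: one delta per ordering
# of the pooled values into the fixed slot structure
oracle_exhaustive_null <- function(values, group) {
  perms <- all_perms(length(values))
  apply(perms, 1, function(ix) {
    v <- values[ix]
    per_resp <- tapply(v, group, function(x) {
      mean(abs(outer(x, x, "-"))[upper.tri(diag(length(x)))])
    })
    mean(per_resp)
  })
}

# BH step-up by the definition, applied to sorted values
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- sorted * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# double-entry correlation built pair by pair
oracle_double_entry_r <- function(cohort, trait) {
  xs <- c(); ys <- c()
  for (id in unique(cohort$respondent_id)) {
    v <- cohort[[trait]][cohort$respondent_id == id]
    v <- v[!is.na(v)]
    if (length(v) < 2) next
    for (j in seq_along(v)) {
      for (k in seq_along(v)) {
        if (j != k) { xs <- c(xs, v[j]); ys <- c(ys, v[k]) }
      }
    }
  }
  cor(xs, ys)
}

# cumulative accumulation reimplemented with bitmask region bookkeeping:
# regions of the running union keyed by the subset of covering traits
oracle_cumulative <- function(simple, shared, order = NULL) {
  traits <- names(simple)
  regions <- list()   # each: list(cover = character vec, size = numeric)
  contribs <- c()
  run_min <- setNames(rep(Inf, length(traits)), traits)
  remaining <- sort(traits)
  included <- character(0)

  raw_contrib <- function(tr) {
    target <- sum(vapply(included, function(i) shared[i, tr], 0))
    denom <- sum(vapply(regions, function(r) length(r$cover) * r$size, 0))
    if (denom == 0) return(list(u = simple[[tr]], s = 0))
    s <- min(target / denom, 1)
    overlap <- s * sum(vapply(regions, function(r) r$size, 0))
    list(u = simple[[tr]] - overlap, s = s)
  }

  for (step in seq_along(traits)) {
    if (step == 1) {
      pick <- if (!is.null(order)) order[1] else {
        cand <- remaining[simple[remaining] == max(simple[remaining])]
        sort(cand)[1]
      }
      u_eff <- simple[[pick]]
    } else {
      effs <- setNames(vapply(remaining, function(tr) {
        rc <- raw_contrib(tr)
        max(0, min(rc$u, run_min[[tr]]))
      }, 0), remaining)
      for (tr in remaining) {
        run_min[[tr]] <- min(run_min[[tr]], raw_contrib(tr)$u)
      }
      pick <- if (!is.null(order)) order[step] else {
        cand <- remaining[effs == max(effs)]
        sort(cand)[1]
      }
      u_eff <- effs[[pick]]
    }
    # split regions into covered/uncovered parts
    overlap_eff <- max(0, simple[[pick]] - u_eff)
    sizes <- vapply(regions, function(r) r$size, 0)
    rc <- if (step == 1) list(s = 0) else raw_contrib(pick)
    x <- if (length(sizes) == 0) numeric(0) else rc$s * sizes
    tot_raw <- sum(x)
    if (length(x) > 0) {
      if (tot_raw > 0) x <- x * overlap_eff / tot_raw
      else if (sum(sizes) > 0) x <- sizes * overlap_eff / sum(sizes)
      x <- pmin(x, sizes)
    }
    new_regions <- list()
    for (q in seq_along(regions)) {
      r <- regions[[q]]
      if (r$size - x[q] > 1e-12) {
        new_regions[[length(new_regions) + 1]] <-
          list(cover = r$cover, size = r$size - x[q])
      }
      if (x[q] > 1e-12) {
        new_regions[[length(new_regions) + 1]] <-
          list(cover = c(r$cover, pick), size = x[q])
      }
    }
    if (u_eff > 1e-12 || step == 1) {
      new_regions[[length(new_regions) + 1]] <-
        list(cover = pick, size = u_eff)
    }
    regions <- new_regions
    contribs[pick] <- u_eff
    included <- c(included, pick)
    remaining <- setdiff(remaining, pick)
  }
  list(contribs = contribs, total = sum(contribs), order = included)
}

# quick long-format cohort builder: values is a named list respondent ->
# vector of partner trait values (last partner flagged father)
make_cohort <- function(values, trait = "extraversion",
                        registry = default_trait_registry()) {
  rows <- do.call(rbind, lapply(names(values), function(id) {
    v <- values[[id]]
    data.frame(respondent_id = id, partner_ordinal = seq_along(v),
               is_father = seq_along(v) == length(v), value = v)
  }))
  names(rows)[names(rows) == "value"] <- trait
  cohort_table(rows, registry[registry$trait == trait, ])
}
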