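#' Respondent-attributable variance (intraclass correlation)
#'
#' Fits a random-intercept model of partner trait values with respondent
#' identity as the sole random factor (REML) and returns the percentage of
#' total variance attributable to the respondent: 100 x var(respondent) /
#' (var(respondent) + var(residual)). This is the intraclass correlation
#' expressed as a percentage, a correlational companion to the relocation
#' effect size. Customary benchmarks: 10% meaningful, 20% medium, 30% large.
#'
#' @inheritParams population_delta
#' @return A one-row tibble: `trait`, `icc_pct`, `icc_label` (benchmark
#'   category), `n_respondents`, `n_partners`. Singular fits return the
#'   boundary estimate 0%.
#' @export
icc_percent <- function(cohort, trait) {
  slots <- informative_slots(cohort, trait)
  if (is.null(slots) || slots$n_groups < 2L) {
    stop("need at least 2 informative respondents for trait '", trait, "'",
         call. = FALSE)
  }
  df <- data.frame(value = slots$values,
                   respondent_id = factor(slots$respondent_id))
  fit <- tryCatch(
    lme4::lmer(value ~ 1 + (1 | respondent_id), data = df, REML = TRUE),
    error = function(e) {
      stop("mixed model for trait '", trait, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_resp <- vc$vcov[vc$grp == "respondent_id"]
  v_resid <- vc$vcov[vc$grp == "Residual"]
  icc <- if (v_resp + v_resid == 0) 0 else 100 * v_resp / (v_resp + v_resid)
  tibble::tibble(
    trait = trait, icc_pct = icc,
    icc_label = cut(icc, c(-Inf, 10, 20, 30, Inf),
                    labels = c("negligible", "meaningful", "medium", "large"),
                    right = FALSE),
    n_respondents = slots$n_groups, n_partners = slots$n_slots)
}

#' Double-entry pairwise Pearson correlation
#'
#' Treats every unordered pair of partners of the same respondent as a unit
#' of analysis. Each pair is entered in both orientations (x, y) and (y, x),
#' which makes the correlation symmetric in the pair members. Respondents
#' with more partners contribute more pairs and hence weigh more.
#'
#' @inheritParams population_delta
#' @return A one-row tibble: `trait`, `pearson_r`, `n_pairs` (unordered
#'   pairs, before double entry).
#' @export
pairwise_pearson <- function(cohort, trait) {
  slots <- informative_slots(cohort, trait)
  if (is.null(slots) || slots$n_groups < 2L) {
    stop("need at least 2 informative respondents for trait '", trait, "'",
         call. = FALSE)
  }
  pairs <- purrr::map_dfr(split(slots$values, slots$group), function(v) {
    idx <- utils::combn(length(v), 2)
    tibble::tibble(x = v[idx[1, ]], y = v[idx[2, ]])
  })
  x2 <- c(pairs$x, pairs$y)
  y2 <- c(pairs$y, pairs$x)
  if (stats::sd(x2) == 0 || stats::sd(y2) == 0) {
    stop("trait '", trait, "' has zero variance across partner pairs",
         call. = FALSE)
  }
  tibble::tibble(trait = trait, pearson_r = stats::cor(x2, y2),
                 n_pairs = nrow(pairs))
}

#' Equivalence of the three consistency measures
#'
#' Correlates the three per-trait consistency measures — relocation effect
#' size, respondent-attributable variance and double-entry Pearson r —
#' across traits, and fits an ordinary least-squares line of the variance
#' percentage on the effect size, the customary conversion between the two
#' scales.
#'
#' @param rows A data frame with one row per trait and numeric columns
#'   `effect_pct`, `icc_pct`, `pearson_r`.
#' @return A one-row tibble of class `equivalence_summary`:
#'   `corr_effect_icc`, `corr_effect_r`, `corr_icc_r`, `slope`, `slope_lo`,
#'   `slope_hi`, `intercept`, `intercept_lo`, `intercept_hi`, `n_traits`.
#' @export
measure_equivalence <- function(rows) {
  need <- c("effect_pct", "icc_pct", "pearson_r")
  miss <- setdiff(need, names(rows))
  if (length(miss) > 0L) {
    stop("rows is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rows <- tidyr::drop_na(tibble::as_tibble(rows)[, need])
  if (nrow(rows) < 3L) stop("need at least 3 traits", call. = FALSE)
  if (any(vapply(rows, stats::sd, numeric(1)) == 0)) {
    stop("constant measure column; correlations undefined", call. = FALSE)
  }
  fit <- stats::lm(icc_pct ~ effect_pct, data = rows)
  ci <- stats::confint(fit, level = 0.95)
  out <- tibble::tibble(
    corr_effect_icc = stats::cor(rows$effect_pct, rows$icc_pct),
    corr_effect_r = stats::cor(rows$effect_pct, rows$pearson_r),
    corr_icc_r = stats::cor(rows$icc_pct, rows$pearson_r),
    slope = unname(stats::coef(fit)[2]),
    slope_lo = ci["effect_pct", 1], slope_hi = ci["effect_pct", 2],
    intercept = unname(stats::coef(fit)[1]),
    intercept_lo = ci["(Intercept)", 1], intercept_hi = ci["(Intercept)", 2],
    n_traits = nrow(rows))
  structure(out, class = c("equivalence_summary", class(out)))
}

#' Partner-level correlations between traits
#'
#' Pearson correlations between all trait pairs with a single partner as the
#' unit of analysis, using pairwise-complete observations. Two-sided
#' p-values are adjusted jointly across all pairs with the Benjamini-Hochberg
#' procedure and flagged at the requested level.
#'
#' @inheritParams consistency_table
#' @param alpha Significance level for the adjusted flags.
#' @return A list of class `trait_correlations`: matrices `r`, `p`, `p_adj`,
#'   logical `significant`, integer `n` (complete observations per pair),
#'   and the long-format tibble `pairs` with one row per unordered pair.
#'   Pairs with fewer than 3 complete observations stay `NA`.
#' @export
trait_correlations <- function(cohort, traits = NULL, alpha = 0.05) {
  traits <- traits %||% intersect(trait_registry(cohort)$trait, names(cohort))
  k <- length(traits)
  if (k < 2L) stop("need at least 2 traits", call. = FALSE)
  M <- as.matrix(tibble::as_tibble(cohort)[, traits])
  idx <- utils::combn(k, 2)
  pairs <- purrr::map_dfr(seq_len(ncol(idx)), function(q) {
    i <- idx[1, q]; j <- idx[2, q]
    ok <- stats::complete.cases(M[, c(i, j)])
    n <- sum(ok)
    if (n < 3L || stats::sd(M[ok, i]) == 0 || stats::sd(M[ok, j]) == 0) {
      return(tibble::tibble(trait_a = traits[i], trait_b = traits[j],
                            r = NA_real_, n = n, p = NA_real_))
    }
    ct <- stats::cor.test(M[ok, i], M[ok, j], method = "pearson")
    tibble::tibble(trait_a = traits[i], trait_b = traits[j],
                   r = unname(ct$estimate), n = n, p = ct$p.value)
  })
  pairs$p_adj <- NA_real_
  ok <- !is.na(pairs$p)
  pairs$p_adj[ok] <- bh_adjust(pairs$p[ok])
  pairs$significant <- !is.na(pairs$p_adj) & pairs$p_adj < alpha

  as_mat <- function(v, default = NA) {
    m <- matrix(default, k, k, dimnames = list(traits, traits))
    for (q in seq_len(nrow(pairs))) {
      m[pairs$trait_a[q], pairs$trait_b[q]] <- v[q]
      m[pairs$trait_b[q], pairs$trait_a[q]] <- v[q]
    }
    m
  }
  r <- as_mat(pairs$r); diag(r) <- 1
  structure(list(r = r, p = as_mat(pairs$p), p_adj = as_mat(pairs$p_adj),
                 significant = as_mat(pairs$significant, default = FALSE),
                 n = as_mat(pairs$n), pairs = pairs, alpha = alpha),
            class = "trait_correlations")
}

#' @export
print.trait_correlations <- function(x, ...) {
  cat("Partner-level trait correlations:", nrow(x$pairs), "pairs;",
      sum(x$pairs$significant, na.rm = TRUE),
      "significant after BH at alpha =", x$alpha, "\n")
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values (a
#' validating wrapper around [stats::p.adjust()]). Output preserves input
#' order, is elementwise at least the input, monotone after sorting, and
#' capped at 1.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-trait association measure table
#'
#' Computes the intraclass-correlation percentage and double-entry pairwise
#' Pearson r for each trait.
#'
#' @inheritParams consistency_table
#' @return A tibble with one row per trait: `trait`, `icc_pct`, `icc_label`,
#'   `pearson_r`, `n_pairs`.
#' @export
association_table <- function(cohort, traits = NULL) {
  traits <- traits %||% intersect(trait_registry(cohort)$trait, names(cohort))
  purrr::map_dfr(traits, function(tr) {
    icc <- tryCatch(icc_percent(cohort, tr), error = function(e) {
      tibble::tibble(trait = tr, icc_pct = NA_real_,
                     icc_label = factor(NA, levels = c("negligible",
                                                       "meaningful", "medium",
                                                       "large")),
                     n_respondents = NA_integer_, n_partners = NA_integer_)
    })
    r <- tryCatch(pairwise_pearson(cohort, tr), error = function(e) {
      tibble::tibble(trait = tr, pearson_r = NA_real_, n_pairs = NA_integer_)
    })
    dplyr::left_join(icc, r, by = "trait")
  })
}
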