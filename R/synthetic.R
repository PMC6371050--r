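#' Configuration for the synthetic cohort generator
#'
#' Describes a questionnaire-style cohort: how many respondents, how many
#' long-term partners each lists, how strongly partner trait values cluster
#' within respondents (the per-trait intraclass correlation), how traits
#' correlate at the partner level, how fathers differ, and how much is
#' missing. Defaults emulate the motivating study population: 537 mothers,
#' partner counts from a discretized normal with mean 2.98 and SD 1.32
#' truncated to 2-10, a trait-dependent consistency profile spanning 0-44%
#' respondent-attributable variance, exactly one father (the last-listed
#' partner) per respondent, neutral father shifts, and sparse
#' completely-at-random cell missingness (0.8% per cell, which leaves about
#' 38% of respondents with at least one skipped item).
#'
#' @param n_respondents Number of respondents.
#' @param partner_count_mean,partner_count_sd Mean and SD of the parent
#'   normal for partner counts, before discretization and truncation.
#' @param partner_count_range Inclusive integer support for partner counts.
#' @param registry Trait registry for the generated traits.
#' @param icc Per-trait intraclass correlation in \[0, 1): a scalar recycled
#'   over traits or a named vector. `NULL` uses the built-in study-like
#'   profile for the default registry (scalar 0.15 otherwise).
#' @param trait_sd Per-trait total SD of the latent (pre-rounding) values;
#'   defaults to one sixth of the scale width.
#' @param trait_corr Optional positive-semidefinite partner-level correlation
#'   matrix across traits (identity when `NULL`).
#' @param father_mean_shift Added to father rows' latent values: scalar or
#'   named per-trait vector (default 0).
#' @param father_sd_ratio Multiplier of father rows' residual SD (default 1).
#' @param extra_father_prob Probability that each non-last partner is also
#'   flagged as a father (default 0: exactly one father per respondent).
#' @param missing_rate Per-cell completely-at-random missingness in \[0, 1).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_respondents = 537L,
                          partner_count_mean = 2.98,
                          partner_count_sd = 1.32,
                          partner_count_range = c(2L, 10L),
                          registry = default_trait_registry(),
                          icc = NULL,
                          trait_sd = NULL,
                          trait_corr = NULL,
                          father_mean_shift = 0,
                          father_sd_ratio = 1,
                          extra_father_prob = 0,
                          missing_rate = 0.008) {
  validate_registry(registry)
  traits <- registry$trait
  icc <- expand_per_trait(icc %||% default_icc_profile(traits), traits, "icc")
  if (any(icc < 0 | icc >= 1)) {
    stop("icc values must lie in [0, 1)", call. = FALSE)
  }
  trait_sd <- expand_per_trait(
    trait_sd %||% (registry$scale_max - registry$scale_min) / 6,
    traits, "trait_sd")
  father_mean_shift <- expand_per_trait(father_mean_shift, traits,
                                        "father_mean_shift")
  father_sd_ratio <- expand_per_trait(father_sd_ratio, traits,
                                      "father_sd_ratio")
  if (any(father_sd_ratio <= 0)) {
    stop("father_sd_ratio must be positive", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  if (partner_count_range[1] < 2L) {
    stop("partner counts below 2 violate the cohort inclusion rule",
         call. = FALSE)
  }
  if (!is.null(trait_corr)) {
    stopifnot(is.matrix(trait_corr),
              nrow(trait_corr) == length(traits),
              ncol(trait_corr) == length(traits))
    ev <- eigen(trait_corr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("trait_corr must be positive semi-definite", call. = FALSE)
    }
  }
  structure(list(n_respondents = as.integer(n_respondents),
                 partner_count_mean = partner_count_mean,
                 partner_count_sd = partner_count_sd,
                 partner_count_range = as.integer(partner_count_range),
                 registry = registry, icc = icc, trait_sd = trait_sd,
                 trait_corr = trait_corr,
                 father_mean_shift = father_mean_shift,
                 father_sd_ratio = father_sd_ratio,
                 extra_father_prob = extra_father_prob,
                 missing_rate = missing_rate),
            class = "cohort_config")
}

expand_per_trait <- function(x, traits, what) {
  if (is.null(names(x))) {
    if (length(x) == 1L) {
      return(rlang::set_names(rep(as.numeric(x), length(traits)), traits))
    }
    if (length(x) == length(traits)) {
      return(rlang::set_names(as.numeric(x), traits))
    }
    stop(what, " must be a scalar, a full-length vector, or named by trait",
         call. = FALSE)
  }
  unknown <- setdiff(names(x), traits)
  if (length(unknown) > 0L) {
    stop(what, " names not in the registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (all(traits %in% names(x))) {
    return(rlang::set_names(as.numeric(x[traits]), traits))
  }
  if (what %in% c("icc", "trait_sd")) {
    stop(what, " given as a named vector must cover every trait",
         call. = FALSE)
  }
  default <- if (what == "father_sd_ratio") 1 else 0
  out <- rlang::set_names(rep(default, length(traits)), traits)
  out[names(x)] <- as.numeric(x)
  out
}

# Study-like per-trait respondent-variance profile (fractions) used as the
# default ICC configuration for the built-in 21-trait registry.
default_icc_profile <- function(traits) {
  prof <- c(
    residence = 0.4358, education = 0.1924, age_difference = 0.1397,
    weight = 0.3377, height = 0.2456, attractiveness = 0.1649,
    masculinity = 0.0971, eye_color = 0.0431, hair_color = 0.1017,
    facial_masculinity = 0, beardedness = 0.0683, muscularity = 0.0343,
    bmi = 0.1187, relative_height = 0.3058, hirsuteness = 0.1031,
    leg_to_body_ratio = 0.1352, extraversion = 0.0932,
    agreeableness = 0.0355, conscientiousness = 0.0508,
    emotional_stability = 0.081, openness = 0.0927)
  if (all(traits %in% names(prof))) prof[traits] else
    rlang::set_names(rep(0.15, length(traits)), traits)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort with the statistical structure the consistency analyses
#' assume. For each trait, the latent value of partner j of respondent i is
#' the scale midpoint plus a Gaussian respondent effect u_i plus Gaussian
#' partner noise e_ij, with var(u) / (var(u) + var(e)) equal to the
#' configured intraclass correlation. Father rows receive the configured
#' mean shift and residual-SD ratio. Integer-coded traits are rounded, all
#' values are clipped to their scale, and cells are blanked completely at
#' random at the configured rate. Rounding and clipping slightly attenuate
#' the realized clustering on coarse ordinal scales.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the same config and seed always reproduce the
#'   identical cohort.
#' @return A list with `cohort` (a `mate_cohort` tibble) and `truth` (the
#'   generating parameters: per-trait `icc`, `father_mean_shift`,
#'   `father_sd_ratio`, the respondent-effect matrix `u`, and `seed`).
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed_if(seed, {
    reg <- config$registry
    traits <- reg$trait
    k <- length(traits)
    n <- config$n_respondents
    counts <- draw_partner_counts(n, config)
    N <- sum(counts)
    resp <- rep(seq_len(n), counts)
    ordinal <- sequence(counts)
    is_father <- ordinal == rep(counts, counts)
    if (config$extra_father_prob > 0) {
      is_father <- is_father |
        (runif(N) < config$extra_father_prob & !is_father)
    }

    L <- if (is.null(config$trait_corr)) diag(k) else {
      ev <- eigen(config$trait_corr, symmetric = TRUE)
      ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k) %*% t(ev$vectors)
    }
    sd_u <- config$trait_sd * sqrt(config$icc)
    sd_e <- config$trait_sd * sqrt(1 - config$icc)
    u <- (matrix(rnorm(n * k), n, k) %*% L) %*% diag(sd_u, k)
    e <- (matrix(rnorm(N * k), N, k) %*% L) %*% diag(sd_e, k)
    e[is_father, ] <- e[is_father, , drop = FALSE] %*%
      diag(config$father_sd_ratio, k)
    mid <- (reg$scale_min + reg$scale_max) / 2
    V <- matrix(mid, N, k, byrow = TRUE) + u[resp, , drop = FALSE] + e
    V[is_father, ] <- V[is_father, , drop = FALSE] +
      matrix(config$father_mean_shift, sum(is_father), k, byrow = TRUE)
    for (q in seq_len(k)) {
      if (reg$integer_valued[q]) V[, q] <- round(V[, q])
      V[, q] <- pmin(pmax(V[, q], reg$scale_min[q]), reg$scale_max[q])
    }
    if (config$missing_rate > 0) {
      V[matrix(runif(N * k) < config$missing_rate, N, k)] <- NA_real_
    }
    colnames(V) <- traits
    data <- tibble::tibble(
      respondent_id = sprintf("R%04d", resp),
      partner_ordinal = as.integer(ordinal),
      is_father = is_father)
    data <- dplyr::bind_cols(data, tibble::as_tibble(V))
    cohort <- cohort_table(data, reg)
    truth <- list(icc = config$icc,
                  father_mean_shift = config$father_mean_shift,
                  father_sd_ratio = config$father_sd_ratio,
                  u = u, seed = seed)
    list(cohort = cohort, truth = truth)
  })
}

draw_partner_counts <- function(n, config) {
  lo <- config$partner_count_range[1]
  hi <- config$partner_count_range[2]
  out <- integer(0)
  while (length(out) < n) {
    cand <- as.integer(round(rnorm(2L * n, config$partner_count_mean,
                                   config$partner_count_sd)))
    out <- c(out, cand[cand >= lo & cand <= hi])
  }
  out[seq_len(n)]
}

#' Exact moments of the partner-count distribution
#'
#' Mean and SD of the discretized, truncated normal used by
#' [generate_cohort()] for partner counts, computed from its probability
#' mass function.
#'
#' @param config A [cohort_config()].
#' @return Named numeric vector with `mean` and `sd`.
#' @export
partner_count_moments <- function(config = cohort_config()) {
  lo <- config$partner_count_range[1]
  hi <- config$partner_count_range[2]
  kk <- lo:hi
  pm <- stats::pnorm(kk + 0.5, config$partner_count_mean,
                     config$partner_count_sd) -
        stats::pnorm(kk - 0.5, config$partner_count_mean,
                     config$partner_count_sd)
  pm <- pm / sum(pm)
  m <- sum(kk * pm)
  c(mean = m, sd = sqrt(sum((kk - m)^2 * pm)))
}

#' Binary eye-colour toy cohort
#'
#' The textbook configuration for the relocation effect size bound: every
#' respondent lists exactly two partners of the same eye colour, half of the
#' respondents all-brown, half all-blue. The observed consistency index is 0
#' (perfect consistency); the maximal index is reached when every respondent
#' holds one partner of each colour, which takes relocating exactly half of
#' all partners.
#'
#' @param n_respondents Even number of respondents.
#' @return A `mate_cohort` with the single trait `eye_color` (blue = 2,
#'   brown = 4 on the 1-5 colour scale).
#' @export
#' @examples
#' toy <- toy_eye_color_cohort(4)
#' population_delta(toy, "eye_color")          # 0
#' minimal_relocation_to_max(toy, "eye_color") # 50
toy_eye_color_cohort <- function(n_respondents) {
  if (n_respondents %% 2L != 0L || n_respondents < 2L) {
    stop("n_respondents must be a positive even number", call. = FALSE)
  }
  n <- as.integer(n_respondents)
  colour <- rep(c(4, 2), each = n / 2L)  # brown = 4, blue = 2
  data <- tibble::tibble(
    respondent_id = sprintf("R%04d", rep(seq_len(n), each = 2L)),
    partner_ordinal = rep(1:2, n),
    is_father = rep(c(FALSE, TRUE), n),
    eye_color = rep(colour, each = 2L))
  reg <- default_trait_registry()
  cohort_table(data, reg[reg$trait == "eye_color", ])
}
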