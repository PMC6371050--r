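small_registry <- function() {
  reg <- default_trait_registry()
  reg[reg$trait %in% c("residence", "weight", "extraversion"), ]
}

test_that("generation is fully reproducible from config and seed", {
  cfg <- cohort_config(n_respondents = 25, registry = small_registry(),
                       icc = c(0.3, 0.2, 0.1), missing_rate = 0.05)
  g1 <- generate_cohort(cfg, seed = 404)
  g2 <- generate_cohort(cfg, seed = 404)
  expect_identical(tibble::as_tibble(g1$cohort), tibble::as_tibble(g2$cohort))
  expect_identical(g1$truth$u, g2$truth$u)
  g3 <- generate_cohort(cfg, seed = 405)
  expect_false(identical(g1$cohort$weight, g3$cohort$weight))
})

test_that("partner counts follow the discretized truncated normal", {
  cfg <- cohort_config(n_respondents = 4000, registry = small_registry(),
                       icc = 0, missing_rate = 0)
  counts <- partner_counts(generate_cohort(cfg, seed = 8)$cohort)$n_partners
  expect_true(all(counts >= 2 & counts <= 10))
  mom <- partner_count_moments(cfg)
  expect_lt(abs(mean(counts) - mom[["mean"]]), 3 * mom[["sd"]] / sqrt(4000))
  expect_lt(abs(sd(counts) - mom[["sd"]]), 0.1)
})

test_that("generated values honour scale bounds, integer coding and missingness", {
  cfg <- cohort_config(n_respondents = 300, registry = default_trait_registry(),
                       missing_rate = 0.05)
  coh <- generate_cohort(cfg, seed = 15)$cohort
  reg <- trait_registry(coh)
  for (i in seq_len(nrow(reg))) {
    v <- coh[[reg$trait[i]]]
    v <- v[!is.na(v)]
    expect_true(all(v >= reg$scale_min[i] & v <= reg$scale_max[i]))
    if (reg$integer_valued[i]) expect_true(all(v == round(v)))
  }
  n_cells <- nrow(coh) * nrow(reg)
  n_missing <- sum(is.na(as.matrix(tibble::as_tibble(coh)[, reg$trait])))
  expect_lt(abs(n_missing / n_cells - 0.05), 0.01)
})

test_that("default father rule flags exactly the last-listed partner", {
  coh <- generate_cohort(cohort_config(n_respondents = 50,
                                       registry = small_registry(),
                                       missing_rate = 0), seed = 2)$cohort
  per <- tapply(coh$is_father, coh$respondent_id, sum)
  expect_true(all(per == 1L))
  last <- tapply(seq_len(nrow(coh)), coh$respondent_id, function(ix) {
    coh$is_father[ix][which.max(coh$partner_ordinal[ix])]
  })
  expect_true(all(unlist(last)))
})

test_that("neutral father settings leave father and non-father margins exchangeable", {
  cfg <- cohort_config(n_respondents = 1500, registry = small_registry(),
                       icc = 0, missing_rate = 0,
                       father_mean_shift = 0, father_sd_ratio = 1)
  coh <- generate_cohort(cfg, seed = 33)$cohort
  w_f <- coh$weight[coh$is_father]
  w_n <- coh$weight[!coh$is_father]
  expect_gt(stats::t.test(w_f, w_n)$p.value, 0.01)
  expect_lt(abs(sd(w_f) / sd(w_n) - 1), 0.1)
})

test_that("father shift and SD ratio reach the generated rows", {
  cfg <- cohort_config(n_respondents = 1200, registry = small_registry(),
                       icc = 0, missing_rate = 0,
                       father_mean_shift = c(weight = 8),
                       father_sd_ratio = c(weight = 2))
  coh <- generate_cohort(cfg, seed = 9)$cohort
  w_f <- coh$weight[coh$is_father]
  w_n <- coh$weight[!coh$is_father]
  expect_lt(abs(mean(w_f) - mean(w_n) - 8), 1.5)
  expect_gt(sd(w_f) / sd(w_n), 1.6)
})

test_that("ICC-0 cohorts yield approximately uniform permutation p-values", {
  # Kolmogorov-Smirnov check over replicate generations
  cfg <- cohort_config(n_respondents = 40, registry = small_registry(),
                       icc = 0, missing_rate = 0)
  seeds <- 1:200
  ps <- vapply(seeds, function(s) {
    coh <- generate_cohort(cfg, seed = s)$cohort
    obs <- population_delta(coh, "weight")
    null <- permutation_null(coh, "weight", n_perm = 80, seed = s + 10000)
    consistency_test(obs, null)
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("configured ICC is recovered by the mixed model on a continuous trait", {
  reg <- default_trait_registry()
  reg <- reg[reg$trait == "weight", ]
  errs <- vapply(1:10, function(s) {
    coh <- generate_cohort(cohort_config(n_respondents = 500, registry = reg,
                                         icc = 0.30, missing_rate = 0),
                           seed = 600 + s)$cohort
    icc_percent(coh, "weight")$icc_pct - 30
  }, numeric(1))
  # the estimator's per-cohort SE is ~3 points; recovery is judged on the
  # average over seeds
  expect_lt(abs(mean(errs)), 5)
  expect_true(all(abs(errs) <= 10))
})

test_that("invalid configurations are refused", {
  expect_error(cohort_config(icc = 1), "\\[0, 1\\)")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
  expect_error(cohort_config(partner_count_range = c(1, 10)), "inclusion")
  expect_error(cohort_config(registry = small_registry(),
                             trait_corr = matrix(c(1, 2, 2, 1), 2)),
               "semi-definite|dimension|nrow|ncol")
})

test_that("the eye-colour toy cohort has the stated structure", {
  toy <- toy_eye_color_cohort(4)
  expect_equal(nrow(toy), 8L)
  expect_equal(as.integer(table(toy$eye_color)), c(4L, 4L))
  expect_equal(population_delta(toy, "eye_color"), 0)

  tiny <- toy_eye_color_cohort(2)
  expect_equal(nrow(tiny), 4L)
  # one cross-respondent swap fully mixes both respondents
  expect_equal(minimal_relocation_to_max(tiny, "eye_color"), 50)
  expect_error(toy_eye_color_cohort(5), "even")
})
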