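test_that("per-respondent mean pairwise difference matches hand calculation", {
  expect_equal(respondent_mean_pairwise_diff(c(5, 10, 7, 14)), 5)
  expect_equal(respondent_mean_pairwise_diff(c(11, 13)), 2)
  expect_equal(respondent_mean_pairwise_diff(rep(3.7, 5)), 0)
  expect_error(respondent_mean_pairwise_diff(c(4, NA)), "at least 2")
})

test_that("population index averages respondents equally and matches brute force", {
  coh <- make_cohort(list(A = c(11, 13), B = c(5, 10, 7, 14)))
  expect_equal(population_delta(coh, "extraversion"), 3.5)

  same <- make_cohort(list(A = c(4, 4, 4), B = c(9, 9)))
  expect_equal(population_delta(same, "extraversion"), 0)

  set.seed(42)
  vals <- lapply(1:10, function(i) sample(2:14, sample(2:5, 1), replace = TRUE))
  names(vals) <- paste0("R", 1:10)
  rnd <- make_cohort(vals)
  expect_equal(population_delta(rnd, "extraversion"),
               oracle_delta(rnd, "extraversion"))
})

test_that("the index is ordering-invariant, translation-invariant and scales by |c|", {
  set.seed(7)
  vals <- lapply(1:8, function(i) sample(40:140, sample(2:4, 1)))
  names(vals) <- paste0("R", 1:8)
  coh <- make_cohort(vals, trait = "weight")
  d0 <- population_delta(coh, "weight")

  shuffled <- coh[sample.int(nrow(coh)), ]
  shuffled$partner_ordinal <- stats::ave(seq_len(nrow(shuffled)),
                                         shuffled$respondent_id,
                                         FUN = seq_along)
  coh2 <- cohort_table(tibble::as_tibble(shuffled), trait_registry(coh))
  expect_equal(population_delta(coh2, "weight"), d0)

  # translation and scaling checked on the raw statistic
  v <- c(5, 9, 2, 11)
  expect_equal(respondent_mean_pairwise_diff(v + 100),
               respondent_mean_pairwise_diff(v))
  expect_equal(respondent_mean_pairwise_diff(v * -2.5),
               2.5 * respondent_mean_pairwise_diff(v))
})

test_that("permutation null matches exhaustive enumeration on a tiny cohort", {
  coh <- make_cohort(list(A = c(1, 1), B = c(2, 2), C = c(3, 3)),
                     trait = "muscularity")
  values <- rep(c(1, 2, 3), each = 2)
  group <- rep(1:3, each = 2)
  exact <- oracle_exhaustive_null(values, group)

  null <- permutation_null(coh, "muscularity", n_perm = 4000, seed = 5)
  mc_se <- stats::sd(exact) / sqrt(null$n_perm)
  expect_lt(abs(null$mean - mean(exact)), 3 * mc_se)

  # one-tailed p equals the exact tail fraction (strict <)
  obs <- population_delta(coh, "muscularity")  # 0, below every arrangement?
  p_exact <- mean(exact < obs)
  p_mc <- consistency_test(obs, null)
  expect_lt(abs(p_mc - p_exact), 0.03)
  # an intermediate threshold exercises a non-degenerate tail
  mid <- stats::median(exact)
  expect_lt(abs(consistency_test(mid, null) - mean(exact < mid)), 0.05)
})

test_that("permutation null is seed-reproducible and preserves partner counts", {
  set.seed(11)
  vals <- lapply(1:6, function(i) sample(1:9, sample(2:4, 1), replace = TRUE))
  names(vals) <- paste0("R", 1:6)
  coh <- make_cohort(vals, trait = "hair_color")
  n1 <- permutation_null(coh, "hair_color", n_perm = 50, seed = 99)
  n2 <- permutation_null(coh, "hair_color", n_perm = 50, seed = 99)
  expect_identical(n1$samples, n2$samples)
  expect_equal(n1$n_perm, 50L)
  expect_equal(n1$mean, mean(n1$samples))
  expect_equal(n1$sd, sd(n1$samples))
})

test_that("degenerate and extreme nulls give p = 1 and p = 0 as defined", {
  const <- make_cohort(list(A = c(3, 3), B = c(3, 3, 3)), trait = "bmi")
  null <- permutation_null(const, "bmi", n_perm = 30, seed = 1)
  expect_true(all(null$samples == 0))
  expect_equal(null$sd, 0)
  expect_equal(consistency_test(0, null), 1)

  spread <- make_cohort(list(A = c(1, 9), B = c(2, 8), C = c(1, 8)),
                        trait = "hair_color")
  null2 <- permutation_null(spread, "hair_color", n_perm = 200, seed = 2)
  expect_equal(consistency_test(-1, null2), 0)            # below every sample
  expect_equal(consistency_test(100, null2), 1)           # above every sample
})

test_that("consistency table adjusts p-values across traits and flags informative sizes", {
  gen <- generate_cohort(
    cohort_config(n_respondents = 30,
                  registry = default_trait_registry()[c(1, 8), ],
                  icc = c(0.5, 0), missing_rate = 0.05),
    seed = 21)
  tab <- consistency_table(gen$cohort, n_perm = 200, seed = 3)
  expect_s3_class(tab, "consistency_tbl")
  expect_equal(tab$trait, c("residence", "eye_color"))
  expect_equal(tab$p_adj, bh_adjust(tab$p))
  expect_true(all(tab$observed_delta >= 0))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_true(all(tab$n_respondents_informative <= 30))
})
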