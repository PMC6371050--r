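# make_cohort flags each respondent's last-listed partner as the father

test_that("father-exclusion change matches brute-force recomputation", {
  coh <- make_cohort(list(A = c(4, 4, 4), B = c(9, 9)))
  expect_equal(father_exclusion_change(coh, "extraversion"), 0)

  # father is the extreme outlier of every set: excluding tightens the index
  out <- make_cohort(list(A = c(5, 6, 14), B = c(7, 8, 2), C = c(9, 9, 3)))
  expect_lt(father_exclusion_change(out, "extraversion"), 0)

  set.seed(55)
  vals <- lapply(1:9, function(i) sample(2:14, sample(2:4, 1), replace = TRUE))
  names(vals) <- paste0("R", 1:9)
  rnd <- make_cohort(vals)
  full <- oracle_delta(rnd, "extraversion")
  restricted <- oracle_delta(rnd[!rnd$is_father, ], "extraversion")
  expect_equal(father_exclusion_change(rnd, "extraversion"),
               restricted - full)
})

test_that("exchangeable fathers give the null change and p = 1", {
  # identical partners within each respondent: any relabelling excludes an
  # identical partner, so every permutation reproduces the observed change
  coh <- make_cohort(list(A = c(4, 4, 4), B = c(9, 9, 9), C = c(13, 13, 13)))
  row <- father_exclusion_test(coh, "extraversion", n_perm = 60, seed = 10)
  expect_equal(row$p, 1)
  expect_equal(row$expected_change_sd, 0)
  expect_equal(row$observed_change, row$expected_change_mean)
})

test_that("permutation tails match exhaustive father relabelling on a tiny cohort", {
  coh <- make_cohort(list(A = c(3, 7, 12), B = c(5, 9), C = c(2, 13, 8)))
  # enumerate every admissible labelling: one father per respondent
  labelings <- expand.grid(a = 1:3, b = 1:2, c = 1:3)
  exact <- apply(labelings, 1, function(lab) {
    excl <- coh$is_father & FALSE
    excl[which(coh$respondent_id == "A")[lab[1]]] <- TRUE
    excl[which(coh$respondent_id == "B")[lab[2]]] <- TRUE
    excl[which(coh$respondent_id == "C")[lab[3]]] <- TRUE
    oracle_delta(coh[!excl, ], "extraversion") -
      oracle_delta(coh, "extraversion")
  })
  row <- father_exclusion_test(coh, "extraversion", n_perm = 3000, seed = 77)
  samples <- attr(row, "samples")
  obs <- row$observed_change
  expect_lt(abs(mean(samples <= obs) - mean(exact <= obs)), 0.05)
  expect_lt(abs(mean(samples >= obs) - mean(exact >= obs)), 0.05)
  expect_lt(abs(row$expected_change_mean - mean(exact)), 0.1)
})

test_that("random father flags yield approximately uniform exclusion p-values", {
  reg <- default_trait_registry()
  reg1 <- reg[reg$trait == "weight", ]
  ps <- vapply(1:120, function(s) {
    coh <- generate_cohort(cohort_config(n_respondents = 35, registry = reg1,
                                         icc = 0.3, missing_rate = 0),
                           seed = 4000 + s)$cohort
    father_exclusion_test(coh, "weight", n_perm = 80, seed = 8000 + s)$p
  }, numeric(1))
  # doubled-tail p-values on a discrete null are conservative near 1; check
  # the lower tail is not inflated and the body is broadly uniform
  expect_lt(mean(ps <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 120))
  expect_gt(mean(ps <= 0.5), 0.5 - 3 * sqrt(0.25 / 120))
})

test_that("group mean model recovers an injected father shift", {
  reg <- default_trait_registry()
  reg1 <- reg[reg$trait == "weight", ]
  coh <- generate_cohort(cohort_config(n_respondents = 500, registry = reg1,
                                       icc = 0.2, missing_rate = 0,
                                       father_mean_shift = c(weight = 5)),
                         seed = 123)$cohort
  row <- group_mean_model(coh, "weight")
  expect_true(is.na(row$note))
  expect_lt(abs(row$effect_father - 5), 1.96 * row$se)
  expect_lt(row$p, 0.001)
  expect_lt(abs(row$intercept_nonfather - 90), 2)  # scale midpoint

  same <- generate_cohort(cohort_config(n_respondents = 300, registry = reg1,
                                        icc = 0.2, missing_rate = 0),
                          seed = 124)$cohort
  row0 <- group_mean_model(same, "weight")
  expect_lt(abs(row0$effect_father), 3 * row0$se)
})

test_that("variance model uses absolute deviations from global group means", {
  # groups {1,3} (non-fathers) and {2,6} (fathers): deviations (1,1) and
  # (2,2) per group, i.e. (1,2,1,2) in row order
  expect_equal(mateperm:::levene_response(c(1, 2, 3, 6),
                                          c(FALSE, TRUE, FALSE, TRUE)),
               c(1, 2, 1, 2))
})

test_that("father SD inflation is detected by the variance contrast", {
  reg <- default_trait_registry()
  reg1 <- reg[reg$trait == "weight", ]
  coh <- generate_cohort(cohort_config(n_respondents = 500, registry = reg1,
                                       icc = 0.1, missing_rate = 0,
                                       father_sd_ratio = c(weight = 2)),
                         seed = 321)$cohort
  row <- group_variance_model(coh, "weight")
  expect_gt(row$effect_father, 0)
  expect_lt(row$p, 0.01)
})

test_that("degenerate father models are reported as inestimable", {
  df <- tibble::tibble(
    respondent_id = rep(c("A", "B"), each = 2),
    partner_ordinal = rep(1:2, 2),
    is_father = rep(c(0, 1), 2),
    bmi = rep(3, 4))
  reg <- default_trait_registry()
  coh <- cohort_table(df, reg[reg$trait == "bmi", ])
  row <- group_mean_model(coh, "bmi")
  expect_true(is.na(row$effect_father))
  expect_match(row$note, "constant|inestimable")

  no_f <- df
  no_f$is_father <- 0
  no_f$bmi <- c(1, 2, 3, 4)
  cohn <- cohort_table(no_f, reg[reg$trait == "bmi", ])
  rown <- group_mean_model(cohn, "bmi")
  expect_match(rown$note, "empty")
})

test_that("father tables adjust p-values within separate families", {
  reg <- default_trait_registry()
  reg2 <- reg[reg$trait %in% c("weight", "extraversion"), ]
  coh <- generate_cohort(cohort_config(n_respondents = 60, registry = reg2,
                                       icc = 0.3, missing_rate = 0.02),
                         seed = 222)$cohort
  ex <- father_exclusion_table(coh, n_perm = 120, seed = 9)
  expect_equal(ex$p_adj, bh_adjust(ex$p))
  fm <- father_model_table(coh)
  expect_equal(nrow(fm), 4L)
  for (mdl in c("mean", "variance")) {
    sub <- fm[fm$model == mdl, ]
    expect_equal(sub$p_adj, bh_adjust(sub$p))
  }
})
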