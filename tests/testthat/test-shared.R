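test_that("shared effect identity reproduces the worked example and clamps", {
  se <- shared_effect(16, 11, 6, 11)
  expect_equal(se$shared, 5)
  expect_equal(se$union, 22)
  # symmetry under exchanging the two traits
  se_rev <- shared_effect(11, 16, 11, 6)
  expect_equal(se_rev$shared, se$shared)
  expect_equal(se_rev$union, se$union)
  # independent traits share nothing
  expect_equal(shared_effect(16, 11, 11, 16)$shared, 0)
  # noisy estimates can push shared below zero; clamp at 0
  clamped <- shared_effect(10, 10, 12, 12)
  expect_equal(clamped$shared, 0)
  expect_equal(clamped$union, 22)
  expect_error(shared_effect(-1, 5, 2, 2), "non-negative")
})

test_that("proportional apportionment reproduces the three-variable example", {
  ap <- apportion_higher_order(20, 15, 10, 10, 4, 3)
  expect_equal(ap$ac_not_b, 2)
  expect_equal(ap$bc_not_a, 1)
  expect_equal(ap$abc, 2)
  expect_equal(ap$unique_c, 5)
  expect_equal(ap$union_abc, 30)
  # disjoint sets: C keeps its full effect
  ap0 <- apportion_higher_order(20, 15, 10, 0, 0, 0)
  expect_equal(ap0$unique_c, 10)
  expect_equal(ap0$union_abc, 45)
  # A identical to B forces everything into the triple intersection
  ap1 <- apportion_higher_order(12, 12, 10, 12, 4, 4)
  expect_equal(ap1$abc, 4)
  expect_equal(c(ap1$ac_not_b, ap1$bc_not_a), c(0, 0))
  expect_error(apportion_higher_order(5, 5, 5, 6, 1, 1), "must not exceed")
})

test_that("residual effect vanishes for a duplicated trait and survives a null trait", {
  set.seed(23)
  vals <- lapply(1:15, function(i) sample(2:14, sample(2:4, 1), replace = TRUE))
  names(vals) <- paste0("R", 1:15)
  coh <- make_cohort(vals)
  # duplicate the column under another registered personality trait
  df <- tibble::as_tibble(coh)
  df$openness <- df$extraversion
  reg <- default_trait_registry()
  coh2 <- cohort_table(df, reg[reg$trait %in% c("extraversion", "openness"), ])
  r <- residual_effect_size(coh2, "extraversion", "openness",
                            n_runs = 25, n_perm = 200, seed = 12)
  expect_lt(r$residual_pct, 1)
})

test_that("eliminating a zero-effect trait leaves the other trait's effect intact", {
  reg <- default_trait_registry()
  reg2 <- reg[reg$trait %in% c("weight", "height"), ]
  coh <- generate_cohort(cohort_config(n_respondents = 70, registry = reg2,
                                       icc = c(height = 0, weight = 0.5),
                                       missing_rate = 0),
                         seed = 77)$cohort
  null_w <- permutation_null(coh, "weight", n_perm = 300, seed = 13)
  simple_w <- stepwise_effect_size(coh, "weight", null_w, n_runs = 25,
                                   seed = 14)$effect_pct
  r <- residual_effect_size(coh, "height", "weight", n_runs = 25,
                            n_perm = 300, seed = 15)
  expect_lt(abs(r$residual_pct - simple_w), 6)
})

test_that("shared-effect tables are symmetric, clamped and CSV round-trip", {
  reg <- default_trait_registry()
  reg2 <- reg[reg$trait %in% c("weight", "height", "extraversion"), ]
  coh <- generate_cohort(cohort_config(n_respondents = 45, registry = reg2,
                                       icc = c(0.35, 0.35, 0.2),
                                       missing_rate = 0.02),
                         seed = 31)$cohort
  st <- shared_effect_table(coh, n_perm = 150, n_runs = 15, seed = 17)
  expect_s3_class(st, "shared_effect_table")
  expect_equal(st$shared, t(st$shared))
  expect_equal(unname(diag(st$shared)), unname(st$simple))
  off <- st$shared[upper.tri(st$shared)]
  caps <- outer(st$simple, st$simple, pmin)[upper.tri(st$shared)]
  expect_true(all(off >= 0 & off <= caps + 1e-9))

  path <- withr::local_tempfile(fileext = ".csv")
  write_shared_table(st, path)
  back <- read_shared_table(path)
  expect_equal(back$simple, st$simple)
  expect_equal(back$shared, st$shared)
  expect_equal(back$corr[upper.tri(back$corr)], st$corr[upper.tri(st$corr)])
})

test_that("cumulative accumulation reproduces the worked example under its order", {
  st <- mateperm:::new_shared_effect_table(
    c("A", "B", "C"), c(A = 20, B = 15, C = 10),
    matrix(c(20, 10, 4, 10, 15, 3, 4, 3, 10), 3, 3,
           dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  cum <- cumulative_effect(st, order = c("A", "B", "C"))
  expect_equal(cum$unique_contribution, c(20, 5, 5))
  expect_equal(attr(cum, "total_pct"), 30)
  # greedy selection prefers the larger second-step contribution (C: 10-4=6)
  greedy <- cumulative_effect(st)
  expect_equal(greedy$trait[1:2], c("A", "C"))
  expect_gt(attr(greedy, "total_pct"), max(st$simple))
  expect_lt(attr(greedy, "total_pct"), sum(st$simple))
})

test_that("cumulative total equals the simple sum when nothing is shared", {
  simple <- c(A = 8, B = 6, C = 4, D = 2)
  sh <- diag(simple)
  dimnames(sh) <- list(names(simple), names(simple))
  st <- mateperm:::new_shared_effect_table(names(simple), simple, sh)
  cum <- cumulative_effect(st)
  expect_equal(attr(cum, "total_pct"), sum(simple))
  expect_equal(cum$trait, c("A", "B", "C", "D"))
})

test_that("cumulative accumulation matches an independent reimplementation", {
  set.seed(41)
  for (rep in 1:5) {
    k <- 4
    traits <- LETTERS[1:k]
    simple <- stats::setNames(round(runif(k, 2, 20), 1), traits)
    sh <- matrix(0, k, k, dimnames = list(traits, traits))
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        sh[i, j] <- sh[j, i] <- round(runif(1, 0, min(simple[i], simple[j])), 1)
      }
    }
    diag(sh) <- simple
    st <- mateperm:::new_shared_effect_table(traits, simple, sh)
    got <- cumulative_effect(st)
    want <- oracle_cumulative(simple, sh)
    expect_equal(attr(got, "total_pct"), want$total, tolerance = 1e-8)
    expect_equal(got$trait, want$order)
    # input ordering must not matter (selection breaks ties by name)
    perm <- sample(k)
    st2 <- mateperm:::new_shared_effect_table(traits[perm], simple[perm],
                                              sh[perm, perm])
    got2 <- cumulative_effect(st2)
    expect_equal(attr(got2, "total_pct"), attr(got, "total_pct"),
                 tolerance = 1e-8)
  }
})

test_that("inconsistent tables error unless explicitly clamped", {
  traits <- c("A", "B")
  sh <- matrix(c(5, 6, 6, 4), 2, 2, dimnames = list(traits, traits))
  st <- mateperm:::new_shared_effect_table(traits, c(A = 5, B = 4), sh)
  expect_error(cumulative_effect(st), "inconsistent")
  expect_message(cum <- cumulative_effect(st, fix_inconsistent = TRUE),
                 "clamping")
  expect_equal(attr(cum, "total_pct"), 5)  # B fully inside A after clamping
})
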