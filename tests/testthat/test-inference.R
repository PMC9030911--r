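test_that("rerandomization relabels each triplet to one of the six arrangements", {
  r <- toy_roster(outcomes = c(1, 0, 1), arms = c("control", "fear", "social"))
  seen <- character(0)
  for (s in 1:40) {
    out <- rerandomize(r, seed = s)
    expect_equal(sort(as.character(out$arm)), c("control", "fear", "social"))
    seen <- union(seen, paste(out$arm, collapse = ""))
  }
  expect_equal(length(seen), 6) # all six arrangements appear
  # outcomes and missingness travel with the participant
  out <- rerandomize(r, seed = 1)
  expect_identical(out$outcome_wk6, r$outcome_wk6)

  empty <- r[0, ]
  expect_equal(nrow(make_triplets(
    tibble::tibble(id = character(), baseline_consistent = integer(),
                   .propensity = numeric())
  )), 0)
})

test_that("joint relabelings of three triplets are uniform over all 216", {
  r <- toy_roster(outcomes = rep(c(1, 0, 1), 3),
                  arms = rep(c("control", "fear", "social"), 3))
  draws <- 21600
  keys <- vapply(seq_len(draws), function(s) {
    paste(rerandomize(r, seed = s)$permutation_index[c(1, 4, 7)],
          collapse = "-")
  }, character(1))
  counts <- table(keys)
  expect_equal(length(counts), 216)
  gof <- chisq.test(as.vector(counts), p = rep(1 / 216, 216))
  expect_gt(gof$p.value, 0.01)
})

test_that("degenerate statistics give the boundary p-values", {
  # constant outcome: the statistic never moves under relabeling, p = 1
  r <- toy_roster(outcomes = rep(1, 9), arms = rep(c("control", "fear", "social"), 3))
  pt <- permutation_test(r, "social", "control", B = 500, seed = 1)
  expect_equal(pt$p_value, 1)

  # observed statistic beyond every permuted value: p = 0 under plain fraction
  outc <- rep(c(1, 0, 0), 30)
  r2 <- toy_roster(outcomes = outc, arms = rep(c("social", "control", "fear"), 30))
  # social wins all 30 triplets (observed log-OR +Inf); a permuted draw
  # ties only when no triplet sends its adherent to control, probability
  # (2/3)^30 ~ 5e-6, so no exceedance occurs in B = 400 draws
  pt2 <- permutation_test(r2, "social", "control", B = 400, seed = 2)
  expect_equal(pt2$p_value, 0)
  expect_equal(pt2$p_value, pt2$exceedances / pt2$B)
})

test_that("engine p-value matches exhaustive enumeration on five triplets", {
  set.seed(123)
  outc <- rbinom(15, 1, 0.5)
  arms <- as.vector(replicate(5, sample(c("control", "fear", "social"))))
  r <- toy_roster(outcomes = outc, arms = arms)
  for (sided in c("one", "two")) {
    exact <- enumerate_exact_p(r, "social", "control", sided = sided)
    pt <- permutation_test(r, "social", "control", sided = sided,
                           B = 20000, seed = 9)
    mc_se <- sqrt(exact * (1 - exact) / 20000)
    expect_lt(abs(pt$p_value - exact), 3 * mc_se + 1e-9,
              label = paste(sided, "sided"))
  }
})

test_that("missing outcomes are recomputed on the permuted analysis subset", {
  set.seed(5)
  outc <- rbinom(18, 1, 0.5)
  outc[c(2, 7, 13)] <- NA
  arms <- as.vector(replicate(6, sample(c("control", "fear", "social"))))
  r <- toy_roster(outcomes = ifelse(is.na(outc), 0, outc), arms = arms)
  r$outcome_wk6[is.na(outc)] <- NA_integer_
  exact <- enumerate_exact_p(r, "social", "control", sided = "one")
  pt <- permutation_test(r, "social", "control", B = 20000, seed = 31)
  expect_lt(abs(pt$p_value - exact),
            3 * sqrt(exact * (1 - exact) / 20000) + 1e-9)
})

test_that("two-sided p is at least the favorable one-sided p on the same draws", {
  cfg <- trial_config(n_participants = 120, effects = list(social = log(2)),
                      seed = 2)
  tr <- simulate_assigned_trial(cfg, seed = 44)
  p1 <- permutation_test(tr, "social", "control", sided = "one",
                         B = 3000, seed = 7)$p_value
  p2 <- permutation_test(tr, "social", "control", sided = "two",
                         B = 3000, seed = 7)$p_value
  expect_gte(p2, p1)
})

test_that("identical seed and plan give identical results", {
  r <- fixture_roster(shuffle_seed = 1)
  a <- permutation_test(r, "social", "control", B = 1000, seed = 12)
  b <- permutation_test(r, "social", "control", B = 1000, seed = 12)
  expect_identical(a, b)
  # plus-one variant is the documented finite-sample option
  d <- permutation_test(r, "social", "control", B = 1000, seed = 12,
                        p_method = "plus_one")
  expect_equal(d$p_value, (a$exceedances + 1) / (1000 + 1))
})

test_that("one-sided tests are refused for the head-to-head contrast", {
  r <- fixture_roster()
  expect_error(permutation_test(r, "social", "fear", sided = "one",
                                B = 10, seed = 1), "control")
  expect_error(permutation_test(r, "social", "control", B = 10, seed = NULL),
               "seed")
})

test_that("Holm-Bonferroni reproduces the published decision and the step-down rule", {
  # the published one-sided primary-family p-values: nothing survives .05/3
  published <- holm_bonferroni(c(fear = .47, social = .04, head = .12))
  expect_false(any(published$reject))
  expect_equal(published$threshold[published$comparison == "social"], .05 / 3)

  # hand-stepped: thresholds .0167, .025, .05 all pass
  all_in <- holm_bonferroni(c(.001, .02, .04))
  expect_true(all(all_in$reject))

  # step-down stops at the first failure even if later p-values are small
  gap <- holm_bonferroni(c(.30, .001, .026))
  expect_equal(gap$reject, c(FALSE, TRUE, FALSE))

  empty <- holm_bonferroni(numeric(0))
  expect_equal(nrow(empty), 0)
  expect_error(holm_bonferroni(c(0.5, 1.2)), "0, 1")

  # adjusted p-values agree with the standard step-down adjustment
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(1:6, 1))
    expect_equal(holm_bonferroni(p)$p_adjusted, p.adjust(p, "holm"))
    # rejection rule is equivalent to p_adjusted <= alpha
    expect_equal(holm_bonferroni(p, alpha = 0.2)$reject,
                 p.adjust(p, "holm") <= 0.2)
  }
})

two_stratum_toy <- function(outc_cons, outc_inc) {
  arms <- rep(c("control", "fear", "social"), length(outc_cons) / 3)
  cons <- toy_roster(outcomes = outc_cons, arms = arms, baseline = 1L)
  inc <- toy_roster(outcomes = outc_inc, arms = arms, baseline = 0L)
  inc$triplet_id <- inc$triplet_id + max(cons$triplet_id)
  inc$id <- paste0(inc$id, "b")
  dplyr::bind_rows(cons, inc)
}

test_that("effect modification: identical stratum tables give a zero statistic", {
  outc <- c(1, 1, 0, 0, 0, 1, 1, 0, 0, 0, 1, 1)
  r <- two_stratum_toy(outc, outc)
  em <- effect_modification_test(r, "social", "control", B = 200, seed = 3)
  expect_equal(em$observed, 0)
  expect_equal(em$sided, "two")
})

test_that("effect-modification p matches enumeration on a small two-stratum design", {
  # 3 triplets per stratum; each arm sees both outcomes in each stratum
  r <- two_stratum_toy(c(1, 1, 0, 0, 0, 1, 1, 0, 0),
                       c(0, 1, 1, 1, 0, 0, 0, 1, 1))
  exact <- enumerate_exact_p(r, "social", "control", sided = "two",
                             statistic = "log_ror")
  em <- effect_modification_test(r, "social", "control", B = 20000, seed = 6)
  expect_lt(abs(em$p_value - exact),
            3 * sqrt(exact * (1 - exact) / 20000) + 1e-9)
})

test_that("sparse contrasts abort when the statistic is mostly undefined", {
  r <- toy_roster(outcomes = c(1, 1, 1, 1, 1, 0),
                  arms = rep(c("control", "fear", "social"), 2))
  # nearly all permuted tables have an empty non-event cell
  expect_error(
    permutation_test(r, "social", "control", B = 500, seed = 2),
    "undefined|sparse"
  )
})

test_that("tidy and glance summarize a permutation test", {
  r <- fixture_roster(shuffle_seed = 2)
  pt <- permutation_test(r, "social", "control", B = 500, seed = 8)
  td <- tidy(pt)
  expect_equal(td$estimate, exp(pt$observed))
  gl <- glance(pt)
  expect_equal(gl$B, 500)
  expect_s3_class(autoplot(pt), "ggplot")
})
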