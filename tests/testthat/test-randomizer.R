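make_covariate_roster <- function(n, seed) {
  cfg <- trial_config(n_participants = n, covariate_link = 0.4, seed = seed)
  simulate_trial(cfg)
}

test_that("intercept-only propensity model scores everyone at the sample rate", {
  roster <- tibble::tibble(
    id = as.character(1:391),
    baseline_consistent = rep(c(1L, 0L), c(207, 184))
  )
  m <- fit_propensity(roster, covariates = character(0))
  scored <- add_propensity(roster, m)
  expect_true(m$converged)
  expect_equal(unique(round(scored$.propensity, 10)), round(207 / 391, 10))
})

test_that("a constant outcome is flagged as separation with pinned scores", {
  roster <- make_covariate_roster(60, seed = 2)
  roster$baseline_consistent <- 1L
  expect_message(m <- fit_propensity(roster, c("district", "night_freq")),
                 "separation")
  expect_true(m$separation)
  expect_true(all(predict(m, roster) > 0.999))
})

test_that("IRLS coefficients match a coarse-to-fine grid-search oracle", {
  set.seed(31)
  n <- 30
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.3 + 0.8 * x1 - 0.5 * x2))
  roster <- tibble::tibble(
    id = as.character(1:n), age = x1, household_size = x2,
    baseline_consistent = y
  )
  m <- fit_propensity(roster, covariates = c("age", "household_size"))
  oracle <- grid_logistic_oracle(cbind(1, x1, x2), y)
  expect_equal(unname(coef(m$fit)), unname(oracle), tolerance = 1e-4)
})

test_that("scoring never fails on records with missing covariates", {
  roster <- make_covariate_roster(200, seed = 5)
  m <- fit_propensity(roster)
  scores <- predict(m, roster)
  expect_false(anyNA(scores))
  expect_true(all(scores > 0 & scores < 1))
})

test_that("stratification partitions by baseline adherence", {
  roster <- tibble::tibble(
    id = as.character(1:391),
    baseline_consistent = rep(c(1L, 0L), c(207, 184))
  )
  s <- stratify(roster)
  expect_equal(nrow(s$consistent), 207)
  expect_equal(nrow(s$inconsistent), 184)
  expect_equal(nrow(s$consistent) + nrow(s$inconsistent), nrow(roster))

  all_cons <- tibble::tibble(id = "a", baseline_consistent = 1L)
  s2 <- stratify(all_cons)
  expect_equal(nrow(s2$inconsistent), 0)

  set.seed(8)
  r100 <- tibble::tibble(id = as.character(1:100),
                         baseline_consistent = rbinom(100, 1, 0.4))
  s3 <- stratify(r100)
  expect_equal(nrow(s3$consistent), sum(r100$baseline_consistent))
})

test_that("triplets group consecutive score runs of three with a leftover", {
  r7 <- tibble::tibble(
    id = sprintf("x%d", 1:7), baseline_consistent = 1L,
    .propensity = c(0.9, 0.2, 0.5, 0.1, 0.7, 0.4, 0.3)
  )
  t7 <- make_triplets(r7)
  expect_equal(sum(!t7$leftover) / 3, 2)
  expect_equal(sum(t7$leftover), 1)
  expect_equal(t7$id[t7$leftover], "x1") # the highest score stays unmatched
  # adjacency: members of a triplet are consecutive in score order
  ord <- t7[order(t7$.propensity), ]
  expect_equal(rle(ord$triplet_id)$lengths, c(3, 3, 1))

  r3 <- tibble::tibble(id = c("a", "b", "c"), baseline_consistent = 0L,
                       .propensity = c(0.2, 0.1, 0.3))
  t3 <- make_triplets(r3)
  expect_false(any(t3$leftover))
  expect_equal(t3$triplet_rank[t3$id == "b"], 1L)

  expect_equal(nrow(make_triplets(r3[0, ])), 0)
})

test_that("strata of 207 and 184 give 69 + 61 triplets and arm sizes 130/130/131", {
  roster <- tibble::tibble(
    id = sprintf("p%03d", 1:391),
    baseline_consistent = rep(c(1L, 0L), c(207, 184)),
    .propensity = withr::with_seed(1, runif(391))
  )
  trip <- make_triplets(roster)
  expect_equal(sum(!trip$leftover) / 3, 69 + 61)
  expect_equal(sum(trip$leftover), 1)
  assigned <- assign_arms(trip, seed = 4)
  expect_setequal(as.vector(table(assigned$arm)), c(130, 130, 131))
  # stratified balance: identical consistent count per arm
  cons <- table(assigned$arm[assigned$baseline_consistent == 1L])
  expect_equal(as.vector(cons), c(69, 69, 69))
})

test_that("permutation draws map ordered members to arms by the ABC convention", {
  r3 <- tibble::tibble(id = c("x1", "x2", "x3"), baseline_consistent = 1L,
                       .propensity = c(0.1, 0.2, 0.3))
  trip <- make_triplets(r3)
  # find seeds that draw each permutation index; check index 3 is B,A,C
  for (s in 1:25) {
    a <- assign_arms(trip, seed = s)
    expect_equal(dplyr::n_distinct(a$arm), 3) # one member per arm, always
    if (a$permutation_index[1] == 3L) {
      expect_equal(as.character(a$arm), c("fear", "control", "social"))
    }
    if (a$permutation_index[1] == 1L) {
      expect_equal(as.character(a$arm), c("control", "fear", "social"))
    }
  }
})

test_that("assignment requires a seed and is deterministic given one", {
  roster <- make_covariate_roster(60, seed = 7)
  m <- fit_propensity(roster, c("district"))
  trip <- make_triplets(add_propensity(roster, m))
  expect_error(assign_arms(trip, seed = NULL), "seed")
  a1 <- assign_arms(trip, seed = 99)
  a2 <- assign_arms(trip, seed = 99)
  expect_identical(a1$arm, a2$arm)
  a3 <- assign_arms(trip, seed = 100)
  expect_false(identical(a1$arm, a3$arm))
})

test_that("permutation indices are uniform over the six arrangements", {
  # 20,000 triplets drawn under each of 3 seeds: 60,000 seeded draws
  big <- tibble::tibble(
    id = as.character(1:60000), baseline_consistent = 1L,
    .propensity = seq(0, 1, length.out = 60000)
  )
  trip <- make_triplets(big)
  counts <- integer(6)
  for (s in 1:3) {
    a <- assign_arms(trip, seed = 1000 + s)
    counts <- counts + tabulate(a$permutation_index[a$triplet_rank == 1], 6)
  }
  draws <- sum(counts)
  expect_equal(draws, 60000)
  se <- sqrt(draws * (1 / 6) * (5 / 6))
  expect_true(all(abs(counts - draws / 6) < 3 * se))
})

test_that("score adjacency holds after full randomization of a linked trial", {
  roster <- make_covariate_roster(120, seed = 13)
  assigned <- randomize_trial(roster, covariates = c("night_freq", "speeding_freq"),
                              seed = 21)
  for (s in c(0L, 1L)) {
    sub <- assigned[assigned$baseline_consistent == s & !assigned$leftover, ]
    ranges <- tapply(sub$.propensity, sub$triplet_id, range)
    mins <- vapply(ranges, `[`, numeric(1), 1)
    maxs <- vapply(ranges, `[`, numeric(1), 2)
    ord <- order(mins)
    # within-triplet ranges never overlap across triplets
    expect_true(all(maxs[ord][-length(ord)] <= mins[ord][-1] + 1e-12))
  }
})
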