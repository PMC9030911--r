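# Independent oracles used to check the package's fitted values and
# permutation p-values. Deliberately implemented from first principles
# (grid search, exhaustive enumeration, hand-computed sums of squares)
# without reusing any package internals.

# Coarse-to-fine grid search over the binomial log-likelihood surface.
# X includes the intercept column; returns the maximizing coefficients.
grid_logistic_oracle <- function(X, y, n_iter = 9, span = 8, pts = 15) {
  p <- ncol(X)
  center <- rep(0, p)
  width <- rep(span, p)
  loglik <- function(beta_mat) {
    eta <- X %*% beta_mat
    colSums(y * eta - log1p(exp(eta)))
  }
  for (it in seq_len(n_iter)) {
    grids <- lapply(seq_len(p), function(j) {
      seq(center[j] - width[j], center[j] + width[j], length.out = pts)
    })
    beta_mat <- t(as.matrix(do.call(expand.grid, grids)))
    lls <- loglik(beta_mat)
    best_idx <- which.max(lls)
    best <- beta_mat[, best_idx]
    at_edge <- vapply(seq_len(p), function(j) {
      best[j] <= center[j] - width[j] + 1e-12 ||
        best[j] >= center[j] + width[j] - 1e-12
    }, logical(1))
    center <- best
    width <- ifelse(at_edge, width, width * 2.2 / (pts - 1))
  }
  center
}

# The six one-per-arm assignments of three ordered triplet members, in
# the conventional order; written out longhand, independent of the
# package's lookup table. Entry [k, m] is the arm of ordered member m.
oracle_perms <- rbind(
  c("control", "fear", "social"),   # ABC
  c("control", "social", "fear"),   # ACB
  c("fear", "control", "social"),   # BAC
  c("fear", "social", "control"),   # BCA
  c("social", "control", "fear"),   # CAB
  c("social", "fear", "control")    # CBA
)

oracle_log_or <- function(arm, y, exposed, reference, mask = TRUE) {
  keep <- !is.na(y) & mask
  a <- sum(keep & arm == exposed & y == 1)
  b <- sum(keep & arm == exposed & y == 0)
  cc <- sum(keep & arm == reference & y == 1)
  d <- sum(keep & arm == reference & y == 0)
  log(a) + log(d) - log(b) - log(cc)
}

# Exact permutation p-value by exhaustive enumeration of all 6^U equally
# likely joint assignments of U units (leftover units take the first
# position(s) of their draw).
enumerate_exact_p <- function(records, exposed, reference, wave = "wk6",
                              sided = "one", statistic = "log_or") {
  y <- switch(wave, wk6 = records$outcome_wk6, wk3 = records$outcome_wk3,
              baseline = records$baseline_consistent)
  stat_of <- function(arm) {
    if (statistic == "log_or") {
      oracle_log_or(arm, y, exposed, reference)
    } else { # log ratio of odds ratios between baseline strata
      oracle_log_or(arm, y, exposed, reference,
                    records$baseline_consistent == 1) -
        oracle_log_or(arm, y, exposed, reference,
                      records$baseline_consistent == 0)
    }
  }
  units <- split(seq_len(nrow(records))[order(records$triplet_rank)],
                 records$triplet_id[order(records$triplet_rank)])
  U <- length(units)
  stopifnot(6^U <= 5e5)
  obs <- stat_of(as.character(records$arm))
  draws <- as.matrix(expand.grid(rep(list(1:6), U)))
  stats <- apply(draws, 1, function(ks) {
    arm <- character(nrow(records))
    for (u in seq_len(U)) {
      rows <- units[[u]]
      arm[rows] <- oracle_perms[ks[u], seq_along(rows)]
    }
    stat_of(arm)
  })
  if (sided == "one") {
    mean(stats >= obs | is.nan(stats))
  } else {
    mean(abs(stats) >= abs(obs) | is.nan(stats))
  }
}

# Minimal hand-built roster: one stratum label per participant, arms
# already assigned one-per-triplet, outcomes supplied directly.
toy_roster <- function(outcomes, arms, baseline = 1L) {
  n <- length(outcomes)
  stopifnot(n %% 3 == 0, length(arms) == n)
  tibble::tibble(
    id = sprintf("T%02d", seq_len(n)),
    baseline_consistent = rep_len(as.integer(baseline), n),
    arm = factor(arms, levels = c("control", "fear", "social")),
    outcome_wk3 = NA_integer_,
    outcome_wk6 = as.integer(outcomes),
    triplet_id = rep(seq_len(n / 3), each = 3),
    triplet_rank = rep(1:3, n / 3),
    leftover = FALSE
  )
}
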