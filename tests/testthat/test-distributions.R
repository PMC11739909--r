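test_that("hypergeometric expected differences equal brute-force enumeration", {
  cases <- expand.grid(n1 = 2:6, n2 = 2:6, total = 0:6)
  cases <- cases[cases$n1 + cases$n2 <= 12 &
                   cases$total <= cases$n1 + cases$n2, ]
  for (i in seq_len(nrow(cases))) {
    n1 <- cases$n1[i]; n2 <- cases$n2[i]; total <- cases$total[i]
    ls <- data.frame(trial_id = "t", variable = "v", level = "l",
                     c1 = 0, c2 = 0, total = total, n1 = n1, n2 = n2)
    got <- expected_diff_distribution(ls, "hypergeometric_exact")
    ref <- brute_force_diff(total, n1, n2)
    full <- numeric(n1 + n2 + 1)
    full[seq_along(got)] <- got
    expect_equal(full, ref, tolerance = 1e-12)
  }
})

test_that("small worked cases of the expected-difference law hold", {
  ls <- function(total, n1, n2)
    data.frame(trial_id = "t", variable = "v", level = "l", c1 = 0,
               c2 = 0, total = total, n1 = n1, n2 = n2)
  # N1 = N2 = 2, T = 2: allocations give d = 0 w.p. 2/3, d = 2 w.p. 1/3
  e <- expected_diff_distribution(ls(2, 2, 2), "hypergeometric_exact")
  expect_equal(unname(e[c("0", "2")]), c(2 / 3, 1 / 3))
  # T = 0 is a point mass at d = 0
  expect_equal(unname(expected_diff_distribution(
    ls(0, 5, 5), "hypergeometric_exact")["0"]), 1)
  expect_warning(expected_diff_distribution(ls(30, 5, 5)), "skipped")
})

test_that("binomial monte-carlo converges to the exact law", {
  set.seed(5)
  ls <- do.call(rbind, lapply(1:20, function(i) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    data.frame(trial_id = paste0("t", i), variable = "v", level = "l",
               c1 = 0, c2 = 0, total = sample(0:(n1 + n2), 1),
               n1 = n1, n2 = n2)
  }))
  n_sims <- 10000
  mc <- expected_diff_distribution(ls, "binomial_mc", n_sims = n_sims,
                                   seed = 8)
  # analytic oracle: P(|X1 - X2| = d) by direct convolution of the two
  # independent binomials with the pooled proportion
  max_d <- max(ls$n1 + ls$n2)
  exact <- numeric(max_d + 1)
  for (i in seq_len(nrow(ls))) {
    p <- ls$total[i] / (ls$n1[i] + ls$n2[i])
    for (x1 in 0:ls$n1[i]) for (x2 in 0:ls$n2[i]) {
      d <- abs(x1 - x2)
      exact[d + 1] <- exact[d + 1] +
        dbinom(x1, ls$n1[i], p) * dbinom(x2, ls$n2[i], p)
    }
  }
  a <- numeric(max_d + 1)
  a[seq_along(mc)] <- mc
  # per-bin MC error: sum over levels of bernoulli variances, bounded by
  # the aggregated expected mass
  tol <- 3 * sqrt(pmax(exact, 1e-3) / n_sims) + 1e-9
  expect_true(all(abs(a - exact) <= tol))
  expect_equal(sum(a), nrow(ls), tolerance = 1e-9)
})

test_that("dropping a redundant level is uniform and seed-stable", {
  v <- make_var(matrix(1:8, 4), name = "stage")
  kept <- with(list(), {
    set.seed(3)
    drop_redundant_level(v)
  })
  expect_equal(nrow(kept$counts), 3)
  set.seed(3)
  again <- drop_redundant_level(v)
  expect_equal(kept$levels, again$levels)

  v2 <- make_var(matrix(c(12, 8, 11, 9), 2), name = "gender")
  set.seed(4)
  expect_equal(nrow(drop_redundant_level(v2)$counts), 1)

  v1 <- cat_variable("only", matrix(c(3L, 4L), 1))
  expect_equal(nrow(drop_redundant_level(v1)$counts), 1)
  expect_match(attr(drop_redundant_level(v1), "note"), "single-level")
})

test_that("observed differences tally the retained levels of two-arm trials", {
  tr <- trial_record("t1", c(15L, 15L), list(
    cat_variable("radiculopathy", matrix(c(6L, 9L, 7L, 8L), 2),
                 levels = c("yes", "no"))))
  tr3 <- trial_record("t3", c(5L, 5L, 5L), list(
    cat_variable("x", matrix(c(2L, 3L, 2L, 3L, 2L, 3L), 2))))
  obs <- observed_diff_histogram(list(tr, tr3), seed = 2)
  expect_equal(obs$n_trials, 1)       # the 3-arm trial is excluded
  expect_equal(sum(obs$counts), 1)    # one retained level
  expect_equal(unname(obs$counts["1"]), 1)  # |6-7| = |9-8| = 1 either way

  # mismatched sums are excluded by default, included on request
  bad <- trial_record("t2", c(15L, 15L), list(
    cat_variable("v", matrix(c(6L, 7L, 7L, 8L), 2))))
  expect_equal(sum(observed_diff_histogram(list(bad), seed = 1)$counts), 0)
  expect_equal(sum(observed_diff_histogram(
    list(bad), seed = 1, include_mismatched_sums = TRUE)$counts), 1)
})

test_that("honest two-arm data shows no systematic difference excess", {
  g <- honest_dataset()
  dd <- freq_diff_distribution(g$trials, seed = 77)
  d <- dd$distribution
  # multiplicity-aware per-bin band (about 30 support points checked)
  chk <- d[d$expected >= 5, ]
  expect_true(all(abs(chk$excess) <= 3.5 * sqrt(chk$expected)))
  expect_equal(sum(d$observed), sum(d$expected), tolerance = 1e-6)
})

test_that("injected over-similarity surfaces as excess at small differences", {
  inj <- injected_dataset()
  dd <- freq_diff_distribution(inj$trials, seed = 78)
  d <- dd$distribution
  excess_small <- sum(d$excess[d$d <= 1])
  expect_gt(excess_small, 0)

  # quantitative recovery: every retained level of an injected variable
  # lands at d <= 1 by construction, so the predicted excess is
  # sum over injected levels of (1 - P_null(d <= 1))
  ls <- observed_diff_histogram(inj$trials, seed = 78)$level_set
  led <- inj$ledger[inj$ledger$anomaly == "over_similar", ]
  key <- paste(ls$trial_id, ls$variable)
  is_inj <- key %in% paste(led$trial_id, led$variable)
  p_small <- vapply(seq_len(nrow(ls)), function(i) {
    pr <- 0
    for (dd_ in 0:1)
      pr <- pr + trialscan:::hypergeom_diff_probs(
        ls$total[i], ls$n1[i], ls$n2[i], dd_)
    min(pr, 1)
  }, numeric(1))
  predicted <- sum(1 - p_small[is_inj])
  sigma <- sqrt(sum(p_small[!is_inj] * (1 - p_small[!is_inj])))
  expect_gt(predicted, 0)
  expect_lt(abs(excess_small - predicted), 3 * sigma)
})

test_that("null dataset simulation preserves margins in expectation", {
  tr <- clean_trial()
  sims <- simulate_null_datasets(list(tr), n_sims = 300, seed = 12)
  expect_length(sims, 300)
  tot <- rowMeans(vapply(sims, function(s)
    rowSums(s[[1]]$variables[[1]]$counts), numeric(2)))
  p_pool <- rowSums(tr$variables[[1]]$counts) / 40
  expect_equal(tot, 40 * p_pool, tolerance = 0.4)
  # group sizes stay fixed
  for (s in sims[1:5])
    expect_equal(unname(colSums(s[[1]]$variables[[1]]$counts)),
                 c(20, 20))
  # a degenerate pooled proportion of 1 reproduces the group sizes
  deg <- trial_record("d", c(4L, 6L), list(
    cat_variable("all", matrix(c(4L, 0L, 6L, 0L), 2))))
  sd_ <- simulate_null_datasets(list(deg), n_sims = 5, seed = 3)
  for (s in sd_)
    expect_equal(unname(s[[1]]$variables[[1]]$counts[1, ]), c(4L, 6L))
})

test_that("gof comparison behaves at its fixed points", {
  per_sim <- matrix(rep(0.1, 10), nrow = 30, ncol = 10, byrow = TRUE)
  obs <- rep(10, 10)
  g <- gof_compare(obs, per_sim)
  expect_equal(g$statistic, 0)
  expect_equal(g$p_mc, 1)

  off <- c(rep(0, 9), 100)
  g2 <- gof_compare(off, per_sim +
                      matrix(rnorm(300, 0, 1e-3), 30, 10))
  expect_lt(g2$p_mc, 0.05)

  # statistic invariant to bin order (same permutation on both inputs)
  set.seed(9)
  per <- matrix(runif(200, 0.05, 0.15), 20, 10)
  per <- per / rowSums(per)
  ob <- rmultinom(1, 200, colMeans(per))[, 1]
  perm <- sample(10)
  expect_equal(gof_compare(ob, per)$statistic,
               gof_compare(ob[perm], per[, perm])$statistic)
})

test_that("p-value distributions are well-formed and policy-sensitive", {
  cfg <- generator_config(n_trials = 40, group_size_range = c(8, 20),
                          seed = 303)
  g <- generate_trials(cfg)
  fis <- empirical_p_distribution(g$trials, "fisher_sparse_2x2",
                                  n_sims = 25, seed = 5)
  mid <- empirical_p_distribution(g$trials, "midp_sparse_2x2",
                                  n_sims = 25, seed = 5)
  expect_equal(sum(fis$distribution$observed), 1, tolerance = 1e-9)
  expect_equal(sum(fis$distribution$expected), 1, tolerance = 1e-9)
  expect_true(all(fis$distribution$observed >= 0 &
                    fis$distribution$observed <= 1))
  # Fisher's conservatism piles exact-test p-values of sparse tables
  # into the top decile; mid-p pulls them down
  top <- nrow(fis$distribution)
  expect_gt(fis$distribution$observed[top], mid$distribution$observed[top])
  expect_error(empirical_p_distribution(g$trials, "no_such_policy"),
               "unknown test policy")
})

test_that("honest non-sparse chi-square p-values look uniform", {
  g <- honest_dataset()
  pd <- empirical_p_distribution(g$trials, "chisq_nonsparse",
                                 n_sims = 40, seed = 6)
  expect_gt(pd$gof$p_mc, 0.01)
  expect_lt(max(abs(pd$distribution$observed - 0.1)), 0.05)
})

test_that("single-study view reflects that trial's p-values", {
  tr <- clean_trial()
  sp <- study_p_distribution(tr, test = "midp", n_sims = 30, seed = 4)
  expect_equal(sp$n_variables, 2)
  expect_equal(sum(sp$distribution$observed), 1, tolerance = 1e-9)
  one <- trial_record("solo", c(10L, 10L), list(
    cat_variable("v", matrix(c(5L, 5L, 5L, 5L), 2))))
  sp1 <- study_p_distribution(one, test = "fisher", n_sims = 20, seed = 4)
  expect_equal(sum(sp1$distribution$observed == 1), 1)  # one-bar histogram
})
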