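test_that("generation is byte-reproducible from config + seed", {
  cfg <- generator_config(n_trials = 12, seed = 55)
  a <- generate_trials(cfg)
  b <- generate_trials(cfg)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_canonical(a$trials, f1)
  write_canonical(b$trials, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(a$ledger, b$ledger)
  c_ <- generate_trials(generator_config(n_trials = 12, seed = 56))
  expect_false(identical(readLines(f1),
                         {write_canonical(c_$trials, f2); readLines(f2)}))
})

test_that("the config is validated and readable from YAML", {
  expect_error(generator_config(n_trials = 5), "seed")
  expect_error(generator_config(seed = 1,
                                anomaly_rates = c(corrupt_p = 1.5)),
               "rates")
  expect_error(generator_config(seed = 1, group_size_range = c(1, 5)),
               "group sizes")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_trials: 7", "seed: 99",
               "anomaly_rates:", "  sum_error: 0.5"), f)
  cfg <- read_generator_config(f)
  expect_equal(cfg$n_trials, 7)
  expect_equal(unname(cfg$anomaly_rates["sum_error"]), 0.5)
  g <- generate_trials(cfg)
  expect_length(g$trials, 7)
})

test_that("honest generation satisfies the downstream honesty invariants", {
  g <- honest_dataset()
  expect_equal(nrow(g$ledger), 0)
  # every column of counts sums to its arm size
  for (tr in g$trials[1:30])
    for (v in tr$variables)
      expect_equal(unname(colSums(v$counts)), as.numeric(tr$group_sizes))
  # reported p-values are strings with recoverable precision
  vars <- unlist(lapply(g$trials, trial_variables), recursive = FALSE)
  rp <- Filter(Negate(is.null), lapply(vars, `[[`, "reported_p"))
  expect_gt(length(rp), 300)
  expect_true(all(vapply(rp, `[[`, "", "kind") == "numeric"))
  expect_true(all(vapply(rp, `[[`, 1L, "decimals") >= 2))
})

test_that("sum-error injection is ledger-exact at the configured rate", {
  inj <- injected_dataset()
  led <- inj$ledger[inj$ledger$anomaly == "sum_error", ]
  n_vars <- dataset_summary(inj$trials)$n_variables_total
  # binomial expectation at rate 0.05
  expect_lt(abs(nrow(led) - 0.05 * n_vars),
            3 * sqrt(n_vars * 0.05 * 0.95) + 1)
  checks <- check_sums_all(inj$trials)
  flagged <- checks[checks$scope == "overall" & checks$flag != "ok", ]
  expect_setequal(paste(flagged$trial_id, flagged$variable),
                  paste(led$trial_id, led$variable))
})

test_that("corrupted p-values are exactly the unmatched ones", {
  inj <- injected_dataset()
  led <- inj$ledger
  corr <- led[led$anomaly == "corrupt_p", ]
  touched_counts <- paste(
    led$trial_id[led$anomaly %in% c("sum_error", "over_similar")],
    led$variable[led$anomaly %in% c("sum_error", "over_similar")])
  m <- match_reported_all(inj$trials, mc_n_sims = 1000)
  # score on variables whose counts were not altered by other anomalies,
  # mirroring the practice of analysing sum-consistent variables apart
  key <- paste(m$trial_id, m$variable)
  clean <- m[!(key %in% touched_counts), , drop = FALSE]
  ck <- paste(clean$trial_id, clean$variable)
  expect_setequal(ck[!clean$matched],
                  intersect(ck, paste(corr$trial_id, corr$variable)))
  n_expected <- sum(paste(corr$trial_id, corr$variable) %in% ck)
  expect_lt(abs(sum(!clean$matched) - n_expected), 1e-9)
})

test_that("each injector modifies only what it claims", {
  set.seed(8)
  base <- generate_trials(generator_config(n_trials = 15, seed = 77,
                                           reported_p_rate = 1))
  # wrong_test: a sparse 2x2 reported via fisher no longer matches chisq
  wt <- inject_anomaly(base$trials, "wrong_test", rate = 1)
  expect_gt(nrow(wt$ledger), 0)
  m <- match_reported_all(wt$trials, mc_n_sims = 500)
  # the swap reports fisher where chi-square was the convention; it only
  # changes 2x2 tables (larger tables already carried the pearson p)
  m22 <- m[m$table_shape == "2x2" & m$matched, , drop = FALSE]
  hit_fisher <- vapply(strsplit(m22$matching_tests, ","), function(t)
    any(t %in% c("fisher", "fisher_mc")), logical(1))
  expect_gt(mean(hit_fisher), 0.9)

  th <- inject_anomaly(base$trials, "threshold_p", rate = 1)
  vars <- unlist(lapply(th$trials, trial_variables), recursive = FALSE)
  rp <- Filter(Negate(is.null), lapply(vars, `[[`, "reported_p"))
  expect_true(all(vapply(rp, `[[`, "", "kind") == "threshold"))

  ov <- inject_anomaly(base$trials, "over_similar", rate = 1)
  two_arm_equal <- vapply(base$trials, function(t)
    length(t$group_sizes) == 2 && t$group_sizes[1] == t$group_sizes[2],
    logical(1))
  for (i in which(two_arm_equal)) {
    for (v in ov$trials[[i]]$variables) {
      expect_true(all(abs(v$counts[, 1] - v$counts[, 2]) <= 1))
    }
  }
  expect_error(inject_anomaly(base$trials, "nonsense"), "unknown anomaly")
})

test_that("written datasets and ground truth land on disk together", {
  out <- withr::local_tempdir()
  cfg <- generator_config(n_trials = 6, seed = 3,
                          anomaly_rates = c(sum_error = 0.3))
  res <- run_simulate(cfg, out)
  expect_true(file.exists(file.path(out, "trials.csv")))
  expect_true(file.exists(file.path(out, "ground_truth.csv")))
  gt <- read.csv(file.path(out, "ground_truth.csv"))
  expect_equal(nrow(gt), nrow(res$ledger))
  back <- load_canonical(file.path(out, "trials.csv"))
  expect_length(back, 6)
})
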