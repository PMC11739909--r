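test_that("expected cells follow row*col/N and drive the sparse rules", {
  ec <- expected_cells(matrix(c(8, 4, 7, 5), 2))
  expect_equal(ec$E, matrix(c(7.5, 4.5, 7.5, 4.5), 2))
  expect_equal(ec$min_expected, 4.5)

  expect_equal(expected_cells(matrix(c(5, 5, 5, 5), 2))$E,
               matrix(5, 2, 2))
  expect_equal(expected_cells(matrix(c(1, 9, 1, 9), 2))$min_expected, 1)

  expect_equal(classify_sparse(matrix(c(8, 4, 7, 5), 2))$status, "sparse")
  expect_equal(classify_sparse(matrix(50, 2, 2))$status, "not_sparse")
  # 3x2 with a thin top row: 2/6 = 33% of cells below 5
  s <- classify_sparse(matrix(c(1, 10, 10, 1, 10, 10), 3))
  expect_equal(s$status, "sparse")
  expect_equal(s$table_shape, "rxc")
})

test_that("pearson and continuity-corrected chi-square match hand values", {
  r <- pearson_chi_square(matrix(c(8, 4, 7, 5), 2))
  expect_equal(r$statistic, 16 / 90, tolerance = 1e-10)
  expect_equal(r$p, pchisq(16 / 90, 1, lower.tail = FALSE))

  expect_equal(pearson_chi_square(matrix(5, 2, 2))$statistic, 0)
  expect_equal(pearson_chi_square(matrix(5, 2, 2))$p, 1)
  expect_lt(pearson_chi_square(matrix(c(20, 0, 0, 20), 2))$p, 1e-8)

  # |O - E| = 0.5 in every cell, so the Yates statistic collapses to 0
  y <- chi_square_continuity(matrix(c(8, 4, 7, 5), 2))
  expect_equal(y$statistic, 0)
  expect_equal(y$p, 1)
  expect_lt(chi_square_continuity(matrix(c(10, 0, 0, 10), 2))$p, 0.001)
  expect_false(chi_square_continuity(matrix(1, 3, 2))$applicable)
  expect_false(pearson_chi_square(matrix(c(0, 0, 3, 4), 2))$applicable)
})

test_that("exact 2x2 Fisher and mid-p agree with enumeration", {
  # pmf over tables with margins (2,2)x(2,2) is {1/6, 4/6, 1/6}
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p, 1 / 3)
  expect_equal(midp_2x2(matrix(c(2, 0, 0, 2), 2))$p, 1 / 6)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p, 1)
  expect_lt(midp_2x2(matrix(c(5, 5, 5, 5), 2))$p, 1)
  # degenerate margins: a single attainable table
  expect_equal(fisher_exact_2x2(matrix(c(0, 10, 0, 10), 2))$p, 1)
})

test_that("fisher matches the reference implementation across random tables", {
  set.seed(4)
  for (i in 1:200) {
    m <- matrix(rpois(4, 6), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact_2x2(m)$p, fisher.test(m)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("mid-p never exceeds fisher on any 2x2 table up to N = 20", {
  # exhaustive sweep by margins: every table appears once per its
  # (row margins, col margin) support point; the acceptance suite
  # extends the same sweep to N = 30
  for (N in 1:20) {
    for (r1 in 0:N) {
      r2 <- N - r1
      for (c1 in 0:N) {
        support <- max(0, c1 - r2):min(r1, c1)
        for (a in support) {
          tab <- matrix(c(a, c1 - a, r1 - a, r2 - (c1 - a)), 2)
          f <- fisher_exact_2x2(tab)$p
          m <- midp_2x2(tab)$p
          if (m > f + 1e-12)
            fail(sprintf("mid-p %g > fisher %g for table (%s)",
                         m, f, paste(tab, collapse = ",")))
        }
      }
    }
  }
  succeed()
})

test_that("monte-carlo fisher tracks the exact enumeration on small tables", {
  # all 2x3 tables with N <= 6 and positive margins, plus 3x3 spot checks
  n_sims <- 4000
  check <- function(tab, seed) {
    p_ref <- fisher.test(tab)$p.value  # network-algorithm oracle
    p_mc <- fisher_montecarlo_rxc(tab, n_sims = n_sims, seed = seed)$p
    tol <- 3 * sqrt(p_ref * (1 - p_ref) / n_sims) + 2 / n_sims
    expect_lt(abs(p_mc - p_ref), tol + 1e-9)
  }
  cnt <- 0
  for (N in 2:6) {
    tabs <- expand.grid(a = 0:N, b = 0:N, c = 0:N, d = 0:N, e = 0:N)
    tabs$f <- N - rowSums(tabs)
    tabs <- tabs[tabs$f >= 0, ]
    for (i in seq_len(nrow(tabs))) {
      tab <- matrix(as.numeric(tabs[i, ]), 2, byrow = TRUE)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      cnt <- cnt + 1
      if (cnt %% 7 != 0) next  # deterministic thinning for run time
      check(tab, seed = 1000 + i)
    }
  }
  check(matrix(c(4, 0, 0, 0, 4, 0, 0, 0, 4), 3), seed = 99)
  expect_lt(fisher_montecarlo_rxc(matrix(c(4, 0, 0, 0, 4, 0, 0, 0, 4), 3),
                                  n_sims = n_sims, seed = 99)$p, 0.01)
})

test_that("monte-carlo fisher is deterministic under a fixed seed", {
  tab <- matrix(c(3, 1, 2, 2, 1, 4), 3)
  a <- fisher_montecarlo_rxc(tab, n_sims = 1000, seed = 7)
  b <- fisher_montecarlo_rxc(tab, n_sims = 1000, seed = 7)
  expect_identical(a$p, b$p)
  expect_true(a$monte_carlo)
  expect_equal(a$n_sims, 1000L)
  expect_equal(a$seed, 7L)
})

test_that("the G-test tracks pearson asymptotically and handles zeros", {
  expect_equal(g_test(matrix(5, 2, 2))$statistic, 0)
  expect_equal(g_test(matrix(5, 2, 2))$p, 1)
  g <- g_test(matrix(c(8, 4, 7, 5), 2))
  p <- pearson_chi_square(matrix(c(8, 4, 7, 5), 2))
  expect_lt(abs(g$p - p$p), 0.02)
  expect_lt(g_test(matrix(c(20, 0, 0, 20), 2))$p, 0.001)
  expect_false(g_test(matrix(c(0, 0, 3, 4), 2))$applicable)
})

test_that("tests are invariant to level and arm permutations", {
  set.seed(11)
  for (i in 1:20) {
    m <- matrix(rpois(6, 5) + 1, 3)
    pr <- sample(3); pc <- sample(2)
    expect_equal(pearson_chi_square(m)$statistic,
                 pearson_chi_square(m[pr, pc])$statistic)
    expect_equal(g_test(m)$p, g_test(m[pr, pc])$p)
  }
  m2 <- matrix(c(9, 3, 4, 8), 2)
  expect_equal(fisher_exact_2x2(m2)$p, fisher_exact_2x2(m2[2:1, 2:1])$p)
  expect_equal(midp_2x2(m2)$p, midp_2x2(m2[2:1, 2:1])$p)
})

test_that("one-way chi-square covers all-or-nothing variables", {
  # characteristic present in everyone: observed equals expected under
  # allocation-proportional expectation
  r <- one_way_chi_square(matrix(c(15, 0, 15, 0), 2), c(15, 15))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  # all-zero counts with unequal arms, equal-split expectation
  r2 <- one_way_chi_square(matrix(c(0, 0), 1), c(10, 30), "equal")
  expect_equal(r2$statistic, (10 - 20)^2 / 20 + (30 - 20)^2 / 20)
  expect_equal(r2$df, 1)
  # mixed variable: not applicable
  expect_false(
    one_way_chi_square(matrix(c(5, 10, 15, 0), 2), c(15, 15))$applicable)
})

test_that("the battery covers each table type appropriately", {
  gs <- c(20L, 20L)
  b <- run_battery(make_var(matrix(c(12, 8, 11, 9), 2)), gs)
  expect_gte(nrow(b), 5)
  expect_setequal(b$test,
                  c("pearson", "continuity", "fisher", "midp", "gtest"))
  expect_true(all(b$p[b$applicable] >= 0 & b$p[b$applicable] <= 1))

  b4 <- run_battery(make_var(matrix(c(5, 5, 5, 5, 6, 4, 5, 5), 4)), gs,
                    mc_n_sims = 500)
  expect_false("midp" %in% b4$test)
  expect_true("fisher_mc" %in% b4$test)

  deg <- run_battery(make_var(matrix(c(20, 0, 20, 0), 2)), gs)
  expect_setequal(deg$test, c("oneway_proportional", "oneway_equal"))
})

test_that("summary t-tests reproduce hand-computed values", {
  tt <- summary_t_test(10, 0.65, 0.03, 10, 0.66, 0.02)
  expect_equal(tt$statistic[tt$test == "t_pooled"], -0.8771,
               tolerance = 1e-4)
  expect_equal(tt$df[tt$test == "t_pooled"], 18)
  expect_equal(tt$p[tt$test == "t_pooled"], 0.392, tolerance = 1e-3)

  eq <- summary_t_test(12, 5, 1, 12, 5, 1)
  expect_equal(eq$p, c(1, 1))
  # equal n and sd: Welch and pooled coincide
  same <- summary_t_test(9, 2.2, 0.8, 9, 1.9, 0.8)
  expect_equal(same$statistic[1], same$statistic[2])
  expect_equal(same$df[1], same$df[2])
  expect_false(all(summary_t_test(1, 5, 1, 10, 5, 1)$applicable))
})
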