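test_that("numeric matching uses the rounding band of the printed decimals", {
  v <- make_var(matrix(c(8, 4, 7, 5), 2), reported_p = "0.67")
  br <- run_battery(v, c(15, 12))
  m <- match_reported(v, br)
  # pearson p = 0.6733 lies inside the 2-decimal band 0.665-0.675
  expect_true(m$matched)
  expect_true(grepl("pearson", m$matching_tests))

  v3 <- make_var(matrix(c(8, 4, 7, 5), 2), reported_p = "0.673")
  expect_true(match_reported(v3, run_battery(v3, c(15, 12)))$matched)

  v_far <- make_var(matrix(c(8, 4, 7, 5), 2), reported_p = "0.20")
  m_far <- match_reported(v_far, run_battery(v_far, c(15, 12)))
  expect_false(m_far$matched)
  expect_gt(m_far$closest_diff, 0)
})

test_that("threshold reports match via the inequality, distance to boundary", {
  v <- make_var(matrix(c(10, 10, 10, 10), 2), reported_p = ">0.9999")
  m <- match_reported(v, run_battery(v, c(20, 20)))
  expect_true(m$matched)  # fisher p = 1 > 0.9999
  expect_equal(m$closest_diff, 0)

  # no calculated p exceeds the boundary: distance measured to it
  v2 <- make_var(matrix(c(14, 6, 8, 12), 2), reported_p = ">0.9999")
  br2 <- run_battery(v2, c(20, 20))
  m2 <- match_reported(v2, br2)
  expect_false(m2$matched)
  expect_equal(m2$closest_diff, 0.9999 - max(br2$p[br2$applicable]))

  v3 <- make_var(matrix(c(18, 2, 3, 17), 2), reported_p = "<0.001")
  expect_true(match_reported(v3, run_battery(v3, c(20, 20)))$matched)
})

test_that("matching is monotone in printed precision", {
  set.seed(31)
  for (i in 1:40) {
    counts <- matrix(rpois(4, 9) + 1, 2)
    br <- run_battery(make_var(counts), c(30, 30))
    p_true <- br$p[br$test == "pearson"]
    for (d in 4:2) {
      vd <- make_var(counts, reported_p = format_p(p_true, d))
      vc <- make_var(counts, reported_p = format_p(p_true, d - 1))
      md <- match_reported(vd, br)
      mc <- match_reported(vc, br)
      if (md$matched) expect_true(mc$matched)  # coarser never breaks it
    }
  }
})

test_that("closest difference of zero implies a match", {
  v <- make_var(matrix(c(10, 10, 10, 10), 2), reported_p = "1")
  m <- match_reported(v, run_battery(v, c(20, 20)))
  expect_true(m$matched)
  expect_equal(m$closest_diff, 0)
  expect_error(match_reported(make_var(matrix(1, 2, 2),
                                       reported_p = "NS"),
                              run_battery(make_var(matrix(1, 2, 2)),
                                          c(2, 2))),
               "no reported p")
})

test_that("sparse chi-square matches are tallied by table shape", {
  mk <- function(id, counts, p) trial_record(id, colSums(counts), list(
    cat_variable("v", counts, reported_p = p)))
  # sparse 2x2 whose pearson p is reported
  c1 <- matrix(c(8L, 4L, 7L, 5L), 2)
  p1 <- format_p(pearson_chi_square(c1)$p, 2)
  # non-sparse 2x2
  c2 <- matrix(c(30L, 30L, 28L, 32L), 2)
  p2 <- format_p(pearson_chi_square(c2)$p, 2)
  # sparse 3x2 matched via pearson
  c3 <- matrix(c(1L, 10L, 10L, 2L, 9L, 10L), 3)
  p3 <- format_p(pearson_chi_square(c3)$p, 2)
  trials <- list(mk("a", c1, p1), mk("b", c2, p2), mk("c", c3, p3))
  m <- match_reported_all(trials, mc_n_sims = 500)
  expect_true(all(m$matched))
  su <- sparse_usage(m)
  expect_equal(su$n_chisq_matched, 3)
  expect_equal(su$n_sparse_chisq_matched, 2)
  expect_equal(unname(su$by_shape), c(1, 1))
  expect_equal(su$trials_affected, 2)

  none <- sparse_usage(m[!m$sparse, , drop = FALSE])
  expect_equal(none$n_sparse_chisq_matched, 0)
})

match_results_fixture <- function() {
  data.frame(
    variable = c("a", "b", "c"), matched = c(TRUE, FALSE, FALSE),
    matching_tests = c("pearson", "", ""), n_tests = 5,
    closest_test = "pearson", closest_p = c(0.40, 0.45, 0.25),
    closest_diff = c(0, 0.05, 0.15), sparse = FALSE,
    table_shape = "2x2", sparse_match_chisq = FALSE,
    reported_raw = c("0.40", "0.50", "0.40"), reported_kind = "numeric",
    reported_value = c(0.40, 0.50, 0.40), reported_decimals = 2L,
    reason = "", trial_id = "t", stringsAsFactors = FALSE)
}

test_that("the difference cross-tab reproduces constructed diffs", {
  m <- match_results_fixture()
  tab <- matching_table(m)
  expect_equal(sum(tab$table$n), 3)
  got <- tapply(tab$table$n, tab$table$diff_band, sum)
  expect_equal(as.numeric(got[c("0", "0.0-0.1", "0.1-0.2")]), c(1, 1, 1))
  expect_equal(tab$row_totals$n[tab$row_totals$diff_band == "0"], 1)
  expect_equal(unname(tab$nonmatch_diff_summary["median"]), 0.1)
})

test_that("honest synthetic reported p-values all match their test", {
  g <- honest_dataset()
  m <- match_reported_all(g$trials, mc_n_sims = 1000)
  expect_gt(nrow(m), 100)
  expect_equal(mean(m$matched), 1)
  # the generating test is recovered almost always (ties aside)
  hit <- vapply(strsplit(m$matching_tests, ","),
                function(t) "pearson" %in% t, logical(1))
  expect_gte(mean(hit), 0.99)
})
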