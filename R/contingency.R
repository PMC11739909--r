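#' Expected cell counts of a contingency table
#'
#' Under independence, the expected count in cell (l, g) is
#' `row_l * col_g / N`. The summary fields feed the sparse-data
#' classification: expected cells below conventional thresholds make the
#' chi-square approximation unreliable.
#'
#' @param counts Integer matrix of observed counts (levels x arms).
#' @return List with `E` (matrix of expected counts), `min_expected`,
#'   `fraction_below_5` and `any_below_1`.
#' @export
expected_cells <- function(counts) {
  counts <- as.matrix(counts)
  n <- sum(counts)
  E <- if (n > 0) outer(rowSums(counts), colSums(counts)) / n
       else counts * 0
  list(E = E, min_expected = min(E),
       fraction_below_5 = mean(E < 5), any_below_1 = any(E < 1))
}

#' Classify a contingency table as sparse or not
#'
#' Applies the conventional expected-cell rules: a 2x2 table is sparse when
#' any expected cell is below 5; a larger table is sparse when any expected
#' cell is below 1 or more than 20% of cells have expected values below 5.
#' Sparse tables call for an exact test rather than the chi-square
#' approximation.
#'
#' @param counts Integer matrix of observed counts.
#' @return List with `status` (`"sparse"` or `"not_sparse"`), `table_shape`
#'   (`"2x2"` or `"rxc"`) and `rule_triggered` (text, empty if not sparse).
#' @export
classify_sparse <- function(counts) {
  counts <- as.matrix(counts)
  ec <- expected_cells(counts)
  shape <- if (all(dim(counts) == c(2L, 2L))) "2x2" else "rxc"
  if (shape == "2x2") {
    sparse <- ec$min_expected < 5
    rule <- if (sparse) sprintf("min expected %.3g < 5", ec$min_expected)
            else ""
  } else {
    sparse <- ec$any_below_1 || ec$fraction_below_5 > 0.20
    rule <- if (ec$any_below_1) "an expected cell < 1"
            else if (ec$fraction_below_5 > 0.20)
              sprintf("%.0f%% of cells with expected < 5",
                      100 * ec$fraction_below_5)
            else ""
  }
  list(status = if (sparse) "sparse" else "not_sparse",
       table_shape = shape, rule_triggered = rule)
}

# One row of battery output; `statistic`/`df` may be NA for
# pure-enumeration tests, `p` is NA when the test is not applicable.
test_result <- function(test, statistic = NA_real_, df = NA_real_,
                        p = NA_real_, applicable = TRUE,
                        monte_carlo = FALSE, n_sims = NA_integer_,
                        seed = NA_integer_, notes = "") {
  data.frame(test = test, statistic = statistic, df = df, p = p,
             applicable = applicable, monte_carlo = monte_carlo,
             n_sims = as.integer(n_sims), seed = as.integer(seed),
             notes = notes, stringsAsFactors = FALSE)
}

has_zero_margin <- function(counts) {
  any(rowSums(counts) == 0) || any(colSums(counts) == 0)
}

#' Pearson chi-square test of a contingency table
#'
#' Statistic `sum((O - E)^2 / E)` on `(L-1)(G-1)` degrees of freedom, no
#' continuity correction, upper-tail p from the chi-square distribution.
#' A zero row or column margin makes the test inapplicable (reported, not
#' an error).
#'
#' @param counts Integer matrix of observed counts.
#' @return One-row data.frame (`test`, `statistic`, `df`, `p`,
#'   `applicable`, ...).
#' @export
pearson_chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (has_zero_margin(counts) || any(dim(counts) < 2L))
    return(test_result("pearson", applicable = FALSE,
                       notes = "zero margin or single level"))
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  test_result("pearson", statistic = unname(ht$statistic),
              df = unname(ht$parameter), p = ht$p.value)
}

#' Continuity-corrected (Yates) chi-square test for 2x2 tables
#'
#' Statistic `sum(max(|O - E| - 0.5, 0)^2 / E)` on 1 degree of freedom.
#' Only defined for 2x2 tables; anything else is inapplicable.
#'
#' @inheritParams pearson_chi_square
#' @return One-row data.frame.
#' @export
chi_square_continuity <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)))
    return(test_result("continuity", applicable = FALSE,
                       notes = "not a 2x2 table"))
  if (has_zero_margin(counts))
    return(test_result("continuity", applicable = FALSE,
                       notes = "zero margin"))
  ht <- suppressWarnings(stats::chisq.test(counts, correct = TRUE))
  test_result("continuity", statistic = unname(ht$statistic),
              df = unname(ht$parameter), p = ht$p.value)
}

# Hypergeometric enumeration of all 2x2 tables with the observed margins.
# Returns the pmf over the support of cell (1,1), the observed index and
# the relative tie tolerance used by both the Fisher and mid-p orderings.
enumerate_2x2 <- function(counts, eps = 1e-7) {
  a <- counts[1, 1]
  r1 <- sum(counts[1, ]); r2 <- sum(counts[2, ]); c1 <- sum(counts[, 1])
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  list(support = support, probs = probs,
       p_obs = stats::dhyper(a, r1, r2, c1), eps = eps)
}

#' Two-sided Fisher exact test for 2x2 tables
#'
#' Probability-ordering definition: the p-value is the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' whose probability does not exceed the observed table's probability, up
#' to a relative tie tolerance of 1e-7. Degenerate margins leave a single
#' attainable table and give p = 1.
#'
#' @inheritParams pearson_chi_square
#' @return One-row data.frame; `statistic` is NA (pure enumeration).
#' @export
fisher_exact_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)))
    return(test_result("fisher", applicable = FALSE,
                       notes = "not a 2x2 table"))
  en <- enumerate_2x2(counts)
  p <- sum(en$probs[en$probs <= en$p_obs * (1 + en$eps)])
  test_result("fisher", p = min(p, 1))
}

#' Mid-p exact test for 2x2 tables
#'
#' As the two-sided Fisher test, but tables tied in probability with the
#' observed one (within the same relative tolerance, including the observed
#' table itself) contribute only half their probability. This reduces the
#' conservatism of the Fisher test for discrete data; by construction
#' mid-p <= Fisher p on every table.
#'
#' @inheritParams pearson_chi_square
#' @return One-row data.frame.
#' @export
midp_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)))
    return(test_result("midp", applicable = FALSE,
                       notes = "not a 2x2 table"))
  en <- enumerate_2x2(counts)
  lower <- en$probs < en$p_obs * (1 - en$eps)
  tied <- !lower & en$probs <= en$p_obs * (1 + en$eps)
  p <- sum(en$probs[lower]) + 0.5 * sum(en$probs[tied])
  test_result("midp", p = min(p, 1))
}

# log probability of an r x c table under fixed margins (multivariate
# hypergeometric); only the -sum(lgamma(x+1)) term varies across tables
# with the same margins.
log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Monte-Carlo Fisher exact test for r x c tables
#'
#' Exact enumeration of larger-than-2x2 tables can be prohibitively
#' expensive, so the null distribution is sampled: `n_sims` tables with the
#' observed margins are drawn uniformly by Patefield's algorithm
#' ([stats::r2dtable()]), and
#' `p = (1 + #\{tables at most as probable as observed\}) / (n_sims + 1)`,
#' with the same relative tie tolerance as the exact 2x2 test. The seed and
#' simulation count are recorded in the result.
#'
#' @inheritParams pearson_chi_square
#' @param n_sims Number of sampled tables.
#' @param seed Integer seed for the sampling (recorded in the result).
#' @return One-row data.frame with `monte_carlo = TRUE`.
#' @export
fisher_montecarlo_rxc <- function(counts, n_sims = 10000, seed = 20260101) {
  counts <- as.matrix(counts)
  if (all(dim(counts) == c(2L, 2L)))
    return(test_result("fisher_mc", applicable = FALSE,
                       notes = "2x2 table: use fisher_exact_2x2"))
  if (has_zero_margin(counts)) {
    # empty rows/columns carry no information; drop them (a single
    # attainable table remains if everything collapses)
    counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
    if (any(dim(counts) < 2L))
      return(test_result("fisher_mc", p = 1, monte_carlo = TRUE,
                         n_sims = n_sims, seed = seed,
                         notes = "degenerate margins"))
  }
  lp_obs <- log_table_prob(counts)
  sims <- with_seed(seed, stats::r2dtable(n_sims, rowSums(counts),
                                          colSums(counts)))
  lp_sim <- vapply(sims, log_table_prob, numeric(1))
  hits <- sum(lp_sim <= lp_obs + log1p(1e-7))
  test_result("fisher_mc", p = (1 + hits) / (n_sims + 1),
              monte_carlo = TRUE, n_sims = n_sims, seed = seed)
}

#' Likelihood-ratio (G) test of a contingency table
#'
#' Statistic `2 * sum(O * log(O / E))` with the `0 * log(0)` terms defined
#' as 0, on the same degrees of freedom as the Pearson test.
#'
#' @inheritParams pearson_chi_square
#' @return One-row data.frame.
#' @export
g_test <- function(counts) {
  counts <- as.matrix(counts)
  if (has_zero_margin(counts) || any(dim(counts) < 2L))
    return(test_result("gtest", applicable = FALSE,
                       notes = "zero margin or single level"))
  E <- expected_cells(counts)$E
  pos <- counts > 0
  stat <- 2 * sum(counts[pos] * log(counts[pos] / E[pos]))
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  test_result("gtest", statistic = stat, df = df,
              p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# A variable is all-or-nothing when every count is 0 or the full group
# size: the characteristic is present in all or none of each group's
# participants, so no two-way table can be formed.
is_all_or_nothing <- function(counts, group_sizes) {
  full <- matrix(group_sizes, nrow(counts), ncol(counts), byrow = TRUE)
  all(counts == 0L | counts == full)
}

#' One-way chi-square for all-or-nothing variables
#'
#' When a characteristic is present in all or none of the participants of
#' every group, no two-way table exists, but the per-group totals can still
#' be tested as a goodness-of-fit against an expected allocation. Two
#' expectation conventions are offered: proportional to the randomized
#' group sizes (default), or an equal split across groups. When all counts
#' are zero the complement counts (the group sizes themselves) are used.
#'
#' @param counts Level x arm count matrix of an all-or-nothing variable.
#' @param group_sizes Randomized N per arm.
#' @param expectation `"proportional"` or `"equal"`.
#' @return One-row data.frame; inapplicable if any count is strictly
#'   between 0 and its group size.
#' @export
one_way_chi_square <- function(counts, group_sizes,
                               expectation = c("proportional", "equal")) {
  expectation <- match.arg(expectation)
  counts <- as.matrix(counts)
  name <- paste0("oneway_", expectation)
  if (!is_all_or_nothing(counts, group_sizes))
    return(test_result(name, applicable = FALSE,
                       notes = "not an all-or-nothing variable"))
  o <- colSums(counts)
  if (all(o == 0)) o <- group_sizes
  E <- if (expectation == "proportional")
    sum(o) * group_sizes / sum(group_sizes)
  else rep(sum(o) / length(o), length(o))
  stat <- sum((o - E)^2 / E)
  df <- length(o) - 1
  test_result(name, statistic = stat, df = df,
              p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Run the full test battery on one baseline variable
#'
#' Recalculates the baseline p-value with every applicable test in the
#' battery, so that a reported p-value can be compared against all the
#' statistical approaches the original authors might have used. For
#' all-or-nothing variables only the one-way goodness-of-fit tests apply
#' (both expectation conventions are returned); otherwise the default
#' battery is Pearson chi-square, continuity-corrected chi-square (2x2),
#' exact Fisher and mid-p (2x2) or Monte-Carlo Fisher (larger), and the
#' G-test. Every row is tagged with the variable's sparse-data status.
#'
#' @param variable A [cat_variable()] (or a bare count matrix).
#' @param group_sizes Randomized N per arm (required when `variable` is a
#'   matrix; otherwise taken from `trial`).
#' @param battery Character vector choosing tests from
#'   `c("pearson", "continuity", "fisher", "midp", "gtest", "oneway")`.
#' @param mc_n_sims,mc_seed Simulation count and seed for the Monte-Carlo
#'   Fisher test on r x c tables.
#' @return data.frame of test results with columns `test`, `statistic`,
#'   `df`, `p`, `applicable`, `monte_carlo`, `n_sims`, `seed`, `notes`,
#'   plus `sparse`, `table_shape`.
#' @export
run_battery <- function(variable, group_sizes,
                        battery = c("pearson", "continuity", "fisher",
                                    "midp", "gtest", "oneway"),
                        mc_n_sims = 10000, mc_seed = 20260101) {
  counts <- if (inherits(variable, "cat_variable")) variable$counts
            else as.matrix(variable)
  sp <- classify_sparse(counts)
  is_2x2 <- all(dim(counts) == c(2L, 2L))
  res <- list()
  if (is_all_or_nothing(counts, group_sizes)) {
    if ("oneway" %in% battery) {
      res$ow_p <- one_way_chi_square(counts, group_sizes, "proportional")
      res$ow_e <- one_way_chi_square(counts, group_sizes, "equal")
    }
  } else {
    if ("pearson" %in% battery) res$pe <- pearson_chi_square(counts)
    if ("continuity" %in% battery && is_2x2)
      res$cc <- chi_square_continuity(counts)
    if ("fisher" %in% battery)
      res$fi <- if (is_2x2) fisher_exact_2x2(counts)
                else fisher_montecarlo_rxc(counts, mc_n_sims, mc_seed)
    if ("midp" %in% battery && is_2x2) res$mp <- midp_2x2(counts)
    if ("gtest" %in% battery) res$gt <- g_test(counts)
  }
  out <- do.call(rbind, unname(res))
  if (is.null(out)) out <- test_result("none")[0, ]
  out$sparse <- rep(sp$status == "sparse", nrow(out))
  out$table_shape <- rep(sp$table_shape, nrow(out))
  rownames(out) <- NULL
  out
}

#' Two-sample t-tests from summary statistics
#'
#' Recomputes a continuous baseline row's p-value from the printed
#' per-group N, mean and SD, with both the pooled-variance Student t
#' (df = n1 + n2 - 2) and the Welch t (Satterthwaite df). Published tables
#' rarely state which variant was used, so both are returned.
#'
#' @param n1,m1,s1 Group 1 size, mean, SD.
#' @param n2,m2,s2 Group 2 size, mean, SD.
#' @return Two-row data.frame (tests `"t_pooled"` and `"t_welch"`);
#'   inapplicable when a group has n < 2 or SD <= 0.
#' @export
summary_t_test <- function(n1, m1, s1, n2, m2, s2) {
  if (any(is.na(c(n1, m1, s1, n2, m2, s2))) || n1 < 2 || n2 < 2 ||
      s1 <= 0 || s2 <= 0)
    return(rbind(test_result("t_pooled", applicable = FALSE,
                             notes = "n < 2 or sd <= 0"),
                 test_result("t_welch", applicable = FALSE,
                             notes = "n < 2 or sd <= 0")))
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  t_p <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df_p <- n1 + n2 - 2
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  t_w <- (m1 - m2) / sqrt(v1 + v2)
  df_w <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  rbind(
    test_result("t_pooled", statistic = t_p, df = df_p,
                p = 2 * stats::pt(-abs(t_p), df_p)),
    test_result("t_welch", statistic = t_w, df = df_w,
                p = 2 * stats::pt(-abs(t_w), df_w))
  )
}
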