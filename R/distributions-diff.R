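#' Randomly drop one redundant level from a variable
#'
#' In a two-arm trial with known group sizes, one level of every
#' categorical variable is redundant: its counts can be recovered from the
#' totals and the other levels. Tallying every level would double-count, so
#' one uniformly chosen level is excluded before building the
#' frequency-difference distribution. The choice is deterministic under a
#' fixed RNG state.
#'
#' @param variable A [cat_variable()] with at least 2 levels; single-level
#'   variables are returned unchanged with a note.
#' @return The variable with one level removed; attributes `dropped_level`
#'   (label, or NA) and `note`.
#' @export
drop_redundant_level <- function(variable) {
  if (length(variable$levels) < 2L) {
    attr(variable, "dropped_level") <- NA_character_
    attr(variable, "note") <- "single-level variable: nothing to drop"
    return(variable)
  }
  drop <- sample.int(length(variable$levels), 1L)
  out <- cat_variable(
    name = variable$name,
    counts = variable$counts[-drop, , drop = FALSE],
    levels = variable$levels[-drop],
    reported_p = variable$reported_p,
    excluded = variable$excluded, exclude_reason = variable$exclude_reason
  )
  attr(out, "dropped_level") <- variable$levels[drop]
  attr(out, "note") <- ""
  out
}

# Build the retained-level records of all two-arm trials: one row per
# retained level with its two arm counts, level total and group sizes.
# The same record set feeds both the observed histogram and the expected
# distribution so the two are always computed on identical levels.
two_arm_level_set <- function(trials, include_mismatched_sums = FALSE) {
  rows <- list()
  for (tr in trials) {
    if (length(tr$group_sizes) != 2L) next
    for (v in trial_variables(tr)) {
      if (sum(v$counts) == 0L) next
      if (!include_mismatched_sums &&
          sum(v$counts) != sum(tr$group_sizes)) next
      keep <- drop_redundant_level(v)
      cc <- keep$counts
      for (l in seq_len(nrow(cc))) {
        rows[[length(rows) + 1L]] <- data.frame(
          trial_id = tr$trial_id, variable = v$name,
          level = keep$levels[l], c1 = cc[l, 1], c2 = cc[l, 2],
          total = cc[l, 1] + cc[l, 2],
          n1 = tr$group_sizes[1], n2 = tr$group_sizes[2],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(trial_id = character(), variable = character(),
                      level = character(), c1 = integer(), c2 = integer(),
                      total = integer(), n1 = integer(), n2 = integer())
  rownames(out) <- NULL
  out
}

#' Observed between-group frequency differences in two-arm trials
#'
#' For every retained level of every analysable variable in the two-arm
#' trials, tallies the absolute difference `d = |count_g1 - count_g2|`.
#' By default only variables whose frequency sum matches the randomized
#' total are used; `include_mismatched_sums = TRUE` is the sensitivity
#' variant that keeps all variables.
#'
#' @param trials List of [trial_record()] objects.
#' @param seed Integer seed governing the random redundant-level drops.
#' @param include_mismatched_sums Keep variables whose sums disagree with
#'   the randomized totals?
#' @return List: `counts` (named vector over d = 0, 1, ...), `level_set`
#'   (the retained-level records), `n_trials`, `n_variables`, `seed`.
#' @export
observed_diff_histogram <- function(trials, seed = 1,
                                    include_mismatched_sums = FALSE) {
  ls <- with_seed(seed, two_arm_level_set(trials, include_mismatched_sums))
  d <- abs(ls$c1 - ls$c2)
  support <- 0:max(0, d)
  counts <- tabulate(d + 1L, nbins = length(support))
  names(counts) <- support
  list(counts = counts, level_set = ls,
       n_trials = length(unique(ls$trial_id)),
       n_variables = length(unique(paste(ls$trial_id, ls$variable))),
       seed = seed)
}

# P(|X - (T - X)| = d) for X ~ Hypergeom(total T successes among
# n1 + n2 participants, n1 drawn), accumulated over a support vector.
hypergeom_diff_probs <- function(total, n1, n2, support) {
  x <- max(0L, total - n2):min(n1, total)
  px <- stats::dhyper(x, total, n1 + n2 - total, n1)
  d <- abs(2L * x - total)
  out <- numeric(length(support))
  for (i in seq_along(x)) {
    j <- match(d[i], support)
    if (!is.na(j)) out[j] <- out[j] + px[i]
  }
  out
}

#' Expected between-group frequency-difference distribution
#'
#' The expected distribution of `d = |count_g1 - count_g2|` under valid
#' randomization, computed on exactly the retained-level set of an
#' observed histogram. Two null models are available: exact hypergeometric
#' conditioning on each level's total and the group sizes (fixed-margins
#' randomization, the default), or a Monte-Carlo binomial model in which
#' each group's count is drawn independently with the pooled level
#' proportion.
#'
#' @param level_set The `level_set` of an [observed_diff_histogram()].
#' @param method `"hypergeometric_exact"` or `"binomial_mc"`.
#' @param n_sims Simulation count for the binomial MC method.
#' @param seed Seed for the MC method.
#' @return Named numeric vector of expected counts over d = 0, 1, ...;
#'   its sum equals the number of retained levels. Levels with
#'   `total > n1 + n2` (inconsistent data) are skipped with a warning.
#' @export
expected_diff_distribution <- function(level_set,
                                       method = c("hypergeometric_exact",
                                                  "binomial_mc"),
                                       n_sims = 10000, seed = 1) {
  method <- match.arg(method)
  bad <- level_set$total > level_set$n1 + level_set$n2
  if (any(bad)) {
    warning(sum(bad), " level(s) with total exceeding the trial size ",
            "skipped in the expected-difference distribution")
    level_set <- level_set[!bad, , drop = FALSE]
  }
  max_d <- max(c(0L, level_set$n1 + level_set$n2))
  support <- 0:max_d
  if (method == "hypergeometric_exact") {
    expected <- numeric(length(support))
    for (i in seq_len(nrow(level_set)))
      expected <- expected + hypergeom_diff_probs(
        level_set$total[i], level_set$n1[i], level_set$n2[i], support)
  } else {
    expected <- with_seed(seed, {
      acc <- numeric(length(support))
      for (s in seq_len(n_sims)) {
        p <- level_set$total / (level_set$n1 + level_set$n2)
        x1 <- stats::rbinom(nrow(level_set), level_set$n1, p)
        x2 <- stats::rbinom(nrow(level_set), level_set$n2, p)
        d <- abs(x1 - x2)
        acc <- acc + tabulate(pmin(d, max_d) + 1L,
                              nbins = length(support))
      }
      acc / n_sims
    })
  }
  names(expected) <- support
  keep <- max(which(expected > 1e-12), 1L)
  expected[1:keep]
}

#' Observed vs expected frequency-difference distribution
#'
#' Convenience wrapper producing the full comparison: observed counts,
#' expected counts on the same retained-level set, and the per-d excess
#' (observed - expected). An excess at small d (levels more similar across
#' arms than randomization predicts) is the signature of over-similar,
#' possibly fabricated, baseline data.
#'
#' @inheritParams observed_diff_histogram
#' @inheritParams expected_diff_distribution
#' @return List of class `diff_distribution`: data.frame `distribution`
#'   (`d`, `observed`, `expected`, `excess`), plus `method`, `n_sims`,
#'   `seed`, `n_trials`, `n_variables`, `n_levels`.
#' @export
freq_diff_distribution <- function(trials,
                                   method = c("hypergeometric_exact",
                                              "binomial_mc"),
                                   n_sims = 10000, seed = 1,
                                   include_mismatched_sums = FALSE) {
  method <- match.arg(method)
  obs <- observed_diff_histogram(trials, seed = seed,
                                 include_mismatched_sums =
                                   include_mismatched_sums)
  exp_ <- expected_diff_distribution(obs$level_set, method = method,
                                     n_sims = n_sims,
                                     seed = child_seed(seed, "diff_mc"))
  len <- max(length(obs$counts), length(exp_))
  o <- e <- numeric(len)
  o[seq_along(obs$counts)] <- obs$counts
  e[seq_along(exp_)] <- exp_
  structure(
    list(distribution = data.frame(d = seq_len(len) - 1L, observed = o,
                                   expected = e, excess = o - e),
         method = method, n_sims = n_sims, seed = seed,
         n_trials = obs$n_trials, n_variables = obs$n_variables,
         n_levels = nrow(obs$level_set)),
    class = "diff_distribution"
  )
}

#' @export
print.diff_distribution <- function(x, ...) {
  cat("<diff_distribution>", x$n_levels, "retained levels from",
      x$n_variables, "variables in", x$n_trials, "two-arm trials (",
      x$method, ")\n")
  print(utils::head(x$distribution, 10))
  invisible(x)
}
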