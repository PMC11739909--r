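#' Combine a trial's baseline p-values into a studywise p-value
#'
#' The Stouffer combination used in baseline-integrity screening of RCTs:
#' each baseline p-value maps to `z_i = qnorm(p_i)` and the studywise
#' p-value is `pnorm(sum(z_i) / sqrt(k))`. With this direction convention,
#' p-values near 1 (arms more similar than chance predicts) push the
#' studywise p towards 1, and p-values near 0 towards 0. A p of exactly 1
#' has no finite z; the conventional substitute z = 3 (comparable to a p
#' of about 0.998) is used and flagged. A p of exactly 0 is handled
#' symmetrically with z = -3 (also flagged; configurable).
#'
#' @param p_values Numeric vector of baseline p-values in \[0, 1\],
#'   length >= 1.
#' @param z_sub Substitute |z| for p exactly 0 or 1 (default 3).
#' @return List of class `studywise_result`: `k`, `z_values`,
#'   `n_substituted`, `combined_z`, `p` (the studywise p-value).
#' @export
stouffer_combine <- function(p_values, z_sub = 3) {
  if (length(p_values) == 0L)
    stop("stouffer_combine() needs at least one p-value", call. = FALSE)
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  z <- stats::qnorm(p_values)
  subst <- !is.finite(z)
  z[p_values >= 1] <- z_sub
  z[p_values <= 0] <- -z_sub
  k <- length(z)
  combined <- sum(z) / sqrt(k)
  structure(
    list(k = k, z_values = z, substituted = subst,
         n_substituted = sum(subst), combined_z = combined,
         p = stats::pnorm(combined)),
    class = "studywise_result"
  )
}

#' @export
print.studywise_result <- function(x, ...) {
  cat(sprintf("<studywise_result> k = %d, combined z = %.3f, p = %.4f",
              x$k, x$combined_z, x$p))
  if (x$n_substituted)
    cat(sprintf(" (%d z-value(s) substituted)", x$n_substituted))
  cat("\n")
  invisible(x)
}

#' Studywise p-values for every trial in a dataset
#'
#' Computes each trial's baseline p-values under a test policy and
#' combines them with [stouffer_combine()]. All-or-nothing variables
#' (every count 0 or the full group size) have no two-way table; they can
#' be included via their one-way goodness-of-fit p-value (default),
#' excluded, or included with the p = 1 substitution convention.
#'
#' @param trials List of [trial_record()] objects.
#' @param policy Test policy name (see [p_policy()]); default
#'   `"chisq_all"`, chi-square for every variable.
#' @param degenerate How to treat all-or-nothing variables:
#'   `"oneway"` (one-way chi-square p, proportional expectation),
#'   `"exclude"`, or `"substitute"` (enter as p = 1, which triggers the
#'   z-substitution).
#' @param z_sub Substitute |z| for p of exactly 0 or 1.
#' @param mc_n_sims Monte-Carlo Fisher simulation count (sparse r x c
#'   tables under Fisher-using policies).
#' @param seed Seed for Monte-Carlo tests.
#' @return data.frame: `trial_id`, `k`, `combined_z`, `p`,
#'   `n_substituted`, `policy`. Trials with no usable p-value are omitted.
#' @export
studywise_all <- function(trials, policy = "chisq_all",
                          degenerate = c("oneway", "exclude", "substitute"),
                          z_sub = 3, mc_n_sims = 2000, seed = 20260101) {
  degenerate <- match.arg(degenerate)
  pol <- p_policy(policy)
  rows <- list()
  for (tr in trials) {
    ps <- numeric(0)
    for (v in trial_variables(tr)) {
      if (is_all_or_nothing(v$counts, tr$group_sizes)) {
        p <- switch(degenerate,
          oneway = one_way_chi_square(v$counts, tr$group_sizes,
                                      "proportional")$p,
          exclude = NA_real_,
          substitute = 1)
      } else {
        p <- policy_p_value(pol, v$counts, tr$group_sizes,
                            mc_n_sims = mc_n_sims,
                            mc_seed = child_seed(seed, v$name))
      }
      if (!is.na(p)) ps <- c(ps, p)
    }
    if (length(ps) == 0L) next
    sw <- stouffer_combine(ps, z_sub = z_sub)
    rows[[length(rows) + 1L]] <- data.frame(
      trial_id = tr$trial_id, k = sw$k, combined_z = sw$combined_z,
      p = sw$p, n_substituted = sw$n_substituted, policy = policy,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(trial_id = character(), k = integer(),
                      combined_z = numeric(), p = numeric(),
                      n_substituted = integer(), policy = character())
  rownames(out) <- NULL
  out
}

#' Flag trials whose studywise p-value is extreme
#'
#' Studywise p-values below `low` (baseline variables too dissimilar) or
#' above `high` (too similar) are considered potentially inconsistent with
#' valid randomization; `very_high` marks the stronger upper flag. Because
#' few baseline p-values per trial give the combination little power, the
#' summary is also stratified by the number of combined p-values.
#'
#' @param results Output of [studywise_all()].
#' @param thresholds Named vector `c(low=, high=, very_high=)`; defaults
#'   0.05 / 0.95 / 0.99.
#' @return List: `results` (input with a `flag` column:
#'   `"none"`, `"low"`, `"high"`, `"very_high"`), `summary` (flag counts
#'   overall and for trials with k >= 5 and k >= 10).
#' @export
flag_studies <- function(results,
                         thresholds = c(low = 0.05, high = 0.95,
                                        very_high = 0.99)) {
  flag <- rep("none", nrow(results))
  flag[results$p > thresholds[["high"]]] <- "high"
  flag[results$p > thresholds[["very_high"]]] <- "very_high"
  flag[results$p < thresholds[["low"]]] <- "low"
  results$flag <- flag
  strat <- function(d) c(
    n = nrow(d),
    n_low = sum(d$flag == "low"),
    n_high = sum(d$flag == "high"),
    n_very_high = sum(d$flag == "very_high"),
    n_flagged = sum(d$flag != "none")
  )
  list(
    results = results,
    summary = list(
      all = strat(results),
      k_ge_5 = strat(results[results$k >= 5, , drop = FALSE]),
      k_ge_10 = strat(results[results$k >= 10, , drop = FALSE]),
      thresholds = thresholds
    )
  )
}
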