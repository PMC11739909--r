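#' Check level-frequency sums against randomized group sizes
#'
#' For each baseline variable the level frequencies should sum to the
#' number of randomized participants: overall (all levels, all arms vs the
#' trial total) and per arm (column sum vs that arm's N). A sum exceeding
#' the randomized N implies impossible data or extraction/typographical
#' errors; a shortfall implies missing data or errors. Discrepancies are
#' reported, never repaired.
#'
#' @param trial A [trial_record()].
#' @param include_excluded Also check variables flagged as excluded?
#' @return data.frame with one `overall` row plus one `per_group` row per
#'   arm for each variable: `trial_id`, `variable`, `scope`, `group_index`
#'   (NA for overall), `sum_counts`, `reported_n`, `diff`
#'   (`sum_counts - reported_n`), `pct_diff` (100 * |diff| / reported_n)
#'   and `flag` (`"ok"`, `"exceeds"` or `"shortfall"`).
#' @export
check_sums <- function(trial, include_excluded = FALSE) {
  vars <- trial_variables(trial, include_excluded)
  rows <- lapply(vars, function(v) {
    per_group <- data.frame(
      trial_id = trial$trial_id, variable = v$name, scope = "per_group",
      group_index = seq_along(trial$group_sizes),
      sum_counts = unname(colSums(v$counts)),
      reported_n = trial$group_sizes, stringsAsFactors = FALSE
    )
    overall <- data.frame(
      trial_id = trial$trial_id, variable = v$name, scope = "overall",
      group_index = NA_integer_, sum_counts = sum(v$counts),
      reported_n = sum(trial$group_sizes), stringsAsFactors = FALSE
    )
    rbind(overall, per_group)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(trial_id = character(), variable = character(),
                      scope = character(), group_index = integer(),
                      sum_counts = integer(), reported_n = integer(),
                      diff = integer(), pct_diff = numeric(),
                      flag = character()))
  out$diff <- out$sum_counts - out$reported_n
  out$pct_diff <- 100 * abs(out$diff) / out$reported_n
  out$flag <- ifelse(out$diff > 0, "exceeds",
                     ifelse(out$diff < 0, "shortfall", "ok"))
  rownames(out) <- NULL
  out
}

#' Check sums for every trial in a dataset
#'
#' @param trials List of [trial_record()] objects.
#' @inheritParams check_sums
#' @return Row-bound [check_sums()] output.
#' @export
check_sums_all <- function(trials, include_excluded = FALSE) {
  do.call(rbind, lapply(trials, check_sums,
                        include_excluded = include_excluded))
}

#' Summarize sum-check results across a dataset
#'
#' @param checks Output of [check_sums_all()].
#' @param scope Which check rows to summarize; the headline counts use
#'   `"overall"` (sum over all levels and arms), `"per_group"` summarizes
#'   arm-level disagreement.
#' @return List: `n_variables`, counts by flag (`n_ok`, `n_exceeds`,
#'   `n_shortfall`, `n_flagged`), trial tallies (`trials_with_exceeds`,
#'   `trials_with_shortfall`, `trials_with_either`, `trials_with_both`),
#'   a bucketed distribution of |diff| among flagged variables
#'   (`diff_buckets`: `1`, `2-9`, `>=10`) and the percent-difference range
#'   (`pct_diff_range`).
#' @export
summarize_sum_checks <- function(checks, scope = "overall") {
  sub <- checks[checks$scope == scope, , drop = FALSE]
  if (scope == "per_group") {
    # collapse to one worst-case row per variable
    key <- paste(sub$trial_id, sub$variable, sep = "\r")
    keep <- !duplicated(key) | sub$flag != "ok"
    agg <- lapply(split(sub, key), function(d) {
      bad <- d[d$flag != "ok", , drop = FALSE]
      if (nrow(bad)) bad[which.max(abs(bad$diff)), ] else d[1, ]
    })
    sub <- do.call(rbind, agg)
  }
  flagged <- sub[sub$flag != "ok", , drop = FALSE]
  by_trial <- split(sub$flag, sub$trial_id)
  has_ex <- vapply(by_trial, function(f) any(f == "exceeds"), logical(1))
  has_sh <- vapply(by_trial, function(f) any(f == "shortfall"), logical(1))
  absd <- abs(flagged$diff)
  list(
    n_variables = nrow(sub),
    n_ok = sum(sub$flag == "ok"),
    n_exceeds = sum(sub$flag == "exceeds"),
    n_shortfall = sum(sub$flag == "shortfall"),
    n_flagged = nrow(flagged),
    trials_with_exceeds = sum(has_ex),
    trials_with_shortfall = sum(has_sh),
    trials_with_either = sum(has_ex | has_sh),
    trials_with_both = sum(has_ex & has_sh),
    diff_buckets = c(`1` = sum(absd == 1),
                     `2-9` = sum(absd >= 2 & absd < 10),
                     `>=10` = sum(absd >= 10)),
    pct_diff_range = if (nrow(flagged)) range(flagged$pct_diff)
                     else c(NA_real_, NA_real_)
  )
}
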