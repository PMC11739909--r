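#' Match a reported p-value against recalculated battery p-values
#'
#' A numeric reported p printed with d decimal places is consistent with a
#' calculated p when `|p_calc - p_reported| <= 0.5 * 10^(-d)`: the
#' rounding-agnostic band that contains every value rounding to the printed
#' one under any tie-breaking convention. A threshold report (e.g.
#' `">0.9999"`) matches when some calculated p satisfies the inequality;
#' its closest-distance is measured to the stated boundary.
#'
#' @param variable A [cat_variable()] with a parsed reported p of kind
#'   `numeric` or `threshold` (kind `missing` is an error; filter first).
#' @param battery_results Output of [run_battery()] for this variable.
#' @return One-row data.frame: `variable`, `matched`, `matching_tests`
#'   (comma-separated), `n_tests` (applicable tests), `closest_test`,
#'   `closest_p`, `closest_diff`, `sparse`, `table_shape`,
#'   `sparse_match_chisq` (matched via a chi-square test while the table is
#'   sparse), `reported_raw`, `reported_kind`, `reported_value`,
#'   `reported_decimals`, `reason` (non-empty when unmatched for a
#'   structural reason such as no applicable test).
#' @export
match_reported <- function(variable, battery_results) {
  rp <- variable$reported_p
  if (is.null(rp) || rp$kind == "missing")
    stop("variable ", sQuote(variable$name),
         " has no reported p-value to match", call. = FALSE)
  res <- battery_results[battery_results$applicable &
                           !is.na(battery_results$p), , drop = FALSE]
  chisq_tests <- c("pearson", "continuity")
  base <- data.frame(
    variable = variable$name, matched = FALSE, matching_tests = "",
    n_tests = nrow(res), closest_test = NA_character_,
    closest_p = NA_real_, closest_diff = NA_real_,
    sparse = if (nrow(battery_results)) battery_results$sparse[1] else NA,
    table_shape = if (nrow(battery_results))
      battery_results$table_shape[1] else NA_character_,
    sparse_match_chisq = FALSE, reported_raw = rp$raw,
    reported_kind = rp$kind, reported_value = rp$value,
    reported_decimals = rp$decimals, reason = "",
    stringsAsFactors = FALSE
  )
  if (nrow(res) == 0L) {
    base$reason <- "no applicable test"
    return(base)
  }
  if (rp$kind == "numeric") {
    band <- 0.5 * 10^(-rp$decimals) + 1e-12
    diffs <- abs(res$p - rp$value)
    hit <- diffs <= band
  } else {
    diffs <- if (rp$direction == ">") pmax(0, rp$value - res$p)
             else pmax(0, res$p - rp$value)
    hit <- if (rp$direction == ">") res$p > rp$value else res$p < rp$value
  }
  i <- which.min(diffs)
  base$matched <- any(hit)
  base$matching_tests <- paste(res$test[hit], collapse = ",")
  base$closest_test <- res$test[i]
  base$closest_p <- res$p[i]
  base$closest_diff <- diffs[i]
  base$sparse_match_chisq <- base$matched && base$sparse &&
    any(res$test[hit] %in% chisq_tests)
  base
}

#' Match every reported p-value in a dataset
#'
#' Runs the battery and the matcher over all non-excluded variables that
#' carry a reported p-value of kind numeric or threshold. Variables whose
#' reported p is a non-numeric marker (kind missing) are skipped and
#' counted in the attribute `n_skipped_missing`.
#'
#' @param trials List of [trial_record()] objects.
#' @param ... Passed to [run_battery()] (battery selection, MC settings).
#' @return data.frame of [match_reported()] rows plus a `trial_id` column.
#' @export
match_reported_all <- function(trials, ...) {
  rows <- list()
  n_missing <- 0L
  for (tr in trials) {
    for (v in trial_variables(tr)) {
      if (is.null(v$reported_p)) next
      if (v$reported_p$kind == "missing") {
        n_missing <- n_missing + 1L
        next
      }
      br <- run_battery(v, tr$group_sizes, ...)
      row <- match_reported(v, br)
      row$trial_id <- tr$trial_id
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- cbind(match_reported_empty(), trial_id = character(0))
  attr(out, "n_skipped_missing") <- n_missing
  out
}

match_reported_empty <- function() {
  data.frame(variable = character(), matched = logical(),
             matching_tests = character(), n_tests = integer(),
             closest_test = character(), closest_p = numeric(),
             closest_diff = numeric(), sparse = logical(),
             table_shape = character(), sparse_match_chisq = logical(),
             reported_raw = character(), reported_kind = character(),
             reported_value = numeric(), reported_decimals = integer(),
             reason = character(), stringsAsFactors = FALSE)
}

#' Cross-tabulate reported-vs-calculated differences by reported decile
#'
#' The headline view of matching performance: rows are bands of the
#' difference between the reported p and the closest calculated p (`0`
#' meaning matched at printed precision, then `(0,0.1]`, `(0.1,0.2]`, ...),
#' columns are deciles of the reported p-value, cells are variable counts.
#'
#' @param match_results Output of [match_reported_all()] (numeric-kind rows
#'   are tabulated; threshold rows are tabulated by boundary value).
#' @return List: `table` (long data.frame `diff_band` x `reported_decile` x
#'   `n`), `row_totals` (with percentages), and `nonmatch_diff_summary`
#'   (median and IQR of closest differences among unmatched variables).
#' @export
matching_table <- function(match_results) {
  m <- match_results[!is.na(match_results$closest_diff), , drop = FALSE]
  band_edges <- seq(0, 1, by = 0.1)
  band_label <- function(d, matched) {
    ifelse(matched, "0",
           as.character(cut(d, band_edges, include.lowest = FALSE,
                            labels = sprintf("%.1f-%.1f", band_edges[-11],
                                             band_edges[-1]))))
  }
  dec_label <- function(p) {
    i <- pmin(pmax(ceiling(p * 10), 1), 10)
    sprintf("%.1f-%.1f", (i - 1) / 10, i / 10)
  }
  bands <- band_label(m$closest_diff, m$matched)
  decs <- dec_label(m$reported_value)
  lv_b <- c("0", sprintf("%.1f-%.1f", band_edges[-11], band_edges[-1]))
  lv_d <- sprintf("%.1f-%.1f", band_edges[-11], band_edges[-1])
  tab <- as.data.frame(table(
    diff_band = factor(bands, levels = lv_b),
    reported_decile = factor(decs, levels = lv_d)
  ), responseName = "n")
  totals <- tapply(tab$n, tab$diff_band, sum)
  row_totals <- data.frame(
    diff_band = names(totals), n = as.integer(totals),
    pct = round(100 * as.integer(totals) / max(1, sum(totals))),
    stringsAsFactors = FALSE
  )
  nm <- m$closest_diff[!m$matched]
  list(
    table = tab,
    row_totals = row_totals,
    nonmatch_diff_summary = c(
      median = if (length(nm)) stats::median(nm) else NA_real_,
      q1 = if (length(nm)) unname(stats::quantile(nm, 0.25)) else NA_real_,
      q3 = if (length(nm)) unname(stats::quantile(nm, 0.75)) else NA_real_
    )
  )
}

#' Tally chi-square matches on sparse tables
#'
#' Counts how often a reported p-value matched a chi-square calculation
#' even though the table's expected cells were too small for the
#' chi-square approximation to be an appropriate choice.
#'
#' @param match_results Output of [match_reported_all()].
#' @return List: `n_chisq_matched` (variables matched via chi-square),
#'   `n_sparse_chisq_matched` with `pct`, the split `by_shape` (2x2 vs
#'   larger), `n_sparse` (all sparse variables among the matched set's
#'   input) and `trials_affected`.
#' @export
sparse_usage <- function(match_results) {
  m <- match_results
  chisq_matched <- m$matched &
    vapply(strsplit(m$matching_tests, ","), function(t)
      any(t %in% c("pearson", "continuity")), logical(1))
  sparse_chisq <- chisq_matched & m$sparse
  list(
    n_variables = nrow(m),
    n_chisq_matched = sum(chisq_matched),
    n_sparse_chisq_matched = sum(sparse_chisq),
    pct_sparse_of_chisq_matched =
      if (sum(chisq_matched)) 100 * sum(sparse_chisq) / sum(chisq_matched)
      else NA_real_,
    by_shape = c(`2x2` = sum(sparse_chisq & m$table_shape == "2x2"),
                 rxc = sum(sparse_chisq & m$table_shape == "rxc")),
    n_sparse = sum(m$sparse, na.rm = TRUE),
    trials_affected = length(unique(m$trial_id[sparse_chisq]))
  )
}
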