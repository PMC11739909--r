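#' Run the full integrity-screening pipeline on a trial dataset
#'
#' Orchestrates every screening stage over one dataset: frequency-sum
#' checks, battery recalculation and matching of reported p-values,
#' sparse-usage tallies, the observed-vs-expected frequency-difference
#' distribution, empirical p-value distributions under the requested
#' policies, and studywise Stouffer combination with flagging. Writes one
#' CSV per stage plus a consolidated `summary.json` into `out_dir` (when
#' given) and returns the same structure invisibly.
#'
#' A single global seed fans out to deterministic per-stage child seeds,
#' so stages are individually re-runnable yet jointly reproducible.
#'
#' @param input A list of [trial_record()] objects, or a path to a
#'   canonical CSV (`format = "canonical"`) or workbook
#'   (`format = "workbook"`).
#' @param format Input format when `input` is a path.
#' @param policies Policy names for the p-value distribution stage (see
#'   [p_policy()]); `character(0)` skips the stage.
#' @param studywise_policy Policy for the studywise combination.
#' @param n_sims Simulated null datasets per p-distribution.
#' @param mc_n_sims Monte-Carlo Fisher simulation count.
#' @param diff_method Null model for the frequency-difference stage.
#' @param thresholds Studywise flag thresholds, as in [flag_studies()].
#' @param seed Mandatory integer seed.
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param layout Workbook layout (only for `format = "workbook"`).
#' @return Invisibly, a list with `summary` (headline counts), `sum_checks`,
#'   `matches`, `sparse_usage`, `diff_distribution`, `p_distributions`,
#'   `studywise`, `dataset_summary`.
#' @export
run_check <- function(input, format = c("trials", "canonical", "workbook"),
                      policies = "chisq_plus_fisher_sparse",
                      studywise_policy = "chisq_all",
                      n_sims = 100, mc_n_sims = 10000,
                      diff_method = "hypergeometric_exact",
                      thresholds = c(low = 0.05, high = 0.95,
                                     very_high = 0.99),
                      seed, out_dir = NULL,
                      layout = workbook_layout()) {
  if (missing(seed)) stop("run_check() requires a seed", call. = FALSE)
  format <- match.arg(format)
  trials <- switch(format,
    trials = input,
    canonical = load_canonical(input),
    workbook = convert_workbook(input, layout)$trials)
  ds <- dataset_summary(trials)

  sum_checks <- check_sums_all(trials)
  sum_summary <- summarize_sum_checks(sum_checks)

  matches <- match_reported_all(trials, mc_n_sims = mc_n_sims,
                                mc_seed = child_seed(seed, "battery_mc"))
  mt <- matching_table(matches)
  su <- sparse_usage(matches)

  dd <- freq_diff_distribution(trials, method = diff_method,
                               n_sims = mc_n_sims,
                               seed = child_seed(seed, "diff"))

  pdists <- list()
  for (pol in policies) {
    pd <- tryCatch(
      empirical_p_distribution(trials, pol, n_sims = n_sims,
                               seed = child_seed(seed, paste0("pd_", pol)),
                               mc_n_sims = min(mc_n_sims, 2000)),
      error = function(e) NULL)  # a policy may select no variables
    if (!is.null(pd)) pdists[[pol]] <- pd
  }

  sw <- studywise_all(trials, policy = studywise_policy,
                      mc_n_sims = min(mc_n_sims, 2000),
                      seed = child_seed(seed, "studywise"))
  fl <- flag_studies(sw, thresholds)

  d12 <- dd$distribution[dd$distribution$d %in% c(1, 2), , drop = FALSE]
  summary <- list(
    n_trials = ds$n_trials,
    n_variables_total = ds$n_variables_total,
    n_variables_analysed = ds$n_variables_analysed,
    n_excluded = ds$n_excluded,
    sum_checks = sum_summary[c("n_variables", "n_flagged", "n_exceeds",
                               "n_shortfall", "trials_with_either",
                               "trials_with_both")],
    matching = list(
      n_with_reported_p = nrow(matches),
      n_matched = sum(matches$matched),
      n_unmatched = sum(!matches$matched),
      match_rate_pct = if (nrow(matches))
        100 * mean(matches$matched) else NA_real_,
      nonmatch_diff = as.list(mt$nonmatch_diff_summary)
    ),
    sparse_usage = su[c("n_chisq_matched", "n_sparse_chisq_matched",
                        "pct_sparse_of_chisq_matched", "n_sparse",
                        "trials_affected")],
    diff_distribution = list(
      n_trials = dd$n_trials, n_variables = dd$n_variables,
      n_levels = dd$n_levels,
      excess_d1 = if (nrow(d12)) d12$excess[d12$d == 1] else NA_real_,
      excess_d2 = if (nrow(d12)) d12$excess[d12$d == 2] else NA_real_
    ),
    p_distributions = lapply(pdists, function(pd)
      list(n_variables = pd$n_variables, gof_statistic = pd$gof$statistic,
           gof_p_mc = pd$gof$p_mc)),
    studywise = lapply(fl$summary, as.list),  # keep names in JSON
    seed = seed
  )

  out <- list(summary = summary, sum_checks = sum_checks,
              matches = matches, matching_table = mt, sparse_usage = su,
              diff_distribution = dd, p_distributions = pdists,
              studywise = fl, dataset_summary = ds)
  if (!is.null(out_dir)) write_check_outputs(out, out_dir)
  invisible(out)
}

write_check_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$sum_checks, file.path(out_dir, "sum_checks.csv"),
                   row.names = FALSE)
  utils::write.csv(out$matches, file.path(out_dir, "match_results.csv"),
                   row.names = FALSE)
  utils::write.csv(out$matching_table$table,
                   file.path(out_dir, "table1.csv"), row.names = FALSE)
  utils::write.csv(out$diff_distribution$distribution,
                   file.path(out_dir, "diff_distribution.csv"),
                   row.names = FALSE)
  for (pol in names(out$p_distributions))
    utils::write.csv(out$p_distributions[[pol]]$distribution,
                     file.path(out_dir,
                               sprintf("p_distribution_%s.csv", pol)),
                     row.names = FALSE)
  utils::write.csv(out$studywise$results,
                   file.path(out_dir, "studywise.csv"), row.names = FALSE)
  jsonlite::write_json(out$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Generate a synthetic dataset and write it to disk
#'
#' Wrapper around [generate_trials()] that writes the canonical CSV and
#' the ground-truth anomaly ledger.
#'
#' @param config A [generator_config()] or a path to a YAML/JSON config.
#' @param out_dir Output directory.
#' @return Invisibly, the [generate_trials()] result.
#' @export
run_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- read_generator_config(config)
  res <- generate_trials(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_canonical(res$trials, file.path(out_dir, "trials.csv"))
  utils::write.csv(res$ledger, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(res)
}

#' Check a standardized baseline table file and write the report
#'
#' Wrapper around [check_baseline_table()] for pipeline/CLI use.
#'
#' @param path Baseline table TSV/CSV (see [read_baseline_table()]).
#' @param out_dir Output directory for `check_report.csv` and a plain-text
#'   rendering; `NULL` writes nothing.
#' @param ... Passed to [check_p_values()].
#' @return The `baseline_check_report`, invisibly.
#' @export
run_tablecheck <- function(path, out_dir = NULL, ...) {
  rep <- check_baseline_table(path, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    gn <- rep$group_numbers
    gn$section <- "group_numbers"
    pv <- rep$p_values
    pv$section <- "p_values"
    common <- c("section", "variable", "flag", "reason")
    utils::write.csv(rbind(gn[, c(common, "N", "n1", "n2")],
                           cbind(pv[, common],
                                 N = NA, n1 = NA, n2 = NA)),
                     file.path(out_dir, "check_report.csv"),
                     row.names = FALSE)
    txt <- utils::capture.output(print(rep))
    writeLines(txt, file.path(out_dir, "check_report.txt"))
  }
  invisible(rep)
}
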