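#' Read a standardized baseline table
#'
#' The standardized submission format is one TSV/CSV row per baseline-table
#' line with the columns
#' `variable, level, type, total_N, total_M, total_S, g1_N, g1_M, g1_S,
#' g2_N, g2_M, g2_S, p, test` and `type` one of `total` (the group-sizes
#' row of a variable), `cat` (one categorical level; counts are carried in
#' the `*_N` slots) or `cont` (a continuous variable; N/mean/SD triples).
#' The `p` column is the verbatim reported p-value and `test` the declared
#' statistical test (e.g. `chisq`, `t-test`) or `NS` when not stated.
#'
#' @param path Path to a `.tsv`/`.txt` (tab-separated) or `.csv` file.
#' @return data.frame of baseline rows with numeric measurement columns.
#' @export
read_baseline_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "\"")
  required <- c("variable", "level", "type", "total_N", "total_M",
                "total_S", "g1_N", "g1_M", "g1_S", "g2_N", "g2_M", "g2_S",
                "p", "test")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("baseline table ", sQuote(path), " is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(df$type %in% c("total", "cat", "cont")))
    stop("baseline table ", sQuote(path),
         " has a type outside {total, cat, cont}", call. = FALSE)
  num_cols <- c("total_N", "total_M", "total_S", "g1_N", "g1_M", "g1_S",
                "g2_N", "g2_M", "g2_S")
  for (cl in num_cols) {
    x <- trimws(df[[cl]])
    x[!nzchar(x)] <- NA
    df[[cl]] <- suppressWarnings(as.numeric(x))
  }
  df$variable <- trimws(df$variable)
  df$p <- trimws(df$p)
  df$test <- trimws(df$test)
  df
}

#' Check group numbers in a standardized baseline table
#'
#' For each categorical variable, the per-group sums of the level counts
#' must equal the group sizes declared on the variable's `total` row, and
#' the group sizes must sum to the total N; continuous variables are
#' checked for `g1_N + g2_N == total_N`. Missing total rows limit the
#' check to the available scopes (with a note), never abort it.
#'
#' @param table Output of [read_baseline_table()].
#' @return data.frame, one row per variable: `variable`, `N`, `n1`, `n2`
#'   (declared), `flag` (empty when consistent) and `reason` (machine
#'   readable: `group_sum_mismatch`, `total_mismatch`, `missing_total`).
#' @export
check_group_numbers <- function(table) {
  rows <- list()
  for (vn in unique(table$variable)) {
    vs <- table[table$variable == vn, , drop = FALSE]
    tot <- vs[vs$type == "total", , drop = FALSE]
    N <- if (nrow(tot)) tot$total_N[1] else NA_real_
    n1 <- if (nrow(tot)) tot$g1_N[1] else NA_real_
    n2 <- if (nrow(tot)) tot$g2_N[1] else NA_real_
    flag <- ""; reason <- ""
    if (nrow(tot) == 0L) {
      flag <- "no total row: group numbers not checked"
      reason <- "missing_total"
    } else if (any(vs$type == "cat")) {
      lv <- vs[vs$type == "cat", , drop = FALSE]
      bad <- character(0)
      for (g in 1:2) {
        ssum <- sum(lv[[paste0("g", g, "_N")]])
        ng <- c(n1, n2)[g]
        if (!is.na(ng) && any(!is.na(lv[[paste0("g", g, "_N")]])) &&
            abs(ssum - ng) > 1e-9)
          bad <- c(bad, sprintf("group %d levels sum to %g, not %g",
                                g, ssum, ng))
      }
      if (!is.na(N) && !is.na(n1) && !is.na(n2) && n1 + n2 != N)
        bad <- c(bad, sprintf("group sizes %g + %g != total %g",
                              n1, n2, N))
      if (length(bad)) { flag <- paste(bad, collapse = "; ")
                         reason <- "group_sum_mismatch" }
    } else if (any(vs$type == "cont")) {
      cv <- vs[vs$type == "cont", , drop = FALSE][1, ]
      if (!is.na(cv$g1_N) && !is.na(cv$g2_N) && !is.na(N) &&
          cv$g1_N + cv$g2_N != N) {
        flag <- sprintf("group sizes %g + %g != total %g",
                        cv$g1_N, cv$g2_N, N)
        reason <- "total_mismatch"
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      variable = vn, N = N, n1 = n1, n2 = n2, flag = flag,
      reason = reason, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Recalculate and check reported p-values in a standardized baseline table
#'
#' For every variable with a reported p-value: categorical variables are
#' rebuilt into a levels x 2 count table and recalculated with the
#' declared test when one is named (`chisq` maps to the Pearson
#' chi-square) and with the full battery otherwise; continuous variables
#' are recalculated from the printed N/mean/SD with pooled and Welch
#' t-tests, a match with either counting as agreement (the printed table
#' rarely states the variant). Matching is rounding-aware at the printed
#' decimal precision. A sparse warning is attached when a chi-square test
#' is declared on a table whose expected cells are below the
#' recommendation.
#'
#' @param table Output of [read_baseline_table()].
#' @param mc_n_sims,mc_seed Monte-Carlo Fisher settings for sparse r x c
#'   tables reached through the battery fallback.
#' @return data.frame, one row per reported p: `variable`, `reported_p`,
#'   `declared_test`, `recalculated_p` (closest), `recalculated_test`,
#'   `match`, `sparse_warning`, `flag`, `reason` (machine readable:
#'   `p_mismatch`, `sparse_chisq`, `unknown_test`).
#' @export
check_p_values <- function(table, mc_n_sims = 10000, mc_seed = 20260101) {
  rows <- list()
  for (vn in unique(table$variable)) {
    vs <- table[table$variable == vn, , drop = FALSE]
    prow <- vs[nzchar(vs$p) & vs$type != "total", , drop = FALSE]
    if (nrow(prow) == 0L) next
    raw <- unique(prow$p)[1]
    declared <- unique(prow$test[nzchar(prow$test)])
    declared <- if (length(declared)) declared[1] else "NS"
    rp <- parse_reported_p(raw, context = vn)
    if (rp$kind == "missing") next
    reason <- character(0)
    sparse_warning <- FALSE

    if (any(prow$type == "cat")) {
      lv <- prow[prow$type == "cat", , drop = FALSE]
      counts <- as.matrix(cbind(lv$g1_N, lv$g2_N))
      if (any(is.na(counts))) next
      v <- cat_variable(vn, counts, levels = lv$level, reported_p = rp)
      gs <- colSums(counts)
      known <- c(chisq = "pearson", `chi-square` = "pearson",
                 fisher = "fisher", `mid-p` = "midp", midp = "midp")
      dt <- known[tolower(declared)]
      br <- run_battery(v, gs, mc_n_sims = mc_n_sims, mc_seed = mc_seed)
      if (!is.na(dt)) {
        use <- br[br$test %in% c(dt, if (dt == "fisher") "fisher_mc"), ,
                  drop = FALSE]
        if (nrow(use) == 0L || !any(use$applicable)) use <- br
      } else {
        use <- br
        if (!tolower(declared) %in% c("ns", ""))
          reason <- c(reason, "unknown_test")
      }
      m <- match_reported(v, use)
      sparse_warning <- identical(unname(dt), "pearson") && isTRUE(m$sparse)
      if (sparse_warning) reason <- c(reason, "sparse_chisq")
    } else {
      cv <- prow[prow$type == "cont", , drop = FALSE][1, ]
      tt <- summary_t_test(cv$g1_N, cv$g1_M, cv$g1_S,
                           cv$g2_N, cv$g2_M, cv$g2_S)
      v <- list(name = vn, reported_p = rp)
      class(v) <- "cat_variable"
      tt$sparse <- FALSE; tt$table_shape <- "cont"
      m <- match_reported(v, tt)
    }
    if (!m$matched) reason <- c(reason, "p_mismatch")
    flag <- c(
      if (!m$matched)
        sprintf("reported p %s does not match (closest calc %s = %.3f)",
                raw, m$closest_test, m$closest_p),
      if (sparse_warning)
        "warning: expected cell counts below the chi-square recommendation"
    )
    rows[[length(rows) + 1L]] <- data.frame(
      variable = vn, reported_p = raw, declared_test = declared,
      recalculated_p = m$closest_p, recalculated_test = m$closest_test,
      match = m$matched, sparse_warning = sparse_warning,
      flag = paste(flag, collapse = "; "),
      reason = paste(reason, collapse = ","), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(variable = character(), reported_p = character(),
                      declared_test = character(),
                      recalculated_p = numeric(),
                      recalculated_test = character(), match = logical(),
                      sparse_warning = logical(), flag = character(),
                      reason = character())
  rownames(out) <- NULL
  out
}

#' Check a standardized baseline table end to end
#'
#' Runs [check_group_numbers()] and [check_p_values()] on a standardized
#' baseline table and bundles the two sections into a report.
#'
#' @param table A file path or the data.frame from
#'   [read_baseline_table()].
#' @param ... Passed to [check_p_values()].
#' @return Object of class `baseline_check_report` with elements
#'   `group_numbers`, `p_values`, `n_flags`.
#' @export
check_baseline_table <- function(table, ...) {
  if (is.character(table)) table <- read_baseline_table(table)
  gn <- check_group_numbers(table)
  pv <- check_p_values(table, ...)
  structure(
    list(group_numbers = gn, p_values = pv,
         n_flags = sum(nzchar(gn$flag)) + sum(nzchar(pv$flag))),
    class = "baseline_check_report"
  )
}

#' @export
print.baseline_check_report <- function(x, ...) {
  cat("check group numbers\n")
  print(x$group_numbers[, c("variable", "flag", "N", "n1", "n2")],
        row.names = FALSE)
  cat("\ncheck p-values\n")
  if (nrow(x$p_values)) {
    show <- x$p_values[, c("variable", "reported_p", "declared_test",
                           "recalculated_p", "match", "flag")]
    show$recalculated_p <- round(show$recalculated_p, 3)
    print(show, row.names = FALSE)
  } else cat("  (no reported p-values)\n")
  cat("\n", x$n_flags, "flag(s) raised\n")
  invisible(x)
}
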