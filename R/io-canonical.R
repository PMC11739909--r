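#' Read a trial dataset from the canonical long-format CSV
#'
#' The canonical on-disk form is a UTF-8 CSV with one row per
#' (variable, level, group) cell and the header
#' `trial_id,variable,level,group_index,count,group_n,reported_p,excluded,exclude_reason`.
#' `group_index` is 1-based; `reported_p` is the verbatim reported string,
#' repeated on every row of its variable (or empty); `group_n` is the
#' randomized N of that arm and must be constant per (trial, group_index).
#'
#' @param path Path to a canonical CSV file.
#' @return List of [trial_record()] objects, trial and row order preserved.
#' @seealso [write_canonical()]
#' @export
load_canonical <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  required <- c("trial_id", "variable", "level", "group_index", "count",
                "group_n", "reported_p", "excluded", "exclude_reason")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("canonical CSV ", sQuote(path), " is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) return(list())
  rowno <- seq_len(nrow(df)) + 1L  # header is line 1

  int_field <- function(x, field, allow_zero = TRUE) {
    ok <- grepl("^\\d+$", x) & (allow_zero | x != "0")
    if (any(!ok)) {
      bad <- which(!ok)[1]
      stop("invalid ", field, " ", sQuote(x[bad]), " at row ",
           rowno[bad], " of ", sQuote(path), call. = FALSE)
    }
    as.integer(x)
  }
  df$count <- int_field(df$count, "count")
  df$group_index <- int_field(df$group_index, "group_index",
                              allow_zero = FALSE)
  df$group_n <- int_field(df$group_n, "group_n", allow_zero = FALSE)

  trials <- list()
  for (tid in unique(df$trial_id)) {
    sub <- df[df$trial_id == tid, , drop = FALSE]
    n_arms <- max(sub$group_index)
    gsize <- integer(n_arms)
    for (g in seq_len(n_arms)) {
      gn <- unique(sub$group_n[sub$group_index == g])
      if (length(gn) != 1L)
        stop("inconsistent group_n for trial ", sQuote(tid), " group ", g,
             call. = FALSE)
      gsize[g] <- gn
    }
    vars <- list()
    for (vn in unique(sub$variable)) {
      vs <- sub[sub$variable == vn, , drop = FALSE]
      levels <- unique(vs$level[vs$group_index == vs$group_index[1]])
      counts <- matrix(0L, length(levels), n_arms,
                       dimnames = list(levels, NULL))
      for (i in seq_len(nrow(vs))) {
        counts[match(vs$level[i], levels), vs$group_index[i]] <- vs$count[i]
      }
      rp <- unique(vs$reported_p)
      if (length(rp) != 1L)
        stop("inconsistent reported_p strings for variable ", sQuote(vn),
             " in trial ", sQuote(tid), call. = FALSE)
      excl <- any(toupper(vs$excluded) %in% c("TRUE", "1", "YES"))
      vars[[length(vars) + 1L]] <- cat_variable(
        name = vn, counts = counts, levels = levels,
        reported_p = if (nzchar(rp)) parse_reported_p(
          rp, context = paste(tid, vn, sep = " / ")) else NULL,
        excluded = excl,
        exclude_reason = vs$exclude_reason[1]
      )
    }
    trials[[length(trials) + 1L]] <- trial_record(tid, gsize, vars,
                                                  source_meta = path)
  }
  trials
}

#' Write a trial dataset to the canonical long-format CSV
#'
#' Inverse of [load_canonical()]: `load_canonical(write_canonical(x, f))`
#' reproduces `x` field for field (reported p-values verbatim).
#'
#' @param trials List of `trial_record` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_canonical <- function(trials, path) {
  rows <- list()
  for (tr in trials) {
    for (v in tr$variables) {
      rp <- if (is.null(v$reported_p)) "" else v$reported_p$raw
      for (g in seq_along(tr$group_sizes)) {
        rows[[length(rows) + 1L]] <- data.frame(
          trial_id = tr$trial_id, variable = v$name, level = v$levels,
          group_index = g, count = v$counts[, g],
          group_n = tr$group_sizes[g], reported_p = rp,
          excluded = v$excluded, exclude_reason = v$exclude_reason,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  # rows are built trial -> variable -> group -> level, which is the
  # canonical order; no reordering needed
  if (length(rows) == 0L) {
    out <- data.frame(trial_id = character(), variable = character(),
                      level = character(), group_index = integer(),
                      count = integer(), group_n = integer(),
                      reported_p = character(), excluded = logical(),
                      exclude_reason = character())
  } else {
    out <- do.call(rbind, rows)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
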