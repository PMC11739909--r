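#' Construct a baseline categorical variable
#'
#' One baseline characteristic of one trial: a levels-by-arms matrix of
#' frequency counts plus the verbatim reported p-value, if any. Counts are
#' strict non-negative integers; fractional counts in a source are an error,
#' never rounded.
#'
#' @param name Variable name, unique within its trial.
#' @param counts Integer matrix, one row per level and one column per arm.
#'   Row names are taken as level labels if `levels` is missing.
#' @param levels Character vector of level labels (length `nrow(counts)`).
#' @param reported_p A `reported_p` object, a verbatim string to be parsed,
#'   or `NULL` when no p-value was reported.
#' @param excluded Logical; excluded variables travel through IO and are
#'   filtered at analysis time, so exclusion bookkeeping stays reproducible.
#' @param exclude_reason Free-text reason, recorded when `excluded`.
#' @return An object of class `cat_variable`.
#' @export
cat_variable <- function(name, counts, levels = rownames(counts),
                         reported_p = NULL, excluded = FALSE,
                         exclude_reason = "") {
  counts <- as.matrix(counts)
  if (is.null(levels)) levels <- paste0("level", seq_len(nrow(counts)))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            length(levels) == nrow(counts))
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts for variable ", sQuote(name),
         " must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(levels, paste0("group", seq_len(ncol(counts))))
  if (is.character(reported_p))
    reported_p <- parse_reported_p(reported_p, context = name)
  if (!is.null(reported_p) && !inherits(reported_p, "reported_p"))
    stop("reported_p must be NULL, a string or a reported_p object",
         call. = FALSE)
  structure(
    list(name = name, levels = as.character(levels), counts = counts,
         reported_p = reported_p, excluded = isTRUE(excluded),
         exclude_reason = as.character(exclude_reason)),
    class = "cat_variable"
  )
}

#' Construct a trial record
#'
#' One randomized controlled trial: the randomized group sizes and its
#' baseline categorical variables.
#'
#' @param trial_id Trial identifier.
#' @param group_sizes Positive integer vector, randomized N per arm.
#' @param variables List of [cat_variable()] objects with unique names and
#'   column counts equal to the number of arms.
#' @param source_meta Free-text provenance note.
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(trial_id, group_sizes, variables = list(),
                         source_meta = "") {
  stopifnot(length(trial_id) == 1L, nzchar(trial_id))
  group_sizes <- as.integer(group_sizes)
  if (length(group_sizes) == 0L || any(is.na(group_sizes)) ||
      any(group_sizes < 1L))
    stop("group_sizes must be a non-empty vector of positive integers",
         call. = FALSE)
  nm <- vapply(variables, function(v) v$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate variable names in trial ", sQuote(trial_id), ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  for (v in variables)
    if (ncol(v$counts) != length(group_sizes))
      stop("variable ", sQuote(v$name), " in trial ", sQuote(trial_id),
           " has ", ncol(v$counts), " columns but the trial has ",
           length(group_sizes), " arms", call. = FALSE)
  structure(
    list(trial_id = as.character(trial_id), group_sizes = group_sizes,
         variables = variables, source_meta = as.character(source_meta)),
    class = "trial_record"
  )
}

#' @export
print.cat_variable <- function(x, ...) {
  cat("<cat_variable>", x$name,
      sprintf("(%d levels x %d arms)", nrow(x$counts), ncol(x$counts)),
      if (x$excluded) paste0("[excluded: ", x$exclude_reason, "]"), "\n")
  print(x$counts)
  if (!is.null(x$reported_p)) cat("reported p:", x$reported_p$raw, "\n")
  invisible(x)
}

#' @export
print.trial_record <- function(x, ...) {
  cat("<trial_record>", x$trial_id, "- arms:",
      paste(x$group_sizes, collapse = "/"),
      "-", length(x$variables), "variables\n")
  invisible(x)
}

#' Variables of a trial, optionally dropping excluded ones
#'
#' @param trial A `trial_record`.
#' @param include_excluded Keep variables flagged as excluded?
#' @return List of `cat_variable` objects.
#' @export
trial_variables <- function(trial, include_excluded = FALSE) {
  v <- trial$variables
  if (!include_excluded) v <- Filter(function(x) !x$excluded, v)
  v
}

#' Summarize a trial dataset's size and exclusion bookkeeping
#'
#' @param trials List of `trial_record` objects.
#' @return An object of class `dataset_summary`: number of trials, total
#'   variables, analysed (non-excluded) variables, excluded variables and
#'   per-reason exclusion counts. The invariant
#'   `n_variables_analysed + n_excluded == n_variables_total` always holds.
#' @export
dataset_summary <- function(trials) {
  vars <- unlist(lapply(trials, function(t) t$variables), recursive = FALSE)
  excl <- vapply(vars, function(v) v$excluded, logical(1))
  reasons <- vapply(vars, function(v) v$exclude_reason, character(1))[excl]
  reasons[!nzchar(reasons)] <- "unspecified"
  structure(
    list(n_trials = length(trials),
         n_variables_total = length(vars),
         n_variables_analysed = sum(!excl),
         n_excluded = sum(excl),
         exclusion_reasons = if (sum(excl)) table(reasons) else table(character())),
    class = "dataset_summary"
  )
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat("<dataset_summary>", x$n_trials, "trials,", x$n_variables_total,
      "variables (", x$n_variables_analysed, "analysed,", x$n_excluded,
      "excluded )\n")
  if (x$n_excluded > 0) print(x$exclusion_reasons)
  invisible(x)
}
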