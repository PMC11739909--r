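#' Default layout configuration for a sheet-per-study workbook
#'
#' Published per-study spreadsheets vary in their column naming; the
#' converter is driven by a layout configuration rather than hard-coded
#' names. The default layout expects, on every study sheet, a `variable`
#' column, a `level` column, one count column per arm matching
#' `group_count_pattern` (a regex whose first capture group is the 1-based
#' arm index), an optional reported p-value column, and one row per
#' (variable, level). Randomized group sizes are taken from a dedicated row
#' whose `variable` cell equals `total_label`. Blank padding rows are
#' tolerated and dropped.
#'
#' @param col_variable,col_level,col_reported_p Column names on each sheet.
#'   `col_reported_p = NULL` means no reported p-values in this workbook.
#' @param group_count_pattern Regex identifying per-arm count columns; its
#'   first capture group must be the arm index (default matches `n1`, `n2`,
#'   ...).
#' @param total_label `variable`-cell label of the group-sizes row.
#' @param sheet_pattern Regex selecting which sheets are study sheets.
#' @return A list usable as `layout` in [convert_workbook()]; the same
#'   structure can be read from a YAML file with [read_layout_config()].
#' @export
workbook_layout <- function(col_variable = "variable",
                            col_level = "level",
                            col_reported_p = "reported_p",
                            group_count_pattern = "^n(\\d+)$",
                            total_label = "N",
                            sheet_pattern = ".*") {
  list(col_variable = col_variable, col_level = col_level,
       col_reported_p = col_reported_p,
       group_count_pattern = group_count_pattern,
       total_label = total_label, sheet_pattern = sheet_pattern)
}

#' Read a workbook layout configuration from YAML or JSON
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file whose keys are
#'   the arguments of [workbook_layout()].
#' @return A layout list; unspecified keys take the defaults.
#' @export
read_layout_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(workbook_layout, cfg[intersect(names(cfg),
                                         names(formals(workbook_layout)))])
}

#' Convert a sheet-per-study workbook to trial records
#'
#' Reads a published workbook in which each sheet describes one study's
#' baseline categorical variables, and assembles the sheets into one
#' dataset. `path` may be an `.xlsx` file (read with \pkg{readxl}) or a
#' directory of per-sheet CSV files with identical layout (the plain-text
#' form of the same workbook). All cells are read as text; counts must be
#' integers and reported p-values are kept verbatim.
#'
#' Variables listed in `exclusions` are retained and flagged, not dropped,
#' so the analysed/excluded bookkeeping is reproducible downstream.
#'
#' @param path Workbook file or sheet directory.
#' @param layout A [workbook_layout()] list.
#' @param exclusions Optional data.frame with columns `trial_id`,
#'   `variable`, `reason` marking variables to flag as excluded.
#' @return List with elements `trials` (list of [trial_record()]) and
#'   `summary` (a [dataset_summary()]).
#' @export
convert_workbook <- function(path, layout = workbook_layout(),
                             exclusions = NULL) {
  sheets <- read_workbook_sheets(path, layout$sheet_pattern)
  trials <- lapply(names(sheets), function(nm) {
    sheet_to_trial(sheets[[nm]], nm, layout)
  })
  if (!is.null(exclusions)) {
    for (i in seq_len(nrow(exclusions))) {
      ti <- match(exclusions$trial_id[i],
                  vapply(trials, `[[`, "", "trial_id"))
      if (is.na(ti)) next
      for (j in seq_along(trials[[ti]]$variables)) {
        if (trials[[ti]]$variables[[j]]$name == exclusions$variable[i]) {
          trials[[ti]]$variables[[j]]$excluded <- TRUE
          trials[[ti]]$variables[[j]]$exclude_reason <-
            as.character(exclusions$reason[i])
        }
      }
    }
  }
  list(trials = trials, summary = dataset_summary(trials))
}

read_workbook_sheets <- function(path, sheet_pattern) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    nms <- sub("\\.csv$", "", basename(files))
    keep <- grepl(sheet_pattern, nms)
    sheets <- lapply(files[keep], utils::read.csv,
                     colClasses = "character", check.names = FALSE,
                     na.strings = NULL)
    names(sheets) <- nms[keep]
  } else if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx workbooks requires the readxl package",
           call. = FALSE)
    nms <- readxl::excel_sheets(path)
    nms <- nms[grepl(sheet_pattern, nms)]
    sheets <- lapply(nms, function(s) {
      df <- readxl::read_excel(path, sheet = s, col_types = "text")
      df <- as.data.frame(df, stringsAsFactors = FALSE)
      df[is.na(df)] <- ""
      df
    })
    names(sheets) <- nms
  } else {
    stop("workbook path ", sQuote(path),
         " is neither an .xlsx file nor a sheet directory", call. = FALSE)
  }
  if (length(sheets) == 0L)
    stop("no study sheets found in ", sQuote(path), call. = FALSE)
  sheets
}

sheet_to_trial <- function(df, sheet_name, layout) {
  need <- c(layout$col_variable, layout$col_level)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sheet ", sQuote(sheet_name), " is missing expected columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  gcols <- grep(layout$group_count_pattern, names(df), value = TRUE)
  if (length(gcols) == 0L)
    stop("sheet ", sQuote(sheet_name), " has no group count columns ",
         "matching ", sQuote(layout$group_count_pattern), call. = FALSE)
  gidx <- as.integer(sub(layout$group_count_pattern, "\\1", gcols))
  gcols <- gcols[order(gidx)]

  # drop blank padding rows
  blank <- !nzchar(trimws(df[[layout$col_variable]])) &
    !nzchar(trimws(df[[layout$col_level]]))
  df <- df[!blank, , drop = FALSE]

  is_total <- trimws(df[[layout$col_variable]]) == layout$total_label
  if (!any(is_total))
    stop("sheet ", sQuote(sheet_name), " has no group-sizes row labelled ",
         sQuote(layout$total_label), call. = FALSE)
  group_sizes <- parse_count_cells(df[which(is_total)[1], gcols],
                                   sheet_name, "group sizes")
  body <- df[!is_total, , drop = FALSE]

  vars <- list()
  for (vn in unique(body[[layout$col_variable]])) {
    vs <- body[body[[layout$col_variable]] == vn, , drop = FALSE]
    counts <- t(vapply(seq_len(nrow(vs)), function(i) {
      parse_count_cells(vs[i, gcols], sheet_name, vn)
    }, integer(length(gcols))))
    rp <- NULL
    if (!is.null(layout$col_reported_p) &&
        layout$col_reported_p %in% names(vs)) {
      raw <- trimws(vs[[layout$col_reported_p]])
      raw <- unique(raw[nzchar(raw)])
      if (length(raw) > 1L)
        stop("conflicting reported p strings for variable ", sQuote(vn),
             " on sheet ", sQuote(sheet_name), call. = FALSE)
      if (length(raw) == 1L)
        rp <- parse_reported_p(raw, context = paste(sheet_name, vn,
                                                    sep = " / "))
    }
    vars[[length(vars) + 1L]] <- cat_variable(
      name = vn, counts = counts, levels = vs[[layout$col_level]],
      reported_p = rp
    )
  }
  trial_record(sheet_name, group_sizes, vars,
               source_meta = paste0("workbook sheet ", sheet_name))
}

parse_count_cells <- function(cells, sheet_name, what) {
  x <- trimws(as.character(unlist(cells)))
  if (any(!grepl("^\\d+$", x)))
    stop("non-integer count ", sQuote(x[!grepl("^\\d+$", x)][1]),
         " for ", what, " on sheet ", sQuote(sheet_name), call. = FALSE)
  as.integer(x)
}
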