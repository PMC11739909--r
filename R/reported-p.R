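#' Parse a reported baseline p-value string
#'
#' Published baseline tables print p-values in several forms: plain decimals
#' (`"0.50"`, `"1"`), threshold inequalities (`">0.9999"`, `"<0.001"`,
#' possibly prefixed with `"p"` or `"p="`), or non-numeric markers such as
#' `"NS"`. The printed form carries information the numeric value does not:
#' the number of decimal places determines how coarsely the original authors
#' rounded, which is what later matching against recalculated p-values must
#' respect. This parser therefore works on the verbatim string and never on a
#' float.
#'
#' @param raw Verbatim reported p-value string. `NA`, the empty string and
#'   common "not stated" markers (`"NS"`, `"n.s."`, `"NA"`, `"-"`, `"NR"`)
#'   parse to `kind = "missing"` with the raw text preserved.
#' @param context Optional label (e.g. `"trial A / smoking"`) interpolated
#'   into parse-error messages.
#'
#' @return An object of class `reported_p`: a list with elements `raw`,
#'   `kind` (`"numeric"`, `"threshold"` or `"missing"`), `value` (numeric
#'   value or threshold boundary; `NA` for missing), `decimals` (decimal
#'   places as printed; 0 for an integer-printed p) and `direction`
#'   (`">"`, `"<"` or `"none"`).
#'
#' @examples
#' parse_reported_p("0.50")     # numeric, value 0.5, 2 decimals
#' parse_reported_p(">0.9999")  # threshold, direction ">"
#' parse_reported_p("NS")       # missing, raw preserved
#' @export
parse_reported_p <- function(raw, context = NULL) {
  ctx <- if (is.null(context)) "" else paste0(" [", context, "]")
  if (length(raw) != 1L)
    stop("parse_reported_p() expects a single string", ctx, call. = FALSE)
  if (is.na(raw) || !nzchar(trimws(raw)))
    return(new_reported_p(raw = if (is.na(raw)) "" else raw, kind = "missing"))
  s <- trimws(raw)
  # strip a leading "p" / "P" and an "=" separator, e.g. "p = 0.03", "P<0.05"
  s2 <- sub("^[pP]\\s*=?\\s*", "", s)

  missing_markers <- c("ns", "n.s.", "n.s", "na", "n/a", "-", "nr", " nr ",
                       "not stated", "not reported")
  if (tolower(s2) %in% missing_markers || tolower(s) %in% missing_markers)
    return(new_reported_p(raw = raw, kind = "missing"))

  num_re <- "^(\\d+)(\\.(\\d+))?$"
  if (grepl("^[<>]", s2)) {
    direction <- substr(s2, 1L, 1L)
    body <- trimws(sub("^[<>]\\s*=?\\s*", "", s2))
    if (!grepl(num_re, body))
      stop("cannot parse threshold p-value string ", sQuote(raw), ctx,
           call. = FALSE)
    value <- as.numeric(body)
    if (is.na(value) || value < 0 || value > 1)
      stop("threshold p-value out of [0, 1]: ", sQuote(raw), ctx,
           call. = FALSE)
    dec <- decimal_places(body)
    return(new_reported_p(raw = raw, kind = "threshold", value = value,
                          decimals = dec, direction = direction))
  }
  if (grepl(num_re, s2)) {
    value <- as.numeric(s2)
    if (is.na(value) || value < 0 || value > 1)
      stop("numeric p-value out of [0, 1]: ", sQuote(raw), ctx, call. = FALSE)
    return(new_reported_p(raw = raw, kind = "numeric", value = value,
                          decimals = decimal_places(s2)))
  }
  stop("cannot parse reported p-value string ", sQuote(raw), ctx,
       call. = FALSE)
}

new_reported_p <- function(raw, kind, value = NA_real_,
                           decimals = NA_integer_, direction = "none") {
  structure(
    list(raw = as.character(raw), kind = kind, value = value,
         decimals = as.integer(decimals), direction = direction),
    class = "reported_p"
  )
}

decimal_places <- function(s) {
  if (!grepl("\\.", s)) return(0L)
  nchar(sub("^\\d*\\.", "", s))
}

#' @export
format.reported_p <- function(x, ...) {
  switch(x$kind,
    missing = sprintf("<reported p: missing (%s)>", dQuote(x$raw)),
    numeric = sprintf("<reported p: %s (%d dp)>", x$raw, x$decimals),
    threshold = sprintf("<reported p: %s %s>", x$direction,
                        format(x$value)))
}

#' @export
print.reported_p <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Format a p-value the way a paper would print it
#'
#' Fixed-notation rounding to `decimals` decimal places with trailing zeros
#' kept, so that `parse_reported_p(format_p(p, d))` recovers `d`.
#'
#' @param p Numeric p-value in \[0, 1\].
#' @param decimals Number of decimal places to print.
#' @return Character string.
#' @export
format_p <- function(p, decimals) {
  formatC(round(p, decimals), format = "f", digits = decimals)
}
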