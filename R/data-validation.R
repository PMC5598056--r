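# Pre-load validation of extracted CSV data: type parses, required fields,
# declared lengths, orphan foreign keys.  Issues carry a severity (ERROR fails
# the extract and forces re-extraction; WARNING is informational) and locate
# the offending record by its 1-based data-file line number only — messages
# never embed cell contents, so reports are safe to share.

ISO_DATE_RE <- "^\\d{4}-\\d{2}-\\d{2}([T ]\\d{2}:\\d{2}:\\d{2}(\\.\\d+)?)?$"

# strict ISO 8601 date/timestamp check (calendar-valid, not just well-formed)
is_valid_date_cell <- function(x) {
  ok <- grepl(ISO_DATE_RE, x)
  d <- substr(x, 1, 10)
  parsed <- as.Date(rep(NA_character_, length(x)))
  parsed[ok] <- as.Date(d[ok], format = "%Y-%m-%d", optional = TRUE)
  ok & !is.na(parsed)
}

is_valid_numeric_cell <- function(x) {
  suppressWarnings(!is.na(as.numeric(trimws(x))))
}

is_valid_integer_cell <- function(x) {
  grepl("^[+-]?\\d+$", trimws(x))
}

read_extract <- function(data_csv) {
  readr::read_csv(data_csv,
                  col_types = readr::cols(.default = readr::col_character()),
                  na = character(), trim_ws = FALSE,
                  progress = FALSE, show_col_types = FALSE)
}

#' Validate an extracted CSV table against its declared spec
#'
#' Applies the standard extract-quality rules, one issue per offending cell:
#'
#' * `invalid_date` (ERROR): a date/timestamp cell cannot be parsed as an
#'   ISO 8601 date.
#' * `missing_required` (ERROR): data is missing in a field declared required.
#' * `invalid_numeric` (ERROR; WARNING in loose mode): a numeric/decimal/
#'   integer cell is not a number.
#' * `overlength` (ERROR; WARNING in loose mode): data is too long for a
#'   text/varchar field with a declared length.
#' * `missing_length_spec` (WARNING, once per column): a varchar column has no
#'   declared length, or a decimal column no precision/scale.
#' * `extra_column` (WARNING, once per column): a file column absent from the
#'   spec.
#'
#' Empty cells and the literal `NULL` (any case) both denote missing values.
#' Line numbers are 1-based over data rows (header excluded).  Strict mode
#' keeps the severities above; loose mode downgrades length overflows and
#' numeric parse failures to warnings (the values are coercible or truncable
#' downstream).  The issue list per rule and table is capped (default 1000)
#' but full counts are preserved in the `full_counts` attribute.
#'
#' @param data_csv Path to the extracted CSV.
#' @param spec The table's [table_spec()].
#' @param mode `"strict"` (default) or `"loose"`.
#' @param max_issues_per_rule Per-rule cap on emitted issues.
#' @return Issue tibble (`rule_id`, `severity`, `table`, `column`,
#'   `line_number`, `rule_order`, `message`), zero rows when conformant.
#' @export
validate_table <- function(data_csv, spec, mode = c("strict", "loose"),
                           max_issues_per_rule = 1000L) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "detl_table_spec"))
  dat <- read_extract(data_csv)
  missing_cols <- setdiff(spec$columns$name, names(dat))
  if (length(missing_cols) > 0) {
    stop(sprintf("table %s: file is missing declared column(s): %s",
                 spec$name, paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  issues <- list()
  add <- function(rule_id, severity, column, lines, message) {
    if (length(lines) == 0) return()
    issues[[length(issues) + 1L]] <<- new_issue_table(
      rule_id = rep(rule_id, length(lines)),
      severity = rep(severity, length(lines)),
      table = rep(spec$name, length(lines)),
      column = rep(column, length(lines)),
      line_number = lines,
      rule_order = rep(NA_integer_, length(lines)),
      message = rep(message, length(lines)))
  }

  for (extra in setdiff(names(dat), spec$columns$name)) {
    add("extra_column", "WARNING", extra, NA_integer_,
        "column present in the data file but not in the schema spec")
  }

  downgrade <- c(invalid_numeric = mode == "loose", overlength = mode == "loose")
  sev <- function(rule_id) {
    if (isTRUE(downgrade[[rule_id]])) "WARNING" else "ERROR"
  }

  for (i in seq_len(nrow(spec$columns))) {
    cl <- spec$columns[i, ]
    x <- dat[[cl$name]]
    miss <- is_missing_cell(x)

    if (cl$type == "varchar" && is.na(cl$length)) {
      add("missing_length_spec", "WARNING", cl$name, NA_integer_,
          "column has a missing length; a default length can be used")
    }
    if (cl$type == "decimal" && (is.na(cl$precision) || is.na(cl$scale))) {
      add("missing_length_spec", "WARNING", cl$name, NA_integer_,
          "column has a missing precision or scale; defaults can be used")
    }
    if (isTRUE(cl$required)) {
      add("missing_required", "ERROR", cl$name, which(miss),
          "data is missing in a field defined as required by the schema")
    }
    present <- which(!miss)
    if (length(present) == 0) next
    xp <- x[present]
    if (cl$type %in% c("date", "timestamp")) {
      bad <- present[!is_valid_date_cell(xp)]
      add("invalid_date", "ERROR", cl$name, bad,
          "value in a date or timestamp column cannot be parsed as a date")
    } else if (cl$type %in% c("numeric", "decimal")) {
      bad <- present[!is_valid_numeric_cell(xp)]
      add("invalid_numeric", sev("invalid_numeric"), cl$name, bad,
          "value in a numeric or decimal column is not a number")
    } else if (cl$type == "integer") {
      bad <- present[!is_valid_integer_cell(xp)]
      add("invalid_numeric", sev("invalid_numeric"), cl$name, bad,
          "value in an integer column is not a whole number")
    } else if (cl$type %in% c("text", "varchar") && !is.na(cl$length)) {
      bad <- present[nchar(xp) > cl$length]
      add("overlength", sev("overlength"), cl$name, bad,
          "data is too long for the declared text or varchar length")
    }
  }
  out <- bind_issues(issues)
  full_counts <- if (nrow(out) > 0) {
    as.data.frame(table(rule_id = out$rule_id), stringsAsFactors = FALSE)
  } else {
    data.frame(rule_id = character(), Freq = integer())
  }
  if (nrow(out) > 0) {
    keep <- unlist(lapply(split(seq_len(nrow(out)), out$rule_id),
                          function(ix) utils::head(ix, max_issues_per_rule)))
    out <- out[sort(keep), ]
  }
  attr(out, "full_counts") <- full_counts
  out
}

#' Detect orphan foreign-key values
#'
#' An orphan is a non-missing value in a child foreign-key column that is
#' absent from the parent table's key column.  Missing foreign-key values are
#' not orphans (they are the required-field rule's concern).
#'
#' @param child_csv Path to the child extract.
#' @param parent_csv Path to the parent extract.
#' @param fk A list with `columns` (child columns), `parent_table`, and
#'   `parent_columns`.
#' @param child_table Child table name for the report (defaults to the file
#'   name without extension).
#' @return Issue tibble, one `orphan_fk` ERROR per offending child line.
#' @export
check_orphan_foreign_keys <- function(child_csv, parent_csv, fk,
                                      child_table = NULL) {
  child <- read_extract(child_csv)
  parent <- read_extract(parent_csv)
  child_table <- child_table %||% sub("\\.[^.]+$", "", basename(child_csv))
  if (!all(fk$columns %in% names(child))) {
    stop(sprintf("foreign-key column(s) missing from child file: %s",
                 paste(setdiff(fk$columns, names(child)), collapse = ", ")),
         call. = FALSE)
  }
  if (!all(fk$parent_columns %in% names(parent))) {
    stop(sprintf("key column(s) missing from parent file: %s",
                 paste(setdiff(fk$parent_columns, names(parent)),
                       collapse = ", ")), call. = FALSE)
  }
  key_of <- function(df, cols) do.call(paste, c(df[cols], sep = "\x1f"))
  cmiss <- Reduce(`|`, lapply(fk$columns, function(cc) is_missing_cell(child[[cc]])))
  ck <- key_of(child, fk$columns)
  pk <- key_of(parent, fk$parent_columns)
  orphan <- which(!cmiss & !(ck %in% pk))
  if (length(orphan) == 0) return(new_issue_table())
  new_issue_table(
    rule_id = rep("orphan_fk", length(orphan)),
    severity = rep("ERROR", length(orphan)),
    table = rep(child_table, length(orphan)),
    column = rep(paste(fk$columns, collapse = ","), length(orphan)),
    line_number = orphan,
    rule_order = rep(NA_integer_, length(orphan)),
    message = rep(sprintf(
      "foreign-key value not present in parent table %s", fk$parent_table),
      length(orphan)))
}

#' Summarize a validation run
#'
#' @param issues Issue tibble (possibly from several tables, row-bound).
#' @return A `detl_validation_report`: overall `verdict` (`"FAIL"` iff any
#'   ERROR; warnings never fail a dataset), counts by severity, by rule and by
#'   table, and the issues themselves.
#' @export
summarize_validation <- function(issues) {
  issues <- if (is.null(issues)) new_issue_table() else issues
  n_error <- sum(issues$severity == "ERROR")
  n_warning <- sum(issues$severity == "WARNING")
  count_by <- function(key) {
    tb <- table(issues[[key]], useNA = "no")
    out <- tibble::tibble(key = names(tb), n = as.integer(tb))
    names(out)[1] <- key
    out
  }
  structure(
    list(verdict = if (n_error > 0) "FAIL" else "PASS",
         n_error = n_error,
         n_warning = n_warning,
         by_rule = count_by("rule_id"),
         by_table = count_by("table"),
         issues = issues),
    class = "detl_validation_report"
  )
}

#' @export
print.detl_validation_report <- function(x, ...) {
  cat(sprintf("<detl_validation_report> %s: %d error(s), %d warning(s)\n",
              x$verdict, x$n_error, x$n_warning))
  if (nrow(x$by_rule) > 0) {
    for (i in seq_len(nrow(x$by_rule))) {
      cat(sprintf("  %-22s %d\n", x$by_rule[[1]][i], x$by_rule$n[i]))
    }
  }
  invisible(x)
}

#' Serialize a validation report to JSON
#' @param report A `detl_validation_report`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The path (invisibly) or a JSON string.
#' @export
validation_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "detl_validation_report"))
  obj <- list(verdict = report$verdict, n_error = report$n_error,
              n_warning = report$n_warning, by_rule = report$by_rule,
              by_table = report$by_table, issues = report$issues)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, na = "null")
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, na = "null")
    invisible(path)
  }
}
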