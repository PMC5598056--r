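`%||%` <- function(a, b) if (is.null(a)) b else a

# collapse internal whitespace and trim; used to canonicalize map-type tokens
squish <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# cells that count as missing in extracted CSVs: empty string or literal NULL
is_missing_cell <- function(x) {
  is.na(x) | x == "" | toupper(trimws(x)) == "NULL"
}

is_identifier <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) &&
    grepl("^[A-Za-z_][A-Za-z0-9_]*$", x)
}

# remove single-quoted SQL string literals (with '' escapes) so that
# identifier scans and statement-separator checks never look inside them
strip_sql_strings <- function(sql) {
  gsub("'(?:[^']|'')*'", "''", sql, perl = TRUE)
}

# tables referenced as <table>.<column> in a SQL fragment
referenced_tables <- function(sql) {
  if (is.na(sql) || !nzchar(sql)) return(character())
  bare <- strip_sql_strings(sql)
  m <- gregexpr("[A-Za-z_][A-Za-z0-9_]*(?=\\s*\\.)", bare, perl = TRUE)
  unique(regmatches(bare, m)[[1]])
}

# a rule's user-supplied fragments must stay a single statement
assert_no_statement_separator <- function(sql, what) {
  if (grepl(";", strip_sql_strings(sql), fixed = TRUE)) {
    stop(sprintf("%s must not contain a statement separator (';'): %s",
                 what, sql), call. = FALSE)
  }
  invisible(sql)
}

new_issue_table <- function(rule_id = character(), severity = character(),
                            table = character(), column = character(),
                            line_number = integer(), rule_order = integer(),
                            message = character()) {
  tibble::tibble(
    rule_id = as.character(rule_id),
    severity = as.character(severity),
    table = as.character(table),
    column = as.character(column),
    line_number = as.integer(line_number),
    rule_order = as.integer(rule_order),
    message = as.character(message)
  )
}

issue_row <- function(rule_id, severity, table = NA_character_,
                      column = NA_character_, line_number = NA_integer_,
                      rule_order = NA_integer_, message = "") {
  new_issue_table(rule_id, severity, table, column, line_number, rule_order,
                  message)
}

bind_issues <- function(lst) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0, lst)
  if (length(lst) == 0) return(new_issue_table())
  do.call(rbind, lst)
}
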