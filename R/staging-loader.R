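# Staging and execution: CSV extracts are imported as-is into an embedded
# SQLite database (the same engine where the transformation runs), each batch
# stamped with a load timestamp used downstream for conflict resolution.
# Generated statements are stored with their rule provenance before execution,
# run in rule order with per-statement status capture, and a failed run can be
# resumed from its checkpoint.

#' Open the embedded ETL database
#'
#' @param path SQLite database file, or `":memory:"` (default) for an
#'   in-memory staging/transformation area.
#' @return A DBI connection.
#' @export
etl_connect <- function(path = ":memory:") {
  DBI::dbConnect(RSQLite::SQLite(), path)
}

coerce_column <- function(x, type, table, name) {
  x[is_missing_cell(x)] <- NA_character_
  if (type == "integer") {
    out <- suppressWarnings(as.integer(x))
  } else if (type %in% c("numeric", "decimal")) {
    out <- suppressWarnings(as.numeric(x))
  } else {
    return(x)  # text/varchar/date/timestamp stay as-is (TEXT storage)
  }
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop(sprintf(
      "table %s, column %s: value at data line %d cannot be loaded as %s (validation gap)",
      table, name, bad[1], type), call. = FALSE)
  }
  out
}

#' Stage a CSV extract into the ETL database
#'
#' Loads the file as-is (no transformation) into a table shaped by `spec`,
#' with an `etl_timestamp` column injected and set to the batch load time —
#' unless the extract already carries one (multi-batch extracts keep their own
#' timestamps).  Empty cells and the literal `NULL` load as SQL NULL.
#'
#' @param con DBI connection from [etl_connect()].
#' @param data_csv Path to the extract.
#' @param spec The table's [table_spec()].
#' @param batch_id Load batch identifier.
#' @param batch_time Load timestamp for the batch (default: current time,
#'   `"%Y-%m-%d %H:%M:%OS3"` UTC).  ISO text so it orders correctly.
#' @param append Append to an existing staged table instead of replacing it.
#' @return A `detl_staged_table` (`name`, `row_count`, `batch_id`,
#'   `batch_time`).
#' @export
stage_csv <- function(con, data_csv, spec, batch_id = "batch-1",
                      batch_time = NULL, append = FALSE) {
  stopifnot(inherits(spec, "detl_table_spec"))
  dat <- read_extract(data_csv)
  missing_cols <- setdiff(spec$columns$name, names(dat))
  if (length(missing_cols) > 0) {
    stop(sprintf("table %s: extract is missing declared column(s): %s",
                 spec$name, paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  dat <- dat[, intersect(c(spec$columns$name, "etl_timestamp"), names(dat))]
  for (i in seq_len(nrow(spec$columns))) {
    cl <- spec$columns[i, ]
    dat[[cl$name]] <- coerce_column(dat[[cl$name]], cl$type, spec$name, cl$name)
  }
  batch_time <- batch_time %||% format(Sys.time(), "%Y-%m-%d %H:%M:%OS3",
                                       tz = "UTC")
  if (!"etl_timestamp" %in% names(dat)) {
    dat$etl_timestamp <- rep(batch_time, nrow(dat))
  } else {
    dat$etl_timestamp[is_missing_cell(dat$etl_timestamp)] <- batch_time
  }
  if (append && DBI::dbExistsTable(con, spec$name)) {
    DBI::dbAppendTable(con, spec$name, dat)
  } else {
    DBI::dbWriteTable(con, spec$name, dat, overwrite = TRUE)
  }
  structure(list(name = spec$name, row_count = nrow(dat),
                 batch_id = batch_id, batch_time = batch_time),
            class = "detl_staged_table")
}

#' Read back a staged table without its load metadata
#'
#' Staging is lossless: dropping the injected `etl_timestamp` column
#' reproduces the extract's data rows.
#'
#' @param con DBI connection.
#' @param table Staged table name.
#' @return Tibble of the staged rows, `etl_timestamp` removed.
#' @export
unload_staged <- function(con, table) {
  dat <- DBI::dbReadTable(con, table)
  dat$etl_timestamp <- NULL
  tibble::as_tibble(dat)
}

#' Create empty target tables from their specs
#'
#' @param con DBI connection.
#' @param specs Named list of `detl_table_spec` (or one spec).
#' @return Invisibly, the table names created.
#' @export
create_target_tables <- function(con, specs) {
  if (inherits(specs, "detl_table_spec")) specs <- list(specs)
  for (spec in specs) {
    cols <- sprintf("%s %s", spec$columns$name,
                    vapply(spec$columns$type, sql_type_for, character(1)))
    DBI::dbExecute(con, sprintf("CREATE TABLE IF NOT EXISTS %s (%s)",
                                spec$name, paste(cols, collapse = ", ")))
  }
  invisible(vapply(specs, function(s) s$name, character(1)))
}

#' Store generated statements with their rule provenance
#'
#' Generated SQL is kept in the database separately from the rules (table
#' `detl_statements`), so designers can inspect, re-run and debug individual
#' statements without the rule file at hand.
#'
#' @param con DBI connection.
#' @param plan A `detl_plan` from [compile_ruleset()], or a list of
#'   `detl_statement`.
#' @return Invisibly, the number of statements stored.
#' @export
store_statements <- function(con, plan) {
  stmts <- if (inherits(plan, "detl_plan")) plan$statements else plan
  df <- do.call(rbind, lapply(stmts, function(s) {
    data.frame(rule_order = s$rule_order,
               rule_description = s$rule_description %||% NA_character_,
               data_source_id = s$data_source_id,
               target_table = s$target_table %||% NA_character_,
               sql_text = s$sql_text,
               generated_at = s$generated_at,
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) return(invisible(0L))
  if (DBI::dbExistsTable(con, "detl_statements")) {
    DBI::dbAppendTable(con, "detl_statements", df)
  } else {
    DBI::dbWriteTable(con, "detl_statements", df)
  }
  invisible(nrow(df))
}

#' Mirror generated statements to .sql files
#'
#' @param plan A `detl_plan` or list of `detl_statement`.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths written.
#' @export
write_sql_files <- function(plan, dir) {
  stmts <- if (inherits(plan, "detl_plan")) plan$statements else plan
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(stmts, function(s) {
    path <- file.path(dir, sprintf("rule_%03d.sql", s$rule_order))
    writeLines(c(sprintf("-- rule %d (%s) -> %s, generated %s",
                         s$rule_order, s$data_source_id,
                         s$target_table %||% "?", s$generated_at),
                 paste0(s$sql_text, ";")), path)
    path
  }, character(1))
}

new_run_report <- function(df, checkpoint) {
  structure(list(statements = tibble::as_tibble(df), checkpoint = checkpoint),
            class = "detl_run_report")
}

#' @export
print.detl_run_report <- function(x, ...) {
  st <- x$statements
  cat(sprintf("<detl_run_report> %d statement(s): %d success, %d failed, %d skipped\n",
              nrow(st), sum(st$status == "success"),
              sum(st$status == "failed"), sum(st$status == "skipped")))
  if (!is.na(x$checkpoint)) {
    cat(sprintf("  resume checkpoint: rule %d\n", x$checkpoint))
  }
  invisible(x)
}

#' Execute a compiled plan in rule order
#'
#' Statements run in ascending `rule_order`.  A SQL error is captured per
#' statement (never aborting the report); all subsequent statements are marked
#' skipped and the failing rule is recorded as the resume checkpoint.
#' Re-invoking with `resume_from` set to that checkpoint continues from the
#' failed statement, leaving earlier (already applied) statements untouched.
#'
#' @param con DBI connection with staged sources and created targets.
#' @param plan A `detl_plan` or list of `detl_statement`.
#' @param resume_from Optional `rule_order` checkpoint to resume from;
#'   statements with a smaller `rule_order` are marked skipped and not re-run.
#' @param refresh Delete existing rows from the plan's target tables before
#'   running (minimal re-load semantics for repeated full runs).
#' @return A `detl_run_report`: per-statement status (`success`/`failed`/
#'   `skipped`), rows inserted, error text, and the resume checkpoint.
#' @export
execute_statements <- function(con, plan, resume_from = NULL,
                               refresh = FALSE) {
  stmts <- if (inherits(plan, "detl_plan")) plan$statements else plan
  ord <- order(vapply(stmts, function(s) s$rule_order, numeric(1)))
  stmts <- stmts[ord]
  if (isTRUE(refresh)) {
    for (tt in unique(stats::na.omit(
           vapply(stmts, function(s) s$target_table %||% NA_character_,
                  character(1))))) {
      if (DBI::dbExistsTable(con, tt)) {
        DBI::dbExecute(con, sprintf("DELETE FROM %s", tt))
      }
    }
  }
  failed <- FALSE
  checkpoint <- NA_integer_
  rows <- lapply(stmts, function(s) {
    if (!is.null(resume_from) && s$rule_order < resume_from) {
      return(data.frame(rule_order = s$rule_order,
                        rule_description = s$rule_description %||% NA_character_,
                        status = "skipped", rows_inserted = NA_integer_,
                        error = "already applied before resume point",
                        stringsAsFactors = FALSE))
    }
    if (failed) {
      return(data.frame(rule_order = s$rule_order,
                        rule_description = s$rule_description %||% NA_character_,
                        status = "skipped", rows_inserted = NA_integer_,
                        error = NA_character_, stringsAsFactors = FALSE))
    }
    res <- tryCatch(DBI::dbExecute(con, s$sql_text), error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- TRUE
      checkpoint <<- s$rule_order
      data.frame(rule_order = s$rule_order,
                 rule_description = s$rule_description %||% NA_character_,
                 status = "failed", rows_inserted = NA_integer_,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(rule_order = s$rule_order,
                 rule_description = s$rule_description %||% NA_character_,
                 status = "success", rows_inserted = as.integer(res),
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  new_run_report(do.call(rbind, rows), checkpoint)
}

#' Compile and execute a single rule (debugging aid)
#'
#' Rule designers track down transformation errors by executing individual
#' rules and inspecting the generated SQL directly.
#'
#' @param con DBI connection.
#' @param rules A `detl_ruleset`.
#' @param rule_order The rule to run.
#' @param opts [compile_options()].
#' @param specs Optional source specs for de-duplication.
#' @return A `detl_run_report` for the single statement, with the generated
#'   SQL text in its `sql_text` attribute (also printed by the report).
#' @export
run_single_rule <- function(con, rules, rule_order,
                            opts = compile_options(), specs = NULL) {
  rule <- get_rule(rules, rule_order)  # errors on unknown rule_order
  st <- compile_rule(rule, opts, specs)
  rep <- execute_statements(con, list(st))
  attr(rep, "sql_text") <- st$sql_text
  rep
}
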