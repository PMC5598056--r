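# The rule engine: translates each well-formed rule into one executable
# INSERT ... SELECT statement.  Referenced source tables are replaced by
# de-duplicating common table expressions (exact duplicates collapse; rows
# that share a record identity but disagree resolve to the latest load
# timestamp), joins and the optional filter are assembled from the rule's
# JOIN-family and WHERE rows, and VALUE expressions are embedded verbatim so
# the full expression power of the backing SQL dialect is available to rule
# authors.

#' Compiler options
#'
#' @param dedup Emit de-duplicating CTEs for every referenced source table
#'   that has a declared spec (default `TRUE`).
#' @param timestamp_column Name of the load-batch timestamp column used to
#'   resolve conflicting records (latest wins).  Default `"etl_timestamp"`.
#' @param select_distinct Emit `SELECT DISTINCT` instead of `SELECT`.  Needed
#'   when the projection itself introduces repeats, e.g. deriving care sites
#'   from claim lines where many claims share one facility.
#' @param dialect Target dialect tag: `"sqlite"` (embedded engine; default) or
#'   `"postgresql"` (qualifies the target with its schema when declared).
#' @return A `detl_compile_options` list.
#' @export
compile_options <- function(dedup = TRUE, timestamp_column = "etl_timestamp",
                            select_distinct = FALSE,
                            dialect = c("sqlite", "postgresql")) {
  if (!is_identifier(timestamp_column)) {
    stop("timestamp_column must be a valid identifier", call. = FALSE)
  }
  structure(list(dedup = isTRUE(dedup),
                 timestamp_column = timestamp_column,
                 select_distinct = isTRUE(select_distinct),
                 dialect = match.arg(dialect)),
            class = "detl_compile_options")
}

new_statement <- function(sql_text, rule, target_table) {
  structure(
    list(sql_text = sql_text,
         rule_order = rule$rows$rule_order[1],
         rule_description = rule$rows$rule_description[1],
         data_source_id = rule$data_source_id,
         target_table = target_table,
         generated_at = format(Sys.time(), "%Y-%m-%d %H:%M:%OS3", tz = "UTC")),
    class = "detl_statement"
  )
}

#' @export
print.detl_statement <- function(x, ...) {
  cat(sprintf("<detl_statement> rule %d (%s) -> %s\n%s\n",
              x$rule_order, x$data_source_id, x$target_table, x$sql_text))
  invisible(x)
}

#' Build the de-duplicating subquery for one source table
#'
#' Produces a named CTE (`<table>__dedup AS (...)`) that replaces the raw
#' table in FROM/JOIN clauses.  Two cleaning passes are stacked:
#'
#' 1. *Exact duplicates* — rows identical in every column except the declared
#'    record identifier (and the load timestamp, which is batch metadata) —
#'    collapse to one row, keeping the smallest record identifier.
#' 2. *Conflicting records* — rows sharing the record identifier but asserting
#'    different values — resolve to the row with the latest value in
#'    `timestamp_column`; ties (or a missing timestamp column) fall back to
#'    the row sorting first lexicographically over the non-key columns, which
#'    is deterministic and independent of input order.
#'
#' With no declared primary key only pass 1 applies; with no timestamp column
#' a warning notes the deterministic fallback.
#'
#' @param table Source table name.
#' @param spec The table's `detl_table_spec` (declares columns and the record
#'   identity).
#' @param opts [compile_options()].
#' @return A single-element character vector: the named CTE fragment.
#' @export
build_dedup_subquery <- function(table, spec, opts = compile_options()) {
  stopifnot(is_identifier(table), inherits(spec, "detl_table_spec"))
  cols <- spec$columns$name
  ts <- opts$timestamp_column
  has_ts <- ts %in% cols
  pk <- spec$primary_key
  nonpk <- setdiff(cols, pk)
  dup_cols <- setdiff(nonpk, ts)
  col_list <- paste(cols, collapse = ", ")

  # pass 1: collapse exact duplicates
  if (length(dup_cols) > 0) {
    ord <- if (length(pk) > 0) paste(pk, collapse = ", ") else dup_cols[1]
    stage1 <- sprintf(
      "SELECT %s FROM (SELECT %s, ROW_NUMBER() OVER (PARTITION BY %s ORDER BY %s) AS rn FROM %s) WHERE rn = 1",
      col_list, col_list, paste(dup_cols, collapse = ", "), ord, table)
  } else {
    stage1 <- sprintf("SELECT %s FROM %s", col_list, table)
  }

  # pass 2: resolve conflicts within a record-identity group
  if (length(pk) > 0 && length(nonpk) > 0) {
    tie <- setdiff(nonpk, ts)
    ord2 <- if (has_ts) {
      c(paste(ts, "DESC"), tie)
    } else {
      warning(sprintf(
        "table '%s' declares a primary key but no '%s' column; conflicting records resolve by lexicographic order of the non-key columns",
        table, ts), call. = FALSE)
      tie
    }
    ord2 <- ord2[nzchar(ord2)]
    if (length(ord2) == 0) ord2 <- pk[1]
    stage2 <- sprintf(
      "SELECT %s FROM (SELECT %s, ROW_NUMBER() OVER (PARTITION BY %s ORDER BY %s) AS rn FROM (%s)) WHERE rn = 1",
      col_list, col_list, paste(pk, collapse = ", "),
      paste(ord2, collapse = ", "), stage1)
  } else {
    stage2 <- stage1
  }
  sprintf("%s__dedup AS (%s)", table, stage2)
}

rule_map <- function(rule) {
  stopifnot(inherits(rule, "detl_rule"))
  r <- rule$rows
  list(
    primary = r[r$map_type %in% "PRIMARY", ],
    joins   = r[r$map_type %in% JOIN_MAP_TYPES, ],
    where   = r[r$map_type %in% "WHERE", ],
    values  = r[r$map_type %in% "VALUE", ],
    custom  = r[r$map_type %in% "CUSTOM", ]
  )
}

#' Compile one rule to an INSERT ... SELECT statement
#'
#' The statement inserts into the rule's single target table the columns named
#' by its VALUE rows (in `map_order`), selecting the corresponding
#' `source_value` expressions verbatim, from the de-duplicated primary table
#' joined (in `map_order`) with each JOIN-family table on its `source_value`
#' condition, filtered by the WHERE row's condition when present.  The literal
#' `NULL` in a `source_value` emits the SQL NULL token.  Every source table
#' referenced by an expression must be introduced by the PRIMARY row or a
#' JOIN-family row.
#'
#' @param rule A `detl_rule` (see [get_rule()]); must be structurally valid
#'   per [validate_ruleset()].  CUSTOM rules are dispatched to
#'   [compile_custom()].
#' @param opts [compile_options()].
#' @param specs Optional named list of `detl_table_spec` for the source
#'   tables; required for de-duplication (tables without a spec are used raw).
#' @return A `detl_statement`: the SQL text plus rule provenance (rule key,
#'   target table, generation time).
#' @export
compile_rule <- function(rule, opts = compile_options(), specs = NULL) {
  m <- rule_map(rule)
  if (nrow(m$custom) > 0) return(compile_custom(rule))
  if (nrow(m$primary) != 1) {
    stop(sprintf("rule %d: exactly one PRIMARY row required",
                 rule$rows$rule_order[1]), call. = FALSE)
  }
  if (nrow(m$values) == 0) {
    stop(sprintf("rule %d: no VALUE rows to populate the target",
                 rule$rows$rule_order[1]), call. = FALSE)
  }
  target_table <- rule$rows$target_table[1]
  if (!is_identifier(target_table)) {
    stop(sprintf("rule %d: invalid target table", rule$rows$rule_order[1]),
         call. = FALSE)
  }

  primary_table <- m$primary$source_table
  if (!is_identifier(primary_table)) {
    stop(sprintf("rule %d: PRIMARY row must name a source table",
                 rule$rows$rule_order[1]), call. = FALSE)
  }
  join_tables <- m$joins$source_table
  known <- c(primary_table, join_tables)

  fragments <- c(m$primary$source_value, m$joins$source_value,
                 m$where$source_value, m$values$source_value)
  for (f in fragments[!is.na(fragments)]) {
    assert_no_statement_separator(f, sprintf("rule %d source_value",
                                             rule$rows$rule_order[1]))
  }
  refs <- unique(unlist(lapply(fragments, referenced_tables)))
  stray <- setdiff(tolower(refs), tolower(known))
  if (length(stray) > 0) {
    stop(sprintf(
      "rule %d references source table(s) absent from PRIMARY/JOIN rows: %s",
      rule$rows$rule_order[1], paste(stray, collapse = ", ")), call. = FALSE)
  }

  # FROM clause over de-duplicated sources; CTEs are aliased back to the
  # original table names so verbatim expressions keep working
  use_dedup <- isTRUE(opts$dedup) && !is.null(specs)
  ctes <- character()
  table_ref <- function(tbl) {
    if (use_dedup && !is.null(specs[[tbl]])) {
      ctes[[tbl]] <<- build_dedup_subquery(tbl, specs[[tbl]], opts)
      sprintf("%s__dedup AS %s", tbl, tbl)
    } else {
      tbl
    }
  }
  from_clause <- sprintf("FROM %s", table_ref(primary_table))
  join_clauses <- character()
  if (nrow(m$joins) > 0) {
    jt <- m$joins[order(m$joins$map_order), ]
    for (i in seq_len(nrow(jt))) {
      if (!is_identifier(jt$source_table[i])) {
        stop(sprintf("rule %d: JOIN row (map_order %d) must name a source table",
                     rule$rows$rule_order[1], jt$map_order[i]), call. = FALSE)
      }
      cond <- jt$source_value[i]
      if (is.na(cond) || !nzchar(cond)) {
        stop(sprintf("rule %d: JOIN row (map_order %d) has no join condition",
                     rule$rows$rule_order[1], jt$map_order[i]), call. = FALSE)
      }
      join_clauses <- c(join_clauses,
                        sprintf("%s %s ON %s", jt$map_type[i],
                                table_ref(jt$source_table[i]), cond))
    }
  }

  vals <- m$values[order(m$values$map_order), ]
  if (any(is.na(vals$source_value) | !nzchar(vals$source_value))) {
    stop(sprintf("rule %d: VALUE row with empty source_value",
                 rule$rows$rule_order[1]), call. = FALSE)
  }
  insert_cols <- paste(vals$target_column, collapse = ", ")
  select_exprs <- paste(vals$source_value, collapse = ",\n       ")

  target_ref <- target_table
  if (opts$dialect == "postgresql" && !is.na(rule$rows$target_schema[1])) {
    target_ref <- paste0(rule$rows$target_schema[1], ".", target_table)
  }

  where_clause <- if (nrow(m$where) == 1) {
    cond <- m$where$source_value[1]
    if (is.na(cond) || !nzchar(cond)) {
      stop(sprintf("rule %d: WHERE row has no condition",
                   rule$rows$rule_order[1]), call. = FALSE)
    }
    sprintf("WHERE %s", cond)
  } else {
    character()
  }

  with_clause <- if (length(ctes) > 0) {
    sprintf("WITH %s", paste(unlist(ctes), collapse = ",\n     "))
  } else {
    character()
  }

  sql <- paste(c(
    with_clause,
    sprintf("INSERT INTO %s (%s)", target_ref, insert_cols),
    sprintf("SELECT%s %s", if (opts$select_distinct) " DISTINCT" else "",
            select_exprs),
    from_clause,
    join_clauses,
    where_clause
  ), collapse = "\n")
  new_statement(sql, rule, target_table)
}

#' Compile a CUSTOM rule
#'
#' A CUSTOM rule carries a complete, verbatim SQL statement in its single
#' row's `source_value`; it is passed through untouched, with the same
#' provenance recording as compiled rules.
#'
#' @param rule A `detl_rule` consisting of one CUSTOM row.
#' @return A `detl_statement`.
#' @export
compile_custom <- function(rule) {
  m <- rule_map(rule)
  if (nrow(m$custom) != 1 || nrow(rule$rows) != nrow(m$custom)) {
    stop(sprintf("rule %d: a CUSTOM rule must consist of exactly one CUSTOM row",
                 rule$rows$rule_order[1]), call. = FALSE)
  }
  sql <- m$custom$source_value[1]
  if (is.na(sql) || !nzchar(trimws(sql))) {
    stop(sprintf("rule %d: CUSTOM rule has empty source_value",
                 rule$rows$rule_order[1]), call. = FALSE)
  }
  new_statement(sql, rule, rule$rows$target_table[1])
}

#' Compile every rule of a rule set
#'
#' Fail-soft batch wrapper: every compilable rule yields a statement (ordered
#' by `rule_order`); per-rule compile errors are collected, not raised.
#'
#' @param rules A `detl_ruleset`.
#' @param opts [compile_options()].
#' @param specs Optional named list of source `detl_table_spec` for
#'   de-duplication.
#' @return A `detl_plan`: `statements` (list of `detl_statement`) and
#'   `errors` (tibble with `rule_order`, `message`).
#' @export
compile_ruleset <- function(rules, opts = compile_options(), specs = NULL) {
  stopifnot(inherits(rules, "detl_ruleset"))
  statements <- list()
  errors <- list()
  for (ord in rule_orders(rules)) {
    st <- tryCatch(compile_rule(get_rule(rules, ord), opts, specs),
                   error = function(e) e)
    if (inherits(st, "error")) {
      errors[[length(errors) + 1L]] <-
        tibble::tibble(rule_order = ord, message = conditionMessage(st))
    } else {
      statements[[length(statements) + 1L]] <- st
    }
  }
  structure(
    list(statements = statements,
         errors = if (length(errors)) do.call(rbind, errors)
                  else tibble::tibble(rule_order = integer(),
                                      message = character())),
    class = "detl_plan"
  )
}

#' @export
print.detl_plan <- function(x, ...) {
  cat(sprintf("<detl_plan> %d statement(s), %d compile error(s)\n",
              length(x$statements), nrow(x$errors)))
  invisible(x)
}
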