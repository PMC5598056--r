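# Declared structure of a source or target table.  Specs drive pre-load
# validation (types, lengths, required flags), staging DDL, and the
# de-duplication CTEs (record identity = declared primary key).

SPEC_TYPES <- c("date", "timestamp", "numeric", "decimal", "integer",
                "text", "varchar")

#' Declare the structure of a source or target table
#'
#' @param name Table name.
#' @param columns A data frame with columns `name`, `type` (one of `date`,
#'   `timestamp`, `numeric`, `decimal`, `integer`, `text`, `varchar`),
#'   and optionally `length`, `precision`, `scale` (numeric, `NA` when not
#'   declared) and `required` (logical, default `FALSE`).
#' @param primary_key Character vector of record-identifier column(s); must be
#'   a subset of `columns$name`.  Used as the record identity for duplicate
#'   collapse and conflict grouping.
#' @param foreign_keys List of foreign keys, each a list with elements
#'   `columns`, `parent_table`, `parent_columns`.
#' @return A `detl_table_spec`.
#' @export
table_spec <- function(name, columns, primary_key = character(),
                       foreign_keys = list()) {
  stopifnot(is_identifier(name), is.data.frame(columns))
  columns <- tibble::as_tibble(columns)
  if (!all(c("name", "type") %in% names(columns))) {
    stop("columns must declare at least 'name' and 'type'", call. = FALSE)
  }
  for (f in c("length", "precision", "scale")) {
    if (!f %in% names(columns)) columns[[f]] <- NA_real_
    columns[[f]] <- as.numeric(columns[[f]])
  }
  if (!"required" %in% names(columns)) columns$required <- FALSE
  columns$required[is.na(columns$required)] <- FALSE
  columns$name <- as.character(columns$name)
  columns$type <- tolower(as.character(columns$type))
  bad <- setdiff(columns$type, SPEC_TYPES)
  if (length(bad) > 0) {
    stop(sprintf("unknown column type(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (!all(primary_key %in% columns$name)) {
    stop("primary_key must be a subset of declared columns", call. = FALSE)
  }
  for (fk in foreign_keys) {
    if (!all(c("columns", "parent_table", "parent_columns") %in% names(fk))) {
      stop("each foreign key needs columns, parent_table, parent_columns",
           call. = FALSE)
    }
  }
  structure(
    list(name = name,
         columns = columns[, c("name", "type", "length", "precision",
                               "scale", "required")],
         primary_key = as.character(primary_key),
         foreign_keys = foreign_keys),
    class = "detl_table_spec"
  )
}

#' @export
print.detl_table_spec <- function(x, ...) {
  cat(sprintf("<detl_table_spec> %s: %d column(s), key (%s)\n",
              x$name, nrow(x$columns),
              paste(x$primary_key, collapse = ", ")))
  invisible(x)
}

spec_to_list <- function(spec) {
  cols <- lapply(seq_len(nrow(spec$columns)), function(i) {
    r <- as.list(spec$columns[i, ])
    r <- r[!vapply(r, function(v) is.na(v) || identical(v, FALSE), logical(1)) |
             names(r) %in% c("name", "type")]
    r
  })
  out <- list(columns = cols)
  if (length(spec$primary_key) > 0) out$primary_key <- as.list(spec$primary_key)
  if (length(spec$foreign_keys) > 0) {
    out$foreign_keys <- lapply(spec$foreign_keys, function(fk) {
      list(columns = as.list(fk$columns),
           parent_table = fk$parent_table,
           parent_columns = as.list(fk$parent_columns))
    })
  }
  out
}

#' Write a schema-spec config file
#'
#' Serializes a list of table specs to a YAML file with one section per table,
#' the format read back by [read_schema_spec()].
#'
#' @param specs A named list of `detl_table_spec` (names are table names), or
#'   a single spec.
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
write_schema_spec <- function(specs, path) {
  if (inherits(specs, "detl_table_spec")) specs <- list(specs)
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  yaml::write_yaml(lapply(specs, spec_to_list), path)
  invisible(path)
}

#' Read a schema-spec config file
#'
#' @param path YAML file written by [write_schema_spec()] (or authored by
#'   hand): a mapping of table name to `columns` / `primary_key` /
#'   `foreign_keys`.
#' @return Named list of `detl_table_spec`.
#' @export
read_schema_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(names(raw), function(nm) {
    tb <- raw[[nm]]
    cols <- do.call(rbind, lapply(tb$columns, function(cl) {
      tibble::tibble(
        name = cl$name, type = cl$type,
        length = as.numeric(cl$length %||% NA),
        precision = as.numeric(cl$precision %||% NA),
        scale = as.numeric(cl$scale %||% NA),
        required = isTRUE(cl$required)
      )
    }))
    fks <- lapply(tb$foreign_keys %||% list(), function(fk) {
      list(columns = unlist(fk$columns),
           parent_table = fk$parent_table,
           parent_columns = unlist(fk$parent_columns))
    })
    table_spec(nm, cols, primary_key = unlist(tb$primary_key %||% list()),
               foreign_keys = fks)
  })
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  specs
}

# SQLite storage class for a declared type
sql_type_for <- function(type) {
  switch(type,
         integer = "INTEGER",
         numeric = , decimal = "REAL",
         "TEXT")
}
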