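# The rule language: 12-attribute mapping rules stored one rule set per CSV
# file.  A rule is an ordered group of rows sharing one rule_order; each rule
# compiles to exactly one INSERT ... SELECT statement against a single target
# table.

RULE_ATTRIBUTES <- c(
  "rule_order", "rule_description",
  "target_database", "target_schema", "target_table", "target_column",
  "map_type", "map_order",
  "source_database", "source_schema", "source_table", "source_value"
)

MAP_TYPES <- c("PRIMARY", "JOIN", "LEFT JOIN", "RIGHT JOIN", "FULL JOIN",
               "WHERE", "VALUE", "CUSTOM")
JOIN_MAP_TYPES <- c("JOIN", "LEFT JOIN", "RIGHT JOIN", "FULL JOIN")

canonical_header <- function(x) {
  x <- tolower(trimws(x))
  gsub("[ .]+", "_", x)
}

new_ruleset <- function(rows, data_source_id, source_file = NA_character_) {
  stopifnot(is.data.frame(rows))
  rows <- tibble::as_tibble(rows)[, RULE_ATTRIBUTES]
  rows$rule_order <- as.integer(rows$rule_order)
  rows$map_order <- as.integer(rows$map_order)
  for (col in setdiff(RULE_ATTRIBUTES, c("rule_order", "map_order"))) {
    rows[[col]] <- as.character(rows[[col]])
  }
  rows <- rows[order(rows$rule_order, rows$map_order, method = "radix"), ]
  structure(
    list(rows = rows,
         data_source_id = as.character(data_source_id),
         source_file = source_file),
    class = "detl_ruleset"
  )
}

#' Parse a rule file
#'
#' Reads one CSV rule file (all mapping rules for a single data source) into a
#' rule set.  The header must name exactly the twelve rule attributes
#' (`rule_order`, `rule_description`, `target_database`, `target_schema`,
#' `target_table`, `target_column`, `map_type`, `map_order`,
#' `source_database`, `source_schema`, `source_table`, `source_value`);
#' matching is case- and space-insensitive and any column order is accepted.
#' Rows are grouped by `rule_order` and sorted by `map_order`, so the physical
#' row order of the file does not matter.  Empty cells become `NA`; the
#' literal text `NULL` in `source_value` is preserved verbatim, since it is a
#' meaningful SQL token.
#'
#' @param rule_csv Path to the rule CSV file.
#' @param data_source_id Identifier of the dataset this rule set applies to.
#'   Together with `rule_order` and `rule_description` it forms the composite
#'   key that uniquely identifies a rule.
#' @return A `detl_ruleset`: the parsed rows plus the data source id and the
#'   source file path.
#' @seealso [validate_ruleset()], [write_rules()], [compile_ruleset()]
#' @export
parse_rules <- function(rule_csv, data_source_id) {
  if (!file.exists(rule_csv)) {
    stop(sprintf("rule file not found: %s", rule_csv), call. = FALSE)
  }
  raw <- readr::read_csv(rule_csv,
                         col_types = readr::cols(.default = readr::col_character()),
                         na = "", progress = FALSE, show_col_types = FALSE)
  hdr <- canonical_header(names(raw))
  unknown <- setdiff(hdr, RULE_ATTRIBUTES)
  if (length(unknown) > 0) {
    stop(sprintf("unknown rule attribute column(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(RULE_ATTRIBUTES, hdr)
  if (length(missing) > 0) {
    stop(sprintf("missing rule attribute column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(hdr)) {
    stop(sprintf("duplicated rule attribute column(s): %s",
                 paste(unique(hdr[duplicated(hdr)]), collapse = ", ")),
         call. = FALSE)
  }
  names(raw) <- hdr
  raw <- raw[, RULE_ATTRIBUTES]

  for (col in c("rule_order", "map_order")) {
    x <- raw[[col]]
    bad <- which(!is.na(x) & !grepl("^-?[0-9]+$", trimws(x)))
    if (length(bad) > 0) {
      stop(sprintf("non-integer %s at data line %d of %s",
                   col, bad[1], rule_csv), call. = FALSE)
    }
    bad_na <- which(is.na(x))
    if (length(bad_na) > 0) {
      stop(sprintf("missing %s at data line %d of %s",
                   col, bad_na[1], rule_csv), call. = FALSE)
    }
    raw[[col]] <- as.integer(trimws(x))
  }
  # canonical map-type spelling: uppercase, internal whitespace collapsed;
  # unrecognized tokens are preserved for validate_ruleset() to flag
  raw$map_type <- ifelse(is.na(raw$map_type), raw$map_type,
                         toupper(squish(raw$map_type)))
  new_ruleset(raw, data_source_id, source_file = rule_csv)
}

#' List rule identifiers in a rule set
#' @param rules A `detl_ruleset`.
#' @return Integer vector of distinct `rule_order` values, ascending.
#' @export
rule_orders <- function(rules) {
  stopifnot(inherits(rules, "detl_ruleset"))
  sort(unique(rules$rows$rule_order))
}

#' Extract one rule from a rule set
#' @param rules A `detl_ruleset`.
#' @param rule_order Integer rule identifier.
#' @return A `detl_rule`: the rule's rows (sorted by `map_order`) plus the
#'   data source id.
#' @export
get_rule <- function(rules, rule_order) {
  stopifnot(inherits(rules, "detl_ruleset"))
  rows <- rules$rows[rules$rows$rule_order == rule_order, ]
  if (nrow(rows) == 0) {
    stop(sprintf("no rule with rule_order %s in rule set", rule_order),
         call. = FALSE)
  }
  structure(list(rows = rows, data_source_id = rules$data_source_id),
            class = "detl_rule")
}

#' Check a rule set against the structural constraints of the rule language
#'
#' Each rule must have exactly one PRIMARY row and it must come first (lowest
#' `map_order`); at most one WHERE row; all rows naming one target table;
#' unique `map_order` values; a uniform `rule_description` of at most 255
#' characters; recognized map types; populated `target_column` on VALUE rows;
#' and a CUSTOM row, when present, must be the rule's only row.  Optionally,
#' rules targeting columns on an exclusion list (e.g. direct identifiers
#' barred from a HIPAA limited data set) are flagged.
#'
#' @param rules A `detl_ruleset`.
#' @param excluded_columns Optional character vector of target columns no rule
#'   may populate.
#' @return A tibble of issues (zero rows when every rule is well-formed) with
#'   columns `rule_id` (the violated constraint), `severity`, `table`,
#'   `column`, `line_number`, `rule_order`, `message`.
#' @export
validate_ruleset <- function(rules, excluded_columns = NULL) {
  stopifnot(inherits(rules, "detl_ruleset"))
  issues <- list()
  add <- function(constraint, rule_order, message, table = NA_character_,
                  column = NA_character_) {
    issues[[length(issues) + 1L]] <<-
      issue_row(constraint, "ERROR", table = table, column = column,
                rule_order = rule_order, message = message)
  }
  for (ord in rule_orders(rules)) {
    r <- rules$rows[rules$rows$rule_order == ord, ]
    tgt <- unique(r$target_table[!is.na(r$target_table)])
    tgt1 <- if (length(tgt) >= 1) tgt[1] else NA_character_

    desc <- unique(r$rule_description[!is.na(r$rule_description)])
    if (length(desc) > 1) {
      add("nonuniform_rule_description", ord, paste(
        "all rows of a rule must share one rule_description;",
        "distinct descriptions break the composite rule key"), tgt1)
    }
    if (any(nchar(r$rule_description) > 255, na.rm = TRUE)) {
      add("rule_description_too_long", ord,
          "rule_description exceeds the maximum length of 255 characters",
          tgt1)
    }
    unknown <- setdiff(unique(r$map_type), c(MAP_TYPES, NA))
    if (length(unknown) > 0 || anyNA(r$map_type)) {
      add("unknown_map_type", ord,
          sprintf("unrecognized map_type value(s): %s",
                  paste(unknown, collapse = ", ")), tgt1)
    }
    if (anyDuplicated(r$map_order)) {
      add("duplicate_map_order", ord,
          "map_order values must be unique within a rule", tgt1)
    }
    if (length(tgt) > 1) {
      add("multiple_target_tables", ord,
          sprintf("a rule can only populate one target table; found: %s",
                  paste(tgt, collapse = ", ")), tgt1)
    }
    is_custom <- r$map_type %in% "CUSTOM"
    if (any(is_custom)) {
      if (!all(is_custom)) {
        add("custom_rule_mixed", ord, paste(
          "a rule containing a CUSTOM row may contain no other map types"),
          tgt1)
      }
      next  # PRIMARY/WHERE cardinality does not apply to custom rules
    }
    n_primary <- sum(r$map_type %in% "PRIMARY")
    if (n_primary != 1L) {
      add("primary_row_cardinality", ord,
          sprintf("a rule must have exactly one PRIMARY row (found %d)",
                  n_primary), tgt1)
    } else if (r$map_type[which.min(r$map_order)] != "PRIMARY") {
      add("primary_row_not_first", ord,
          "the PRIMARY row must be the first row of the rule", tgt1)
    }
    if (sum(r$map_type %in% "WHERE") > 1L) {
      add("where_row_cardinality", ord,
          "each rule can only have one WHERE clause", tgt1)
    }
    val <- r[r$map_type %in% "VALUE", ]
    if (nrow(val) > 0 && anyNA(val$target_column)) {
      add("value_row_missing_target_column", ord,
          "VALUE rows must populate target_column", tgt1)
    }
    if (!is.null(excluded_columns) && nrow(val) > 0) {
      hit <- intersect(tolower(val$target_column), tolower(excluded_columns))
      for (h in hit) {
        add("excluded_target_column", ord,
            sprintf("rule populates excluded column '%s'", h), tgt1, h)
      }
    }
  }
  bind_issues(issues)
}

#' Write a rule set back to CSV
#'
#' Inverse of [parse_rules()]: emits an RFC 4180 CSV with the twelve canonical
#' attribute columns, such that re-parsing the file reproduces the rule set
#' field for field.
#'
#' @param rules A `detl_ruleset`.
#' @param out Output file path.
#' @return The output path, invisibly.
#' @export
write_rules <- function(rules, out) {
  stopifnot(inherits(rules, "detl_ruleset"))
  readr::write_csv(rules$rows, out, na = "")
  invisible(out)
}

#' @export
print.detl_ruleset <- function(x, ...) {
  orders <- rule_orders(x)
  cat(sprintf("<detl_ruleset> data source '%s': %d rule(s), %d row(s)\n",
              x$data_source_id, length(orders), nrow(x$rows)))
  for (ord in orders) {
    r <- x$rows[x$rows$rule_order == ord, ]
    cat(sprintf("  rule %d -> %s (%d rows): %s\n", ord,
                r$target_table[1] %||% "?", nrow(r),
                r$rule_description[1]))
  }
  invisible(x)
}

#' @export
print.detl_rule <- function(x, ...) {
  cat(sprintf("<detl_rule> rule %d -> %s (%d rows)\n",
              x$rows$rule_order[1], x$rows$target_table[1], nrow(x$rows)))
  invisible(x)
}
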