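# Shared fixtures: the worked claims-to-care-site rule as a CSV transcription
# (prose-style headers, to exercise case/space-insensitive matching), and a
# generator of random well-formed rule sets for round-trip properties.

care_site_rule_csv <- function(path = tempfile(fileext = ".csv")) {
  desc <- "Medical_claims to Care_site"
  rows <- list(
    c("1", desc, "", "", "Care_site", "", "PRIMARY", "1", "", "", "Medical_claims",
      "medical_claims.billing_provider_id, medical_claims.place_of_service_code, provider.provider_organization_type"),
    c("1", desc, "", "", "Care_site", "", "JOIN", "2", "", "", "provider",
      "medical_claims.billing_provider_id = provider.provider_id"),
    c("1", desc, "", "", "Care_site", "", "WHERE", "3", "", "", "",
      "provider.provider_organization_type in ('1', '2')"),
    c("1", desc, "", "", "Care_site", "care_site_source_value", "VALUE", "4", "", "", "",
      "medical_claims.billing_provider_id || '-' || medical_claims.place_of_service_code || '-' || provider.provider_organization_type"),
    c("1", desc, "", "", "Care_site", "organization_source_value", "VALUE", "5", "", "", "", "NULL"),
    c("1", desc, "", "", "Care_site", "place_of_service_source_value", "VALUE", "6", "", "", "",
      "medical_claims.place_of_service_code"),
    c("1", desc, "", "", "Care_site", "care_site_address_1", "VALUE", "7", "", "", "",
      "provider.provider_address_first_line"),
    c("1", desc, "", "", "Care_site", "care_site_address_2", "VALUE", "8", "", "", "",
      "provider.provider_street"),
    c("1", desc, "", "", "Care_site", "care_site_city", "VALUE", "9", "", "", "",
      "provider.provider_city"),
    c("1", desc, "", "", "Care_site", "care_site_state", "VALUE", "10", "", "", "",
      "provider.provider_state"),
    c("1", desc, "", "", "Care_site", "care_site_zip", "VALUE", "11", "", "", "",
      "provider.provider_zip"),
    c("1", desc, "", "", "Care_site", "care_site_county", "VALUE", "12", "", "", "", "NULL"))
  header <- c("Rule Order", "Rule Description", "Target Database",
              "Target Schema", "Target Table", "Target Column", "Map Type",
              "Map Order", "Source Database", "Source Schema", "Source Table",
              "Source Value")
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- header
  readr::write_csv(df, path, na = "")
  path
}

# build a ruleset tibble row (canonical column order)
rule_row <- function(rule_order, rule_description, target_table,
                     target_column, map_type, map_order, source_table,
                     source_value, target_schema = NA_character_) {
  tibble::tibble(
    rule_order = as.integer(rule_order), rule_description = rule_description,
    target_database = NA_character_, target_schema = target_schema,
    target_table = target_table, target_column = target_column,
    map_type = map_type, map_order = as.integer(map_order),
    source_database = NA_character_, source_schema = NA_character_,
    source_table = source_table, source_value = source_value)
}

ruleset_from_rows <- function(rows, data_source_id = "test") {
  f <- tempfile(fileext = ".csv")
  readr::write_csv(rows, f, na = "")
  parse_rules(f, data_source_id)
}

# random well-formed rule set (round-trip property fodder); descriptions
# include CSV-hostile characters to exercise RFC 4180 quoting
random_ruleset <- function(seed) {
  set.seed(seed)
  n_rules <- sample(1:5, 1)
  rows <- list()
  for (ord in seq_len(n_rules)) {
    tgt <- sprintf("target_%d", sample(1:9, 1))
    desc <- paste0("rule ", ord, sample(c("", ", with a comma",
                                          " and \"quotes\"",
                                          " and\nnewline"), 1))
    mo <- 1L
    add <- function(...) rows[[length(rows) + 1L]] <<- rule_row(...)
    add(ord, desc, tgt, NA, "PRIMARY", mo, "src", "src.id")
    mo <- mo + 1L
    for (j in seq_len(sample(0:2, 1))) {
      add(ord, desc, tgt, NA, sample(c("JOIN", "LEFT JOIN", "RIGHT JOIN",
                                       "FULL JOIN"), 1), mo,
          sprintf("aux_%d", j), sprintf("src.k = aux_%d.k", j))
      mo <- mo + 1L
    }
    if (stats::runif(1) < 0.5) {
      add(ord, desc, tgt, NA, "WHERE", mo, NA, "src.flag = 'Y'")
      mo <- mo + 1L
    }
    for (j in seq_len(sample(1:6, 1))) {
      add(ord, desc, tgt, sprintf("col_%d", j), "VALUE", mo,
          NA, sample(c(sprintf("src.c%d", j), "NULL", "'lit'"), 1))
      mo <- mo + 1L
    }
  }
  ruleset_from_rows(do.call(rbind, rows),
                    data_source_id = sprintf("ds-%d", seed))
}

# canonical form for multiset comparison of relational results
canon_rows <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df[] <- lapply(df, as.character)
  if (nrow(df) > 1) {
    df <- df[do.call(order, c(unname(df), list(method = "radix"))), ,
             drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

expect_same_multiset <- function(got, want) {
  expect_equal(canon_rows(got), canon_rows(want))
}
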