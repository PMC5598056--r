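test_that("clean generation validates cleanly and is byte-deterministic", {
  cfg <- generator_config(seed = 5, n_claims = 50, n_providers = 10,
                          n_persons = 50)
  d1 <- tempfile(); d2 <- tempfile()
  g1 <- generate_extracts(cfg, d1)
  g2 <- generate_extracts(cfg, d2)
  for (nm in c("medical_claims", "provider", "demographic",
               "source_to_concept_map", "schema")) {
    expect_identical(readLines(g1$files[[nm]]), readLines(g2$files[[nm]]),
                     label = sprintf("%s deterministic", nm))
  }
  # all rates zero: no injections recorded, no validator findings
  expect_true(all(vapply(g1$ledger, nrow, integer(1)) == 0L))
  for (nm in c("medical_claims", "provider", "demographic",
               "source_to_concept_map")) {
    iss <- validate_table(g1$files[[nm]], g1$specs[[nm]], mode = "strict")
    expect_equal(nrow(iss), 0L, label = sprintf("%s clean", nm))
  }
  orphans <- check_orphan_foreign_keys(
    g1$files[["medical_claims"]], g1$files[["provider"]],
    g1$specs$medical_claims$foreign_keys[[1]])
  expect_equal(nrow(orphans), 0L)
})

test_that("the emitted schema spec round-trips through YAML", {
  d <- tempfile()
  g <- generate_extracts(generator_config(seed = 2, n_claims = 10,
                                          n_providers = 5, n_persons = 5), d)
  specs <- read_schema_spec(g$files[["schema"]])
  expect_setequal(names(specs), names(g$specs))
  for (nm in names(specs)) {
    expect_equal(specs[[nm]]$columns, g$specs[[nm]]$columns,
                 label = sprintf("%s columns", nm))
    expect_equal(specs[[nm]]$primary_key, g$specs[[nm]]$primary_key)
  }
  expect_equal(specs$medical_claims$foreign_keys[[1]]$parent_table,
               "provider")
})

test_that("strict validation findings equal the injection ledger exactly", {
  cfg <- generator_config(seed = 11, n_claims = 300, n_providers = 60,
                          n_persons = 150, invalid_date_rate = 0.04,
                          invalid_numeric_rate = 0.03, overlength_rate = 0.05,
                          missing_required_rate = 0.02, orphan_fk_rate = 0.03)
  d <- tempfile()
  g <- generate_extracts(cfg, d)
  ledger <- g$ledger
  # at these rates every class must actually be drawn
  for (cl in c("invalid_date", "invalid_numeric", "overlength",
               "missing_required", "orphan_fk")) {
    expect_gt(nrow(ledger[[cl]]), 0L, label = cl)
  }
  issues <- list()
  for (nm in c("medical_claims", "provider", "demographic")) {
    issues[[nm]] <- validate_table(g$files[[nm]], g$specs[[nm]],
                                   mode = "strict")
  }
  fk_issues <- check_orphan_foreign_keys(
    g$files[["medical_claims"]], g$files[["provider"]],
    g$specs$medical_claims$foreign_keys[[1]],
    child_table = "medical_claims")
  all_issues <- rbind(do.call(rbind, issues), fk_issues)
  key <- function(df, tbl_col = "table", ln = "line_number",
                  col = "column") {
    sort(paste(df[[tbl_col]], df[[ln]], df[[col]]))
  }
  want <- lapply(c(invalid_date = "invalid_date",
                   invalid_numeric = "invalid_numeric",
                   overlength = "overlength",
                   missing_required = "missing_required",
                   orphan_fk = "orphan_fk"),
                 function(cl) key(ledger[[cl]]))
  got <- lapply(names(want), function(cl) {
    key(all_issues[all_issues$rule_id == cl, ])
  })
  names(got) <- names(want)
  expect_equal(got, want)  # exact: no false positives or negatives
  # and nothing else fired
  expect_setequal(unique(all_issues$rule_id), names(want))
})

test_that("reference rules are well-formed and map race codes via the concept map", {
  rs <- reference_rules()
  expect_equal(rule_orders(rs), c(1L, 2L))
  expect_equal(nrow(get_rule(rs, 1)$rows), 12L)
  r2 <- get_rule(rs, 2)
  expect_gte(length(unique(stats::na.omit(r2$rows$source_table))), 2L)
  expect_true("source_to_concept_map" %in% r2$rows$source_table)
  expect_equal(nrow(validate_ruleset(rs)), 0L)
})

test_that("target schema covers the worked rule and enforces exclusions", {
  targets <- mini_target_schema()
  rs <- reference_rules()
  want_cols <- get_rule(rs, 1)$rows$target_column
  want_cols <- want_cols[!is.na(want_cols)]
  expect_length(want_cols, 9L)
  expect_true(all(want_cols %in% targets$care_site$columns$name))
  excl <- attr(targets, "excluded_columns")
  expect_true(length(excl) > 0)
  bad <- rbind(
    rule_row(9, "bad", "person", NA, "PRIMARY", 1, "demographic",
             "demographic.person_id"),
    rule_row(9, "bad", "person", excl[1], "VALUE", 2, NA,
             "demographic.person_id"))
  iss <- validate_ruleset(ruleset_from_rows(bad), excluded_columns = excl)
  expect_true("excluded_target_column" %in% iss$rule_id)

  # person spec round-trips through staging
  con <- etl_connect()
  on.exit(DBI::dbDisconnect(con))
  df <- tibble::tibble(person_source_value = "PE1", year_of_birth = "1970",
                       gender_source_value = "F", race_concept_id = "8527",
                       race_source_value = "2106-3",
                       ethnicity_concept_id = "")
  f <- tempfile(fileext = ".csv")
  readr::write_csv(df, f, na = "")
  st <- stage_csv(con, f, targets$person)
  expect_equal(st$row_count, 1L)
  back <- unload_staged(con, "person")
  expect_equal(back$year_of_birth, 1970L)
  expect_true(is.na(back$ethnicity_concept_id))
})

test_that("dedup of injected duplicates and conflicts matches the ledger", {
  cfg <- generator_config(seed = 13, n_claims = 200, n_providers = 30,
                          n_persons = 50, dup_rate = 0.1,
                          conflict_rate = 0.05)
  d <- tempfile()
  g <- generate_extracts(cfg, d)
  led <- g$ledger
  expect_gt(nrow(led$duplicates[led$duplicates$table == "medical_claims", ]), 0L)
  expect_gt(nrow(led$conflicts[led$conflicts$table == "medical_claims", ]), 0L)

  con <- etl_connect()
  on.exit(DBI::dbDisconnect(con))
  stage_csv(con, g$files[["medical_claims"]], g$specs$medical_claims)
  cte <- build_dedup_subquery("medical_claims", g$specs$medical_claims,
                              compile_options())
  out <- DBI::dbGetQuery(con, paste0(
    "WITH ", cte, " SELECT * FROM medical_claims__dedup"))

  raw <- readr::read_csv(g$files[["medical_claims"]],
                         col_types = readr::cols(.default = "c"),
                         show_col_types = FALSE)
  n_base <- cfg$n_claims
  dups <- led$duplicates[led$duplicates$table == "medical_claims", ]
  confs <- led$conflicts[led$conflicts$table == "medical_claims", ]
  # every base record survives exactly once: appended duplicates collapse,
  # conflict pairs merge
  expect_equal(nrow(out), n_base)
  expect_false(any(raw$claim_id[dups$dup_line] %in% out$claim_id))
  # each conflict group resolves to the row with the later load timestamp
  for (i in seq_len(nrow(confs))) {
    winner <- raw[confs$winner_line[i], ]
    got <- out[out$claim_id == confs$key[i], ]
    expect_equal(got$place_of_service_code, winner$place_of_service_code)
    expect_equal(got$etl_timestamp, winner$etl_timestamp)
  }
  # agreement with the independent group-by/arg-max oracle
  want <- oracle_dedup(as.data.frame(raw), "claim_id")
  want$paid_amount <- as.numeric(want$paid_amount)
  out$paid_amount <- as.numeric(out$paid_amount)
  expect_same_multiset(out, want)
})
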