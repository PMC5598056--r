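test_that("the worked rule compiles to the expected INSERT...SELECT", {
  rs <- parse_rules(care_site_rule_csv(), "claims-src")
  st <- compile_rule(get_rule(rs, 1), compile_options(dedup = FALSE))
  expect_s3_class(st, "detl_statement")
  sql <- st$sql_text
  expect_match(sql, "^INSERT INTO Care_site \\(care_site_source_value, organization_source_value, place_of_service_source_value, care_site_address_1, care_site_address_2, care_site_city, care_site_state, care_site_zip, care_site_county\\)")
  expect_match(sql, "FROM Medical_claims", fixed = TRUE)
  expect_match(sql,
               "JOIN provider ON medical_claims.billing_provider_id = provider.provider_id",
               fixed = TRUE)
  expect_match(sql, "WHERE provider.provider_organization_type in ('1', '2')",
               fixed = TRUE)
  # the 9 VALUE expressions appear in map_order; NULL emitted as the SQL token
  select_part <- sub(".*SELECT", "SELECT", sql)
  exprs <- strsplit(sub("\nFROM.*", "", sub("SELECT ", "", select_part)),
                    ",\n\\s*")[[1]]
  expect_length(exprs, 9L)
  expect_equal(trimws(exprs[2]), "NULL")
  expect_equal(trimws(exprs[9]), "NULL")
  expect_equal(st$rule_order, 1L)
  expect_equal(st$data_source_id, "claims-src")
  expect_equal(st$target_table, "Care_site")
})

test_that("a minimal rule compiles to INSERT INTO t(c) SELECT s.col FROM s", {
  rows <- rbind(rule_row(1, "min", "t", NA, "PRIMARY", 1, "s", "s.id"),
                rule_row(1, "min", "t", "c", "VALUE", 2, NA, "s.col"))
  st <- compile_rule(get_rule(ruleset_from_rows(rows), 1),
                     compile_options(dedup = FALSE))
  expect_equal(st$sql_text, "INSERT INTO t (c)\nSELECT s.col\nFROM s")
})

test_that("expressions referencing undeclared source tables are rejected", {
  rows <- rbind(rule_row(1, "r", "t", NA, "PRIMARY", 1, "s", "s.id"),
                rule_row(1, "r", "t", "c", "VALUE", 2, NA, "mystery.col"))
  expect_error(compile_rule(get_rule(ruleset_from_rows(rows), 1)),
               "mystery")
  # table names inside string literals must not count as references
  rows2 <- rbind(rule_row(1, "r", "t", NA, "PRIMARY", 1, "s", "s.id"),
                 rule_row(1, "r", "t", "c", "VALUE", 2, NA,
                          "'mystery.col is just text'"))
  expect_silent(compile_rule(get_rule(ruleset_from_rows(rows2), 1),
                             compile_options(dedup = FALSE)))
})

test_that("statement separators in rule fragments are rejected", {
  rows <- rbind(rule_row(1, "r", "t", NA, "PRIMARY", 1, "s", "s.id"),
                rule_row(1, "r", "t", "c", "VALUE", 2, NA,
                         "s.col; DROP TABLE s"))
  expect_error(compile_rule(get_rule(ruleset_from_rows(rows), 1)),
               "statement separator")
  # a quoted semicolon is data, not a separator
  rows2 <- rbind(rule_row(1, "r", "t", NA, "PRIMARY", 1, "s", "s.id"),
                 rule_row(1, "r", "t", "c", "VALUE", 2, NA, "';'"))
  expect_silent(compile_rule(get_rule(ruleset_from_rows(rows2), 1),
                             compile_options(dedup = FALSE)))
})

test_that("custom rules pass through verbatim and reject empty statements", {
  rows <- rule_row(5, "custom load", "t", NA, "CUSTOM", 1, NA,
                   "INSERT INTO t SELECT 1")
  st <- compile_rule(get_rule(ruleset_from_rows(rows), 5))
  expect_equal(st$sql_text, "INSERT INTO t SELECT 1")
  expect_equal(st$rule_order, 5L)

  empty <- rule_row(6, "bad custom", "t", NA, "CUSTOM", 1, NA, NA)
  expect_error(compile_rule(get_rule(ruleset_from_rows(empty), 6)),
               "empty source_value")

  # executing the pass-through affects the target exactly like running it
  # by hand
  con <- etl_connect()
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con, "CREATE TABLE t (x INTEGER)")
  DBI::dbExecute(con, "CREATE TABLE t_manual (x INTEGER)")
  execute_statements(con, list(st))
  DBI::dbExecute(con, "INSERT INTO t_manual SELECT 1")
  expect_same_multiset(DBI::dbGetQuery(con, "SELECT * FROM t"),
                       DBI::dbGetQuery(con, "SELECT * FROM t_manual"))
})

test_that("dedup subquery collapses duplicates and resolves conflicts", {
  spec <- table_spec("src", tibble::tibble(
    name = c("id", "city", "val", "etl_timestamp"),
    type = c("varchar", "varchar", "varchar", "timestamp"),
    length = NA, precision = NA, scale = NA,
    required = FALSE), primary_key = "id")
  con <- etl_connect()
  on.exit(DBI::dbDisconnect(con))
  df <- data.frame(
    id   = c("r1", "r2", "r3", "r3", "r4"),
    city = c("Aurora", "Aurora", "Denver", "Boulder", "Golden"),
    val  = c("v", "v", "x", "x", "y"),
    etl_timestamp = c("2017-01-01 00:00:01", "2017-01-01 00:00:02",
                      "2017-01-01 00:00:01", "2017-01-02 00:00:00",
                      "2017-01-01 00:00:01"),
    stringsAsFactors = FALSE)
  DBI::dbWriteTable(con, "src", df)
  cte <- build_dedup_subquery("src", spec, compile_options())
  out <- DBI::dbGetQuery(con, paste0("WITH ", cte,
                                     " SELECT * FROM src__dedup"))
  # r1/r2 are exact duplicates (ts is load metadata): smallest id survives;
  # r3's conflict resolves to the later timestamp (Boulder)
  expect_equal(sort(out$id), c("r1", "r3", "r4"))
  expect_equal(out$city[out$id == "r3"], "Boulder")
  expect_false("r2" %in% out$id)

  # idempotence: de-duplicating the de-duplicated output changes nothing
  DBI::dbWriteTable(con, "src2", out, overwrite = TRUE)
  cte2 <- build_dedup_subquery("src2", spec, compile_options())
  out2 <- DBI::dbGetQuery(con, paste0("WITH ", cte2,
                                      " SELECT * FROM src2__dedup"))
  expect_same_multiset(out2, out)
})

test_that("conflict fallback without a timestamp column is deterministic", {
  spec <- table_spec("src", tibble::tibble(
    name = c("id", "city"), type = "varchar", length = NA,
    precision = NA, scale = NA, required = FALSE), primary_key = "id")
  expect_warning(cte <- build_dedup_subquery("src", spec, compile_options()),
                 "lexicographic")
  con <- etl_connect()
  on.exit(DBI::dbDisconnect(con))
  for (perm in list(1:2, 2:1)) {
    df <- data.frame(id = c("r1", "r1"), city = c("Boulder", "Aurora"),
                     stringsAsFactors = FALSE)[perm, ]
    DBI::dbWriteTable(con, "src", df, overwrite = TRUE)
    out <- DBI::dbGetQuery(con, paste0("WITH ", cte,
                                       " SELECT * FROM src__dedup"))
    expect_equal(out$city, "Aurora")  # sorts first, input order irrelevant
  }
})

test_that("compiled statements agree with the in-memory relational oracle", {
  con <- etl_connect()
  on.exit(DBI::dbDisconnect(con))
  for (seed in 1:25) {
    res <- run_instance(random_instance(seed), con)
    expect_same_multiset(res$engine, res$oracle)
  }
})

test_that("column/expression alignment holds under sentinel values", {
  # each target column must receive exactly its own VALUE expression
  rows <- rbind(
    rule_row(1, "align", "tt", NA, "PRIMARY", 1, "s", "s.id"),
    rule_row(1, "align", "tt", "c3", "VALUE", 2, NA, "'sent3'"),
    rule_row(1, "align", "tt", "c1", "VALUE", 3, NA, "'sent1'"),
    rule_row(1, "align", "tt", "c2", "VALUE", 4, NA, "'sent2'"))
  con <- etl_connect()
  on.exit(DBI::dbDisconnect(con))
  DBI::dbWriteTable(con, "s", data.frame(id = "x"))
  DBI::dbExecute(con, "CREATE TABLE tt (c1 TEXT, c2 TEXT, c3 TEXT)")
  st <- compile_rule(get_rule(ruleset_from_rows(rows), 1),
                     compile_options(dedup = FALSE))
  DBI::dbExecute(con, st$sql_text)
  got <- DBI::dbGetQuery(con, "SELECT c1, c2, c3 FROM tt")
  expect_equal(unlist(got, use.names = FALSE), c("sent1", "sent2", "sent3"))
})

test_that("deleting the WHERE row can only enlarge the output", {
  for (seed in c(11, 12, 13, 14)) {
    inst <- random_instance(seed)
    if (is.null(inst$where)) next
    con <- etl_connect()
    res_with <- run_instance(inst, con)
    inst_no <- inst
    inst_no$where <- NULL
    res_without <- run_instance(inst_no, con)
    DBI::dbDisconnect(con)
    with_keys <- do.call(paste, c(canon_rows(res_with$engine), sep = "\x1f"))
    without_keys <- do.call(paste, c(canon_rows(res_without$engine),
                                     sep = "\x1f"))
    expect_true(all(with_keys %in% without_keys))
    expect_lte(length(with_keys), length(without_keys))
  }
})

test_that("compile_ruleset is fail-soft: one statement per compilable rule", {
  rows <- rbind(
    rule_row(1, "ok1", "t", NA, "PRIMARY", 1, "s", "s.id"),
    rule_row(1, "ok1", "t", "c", "VALUE", 2, NA, "s.a"),
    rule_row(2, "broken", "t", NA, "PRIMARY", 1, "s", "s.id"),
    rule_row(2, "broken", "t", "c", "VALUE", 2, NA, "ghost.a"),
    rule_row(3, "ok2", "t", NA, "PRIMARY", 1, "s", "s.id"),
    rule_row(3, "ok2", "t", "c", "VALUE", 2, NA, "s.b"))
  plan <- compile_ruleset(ruleset_from_rows(rows))
  expect_length(plan$statements, 2L)
  expect_equal(plan$errors$rule_order, 2L)
  expect_match(plan$errors$message, "ghost")
  expect_equal(vapply(plan$statements, function(s) s$rule_order, integer(1)),
               c(1L, 3L))

  # all-valid sets give exactly one statement per rule
  all_ok <- random_ruleset(42)
  plan2 <- compile_ruleset(all_ok, compile_options(dedup = FALSE))
  expect_length(plan2$statements, length(rule_orders(all_ok)))
  expect_equal(nrow(plan2$errors), 0L)
})
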