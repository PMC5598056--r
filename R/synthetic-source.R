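# Reproducible toy claims + clinical extracts with a ground-truth injection
# ledger.  The generator emulates the source tables the reference rules map
# from (medical_claims, provider, demographic, source_to_concept_map) and can
# inject, at configurable rates, the data problems the rest of the toolkit
# exists to handle: full-row duplicates, conflicting records, orphan foreign
# keys, invalid dates and numerics, over-length text, and missing required
# fields.  Every injection is recorded in the ledger so validator and engine
# output can be checked cell-for-cell against ground truth.

GEN_BASE_TS <- "2017-01-01 00:00:00"
GEN_CONFLICT_TS <- "2017-01-02 00:00:00"

HL7_RACE_CODES <- c("1002-5", "2028-9", "2054-5", "2076-8", "2106-3", "2131-1")
# OMOP-style standard concept ids for the same race categories
RACE_CONCEPT_IDS <- c(8657L, 8515L, 8516L, 8557L, 8527L, 8522L)
RACE_DESCRIPTIONS <- c("American Indian or Alaska Native", "Asian",
                       "Black or African American",
                       "Native Hawaiian or Other Pacific Islander",
                       "White", "Other Race")

#' Configuration for the synthetic-source generator
#'
#' @param seed Integer seed; identical seed + config gives byte-identical
#'   output files.
#' @param n_claims,n_providers,n_persons Base row counts before injections.
#' @param dup_rate Probability that a base row gains a full-row duplicate
#'   (same values, new record identifier).
#' @param conflict_rate Probability that a base row gains a conflicting record
#'   (same record identifier, one non-key column altered, later load
#'   timestamp).
#' @param orphan_fk_rate Probability that a claim's `billing_provider_id`
#'   points to a non-existent provider.
#' @param invalid_date_rate,invalid_numeric_rate,overlength_rate,missing_required_rate
#'   Per-cell corruption probabilities for the corresponding validation rule.
#' @return A `detl_generator_config`.
#' @export
generator_config <- function(seed = 1L, n_claims = 200L, n_providers = 40L,
                             n_persons = 100L,
                             dup_rate = 0, conflict_rate = 0,
                             orphan_fk_rate = 0, invalid_date_rate = 0,
                             invalid_numeric_rate = 0, overlength_rate = 0,
                             missing_required_rate = 0) {
  rates <- c(dup_rate, conflict_rate, orphan_fk_rate, invalid_date_rate,
             invalid_numeric_rate, overlength_rate, missing_required_rate)
  stopifnot(all(rates >= 0 & rates <= 1),
            n_claims >= 0, n_providers >= 1, n_persons >= 0)
  structure(list(seed = as.integer(seed), n_claims = as.integer(n_claims),
                 n_providers = as.integer(n_providers),
                 n_persons = as.integer(n_persons),
                 dup_rate = dup_rate, conflict_rate = conflict_rate,
                 orphan_fk_rate = orphan_fk_rate,
                 invalid_date_rate = invalid_date_rate,
                 invalid_numeric_rate = invalid_numeric_rate,
                 overlength_rate = overlength_rate,
                 missing_required_rate = missing_required_rate),
            class = "detl_generator_config")
}

#' Specs for the synthetic source extracts
#'
#' @return Named list of `detl_table_spec` for `medical_claims`, `provider`,
#'   `demographic` and `source_to_concept_map` (including the
#'   `etl_timestamp` batch column carried by the entity extracts).
#' @export
source_schema <- function() {
  ts_col <- function() tibble::tibble(
    name = "etl_timestamp", type = "timestamp", length = NA, precision = NA,
    scale = NA, required = FALSE)
  claims <- table_spec(
    "medical_claims",
    rbind(
      tibble::tibble(name = "claim_id", type = "varchar", length = 10,
                     precision = NA, scale = NA, required = TRUE),
      tibble::tibble(name = "billing_provider_id", type = "varchar",
                     length = 10, precision = NA, scale = NA, required = TRUE),
      tibble::tibble(name = "place_of_service_code", type = "varchar",
                     length = 2, precision = NA, scale = NA, required = TRUE),
      tibble::tibble(name = "service_date", type = "date", length = NA,
                     precision = NA, scale = NA, required = TRUE),
      tibble::tibble(name = "paid_amount", type = "numeric", length = NA,
                     precision = NA, scale = NA, required = FALSE),
      ts_col()),
    primary_key = "claim_id",
    foreign_keys = list(list(columns = "billing_provider_id",
                             parent_table = "provider",
                             parent_columns = "provider_id")))
  provider <- table_spec(
    "provider",
    rbind(
      tibble::tibble(name = "provider_id", type = "varchar", length = 10,
                     precision = NA, scale = NA, required = TRUE),
      tibble::tibble(name = "provider_organization_type", type = "varchar",
                     length = 1, precision = NA, scale = NA, required = TRUE),
      tibble::tibble(name = "provider_address_first_line", type = "varchar",
                     length = 40, precision = NA, scale = NA, required = FALSE),
      tibble::tibble(name = "provider_street", type = "varchar", length = 40,
                     precision = NA, scale = NA, required = FALSE),
      tibble::tibble(name = "provider_city", type = "varchar", length = 20,
                     precision = NA, scale = NA, required = FALSE),
      tibble::tibble(name = "provider_state", type = "varchar", length = 2,
                     precision = NA, scale = NA, required = FALSE),
      tibble::tibble(name = "provider_zip", type = "varchar", length = 5,
                     precision = NA, scale = NA, required = FALSE),
      ts_col()),
    primary_key = "provider_id")
  demographic <- table_spec(
    "demographic",
    rbind(
      tibble::tibble(name = "person_id", type = "varchar", length = 10,
                     precision = NA, scale = NA, required = TRUE),
      tibble::tibble(name = "race", type = "varchar", length = 10,
                     precision = NA, scale = NA, required = FALSE),
      tibble::tibble(name = "gender", type = "varchar", length = 1,
                     precision = NA, scale = NA, required = FALSE),
      tibble::tibble(name = "birth_date", type = "date", length = NA,
                     precision = NA, scale = NA, required = TRUE),
      tibble::tibble(name = "state", type = "varchar", length = 2,
                     precision = NA, scale = NA, required = FALSE),
      tibble::tibble(name = "zip3", type = "varchar", length = 3,
                     precision = NA, scale = NA, required = FALSE),
      ts_col()),
    primary_key = "person_id")
  s2cm <- table_spec(
    "source_to_concept_map",
    rbind(
      tibble::tibble(name = "source_code", type = "varchar", length = 10,
                     precision = NA, scale = NA, required = TRUE),
      tibble::tibble(name = "source_vocabulary", type = "varchar", length = 10,
                     precision = NA, scale = NA, required = TRUE),
      tibble::tibble(name = "source_code_description", type = "varchar",
                     length = 60, precision = NA, scale = NA, required = FALSE),
      tibble::tibble(name = "target_concept_id", type = "integer", length = NA,
                     precision = NA, scale = NA, required = TRUE),
      tibble::tibble(name = "target_vocabulary", type = "varchar", length = 10,
                     precision = NA, scale = NA, required = TRUE)))
  # the concept map is a static lookup with no batch timestamp: only the
  # exact-duplicate pass applies, so no record identifier is declared
  list(medical_claims = claims, provider = provider,
       demographic = demographic, source_to_concept_map = s2cm)
}

#' Mini target schema (common-data-model subset)
#'
#' Two OMOP-v4-style target tables, `care_site` and `person`, plus a
#' configurable excluded-column list modeling limited-data-set restrictions
#' (no direct identifiers; state and 3-digit ZIP retained) attached as the
#' `excluded_columns` attribute.
#'
#' @param excluded_columns Target columns no rule may populate.
#' @return Named list of `detl_table_spec` with attribute `excluded_columns`.
#' @export
mini_target_schema <- function(excluded_columns = c(
    "person_name", "person_ssn", "person_phone", "person_address_1")) {
  vcol <- function(name, length = 50, type = "varchar", required = FALSE) {
    tibble::tibble(name = name, type = type,
                   length = if (type == "varchar") length else NA,
                   precision = NA, scale = NA, required = required)
  }
  care_site <- table_spec(
    "care_site",
    rbind(vcol("care_site_source_value", 50, required = TRUE),
          vcol("organization_source_value", 50),
          vcol("place_of_service_source_value", 50),
          vcol("care_site_address_1", 50),
          vcol("care_site_address_2", 50),
          vcol("care_site_city", 50),
          vcol("care_site_state", 2),
          vcol("care_site_zip", 5),
          vcol("care_site_county", 20)),
    primary_key = "care_site_source_value")
  person <- table_spec(
    "person",
    rbind(vcol("person_source_value", 50, required = TRUE),
          vcol("year_of_birth", type = "integer"),
          vcol("gender_source_value", 10),
          vcol("race_concept_id", type = "integer"),
          vcol("race_source_value", 20),
          vcol("ethnicity_concept_id", type = "integer")),
    primary_key = "person_source_value")
  structure(list(care_site = care_site, person = person),
            excluded_columns = excluded_columns)
}

# deterministic id helpers
pad_id <- function(prefix, i, width) sprintf("%s%0*d", prefix, width, i)

empty_ledger <- function() {
  cell <- tibble::tibble(table = character(), line_number = integer(),
                         column = character())
  list(invalid_date = cell, invalid_numeric = cell, overlength = cell,
       missing_required = cell, orphan_fk = cell,
       duplicates = tibble::tibble(table = character(), key = character(),
                                   orig_line = integer(), dup_line = integer()),
       conflicts = tibble::tibble(table = character(), key = character(),
                                  column = character(), orig_line = integer(),
                                  conflict_line = integer(),
                                  winner_line = integer()))
}

#' Generate synthetic claims and clinical extracts
#'
#' Writes `medical_claims.csv`, `provider.csv`, `demographic.csv` (HL7-coded
#' race) and `source_to_concept_map.csv` (HL7 to SNOMED-mapped race concepts)
#' to `out_dir`, together with the schema-spec config (`schema.yml`) and the
#' injection ledger (`ledger.json`).  Injection sites for the different error
#' classes are disjoint per cell; duplicates are full-row copies with a new
#' record identifier appended at the end of the file; conflicts reuse the
#' record identifier, alter one designated non-key column and carry a later
#' `etl_timestamp` (so the conflicting row wins resolution).  All randomness
#' flows from `cfg$seed` and all timestamps are fixed offsets from a constant
#' epoch, so identical configurations give byte-identical files.
#'
#' @param cfg A [generator_config()].
#' @param out_dir Output directory (created if needed).
#' @return List with `files` (named paths), `ledger` (list of tibbles) and
#'   `specs` (the source [table_spec()]s).
#' @export
generate_extracts <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "detl_generator_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  specs <- source_schema()
  ledger <- empty_ledger()

  cities <- c("Aurora", "Denver", "Boulder", "Pueblo", "Greeley", "Golden")
  states <- c("CO", "WY", "NM", "KS")
  streets <- c("Main St", "Oak Ave", "Pine Rd", "Elm Dr", "Maple Ln")

  n_prov <- cfg$n_providers
  provider <- tibble::tibble(
    provider_id = pad_id("P", seq_len(n_prov), 4),
    provider_organization_type = sample(c("1", "2", "3"), n_prov,
                                        replace = TRUE, prob = c(.4, .3, .3)),
    provider_address_first_line = paste(sample(100:999, n_prov, replace = TRUE),
                                        sample(streets, n_prov, replace = TRUE)),
    provider_street = paste("Suite", sample(1:50, n_prov, replace = TRUE)),
    provider_city = sample(cities, n_prov, replace = TRUE),
    provider_state = sample(states, n_prov, replace = TRUE),
    provider_zip = sprintf("8%04d", sample(0:9999, n_prov, replace = TRUE)),
    etl_timestamp = GEN_BASE_TS)

  n_cl <- cfg$n_claims
  claims <- tibble::tibble(
    claim_id = pad_id("C", seq_len(n_cl), 6),
    billing_provider_id = sample(provider$provider_id, n_cl, replace = TRUE),
    place_of_service_code = sample(c("11", "21", "22", "23"), n_cl,
                                   replace = TRUE),
    service_date = format(as.Date("2016-01-01") +
                            sample(0:364, n_cl, replace = TRUE)),
    paid_amount = sprintf("%.2f", stats::runif(n_cl, 10, 500)),
    etl_timestamp = GEN_BASE_TS)

  n_pe <- cfg$n_persons
  demographic <- tibble::tibble(
    person_id = pad_id("PE", seq_len(n_pe), 5),
    race = sample(HL7_RACE_CODES, n_pe, replace = TRUE),
    gender = sample(c("M", "F"), n_pe, replace = TRUE),
    birth_date = format(as.Date("1940-01-01") +
                          sample(0:25000, n_pe, replace = TRUE)),
    state = sample(states, n_pe, replace = TRUE),
    zip3 = sprintf("8%02d", sample(0:99, n_pe, replace = TRUE)),
    etl_timestamp = GEN_BASE_TS)

  s2cm <- tibble::tibble(
    source_code = HL7_RACE_CODES,
    source_vocabulary = "HL7",
    source_code_description = RACE_DESCRIPTIONS,
    target_concept_id = as.character(RACE_CONCEPT_IDS),
    target_vocabulary = "SNOMED")

  # per-table cell corruption plans; sites are disjoint because each base row
  # is assigned to at most one class (a single shuffled index pool per table)
  corrupt <- function(df, tbl, classes) {
    n <- nrow(df)
    pool <- sample(seq_len(n))
    taken <- 0L
    plan <- list()
    for (cl_name in names(classes)) {
      rate <- classes[[cl_name]]$rate
      k <- sum(stats::runif(n) < rate)
      k <- min(k, n - taken)
      plan[[cl_name]] <- if (k > 0) pool[taken + seq_len(k)] else integer()
      taken <- taken + k
    }
    for (cl_name in names(classes)) {
      idx <- plan[[cl_name]]
      if (length(idx) == 0) next
      cls <- classes[[cl_name]]
      df[[cls$column]][idx] <- cls$value(df[[cls$column]][idx])
      ledger[[cls$ledger]] <<- rbind(
        ledger[[cls$ledger]],
        tibble::tibble(table = tbl, line_number = sort(as.integer(idx)),
                       column = cls$column))
    }
    df
  }

  claims <- corrupt(claims, "medical_claims", list(
    invalid_date = list(rate = cfg$invalid_date_rate, column = "service_date",
                        ledger = "invalid_date",
                        value = function(x) "2016-13-45"),
    invalid_numeric = list(rate = cfg$invalid_numeric_rate,
                           column = "paid_amount", ledger = "invalid_numeric",
                           value = function(x) "12.3.4"),
    missing_required = list(rate = cfg$missing_required_rate,
                            column = "place_of_service_code",
                            ledger = "missing_required",
                            value = function(x) ""),
    orphan_fk = list(rate = cfg$orphan_fk_rate,
                     column = "billing_provider_id", ledger = "orphan_fk",
                     value = function(x) pad_id("PX", seq_along(x), 4))))

  provider <- corrupt(provider, "provider", list(
    overlength = list(rate = cfg$overlength_rate, column = "provider_city",
                      ledger = "overlength",
                      value = function(x) strrep("Longtownname", 3))))

  demographic <- corrupt(demographic, "demographic", list(
    invalid_date = list(rate = cfg$invalid_date_rate, column = "birth_date",
                        ledger = "invalid_date",
                        value = function(x) "02/30/1950")))

  # duplicates and conflicts: appended rows, drawn from untouched base rows
  touched <- function(tbl, n) {
    cellish <- c("invalid_date", "invalid_numeric", "overlength",
                 "missing_required", "orphan_fk")
    used <- unlist(lapply(ledger[cellish], function(df) {
      df$line_number[df$table == tbl]
    }))
    setdiff(seq_len(n), used)
  }
  dup_conflict <- function(df, tbl, pk, conflict_col, alt_value) {
    clean <- touched(tbl, nrow(df))
    n <- nrow(df)
    pick <- clean[stats::runif(length(clean)) < cfg$dup_rate]
    if (length(pick) > 0) {
      dup <- df[pick, ]
      dup[[pk]] <- pad_id("D", seq_along(pick), 5)  # new record identifier
      ledger$duplicates <<- rbind(
        ledger$duplicates,
        tibble::tibble(table = tbl, key = df[[pk]][pick],
                       orig_line = as.integer(pick),
                       dup_line = n + seq_along(pick)))
      df <- rbind(df, dup)
      clean <- setdiff(clean, pick)
    }
    n2 <- nrow(df)
    pick2 <- clean[stats::runif(length(clean)) < cfg$conflict_rate]
    if (length(pick2) > 0) {
      conf <- df[pick2, ]
      conf[[conflict_col]] <- alt_value(conf[[conflict_col]])
      conf$etl_timestamp <- GEN_CONFLICT_TS
      ledger$conflicts <<- rbind(
        ledger$conflicts,
        tibble::tibble(table = tbl, key = df[[pk]][pick2],
                       column = conflict_col,
                       orig_line = as.integer(pick2),
                       conflict_line = n2 + seq_along(pick2),
                       winner_line = n2 + seq_along(pick2)))
      df <- rbind(df, conf)
    }
    df
  }
  claims <- dup_conflict(claims, "medical_claims", "claim_id",
                         "place_of_service_code",
                         function(x) ifelse(x == "11", "21", "11"))
  provider <- dup_conflict(provider, "provider", "provider_id",
                           "provider_city",
                           function(x) ifelse(x == "Aurora", "Denver", "Aurora"))
  demographic <- dup_conflict(demographic, "demographic", "person_id", "race",
                              function(x) ifelse(x == "2106-3", "2054-5",
                                                 "2106-3"))

  files <- c(medical_claims = file.path(out_dir, "medical_claims.csv"),
             provider = file.path(out_dir, "provider.csv"),
             demographic = file.path(out_dir, "demographic.csv"),
             source_to_concept_map = file.path(out_dir,
                                               "source_to_concept_map.csv"))
  readr::write_csv(claims, files[["medical_claims"]], na = "")
  readr::write_csv(provider, files[["provider"]], na = "")
  readr::write_csv(demographic, files[["demographic"]], na = "")
  readr::write_csv(s2cm, files[["source_to_concept_map"]], na = "")
  write_schema_spec(specs, file.path(out_dir, "schema.yml"))
  jsonlite::write_json(ledger, file.path(out_dir, "ledger.json"),
                       auto_unbox = FALSE, na = "null", digits = NA)
  files <- c(files, schema = file.path(out_dir, "schema.yml"),
             ledger = file.path(out_dir, "ledger.json"))
  list(files = files, ledger = ledger, specs = specs)
}

ref_rule_row <- function(rule_order, rule_description, target_table,
                         target_column, map_type, map_order,
                         source_table, source_value) {
  tibble::tibble(
    rule_order = as.integer(rule_order), rule_description = rule_description,
    target_database = NA_character_, target_schema = NA_character_,
    target_table = target_table, target_column = target_column,
    map_type = map_type, map_order = as.integer(map_order),
    source_database = NA_character_, source_schema = NA_character_,
    source_table = source_table, source_value = source_value)
}

#' Packaged reference rule set
#'
#' Two rules exercising the core of the rule language: (1) the claims-to-
#' care-site rule — primary table `medical_claims` joined to `provider` on the
#' billing provider id, filtered to organization types '1' and '2', with nine
#' VALUE mappings including a three-part concatenated source value and
#' explicit NULLs for unpopulated columns; (2) a demographic-to-person rule
#' that joins `source_to_concept_map` to translate HL7 race codes into
#' standard (SNOMED-mapped) concept ids.
#'
#' @param data_source_id Data source identifier for the returned set.
#' @return A `detl_ruleset` of two rules.
#' @export
reference_rules <- function(data_source_id = "synthetic-claims") {
  d1 <- "Medical_claims to Care_site"
  r1 <- rbind(
    ref_rule_row(1, d1, "care_site", NA, "PRIMARY", 1, "medical_claims",
                 "medical_claims.billing_provider_id, medical_claims.place_of_service_code, provider.provider_organization_type"),
    ref_rule_row(1, d1, "care_site", NA, "JOIN", 2, "provider",
                 "medical_claims.billing_provider_id = provider.provider_id"),
    ref_rule_row(1, d1, "care_site", NA, "WHERE", 3, NA,
                 "provider.provider_organization_type in ('1', '2')"),
    ref_rule_row(1, d1, "care_site", "care_site_source_value", "VALUE", 4, NA,
                 "medical_claims.billing_provider_id || '-' || medical_claims.place_of_service_code || '-' || provider.provider_organization_type"),
    ref_rule_row(1, d1, "care_site", "organization_source_value", "VALUE", 5,
                 NA, "NULL"),
    ref_rule_row(1, d1, "care_site", "place_of_service_source_value", "VALUE",
                 6, NA, "medical_claims.place_of_service_code"),
    ref_rule_row(1, d1, "care_site", "care_site_address_1", "VALUE", 7, NA,
                 "provider.provider_address_first_line"),
    ref_rule_row(1, d1, "care_site", "care_site_address_2", "VALUE", 8, NA,
                 "provider.provider_street"),
    ref_rule_row(1, d1, "care_site", "care_site_city", "VALUE", 9, NA,
                 "provider.provider_city"),
    ref_rule_row(1, d1, "care_site", "care_site_state", "VALUE", 10, NA,
                 "provider.provider_state"),
    ref_rule_row(1, d1, "care_site", "care_site_zip", "VALUE", 11, NA,
                 "provider.provider_zip"),
    ref_rule_row(1, d1, "care_site", "care_site_county", "VALUE", 12, NA,
                 "NULL"))
  d2 <- "Demographic to Person"
  r2 <- rbind(
    ref_rule_row(2, d2, "person", NA, "PRIMARY", 1, "demographic",
                 "demographic.person_id"),
    ref_rule_row(2, d2, "person", NA, "JOIN", 2, "source_to_concept_map",
                 "demographic.race = source_to_concept_map.source_code"),
    ref_rule_row(2, d2, "person", NA, "WHERE", 3, NA,
                 "source_to_concept_map.source_vocabulary = 'HL7'"),
    ref_rule_row(2, d2, "person", "person_source_value", "VALUE", 4, NA,
                 "demographic.person_id"),
    ref_rule_row(2, d2, "person", "year_of_birth", "VALUE", 5, NA,
                 "CAST(substr(demographic.birth_date, 1, 4) AS INTEGER)"),
    ref_rule_row(2, d2, "person", "gender_source_value", "VALUE", 6, NA,
                 "demographic.gender"),
    ref_rule_row(2, d2, "person", "race_concept_id", "VALUE", 7, NA,
                 "source_to_concept_map.target_concept_id"),
    ref_rule_row(2, d2, "person", "race_source_value", "VALUE", 8, NA,
                 "demographic.race"),
    ref_rule_row(2, d2, "person", "ethnicity_concept_id", "VALUE", 9, NA,
                 "NULL"))
  new_ruleset(rbind(r1, r2), data_source_id)
}
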