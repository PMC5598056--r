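---
title: "Rule-based ETL for clinical common data models: methods and design"
author: "detl authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based ETL for clinical common data models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(detl)
```

## The problem

Health data networks harmonize electronic health record (EHR) and claims
extracts from many organizations into a common data model (CDM) so that the
same analysis can run against every site.  The transformation step is the
bottleneck: it normally requires hand-written SQL for every source schema,
and the people who understand the source data (health data domain experts)
are rarely the people who write SQL.  Two data problems dominate in practice:

* **Duplicate records** — rows identical in every column except the
  primary-key record identifier (e.g. the same claim exported twice under
  two surrogate ids).
* **Conflicting records** — rows that share an identity key (same claim id,
  same encounter number) but assert different values for a fact.

`detl` addresses this by making the transformation *declarative*: all mapping
logic for one data source lives in one CSV file of 12-attribute rules that a
domain expert can author in a spreadsheet, and a rule engine compiles each
rule into exactly one `INSERT ... SELECT` statement with de-duplication,
conflict resolution, joins and filters assembled automatically.  The
generated SQL is stored with full rule provenance, so designers debug at the
statement level, rule by rule.

## The rule language

A rule is an ordered group of CSV rows sharing one `rule_order`.  Each row
has 12 attributes: identification (`rule_order`, `rule_description`,
`map_order`), output destination (`target_database`, `target_schema`,
`target_table`, `target_column`) and source (`map_type`, `source_database`,
`source_schema`, `source_table`, `source_value`).  The row's role is set by
`map_type`:

| map_type | role of `source_value` |
|---|---|
| `PRIMARY` | main source table; the fields populating the target's record key |
| `JOIN`, `LEFT JOIN`, `RIGHT JOIN`, `FULL JOIN` | join condition for an additional source table |
| `WHERE` | filter condition (at most one per rule) |
| `VALUE` | SQL expression populating one target column |
| `CUSTOM` | a complete verbatim SQL statement (the rule's only row) |

A rule populates exactly one target table; the first row is always the
PRIMARY row; `map_order` orders rows within the rule and fixes both the
inserted column order and the join order.  Together with a rule-set-level
`data_source_id`, `(rule_order, rule_description, data_source_id)` is the
composite key identifying a rule; `rule_order` is unique within a rule set
but not across sets.  `VALUE` expressions are embedded verbatim, so the full
operator and function vocabulary of the backing database is available to
rule authors; the flip side, discussed under *Trust model* below, is that
rule files are trusted input.

## Compilation

`compile_rule()` emits, per rule:

```
WITH <table>__dedup AS (...), ...
INSERT INTO <target_table> (<VALUE target columns, in map_order>)
SELECT <VALUE expressions, verbatim, in map_order>
FROM <primary table>
<JOIN-family clauses, in map_order, ON their verbatim conditions>
WHERE <verbatim condition, when a WHERE row exists>
```

Every referenced source table with a declared spec is replaced by a
de-duplicating common table expression aliased back to the original name, so
verbatim expressions keep resolving.  De-duplication applies to *every*
referenced table, not just the primary one — conservative, and harmless for
already-clean tables.  Two passes are stacked inside each CTE:

1. **Exact-duplicate collapse.**  Rows identical in all columns except the
   declared record identifier (and the load timestamp, which is batch
   metadata rather than source data) collapse to one, keeping the smallest
   record identifier.  Keeping the *smallest* is arbitrary but deterministic;
   any fixed choice works because the surviving columns are identical.
2. **Conflict resolution.**  Rows sharing the record identifier resolve to
   the one with the latest `etl_timestamp` — later batches supersede earlier
   ones.  With tied timestamps, or when no timestamp column is declared, the
   row sorting first lexicographically over the non-key columns wins; this
   fallback is deterministic and independent of input order, and the
   compiler warns when it is all that is available.

Both passes are windowed `ROW_NUMBER()` subqueries, so the whole statement
remains a single `INSERT`, executable and inspectable as-is.

Plain `SELECT` is the default; `compile_options(select_distinct = TRUE)`
switches to `SELECT DISTINCT`.  DISTINCT matters whenever the projection
itself introduces repeats — deriving care sites from claim *lines* is the
canonical case, since hundreds of claims share one facility and the target
should hold one row per distinct facility key.

The dialect is a portable core (ANSI joins, `||`, `IN`, CTEs, window
functions) executed on the embedded SQLite engine; `dialect = "postgresql"`
additionally qualifies targets with their schema for server deployments.
Cross-dialect translation of rule expressions is out of scope.

### Trust model and statement integrity

Rule expressions are deliberately verbatim, so a rule file is as privileged
as the SQL it generates.  The engine enforces one invariant mechanically:
a non-CUSTOM rule compiles to exactly one statement, and any statement
separator (`;`) outside a string literal in a rule fragment is a compile
error.  Identifier scans and the separator check both ignore the inside of
single-quoted SQL strings.

## Pre-load validation

Extracts are CSV (RFC 4180, UTF-8), validated before staging.  Per-cell
rules and severities:

* date/timestamp cell unparseable as a date — ERROR;
* missing value in a required field — ERROR;
* numeric/decimal/integer cell not a number — ERROR;
* text/varchar value longer than the declared length — ERROR;
* column with no declared length/precision/scale — WARNING, once per column;
* foreign-key value absent from the parent key column (orphan) — ERROR.

Any ERROR fails the dataset (it must be re-extracted); warnings never do.
Issues carry the 1-based *data-row* line number and never the cell contents,
so reports cannot leak protected health information.  Two severity modes are
provided: `strict` keeps the severities above; `loose` downgrades length
overflows and numeric parse failures to warnings, for sites that truncate or
coerce downstream.  The split is a package convention (configurable in the
sense that both modes are always computed from the same detected cells, only
severity differs).

Design choices worth stating: dates must be ISO 8601 (`YYYY-MM-DD`, optional
time part) and calendar-valid — a single canonical grammar keeps the
extraction convention explicit; empty cells and the literal `NULL` (any
case) both denote missing, since both occur in real extracts; per-rule issue
lists are capped at 1000 rows per table with full counts preserved, to bound
report size on pathological inputs.

## Staging and execution

`stage_csv()` loads extracts as-is into the embedded database, shaped by the
table spec (integers and numerics coerced, everything else stored as text;
a coercion failure is reported as a validation gap, not silently nulled).
An `etl_timestamp` column is injected with the batch load time unless the
extract already carries one — multi-batch extracts keep their own
timestamps, which is exactly what conflict resolution consumes.

`execute_statements()` runs a compiled plan in ascending `rule_order`.  A
SQL error is captured per statement; subsequent statements are marked
`skipped` and the failing rule becomes the resume checkpoint.  Re-invoking
with `resume_from` continues from the checkpoint, and the resumed target
state is identical to an uninterrupted run (this is tested).  Generated
statements are stored in the database (`detl_statements`) with rule key,
target and generation time, and mirrored to `.sql` files — enough provenance
to re-execute a plan without the rule file.  `run_single_rule()` compiles
and runs one rule and hands back its SQL, the primary debugging loop.
Re-running a full plan with `refresh = TRUE` first deletes existing rows
from the plan's target tables; full incremental-merge semantics are
deliberately out of scope.

## The synthetic-source generator

Real partner extracts cannot be redistributed, so the package carries a
generator that emulates their *structure*: `medical_claims` (claim id,
billing provider, place-of-service code, service date, paid amount),
`provider` (id, organization type, address fields), `demographic` (person
id, HL7-coded race, gender, birth date, state, 3-digit ZIP — the limited
data set shape) and a static `source_to_concept_map` translating the six
HL7 race codes to standard concept ids.  Values are small categorical draws
from fixed vocabularies; realism beyond structure is not the point, because
what is under test is the engine, not the data.

Anomalies are injected at configurable per-cell or per-row rates —
duplicates, conflicts, orphan foreign keys, invalid dates, bad numerics,
over-length text, missing required values — and every injection site is
recorded in a ledger, giving tests exact ground truth (zero tolerated false
positives or negatives).  Injection sites are disjoint per cell: each base
row is assigned to at most one anomaly class, so every detected issue has
one intended cause.  Conflicts are only injected on tables with a declared
record identifier and always carry a later load timestamp, so resolution is
well-defined and the injected row is the expected winner.  Determinism is a
contract: all randomness flows from the seed and all timestamps are fixed
offsets from a constant epoch, so identical configurations yield
byte-identical files.

Default study conditions used by the test suite and the acceptance script:
duplicate rate 0.1 and conflict rate 0.05 at 1000 claims for the
de-duplication checks; each validation-anomaly class at rate 0.02 with 1000
rows per table for the validation checks; 100 randomized two-table instances
of up to ~160 rows for the compiler-versus-oracle sweep; 500 claims / 200
persons for the end-to-end reference pipeline.  These sizes keep a full run
in seconds while every class of draw is guaranteed non-empty.

What passing on generated data does *not* show: robustness to real-world
date formats beyond ISO 8601, character encodings other than UTF-8,
free-text clinical content, or cross-source patient linkage — all outside
the package's scope.

## Verification strategy

The compiler is verified against an independent brute-force oracle: plain
data-frame evaluation (de-duplicate each table in memory, `merge` for the
join, vectorized filters and projections) of the same structured instance,
compared multiset-exactly with the executed SQL's output.  The oracle shares
no code with the SQL path.  Random instances draw join types across
inner/left/right/full, nullable attribute columns (exercising NULL
propagation through concatenation and filters), injected duplicates and
conflicts, and random projections including constants and NULLs.  One
numerical subtlety is worth recording: string ordering in the oracle uses
radix (C-locale) ordering to match SQLite's binary collation, and generated
instances give every row a distinct load timestamp so conflict resolution
never depends on the lexicographic tie-break when NULLs are present (SQLite
sorts NULL first ascending, R sorts NA last — the one place the two systems
disagree; the tie-break itself is tested separately with non-NULL data).

## Known limitations

* No real-time rule syntax checking while authoring; errors surface at
  compile or execute time.
* No automatic schema-mapping inference and no SQL-dialect translation of
  rule expressions.
* Incremental load is delete-then-insert at plan-target scope, not a merge.
* The mini target schema models two CDM tables (`care_site`, `person`);
  a production deployment would declare the full model the same way.
* CUSTOM rules are single verbatim statements; multi-statement custom
  procedures must be split across rules.
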