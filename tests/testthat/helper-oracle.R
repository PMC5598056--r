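# Independent in-memory relational oracle: brute-force evaluation of
# projection over the filtered join of de-duplicated inputs, written against
# plain data frames (merge/paste/order) and never touching the SQL path it
# checks.

oracle_dedup <- function(df, pk, ts = "etl_timestamp") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  dup_cols <- setdiff(names(df), c(pk, ts))
  if (length(dup_cols) > 0) {
    if (length(pk) > 0) {
      df <- df[order(df[[pk[1]]], method = "radix"), , drop = FALSE]
    }
    df <- df[!duplicated(df[dup_cols]), , drop = FALSE]
  }
  if (length(pk) > 0) {
    nonpk <- setdiff(names(df), pk)
    groups <- split(seq_len(nrow(df)), df[pk], drop = TRUE)
    keep <- vapply(groups, function(ix) {
      if (length(ix) == 1) return(ix)
      sub <- df[ix, , drop = FALSE]
      ord_cols <- c(intersect(ts, names(sub)), setdiff(nonpk, ts))
      dec <- c(rep(TRUE, length(intersect(ts, names(sub)))),
               rep(FALSE, length(setdiff(nonpk, ts))))
      o <- do.call(order, c(unname(sub[ord_cols]),
                            list(method = "radix", decreasing = dec)))
      ix[o[1]]
    }, integer(1))
    df <- df[sort(keep), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

# structured expressions the oracle understands:
#   list(kind = "col", col = "t1.a")
#   list(kind = "const", value = "x")
#   list(kind = "null")
#   list(kind = "concat", cols = c("t1.a", "t2.c"), sep = "-")
oracle_expr_sql <- function(e) {
  switch(e$kind,
         col = e$col,
         const = sprintf("'%s'", e$value),
         null = "NULL",
         concat = paste(e$cols, collapse = sprintf(" || '%s' || ", e$sep)))
}

oracle_expr_eval <- function(e, env) {
  # env maps qualified column name -> vector over the joined rows
  switch(e$kind,
         col = env[[e$col]],
         const = rep(e$value, length(env[[1]])),
         null = rep(NA_character_, length(env[[1]])),
         concat = {
           parts <- lapply(e$cols, function(cc) env[[cc]])
           out <- do.call(paste, c(parts, sep = e$sep))
           out[Reduce(`|`, lapply(parts, is.na))] <- NA_character_
           out
         })
}

# full oracle for a structured two-table instance (see random_instance)
oracle_eval_instance <- function(inst) {
  d1 <- oracle_dedup(inst$t1, inst$pk1)
  d2 <- oracle_dedup(inst$t2, inst$pk2)
  jt <- inst$join_type
  joined <- merge(d1, d2, by.x = inst$join_on[1], by.y = inst$join_on[2],
                  all.x = jt %in% c("LEFT JOIN", "FULL JOIN"),
                  all.y = jt %in% c("RIGHT JOIN", "FULL JOIN"))
  # rebuild both qualified key columns (merge collapses them to one)
  env <- list()
  for (cc in names(inst$t1)) {
    src <- if (cc == inst$join_on[1]) inst$join_on[1] else cc
    v <- joined[[src]]
    # left columns are NULL on right-only rows of a RIGHT/FULL JOIN: merge
    # already yields NA there, except the join key itself, which SQL keeps
    # NULL on the left side; project it from membership in d1
    env[[paste0("t1.", cc)]] <- v
  }
  for (cc in names(inst$t2)) {
    src <- if (cc == inst$join_on[2]) inst$join_on[1] else cc
    env[[paste0("t2.", cc)]] <- joined[[src]]
  }
  if (jt %in% c("RIGHT JOIN", "FULL JOIN")) {
    right_only <- is.na(joined[[inst$pk1]])
    for (cc in names(inst$t1)) {
      env[[paste0("t1.", cc)]][right_only] <- NA_character_
    }
  }
  if (jt %in% c("LEFT JOIN", "FULL JOIN")) {
    left_only <- is.na(joined[[inst$pk2]])
    for (cc in names(inst$t2)) {
      env[[paste0("t2.", cc)]][left_only] <- NA_character_
    }
  }
  keep <- rep(TRUE, nrow(joined))
  if (!is.null(inst$where)) {
    x <- env[[inst$where$col]]
    keep <- !is.na(x) & x %in% inst$where$vals
  }
  out <- lapply(inst$values, function(e) oracle_expr_eval(e, env)[keep])
  names(out) <- sprintf("c%d", seq_along(out))
  as.data.frame(out, stringsAsFactors = FALSE, optional = TRUE)
}

ts_of <- function(i) {
  sprintf("2017-01-01 %02d:%02d:%02d", i %/% 3600L, (i %/% 60L) %% 60L,
          i %% 60L)
}

# random small instance: two tables with injected duplicates and conflicts,
# a random join type, optional filter, and 3-5 projection expressions
random_instance <- function(seed, max_rows = 80) {
  set.seed(seed)
  n1 <- sample(15:max_rows, 1)
  n2 <- sample(8:max(8, max_rows %/% 2), 1)
  keys <- sprintf("K%d", 1:6)
  t1 <- data.frame(
    id = sprintf("A%04d", seq_len(n1)),
    k = sample(keys, n1, replace = TRUE),
    a = sample(c("a1", "a2", "a3"), n1, replace = TRUE),
    b = sample(c("b1", "b2", NA), n1, replace = TRUE),
    stringsAsFactors = FALSE)
  t2 <- data.frame(
    id2 = sprintf("B%04d", seq_len(n2)),
    k2 = sample(keys, n2, replace = TRUE),
    cc = sample(c("c1", "c2", NA), n2, replace = TRUE),
    d = sample(c("d1", "d2"), n2, replace = TRUE),
    stringsAsFactors = FALSE)

  inject <- function(df, pk_col, prefix, mutate_col, mutate_vals) {
    n <- nrow(df)
    df$etl_timestamp <- ts_of(seq_len(n))
    ndup <- sample(0:3, 1)
    if (ndup > 0) {
      pick <- sample(n, ndup)
      dup <- df[pick, , drop = FALSE]
      dup[[pk_col]] <- sprintf("%s%04d", prefix, seq_len(ndup))
      dup$etl_timestamp <- ts_of(n + seq_len(ndup))
      df <- rbind(df, dup)
    }
    ncf <- sample(0:3, 1)
    if (ncf > 0) {
      pick <- sample(n, ncf)
      cf <- df[pick, , drop = FALSE]
      cf[[mutate_col]] <- sample(mutate_vals, ncf, replace = TRUE)
      cf$etl_timestamp <- ts_of(n + 10L + seq_len(ncf))
      df <- rbind(df, cf)
    }
    rownames(df) <- NULL
    df
  }
  t1 <- inject(t1, "id", "X", "a", c("a1", "a2", "a3"))
  t2 <- inject(t2, "id2", "Y", "d", c("d1", "d2"))

  join_type <- sample(c("JOIN", "LEFT JOIN", "RIGHT JOIN", "FULL JOIN"), 1)
  where <- if (stats::runif(1) < 0.6) {
    if (stats::runif(1) < 0.5) {
      list(col = "t1.a", vals = c("a1", "a2"))
    } else {
      list(col = "t2.d", vals = "d1")
    }
  }
  cols1 <- paste0("t1.", c("id", "k", "a", "b"))
  cols2 <- paste0("t2.", c("id2", "k2", "cc", "d"))
  rand_expr <- function() {
    r <- stats::runif(1)
    if (r < 0.5) {
      list(kind = "col", col = sample(c(cols1, cols2), 1))
    } else if (r < 0.65) {
      list(kind = "const", value = sample(c("s1", "s2"), 1))
    } else if (r < 0.75) {
      list(kind = "null")
    } else {
      list(kind = "concat", cols = sample(c(cols1, cols2), 2), sep = "-")
    }
  }
  values <- lapply(seq_len(sample(3:5, 1)), function(i) rand_expr())
  list(t1 = t1, t2 = t2, pk1 = "id", pk2 = "id2",
       join_type = join_type, join_on = c("k", "k2"),
       where = where, values = values)
}

instance_specs <- function(inst) {
  vc <- function(nm, ty = "varchar") {
    tibble::tibble(name = nm, type = ty, length = NA, precision = NA,
                   scale = NA, required = FALSE)
  }
  list(
    t1 = table_spec("t1", rbind(vc("id"), vc("k"), vc("a"), vc("b"),
                                vc("etl_timestamp", "timestamp")),
                    primary_key = "id"),
    t2 = table_spec("t2", rbind(vc("id2"), vc("k2"), vc("cc"), vc("d"),
                                vc("etl_timestamp", "timestamp")),
                    primary_key = "id2"))
}

instance_ruleset <- function(inst) {
  desc <- "random instance rule"
  rows <- list(rule_row(1, desc, "t_target", NA, "PRIMARY", 1, "t1", "t1.id"),
               rule_row(1, desc, "t_target", NA, inst$join_type, 2, "t2",
                        sprintf("t1.%s = t2.%s", inst$join_on[1],
                                inst$join_on[2])))
  mo <- 3L
  if (!is.null(inst$where)) {
    rows[[length(rows) + 1L]] <- rule_row(
      1, desc, "t_target", NA, "WHERE", mo, NA,
      sprintf("%s IN (%s)", inst$where$col,
              paste(sprintf("'%s'", inst$where$vals), collapse = ", ")))
    mo <- mo + 1L
  }
  for (i in seq_along(inst$values)) {
    rows[[length(rows) + 1L]] <- rule_row(
      1, desc, "t_target", sprintf("c%d", i), "VALUE", mo,
      NA, oracle_expr_sql(inst$values[[i]]))
    mo <- mo + 1L
  }
  ruleset_from_rows(do.call(rbind, rows), data_source_id = "oracle")
}

# run one random instance through the engine; returns engine + oracle results
run_instance <- function(inst, con = NULL) {
  own <- is.null(con)
  if (own) con <- etl_connect()
  on.exit(if (own) DBI::dbDisconnect(con), add = TRUE)
  DBI::dbWriteTable(con, "t1", inst$t1, overwrite = TRUE)
  DBI::dbWriteTable(con, "t2", inst$t2, overwrite = TRUE)
  ncol_target <- length(inst$values)
  DBI::dbExecute(con, sprintf(
    "DROP TABLE IF EXISTS t_target"))
  DBI::dbExecute(con, sprintf(
    "CREATE TABLE t_target (%s)",
    paste(sprintf("c%d TEXT", seq_len(ncol_target)), collapse = ", ")))
  rs <- instance_ruleset(inst)
  st <- compile_rule(get_rule(rs, 1), compile_options(), instance_specs(inst))
  DBI::dbExecute(con, st$sql_text)
  list(engine = DBI::dbGetQuery(con, "SELECT * FROM t_target"),
       oracle = oracle_eval_instance(inst),
       sql = st$sql_text)
}
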