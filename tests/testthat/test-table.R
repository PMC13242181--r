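# Relational table engine: schema checks, operations vs brute-force
# oracles, memory/disk differential behavior, persistence.

test_that("table creation validates schema and rows", {
  t0 <- createTable(c("a", "b"), c("integer", "text"))
  expect_equal(numRows(t0), 0L)
  expect_error(createTable(c("a", "a"), c("integer", "integer")),
               "duplicate column")
  expect_error(createTable("a", "integer", rows = list(list("x"))),
               "row 1.*column 'a'")
  expect_error(createTable("a", "wat"), "unknown column type")
  # 1000 random rows preserve the row multiset and order
  set.seed(1)
  v <- sample.int(100L, 1000L, replace = TRUE)
  t <- createTable("a", "integer", rows = list(a = v))
  expect_identical(asDataFrame(t)$a, v)
})

test_that("filter matches a row-by-row oracle and respects missing", {
  for (seed in 1:8) {
    t <- randomTable(seed)
    df <- asDataFrame(t)
    exprs <- list(col("x") > 0,
                  col("id") %% 2L == 0L,
                  col("flag") & col("x") < 0.5,
                  isMissing(col("grp")) | col("flag"),
                  !isMissing(col("x")) & col("x") * 2 >= -0.3)
    for (e in exprs)
      expectTableEqualsDf(filterRows(t, e), oracleFilter(df, e))
  }
  t <- randomTable(99)
  expect_equal(numRows(filterRows(t, lit(TRUE))), numRows(t))
  expect_equal(numRows(filterRows(t, lit(FALSE))), 0L)
  expect_error(filterRows(t, col("nope") > 1), "unknown column")
  expect_error(filterRows(t, col("x") + 1), "must be boolean")
})

test_that("strict missing propagation holds for every binary operator", {
  t <- createTable(c("a", "b"), c("real", "boolean"),
                   rows = list(list(1, TRUE), list(NA, FALSE),
                               list(2, NA)))
  # FALSE & missing is missing here (stricter than SQL/Kleene)
  got <- asDataFrame(addColumn(t, "c", col("b") & lit(FALSE)))$c
  expect_identical(got, c(FALSE, FALSE, NA))
  got2 <- asDataFrame(addColumn(t, "d", col("a") + 1))$d
  expect_identical(is.na(got2), c(FALSE, TRUE, FALSE))
  # filter never selects rows whose predicate is missing
  expect_equal(numRows(filterRows(t, col("b") | lit(TRUE))), 2L)
})

test_that("joins match the nested-loop oracle in content and order", {
  for (seed in c(3, 14)) {
    set.seed(seed)
    a <- createTable(c("k", "x"), c("integer", "real"),
                     rows = list(k = sample.int(5L, 40, replace = TRUE),
                                 x = round(rnorm(40), 2)))
    b <- createTable(c("k", "y"), c("integer", "text"),
                     rows = list(k = sample.int(5L, 30, replace = TRUE),
                                 y = sample(letters[1:4], 30,
                                            replace = TRUE)))
    on <- col("k") == col("k__1")
    expectTableEqualsDf(joinTables(a, b, on),
                        oracleJoin(asDataFrame(a), asDataFrame(b), on))
    expectTableEqualsDf(leftJoin(a, b, on),
                        oracleJoin(asDataFrame(a), asDataFrame(b), on,
                                   left = TRUE))
  }
  a <- createTable(c("k"), c("integer"), rows = list(k = 1:5))
  expect_equal(numRows(joinTables(a, a, lit(FALSE))), 0L)
  expect_equal(numRows(leftJoin(a, a, lit(FALSE))), 5L)
  # self-join on a unique key keeps exactly one match per row
  expect_equal(numRows(joinTables(a, a, col("k") == col("k__1"))), 5L)
})

test_that("grouped aggregation matches the dictionary oracle", {
  for (seed in c(7, 21)) {
    t <- randomTable(seed)
    df <- asDataFrame(t)
    aggs <- list(n = c("count", "x"), s = c("sum", "x"),
                 m = c("mean", "x"), lo = c("min", "x"),
                 hi = c("max", "x"), md = c("median", "x"),
                 f1 = c("first", "id"))
    expectTableEqualsDf(groupAggregate(t, "grp", aggs),
                        oracleAggregate(df, "grp", aggs))
    expectTableEqualsDf(groupAggregate(t, c("grp", "flag"), aggs),
                        oracleAggregate(df, c("grp", "flag"), aggs))
    # empty key set: one whole-table group
    expect_equal(numRows(groupAggregate(t, character(0), aggs)), 1L)
  }
  t <- createTable(c("id", "txt"), c("integer", "text"),
                   rows = list(list(1L, "a")))
  expect_error(groupAggregate(t, "id", list(s = c("sum", "txt"))),
               "cannot sum")
  # key = unique id keeps the row count
  t2 <- createTable("id", "integer", rows = list(id = 1:17))
  expect_equal(numRows(groupAggregate(t2, "id",
                                      list(n = c("count", "id")))), 17L)
})

test_that("sort is stable and add_column computes per row", {
  t <- createTable(c("k", "ord"), c("integer", "integer"),
                   rows = list(k = c(2L, 1L, 2L, 1L, 2L),
                               ord = 1:5))
  s <- sortTable(t, "k")
  expect_equal(asDataFrame(s)$ord, c(2L, 4L, 1L, 3L, 5L))
  expect_identical(asDataFrame(sortTable(s, "k")), asDataFrame(s))
  sd <- sortTable(t, "k", descending = TRUE)
  expect_equal(asDataFrame(sd)$ord, c(1L, 3L, 5L, 2L, 4L))
  t2 <- addColumn(t, "sq", col("k") * col("k"))
  expect_equal(asDataFrame(t2)$sq, asDataFrame(t)$k^2)
  expect_error(addColumn(t, "k", col("k")), "already exists")
  # missing keys sort last
  tm <- createTable("k", "integer",
                    rows = list(list(NA), list(2L), list(1L)))
  expect_equal(asDataFrame(sortTable(tm, "k"))$k, c(1L, 2L, NA))
})

test_that("memory and disk mode agree on randomized op sequences", {
  for (seed in 1:12) {
    tm <- randomTable(seed)
    td <- setStorageMode(tm, "disk")
    expect_equal(storageMode(td), "disk")
    set.seed(seed * 1000L)
    for (step in 1:3) {
      op <- sample(c("filter", "add", "sort"), 1)
      if (op == "filter") {
        e <- col("x") > round(rnorm(1), 2)
        tm <- filterRows(tm, e); td <- filterRows(td, e)
      } else if (op == "add") {
        nm <- paste0("c", step)
        e <- col("x") * 2 + 1
        tm <- addColumn(tm, nm, e); td <- addColumn(td, nm, e)
      } else {
        tm <- sortTable(tm, "x"); td <- sortTable(td, "x")
      }
      expect_identical(asDataFrame(td), asDataFrame(tm))
    }
    # aggregation last (it replaces the schema)
    aggs <- list(n = c("count", "x"), m = c("mean", "x"))
    expect_identical(asDataFrame(groupAggregate(td, "grp", aggs)),
                     asDataFrame(groupAggregate(tm, "grp", aggs)))
  }
})

test_that("operations leave their inputs unchanged", {
  t <- randomTable(5)
  before <- asDataFrame(t)
  invisible(filterRows(t, col("x") > 0))
  invisible(addColumn(t, "z", col("x") + 1))
  invisible(sortTable(t, "x"))
  invisible(groupAggregate(t, "grp", list(n = c("count", "x"))))
  expect_identical(asDataFrame(t), before)
  td <- setStorageMode(t, "disk")
  invisible(filterRows(td, col("x") > 0))
  expect_identical(asDataFrame(td), before)
})

test_that("mode switches round-trip and applyRows is memory-only", {
  t <- randomTable(8)
  t2 <- setStorageMode(setStorageMode(t, "disk"), "memory")
  expect_equal(storageMode(t2), "memory")
  expect_identical(asDataFrame(t2), asDataFrame(t))
  td <- setStorageMode(t, "disk")
  expect_error(applyRows(td, function(r) r$x), "memory-mode-only")
  sums <- applyRows(t, function(r) r$id)
  expect_equal(unlist(sums), asDataFrame(t)$id)
})

test_that("save/load round-trips schema, rows, metadata and references", {
  for (seed in c(2, 13)) {
    t <- randomTable(seed)
    path <- withr::local_tempfile(fileext = ".table")
    saveTable(t, path)
    t2 <- loadTable(path)
    expect_identical(asDataFrame(t2), asDataFrame(t))
    expect_identical(columnTypes(t2), columnTypes(t))
  }
  # empty table
  p0 <- withr::local_tempfile(fileext = ".table")
  saveTable(createTable(c("a"), c("real")), p0)
  expect_equal(numRows(loadTable(p0)), 0L)
})

test_that("a peakmap referenced from two rows is stored once", {
  pm <- makeGaussianMap(131.0946, 1e4, 300, interval = 1,
                        span = c(280, 320))
  pt <- createTable(c("id", "peakmap"), c("integer", "peakmap"))
  key <- registerRef(pt, pm)
  pt <- createTable(c("id", "peakmap"), c("integer", "peakmap"),
                    rows = list(list(1L, key), list(2L, key)),
                    registry = pt@registry)
  path <- withr::local_tempfile(fileext = ".table")
  saveTable(pt, path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  nObjects <- DBI::dbGetQuery(con, "SELECT COUNT(*) AS n FROM objects")$n
  DBI::dbDisconnect(con)
  expect_equal(nObjects, 1L)
  t2 <- loadTable(path)
  pm2 <- refObject(t2, asDataFrame(t2)$peakmap[1])
  expect_identical(spectraRt(pm2), spectraRt(pm))
  # version guard
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(con,
    "UPDATE mzforge_meta SET value = '99' WHERE key = 'format_version'")
  DBI::dbDisconnect(con)
  expect_error(loadTable(path), "version")
})

test_that("nested table references survive persistence", {
  inner <- createTable("v", "real", rows = list(v = c(1.5, 2.5)))
  outer <- createTable(c("id", "sub"), c("integer", "table"))
  key <- registerRef(outer, inner)
  outer <- createTable(c("id", "sub"), c("integer", "table"),
                       rows = list(list(1L, key)),
                       registry = outer@registry)
  path <- withr::local_tempfile(fileext = ".table")
  saveTable(outer, path)
  o2 <- loadTable(path)
  inner2 <- refObject(o2, asDataFrame(o2)$sub[1])
  expect_identical(asDataFrame(inner2), asDataFrame(inner))
})

test_that("CSV round-trip with explicit types preserves values", {
  t <- randomTable(6)
  path <- withr::local_tempfile(fileext = ".csv")
  writeTableCsv(t, path)
  t2 <- readTableCsv(path, columnTypes(t))
  expect_identical(asDataFrame(t2), asDataFrame(t))
  expect_error(readTableCsv(path, c("integer")), "does not match")
})
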