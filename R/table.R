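# The MzTable relational engine. Rows live either in memory (a list of
# typed column vectors) or out-of-core in an embedded SQLite database
# file. Every operation runs the same chunked pipeline in both modes, so
# results are observationally identical; in disk mode the streaming
# operations (filter, addColumn, groupAggregate) hold only one chunk of
# rows resident at a time.

.SQL_TYPE <- c(integer = "INTEGER", real = "REAL", text = "TEXT",
               boolean = "INTEGER", peakmap = "INTEGER",
               table = "INTEGER")

.chunkSize <- function() getOption("mzforge.chunkSize", 10000L)

# ---- registry (shared reference store for peakmap / nested-table cells)

.newRegistry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$objs <- list()
  reg
}

.registerObject <- function(reg, obj) {
  for (k in seq_along(reg$objs))             # dedup by identity
    if (identical(reg$objs[[k]], obj)) return(k)
  reg$objs[[length(reg$objs) + 1L]] <- obj
  length(reg$objs)
}

#' Resolve a reference cell
#'
#' Reference-typed columns (`"peakmap"`, `"table"`) store integer keys;
#' this returns the referenced object.
#'
#' @param t An [MzTable-class].
#' @param key Integer key from a reference cell.
#' @return The referenced [PeakMap-class] or [MzTable-class].
#' @export
refObject <- function(t, key) {
  stopifnot(is(t, "MzTable"))
  if (is.na(key)) return(NULL)
  t@registry$objs[[key]]
}

#' Register an object for reference cells
#'
#' Registers a [PeakMap-class] or nested [MzTable-class] in the table's
#' registry and returns the integer key to store in a reference cell. The
#' same object (by identity) registers once, so a peakmap referenced from
#' many rows is held and persisted a single time.
#'
#' @param t An [MzTable-class].
#' @param obj The object to register.
#' @return Integer key.
#' @export
registerRef <- function(t, obj) .registerObject(t@registry, obj)

# ---- disk store

.newStore <- function(path) {
  store <- new.env(parent = emptyenv())
  store$path <- path
  store$con <- DBI::dbConnect(RSQLite::SQLite(), path)
  store$nextId <- 1L
  reg.finalizer(store, function(e)
    try(DBI::dbDisconnect(e$con), silent = TRUE), onexit = TRUE)
  store
}

.freshTab <- function(store) {
  id <- store$nextId
  store$nextId <- id + 1L
  sprintf("t%06d", id)
}

.qid <- function(x) paste0('"', gsub('"', '""', x), '"')

.createSqlTable <- function(store, tab, colNames, colTypes) {
  cols <- paste(.qid(colNames), .SQL_TYPE[colTypes], collapse = ", ")
  DBI::dbExecute(store$con, sprintf("CREATE TABLE %s (%s)", .qid(tab),
                                    cols))
}

# convert an R chunk (list of vectors) to / from SQLite representation
.toSql <- function(chunk, colTypes) {
  out <- chunk
  for (i in seq_along(out))
    if (colTypes[i] == "boolean") out[[i]] <- as.integer(out[[i]])
  as.data.frame(out, optional = TRUE, stringsAsFactors = FALSE)
}

.fromSql <- function(df, colNames, colTypes) {
  out <- vector("list", length(colNames))
  names(out) <- colNames
  for (i in seq_along(colNames)) {
    v <- df[[colNames[i]]]
    out[[i]] <- switch(colTypes[i],
      integer = as.integer(v),
      real = as.numeric(v),
      text = as.character(v),
      boolean = as.logical(v),
      peakmap = as.integer(v),
      table = as.integer(v))
  }
  out
}

# ---- construction

.emptyColumn <- function(type, n = 0L) {
  switch(type,
    integer = rep(NA_integer_, n), real = rep(NA_real_, n),
    text = rep(NA_character_, n), boolean = rep(NA, n),
    peakmap = rep(NA_integer_, n), table = rep(NA_integer_, n))
}

.newTable <- function(colNames, colTypes, formats, mode, registry,
                      meta = list(), store = NULL, path = NULL) {
  backend <- new.env(parent = emptyenv())
  if (mode == "memory") {
    backend$data <- lapply(colTypes, .emptyColumn)
    names(backend$data) <- colNames
  } else {
    if (is.null(store)) store <- .newStore(
      if (is.null(path)) tempfile(fileext = ".mztab") else path)
    backend$store <- store
    backend$tab <- .freshTab(store)
    .createSqlTable(store, backend$tab, colNames, colTypes)
  }
  new("MzTable", colNames = colNames, colTypes = colTypes,
      formats = formats, mode = mode, backend = backend,
      registry = registry, meta = meta)
}

.appendChunk <- function(t, chunk) {
  # chunk: named list of equal-length vectors in schema order
  if (!length(chunk[[1]]) && length(t@colNames)) return(invisible(t))
  if (t@mode == "memory") {
    for (i in seq_along(t@colNames)) {
      nm <- t@colNames[i]
      t@backend$data[[nm]] <- c(t@backend$data[[nm]], chunk[[nm]])
    }
  } else {
    DBI::dbWriteTable(t@backend$store$con, t@backend$tab,
                      .toSql(chunk[t@colNames], t@colTypes),
                      append = TRUE, row.names = FALSE)
  }
  invisible(t)
}

# iterate row chunks in stable order; f(chunk, n) is called per chunk
.forEachChunk <- function(t, f, chunkSize = .chunkSize()) {
  if (t@mode == "memory") {
    n <- .tblNRow(t)
    if (n > 0L || length(t@colNames) == 0L) f(t@backend$data, n)
    else f(t@backend$data, 0L)
    return(invisible(NULL))
  }
  # keyset pagination over rowid: avoids holding a cursor open, so the
  # callback may itself run statements on the shared connection
  con <- t@backend$store$con
  last <- -1
  repeat {
    df <- DBI::dbGetQuery(con, sprintf(
      "SELECT rowid AS mzforge_rid__, * FROM %s WHERE rowid > %.0f ORDER BY rowid LIMIT %d",
      .qid(t@backend$tab), last, as.integer(chunkSize)))
    if (!nrow(df)) break
    last <- max(df$mzforge_rid__)
    f(.fromSql(df, t@colNames, t@colTypes), nrow(df))
  }
  invisible(NULL)
}

# full materialization (used by join / sort / persistence)
.tblData <- function(t) {
  acc <- lapply(t@colTypes, .emptyColumn)
  names(acc) <- t@colNames
  .forEachChunk(t, function(chunk, n) {
    for (nm in t@colNames) acc[[nm]] <<- c(acc[[nm]], chunk[[nm]])
  })
  acc
}

.tblNRow <- function(t) {
  if (t@mode == "memory") {
    if (!length(t@colNames)) return(0L)
    length(t@backend$data[[1]])
  } else {
    as.integer(DBI::dbGetQuery(t@backend$store$con, sprintf(
      "SELECT COUNT(*) AS n FROM %s", .qid(t@backend$tab)))$n)
  }
}

.checkCell <- function(value, type, row, colName) {
  if (length(value) != 1L)
    stop("cell (row ", row, ", column '", colName, "') is not a scalar")
  if (is.na(value)) return(.naOf(type))
  ok <- switch(type,
    integer = is.numeric(value) && !is.na(value) &&
      abs(value - round(value)) < 1e-9,
    real = is.numeric(value),
    text = is.character(value),
    boolean = is.logical(value) || (is.numeric(value) && value %in% 0:1),
    peakmap = is.numeric(value) && value == round(value),
    table = is.numeric(value) && value == round(value))
  if (!ok)
    stop("type mismatch at row ", row, ", column '", colName,
         "': expected ", type, ", got ", class(value)[1])
  switch(type,
    integer = as.integer(round(value)), real = as.numeric(value),
    text = as.character(value), boolean = as.logical(value),
    peakmap = as.integer(value), table = as.integer(value))
}

.naOf <- function(type)
  switch(type, integer = NA_integer_, real = NA_real_,
         text = NA_character_, boolean = NA, peakmap = NA_integer_,
         table = NA_integer_)

#' Create a table
#'
#' @param colNames Unique column names (case-sensitive identifiers).
#' @param colTypes Types, one of `"integer"`, `"real"`, `"text"`,
#'   `"boolean"`, `"peakmap"`, `"table"`.
#' @param rows Either a list of row lists, or a data.frame / named list of
#'   column vectors. Missing cells are allowed (`NA`).
#' @param formats Display format strings, recycled.
#' @param mode `"memory"` (default) or `"disk"`.
#' @param path SQLite file backing a disk-mode table (tempfile by
#'   default).
#' @param registry Optionally share the reference registry of another
#'   table.
#' @param meta Named list of table metadata.
#' @return An [MzTable-class].
#' @examples
#' t <- createTable(c("id", "mz"), c("integer", "real"),
#'                  list(list(1L, 131.09), list(2L, 132.10)))
#' numRows(t)
#' @export
createTable <- function(colNames, colTypes, rows = list(),
                        formats = "%s", mode = c("memory", "disk"),
                        path = NULL, registry = NULL, meta = list()) {
  mode <- match.arg(mode)
  colNames <- as.character(colNames)
  colTypes <- as.character(colTypes)
  if (anyDuplicated(colNames))
    stop("duplicate column name: ",
         colNames[duplicated(colNames)][1])
  if (length(colTypes) != length(colNames))
    stop("colTypes must match colNames in length")
  formats <- rep_len(as.character(formats), length(colNames))
  if (is.null(registry)) registry <- .newRegistry()
  t <- .newTable(colNames, colTypes, formats, mode, registry,
                 meta = meta, path = path)

  if (is.data.frame(rows) || (is.list(rows) && !is.null(names(rows)) &&
                              length(rows) == length(colNames) &&
                              all(colNames %in% names(rows)))) {
    n <- if (is.data.frame(rows)) nrow(rows) else
      if (length(rows)) length(rows[[1]]) else 0L
    chunk <- lapply(seq_along(colNames), function(i) {
      v <- rows[[colNames[i]]]
      vapply(seq_len(n), function(r) .checkCell(v[[r]], colTypes[i], r,
                                                colNames[i]),
             .naOf(colTypes[i]))
    })
    names(chunk) <- colNames
    if (n > 0L) .appendChunk(t, chunk)
  } else if (length(rows)) {
    chunk <- lapply(colTypes, .emptyColumn, n = length(rows))
    names(chunk) <- colNames
    for (r in seq_along(rows)) {
      row <- rows[[r]]
      if (length(row) != length(colNames))
        stop("row ", r, " has ", length(row), " cells; expected ",
             length(colNames))
      for (i in seq_along(colNames))
        chunk[[i]][r] <- .checkCell(row[[i]], colTypes[i], r, colNames[i])
    }
    .appendChunk(t, chunk)
  }
  t
}

#' @rdname numRows
#' @export
setMethod("numRows", "MzTable", function(x) .tblNRow(x))

#' @rdname columnNames
#' @export
setMethod("columnNames", "MzTable", function(x) x@colNames)

#' @rdname columnTypes
#' @export
setMethod("columnTypes", "MzTable", function(x) x@colTypes)

#' @rdname storageMode
#' @export
setMethod("storageMode", "MzTable", function(x) x@mode)

#' Table metadata
#' @param t An [MzTable-class].
#' @return Named list.
#' @export
tableMeta <- function(t) t@meta

setMethod("show", "MzTable", function(object) {
  n <- .tblNRow(object)
  cat(sprintf("MzTable: %d rows x %d columns [%s]\n", n,
              length(object@colNames), object@mode))
  cat("  ", paste(object@colNames, " <", object@colTypes, ">",
                  sep = "", collapse = ", "), "\n", sep = "")
  if (n > 0L) {
    df <- asDataFrame(utils::head(asDataFrame(object), 6L))
    print(utils::head(df, 6L))
    if (n > 6L) cat("  ... and", n - 6L, "more rows\n")
  }
})

#' Materialize a table as a data.frame
#'
#' Reference columns come back as integer keys (resolve with
#' [refObject()]).
#'
#' @param t An [MzTable-class] or data.frame (returned unchanged).
#' @return A data.frame in row order.
#' @export
asDataFrame <- function(t) {
  if (is.data.frame(t)) return(t)
  d <- .tblData(t)
  if (!length(d)) return(data.frame())
  as.data.frame(d, optional = TRUE, stringsAsFactors = FALSE)
}

.derive <- function(t, colNames = t@colNames, colTypes = t@colTypes,
                    formats = t@formats, meta = t@meta) {
  store <- if (t@mode == "disk") t@backend$store else NULL
  .newTable(colNames, colTypes, formats, t@mode, t@registry, meta = meta,
            store = store)
}

#' Filter rows by a predicate expression
#'
#' Keeps rows where the boolean expression evaluates to true, preserving
#' order. A missing predicate never selects a row (three-valued logic).
#'
#' @param t An [MzTable-class].
#' @param e A boolean [TableExpr-class], e.g. `col("area") > 100`.
#' @return A new [MzTable-class]; the input is unchanged.
#' @export
filterRows <- function(t, e) {
  stopifnot(is(t, "MzTable"), is(e, "TableExpr"))
  if (.exprType(e@node, t@colNames, t@colTypes) != "boolean")
    stop("filter expression must be boolean")
  out <- .derive(t)
  .forEachChunk(t, function(chunk, n) {
    keep <- .exprEval(e@node, chunk, n)
    keep <- !is.na(keep) & keep
    .appendChunk(out, lapply(chunk, `[`, keep))
  })
  out
}

#' Append a computed column
#'
#' @param t An [MzTable-class].
#' @param name New column name (must not collide).
#' @param e A [TableExpr-class] computed per row.
#' @param format Display format string.
#' @return A new [MzTable-class] with the extra column.
#' @export
addColumn <- function(t, name, e, format = "%s") {
  stopifnot(is(t, "MzTable"), is(e, "TableExpr"))
  if (name %in% t@colNames) stop("column already exists: ", name)
  type <- .exprType(e@node, t@colNames, t@colTypes)
  out <- .derive(t, colNames = c(t@colNames, name),
                 colTypes = c(t@colTypes, type),
                 formats = c(t@formats, format))
  .forEachChunk(t, function(chunk, n) {
    v <- .exprEval(e@node, chunk, n)
    chunk[[name]] <- rep_len(v, n)
    .appendChunk(out, chunk)
  })
  out
}

#' Stable sort
#'
#' Sorts by one or more columns; ties keep their original order and
#' missing values sort last.
#'
#' @param t An [MzTable-class].
#' @param by Column names.
#' @param descending Logical, recycled over `by`.
#' @return A new sorted [MzTable-class].
#' @export
sortTable <- function(t, by, descending = FALSE) {
  stopifnot(is(t, "MzTable"), all(by %in% t@colNames))
  descending <- rep_len(descending, length(by))
  d <- .tblData(t)
  keys <- lapply(seq_along(by), function(i) {
    v <- d[[by[i]]]
    if (is.character(v)) v <- xtfrm(v)
    if (descending[i]) -xtfrm(v) else xtfrm(v)
  })
  o <- do.call(order, c(keys, list(na.last = TRUE, method = "radix")))
  out <- .derive(t)
  .appendChunk(out, lapply(d, `[`, o))
  out
}

#' Join two tables on a predicate
#'
#' Inner join emits every (left row, right row) pair satisfying `on`,
#' ordered by left row then right row; [leftJoin()] additionally emits
#' unmatched left rows with missing right cells. Right-side columns whose
#' names collide with left-side names are suffixed with `suffix` — the
#' `on` expression is written against the suffixed schema.
#'
#' @param left,right [MzTable-class] objects.
#' @param on A boolean [TableExpr-class] over the combined schema.
#' @param suffix Collision suffix for right-side names (default `"__1"`).
#' @return A new [MzTable-class].
#' @export
joinTables <- function(left, right, on, suffix = "__1") {
  .joinImpl(left, right, on, suffix, keepUnmatched = FALSE)
}

#' @rdname joinTables
#' @export
leftJoin <- function(left, right, on, suffix = "__1") {
  .joinImpl(left, right, on, suffix, keepUnmatched = TRUE)
}

.joinImpl <- function(left, right, on, suffix, keepUnmatched) {
  stopifnot(is(left, "MzTable"), is(right, "MzTable"), is(on, "TableExpr"))
  rNames <- ifelse(right@colNames %in% left@colNames,
                   paste0(right@colNames, suffix), right@colNames)
  if (anyDuplicated(c(left@colNames, rNames)))
    stop("column name collision persists after suffixing")
  outNames <- c(left@colNames, rNames)
  outTypes <- c(left@colTypes, right@colTypes)
  if (.exprType(on@node, outNames, outTypes) != "boolean")
    stop("join predicate must be boolean")
  # merge registries: right-side reference keys are remapped
  registry <- left@registry
  remap <- vapply(seq_along(right@registry$objs), function(k)
    .registerObject(registry, right@registry$objs[[k]]), integer(1))
  rData <- .tblData(right)
  names(rData) <- rNames
  refCols <- rNames[right@colTypes %in% c("peakmap", "table")]
  for (nm in refCols) {
    v <- rData[[nm]]
    v[!is.na(v)] <- remap[v[!is.na(v)]]
    rData[[nm]] <- v
  }
  nR <- if (length(rData)) length(rData[[1]]) else 0L

  store <- if (left@mode == "disk") left@backend$store else NULL
  out <- .newTable(outNames, outTypes,
                   c(left@formats, right@formats), left@mode, registry,
                   meta = left@meta, store = store)
  .forEachChunk(left, function(chunk, n) {
    for (r in seq_len(n)) {
      lrow <- lapply(chunk, `[`, r)
      combined <- c(lapply(lrow, rep, nR), rData)
      hit <- if (nR) {
        v <- .exprEval(on@node, combined, nR)
        which(!is.na(v) & v)
      } else integer(0)
      if (length(hit)) {
        block <- c(lapply(lrow, rep, length(hit)),
                   lapply(rData, `[`, hit))
        .appendChunk(out, block)
      } else if (keepUnmatched) {
        block <- c(lrow, lapply(seq_along(rNames), function(i)
          .naOf(right@colTypes[i])))
        names(block) <- outNames
        .appendChunk(out, block)
      }
    }
  })
  out
}

# ---- grouped aggregation

.AGGS <- c("count", "sum", "mean", "min", "max", "median", "first")

.aggOutType <- function(fun, type) {
  num <- c("integer", "real", "boolean")
  switch(fun,
    count = "integer",
    sum = {
      if (!type %in% num) stop("cannot sum a ", type, " column")
      if (type == "real") "real" else "integer"
    },
    mean = , median = {
      if (!type %in% num) stop("cannot take ", fun, " of a ", type,
                               " column")
      "real"
    },
    min = , max = {
      if (!type %in% c(num, "text"))
        stop("cannot take ", fun, " of a ", type, " column")
      if (type == "boolean") "boolean" else type
    },
    first = type)
}

#' Grouped aggregation
#'
#' One output row per distinct key tuple (missing keys group together),
#' ordered by first appearance. Aggregates ignore missing values; `count`
#' counts non-missing cells.
#'
#' @param t An [MzTable-class].
#' @param keys Character vector of key column names (may be empty for a
#'   single whole-table group).
#' @param aggregations Named list; each element is `c(fun, column)` with
#'   `fun` one of `count`, `sum`, `mean`, `min`, `max`, `median`,
#'   `first`. Names become output column names.
#' @return A new [MzTable-class] with the key columns followed by the
#'   aggregate columns.
#' @export
groupAggregate <- function(t, keys, aggregations) {
  stopifnot(is(t, "MzTable"), all(keys %in% t@colNames))
  funs <- vapply(aggregations, `[`, character(1), 1L)
  cols <- vapply(aggregations, `[`, character(1), 2L)
  if (!all(funs %in% .AGGS))
    stop("unknown aggregate: ", paste(setdiff(funs, .AGGS), collapse = ", "))
  if (!all(cols %in% t@colNames))
    stop("unknown column: ", paste(setdiff(cols, t@colNames),
                                   collapse = ", "))
  srcTypes <- t@colTypes[match(cols, t@colNames)]
  outTypes <- mapply(.aggOutType, funs, srcTypes)
  outNames <- c(keys, names(aggregations))
  if (anyDuplicated(outNames)) stop("duplicate output column names")

  groups <- new.env(parent = emptyenv())   # key string -> state
  order_ <- character(0)
  keyTypes <- t@colTypes[match(keys, t@colNames)]

  .forEachChunk(t, function(chunk, n) {
    keyStr <- if (length(keys)) {
      parts <- lapply(keys, function(k) {
        v <- chunk[[k]]
        ifelse(is.na(v), "\x01NA", paste0("v", as.character(v)))
      })
      paste0("k", do.call(paste, c(parts, list(sep = "\x1f"))))
    } else rep("k", n)
    for (r in seq_len(n)) {
      ks <- keyStr[r]
      st <- groups[[ks]]
      if (is.null(st)) {
        st <- list(key = lapply(keys, function(k) chunk[[k]][r]),
                   acc = lapply(seq_along(funs), function(j)
                     list(n = 0L, sum = 0, min = NULL, max = NULL,
                          first = NULL, values = NULL)))
        order_ <<- c(order_, ks)
      }
      for (j in seq_along(funs)) {
        v <- chunk[[cols[j]]][r]
        if (is.na(v)) next
        a <- st$acc[[j]]
        a$n <- a$n + 1L
        if (funs[j] == "sum" || funs[j] == "mean")
          a$sum <- a$sum + as.numeric(v)
        if (funs[j] == "min")
          a$min <- if (is.null(a$min)) v else min(a$min, v)
        if (funs[j] == "max")
          a$max <- if (is.null(a$max)) v else max(a$max, v)
        if (funs[j] == "first" && is.null(a$first)) a$first <- v
        if (funs[j] == "median") a$values <- c(a$values, v)
        st$acc[[j]] <- a
      }
      groups[[ks]] <- st
    }
  })

  store <- if (t@mode == "disk") t@backend$store else NULL
  out <- .newTable(outNames, c(keyTypes, unname(outTypes)),
                   rep("%s", length(outNames)), t@mode, t@registry,
                   meta = t@meta, store = store)
  m <- length(order_)
  chunk <- lapply(c(keyTypes, unname(outTypes)), .emptyColumn, n = m)
  names(chunk) <- outNames
  for (g in seq_len(m)) {
    st <- groups[[order_[g]]]
    for (i in seq_along(keys))
      chunk[[keys[i]]][g] <- st$key[[i]]
    for (j in seq_along(funs)) {
      a <- st$acc[[j]]
      nm <- names(aggregations)[j]
      val <- switch(funs[j],
        count = a$n,
        sum = if (a$n) a$sum else NA,
        mean = if (a$n) a$sum / a$n else NA,
        min = if (is.null(a$min)) NA else a$min,
        max = if (is.null(a$max)) NA else a$max,
        median = if (is.null(a$values)) NA
                 else stats::median(as.numeric(a$values)),
        first = if (is.null(a$first)) NA else a$first)
      if (!is.na(val) || TRUE)
        chunk[[nm]][g] <- if (is.na(val)) .naOf(unname(outTypes[j]))
                          else .checkCell(val, unname(outTypes[j]), g, nm)
    }
  }
  if (m > 0L) .appendChunk(out, chunk)
  out
}

#' Switch storage mode
#'
#' Copies the table into the other backend. The result is observationally
#' identical under every table operation; in disk mode the streaming
#' operations keep only one chunk of rows in memory.
#'
#' @param t An [MzTable-class].
#' @param mode `"memory"` or `"disk"`.
#' @param path SQLite file for disk mode (tempfile by default).
#' @return A new [MzTable-class] in the requested mode.
#' @export
setStorageMode <- function(t, mode = c("memory", "disk"), path = NULL) {
  mode <- match.arg(mode)
  if (mode == t@mode) return(t)
  out <- .newTable(t@colNames, t@colTypes, t@formats, mode, t@registry,
                   meta = t@meta, path = path)
  .forEachChunk(t, function(chunk, n) .appendChunk(out, chunk))
  out
}

#' Row-wise apply (escape hatch)
#'
#' Applies `f` to every row (as a named list). This leaves the closed
#' expression language and therefore requires memory mode.
#'
#' @param t A memory-mode [MzTable-class].
#' @param f Function of one row list.
#' @return List of results, one per row.
#' @export
applyRows <- function(t, f) {
  stopifnot(is(t, "MzTable"))
  if (t@mode != "memory")
    stop("applyRows is memory-mode-only; use setStorageMode() first")
  d <- t@backend$data
  n <- .tblNRow(t)
  lapply(seq_len(n), function(r) f(lapply(d, `[`, r)))
}
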