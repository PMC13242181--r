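# Single-file table persistence (SQLite, versioned schema) and delimited
# text import/export.
#
# File layout (format version 1):
#   mzforge_meta : key / value pairs — format_version, schema (JSON:
#                  colNames, colTypes, formats), meta (JSON)
#   rows         : the data, one SQL column per table column (booleans as
#                  0/1 integers, reference cells as integer keys)
#   objects      : key / kind / data — each referenced object serialized
#                  once (peakmaps and nested tables are deduplicated by
#                  reference key)

.FORMAT_VERSION <- 1L

# portable representation of a table (used for nested-table blobs)
.tableToList <- function(t) {
  d <- .tblData(t)
  usedKeys <- sort(unique(unlist(lapply(
    which(t@colTypes %in% c("peakmap", "table")),
    function(i) d[[i]][!is.na(d[[i]])]))))
  objs <- lapply(usedKeys, function(k) {
    obj <- t@registry$objs[[k]]
    if (is(obj, "MzTable")) list(kind = "table", value = .tableToList(obj))
    else list(kind = "peakmap", value = obj)
  })
  list(colNames = t@colNames, colTypes = t@colTypes,
       formats = t@formats, meta = t@meta, data = d,
       objKeys = usedKeys, objs = objs)
}

.tableFromList <- function(x, mode = "memory", path = NULL) {
  registry <- .newRegistry()
  remap <- integer(0)
  for (i in seq_along(x$objKeys)) {
    o <- x$objs[[i]]
    obj <- if (o$kind == "table") .tableFromList(o$value) else o$value
    remap[x$objKeys[i]] <- .registerObject(registry, obj)
  }
  d <- x$data
  for (i in which(x$colTypes %in% c("peakmap", "table"))) {
    v <- d[[i]]
    v[!is.na(v)] <- remap[v[!is.na(v)]]
    d[[i]] <- v
  }
  t <- .newTable(x$colNames, x$colTypes, x$formats, mode, registry,
                 meta = x$meta, path = path)
  n <- if (length(d)) length(d[[1]]) else 0L
  if (n > 0L) .appendChunk(t, d)
  t
}

#' Save a table to a single file
#'
#' Persists schema, rows, metadata and all referenced objects into one
#' SQLite database file. Objects referenced from several cells are stored
#' once. The file carries a format version; [loadTable()] rejects files
#' with an unsupported version.
#'
#' @param t An [MzTable-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
saveTable <- function(t, path) {
  stopifnot(is(t, "MzTable"))
  if (file.exists(path)) file.remove(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con,
    "CREATE TABLE mzforge_meta (key TEXT PRIMARY KEY, value TEXT)")
  schema <- jsonlite::toJSON(list(colNames = t@colNames,
                                  colTypes = t@colTypes,
                                  formats = t@formats))
  DBI::dbExecute(con, "INSERT INTO mzforge_meta VALUES (?, ?)",
                 params = list(c("format_version", "schema", "meta"),
                               c(as.character(.FORMAT_VERSION),
                                 as.character(schema),
                                 as.character(jsonlite::serializeJSON(
                                   t@meta)))))
  cols <- paste(.qid(t@colNames), .SQL_TYPE[t@colTypes], collapse = ", ")
  if (length(t@colNames))
    DBI::dbExecute(con, sprintf("CREATE TABLE rows (%s)", cols))
  else
    DBI::dbExecute(con, "CREATE TABLE rows (dummy__ INTEGER)")
  d <- .tblData(t)
  n <- if (length(d)) length(d[[1]]) else 0L
  if (n > 0L)
    DBI::dbWriteTable(con, "rows", .toSql(d, t@colTypes), append = TRUE,
                      row.names = FALSE)
  DBI::dbExecute(con,
    "CREATE TABLE objects (key INTEGER PRIMARY KEY, kind TEXT, data BLOB)")
  usedKeys <- sort(unique(unlist(lapply(
    which(t@colTypes %in% c("peakmap", "table")),
    function(i) d[[i]][!is.na(d[[i]])]))))
  for (k in usedKeys) {
    obj <- t@registry$objs[[k]]
    if (is(obj, "MzTable")) {
      kind <- "table"
      blob <- serialize(.tableToList(obj), NULL)
    } else {
      kind <- "peakmap"
      blob <- serialize(obj, NULL)
    }
    DBI::dbExecute(con, "INSERT INTO objects VALUES (?, ?, ?)",
                   params = list(as.integer(k), kind, list(blob)))
  }
  invisible(path)
}

#' Load a table from a single file
#'
#' @param path File written by [saveTable()].
#' @param mode Storage mode of the loaded table.
#' @return An [MzTable-class].
#' @export
loadTable <- function(path, mode = c("memory", "disk")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  meta <- DBI::dbReadTable(con, "mzforge_meta")
  ver <- as.integer(meta$value[meta$key == "format_version"])
  if (!length(ver) || ver != .FORMAT_VERSION)
    stop("unsupported table file format version: ",
         if (length(ver)) ver else "missing")
  schema <- jsonlite::fromJSON(meta$value[meta$key == "schema"])
  tmeta <- jsonlite::unserializeJSON(meta$value[meta$key == "meta"])
  df <- DBI::dbReadTable(con, "rows")
  objects <- DBI::dbReadTable(con, "objects")

  registry <- .newRegistry()
  if (nrow(objects)) {
    for (i in seq_len(nrow(objects))) {
      obj <- unserialize(objects$data[[i]])
      if (objects$kind[i] == "table") obj <- .tableFromList(obj)
      registry$objs[[objects$key[i]]] <- obj
    }
  }
  colNames <- as.character(schema$colNames)
  colTypes <- as.character(schema$colTypes)
  t <- .newTable(colNames, colTypes, as.character(schema$formats), mode,
                 registry, meta = tmeta)
  if (nrow(df) && length(colNames))
    .appendChunk(t, .fromSql(df, colNames, colTypes))
  t
}

#' Export a table to delimited text
#'
#' Writes CSV (or TSV) with a header. Reference columns are written as
#' their integer keys.
#'
#' @param t An [MzTable-class].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
writeTableCsv <- function(t, path, sep = ",") {
  df <- asDataFrame(t)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = TRUE, na = "")
  invisible(path)
}

#' Import a table from delimited text
#'
#' Column types are explicit: no type sniffing is performed.
#'
#' @param path Input path with a header row.
#' @param colTypes Character vector of types in file column order.
#' @param sep Field separator (sniffed between comma and tab from the
#'   header line only).
#' @return An [MzTable-class].
#' @export
readTableCsv <- function(path, colTypes, sep = NULL) {
  if (is.null(sep)) sep <- .sniffSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE, na.strings = "",
                          check.names = FALSE)
  if (length(colTypes) != ncol(df))
    stop("colTypes length ", length(colTypes), " does not match ",
         ncol(df), " file columns")
  cols <- lapply(seq_along(colTypes), function(i) {
    v <- df[[i]]
    switch(colTypes[i],
      integer = as.integer(v), real = as.numeric(v), text = v,
      boolean = as.logical(v), peakmap = as.integer(v),
      table = as.integer(v))
  })
  names(cols) <- names(df)
  createTable(names(df), colTypes, rows = cols)
}
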