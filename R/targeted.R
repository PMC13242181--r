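# Targeted extraction: peak tables from target lists, reference-based
# RT-shift estimation, and the end-to-end workflow that corrects
# integration windows for co-eluting mass isomers.

#' Read a target list
#'
#' Delimited text (comma or tab) with header columns `name`, `formula`,
#' `adduct`, `rt_sec`, `rt_tol_sec`, `mz_tol`, `role`. `mz_tol` carries
#' its unit as a suffix: `"10ppm"` or `"0.003da"`. `role` is
#' `"reference"` or `"analyte"`.
#'
#' @param path File path.
#' @return A data.frame of validated targets with numeric `mz_tol` and a
#'   separate `mz_tol_unit` column.
#' @export
readTargets <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sniffSep(path),
                          stringsAsFactors = FALSE)
  need <- c("name", "formula", "adduct", "rt_sec", "rt_tol_sec",
            "mz_tol", "role")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("target list lacks columns: ", paste(miss, collapse = ", "))
  tol <- as.character(df$mz_tol)
  unit <- ifelse(grepl("ppm$", tol, ignore.case = TRUE), "ppm",
          ifelse(grepl("da$", tol, ignore.case = TRUE), "da", NA))
  if (any(is.na(unit)))
    stop("mz_tol needs a 'ppm' or 'da' suffix: ",
         paste(tol[is.na(unit)], collapse = ", "))
  df$mz_tol <- as.numeric(sub("(ppm|da)$", "", tol, ignore.case = TRUE))
  df$mz_tol_unit <- unit
  validTargets(df)
}

#' Validate a target data.frame
#'
#' @param targets data.frame with the columns of [readTargets()]
#'   (`mz_tol` numeric plus `mz_tol_unit`).
#' @return The validated data.frame.
#' @export
validTargets <- function(targets) {
  stopifnot(is.data.frame(targets))
  if (any(targets$rt_tol_sec <= 0) || any(targets$mz_tol <= 0))
    stop("target tolerances must be > 0")
  if (any(targets$rt_sec < 0)) stop("expected rt must be >= 0")
  if (!all(targets$role %in% c("reference", "analyte")))
    stop("target role must be 'reference' or 'analyte'")
  if (anyDuplicated(targets$name)) stop("target names must be unique")
  targets
}

# theoretical m/z and Da tolerance for one target row
.targetMz <- function(tg, lib = defaultAdducts()) {
  ad <- lib[[tg$adduct]]
  if (is.null(ad))
    stop("target '", tg$name, "': unknown adduct ", tg$adduct)
  mz <- tryCatch(adductMz(monoisotopicMass(tg$formula), ad),
                 error = function(e)
                   stop("target '", tg$name, "': ", conditionMessage(e),
                        call. = FALSE))
  tolDa <- if (tg$mz_tol_unit == "ppm") mz * tg$mz_tol * 1e-6
           else tg$mz_tol
  list(mz = mz, tolDa = tolDa)
}

#' Build a peak table from targets
#'
#' One row per target: theoretical m/z from formula and adduct, m/z
#' window `mz -/+ tolerance` (ppm tolerances converted at the theoretical
#' m/z), rt window `rt_sec -/+ rt_tol_sec`, and a reference to the
#' peakmap — the peak-table convention consumed by [integrateTable()].
#'
#' @param targets Validated target data.frame (see [readTargets()]).
#' @param pm A [PeakMap-class].
#' @return An [MzTable-class] with columns `id`, `name`, `role`, `mz`,
#'   `mzmin`, `mzmax`, `rtmin`, `rtmax`, `peakmap`.
#' @export
buildPeakTable <- function(targets, pm) {
  targets <- validTargets(targets)
  lib <- defaultAdducts()
  pt <- createTable(
    c("id", "name", "role", "mz", "mzmin", "mzmax", "rtmin", "rtmax",
      "peakmap"),
    c("integer", "text", "text", "real", "real", "real", "real", "real",
      "peakmap"))
  key <- if (nrow(targets)) registerRef(pt, pm) else NA_integer_
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    tg <- targets[i, ]
    z <- .targetMz(tg, lib)
    list(as.integer(i), tg$name, tg$role, z$mz, z$mz - z$tolDa,
         z$mz + z$tolDa, tg$rt_sec - tg$rt_tol_sec,
         tg$rt_sec + tg$rt_tol_sec, key)
  })
  if (length(rows))
    pt <- createTable(columnNames(pt), columnTypes(pt), rows,
                      registry = pt@registry)
  pt
}

#' Locate the EIC apex of a target
#'
#' Extracts the target's EIC over the given window and returns the rt of
#' its maximum (earliest rt on ties), refined below the sampling interval
#' by the standard three-point parabolic interpolation around the apex
#' sample (the vertex is clamped to the two neighbouring samples, so the
#' refinement can never move the apex by more than one scan). A maximum
#' of zero counts as not found — not an error.
#'
#' @param pm A [PeakMap-class].
#' @param mzmin,mzmax,rtmin,rtmax Extraction window.
#' @param smoothPts Savitzky-Golay window (odd) applied to the EIC before
#'   apex picking when the trace has at least that many points; 0
#'   disables smoothing.
#' @return `list(found, rt, intensity)`; `found = FALSE` when the window
#'   holds no signal.
#' @export
locateApex <- function(pm, mzmin, mzmax, rtmin, rtmax, smoothPts = 7L) {
  eic <- extractEIC(pm, mzmin, mzmax, rtmin, rtmax)
  if (!length(eic@rt) || max(eic@intensity) <= 0)
    return(list(found = FALSE, rt = NA_real_, intensity = NA_real_))
  y <- eic@intensity
  if (smoothPts >= 3L && length(y) >= smoothPts)
    y <- signal::sgolayfilt(y, p = 2L, n = as.integer(smoothPts))
  i <- which.max(y)                       # earliest rt on ties
  rtApex <- eic@rt[i]
  n <- length(eic@rt)
  if (i > 1L && i < n) {
    y0 <- y[i - 1L]; y1 <- y[i]; y2 <- y[i + 1L]
    denom <- y0 - 2 * y1 + y2
    # strict local maximum and negative curvature -> parabolic vertex
    if (denom < 0 && (y1 > y0 || y1 > y2)) {
      h <- (eic@rt[i + 1L] - eic@rt[i - 1L]) / 2
      off <- 0.5 * (y0 - y2) / denom * h
      rtApex <- eic@rt[i] + max(min(off, h), -h)
    }
  }
  list(found = TRUE, rt = rtApex, intensity = eic@intensity[i])
}

#' Estimate a per-sample RT shift from reference compounds
#'
#' Each reference target is searched in a widened window
#' (`rt_tol_sec * searchFactor`); the shift is the configured robust
#' summary (median by default) of apex-minus-expected rt over the located
#' references. References without signal are excluded; zero located
#' references is an error naming the sample.
#'
#' @param pm A [PeakMap-class].
#' @param targets Target data.frame; rows with `role == "reference"` are
#'   used.
#' @param searchFactor Widening factor for the reference search window
#'   (default 3).
#' @param summary `"median"` (robust to one failed reference) or
#'   `"mean"`.
#' @param sampleId Identifier used in messages and the result.
#' @return An [RtShiftEstimate-class].
#' @export
estimateRtShift <- function(pm, targets, searchFactor = 3,
                            summary = c("median", "mean"),
                            sampleId = "sample") {
  summary <- match.arg(summary)
  refs <- validTargets(targets)
  refs <- refs[refs$role == "reference", , drop = FALSE]
  if (!nrow(refs)) stop("no reference targets for sample ", sampleId)
  lib <- defaultAdducts()
  dev <- data.frame(name = character(0), deltaRt = numeric(0))
  for (i in seq_len(nrow(refs))) {
    tg <- refs[i, ]
    z <- .targetMz(tg, lib)
    half <- tg$rt_tol_sec * searchFactor
    ap <- locateApex(pm, z$mz - z$tolDa, z$mz + z$tolDa,
                     tg$rt_sec - half, tg$rt_sec + half)
    if (ap$found)
      dev <- rbind(dev, data.frame(name = tg$name,
                                   deltaRt = ap$rt - tg$rt_sec))
  }
  if (!nrow(dev))
    stop("rt-shift estimation failed for sample ", sampleId,
         ": no reference located")
  shift <- if (summary == "median") stats::median(dev$deltaRt)
           else mean(dev$deltaRt)
  new("RtShiftEstimate", sampleId = sampleId, shift = shift,
      deviations = dev, nUsed = nrow(dev), summary = summary)
}

setMethod("show", "RtShiftEstimate", function(object) {
  cat(sprintf("RtShiftEstimate [%s]: %+.3f s (%s of %d references)\n",
              object@sampleId, object@shift, object@summary,
              object@nUsed))
})

#' @describeIn estimateRtShift The estimated shift in seconds.
#' @param x An [RtShiftEstimate-class].
#' @export
shiftSeconds <- function(x) x@shift

#' Shift the rt windows of selected targets
#'
#' Translates `rtmin`/`rtmax` of the selected rows by `shift` seconds;
#' all other columns and rows are unchanged. Translation preserves window
#' gaps, so windows that did not overlap before shifting do not overlap
#' after.
#'
#' @param pt A peak table with a `name` column (from
#'   [buildPeakTable()]).
#' @param shift Shift in seconds (signed).
#' @param names Target names to shift; `NULL` shifts every row.
#' @return A new [MzTable-class].
#' @export
applyRtShift <- function(pt, shift, names = NULL) {
  d <- asDataFrame(pt)
  sel <- if (is.null(names)) rep(TRUE, nrow(d)) else {
    unknown <- setdiff(names, d$name)
    if (length(unknown))
      stop("unknown target name: ", paste(unknown, collapse = ", "))
    d$name %in% names
  }
  d$rtmin[sel] <- d$rtmin[sel] + shift
  d$rtmax[sel] <- d$rtmax[sel] + shift
  out <- .newTable(pt@colNames, pt@colTypes, pt@formats, pt@mode,
                   pt@registry, meta = pt@meta,
                   store = if (pt@mode == "disk") pt@backend$store)
  .appendChunk(out, as.list(d)[pt@colNames])
  out
}

#' Run the targeted workflow over samples
#'
#' For every sample: load (if a path), build the peak table, optionally
#' estimate the rt shift from the reference targets and translate the
#' integration windows of the selected analytes, integrate, and locate
#' each target's apex. Samples whose shift estimation fails are emitted
#' with `shiftOk = FALSE` and integrated uncorrected rather than dropped;
#' unreadable sample files yield flagged rows and the run continues.
#'
#' @param samples Named list of [PeakMap-class] objects or mzML paths;
#'   names become sample ids.
#' @param targets Target data.frame (see [readTargets()]).
#' @param correction Apply reference-based rt-shift correction.
#' @param shiftNames Target names whose windows are shifted; `NULL`
#'   shifts all targets.
#' @param method,params Integration method and extra arguments (see
#'   [integrateTable()]).
#' @param searchFactor,summary Passed to [estimateRtShift()].
#' @param workers Parallel workers for integration.
#' @return A long-format [MzTable-class], one row per sample x target:
#'   `sample`, `name`, `role`, `mz`, `shift`, `shiftOk`, `method`,
#'   `area`, `rmse`, `apexRt`.
#' @export
runTargetedWorkflow <- function(samples, targets, correction = TRUE,
                                shiftNames = NULL, method = "trapezoid",
                                params = list(), searchFactor = 3,
                                summary = "median", workers = 1L) {
  stopifnot(length(samples) >= 1L)
  targets <- validTargets(targets)
  if (correction && !any(targets$role == "reference"))
    stop("rt-shift correction needs at least one reference target")
  ids <- names(samples)
  if (is.null(ids)) ids <- paste0("sample", seq_along(samples))

  out <- createTable(
    c("sample", "name", "role", "mz", "shift", "shiftOk", "method",
      "area", "rmse", "apexRt"),
    c("text", "text", "text", "real", "real", "boolean", "text", "real",
      "real", "real"))
  allRows <- list()
  for (si in seq_along(samples)) {
    pm <- samples[[si]]
    if (is.character(pm))
      pm <- tryCatch(readMzML(pm), error = function(e) e)
    if (inherits(pm, "error")) {
      for (ti in seq_len(nrow(targets)))
        allRows[[length(allRows) + 1L]] <- list(
          ids[si], targets$name[ti], targets$role[ti], NA_real_,
          NA_real_, FALSE, "sample_load_failed", NA_real_, NA_real_,
          NA_real_)
      next
    }
    pt <- buildPeakTable(targets, pm)
    shift <- 0
    shiftOk <- TRUE
    if (correction) {
      est <- tryCatch(
        estimateRtShift(pm, targets, searchFactor = searchFactor,
                        summary = summary, sampleId = ids[si]),
        error = function(e) e)
      if (inherits(est, "error")) {
        shift <- NA_real_
        shiftOk <- FALSE
      } else {
        shift <- est@shift
        pt <- applyRtShift(pt, shift, shiftNames)
      }
    }
    it <- integrateTable(pt, method = method, params = params,
                         workers = workers)
    d <- asDataFrame(it)
    for (r in seq_len(nrow(d))) {
      ap <- locateApex(pm, d$mzmin[r], d$mzmax[r], d$rtmin[r],
                       d$rtmax[r])
      allRows[[length(allRows) + 1L]] <- list(
        ids[si], d$name[r], d$role[r], d$mz[r],
        if (correction) shift else NA_real_, shiftOk, d$method[r],
        d$area[r], d$rmse[r], ap$rt)
    }
  }
  if (length(allRows))
    out <- createTable(columnNames(out), columnTypes(out), allRows)
  out
}
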