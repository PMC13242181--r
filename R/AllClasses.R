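#' @import methods
NULL

#' MolecularFormula
#'
#' An element/isotope composition. Counts are stored as a named integer
#' vector; names are plain element symbols (`"C"`) or isotope-fixed symbols
#' (`"[13]C"`). All counts are >= 1; an empty composition is allowed and has
#' mass zero.
#'
#' @slot counts Named integer vector of atom counts.
#' @seealso [parseFormula()], [monoisotopicMass()], [isotopePattern()]
#' @export
setClass("MolecularFormula", representation(counts = "integer"))

setValidity("MolecularFormula", function(object) {
  cnt <- object@counts
  if (length(cnt) == 0L) return(TRUE)
  if (is.null(names(cnt)) || any(!nzchar(names(cnt))))
    return("all counts must be named")
  if (anyDuplicated(names(cnt))) return("duplicate element keys")
  if (any(is.na(cnt)) || any(cnt < 1L)) return("all counts must be >= 1")
  for (key in names(cnt)) {
    sym <- sub("^\\[[0-9]+\\]", "", key)
    if (!sym %in% names(.ELEMENTS)) return(paste("unknown element:", sym))
    m <- regmatches(key, regexpr("^\\[[0-9]+\\]", key))
    if (length(m) && !as.integer(gsub("\\[|\\]", "", m)) %in%
        .ELEMENTS[[sym]]$massnum)
      return(paste("unknown isotope:", key))
  }
  TRUE
})

#' IsotopePattern
#'
#' An isotope pattern: masses (Da, ascending) with absolute abundances
#' (sum <= 1). `pruned` records the total abundance discarded during
#' convolution so mass conservation remains checkable:
#' `sum(abundance(x)) >= 1 - prunedAbundance(x)`.
#'
#' @slot mass Numeric, ascending masses in Da.
#' @slot abundance Numeric in (0, 1], same length as `mass`.
#' @slot pruned Total abundance pruned away.
#' @slot threshold The pruning threshold that was applied.
#' @export
setClass("IsotopePattern", representation(
  mass = "numeric", abundance = "numeric",
  pruned = "numeric", threshold = "numeric"))

setValidity("IsotopePattern", function(object) {
  if (length(object@mass) != length(object@abundance))
    return("mass and abundance lengths differ")
  if (is.unsorted(object@mass, strictly = TRUE))
    return("masses must be strictly ascending")
  if (any(object@abundance <= 0) || any(object@abundance > 1 + 1e-12))
    return("abundances must lie in (0, 1]")
  s <- sum(object@abundance)
  if (s > 1 + 1e-9) return("abundances sum above 1")
  if (s < 1 - object@pruned - 1e-9)
    return("abundance sum below 1 - pruned mass")
  TRUE
})

#' Adduct
#'
#' An ionization adduct: observed m/z = (multiplier * M + delta) / |charge|
#' where M is the neutral monoisotopic mass and `delta` already accounts for
#' gained or lost electrons.
#'
#' @slot name Display name, e.g. `"[M+H]+"`.
#' @slot delta Mass delta in Da.
#' @slot charge Signed integer charge, never 0.
#' @slot multiplier Molecular multiplier (1 for `[M+H]+`, 2 for `[2M+H]+`).
#' @export
setClass("Adduct", representation(
  name = "character", delta = "numeric",
  charge = "integer", multiplier = "integer"))

setValidity("Adduct", function(object) {
  if (length(object@charge) != 1L || object@charge == 0L)
    return("charge must be a single non-zero integer")
  if (length(object@multiplier) != 1L || object@multiplier < 1L)
    return("multiplier must be >= 1")
  TRUE
})

#' Spectrum
#'
#' One centroided mass spectrum: retention time (seconds), MS level,
#' polarity (+1, -1, or 0 for unknown), optional precursor records for
#' MS^n, and parallel m/z / intensity arrays with m/z strictly ascending.
#'
#' @slot rt Retention time in seconds.
#' @slot msLevel MS level (1 for full scans).
#' @slot polarity Integer: 1 positive, -1 negative, 0 unknown.
#' @slot precursors data.frame with columns `mz`, `charge`,
#'   `isolationWidth` (NA allowed); at least one row when msLevel >= 2.
#' @slot mz Strictly ascending m/z values.
#' @slot intensity Non-negative intensities, parallel to `mz`.
#' @export
setClass("Spectrum", representation(
  rt = "numeric", msLevel = "integer", polarity = "integer",
  precursors = "data.frame", mz = "numeric", intensity = "numeric"))

setValidity("Spectrum", function(object) {
  if (length(object@mz) != length(object@intensity))
    return("mz and intensity lengths differ")
  if (is.unsorted(object@mz, strictly = TRUE))
    return("m/z values must be strictly ascending")
  if (any(object@intensity < 0)) return("negative intensity")
  if (object@msLevel >= 2L && nrow(object@precursors) < 1L)
    return("MS level >= 2 requires at least one precursor")
  TRUE
})

#' Chromatogram
#'
#' An intensity trace over retention time. `kind` is one of `"SRM"` (a
#' recorded precursor->product transition), `"EIC"` or `"TIC"`. SRM
#' chromatograms carry both precursor and product m/z.
#'
#' @slot kind `"SRM"`, `"EIC"` or `"TIC"`.
#' @slot precursorMz Precursor m/z or NA.
#' @slot productMz Product m/z or NA.
#' @slot rt Strictly ascending retention times (seconds).
#' @slot intensity Non-negative intensities, parallel to `rt`.
#' @export
setClass("Chromatogram", representation(
  kind = "character", precursorMz = "numeric", productMz = "numeric",
  rt = "numeric", intensity = "numeric"))

setValidity("Chromatogram", function(object) {
  if (!object@kind %in% c("SRM", "EIC", "TIC")) return("bad kind")
  if (length(object@rt) != length(object@intensity))
    return("rt and intensity lengths differ")
  if (is.unsorted(object@rt, strictly = TRUE))
    return("rt must be strictly ascending")
  if (any(object@intensity < 0)) return("negative intensity")
  if (object@kind == "SRM" &&
      (is.na(object@precursorMz) || is.na(object@productMz)))
    return("SRM chromatogram requires precursor and product m/z")
  TRUE
})

#' PeakMap
#'
#' The full raw dataset of one LC-MS/MS run: centroided spectra sorted by
#' retention time and/or MRM chromatograms, plus acquisition metadata. A
#' PeakMap may hold spectra only, chromatograms only, or both.
#'
#' @slot spectra List of [Spectrum-class], non-decreasing in rt.
#' @slot chromatograms List of [Chromatogram-class].
#' @slot metadata Named list (source path, instrument, run id).
#' @export
setClass("PeakMap", representation(
  spectra = "list", chromatograms = "list", metadata = "list"))

setValidity("PeakMap", function(object) {
  if (length(object@spectra)) {
    rts <- vapply(object@spectra, function(s) s@rt, numeric(1))
    if (is.unsorted(rts)) return("spectra must be non-decreasing in rt")
  }
  TRUE
})

#' EIC
#'
#' An extracted ion chromatogram: one point per source spectrum of the
#' requested MS level whose rt falls in the extraction window; spectra with
#' no peak in the m/z window contribute an explicit zero point.
#'
#' @slot rt Ascending retention times (seconds).
#' @slot intensity Summed intensities, parallel to `rt`.
#' @slot mzmin,mzmax,rtmin,rtmax The generating window (closed intervals).
#' @slot msLevel MS level the EIC was extracted from.
#' @export
setClass("EIC", representation(
  rt = "numeric", intensity = "numeric",
  mzmin = "numeric", mzmax = "numeric",
  rtmin = "numeric", rtmax = "numeric", msLevel = "integer"))

setValidity("EIC", function(object) {
  if (length(object@rt) != length(object@intensity))
    return("rt and intensity lengths differ")
  if (is.unsorted(object@rt)) return("rt must be ascending")
  TRUE
})

#' IntegrationResult
#'
#' The result of integrating one chromatographic peak: the method used,
#' the area (intensity * seconds; NA for a failed model fit), the model
#' root-mean-square error where a model was fitted, method-specific
#' parameters, the constant baseline that was subtracted, and a diagnostic
#' message for failed fits.
#'
#' @slot method One of `"trapezoid"`, `"sgolay"`,
#'   `"sgolay_fallback_trapezoid"`, `"emg"`, `"max"`, `"no_integration"`.
#' @slot area Peak area, or NA when a fit failed.
#' @slot rmse Root-mean-square error of the model (NA for quadrature
#'   methods).
#' @slot params Named list of model parameters (EMG: `H`, `mu`, `sigma`,
#'   `tau`).
#' @slot baseline Constant baseline subtracted before integration.
#' @slot message Diagnostic text, empty on success.
#' @export
setClass("IntegrationResult", representation(
  method = "character", area = "numeric", rmse = "numeric",
  params = "list", baseline = "numeric", message = "character"))

#' RtAlignmentModel
#'
#' A fitted monotone mapping from observed to reference retention time,
#' anchored on matched compound pairs. Piecewise-linear models interpolate
#' the anchors exactly; local-regression models smooth them. Monotonicity
#' is enforced by isotonic repair of the fitted values; beyond the anchor
#' span the map continues linearly.
#'
#' @slot kind `"piecewise-linear"` or `"local-regression"`.
#' @slot rtObserved,rtFitted Anchor rts and (repaired) fitted target rts.
#' @slot repaired TRUE when isotonic repair changed the targets.
#' @export
setClass("RtAlignmentModel", representation(
  kind = "character", rtObserved = "numeric", rtFitted = "numeric",
  repaired = "logical"))

#' MzCalibration
#'
#' An affine m/z recalibration `mz' = a * mz + b` fitted by least squares
#' to matched (observed, reference) pairs, with the RMS residual of the
#' corrected values.
#'
#' @slot a,b Affine coefficients.
#' @slot rmse RMS of corrected minus reference, in Da.
#' @export
setClass("MzCalibration", representation(
  a = "numeric", b = "numeric", rmse = "numeric"))

#' MzTable
#'
#' A typed, named-column relational table for LC-MS peak lists. Columns have
#' one of the types `"integer"`, `"real"`, `"text"`, `"boolean"`,
#' `"peakmap"` (a reference to a [PeakMap-class]) or `"table"` (a reference
#' to a nested MzTable). Cells may be missing. Rows keep stable insertion
#' order. Storage is either fully in memory or out-of-core in an embedded
#' SQLite database file; every operation behaves identically in both modes.
#'
#' Reference-typed cells store integer keys into a registry shared by
#' derived tables, so a peakmap referenced from many rows is held (and
#' persisted) once.
#'
#' @slot colNames Character vector of unique column names.
#' @slot colTypes Character vector of column types.
#' @slot formats Display format strings (one per column).
#' @slot mode `"memory"` or `"disk"`.
#' @slot backend Environment holding the row storage (`data` for memory
#'   mode; `con`/`tab`/`path` for disk mode).
#' @slot registry Environment mapping reference keys to objects.
#' @slot meta Named list of table-level metadata.
#' @seealso [createTable()], [filterRows()], [joinTables()],
#'   [groupAggregate()], [saveTable()], [setStorageMode()]
#' @export
setClass("MzTable", representation(
  colNames = "character", colTypes = "character", formats = "character",
  mode = "character", backend = "environment", registry = "environment",
  meta = "list"))

setValidity("MzTable", function(object) {
  if (anyDuplicated(object@colNames)) return("duplicate column names")
  if (length(object@colTypes) != length(object@colNames))
    return("colTypes length mismatch")
  ok <- c("integer", "real", "text", "boolean", "peakmap", "table")
  if (!all(object@colTypes %in% ok))
    return(paste("unknown column type:",
                 paste(setdiff(object@colTypes, ok), collapse = ", ")))
  if (!object@mode %in% c("memory", "disk")) return("bad storage mode")
  TRUE
})

#' RtShiftEstimate
#'
#' A per-sample retention-time shift estimated from reference compounds:
#' the robust summary (median by default) of apex-minus-expected rt over
#' the references that were located, the per-reference deviations, and the
#' number of references used.
#'
#' @slot sampleId Sample identifier.
#' @slot shift Estimated shift in seconds (signed).
#' @slot deviations data.frame with columns `name`, `deltaRt`
#'   (located references only).
#' @slot nUsed Number of references used.
#' @slot summary `"median"` or `"mean"`.
#' @export
setClass("RtShiftEstimate", representation(
  sampleId = "character", shift = "numeric", deviations = "data.frame",
  nUsed = "integer", summary = "character"))

#' TableExpr
#'
#' A small closed expression language over table columns: column
#' references created with [col()], literals, arithmetic and comparison
#' operators, `&`, `|`, `!`, and the missing-value test [isMissing()].
#' Operators follow strict missing propagation: any binary operation with
#' a missing operand is missing; only `isMissing()` inspects missingness.
#'
#' @slot node The expression tree (nested lists).
#' @export
setClass("TableExpr", representation(node = "list"))
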