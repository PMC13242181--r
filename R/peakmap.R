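# PeakMap construction, accessors and peak-level operations.

#' Construct a Spectrum
#'
#' @param rt Retention time in seconds.
#' @param mz,intensity Parallel arrays; `mz` strictly ascending,
#'   intensities non-negative. Unsorted input is sorted (ties collapse is
#'   the caller's job).
#' @param msLevel MS level, default 1.
#' @param polarity 1, -1 or 0 (unknown).
#' @param precursors data.frame with columns `mz`, `charge`,
#'   `isolationWidth`; required non-empty for msLevel >= 2.
#' @return A [Spectrum-class].
#' @export
spectrum <- function(rt, mz, intensity, msLevel = 1L, polarity = 0L,
                     precursors = NULL) {
  if (is.null(precursors))
    precursors <- data.frame(mz = numeric(0), charge = integer(0),
                             isolationWidth = numeric(0))
  o <- order(mz)
  new("Spectrum", rt = as.numeric(rt), msLevel = as.integer(msLevel),
      polarity = as.integer(polarity), precursors = precursors,
      mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]))
}

#' Construct a Chromatogram
#'
#' @param rt,intensity Parallel arrays; `rt` strictly ascending (seconds).
#' @param kind `"SRM"`, `"EIC"` or `"TIC"`.
#' @param precursorMz,productMz Transition m/z values (required for SRM).
#' @return A [Chromatogram-class].
#' @export
chromatogram <- function(rt, intensity, kind = "SRM",
                         precursorMz = NA_real_, productMz = NA_real_) {
  new("Chromatogram", kind = kind, precursorMz = as.numeric(precursorMz),
      productMz = as.numeric(productMz), rt = as.numeric(rt),
      intensity = as.numeric(intensity))
}

#' Construct a PeakMap
#'
#' @param spectra List of [Spectrum-class]; sorted by rt on construction.
#' @param chromatograms List of [Chromatogram-class].
#' @param metadata Named list (e.g. `source`, `instrument`, `runId`).
#' @return A [PeakMap-class].
#' @export
peakMap <- function(spectra = list(), chromatograms = list(),
                    metadata = list()) {
  if (length(spectra)) {
    rts <- vapply(spectra, function(s) s@rt, numeric(1))
    spectra <- spectra[order(rts)]
  }
  new("PeakMap", spectra = spectra, chromatograms = chromatograms,
      metadata = metadata)
}

#' @describeIn peakMap List of spectra.
#' @param pm A [PeakMap-class].
#' @export
spectra <- function(pm) pm@spectra

#' @describeIn peakMap List of chromatograms.
#' @export
chromatograms <- function(pm) pm@chromatograms

#' @describeIn peakMap Metadata list.
#' @export
peakMapMeta <- function(pm) pm@metadata

#' @describeIn peakMap Retention times of all spectra (seconds).
#' @export
spectraRt <- function(pm)
  vapply(pm@spectra, function(s) s@rt, numeric(1))

setMethod("show", "PeakMap", function(object) {
  ns <- length(object@spectra)
  lv <- if (ns) table(vapply(object@spectra, function(s) s@msLevel,
                             integer(1))) else integer(0)
  cat("PeakMap:", ns, "spectra,",
      length(object@chromatograms), "chromatograms\n")
  if (ns) {
    rts <- spectraRt(object)
    cat(sprintf("  rt span %.2f - %.2f s; MS levels: %s\n",
                min(rts), max(rts),
                paste(names(lv), lv, sep = ":", collapse = " ")))
  }
  if (!is.null(object@metadata$source))
    cat("  source:", object@metadata$source, "\n")
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: rt %.2f s, MS%d, %d peaks\n",
              object@rt, object@msLevel, length(object@mz)))
})

setMethod("show", "Chromatogram", function(object) {
  cat(sprintf("Chromatogram (%s): %d points", object@kind,
              length(object@rt)))
  if (!is.na(object@precursorMz))
    cat(sprintf(", Q1 %.4f", object@precursorMz))
  if (!is.na(object@productMz))
    cat(sprintf(", Q3 %.4f", object@productMz))
  cat("\n")
})

setMethod("show", "EIC", function(object) {
  cat(sprintf("EIC: %d points, m/z [%.4f, %.4f], rt [%.2f, %.2f] s, MS%d\n",
              length(object@rt), object@mzmin, object@mzmax,
              object@rtmin, object@rtmax, object@msLevel))
})

#' Extract an ion chromatogram
#'
#' For every spectrum of the requested MS level with rt in
#' `[rtmin, rtmax]` (closed), one EIC point is emitted whose intensity is
#' the sum of peak intensities with m/z in `[mzmin, mzmax]` (closed).
#' Spectra with no peak in the window contribute an explicit zero, so the
#' point count is determined by the rt window alone.
#'
#' @param pm A [PeakMap-class].
#' @param mzmin,mzmax Closed m/z window.
#' @param rtmin,rtmax Closed rt window in seconds (default: all spectra).
#' @param msLevel MS level to extract from.
#' @return An [EIC-class] (zero points when no spectrum matches).
#' @export
extractEIC <- function(pm, mzmin, mzmax, rtmin = -Inf, rtmax = Inf,
                       msLevel = 1L) {
  stopifnot(mzmin <= mzmax, rtmin <= rtmax)
  msLevel <- as.integer(msLevel)
  rt <- numeric(0); int <- numeric(0)
  for (s in pm@spectra) {
    if (s@msLevel != msLevel) next
    if (s@rt < rtmin || s@rt > rtmax) next
    lo <- findInterval(mzmin, s@mz, left.open = TRUE) + 1L
    hi <- findInterval(mzmax, s@mz)
    v <- if (hi >= lo) sum(s@intensity[lo:hi]) else 0
    rt <- c(rt, s@rt); int <- c(int, v)
  }
  new("EIC", rt = rt, intensity = int,
      mzmin = as.numeric(mzmin), mzmax = as.numeric(mzmax),
      rtmin = as.numeric(rtmin), rtmax = as.numeric(rtmax),
      msLevel = msLevel)
}

#' @describeIn extractEIC rt values of an EIC or Chromatogram.
#' @param x An [EIC-class] or [Chromatogram-class].
#' @export
traceRt <- function(x) x@rt

#' @describeIn extractEIC intensity values of an EIC or Chromatogram.
#' @export
traceIntensity <- function(x) x@intensity

#' Export an EIC to delimited text
#'
#' Writes two columns `rt`, `intensity` as CSV.
#'
#' @param eic An [EIC-class].
#' @param path Output path.
#' @export
writeEIC <- function(eic, path) {
  utils::write.csv(data.frame(rt = eic@rt, intensity = eic@intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Look up an MRM transition trace
#'
#' Finds the unique SRM chromatogram whose precursor and product m/z both
#' lie within `tolMz` of the query.
#'
#' @param pm A [PeakMap-class] with chromatograms.
#' @param precursorMz,productMz Queried transition.
#' @param tolMz Absolute m/z tolerance applied to both values.
#' @return The matching [Chromatogram-class]. Zero matches or more than
#'   one match raise an error (the ambiguity error lists the candidates).
#' @export
extractMRMTrace <- function(pm, precursorMz, productMz, tolMz = 0.1) {
  srm <- Filter(function(ch) ch@kind == "SRM", pm@chromatograms)
  if (!length(srm)) stop("peakmap has no SRM chromatograms")
  hit <- vapply(srm, function(ch)
    abs(ch@precursorMz - precursorMz) <= tolMz &&
    abs(ch@productMz - productMz) <= tolMz, logical(1))
  if (sum(hit) == 0L)
    stop(sprintf("no SRM transition within %.4g of %.4f -> %.4f",
                 tolMz, precursorMz, productMz))
  if (sum(hit) > 1L) {
    cand <- vapply(srm[hit], function(ch)
      sprintf("%.4f -> %.4f", ch@precursorMz, ch@productMz), character(1))
    stop("ambiguous SRM query; candidates: ", paste(cand, collapse = "; "))
  }
  srm[[which(hit)]]
}

#' Total ion current
#'
#' Per-spectrum summed intensity for one MS level, as a TIC
#' [Chromatogram-class]. Equal to [extractEIC()] over the full m/z range.
#'
#' @param pm A [PeakMap-class].
#' @param msLevel MS level.
#' @export
totalIonCurrent <- function(pm, msLevel = 1L) {
  sel <- Filter(function(s) s@msLevel == msLevel, pm@spectra)
  chromatogram(rt = vapply(sel, function(s) s@rt, numeric(1)),
               intensity = vapply(sel, function(s) sum(s@intensity),
                                  numeric(1)),
               kind = "TIC")
}

#' 2D intensity binning
#'
#' Bins all peaks of the requested MS level into an rt x m/z histogram:
#' `matrix[i, j]` sums intensities of peaks with rt in
#' `[rtEdges[i], rtEdges[i+1])` and m/z in `[mzEdges[j], mzEdges[j+1])`
#' (half-open bins). The grand total equals the total intensity of
#' in-range peaks. This is the computation behind peakmap heat-map
#' displays.
#'
#' @param pm A [PeakMap-class].
#' @param rtEdges,mzEdges Ascending bin edges.
#' @param msLevel MS level.
#' @return Numeric matrix of dimension
#'   `(length(rtEdges)-1) x (length(mzEdges)-1)`.
#' @export
bin2d <- function(pm, rtEdges, mzEdges, msLevel = 1L) {
  stopifnot(!is.unsorted(rtEdges, strictly = TRUE),
            !is.unsorted(mzEdges, strictly = TRUE))
  nr <- length(rtEdges) - 1L
  nc <- length(mzEdges) - 1L
  m <- matrix(0, nr, nc)
  for (s in pm@spectra) {
    if (s@msLevel != msLevel) next
    i <- findInterval(s@rt, rtEdges)        # half-open [edge_i, edge_{i+1})
    if (i < 1L || i > nr) next
    j <- findInterval(s@mz, mzEdges)
    keep <- j >= 1L & j <= nc
    if (!any(keep)) next
    add <- tapply(s@intensity[keep], j[keep], sum)
    jj <- as.integer(names(add))
    m[i, jj] <- m[i, jj] + as.numeric(add)
  }
  m
}
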