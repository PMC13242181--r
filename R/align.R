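# RT alignment, m/z recalibration, and isotope/adduct grouping.

#' Fit an RT alignment model
#'
#' Fits a monotone map from observed to reference retention time through
#' anchor pairs (matched compounds seen in both runs). Piecewise-linear
#' models pass exactly through the anchors; local-regression models
#' (loess) smooth them first. Non-monotone target values are repaired
#' isotonically (weighted least-squares monotone fit) with a warning —
#' alignment must never reorder spectra. Beyond the anchor span the map
#' continues linearly with the terminal segment slopes.
#'
#' @param anchors data.frame (or 2-column matrix) with columns
#'   `rtObserved`, `rtReference`, both in seconds; at least 2 rows,
#'   observed values unique.
#' @param kind `"piecewise-linear"` or `"local-regression"`.
#' @param span loess span for `"local-regression"`.
#' @return An [RtAlignmentModel-class].
#' @examples
#' m <- fitRtAlignment(data.frame(rtObserved = c(100, 200, 300),
#'                                rtReference = c(107, 207, 307)))
#' mapRt(m, 150)   # 157
#' @export
fitRtAlignment <- function(anchors, kind = c("piecewise-linear",
                                             "local-regression"),
                           span = 0.75) {
  kind <- match.arg(kind)
  anchors <- as.data.frame(anchors)
  if (ncol(anchors) >= 2 && !all(c("rtObserved", "rtReference") %in%
                                 names(anchors)))
    names(anchors)[1:2] <- c("rtObserved", "rtReference")
  if (nrow(anchors) < 2L) stop("need at least 2 anchors")
  o <- order(anchors$rtObserved)
  obs <- anchors$rtObserved[o]
  ref <- anchors$rtReference[o]
  if (any(diff(obs) <= 0)) stop("observed anchor rts must be distinct")

  fitted <- if (kind == "piecewise-linear") ref
  else {
    fit <- stats::loess(ref ~ obs, span = span, degree = 1L,
                        surface = "direct")
    stats::predict(fit, obs)
  }

  repaired <- FALSE
  if (any(diff(fitted) <= 0)) {
    warning("non-monotone anchor targets; applying isotonic repair")
    fitted <- stats::isoreg(obs, fitted)$yf
    # break flat runs so the map stays strictly increasing (invertible)
    eps <- diff(range(obs)) * 1e-9
    fitted <- fitted + seq_along(fitted) * eps
    repaired <- TRUE
  }
  new("RtAlignmentModel", kind = kind, rtObserved = obs,
      rtFitted = fitted, repaired = repaired)
}

#' Map retention times through an alignment model
#'
#' @param model An [RtAlignmentModel-class].
#' @param rt Numeric rt values (seconds).
#' @return Mapped rt values.
#' @export
mapRt <- function(model, rt) {
  obs <- model@rtObserved
  fit <- model@rtFitted
  n <- length(obs)
  out <- stats::approx(obs, fit, xout = rt, rule = 1)$y
  # linear continuation beyond the anchor span
  sl1 <- (fit[2] - fit[1]) / (obs[2] - obs[1])
  sln <- (fit[n] - fit[n - 1]) / (obs[n] - obs[n - 1])
  low <- rt < obs[1]
  high <- rt > obs[n]
  out[low] <- fit[1] + (rt[low] - obs[1]) * sl1
  out[high] <- fit[n] + (rt[high] - obs[n]) * sln
  out
}

#' Invert a piecewise-linear alignment model
#'
#' @param model A strictly monotone [RtAlignmentModel-class].
#' @return The inverse model (reference -> observed).
#' @export
invertAlignment <- function(model) {
  new("RtAlignmentModel", kind = "piecewise-linear",
      rtObserved = model@rtFitted, rtFitted = model@rtObserved,
      repaired = model@repaired)
}

setMethod("show", "RtAlignmentModel", function(object) {
  cat(sprintf("RtAlignmentModel (%s): %d anchors, span %.2f - %.2f s%s\n",
              object@kind, length(object@rtObserved),
              min(object@rtObserved), max(object@rtObserved),
              if (object@repaired) " [isotonically repaired]" else ""))
})

#' @describeIn applyRtAlignment Maps every spectrum and chromatogram rt;
#'   monotonicity preserves ordering invariants.
#' @export
setMethod("applyRtAlignment", "PeakMap", function(x, model) {
  specs <- lapply(x@spectra, function(s) {
    s@rt <- mapRt(model, s@rt)
    s
  })
  chroms <- lapply(x@chromatograms, function(ch) {
    ch@rt <- mapRt(model, ch@rt)
    ch
  })
  peakMap(spectra = specs, chromatograms = chroms, metadata = x@metadata)
})

#' Apply an RT alignment
#'
#' Maps all retention-time fields of the target through the model: for a
#' [PeakMap-class] the spectrum and chromatogram rts, for an
#' [MzTable-class] the columns `rt`, `rtmin`, `rtmax`, `rtApex` (those
#' that exist). `rtmin <= rtmax` is preserved because the map is
#' monotone.
#'
#' @param x A [PeakMap-class] or [MzTable-class].
#' @param model An [RtAlignmentModel-class].
#' @return An object of the same kind as `x`.
#' @export
setMethod("applyRtAlignment", "MzTable", function(x, model) {
  d <- .tblData(x)
  for (nm in intersect(c("rt", "rtmin", "rtmax", "rtApex"), x@colNames))
    d[[nm]] <- mapRt(model, d[[nm]])
  out <- .newTable(x@colNames, x@colTypes, x@formats, x@mode, x@registry,
                   meta = x@meta,
                   store = if (x@mode == "disk") x@backend$store)
  .appendChunk(out, d)
  out
})

#' Fit an affine m/z calibration
#'
#' Least-squares fit of `reference = a * observed + b` over matched peak
#' pairs; warns when the gain leaves `[0.99, 1.01]`.
#'
#' @param observed,reference Matched m/z vectors (>= 2 pairs).
#' @return An [MzCalibration-class] with the RMS residual of the
#'   corrected values.
#' @export
fitMzCalibration <- function(observed, reference) {
  if (length(observed) < 2L || length(observed) != length(reference))
    stop("need at least 2 matched (observed, reference) pairs")
  fit <- stats::lm(reference ~ observed)
  a <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  rmse <- sqrt(mean((a * observed + b - reference)^2))
  if (a < 0.99 || a > 1.01)
    warning(sprintf("m/z calibration gain %.6f outside [0.99, 1.01]", a))
  new("MzCalibration", a = a, b = b, rmse = rmse)
}

#' Apply an m/z calibration
#'
#' @param x Numeric m/z values or a [PeakMap-class].
#' @param cal An [MzCalibration-class].
#' @return Corrected m/z values, or a corrected PeakMap.
#' @export
applyMzCalibration <- function(x, cal) {
  if (is.numeric(x)) return(cal@a * x + cal@b)
  stopifnot(is(x, "PeakMap"))
  specs <- lapply(x@spectra, function(s) {
    s@mz <- cal@a * s@mz + cal@b
    s
  })
  peakMap(spectra = specs, chromatograms = x@chromatograms,
          metadata = x@metadata)
}

setMethod("show", "MzCalibration", function(object) {
  cat(sprintf("MzCalibration: mz' = %.8f * mz %+.6f, rmse %.2e Da\n",
              object@a, object@b, object@rmse))
})

#' Group isotopologue peaks
#'
#' Partitions a feature table into isotopologue groups by greedy seeding:
#' peaks are visited in descending intensity (ties by ascending m/z); each
#' unclaimed seed claims unclaimed peaks at
#' `mz_seed + k * 1.0033548378 / z` (k = 1, 2, ...) within `mzTol` that
#' co-elute within `rtTol`, trying z = 1..maxCharge and keeping the charge
#' that explains the most members. Every peak ends up in exactly one
#' group; unmatched peaks form singleton groups.
#'
#' @param ft An [MzTable-class] (or data.frame) with columns `mz`, `rt`,
#'   `intensity`.
#' @param mzTol Absolute m/z tolerance in Da.
#' @param rtTol Co-elution tolerance in seconds.
#' @param maxCharge Highest charge state considered.
#' @return The input with added integer columns `groupId`, `charge`,
#'   `isotopologue` (0 = monoisotopic member), as the input's kind.
#' @export
groupIsotopes <- function(ft, mzTol = 0.003, rtTol = 5, maxCharge = 2L) {
  isTable <- is(ft, "MzTable")
  d <- if (isTable) asDataFrame(ft) else as.data.frame(ft)
  stopifnot(all(c("mz", "rt", "intensity") %in% names(d)))
  n <- nrow(d)
  groupId <- rep(NA_integer_, n)
  charge <- rep(NA_integer_, n)
  isoIdx <- rep(NA_integer_, n)
  seedOrder <- order(-d$intensity, d$mz)
  gid <- 0L
  for (s in seedOrder) {
    if (!is.na(groupId[s])) next
    best <- list(members = integer(0), z = 1L)
    for (z in seq_len(maxCharge)) {
      members <- integer(0)
      k <- 1L
      repeat {
        target <- d$mz[s] + k * .ISOTOPE_SPACING / z
        cand <- which(is.na(groupId) & !seq_len(n) %in% members &
                        abs(d$mz - target) <= mzTol &
                        abs(d$rt - d$rt[s]) <= rtTol)
        if (!length(cand)) break
        members <- c(members, cand[which.min(abs(d$mz[cand] - target))])
        k <- k + 1L
      }
      if (length(members) > length(best$members))
        best <- list(members = members, z = as.integer(z))
    }
    gid <- gid + 1L
    chain <- c(s, best$members)
    groupId[chain] <- gid
    charge[chain] <- if (length(best$members)) best$z else 1L
    isoIdx[chain] <- seq_along(chain) - 1L
  }
  d$groupId <- groupId
  d$charge <- charge
  d$isotopologue <- isoIdx
  if (!isTable) return(d)
  out <- .newTable(c(ft@colNames, "groupId", "charge", "isotopologue"),
                   c(ft@colTypes, "integer", "integer", "integer"),
                   c(ft@formats, "%d", "%d", "%d"), ft@mode, ft@registry,
                   meta = ft@meta,
                   store = if (ft@mode == "disk") ft@backend$store)
  .appendChunk(out, as.list(d)[columnNames(out)])
  out
}

#' Annotate adduct relationships between isotope groups
#'
#' Links isotope groups whose monoisotopic m/z values are consistent with
#' a pair of library adducts of one shared neutral mass: for every
#' co-eluting pair of groups (monoisotopic members within `rtTol`) and
#' every adduct pair matching the groups' charges, the implied neutral
#' masses `(|z| * mz - delta) / multiplier` are compared within `mzTol`.
#' Linked groups share an `adductGroup` id and receive the consistent
#' `neutralMass` and their `adductName`.
#'
#' @param gt Output of [groupIsotopes()] (table or data.frame).
#' @param adducts Adduct library (named list of [Adduct-class]), default
#'   [defaultAdducts()].
#' @param mzTol Neutral-mass tolerance in Da.
#' @param rtTol Co-elution tolerance in seconds.
#' @return The input with added columns `adductGroup` (integer),
#'   `neutralMass` (real) and `adductName` (text); unlinked groups keep
#'   missing annotations.
#' @export
groupAdducts <- function(gt, adducts = defaultAdducts(), mzTol = 0.003,
                         rtTol = 5) {
  isTable <- is(gt, "MzTable")
  d <- if (isTable) asDataFrame(gt) else as.data.frame(gt)
  stopifnot(all(c("mz", "rt", "groupId", "charge", "isotopologue") %in%
                  names(d)))
  mono <- d[d$isotopologue == 0L, , drop = FALSE]
  ng <- nrow(mono)
  d$adductGroup <- NA_integer_
  d$neutralMass <- NA_real_
  d$adductName <- NA_character_

  if (ng >= 2L && length(adducts)) {
    # candidate neutral masses per group x adduct with matching |charge|
    cand <- list()
    for (g in seq_len(ng)) {
      for (a in adducts) {
        if (abs(a@charge) != mono$charge[g]) next
        M <- (abs(a@charge) * mono$mz[g] - a@delta) / a@multiplier
        cand[[length(cand) + 1L]] <- data.frame(
          g = g, name = a@name, M = M)
      }
    }
    cand <- if (length(cand)) do.call(rbind, cand) else NULL
    parent <- seq_len(ng)
    findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    hyp <- vector("list", ng)   # chosen (name, M) per group
    if (!is.null(cand)) {
      for (i in seq_len(ng - 1L)) for (j in seq(i + 1L, ng)) {
        if (abs(mono$rt[i] - mono$rt[j]) > rtTol) next
        ci <- cand[cand$g == i, , drop = FALSE]
        cj <- cand[cand$g == j, , drop = FALSE]
        if (!nrow(ci) || !nrow(cj)) next
        dm <- abs(outer(ci$M, cj$M, "-"))
        hit <- which(dm <= mzTol, arr.ind = TRUE)
        hit <- hit[ci$name[hit[, 1]] != cj$name[hit[, 2]], , drop = FALSE]
        if (!nrow(hit)) next
        k <- which.min(dm[hit])
        ri <- findRoot(i); rj <- findRoot(j)
        parent[max(ri, rj)] <- min(ri, rj)
        hyp[[i]] <- list(name = ci$name[hit[k, 1]], M = ci$M[hit[k, 1]])
        hyp[[j]] <- list(name = cj$name[hit[k, 2]], M = cj$M[hit[k, 2]])
      }
    }
    roots <- vapply(seq_len(ng), findRoot, integer(1))
    linked <- which(vapply(seq_len(ng), function(g)
      sum(roots == roots[g]) > 1L && !is.null(hyp[[g]]), logical(1)))
    if (length(linked)) {
      rootIds <- match(roots, sort(unique(roots[linked])))
      for (g in linked) {
        rows <- d$groupId == mono$groupId[g]
        d$adductGroup[rows] <- rootIds[g]
        Ms <- vapply(which(roots == roots[g] & seq_len(ng) %in% linked),
                     function(h) hyp[[h]]$M, numeric(1))
        d$neutralMass[rows] <- mean(Ms)
        d$adductName[rows] <- hyp[[g]]$name
      }
    }
  }
  if (!isTable) return(d)
  out <- .newTable(c(gt@colNames, "adductGroup", "neutralMass",
                     "adductName"),
                   c(gt@colTypes, "integer", "real", "text"),
                   c(gt@formats, "%d", "%.5f", "%s"), gt@mode,
                   gt@registry, meta = gt@meta,
                   store = if (gt@mode == "disk") gt@backend$store)
  .appendChunk(out, as.list(d)[columnNames(out)])
  out
}
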