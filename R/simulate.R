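# Seeded synthetic LC-MS runs with exact ground truth. Peak shapes are
# parametric (Gaussian or exponentially modified Gaussian); isotopologue
# envelopes come from the chemistry module at natural abundances. No
# chromatographic physics is modelled.

#' Describe compounds for a simulated run
#'
#' Convenience constructor for the compound table consumed by
#' [simulateRun()].
#'
#' @param name Compound names (unique).
#' @param formula Molecular formula strings.
#' @param adduct Adduct names resolved in [defaultAdducts()], or a list of
#'   [Adduct-class] objects.
#' @param area True peak areas (intensity * seconds) of the monoisotopic
#'   trace before abundance scaling.
#' @param rt True apex retention times in seconds (before any global
#'   shift).
#' @param sigma Gaussian widths in seconds.
#' @param tau EMG tailing constants in seconds (0 selects a pure
#'   Gaussian).
#' @param shape `"gaussian"` or `"emg"`, recycled.
#' @return A data.frame ready for [simulateRun()].
#' @export
simCompounds <- function(name, formula, adduct = "[M+H]+", area = 1e5,
                         rt, sigma = 2, tau = 0, shape = "gaussian") {
  data.frame(name = name, formula = formula, adduct = adduct,
             area = area, rt = rt, sigma = sigma, tau = tau,
             shape = shape, stringsAsFactors = FALSE)
}

# closed-form trace value at times t for unit area; Gaussian or EMG pdf
.shapeProfile <- function(t, shape, mu, sigma, tau) {
  if (shape == "emg" && tau > 0)
    .emgDensity(t, mu, sigma, tau)
  else
    stats::dnorm(t, mu, sigma)
}

#' Simulate a centroided MS1 run
#'
#' Generates centroided MS1 spectra on a regular scan grid. Every compound
#' contributes one m/z channel per isotopologue above `minRelAbundance`
#' relative abundance; channel intensity over rt follows the compound's
#' peak shape scaled to its true area. Noise is additive Gaussian
#' (`noiseSd`) plus multiplicative Gaussian (`noiseRel`), on top of a
#' constant `baseline`, floored at zero. Identical seed and parameters
#' give a bit-identical run (and identical mzML bytes via [writeMzML()]).
#'
#' @param compounds data.frame from [simCompounds()].
#' @param scanInterval Scan spacing in seconds.
#' @param rtSpan Length-2 numeric, acquisition window in seconds.
#' @param globalShift Run-wide rt shift in seconds applied to every
#'   compound (emulating inter-sample rt drift).
#' @param baseline Constant baseline intensity added to every channel.
#' @param noiseSd Additive noise standard deviation (intensity units).
#' @param noiseRel Multiplicative noise standard deviation (fraction).
#' @param minRelAbundance Isotopologues below this relative abundance are
#'   not emitted (default 0.1%).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list with elements `peakmap` ([PeakMap-class]) and `truth`, a
#'   data.frame with one row per compound per emitted isotopologue:
#'   `name`, `isotopologue`, `mz`, `rtApex` (shift included), `area`
#'   (closed-form area times isotopologue abundance), `sigma`, `tau`,
#'   `shape`.
#' @export
simulateRun <- function(compounds, scanInterval = 0.5,
                        rtSpan = c(0, 600), globalShift = 0,
                        baseline = 0, noiseSd = 0, noiseRel = 0,
                        minRelAbundance = 1e-3, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  lib <- defaultAdducts()
  grid <- seq(rtSpan[1], rtSpan[2], by = scanInterval)

  channels <- list()   # per channel: mz, trace, truth row
  if (nrow(compounds)) {
    for (i in seq_len(nrow(compounds))) {
      cp <- compounds[i, ]
      ad <- if (is.list(compounds$adduct)) cp$adduct[[1]]
            else lib[[cp$adduct]]
      if (is.null(ad)) stop("unknown adduct for compound ", cp$name)
      f <- parseFormula(cp$formula)
      pat <- isotopePattern(f, minAbundance = 1e-6)
      rel <- patternAbundance(pat) / max(patternAbundance(pat))
      keep <- which(rel >= minRelAbundance)
      mzs <- vapply(patternMass(pat)[keep], function(m)
        (ad@multiplier * m + ad@delta) / abs(ad@charge), numeric(1))
      mu <- cp$rt + globalShift
      prof <- .shapeProfile(grid, cp$shape, mu, cp$sigma, cp$tau)
      for (k in seq_along(keep)) {
        a <- cp$area * patternAbundance(pat)[keep[k]]
        channels[[length(channels) + 1L]] <- list(
          mz = mzs[k], trace = a * prof,
          truth = data.frame(name = cp$name,
                             isotopologue = keep[k] - 1L,
                             mz = mzs[k], rtApex = mu, area = a,
                             sigma = cp$sigma, tau = cp$tau,
                             shape = cp$shape,
                             stringsAsFactors = FALSE))
      }
    }
    # ambiguous ground truth: identical m/z and identical apex rt
    mzv <- vapply(channels, `[[`, numeric(1), "mz")
    rtv <- vapply(channels, function(ch) ch$truth$rtApex, numeric(1))
    o <- order(mzv, rtv)
    dupe <- which(diff(mzv[o]) < 1e-6 & abs(diff(rtv[o])) < 1e-9)
    if (length(dupe))
      stop("ambiguous simulation: compounds share m/z within 1e-6 Da ",
           "at identical rt")
  }

  nChan <- length(channels)
  mzChan <- if (nChan) vapply(channels, `[[`, numeric(1), "mz")
            else numeric(0)
  specs <- vector("list", length(grid))
  traces <- if (nChan)
    vapply(channels, `[[`, numeric(length(grid)), "trace")
  else matrix(0, length(grid), 0L)
  if (nChan == 1L) traces <- matrix(traces, ncol = 1L)
  for (si in seq_along(grid)) {
    v <- if (nChan) traces[si, ] else numeric(0)
    if (nChan) {
      if (noiseRel > 0) v <- v * (1 + stats::rnorm(nChan, 0, noiseRel))
      v <- v + baseline
      if (noiseSd > 0) v <- v + stats::rnorm(nChan, 0, noiseSd)
      v <- pmax(v, 0)
    }
    keep <- v > 0
    mzk <- mzChan[keep]; vk <- v[keep]
    if (length(mzk)) {
      o <- order(mzk)
      mzk <- mzk[o]; vk <- vk[o]
      # merge channels that collide in m/z (isobars at different rt)
      grp <- cumsum(c(TRUE, diff(mzk) > 1e-9))
      vk <- as.numeric(tapply(vk, grp, sum))
      mzk <- as.numeric(tapply(mzk, grp, `[`, 1L))
    }
    specs[[si]] <- spectrum(rt = grid[si], mz = mzk, intensity = vk,
                            msLevel = 1L, polarity = 1L)
  }
  truth <- if (nChan)
    do.call(rbind, lapply(channels, `[[`, "truth"))
  else data.frame(name = character(0), isotopologue = integer(0),
                  mz = numeric(0), rtApex = numeric(0), area = numeric(0),
                  sigma = numeric(0), tau = numeric(0),
                  shape = character(0))
  list(peakmap = peakMap(spectra = specs,
                         metadata = list(runId = "simulated",
                                         scanInterval = scanInterval,
                                         globalShift = globalShift,
                                         rng = "Mersenne-Twister",
                                         seed = seed)),
       truth = truth)
}

#' Simulate an MRM run
#'
#' Generates SRM chromatograms on a regular time grid, one per transition,
#' with the same shape, noise and determinism contract as
#' [simulateRun()].
#'
#' @param transitions data.frame with columns `precursor`, `product`,
#'   `area`, `rt`, `sigma`, and optionally `tau`, `shape`. Duplicate
#'   (precursor, product) pairs are rejected.
#' @param scanInterval,rtSpan,baseline,noiseSd,seed As in
#'   [simulateRun()].
#' @return A list with `peakmap` (chromatograms only) and `truth` (one row
#'   per transition with its closed-form area).
#' @export
simulateMrmRun <- function(transitions, scanInterval = 0.5,
                           rtSpan = c(0, 600), baseline = 0,
                           noiseSd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (anyDuplicated(transitions[, c("precursor", "product")]))
    stop("duplicate transitions in MRM simulation")
  if (is.null(transitions$tau)) transitions$tau <- 0
  if (is.null(transitions$shape)) transitions$shape <- "gaussian"
  grid <- seq(rtSpan[1], rtSpan[2], by = scanInterval)
  chroms <- vector("list", nrow(transitions))
  for (i in seq_len(nrow(transitions))) {
    tr <- transitions[i, ]
    v <- tr$area * .shapeProfile(grid, tr$shape, tr$rt, tr$sigma, tr$tau) +
      baseline
    if (noiseSd > 0) v <- v + stats::rnorm(length(grid), 0, noiseSd)
    v <- pmax(v, 0)
    chroms[[i]] <- chromatogram(rt = grid, intensity = v, kind = "SRM",
                                precursorMz = tr$precursor,
                                productMz = tr$product)
  }
  truth <- data.frame(precursor = transitions$precursor,
                      product = transitions$product,
                      rtApex = transitions$rt, area = transitions$area)
  list(peakmap = peakMap(chromatograms = chroms,
                         metadata = list(runId = "simulated-mrm",
                                         scanInterval = scanInterval,
                                         rng = "Mersenne-Twister",
                                         seed = seed)),
       truth = truth)
}
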