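# Chromatographic peak integrators and table-level (re-)integration.
# All integrators accept an EIC or a Chromatogram (anything with rt /
# intensity traces) plus a closed rt window and a constant baseline.

.traceWindow <- function(x, rtmin, rtmax) {
  stopifnot(rtmin <= rtmax)
  sel <- x@rt >= rtmin & x@rt <= rtmax
  list(rt = x@rt[sel], intensity = x@intensity[sel])
}

.trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

.result <- function(method, area, rmse = NA_real_, params = list(),
                    baseline = 0, message = "") {
  new("IntegrationResult", method = method, area = as.numeric(area),
      rmse = as.numeric(rmse), params = params,
      baseline = as.numeric(baseline), message = message)
}

setMethod("show", "IntegrationResult", function(object) {
  cat(sprintf("IntegrationResult [%s]: area %.6g", object@method,
              object@area))
  if (!is.na(object@rmse)) cat(sprintf(", rmse %.4g", object@rmse))
  if (length(object@params))
    cat("; ", paste(names(object@params),
                    signif(unlist(object@params), 6),
                    sep = "=", collapse = ", "), sep = "")
  if (nzchar(object@message)) cat(" (", object@message, ")", sep = "")
  cat("\n")
})

#' @describeIn integrateTrapezoid Area of an integration result.
#' @param r An [IntegrationResult-class].
#' @export
resultArea <- function(r) r@area

#' @describeIn integrateTrapezoid Method identifier of a result.
#' @export
resultMethod <- function(r) r@method

#' @describeIn integrateTrapezoid Model parameters of a result.
#' @export
resultParams <- function(r) r@params

#' @describeIn integrateTrapezoid Model RMSE of a result.
#' @export
resultRmse <- function(r) r@rmse

#' Trapezoidal peak integration
#'
#' Trapezoidal quadrature of `intensity - baseline`, clipped at zero, over
#' trace points with rt in the closed window. Fewer than two points give
#' area 0.
#'
#' @param x An [EIC-class] or [Chromatogram-class].
#' @param rtmin,rtmax Closed rt window (seconds).
#' @param baseline Constant baseline to subtract (default 0).
#' @return An [IntegrationResult-class] with method `"trapezoid"`.
#' @export
integrateTrapezoid <- function(x, rtmin = -Inf, rtmax = Inf,
                               baseline = 0) {
  w <- .traceWindow(x, rtmin, rtmax)
  y <- pmax(w$intensity - baseline, 0)
  .result("trapezoid", .trapz(w$rt, y), baseline = baseline)
}

#' Savitzky-Golay smoothed integration
#'
#' Fits a Savitzky-Golay polynomial filter to the windowed trace, then
#' integrates the smoothed trace by trapezoid; the reported rmse is the
#' root mean square of raw minus smoothed. With fewer window points than
#' the filter length the method falls back to the raw trapezoid and flags
#' this in the method id.
#'
#' @param x An [EIC-class] or [Chromatogram-class].
#' @param rtmin,rtmax Closed rt window.
#' @param windowPts Filter length (odd, > `polyOrder`).
#' @param polyOrder Polynomial order.
#' @param baseline Constant baseline.
#' @return An [IntegrationResult-class] with method `"sgolay"` (or
#'   `"sgolay_fallback_trapezoid"`).
#' @export
integrateSGolay <- function(x, rtmin = -Inf, rtmax = Inf, windowPts = 7L,
                            polyOrder = 2L, baseline = 0) {
  stopifnot(windowPts %% 2L == 1L, windowPts > polyOrder)
  w <- .traceWindow(x, rtmin, rtmax)
  if (length(w$rt) < windowPts) {
    r <- integrateTrapezoid(x, rtmin, rtmax, baseline)
    return(.result("sgolay_fallback_trapezoid", r@area,
                   baseline = baseline,
                   message = "too few points for filter"))
  }
  sm <- signal::sgolayfilt(w$intensity, p = polyOrder, n = windowPts)
  rmse <- sqrt(mean((w$intensity - sm)^2))
  y <- pmax(sm - baseline, 0)
  .result("sgolay", .trapz(w$rt, y), rmse = rmse,
          params = list(windowPts = windowPts, polyOrder = polyOrder),
          baseline = baseline)
}

#' Peak maximum "integration"
#'
#' Reports the maximum intensity above baseline in the window (with its
#' rt) instead of an area; useful for quick screening.
#'
#' @inheritParams integrateTrapezoid
#' @return An [IntegrationResult-class] with method `"max"`; the area slot
#'   holds the maximum.
#' @export
integrateMax <- function(x, rtmin = -Inf, rtmax = Inf, baseline = 0) {
  w <- .traceWindow(x, rtmin, rtmax)
  if (!length(w$rt)) return(.result("max", 0, baseline = baseline))
  y <- pmax(w$intensity - baseline, 0)
  i <- which.max(y)   # earliest rt on ties
  .result("max", y[i], params = list(rtAtMax = w$rt[i]),
          baseline = baseline)
}

#' @describeIn integrateTrapezoid A no-op integrator: area missing,
#'   method `"no_integration"`.
#' @inheritParams integrateTrapezoid
#' @export
noIntegration <- function(x, rtmin = -Inf, rtmax = Inf, baseline = 0) {
  .result("no_integration", NA_real_, baseline = baseline)
}

# EMG profile in the numerically stable erfcx form:
#   h(t) = H * u * sqrt(pi/2) * erfcx((u - w)/sqrt(2)) * exp(-w^2/2),
#   u = sigma/tau, w = (t - mu)/sigma.
# Integrates to H * sigma * sqrt(2*pi) for every tau, and tends to the
# Gaussian H * exp(-w^2/2) as tau -> 0.
.emgDensity <- function(t, mu, sigma, tau) {
  # exponnorm density (integrates to 1), branched for stability:
  # left of the peak erfcx avoids underflow; far right erfcx overflows,
  # so use erfc (bounded by 2) with the algebraically equal exponent.
  u <- sigma / tau
  w <- (t - mu) / sigma
  z <- (u - w) / sqrt(2)
  out <- numeric(length(w))
  left <- z >= 0
  out[left] <- pracma::erfcx(z[left]) * exp(-w[left]^2 / 2) / (2 * tau)
  out[!left] <- pracma::erfc(z[!left]) *
    exp(u^2 / 2 - u * w[!left]) / (2 * tau)
  out
}

.emgHeight <- function(t, H, mu, sigma, tau) {
  if (tau <= 0) return(H * exp(-((t - mu) / sigma)^2 / 2))
  H * sigma * sqrt(2 * pi) * .emgDensity(t, mu, sigma, tau)
}

#' Exponentially-modified-Gaussian peak fit
#'
#' Least-squares fit of the EMG model `h(t; H, mu, sigma, tau)` to the
#' windowed trace (Levenberg-Marquardt). The parameterization uses the
#' exponential-convolution form evaluated through scaled complementary
#' error functions, which stays stable for large `sigma/tau`; the model
#' area has the closed form `H * sigma * sqrt(2*pi)`. Initialization is
#' deterministic: `mu0` = rt of the maximum (earliest on ties), `sigma0` =
#' half width at half maximum, `tau0 = sigma0`, `H0` = maximum intensity.
#' Non-convergence yields a failed-fit result (area missing, diagnostic
#' message), never an error.
#'
#' @param x An [EIC-class] or [Chromatogram-class] with at least 5 points
#'   in the window.
#' @param rtmin,rtmax Closed rt window.
#' @param baseline Constant baseline subtracted before fitting.
#' @return An [IntegrationResult-class] with method `"emg"`, parameters
#'   `H`, `mu`, `sigma`, `tau`, and the fit rmse.
#' @export
fitEMG <- function(x, rtmin = -Inf, rtmax = Inf, baseline = 0) {
  w <- .traceWindow(x, rtmin, rtmax)
  failed <- function(msg) .result("emg", NA_real_, baseline = baseline,
                                  message = msg)
  if (length(w$rt) < 5L) return(failed("fewer than 5 points in window"))
  y <- w$intensity - baseline
  ymax <- max(y)
  if (ymax <= 0) return(failed("no signal above baseline"))
  imax <- which.max(y)                     # earliest rt on ties
  mu0 <- w$rt[imax]
  above <- which(y >= ymax / 2)
  hwhm <- max((w$rt[max(above)] - w$rt[min(above)]) / 2,
              diff(range(w$rt)) / (2 * length(w$rt)))
  sigma0 <- hwhm / sqrt(2 * log(2))
  start <- c(H = ymax, mu = mu0, sigma = sigma0, tau = sigma0)

  resid <- function(p)
    .emgHeight(w$rt, p[1], p[2], p[3], p[4]) - y
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid,
                       lower = c(0, rtmin, 1e-6, 1e-6),
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4 || !all(is.finite(fit$par)))
    return(failed(if (is.null(fit)) "optimizer error"
                  else paste("no convergence:", fit$message)))
  p <- fit$par
  area <- p[["H"]] * p[["sigma"]] * sqrt(2 * pi)
  rmse <- sqrt(mean(resid(p)^2))
  .result("emg", area, rmse = rmse,
          params = list(H = p[["H"]], mu = p[["mu"]],
                        sigma = p[["sigma"]], tau = p[["tau"]]),
          baseline = baseline)
}

.INTEGRATORS <- list(trapezoid = integrateTrapezoid,
                     sgolay = integrateSGolay,
                     emg = fitEMG,
                     max = integrateMax,
                     no_integration = noIntegration)

# check the peak-table convention: id, mzmin, mzmax, rtmin, rtmax, peakmap
.checkPeakTable <- function(pt) {
  need <- c("id", "mzmin", "mzmax", "rtmin", "rtmax", "peakmap")
  miss <- setdiff(need, pt@colNames)
  if (length(miss))
    stop("peak table lacks required columns: ",
         paste(miss, collapse = ", "))
  d <- asDataFrame(pt)
  if (anyDuplicated(d$id)) stop("peak table ids must be unique")
  if (any(d$mzmin > d$mzmax, na.rm = TRUE) ||
      any(d$rtmin > d$rtmax, na.rm = TRUE))
    stop("peak table windows must satisfy mzmin <= mzmax, rtmin <= rtmax")
  d
}

.integrateRow <- function(row, registry, method, params) {
  pm <- if (is.na(row$peakmap) || row$peakmap > length(registry$objs))
    NULL else registry$objs[[row$peakmap]]
  if (is.null(pm) || !is(pm, "PeakMap"))
    return(.result("unresolved_peakmap", NA_real_,
                   message = "peakmap reference not resolvable"))
  eic <- extractEIC(pm, row$mzmin, row$mzmax, row$rtmin, row$rtmax)
  do.call(.INTEGRATORS[[method]],
          c(list(eic, rtmin = row$rtmin, rtmax = row$rtmax), params))
}

#' Integrate every peak of a peak table
#'
#' A peak table has columns `id` (unique), `mzmin`, `mzmax`, `rtmin`,
#' `rtmax` and `peakmap` (a reference column). One EIC is extracted and
#' integrated per row; the result columns `method`, `area`, `rmse` and
#' `params` (model parameters as JSON text) are appended. Rows whose
#' peakmap reference cannot be resolved are flagged
#' (`method = "unresolved_peakmap"`) and the remaining rows proceed.
#' Output is identical for any worker count and row order.
#'
#' @param pt A peak table ([MzTable-class]).
#' @param method One of `"trapezoid"`, `"sgolay"`, `"emg"`, `"max"`,
#'   `"no_integration"`.
#' @param params Named list of extra integrator arguments (e.g.
#'   `baseline`, `windowPts`).
#' @param workers Parallel workers (forked; results are worker-count
#'   independent).
#' @return A new [MzTable-class] with the result columns.
#' @export
integrateTable <- function(pt, method = "trapezoid", params = list(),
                           workers = 1L) {
  stopifnot(method %in% names(.INTEGRATORS))
  d <- .checkPeakTable(pt)
  n <- nrow(d)
  run1 <- function(r) .integrateRow(d[r, ], pt@registry, method, params)
  results <- if (workers > 1L && n > 0L)
    parallel::mclapply(seq_len(n), run1, mc.cores = workers)
  else lapply(seq_len(n), run1)

  add <- list(
    method = vapply(results, function(r) r@method, character(1)),
    area = vapply(results, function(r) r@area, numeric(1)),
    rmse = vapply(results, function(r) r@rmse, numeric(1)),
    params = vapply(results, function(r)
      as.character(jsonlite::toJSON(c(r@params,
        if (nzchar(r@message)) list(message = r@message)),
        auto_unbox = TRUE, digits = NA)), character(1)))

  keep <- setdiff(pt@colNames, names(add))
  outNames <- c(keep, names(add))
  outTypes <- c(pt@colTypes[match(keep, pt@colNames)],
                c("text", "real", "real", "text"))
  out <- .newTable(outNames, outTypes, rep("%s", length(outNames)),
                   pt@mode, pt@registry, meta = pt@meta,
                   store = if (pt@mode == "disk") pt@backend$store)
  chunk <- c(lapply(keep, function(nm) d[[nm]]), add)
  names(chunk) <- outNames
  if (n > 0L) .appendChunk(out, chunk)
  out
}

#' Re-integrate one peak
#'
#' Changes a single row's rt window and recomputes its integration result;
#' every other row (and column) is left untouched. This is the
#' programmatic core of interactive peak re-integration.
#'
#' @param pt An integrated peak table (from [integrateTable()]).
#' @param id Row id.
#' @param rtmin,rtmax New window; defaults keep the current values.
#' @param method Integration method for the row.
#' @param params Extra integrator arguments.
#' @return A new [MzTable-class].
#' @export
reintegrate <- function(pt, id, rtmin = NULL, rtmax = NULL,
                        method = "trapezoid", params = list()) {
  d <- asDataFrame(pt)
  i <- match(id, d$id)
  if (is.na(i)) stop("no peak with id ", id)
  if (!is.null(rtmin)) d$rtmin[i] <- rtmin
  if (!is.null(rtmax)) d$rtmax[i] <- rtmax
  r <- .integrateRow(d[i, ], pt@registry, method, params)
  if ("method" %in% names(d)) {
    d$method[i] <- r@method
    d$area[i] <- r@area
    d$rmse[i] <- r@rmse
    d$params[i] <- as.character(jsonlite::toJSON(c(r@params,
      if (nzchar(r@message)) list(message = r@message)),
      auto_unbox = TRUE, digits = NA))
  }
  out <- .newTable(pt@colNames, pt@colTypes, pt@formats, pt@mode,
                   pt@registry, meta = pt@meta,
                   store = if (pt@mode == "disk") pt@backend$store)
  .appendChunk(out, as.list(d)[pt@colNames])
  out
}
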