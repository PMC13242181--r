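# Peak integrators: quadrature, smoothing, EMG model fits, table-level
# integration and re-integration.

gaussianEic <- function(H = 1000, mu = 300, sigma = 5, step = 1,
                        halfSpan = 5 * sigma) {
  rt <- seq(mu - halfSpan, mu + halfSpan, by = step)
  new("EIC", rt = rt, intensity = H * exp(-((rt - mu) / sigma)^2 / 2),
      mzmin = 0, mzmax = 1, rtmin = min(rt), rtmax = max(rt),
      msLevel = 1L)
}

test_that("trapezoid integrates known closed forms", {
  tri <- new("EIC", rt = c(0, 1, 2), intensity = c(0, 10, 0),
             mzmin = 0, mzmax = 1, rtmin = 0, rtmax = 2, msLevel = 1L)
  expect_equal(resultArea(integrateTrapezoid(tri, 0, 2)), 10)
  expect_equal(resultArea(integrateTrapezoid(tri, 5, 9)), 0)
  e <- gaussianEic()
  truth <- 1000 * 5 * sqrt(2 * pi)
  expect_equal(resultArea(integrateTrapezoid(e)), truth,
               tolerance = 0.01)
  # constant baseline is subtracted before integrating
  e2 <- new("EIC", rt = e@rt, intensity = e@intensity + 50,
            mzmin = 0, mzmax = 1, rtmin = 0, rtmax = 600, msLevel = 1L)
  expect_equal(resultArea(integrateTrapezoid(e2, baseline = 50)),
               resultArea(integrateTrapezoid(e)), tolerance = 1e-9)
})

test_that("trapezoid error strictly decreases under grid refinement", {
  truth <- 1000 * 5 * sqrt(2 * pi)
  errs <- vapply(c(5 / 2, 5 / 4, 5 / 8), function(step)
    abs(resultArea(integrateTrapezoid(gaussianEic(step = step))) - truth),
    numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[1] / truth, 0.01)
})

test_that("savitzky-golay reproduces polynomials and falls back", {
  rt <- as.numeric(0:30)
  y <- 5 + 2 * rt - 0.05 * rt^2
  e <- new("EIC", rt = rt, intensity = pmax(y, 0), mzmin = 0, mzmax = 1,
           rtmin = 0, rtmax = 30, msLevel = 1L)
  r <- integrateSGolay(e, 0, 30, windowPts = 7L, polyOrder = 2L)
  expect_lt(resultRmse(r), 1e-9)
  expect_equal(resultArea(r), resultArea(integrateTrapezoid(e, 0, 30)),
               tolerance = 1e-9)
  # constant trace integrates to constant x span
  ec <- new("EIC", rt = rt, intensity = rep(10, 31), mzmin = 0,
            mzmax = 1, rtmin = 0, rtmax = 30, msLevel = 1L)
  expect_equal(resultArea(integrateSGolay(ec, 0, 30)), 300)
  # too few points -> flagged trapezoid fallback
  r2 <- integrateSGolay(e, 0, 3, windowPts = 9L, polyOrder = 2L)
  expect_equal(resultMethod(r2), "sgolay_fallback_trapezoid")
  expect_error(integrateSGolay(e, 0, 30, windowPts = 6L), "windowPts")
})

test_that("smoothing suppresses superimposed white noise", {
  # statistical oracle over seeds: the smoothed trace is closer to the
  # true (flat) signal than the raw trace, and the reported rmse is the
  # rms of raw minus smoothed
  set.seed(77)
  wins <- vapply(1:20, function(i) {
    rt <- as.numeric(0:60)
    y <- 50 + rnorm(61, 0, 10)
    e <- new("EIC", rt = rt, intensity = pmax(y, 0), mzmin = 0,
             mzmax = 1, rtmin = 0, rtmax = 60, msLevel = 1L)
    r <- integrateSGolay(e, 0, 60)
    sm <- signal::sgolayfilt(e@intensity, p = 2, n = 7)
    expect_equal(resultRmse(r), sqrt(mean((e@intensity - sm)^2)))
    sd(sm - 50) < sd(e@intensity - 50)
  }, logical(1))
  expect_gt(mean(wins), 0.9)
})

test_that("EMG fits recover noise-free parameters within 0.5%", {
  rt <- seq(260, 380, by = 0.5)
  H <- 500; mu <- 300; sg <- 4; tau <- 6
  y <- mzforge:::.emgHeight(rt, H, mu, sg, tau)
  e <- new("EIC", rt = rt, intensity = y, mzmin = 0, mzmax = 1,
           rtmin = 260, rtmax = 380, msLevel = 1L)
  r <- fitEMG(e)
  p <- resultParams(r)
  truthArea <- H * sg * sqrt(2 * pi)
  expect_equal(resultArea(r), truthArea, tolerance = 5e-3)
  expect_equal(p$mu, mu, tolerance = 5e-3)
  expect_equal(p$sigma, sg, tolerance = 5e-3)
  expect_equal(p$tau, tau, tolerance = 5e-3)
  expect_lt(resultRmse(r), 1e-6 * H)
})

test_that("EMG tends to the Gaussian closed form as tau -> 0", {
  e <- gaussianEic(H = 800, mu = 300, sigma = 5, step = 0.5)
  r <- fitEMG(e)
  expect_equal(resultArea(r), 800 * 5 * sqrt(2 * pi), tolerance = 0.01)
})

test_that("EMG failure modes return failed-fit results, not errors", {
  rt <- seq(0, 10, by = 1)
  zero <- new("EIC", rt = rt, intensity = rep(0, 11), mzmin = 0,
              mzmax = 1, rtmin = 0, rtmax = 10, msLevel = 1L)
  r <- fitEMG(zero)
  expect_equal(resultMethod(r), "emg")
  expect_true(is.na(resultArea(r)))
  expect_match(r@message, "signal")
  few <- new("EIC", rt = c(1, 2, 3), intensity = c(1, 5, 1), mzmin = 0,
             mzmax = 1, rtmin = 0, rtmax = 10, msLevel = 1L)
  expect_true(is.na(resultArea(fitEMG(few))))
})

test_that("EMG recovery stays accurate across noisy replicates", {
  # SNR 50: noise sd = H / 50
  rt <- seq(260, 380, by = 0.5)
  H <- 500; mu <- 300; sg <- 4; tau <- 6
  truthArea <- H * sg * sqrt(2 * pi)
  clean <- mzforge:::.emgHeight(rt, H, mu, sg, tau)
  set.seed(123)
  relErr <- vapply(1:100, function(i) {
    y <- pmax(clean + rnorm(length(rt), 0, H / 50), 0)
    e <- new("EIC", rt = rt, intensity = y, mzmin = 0, mzmax = 1,
             rtmin = 260, rtmax = 380, msLevel = 1L)
    abs(resultArea(fitEMG(e)) - truthArea) / truthArea
  }, numeric(1))
  expect_lte(stats::median(relErr), 0.01)
})

test_that("table integration is worker-count independent and flags bad refs", {
  fx <- makeIntegratedPeakTable(8)
  t1 <- integrateTable(fx$pt, "trapezoid", workers = 1L)
  t2 <- integrateTable(fx$pt, "trapezoid", workers = 4L)
  expect_identical(asDataFrame(t1), asDataFrame(t2))
  d <- asDataFrame(t1)
  expect_equal(d$area, fx$areas, tolerance = 0.01)
  expect_true(all(d$method == "trapezoid"))
  # row order permutation integrates to the same per-id results
  perm <- sortTable(fx$pt, "rtmin", descending = TRUE)
  dp <- asDataFrame(integrateTable(perm, "trapezoid"))
  expect_equal(dp$area[order(dp$id)], d$area[order(d$id)])
  # unresolvable reference flags the row, others proceed
  bad <- createTable(columnNames(fx$pt), columnTypes(fx$pt),
                     list(list(99L, 150.0, 150.1, 90, 110, 999L)),
                     registry = fx$pt@registry)
  db <- asDataFrame(integrateTable(bad, "trapezoid"))
  expect_equal(db$method, "unresolved_peakmap")
  expect_true(is.na(db$area))
  # degenerate windows integrate to zero without error
  pt0 <- createTable(columnNames(fx$pt), columnTypes(fx$pt),
                     list(list(1L, 150.0, 150.1, 100, 100, fx$key)),
                     registry = fx$pt@registry)
  expect_equal(asDataFrame(integrateTable(pt0, "trapezoid"))$area, 0)
  # empty table stays empty
  e <- createTable(columnNames(fx$pt), columnTypes(fx$pt))
  expect_equal(numRows(integrateTable(e)), 0L)
})

test_that("reintegrate changes exactly one row and is idempotent", {
  fx <- makeIntegratedPeakTable(5)
  it <- integrateTable(fx$pt, "trapezoid")
  before <- asDataFrame(it)
  # unchanged window reproduces the original result exactly
  same <- asDataFrame(reintegrate(it, 3L, method = "trapezoid"))
  expect_identical(same, before)
  # widening a window on a nonnegative trace never decreases the area
  wide <- asDataFrame(reintegrate(it, 3L,
                                  rtmin = before$rtmin[3] - 5,
                                  rtmax = before$rtmax[3] + 5))
  expect_gte(wide$area[3], before$area[3])
  expect_identical(wide[-3, setdiff(names(wide), c("rtmin", "rtmax"))],
                   before[-3, setdiff(names(before),
                                      c("rtmin", "rtmax"))])
  # shrinking to a point zeroes the area
  pt <- asDataFrame(reintegrate(it, 3L, rtmin = before$rtmin[3],
                                rtmax = before$rtmin[3]))
  expect_equal(pt$area[3], 0)
  expect_error(reintegrate(it, 12345L), "no peak with id")
})

test_that("max integrator reports the apex with earliest-rt ties", {
  e <- new("EIC", rt = c(0, 1, 2, 3), intensity = c(1, 7, 7, 2),
           mzmin = 0, mzmax = 1, rtmin = 0, rtmax = 3, msLevel = 1L)
  r <- integrateMax(e, 0, 3)
  expect_equal(resultArea(r), 7)
  expect_equal(resultParams(r)$rtAtMax, 1)
  expect_true(is.na(resultArea(noIntegration(e))))
})
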