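# RT alignment, m/z recalibration, isotope and adduct grouping.

test_that("piecewise-linear alignment reproduces anchor maps exactly", {
  id <- fitRtAlignment(data.frame(rtObserved = c(100, 200, 300),
                                  rtReference = c(100, 200, 300)))
  q <- c(50, 100, 137.5, 250, 300, 400)
  expect_equal(mapRt(id, q), q)
  shift <- fitRtAlignment(data.frame(rtObserved = c(100, 200, 300),
                                     rtReference = c(107, 207, 307)))
  expect_equal(mapRt(shift, q), q + 7)
  expect_error(fitRtAlignment(data.frame(rtObserved = 1,
                                         rtReference = 1)), "at least 2")
  expect_error(fitRtAlignment(data.frame(rtObserved = c(1, 1),
                                         rtReference = c(1, 2))),
               "distinct")
})

test_that("alignment interpolates a monotone warp accurately", {
  truth <- function(rt) rt + 10 * sin(rt / 200) + 0.02 * rt
  anchors <- data.frame(rtObserved = seq(50, 550, length.out = 10))
  anchors$rtReference <- truth(anchors$rtObserved)
  m <- fitRtAlignment(anchors)
  q <- seq(50, 550, by = 1)
  expect_lt(max(abs(mapRt(m, q) - truth(q))), 0.5)
})

test_that("alignment round-trips through its inverse", {
  anchors <- data.frame(rtObserved = c(60, 120, 260, 480),
                        rtReference = c(65, 131, 266, 488))
  m <- fitRtAlignment(anchors)
  inv <- invertAlignment(m)
  q <- seq(60, 480, by = 7)
  expect_equal(mapRt(inv, mapRt(m, q)), q, tolerance = 1e-9)
})

test_that("fitting on already-aligned anchors returns the identity", {
  anchors <- data.frame(rtObserved = c(100, 250, 400),
                        rtReference = c(100, 250, 400))
  m <- fitRtAlignment(anchors)
  expect_equal(mapRt(m, c(100, 175, 400)), c(100, 175, 400),
               tolerance = 1e-9)
})

test_that("non-monotone targets are isotonically repaired with warning", {
  expect_warning(
    m <- fitRtAlignment(data.frame(rtObserved = c(100, 200, 300),
                                   rtReference = c(110, 105, 310))),
    "isotonic")
  expect_true(m@repaired)
  v <- mapRt(m, seq(100, 300, by = 5))
  expect_true(all(diff(v) > 0))
})

test_that("alignment applies to peakmaps and tables order-preservingly", {
  pm <- makeGaussianMap(150, 1e4, 100, interval = 2, span = c(50, 150))
  m <- fitRtAlignment(data.frame(rtObserved = c(50, 150),
                                 rtReference = c(55, 160)))
  pm2 <- applyRtAlignment(pm, m)
  expect_equal(spectraRt(pm2), mapRt(m, spectraRt(pm)))
  expect_false(is.unsorted(spectraRt(pm2)))
  t <- createTable(c("rtmin", "rtmax"), c("real", "real"),
                   rows = list(list(60, 80), list(100, 140)))
  t2 <- applyRtAlignment(t, m)
  d <- asDataFrame(t2)
  expect_true(all(d$rtmin <= d$rtmax))
  expect_equal(d$rtmin, mapRt(m, c(60, 100)))
  # identity model keeps the object equal
  idm <- fitRtAlignment(data.frame(rtObserved = c(0, 600),
                                   rtReference = c(0, 600)))
  expect_equal(spectraRt(applyRtAlignment(pm, idm)), spectraRt(pm))
})

test_that("m/z calibration recovers affine distortions", {
  obs <- seq(100, 900, length.out = 20)
  cal0 <- fitMzCalibration(obs, obs)
  expect_equal(cal0@a, 1, tolerance = 1e-12)
  expect_equal(cal0@b, 0, tolerance = 1e-10)
  calOff <- fitMzCalibration(obs, obs + 0.005)
  expect_equal(calOff@b, 0.005, tolerance = 1e-9)
  expect_equal(calOff@a, 1, tolerance = 1e-12)
  # gain recovery under noise, within 3 standard errors
  set.seed(55)
  obs <- runif(50, 100, 1000)
  ref <- 1.00002 * obs + rnorm(50, 0, 1e-4)
  cal <- fitMzCalibration(obs, ref)
  se <- summary(lm(ref ~ obs))$coefficients["obs", "Std. Error"]
  expect_lt(abs(cal@a - 1.00002), 3 * se)
  expect_equal(applyMzCalibration(100, calOff), 100.005,
               tolerance = 1e-9)
  expect_error(fitMzCalibration(1, numeric(0)), "at least 2")
  expect_warning(fitMzCalibration(c(100, 200), c(90, 180)), "gain")
})

test_that("isotope grouping recovers planted chains and charges", {
  delta <- 1.0033548378
  ft <- data.frame(
    mz = c(131.0946, 131.0946 + delta, 131.0946 + 2 * delta),
    rt = c(300, 300.1, 299.9),
    intensity = c(1000, 120, 8))
  g <- groupIsotopes(ft, mzTol = 0.002, rtTol = 2, maxCharge = 2L)
  expect_equal(g$groupId, c(1L, 1L, 1L))
  expect_equal(g$charge, c(1L, 1L, 1L))
  expect_equal(g$isotopologue, 0:2)
  # doubly charged spacing delta/2
  ft2 <- data.frame(mz = c(400.2, 400.2 + delta / 2),
                    rt = c(200, 200), intensity = c(500, 100))
  g2 <- groupIsotopes(ft2, mzTol = 0.002, rtTol = 2, maxCharge = 2L)
  expect_equal(g2$groupId, c(1L, 1L))
  expect_equal(g2$charge, c(2L, 2L))
  # singleton
  g3 <- groupIsotopes(data.frame(mz = 100, rt = 10, intensity = 5))
  expect_equal(g3$groupId, 1L)
  expect_equal(g3$isotopologue, 0L)
  # non-coeluting peaks do not group
  ft4 <- data.frame(mz = c(131.0946, 131.0946 + delta),
                    rt = c(300, 330), intensity = c(1000, 120))
  g4 <- groupIsotopes(ft4, mzTol = 0.002, rtTol = 2)
  expect_equal(sort(unique(g4$groupId)), c(1L, 2L))
})

test_that("isotope grouping partitions any input deterministically", {
  set.seed(66)
  for (i in 1:5) {
    n <- 60
    ft <- data.frame(mz = runif(n, 100, 600), rt = runif(n, 0, 500),
                     intensity = runif(n, 1, 1e4))
    g <- groupIsotopes(ft, mzTol = 0.005, rtTol = 5, maxCharge = 2L)
    expect_false(any(is.na(g$groupId)))   # every peak in exactly one group
    expect_false(any(is.na(g$isotopologue)))
    # permutation invariance (ids relabel, membership identical)
    perm <- sample(n)
    gp <- groupIsotopes(ft[perm, ], mzTol = 0.005, rtTol = 5,
                        maxCharge = 2L)
    back <- gp[order(perm), ]
    samePartition <- outer(g$groupId, g$groupId, "==") ==
      outer(back$groupId, back$groupId, "==")
    expect_true(all(samePartition))
  }
})

test_that("grouping works on MzTable input and through the table engine", {
  ft <- createTable(c("mz", "rt", "intensity"),
                    c("real", "real", "real"),
                    rows = list(list(131.0946, 300, 1000),
                                list(132.0980, 300, 120)))
  g <- groupIsotopes(ft, mzTol = 0.002, rtTol = 2)
  expect_s4_class(g, "MzTable")
  d <- asDataFrame(g)
  expect_equal(d$groupId, c(1L, 1L))
})

test_that("adduct grouping links co-eluting ion species of one neutral", {
  M <- 180.063388
  lib <- defaultAdducts()
  peaks <- data.frame(
    mz = c(M + 1.007276466621 - 0.00054857990907 * 0,
           M + 22.989218),
    rt = c(200, 200.5), intensity = c(1000, 400))
  peaks$mz <- c(adductMz(M, lib[["[M+H]+"]]), adductMz(M, lib[["[M+Na]+"]]))
  g <- groupIsotopes(peaks, mzTol = 0.002, rtTol = 2)
  a <- groupAdducts(g, lib, mzTol = 0.002, rtTol = 2)
  expect_equal(a$adductGroup, c(1L, 1L))
  expect_equal(a$neutralMass, rep(M, 2), tolerance = 1e-4)
  expect_setequal(a$adductName, c("[M+H]+", "[M+Na]+"))
  # no co-elution -> no link
  peaks2 <- peaks
  peaks2$rt <- c(200, 300)
  a2 <- groupAdducts(groupIsotopes(peaks2, mzTol = 0.002, rtTol = 2),
                     lib, mzTol = 0.002, rtTol = 2)
  expect_true(all(is.na(a2$adductGroup)))
  # empty library -> no annotations
  a3 <- groupAdducts(g, list(), mzTol = 0.002, rtTol = 2)
  expect_true(all(is.na(a3$adductGroup)))
})
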