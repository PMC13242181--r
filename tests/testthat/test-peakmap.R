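# PeakMap model, EIC extraction, 2D binning, MRM lookup, mzML round-trip.

test_that("type invariants are enforced at construction", {
  expect_error(new("Spectrum", rt = 1, msLevel = 1L, polarity = 0L,
                   precursors = data.frame(), mz = c(2, 1),
                   intensity = c(1, 1)), "ascending")
  expect_error(new("Spectrum", rt = 1, msLevel = 2L, polarity = 0L,
                   precursors = data.frame(), mz = 1, intensity = 1),
               "precursor")
  expect_error(chromatogram(c(1, 2), c(1, 1), kind = "SRM"),
               "precursor and product")
  # peakMap sorts spectra by rt on construction
  pm <- peakMap(list(spectrum(10, 1, 1), spectrum(5, 1, 1)))
  expect_equal(spectraRt(pm), c(5, 10))
})

test_that("EIC extraction windows are closed and zero-filled", {
  pm <- makeGaussianMap(mzs = 131.0946, areas = 1e4, mus = 300,
                        sigma = 2, interval = 1, span = c(290, 309))
  e <- extractEIC(pm, 131.0946 - 0.003, 131.0946 + 0.003)
  expect_length(traceRt(e), 20)
  expect_equal(traceIntensity(e), 1e4 * dnorm(290:309, 300, 2))
  # no spectra in window -> empty EIC, not an error
  e2 <- extractEIC(pm, 100, 101, rtmin = 700, rtmax = 800)
  expect_length(traceRt(e2), 0)
  # spectra with no peak in the m/z window contribute explicit zeros
  e3 <- extractEIC(pm, 500, 501)
  expect_equal(traceIntensity(e3), rep(0, 20))
})

test_that("full-m/z EIC reproduces the total ion current", {
  set.seed(4)
  specs <- lapply(seq(0, 30, by = 3), function(t)
    spectrum(t, sort(runif(5, 100, 900)), runif(5, 0, 1e4)))
  pm <- peakMap(specs)
  e <- extractEIC(pm, 0, 1000)
  tic <- totalIonCurrent(pm)
  expect_equal(traceIntensity(e), traceIntensity(tic))
  expect_equal(traceRt(e), traceRt(tic))
})

test_that("enlarging the m/z window never decreases EIC intensities", {
  set.seed(9)
  specs <- lapply(seq(0, 20, by = 2), function(t)
    spectrum(t, sort(runif(20, 100, 200)), runif(20, 0, 100)))
  pm <- peakMap(specs)
  widths <- c(1, 5, 20, 60)
  prev <- NULL
  for (w in widths) {
    e <- traceIntensity(extractEIC(pm, 150 - w, 150 + w))
    if (!is.null(prev)) expect_true(all(e >= prev - 1e-12))
    prev <- e
  }
})

test_that("bin2d matches a brute-force double loop and conserves", {
  set.seed(31)
  specs <- lapply(seq(0, 50, by = 5), function(t)
    spectrum(t, sort(runif(10, 100, 500)), runif(10, 0, 100)))
  pm <- peakMap(specs)
  rtE <- seq(-1, 51, length.out = 6)
  mzE <- seq(99, 501, length.out = 8)
  m <- bin2d(pm, rtE, mzE)
  brute <- matrix(0, 5, 7)
  tot <- 0
  for (s in spectra(pm)) for (k in seq_along(s@mz)) {
    tot <- tot + s@intensity[k]
    i <- max(which(rtE <= s@rt)); j <- max(which(mzE <= s@mz[k]))
    if (i <= 5 && j <= 7) brute[i, j] <- brute[i, j] + s@intensity[k]
  }
  expect_equal(m, brute)
  expect_equal(sum(m), tot)
  # single-peak map -> exactly one nonzero cell
  m1 <- bin2d(peakMap(list(spectrum(10, 150, 42))), rtE, mzE)
  expect_equal(sum(m1 > 0), 1)
  expect_equal(sum(m1), 42)
})

test_that("MRM trace lookup resolves unique transitions", {
  sim <- simulateMrmRun(data.frame(precursor = c(132.1, 132.4),
                                   product = c(86.1, 86.2),
                                   area = c(1e4, 2e4), rt = c(100, 150),
                                   sigma = 2),
                        rtSpan = c(50, 200), seed = 5)
  pm <- sim$peakmap
  ch <- extractMRMTrace(pm, 132.1, 86.1, tolMz = 0.1)
  expect_equal(ch@precursorMz, 132.1)
  # tol 0 with exact stored values still matches
  ch0 <- extractMRMTrace(pm, 132.4, 86.2, tolMz = 0)
  expect_equal(ch0@productMz, 86.2)
  expect_error(extractMRMTrace(pm, 132.25, 86.15, tolMz = 0.5),
               "ambiguous")
  expect_error(extractMRMTrace(pm, 900, 100, tolMz = 0.1), "no SRM")
})

test_that("mzML round-trip is bit-identical for spectra and SRM traces", {
  cp <- simCompounds(name = c("a", "b"),
                     formula = c("C6H13NO2", "C3H7NO2"),
                     rt = c(120, 200), area = c(1e5, 5e4), sigma = 2)
  sim <- simulateRun(cp, rtSpan = c(100, 220), baseline = 10,
                     noiseSd = 2, seed = 42)
  mrm <- simulateMrmRun(data.frame(precursor = 132.1, product = 86.1,
                                   area = 1e4, rt = 150, sigma = 2),
                        rtSpan = c(100, 220), noiseSd = 1, seed = 43)
  pm <- peakMap(spectra = spectra(sim$peakmap),
                chromatograms = chromatograms(mrm$peakmap))
  path <- withr::local_tempfile(fileext = ".mzML")
  writeMzML(pm, path)
  pm2 <- readMzML(path)
  expect_length(spectra(pm2), length(spectra(pm)))
  for (i in seq_along(spectra(pm))) {
    expect_identical(pm2@spectra[[i]]@mz, pm@spectra[[i]]@mz)
    expect_identical(pm2@spectra[[i]]@intensity,
                     pm@spectra[[i]]@intensity)
    expect_identical(pm2@spectra[[i]]@rt, pm@spectra[[i]]@rt)
  }
  expect_length(chromatograms(pm2), 1)
  expect_identical(pm2@chromatograms[[1]]@rt, pm@chromatograms[[1]]@rt)
  expect_identical(pm2@chromatograms[[1]]@intensity,
                   pm@chromatograms[[1]]@intensity)
  expect_equal(pm2@chromatograms[[1]]@kind, "SRM")
})

test_that("MS2 spectra keep precursor information through mzML", {
  ms2 <- spectrum(50, c(86.096, 132.102), c(500, 100), msLevel = 2L,
                  polarity = 1L,
                  precursors = data.frame(mz = 132.10191, charge = 1L,
                                          isolationWidth = 0.5))
  pm <- peakMap(list(spectrum(49, 132.10191, 800), ms2))
  path <- withr::local_tempfile(fileext = ".mzML")
  writeMzML(pm, path)
  pm2 <- readMzML(path)
  s2 <- spectra(pm2)[[2]]
  expect_equal(s2@msLevel, 2L)
  expect_equal(s2@precursors$mz, 132.10191, tolerance = 1e-6)
})

test_that("degenerate peakmaps survive the mzML round-trip", {
  path <- withr::local_tempfile(fileext = ".mzML")
  writeMzML(peakMap(), path)
  pm <- readMzML(path)
  expect_length(spectra(pm), 0)
  expect_length(chromatograms(pm), 0)
  # chromatogram-only file
  mrm <- simulateMrmRun(data.frame(precursor = 100.1, product = 60.2,
                                   area = 1e3, rt = 30, sigma = 1),
                        rtSpan = c(0, 60), seed = 1)
  writeMzML(mrm$peakmap, path)
  pm2 <- readMzML(path)
  expect_length(spectra(pm2), 0)
  expect_length(chromatograms(pm2), 1)
  expect_error(readMzML(file.path(tempdir(), "absent.mzML")),
               "not found")
})

test_that("chromatogram times declared in minutes are converted", {
  mrm <- simulateMrmRun(data.frame(precursor = 100.1, product = 60.2,
                                   area = 1e3, rt = 30, sigma = 1),
                        rtSpan = c(0, 60), seed = 1)
  path <- withr::local_tempfile(fileext = ".mzML")
  path2 <- withr::local_tempfile(fileext = ".mzML")
  writeMzML(mrm$peakmap, path)
  txt <- readChar(path, file.size(path), useBytes = TRUE)
  # rewrite the time-array unit as minutes without touching the values
  # (replacement strings have equal byte length, so the index stays valid)
  txt2 <- gsub(paste0('accession="MS:1000595" name="time array" ',
                      'unitCvRef="UO" unitAccession="UO:0000010" ',
                      'unitName="second"'),
               paste0('accession="MS:1000595" name="time array" ',
                      'unitCvRef="UO" unitAccession="UO:0000031" ',
                      'unitName="minute"'),
               txt, fixed = TRUE)
  writeChar(txt2, path2, eos = NULL)
  pm <- readMzML(path2)
  expect_equal(pm@chromatograms[[1]]@rt,
               mrm$peakmap@chromatograms[[1]]@rt * 60)
})
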