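# mzforge

Targeted and untargeted LC-MS/MS peak-list processing for R.

Liquid chromatography–mass spectrometry runs produce thousands of
centroided spectra (and, on triple-quadrupole instruments, MRM/SRM
transition chromatograms). Turning them into quantitative peak lists
takes a stack of small, reliable operations: extracting ion
chromatograms, integrating chromatographic peaks, correcting
retention-time drift between samples, grouping isotopologues and
adducts, and managing the resulting peak lists relationally. `mzforge`
provides that stack as composable S4 building blocks for analysts who
script their own workflows — for example when two *mass isomers* such as
leucine and isoleucine (both C6H13NO2, monoisotopic mass 131.094629 Da)
share one m/z trace and can only be told apart by elution time, so that
inter-sample RT shifts silently corrupt fixed integration windows.

## What is inside

* **PeakMap** — centroided MS^n spectra plus MRM chromatograms, with
  mzML reading (via Bioconductor's `mzR`/proteowizard) and writing
  (indexed mzML, 64-bit zlib arrays, bit-identical round trips), EIC
  extraction, TIC, and 2D rt × m/z binning.
* **MzTable** — a typed, named-column relational table for peak lists
  with filter / join / group-aggregate / sort / computed columns over a
  closed expression language, strict three-valued missing semantics,
  in-memory or out-of-core SQLite storage (observationally identical),
  and single-file persistence in which referenced peakmaps are stored
  once.
* **Chemistry** — molecular-formula parsing (`"[13]C2C4H13NO2"`), exact
  monoisotopic/average masses, isotope patterns by per-element
  convolution with tracked pruning, and a 20-adduct ESI library with
  deltas derived from the element table.
* **Integrators** — trapezoid, Savitzky–Golay, exponentially modified
  Gaussian (closed-form area `H·σ·√(2π)`, stable erfcx evaluation), max,
  and table-level parallel (re-)integration.
* **Alignment & grouping** — anchor-based monotone RT maps
  (piecewise-linear or loess, isotonic repair), affine m/z
  recalibration, greedy isotopologue grouping (Δ = 1.0033548378 Da / z)
  and adduct annotation under shared neutral-mass hypotheses.
* **Targeted workflow** — target lists → peak tables, reference-based
  per-sample RT-shift estimation (median apex deviation of reference
  compounds), window shifting for selected analytes, end-to-end
  extraction + integration over many samples.
* **Simulator** — seeded synthetic MS1 and MRM runs with exact
  closed-form ground truth, used throughout the test suite.

## Worked example

Correct RT drift for a co-eluting isomer pair using other amino acids
as references:

```r
library(mzforge)

targets <- data.frame(
  name    = c("Gly", "Ala", "Val", "Leu", "Ile"),
  formula = c("C2H5NO2", "C3H7NO2", "C5H11NO2", "C6H13NO2", "C6H13NO2"),
  adduct  = "[M+H]+",
  rt_sec  = c(100, 170, 240, 300, 320),
  rt_tol_sec = 6, mz_tol = 10, mz_tol_unit = "ppm",
  role = c("reference", "reference", "reference", "analyte", "analyte"))

cp  <- simCompounds(targets$name, targets$formula,
                    area = c(2e5, 3e5, 2.5e5, 1e5, 1.5e5),
                    rt = targets$rt_sec, sigma = 2)
run <- simulateRun(cp, scanInterval = 0.5, rtSpan = c(40, 400),
                   globalShift = 9, baseline = 5, noiseSd = 2, seed = 1)

est <- estimateRtShift(run$peakmap, targets, sampleId = "s1")
est
#> RtShiftEstimate [s1]: +9.000 s (median of 3 references)

res <- runTargetedWorkflow(list(s1 = run$peakmap), targets,
                           correction = TRUE, params = list(baseline = 5))
asDataFrame(res)[, c("name", "shift", "area", "apexRt")]
#>   name    shift      area   apexRt
#> 1  Gly 8.999998 193090.20 109.0000
#> 2  Ala 8.999998 286475.58 178.9998
#> 3  Val 8.999998 233542.95 249.0000
#> 4  Leu 8.999998  92457.54 308.9996
#> 5  Ile 8.999998 138649.12 329.0000
```

The estimated shift (+9.0 s) recenters every 6-s integration window, so
the leucine/isoleucine areas land within 0.5% of their simulated ground
truth (monoisotopic isotopologue areas 92 816 and 139 224). With
`correction = FALSE` the same windows miss the shifted peaks almost
entirely: the Leu window then integrates 6 366 — 7% of the true area —
and Ile 10 095.

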