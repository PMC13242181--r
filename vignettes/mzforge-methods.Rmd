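---
title: "mzforge: models, conventions and design choices"
author: "mzforge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mzforge: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzforge)
```

This vignette explains the science and the engineering conventions
behind `mzforge`: what each component computes, which parameters matter
and why their defaults are what they are, what the synthetic-data
generator does and does not emulate, and where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Chemistry

A `MolecularFormula` is a multiset of atoms; isotope-fixed atoms
(`"[13]C6"`) are distinct keys. The grammar accepts element tokens with
counts, parenthesized groups with multipliers, and bracketed mass-number
prefixes, and deliberately rejects charge notation: charges live in
`Adduct` objects, which keeps formula addition closed and associative.
Monoisotopic mass sums the most-abundant-isotope masses (or the fixed
isotope's mass); it is additive over formula addition to ~1e-9 Da, which
the suite checks on random formulas. The embedded element table
(CIAAW/NIST values, 21 elements) is validated at load: abundances sum to
1 within 1e-6 and isotope masses increase strictly with mass number.

Isotope patterns are computed by per-atom convolution of the element
isotope distributions. Two numerical conventions matter:

* entries closer than 1e-9 Da merge by abundance-weighted mass, so
  near-degenerate isotopologue combinations do not explode the support;
* pruning below `minAbundance` (default 1e-4) happens after *every*
  convolution step, bounding memory, and the pruned probability mass is
  accumulated so the conservation bound
  `sum(abundance) >= 1 - prunedAbundance` stays checkable.

Abundances are reported absolutely (sum ≤ 1), not max-normalized;
normalization is a one-line transform the caller can apply. For
single-element formulas the pattern equals the multinomial closed form,
which the suite verifies against `dbinom` for C_n up to n = 50 at 1e-9.

The default adduct library holds 20 common ESI species. Deltas are not
hard-coded: they are derived at load from the element table plus the
electron mass, so `[M+H]+` carries the proton mass (1.007276 Da) and a
radical cation `[M]+` loses exactly one electron mass. The library can
be replaced from a delimited file (`readAdducts`).

## PeakMap and mzML

Retention time is in seconds everywhere. All extraction windows (m/z and
rt) are closed intervals. An EIC has one point per source spectrum of
the requested MS level inside the rt window; spectra with no peak in the
m/z window contribute an explicit zero. The zero-point convention makes
the EIC's length depend only on the rt window, which in turn makes
apex localization and quadrature behave predictably on sparse data.

Reading goes through `mzR` (proteowizard), accepting 32-bit and
uncompressed arrays; spectrum times are normalized to seconds by the
backend, and chromatogram time units are read from the file's unit
declarations (minute-based files are converted). Profile-mode spectra
load unchanged with a warning — centroiding is out of scope. Writing is
generated directly by the package (indexed mzML, 64-bit zlib-compressed
arrays, spectrumList plus chromatogramList) because the established
writer cannot emit SRM chromatograms; the suite asserts bit-identical
round trips for both spectra and transitions.

`bin2d` uses half-open bins `[edge_i, edge_{i+1})` on both axes so every
peak lands in at most one cell and the matrix total conserves in-range
intensity exactly.

## The table engine

`MzTable` is a typed relational container for peak lists: columns are
`integer`, `real`, `text`, `boolean`, or references to peakmaps and
nested tables. Reference cells hold integer keys into a registry shared
by derived tables; registration deduplicates by object identity, so a
peakmap referenced from a thousand rows is held — and persisted — once.

Expressions form a closed language (`col`, literals, arithmetic,
comparisons, `&`, `|`, `!`, `isMissing`). Missing values propagate
strictly: *any* binary operation with a missing operand is missing, so
`FALSE & NA` is `NA` here, unlike both base R and SQL's Kleene logic.
This was a deliberate choice: one simple rule that filter semantics
("missing never selects") makes safe, and — crucially — one that both
storage modes implement with the same evaluator, so memory and disk mode
cannot drift apart semantically. The differential suite runs 500
randomized operation sequences against a naive list-of-rows oracle to
hold that contract.

Disk mode stores rows in an SQLite file. Streaming operations (filter,
computed columns, aggregation) page over rowid in chunks (default
10 000; `options(mzforge.chunkSize=)`), so resident memory is bounded by
the chunk, not the table. Keyset pagination (rather than an open cursor)
lets the output table be appended on the same connection mid-scan. Sort
and join may materialize: the engine contract bounds memory only for the
streaming operations. Aggregation accumulates per-group state (count,
sum, extrema, first) in O(groups); `median` necessarily buffers its
group's values. Join output order is (left row, right row) nested order,
and right-side name collisions take a configurable `"__1"` suffix —
both fixed so results are deterministic and testable.

Persistence writes one SQLite file with a `format_version` tag, a
schema/metadata key-value table, the rows, and each referenced object
serialized once. Loading rejects unknown versions explicitly. CSV
import takes explicit column types; no sniffing.

The row-wise `applyRows` escape hatch leaves the closed language and is
memory-mode-only by design.

## Integrators

All integrators take a trace (EIC or chromatogram), a closed rt window,
and a constant baseline (default 0 — no automatic baseline estimation).
Trapezoid clips `intensity − baseline` at zero, so areas are
non-negative on non-negative traces and window widening is monotone.
Savitzky–Golay (window 7, order 2 by default) integrates the smoothed
trace and reports `rmse = rms(raw − smoothed)`; with fewer points than
the filter length it falls back to the raw trapezoid and flags the
method id. Note that on a non-negative noise-only trace smoothing does
not shrink the trapezoid area in expectation (the clipped noise mean is
preserved); what smoothing buys is pointwise noise suppression, and that
is the property the suite asserts.

The EMG model is evaluated in the erfcx form
`h(t) = H·u·√(π/2)·erfcx((u−w)/√2)·exp(−w²/2)` with `u = σ/τ`,
`w = (t−μ)/σ`, branched to `erfc` on the right tail where erfcx
overflows. This form is stable for large σ/τ, integrates to
`H·σ·√(2π)` for every τ, and tends to the Gaussian `H·exp(−w²/2)` as
τ → 0, so the fitted area has a closed form and the Gaussian limit is a
genuine special case. Fitting is Levenberg–Marquardt with a
deterministic initialization (μ₀ = rt of maximum, earliest on ties;
σ₀ = HWHM/√(2 ln 2); τ₀ = σ₀; H₀ = max) and box constraints keeping σ
and τ positive. Non-convergence returns a failed-fit result with a
message — never an exception — so table-level integration can proceed
row by row.

`integrateTable` integrates one EIC per peak-table row
(`id, mzmin, mzmax, rtmin, rtmax, peakmap`), optionally forked across
workers; rows are independent and results are exactly worker-count- and
row-order-independent. Unresolvable peakmap references flag their row
and leave the rest alone. `reintegrate` re-derives a single row under a
new window and touches nothing else.

## Alignment and grouping

RT alignment fits a monotone map through anchor pairs. Piecewise-linear
interpolation passes through the anchors exactly; the loess variant
smooths them first. If fitted targets are non-monotone the package
repairs them isotonically (then spreads flat runs by a relative 1e-9) and
warns, rather than rejecting: alignment must never reorder spectra, and
a repaired monotone map is more useful than a refusal. Beyond the anchor
span the map continues linearly with the terminal slopes. m/z
recalibration is an affine least-squares fit with a sanity warning when
the gain leaves [0.99, 1.01].

Isotope grouping is greedy: seeds in descending intensity (ties by
ascending m/z — this makes the partition invariant under row
permutation), each claiming unclaimed peaks along
`mz + k·1.0033548378/z` chains within the m/z and co-elution tolerances,
keeping the charge that explains the most members. Every peak ends in
exactly one group. Averagine-style spacing refinements are intentionally
out of scope. Adduct annotation then links co-eluting groups whose
implied neutral masses `(|z|·mz − delta)/multiplier` agree within
tolerance for a pair of distinct library adducts, via union-find.

## The targeted workflow and its shift model

Peak tables come from target lists (name, formula, adduct, expected rt,
tolerances, role). ppm tolerances convert at the target's theoretical
m/z. The failure mode the workflow addresses: two mass isomers share
m/z, so when a sample's retention drifts by more than the window
half-width, fixed windows integrate nothing — or, worse, the wrong
isomer. Widening windows cannot help once the drift exceeds the isomer
separation.

The correction estimates one global shift per sample (not an
rt-dependent warp — the drift being corrected is a run-level offset and
a single number keeps the method transparent): each *reference* target
is searched in a 3× widened window, its apex located, and the shift is
the median (configurable to mean) of apex-minus-expected deviations.
The median tolerates a failed or outlying reference. Apex localization
smooths the EIC (Savitzky–Golay, window 7) and refines the maximum by
three-point parabolic interpolation clamped to one scan — the standard
way to beat grid quantization; without it, scan-width quantization plus
noise caps achievable shift accuracy at the sampling interval. Which
analytes get shifted is a parameter (`shiftNames`; default all), since
shifting reference windows too is harmless and simpler.

Samples whose shift estimation fails are integrated uncorrected and
flagged, not dropped; unreadable files produce flagged row blocks. The
result is a long sample × target table.

## The simulator: what it does and does not emulate

`simulateRun` places one m/z channel per isotopologue (those above 0.1%
relative abundance) of each compound, with Gaussian or EMG shapes of
known closed-form area, on a regular scan grid, plus a constant
baseline, multiplicative and additive Gaussian noise floored at zero,
and an optional run-wide rt shift. Identical seeds give bit-identical
runs (and mzML bytes). Channels that collide in m/z at the same apex rt
are rejected as ambiguous ground truth; collisions at different rt
(co-eluting isomers — the interesting case) merge within spectra, as
they would in a real instrument.

The simulator emulates exactly the features the methods consume —
isotopologue envelopes, parametric peak shapes, run-level drift,
amplitude noise — and none of the physics it does not: no column model,
no rt-dependent warping, no detector saturation, no chemical noise or
coalescing background. Passing tests therefore demonstrate algorithmic
correctness against known truth, not robustness to every artifact of
real chromatography.

Default study conditions used by the suite and the acceptance script:
scan interval 0.5 s; peak σ = 2 s; reference amino acids (Gly, Ala, Val,
areas 2–3·10⁵) at 100/170/240 s; a leucine/isoleucine-like analyte pair
(both C6H13NO2) at 300 and 320 s with ±6 s windows; simulated shifts on
a ±10 s grid; additive noise up to σ = 1500 (weakest-reference SNR
≈ 26) for shift-recovery runs. The isomer separation (20 s) was chosen
so each ±6 s window sees only its own peak even under a 9 s drift: with
isomers closer than the drift, a shifted partner falls into the other's
uncorrected window and the "uncorrected windows fail" comparison would
be confounded by misassigned (rather than lost) area. The qualitative
point survives: windows widened to cover ±(6+10) s would abut the
neighbouring isomer's window, so widening is still not a remedy.
Problem sizes throughout (hundreds of table sequences, tens of mzML
round trips, 100-run shift grids) were chosen as the smallest that
exercise each contract convincingly.

## Known limitations

* No untargeted feature finding; peak tables come from target lists or
  external tools.
* No vendor raw formats or mzXML; no ion mobility; no centroiding.
* A single global rt shift per sample; anchor-based warping exists in
  the alignment module but the targeted workflow deliberately does not
  use it.
* The table engine's join and sort materialize their inputs; only
  filter, computed columns and aggregation are fully streaming.
* Isotope grouping assumes the monoisotopic member is the most intense
  in its chain (true for small molecules; not for large peptides).
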