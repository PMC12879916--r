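---
title: "Species-unspecific isotope dilution for serum selenoprotein speciation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-unspecific isotope dilution for serum selenoprotein speciation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selenoquant)
```

## The measurement model

Serum selenoproteins are separated by a two-dimensional
size-exclusion/affinity method with column switching; the effluent
reaches an ICP-QQQ mass spectrometer monitoring five Se isotopes (74,
76, 77, 78, 80) at 0.3 s dwell each over a 50 min run. A solution of
enriched ⁷⁴Se merges with the effluent at constant flow just before
the nebulizer. Because every Se species contributes the same natural
isotope pattern, the measured ⁷⁸Se/⁷⁴Se ratio at any instant encodes
how much sample Se is diluting the spike — regardless of which species
is eluting. That is the species-unspecific property: one spike
quantifies all species without species-specific standards, and the
ratio is immune to drift and matrix effects that scale both channels
together.

`mass_flow()` implements the on-line IDA equation (documented with its
algebra on the help page): the measured ratio trace is mapped through

$$\mathrm{MF}(t) = \mathrm{MF}_{sp}\,
  \frac{Aw_{nat}}{Aw_{sp}}\,
  \frac{a_{sp,74}}{a_{nat,78}}\,
  \frac{R(t) - R_{sp}}{1 - R(t)\,R_{nat}}$$

into ng of natural-composition Se per minute. Two identities pin the
equation down and are enforced as tests: the mass flow is exactly zero
when the measured ratio equals the spike's own ⁷⁸/⁷⁴ ratio, and it
diverges as the measured ratio approaches the natural composition
(spike fully diluted). Points within `denom_tol = 1e-9` of that pole
are masked and counted, never interpolated or zeroed, so a
quantification that ran out of spike is visible in the output rather
than silently wrong.

Integrating the mass-flow trace over a retention window gives the
absolute Se mass of the species in that window; dividing by the sample
mass introduced (0.1000 g) gives ng Se/mL. Serum density is taken as
1.000 g/mL, so 100 µL injected ≡ 0.1000 g and ng/g ≡ ng/mL; the
reported tables use the per-mL convention.

## Parameters that matter

* **Retention windows** (min): GPx 2–4, selenometabolites 4–8,
  SELENOP 15–23, SELENOW-containing fraction 23–28, SeAlb 28–35,
  matching the elution order of the optimized separation (≈3, 5, 20,
  25 and 31 min). Windows are fixed-time rather than valley-detected:
  named peaks at known retention times integrate deterministically,
  and the optimized method resolves the former SELENOP/unknown
  coelution, so no deconvolution is attempted.
* **Spike configuration**: the spike isotopic composition defaults to
  99.9% ⁷⁴Se / 0.1% ⁷⁸Se; concentration and flow default to
  100 ng/mL × 0.1 mL/min = 10 ng Se/min. No published values exist
  for spike concentration, flow or detector sensitivity, so all three
  are free parameters of the simulator; the defaults put the constant
  ⁷⁴Se baseline within an order of magnitude of the tallest ⁷⁸Se peak
  counts, which is where an operator would set an on-line IDA spike.
* **Natural Se constants**: IUPAC/CIAAW abundances (0.89% ⁷⁴Se, 9.37%
  ⁷⁶Se, 7.63% ⁷⁷Se, 23.77% ⁷⁸Se, 49.61% ⁸⁰Se, 8.73% ⁸²Se) and
  standard atomic weight 78.971 g/mol. The spike atomic weight is
  always recomputed from its abundance vector and the bundled isotope
  masses; a user-supplied value that disagrees is rejected. Note that
  the abundance-weighted isotope masses of natural Se give 78.959 —
  the bundled 78.971 is the standard atomic weight, and the ~0.015%
  difference is far below every tolerance in the pipeline.
* **Ratio smoothing** (`smoothing_points`): centred moving average on
  both channels before the ratio; default 1 (off), since nothing is
  published about smoothing in this workflow and integrated masses on
  clean data change by <0.2% for windows of 1–5 points.
* **Mass bias** (`mass_bias_per_amu`): linear model, channel j scaled
  by `1 + f·(m_j − 78)`; `mass_bias_correct()` divides the ratio by
  `1 + 4f`. Default 0 — the ratio method needs no correction when
  simulator and quantifier agree, and the reference workflow reports
  none. The forward/backward pair leaves a second-order residual
  `1 − 16f²` (0.04% at f = 0.005), well inside the 0.5% round-trip
  tolerance.
* **Peptide matching**: trypsin rule (cleave after K/R, not before P),
  monoisotopic masses, fixed carbamidomethyl-C (+57.02146 Da),
  variable Sec→dehydroalanine (−81.93217 Da, the loss of H₂Se that
  explains why Sec peptides appear without their selenium), 20 ppm
  tolerance, greedy one-to-one matching by ascending ppm error with
  ties broken by fewer missed cleavages then earlier start. "Match
  percentage" is interpreted as residue-level sequence coverage — the
  union of matched peptide intervals over the protein length — which
  is the only reading consistent with a reported 88.24% on an
  85-residue protein (75/85). Confirmation tiers: <60% not confirmed,
  60–85% partially confirmed, ≥85% confirmed. The 85% default is a
  package choice: the reference tiering leaves 75–88% unaddressed, and
  85% keeps the confirmed example confirmed while refusing the
  partially-confirmed band; it is configurable.

## What the simulator emulates — and what it does not

`simulate_chromatogram()` is a forward model of the instrument:
Gaussian species peaks (each integrating to its injected ng of Se) sum
into a natural-Se mass flow, the constant spike adds its own isotope
pattern, each channel is scaled by sensitivity and optional mass bias,
and Poisson counting noise is drawn per reading. The five channels
share one time grid of one reading per 1.5 s cycle (5 isotopes ×
0.3 s); the sub-cycle stagger of a sequencing quadrupole is ignored as
negligible against minute-wide peaks. An exponentially-modified
Gaussian peak shape is available (`peak_shape = "emg"`) for tailing
studies but is not the default, no peak model being published.

Default peak sigma is 0.12 min. This is deliberately at the narrow end
of plausible for the separation: it places every default window edge
at least eight sigma from its peak apex, so the fixed windows capture
each peak's mass to within double precision and window truncation
cannot bias the recovered concentrations. That matters because one
reference statistic (the GPx cohort mean, exactly 3.55 before
rounding) sits on a rounding boundary where even a 10⁻⁴ relative loss
would flip the reported value. With wider peaks the method still
works; the round-trip tolerance simply inherits the truncated tail
mass.

The simulator does **not** model spectral interferences (argon dimers
and hydrides are removed instrumentally by the O₂/H₂ reaction cell),
detector dead time, cross-calibration between channels, retention-time
drift, column carryover, or any baseline from natural Se in reagents
(its blank baseline is exactly the spike pattern). Passing round-trip
tests therefore demonstrates that the inverse pipeline is faithful to
the forward model and unbiased under counting statistics — not that
real chromatograms are free of those effects. Validation against a
certified reference material, supported by `validation_stats()`
(recovery, 3σ/10σ blank-based LOD/LOQ), remains the empirical check on
real data.

The simulated cohort uses the bundled 13-sample concentration table as
ground truth (ng/mL × 0.1 mL injected = ng on column), so the
end-to-end demonstration reproduces that table's aggregate rows by
construction *plus* whatever error the pipeline introduces — which is
the point of the exercise: the aggregate reproduction only succeeds if
simulation, IDA inversion, baseline handling, integration and
statistics are all consistent.

## Numerical choices

* **Integration**: composite trapezoid on the reading grid (~0.025 min
  spacing, ≥12 points per sigma); against a Gaussian the rule is
  spectrally accurate, and higher-order schemes change results by far
  less than counting noise. Contiguous windows share boundary points,
  which keeps window integrals exactly additive over unions.
* **Baseline**: median mass flow over a 40–48 min blank window
  (post-SeAlb, pre-re-equilibration), robust to stray spikes; at least
  5 valid points are required. On noise-free simulations the baseline
  is zero to 10⁻⁹.
* **Negative areas** are clipped to zero only at the reporting stage,
  with the raw value retained and a `clipped` flag, so diagnostics
  never lose information. Windows with more than 20% masked points are
  flagged `unreliable` rather than dropped.
* **Statistics**: SD uses the n−1 denominator and SEM = SD/√n — the
  only convention that reproduces the bundled table's own statistic
  rows. Report rounding is half-away-from-zero (3.55 → 3.6); banker's
  rounding disagrees with the reference table and is not used. Percent
  composition is computed from full-precision column means and rounded
  once, at the end, to integers.
* **Degenerate inputs**: all-masked ratio traces, too-short runs,
  overlapping windows, abundance vectors that do not sum to one, and
  non-stoichiometric protein conversions each fail loudly with the
  offending item named; nothing is silently coerced.

## Known limitations and open points

* The GPx percentage is reported as computed (3% of total Se from the
  bundled table) although the reference figure prints 2%; the two are
  internally inconsistent and the package sides with its own table.
* The molar masses behind the protein conversions (49,985 g/mol for
  SELENOP, 27,362 g/mol for GPx) are back-derived fixtures consistent
  with the bundled cohort means, not certified constants; the
  conversion is a regression check, not an independent validation.
* Coverage-based confirmation has no decoy/FDR control; with a 20 ppm
  tolerance and small mass lists the false-match risk is low, but the
  tier is a screening call, not statistical identification. Se
  isotope-pattern confirmation in ESI spectra is out of scope — in
  practice the Sec residue is lost to dehydroalanine.
* Problem sizes used throughout the tests and the acceptance script:
  2,000-point chromatograms (50 min at 1.5 s cycles), the 13-sample
  cohort, and 50 Poisson seeds on the cohort-average injection; these
  sizes make every stochastic check reproducible in seconds while
  keeping counting statistics realistic (10⁴–10⁵ counts per reading).

## A compact end-to-end run

```{r demo, eval = FALSE}
out <- run_speciation_demo(tempfile(), seed = 0, noise = "none")
out$aggregate          # reproduces the bundled cohort statistics
out$percent            # SELENOP 57%, SELENOW fraction 33%, ...

sim <- simulate_chromatogram(simulation_spec(
  default_serum_species(c(SELENOP = 5.92)), noise = "poisson", seed = 1))
quantify_chromatogram(sim$chromatogram)
```
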