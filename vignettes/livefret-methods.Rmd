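---
title: "Models and methods behind livefret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind livefret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(livefret)
```

This vignette explains the models the package implements, the parameters
that matter, the numerical choices made where the underlying experimental
procedure is open to interpretation, and what the synthetic-data tests do
and do not demonstrate about real microscope data.

## The measurement

A labeled 20-mer antisense RNA probe hybridizes to its target mRNA; a
labeled dsRNA-binding protein (the dsRNA-binding domain of protein kinase
R, residues 1–169) binds the resulting duplex.  Binding requires roughly
18–20 bp of dsRNA, which is exactly the duplex a 20-mer probe forms, and is
sequence-independent, so one protein reagent serves every probe.  Donor
(protein, AF488, quantum yield 0.92) and acceptor (probe, AF546/AF594/AF647)
come into FRET range only on target-bound probes, so sensitized emission
reports target abundance.

## Synthetic scenes: the ground-truth generator

Everything downstream is tested by recovery against `simulate_scene()`,
which the package treats as the definition of its study conditions:

* **Geometry** — `n_cells` non-overlapping ellipses (default semi-axes
  14 × 10 px on a 128² image) with concentric elliptical nuclei at 0.45 of
  the cell axes.  Cells are placed by rejection sampling with a jittered
  grid fallback; infeasible requests fail loudly.  Real cells are not
  ellipses; this simplification is adequate because every metric under
  test is mask-based, not shape-based.
* **Expression** — per-cell abundance is log-normal (`meanlog = 4`,
  `sdlog = 0.5`), the canonical shape of expression distributions; a
  per-cell `nuclear_retention` fraction (default 0.25) splits each cell's
  transcripts between nucleus and cytoplasm, emulating the nuclear-retention
  phenotype that the n/c ratio is designed to detect.
* **Optics/detector** — signal is linear in abundance (`signal_scale`
  counts per abundance unit per pixel, default 3500, which puts typical
  pixels near 400 counts ≈ shot-noise SNR 20); noise is
  Poisson(gain·µ)/gain + Gaussian read noise (sd 2 counts), clipped at
  `2^bit_depth − 1` (12-bit default).  The acquisition bit depth and
  detector noise are declared defaults, not values inferred from any
  instrument.
* **FRET** — a single effective efficiency `E` (default 0.35): probe-bound
  donor emission is quenched by `(1 − E)` and a sensitized term
  `sens_gain · S · density · E` appears in the raw FRET channel together
  with donor bleed-through `a·I_DD` (a = 0.2) and direct acceptor
  excitation `b·I_AA` (b = 0.1).  No photophysical kinetics are modeled;
  all downstream math is intensity-linear, so an effective-efficiency
  model is sufficient.

`simulate_emsa()` generates Hill-model binding series with truncated
Gaussian noise, and `simulate_spots()` renders diffraction-limited
Gaussian spots at uniform in-cell positions for the counting tests.

What passing these tests shows: the algebra of every correction is right,
estimators are unbiased under the stated noise model, and the pipeline
preserves relative expression.  What it does not show: robustness to
autofluorescence, fixation artifacts, chromatic misregistration beyond
integer shifts, non-elliptical morphology, or 3-D effects — none of which
the generator emulates.

## Sensitized-emission cFRET

The corrected image is `cFRET = I_DA − a·I_DD − b·I_AA` per valid pixel.
Choices around that equation:

* **Background.**  The default for a full cube is a *joint* cell-free
  region: each channel's Otsu split (guarded against unimodal histograms by
  requiring the class means to differ by ≥ 4 sd of the lower class)
  proposes signal pixels; the union defines the specimen footprint; each
  channel's background is its mean over the rest.  A per-channel histogram
  estimate fails on channels with weak but real signal — the raw FRET
  channel of an acceptor-only control holds only ~b·signal counts, far too
  little for its own histogram to separate — and the histogram *mode*
  (rather than the background-region mean) sits ~0.5 counts below the mean
  for Poisson counts, enough to bias null controls.  Both alternatives
  remain available in `preprocess_channel()`.
* **Negatives.**  `preprocess_channel()` floors background-subtracted
  images at zero by default (sensible for display), but `cfret_pipeline()`
  disables the floor: rectifying zero-mean noise on a signal-free channel
  adds `sd/√(2π)` ≈ 2 counts on average, which propagates as a
  −a·2-count bias into cFRET null statistics.  Negative cFRET values are
  likewise retained for statistics and clipped only by `cfret_display()`.
* **Median filter.**  A radius-1 (3×3) median filter runs on the combined
  cFRET image, not on the raw channels: the median of skewed low-count
  Poisson data sits ~1/3 count below its mean, and filtering channels
  individually was measured to bias the bleed-through constants by −2 to
  −3%.  cFRET noise is approximately symmetric, so filtering after the
  subtraction denoises without shifting means.  The filter ignores invalid
  pixels rather than smoothing over them.
* **Saturation and exclusion.**  Pixels at or above `2^bit_depth − 1`
  (configurable) in any channel are excluded from the cFRET image and from
  every per-cell statistic, in both numerator and denominator.
* **Bleed-through constants.**  `a` is the least-squares slope through the
  origin of `I_DA` on `I_DD` over bright valid pixels of a donor-only
  control (`b` analogously from an acceptor-only control), with a
  heteroscedasticity-robust standard error; a median-of-ratios variant is
  available for robustness checks.  Controls are required per run — the
  package takes no position on whether constants are stable across
  sessions.
* **Registration.**  Integer-pixel translation via FFT cross-correlation
  of zero-mean images; constant images are rejected as degenerate.

## Spectral unmixing

A lambda stack holds, per laser (488/561/639 nm by default; 552/638 are
accepted wherever a laser list is taken), one image per 10-nm detection
window over 500–740 nm (24 windows).  Per valid pixel the abundances solve
`min ‖F·w − s‖²` with `w ≥ 0` (Lawson–Hanson active-set NNLS; pixels whose
unconstrained solution is already nonnegative are solved in one vectorized
pass).  Fingerprints are L1-normalized mean control spectra after
background subtraction; a condition-number guard (10⁶) rejects collinear
fingerprint sets and names the worst pair.

The FRET signal is its own unmixing component: acceptor-shaped emission
excited through the donor, i.e. the acceptor's window profile replicated
into each laser block in proportion to the donor's excitation efficiency.
The acceptor's *own* fingerprint is restricted to the non-donor blocks;
consequently the directly excited acceptor emission under the donor laser
lands in the FRET component — this is precisely the acceptor bleed-through
that linear unmixing cannot remove, and it is removed computationally as
`FRET − b·acceptor` with `b` measured on an acceptor-only control.

Two numerical points deserve emphasis:

* **Nonnegativity truncation.**  Where the true FRET component is within
  ~2 sd of zero, NNLS truncation biases its mean upward, and the bias
  depends on the intensity distribution.  `estimate_unmix_bleedthrough()`
  therefore uses a ratio-of-sums estimator (total FRET over total acceptor
  on signal pixels), which measures exactly the quantity the correction
  must cancel on comparable specimens; and the spectral study conditions
  use a larger photon budget (`signal_scale = 56000`) so each 10-nm window
  collects counts comparable to a wide-band channel, keeping the FRET
  component well above the floor.  This mirrors real spectral acquisition,
  where dwell times are chosen so that narrow windows still accumulate
  workable counts.
* **Stability diagnostic.**  Computational bleed-through removal is only
  valid if `b` does not drift with brightness.
  `assess_bleedthrough_stability()` regresses the apparent ratio on log10
  mean acceptor intensity across ≥3 graded controls and flags the series
  stable when the drift per intensity decade is below 5% of the mean ratio
  (configurable).

## Per-cell metrics

* FRET/cell is reported both as the sum over valid in-cell pixels
  (`fret_sum`) and as the mean (`fret_mean`); the per-area value divides
  by the valid-pixel count.  Which of sum or mean a given figure of merit
  should use is left to the caller; both are emitted.
* "Normalized FRET/cell" divides by the population maximum within the
  analysis batch.  This is a declared convention (the plotted quantity is
  dimensionless and the normalizer is not otherwise pinned down); any
  monotone normalizer would preserve the rank-based conclusions.
* The n/c ratio is the mean nuclear over mean cytoplasmic intensity on
  valid pixels; it is exactly 1 on uniform fields regardless of geometry.
* "MOC" is the single Manders overlap coefficient
  `Σ(R·G)/√(ΣR²·ΣG²)` ∈ [0, 1]; the split coefficients M1/M2 are
  auxiliary outputs of `manders_coefficients()`.
* Spot counting is a scale-normalized Laplacian-of-Gaussian detector:
  local maxima above `median + k·MAD` of the masked response
  (k = 8), minimum separation 2σ, plus a prominence floor at 10% of the
  strongest response that suppresses the sidelobes a Gaussian spot leaves
  in a nearly noise-free image, where the MAD threshold degenerates to
  zero.  It stands in for interactive commercial spot-counting tools;
  parameters are exposed.

## Binding models

`fit_hill()` fits `θ = ε·c^n/(c^n + Kd^n)` by bounded
Levenberg–Marquardt: start at `ε = max θ`, `n = 1`, `Kd` at the
half-saturation concentration; bounds `n ∈ [0.5, 6]`, `ε ∈ (0, 1.2]` (the
headroom above 1 absorbs normalization error), `Kd` within three decades
of the measured range.  Non-convergence or a parameter pinned at a bound
flags the fit, and flagged fits are refused by `kd_fold_change()`.  Both
free-`n` and fixed-`n` fits are available since affinity comparisons can
reasonably constrain the Hill coefficient.

Uncertainty is a seeded residual bootstrap (B = 200).  Residuals of a
p-parameter fit on n points are shrunk by ≈ √((n−p)/n) and are re-inflated
before resampling.  Intervals default to estimate ± t·(bootstrap SE):
with raw percentile intervals, measured coverage of the generative Kd at
n = 12 and σ = 0.02 was ~77% at nominal 95%, a known small-sample
pathology; the t-form restores near-nominal coverage.  Percentile
intervals remain available.

Fold changes in Kd are taken as ratios of fitted Kd values with intervals
from paired bootstrap replicates.  Recovery tests run triplicate simulated
gel series per preparation and compare the geometric-mean ratio — matching
how a real EMSA comparison would be replicated, and necessary because a
single series pair at σ = 0.02 leaves ~7% sd on the ratio.

Gel lane arithmetic defines fraction bound (and hybridized fraction) as
`shifted/(shifted + free)` within the RNA channel, and the FRET/shift
ratio as FRET-channel shifted-band intensity over RNA-channel shifted-band
intensity.  The degree of labeling is
`(A_dye/ε_dye) / ((A280 − cf·A_dye)/ε_protein)` with the protein
extinction coefficient defaulting to 12045 M⁻¹cm⁻¹ (the value computed for
the dsRNA-binding domain); dye coefficients and 280-nm correction factors
are vendor constants supplied by the caller.

## Probe tools

Probe records store sequences in the printed DNA (T) alphabet with an RNA
view on demand; label sites are the U/T count, since aminoallyl-modified
uridines carry the dyes.  One- and two-label probes are classed `optimal`;
three or more are `quench_risk` (over-labeling measurably quenches
fluorescence and the resulting FRET) — a warning class, not a failure.
Target coordinates follow the printed descending convention (the probe's
5′ end pairs with the higher mRNA coordinate, 1-based inclusive), which is
self-consistent with 20-mer spans such as 507−488+1 = 20.
`validate_probe()` finds the longest exact antisense match (≥ 8 bp),
reports mismatch positions over the full footprint, and applies the 18-bp
minimum-duplex rule; probes with no match are reported as no-target, the
behavior expected of the control probe.  T7 templates prepend the standard
promoter `TAATACGACTCACTATAG` (configurable — the polymerase is specified
upstream, the promoter sequence is the standard one); no 5′-GG initiation
constraint is enforced, since the shipped probe set itself contains one
probe that does not begin GG.  Secondary-structure accessibility screening
is out of scope; site openness scores from external tools can be applied
by the caller when choosing coordinates.

## Problem sizes

The test suite and the acceptance script run scenes of 96²–192² pixels
with 6–14 cells, 72-channel lambda stacks, 200 Monte-Carlo Hill fits and
B = 200 bootstraps; the full suite completes in well under a minute of
compute per module.  These sizes were chosen because every statistical
bound under test (2-SE nulls, 2% recovery, 10% Monte-Carlo medians) is
already sharply resolved at them; all generators scale to larger scenes
with the same code paths.

## Known limitations

* The generator's cells are 2-D ellipses with uniform compartment
  densities; no 3-D, no texture, no photobleaching, no chromatic
  aberration beyond integer shifts.
* FRET is an effective-efficiency linear term; donor lifetime effects and
  acceptor photophysics are out of scope.
* Spot detection is a LoG detector with fixed σ; clustered spots closer
  than 2σ merge.
* Blind (control-free) unmixing is deliberately not provided; fingerprints
  must come from single-label controls acquired under the run's settings.
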