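---
title: "Methods: diffusive-state analysis of tracked RNA-binding proteins and mRNA decay fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffusive-state analysis of tracked RNA-binding proteins and mRNA decay fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptq)
```

# Scope and model

`sptq` analyses live-cell single-molecule localization movies of
photoconvertible-protein fusions in bacteria, with the goal of resolving the
diffusive states of an RNA-binding protein (fast, RNA-free versus slow,
RNA-associated) and, in a companion module, of measuring mRNA half-lives
from rifampicin-chase intensity series. The chain is

localization → drift correction → linking → one-step displacements →
MSD fit + mixture CDF fit → spatial enrichment,

plus an independent decay-fitting branch. Every stage is exercised against
a ground-truthed simulator, because the statistical guarantees of the
estimators — not any particular dataset — are what the package tests.

## Localization

Candidate spots in a frame are pixels strictly above the frame mean plus
`k_sd` (default 3) standard deviations of the frame's pixel intensities,
that are also maximal within their centred 5×5 neighbourhood. We use
mean + 3·sd rather than a bare multiple of the standard deviation because a
pure 3·sd threshold is meaningless for cameras with a non-zero offset; the
baseline is configurable. Ties on a plateau are broken by keeping the
lexicographically smallest (row, col) pixel, so a flat-topped spot yields
one candidate, and candidates within 3 px of the border are dropped so the
fitting window fits.

Each candidate is fit by least squares (Levenberg–Marquardt, via
`minpack.lm`) with a symmetric pixel-integrated 2D Gaussian plus constant
offset on the surrounding 7×7 window. A fit is discarded (`fit_ok = FALSE`)
when the optimizer fails, the amplitude is non-positive, the fitted σ
leaves [0.5, 3.5] px, the centre leaves the window, or the fitted peak
height does not exceed 3× the shot noise of the fitted background. The
last criterion matters in practice: on sparse movies, Poisson background
fluctuations otherwise pass the geometric checks at a rate of a few tenths
of a spurious localization per frame, which poisons drift estimation and
enrichment. A fit indistinguishable from background has not converged on a
spot.

Least squares (not maximum likelihood) is used deliberately: it matches
the era and style of the reconstruction codes this pipeline mirrors, and
its precision is within a modest factor of the shot-noise limit, which the
test suite verifies as 1/√photons scaling.

## Drift correction

Lateral stage drift is estimated by Fourier cross-correlation: frames are
grouped into blocks (default 1000 frames), each block's localizations are
rendered as a 2× upsampled histogram, and each block is correlated against
the first with Gaussian regularization and parabolic subpixel peak
refinement. Per-frame drift interpolates linearly between block centres and
extrapolates linearly at the ends (constant extrapolation systematically
under-corrects steady drift in the first and last half-blocks). Correction
subtracts the interpolated shift.

Two caveats the simulator makes explicit. First, block correlation needs
shared structure between blocks: with fast-bleaching emitters and no
underlying labeled feature, distant blocks are independent point patterns
drawn from the cell envelope, and the correlation peak is broad and noisy.
Real movies correlate well because labeled structure persists; our drift
tests therefore use long-lived (fiducial-like) emitters. Second, emitters
whose lifetimes straddle block boundaries bias the apparent inter-block
shift low (their temporal centroids within adjacent blocks are closer than
one block); the bias disappears for persistent emitters and is small
relative to the 20% recovery tolerance we test.

## Linking and filtering

Localizations in consecutive frames are linked greedily by mutual nearest
neighbours, accepting the closest remaining pair while its distance is at
most `max_disp` (default 0.400 µm at the 5.76 ms frame interval, the
empirical cutoff that suppresses cross-molecule links; the package can
recompute a recommended cutoff from fixed-cell data as the 0.999 quantile
of apparent immobile-emitter displacements, which for pure localization
noise is a Rayleigh quantile). Unmatched localizations start new
trajectories. We do not link across activation frames: the
one-step-displacement statistics require a uniform frame interval, and
whether the original analysis bridged the doubled interval is unstated, so
trajectories terminate at the gap. No gap closing, merging or splitting is
attempted (multi-hypothesis tracking is out of scope). The exhaustive
optimal assignment is kept as a test oracle; on sparse data the greedy
mutual-NN solution coincides with it.

Length filters are strict: "longer than N steps" keeps trajectories with
more than N steps. The defaults follow the field convention of > 5 steps
for MSD/diffusion-coefficient estimation and > 3 steps for
one-step-displacement analyses.

## Diffusion estimation

The ensemble MSD at lag m·Δt₀ averages squared displacements over all
trajectories and start points. The diffusion coefficient is the
zero-intercept least-squares slope of MSD against Δt over the first 4 lags
(the source model is the straight line MSD = D×Δt with no intercept term;
the fit range is unstated there, so 4 lags is our default and it is
configurable). The slope itself is reported as `D_slope`; the conventional
2D coefficient is `D_conv = D_slope/4` and the identity `D_slope = 4·D_conv`
holds exactly by construction.

For a static mixture of n diffusive states, the one-step squared
displacement has the cumulative distribution

CDF(osd²) = 1 − Σᵢ Pᵢ exp(−osd² / (4 D′ᵢ t)),  Σᵢ Pᵢ = 1,

with t = Δt₀ = 5.76 ms (only one-step displacements enter). `fit_cdf_mixture`
fits this model to the empirical CDF evaluated on 200 quantile-spaced
points — quantile spacing avoids over-weighting the dense small-osd²
region — by Levenberg–Marquardt on log-D′ and softmax-weight coordinates,
with 5 multi-starts from quantile-based guesses (the original single-run
optimizer settings are unknown, so multi-start is cheap insurance).
Localization error inflates the apparent coefficients: with per-axis error
σ, D′ᵢ = D_conv,ᵢ + σ²/Δt₀; the package tests the identity at σ = 0 and the
mean-osd² form with noise. States are reported fast-first (descending D′),
and one-step coefficients are also given on the conventional scale
Dᵢ = 4·D′ᵢ, exactly.

State count selection fits n = 1, 2, 3 and keeps the smallest n whose
successor improves the residual sum of squares by less than a factor of 3.
The factor is larger than a naive 2 because overfitting pure one-state
data with a second state can nearly halve the residual on the quantile
grid, while a genuine second state improves it by orders of magnitude; 3
separates the regimes and is configurable. Fitted states closer than 10%
in D′ are flagged degenerate.

When a reference condition pins the fast state (e.g. transcription-inhibited
cells in which most of the protein is RNA-free), replicate fits define the
admissible interval mean(D₁) ± 2·sd(D₁) (sample standard deviation), and
all other conditions are fit with D′₁ box-bounded inside it (on the D′ = D/4
scale). The bound is enforced for every state slot so the fast state after
sorting is guaranteed inside the interval.

## Spatial enrichment

The cell is partitioned into membrane (a boundary band, default one pixel
≈ 0.173 µm — the band width is a package default, not a published value),
nucleoid (from a DNA-stain image, Otsu-thresholded within the cell, or an
ellipse in the synthetic geometry) and cytoplasm (the remainder). The three
regions are disjoint and tile the cell exactly, pixelwise. Enrichment of a
region is (fraction of in-cell localizations in the region) / (fraction of
cell area in the region); the area-weighted mean over the partition is 1
identically, which the tests assert. Localizations map to regions by
containing pixel; steps map by midpoint, which also yields per-region mean
one-step speeds (osd/Δt₀). Summaries can be made per cell and pooled —
whether the original figures pooled or averaged per cell is unstated, so
both are available.

## mRNA decay fitting

Chase intensities normalized to time zero are fit in log space by the
piecewise model: ln I(t) = ln I(0) for t ≤ α and ln I(0) − k(t − α)
afterwards, continuous at α. The half-life is τ = ln(2)/k — the log in the
published formula is the natural log, since the model is a natural
exponential in log space; τ·k = ln 2 holds exactly for every fit. For
fixed α the model is linear in (ln I(0), k), so α is profiled on a 201-point
grid over [0, alpha_max] (default: the second-to-last timepoint) and
polished by 1D optimization; k is clamped at 0 and a non-decaying series is
flagged with τ = ∞ rather than an error. Fitting on ln I weights late,
low-intensity points relatively more than a linear-scale fit would — this
follows the published procedure and is worth remembering when residuals
look heteroskedastic. ln I(0) is fitted by default; `fix_I0 = TRUE` pins it
at 0 after internal normalization (whether the original analysis fixed or
fitted it is unstated). The fit is invariant to rescaling all intensities.
Condition comparisons report per-condition mean ± sample s.d. of τ over
replicates, pairwise fold changes of means and two-sample (Welch) t-tests;
τ = ∞ replicates are excluded from summaries and listed.

# The synthetic-data generator

The simulator provides the ground truth the estimators are judged against.
It emulates: sparse photoactivation (one activation frame followed by 10
imaging frames; Poisson number of new emitters per pulse), a static
two-state diffusivity mixture (each emitter keeps its state — the mixture
CDF model itself assumes no interconversion on tracking timescales; a
switching option is deliberately absent), reflective-boundary Brownian
motion on the 2D spherocylinder projection (the minimal confinement model;
the original motion model is unstated), geometric photobleaching,
pixel-integrated Gaussian PSF rendering with Poisson shot noise and uniform
Poisson background, at 5.76 ms frame interval and 173 nm pixels. Default
geometry is a 3 × 1 µm cell with (1.0, 0.3) µm nucleoid semi-axes — a
plausible *E. coli* scale chosen once, not a published value.

It does not emulate: 3D diffusion or astigmatic detection, dark-state /
triplet photophysics, polarization, sCMOS pixel noise maps, or motion blur
by default (the 2.4 ms exposure within the 5.76 ms interval is available as
an option, but analyses here use instantaneous sampling, since how blur was
treated originally is unstated). Passing tests therefore demonstrate
estimator correctness under the stated forward model, not robustness to
every real-data artifact.

A shortcut generator, `simulate_osd2()`, draws one-step squared
displacements directly from the exponential mixture (mean 4·D′ᵢ·t per
state); it is the workhorse of the mixture-recovery tests because it
isolates the estimator from the imaging chain.

# Numerical choices and degenerate inputs

* Constant frames yield no candidates (not an error); flat 7×7 windows
  yield `fit_ok = FALSE`.
* Candidate ties are broken lexicographically; candidate lists are sorted
  (row, col).
* Empty drift blocks carry the previous shift with a warning; drift needs
  at least 2 blocks.
* A negative MSD slope is clamped to 0 and flagged.
* Mixture fits require ≥ 500 samples and error after all multi-starts fail.
* Zero-area regions have undefined (NA) enrichment; out-of-cell
  localizations are dropped and counted.
* Non-decaying series: k = 0, τ = ∞, flagged.
* Simulation refuses per-frame steps larger than a quarter cell width
  ("temporal resolution too coarse for confinement").
* All randomness flows from explicit integer seeds; seeded runs are
  bit-reproducible end to end, including the JSON pipeline report.

# Problem sizes used in the test suite

Mixture recovery uses 2×10⁴ steps per seed across 10 seeds; MSD recovery
uses ≈ 4×10⁵ displacement pairs; movie-level fidelity uses a ~26×42 px,
3300-frame sparse movie (≈ 200 visible emitter-frames) for localization and
a 48×100 px, 440-frame fixed field with persistent emitters for drift;
enrichment identities use 4×10⁵ uniform points; decay recovery uses 8
timepoints at 10% intensity CV. These sizes were chosen as the smallest
that make the stated tolerances statistically comfortable.

# A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  seed = 3,
  simulate = list(n_frames = 330, mean_activations_per_pulse = 0.5,
                  bleach_mean_frames = 10,
                  states = list(fraction = c(0.5, 0.5), D = c(0.05, 1.0))),
  localize = list(drift_block_size = NULL),
  decay = list(enabled = TRUE, noise_cv = 0.1, n_replicates = 3))
report <- run_pipeline(cfg, out_dir = "sptq_demo")
str(report$tracking)
```

# Known limitations

* The greedy mutual-NN linker degrades at densities where inter-emitter
  spacing approaches `max_disp` (it warns); the brute-force oracle shows
  agreement only in the sparse regime.
* Drift estimation requires persistent structure across blocks; pure
  fast-bleaching point patterns without underlying features make block
  correlation unreliable, and short-lived emitters bias inter-block shifts
  slightly low.
* The mixture CDF fit treats steps as i.i.d., ignoring within-trajectory
  correlation induced by localization noise sharing and confinement; at
  bacterial cell sizes, confinement also depresses apparent long-lag MSD,
  which is why the default fit uses early lags only.
* Enrichment at one-pixel band widths inherits rasterization granularity;
  sub-pixel membrane geometry is not modelled.
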