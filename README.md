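# sptq — single-particle tracking of bacterial RNA-binding proteins

`sptq` is an R package for quantifying the diffusive states of RNA-binding
proteins in live bacteria from single-molecule localization microscopy
(SMLM) movies, and for measuring mRNA half-lives from rifampicin-chase
intensity series. It is aimed at groups doing photoactivated
single-particle tracking of protein–mMaple3-style fusions in *E. coli* and
similar rods, where the central question is what fraction of a protein
(e.g. the RNA chaperone Hfq) is RNA-associated versus free, and where in
the cell it sits.

## What it computes

**Tracking branch.** Raw multi-frame stacks are reduced to localizations
(frame-adaptive threshold, 5×5 maxima, 7×7 pixel-integrated 2D Gaussian
least-squares fits), drift-corrected by block-wise FFT cross-correlation,
and linked into trajectories with a maximum one-step displacement cutoff
(default 400 nm per 5.76 ms frame). From the trajectories:

* the effective diffusion coefficient *D* as the zero-intercept slope of
  the ensemble mean squared displacement, MSD = *D*·Δt (the conventional
  2D coefficient is *D*/4);
* the diffusive-state decomposition, by fitting the cumulative
  distribution of one-step squared displacements (osd²) with the n-state
  mixture

  CDF(osd²) = 1 − Σᵢ Pᵢ exp(−osd² / (4 D′ᵢ t)),  ΣPᵢ = 1,

  with state count selection over n = 1…3, the one-step coefficients
  reported as Dᵢ = 4·D′ᵢ, and optional box-constraints on the fast state
  taken from reference-condition replicates (mean ± 2 s.d.);
* one-step speeds (osd/Δt₀) and their per-region means;
* subcellular enrichment over a nucleoid / membrane / cytoplasm partition:
  (fraction of localizations in region) / (fraction of cell area).

**Decay branch.** Band intensities I(t), normalized to t = 0, are fit in
log space by the piecewise delayed-exponential ln I(t) = ln I(0) for
t ≤ α, ln I(0) − k(t − α) after the delay; half-lives are τ = ln(2)/k, and
conditions are compared by replicate means ± s.d., fold changes and
t-tests.

**Synthetic data.** Because the estimators' guarantees are statistical, the
package ships a ground-truthed simulator: photoactivated emitters with a
static two-state diffusivity mixture, reflective Brownian motion in a 2D
spherocylindrical cell, pixel-integrated Gaussian PSF with Poisson noise,
interleaved activation frames (1:10), geometric bleaching, and piecewise
decay series with lognormal noise. Every analysis stage is tested against
it; see the methods vignette (`vignettes/sptq-methods.Rmd`).

## A worked example

Two-state mixture recovery from 2×10⁴ simulated one-step squared
displacements (60% slow at D′ = 0.05 µm²/s, 40% fast at D′ = 2.0 µm²/s):

```r
library(sptq)
o2  <- simulate_osd2(2e4, c(0.6, 0.4), c(0.05, 2.0), t = 0.00576, seed = 1)
fit <- fit_cdf_mixture(o2, n = 2, t = 0.00576)
fit
#> 2-state squared-displacement mixture fit (t = 5.76 ms, 20000 steps)
#>   state 1: P = 0.399, D' = 2.015 um^2/s (D = 4D' = 8.062)
#>   state 2: P = 0.601, D' = 0.04938 um^2/s (D = 4D' = 0.1975)
#>   RSS on 200-point CDF grid: 0.0002679
```

State 1 is the fast (RNA-free) state, state 2 the slow (RNA-associated)
state; the generating fractions (0.4/0.6) and coefficients are recovered
within a percent here. A decay fit on a simulated chase (true α = 2 min,
k = 0.231/min, 10% noise):

```r
s <- simulate_decay_series(1, alpha = 2, k = 0.231,
                           timepoints = c(0, 1, 2, 4, 6, 8, 12, 16),
                           noise_cv = 0.1, seed = 2)
fit_piecewise_decay(s, alpha_max = 8)
#> Piecewise delayed-exponential decay fit (log space)
#>   k     : 0.2306 /min
#>   alpha : 2 min (initial delay)
#>   tau   : 3.006 min (half-life, ln2/k)
#>   I(0)  : 0.9966, RSS(ln I) = 0.0518
```

The full chain (simulate → localize → track → diffusion fits → enrichment,
plus the decay branch) runs from a single seeded config via
`run_pipeline(pipeline_config(seed = 3, ...))`, writing a machine-readable
JSON report; a thin command-line wrapper with per-stage subcommands is in
`inst/scripts/sptq.R`.

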