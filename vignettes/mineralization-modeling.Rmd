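---
title: "Modeling enamel mineralization from an ontogenetic density series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling enamel mineralization from an ontogenetic density series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enamelwave)
```

## The problem

Enamel forms in two phases. *Secretion* lays down a partially mineralized
matrix (roughly a quarter of mature mineral content) as the secretory
front extends from the dentin horn along the enamel–dentin junction (EDJ)
and the tissue thickens by apposition. *Maturation* adds most of the
mineral later, as a lagged wave. Because a cross-sectional sample of teeth
from animals of different death ages captures each crown at a single
frozen moment, inferring the *dynamics* — when each location gained its
mineral — requires (i) placing all specimens on a common developmental
axis and (ii) inferring, per location, a plausible set of monotone density
histories consistent with the static snapshots. `enamelwave` implements
both steps, plus the simulation machinery needed to validate them.

## Growth model and age re-assignment

Crown extension is modeled as an integrated Gaussian,

$$e_l(t) = e_{l\max} - a + a\,\mathrm{erf}(s\,t - o\,s),$$

with amplitude $a$ (mm), slope $s$ (day⁻¹), offset $o$ (days) and mature
length $e_{l\max}$ (mm). A Gaussian rate profile is used because extension
rates peak shortly after initiation and decline thereafter. Inverting the
curve re-assigns a *size-modeled age*

$$t_m = \frac{\mathrm{erf}^{-1}\!\big((a + e_l - e_{l\max})/a\big) + o\,s}{s}$$

to each specimen from its measured extension length, which removes
individual growth-rate variation from the developmental axis
(`extension_age()`, `reassign_ages()`). Specimens at $e_{l\max}$ keep
their chronological age: size carries no information once growth stops.

**Fitting.** `fit_growth_curve()` minimizes squared residuals in
*position* space (position is the measured quantity at a known death age,
and the inverse map is singular near $e_{l\max}$), subject to the crown
having physical length at initiation: $0 \le e_l(t_{init}) \le 0.25$ mm,
with $t_{init} = -49$ d for first molars and $+84$ d for second molars.
The two-sided form matters: with only the upper bound, a ridge of
large-amplitude curves that pass far *below* zero at initiation fits
noisy data marginally better while being biologically meaningless, and
the offset parameter becomes unidentifiable. The optimizer mirrors the
usual global-then-local treatment of this non-convex problem: the
amplitude is profiled out in closed form (the model is linear in $a$
given $s, o$), a Latin-hypercube multistart (200 points by default)
covers a bounded $(\log_{10} s, o)$ box, and the best starts are refined
with Nelder–Mead under an exact penalty; a fit that cannot satisfy the
initiation constraint raises an error rather than returning a compromised
curve.

## Landmarks and standardization

`trace_edj()` extracts the dentin-facing boundary of the enamel mask
(principal-axis binning, dentin-side extreme per 1-px bin, short moving
average so pixel staircases do not inflate arc length; endpoints pinned).
Components smaller than ~5 px are treated as segmentation speckle — the
sub-pixel-thin secretory front fragments in any pixelated image — while
multiple large components raise an error. `flatten_enamel()` resamples
densities along local normals into (EDJ distance bin × relative depth
bin) coordinates; distance bins are one pixel of arc, depth is resampled
at 20 bin centers by default with mask-aware bilinear interpolation.

Landmarks follow the field's definitions: maturation onset and completion
are the farthest positions where the mid-depth (relative depth 0.5)
profile reaches 40% and 85% of the 2.62 g/cm³ reference maximum. The
profile is median-filtered over 3 bins so isolated noisy bins cannot
shift a crossing; the *farthest qualifying bin* rule (rather than
first-gap) is robust to interior dips. Worn cusps are handled by
`estimate_horn_offset()`: least-squares alignment of the worn specimen's
mid-depth profile against the unworn reference closest in apparent stage.

One subtlety deserves emphasis. The *landmark* depth axis spans the
**current** outer surface (that is how mid-depth is defined on a growing
tooth), but the *dynamic model* must live on the **final** crown shape —
otherwise outer-enamel pixels appear "present" from first secretion and
the appositional delay in mineral arrival is lost. `build_pixel_stack()`
therefore re-standardizes each specimen's depth profile against the
mature thickness at that position (the maximum observed across the
series) and marks not-yet-deposited depths as absent. This is what lets
the assembled model resolve the depth gradient in time averaging.

## Trajectory posterior

For a pixel observed at size-modeled ages $t$ with densities
$\rho^d_t$, the likelihood of a candidate history $\rho^m$ is

$$\log L = \sum_t -\frac{(\rho^m_t - \rho^d_t)^2}{2\sigma_t^2},$$

with a flat prior over the feasible set: trajectories non-decreasing by
at least $10^{-5}$ g/cm³ per interval, bounded by $1.05\times$ the
reference maximum. The measurement error is 5% of measurable HAp density;
we use the constant form $\sigma = 0.05 \times 2.62$ g/cm³ because a
proportional form would make near-zero early densities implausibly
precise (the proportional alternative is available via the `sigma`
argument). Ties in size-modeled ages are broken by a deterministic
$10^{-6}$ d × rank jitter so the time grid is strictly increasing.

`sample_pixel()` runs Metropolis–Hastings with (by default) 4 walkers and
150,000 total samples, retaining 100 trajectories pooled evenly across
walkers by uniform thinning of the post-burn-in half of each chain.
Walkers start from the isotonic regression (pool-adjacent-violators) of
the data, jittered per walker and projected into the feasible set by a
ceiling-aware backward cap and forward raise. The single-site Gaussian
proposal is symmetric; infeasible candidates are rejected outright, which
leaves the flat-prior posterior invariant. Step size adapts towards 25%
acceptance by Robbins–Monro *during burn-in only* and is frozen
afterwards, preserving detailed balance. The sampler is implemented in
C++ with its own RNG stream, so results are bit-identical for a given
seed regardless of R's RNG state.

**Verification.** The sampler accepts an optional discrete density grid;
on a grid, feasible trajectories are strictly increasing level sequences
and the posterior can be enumerated exhaustively
(`enumerate_trajectory_posterior()`, pure R, independent of the C++
path). The test suite requires the sampler's marginals to match the
enumeration within total-variation 0.05 on 3- and 4-time-point instances,
and also checks continuous-mode marginal means against a fine-grid
enumeration on plateau data.

**A calibration caveat.** The flat prior over the monotone cone is
informative in an unintuitive way: when many specimens record the same
plateau density, the marginal posteriors behave like order statistics,
spreading over roughly ±2σ regardless of how many observations agree.
This is the *exact* posterior (it matches the enumeration oracle), but it
means pointwise credible bands are anti-conservative against a flat
truth: in simulation, 90% bands cover the truth at roughly three quarters
of actively mineralizing time points and much less on plateaus. Users
should treat the retained trajectories as samples of plausible monotone
histories, not as calibrated pointwise confidence envelopes; the tests
assert the oracle-verified behavior rather than nominal coverage.

## Assembly and derived products

`assemble_model()` writes the standard four-dataset HDF5 schema —
`age_mask` (specimens × pixels), `ages`, `locations` (pixels × 2),
`pct_min_samples` (samples × pixels × specimen-ages, percent of the
reference maximum) — with a −1 sentinel and `age_mask` 0 for absent
pixel-ages, plus file attributes for the reference density and seed.
`interpolate_daily()` linearly interpolates each retained sample onto a
daily grid (280 days by default; at the published scale of 12,000 pixels
× 280 days × 100 samples this is 336 million estimates — the package
verifies that count from shape metadata without materializing it).
Linear interpolation preserves monotonicity. `rate_field()` takes first
differences of the posterior mean (or median) trajectory;
`time_averaging_map()` reports, per pixel, the days between first
mineral deposition and attainment of 85% — the window over which
chemical inputs are blended — with depth-band summaries; and
`export_animation_frames()` writes rate frames blurred with σ = 1 px
spatially and σ = 8 d temporally (an edge-renormalized separable
Gaussian, so interior mass is conserved).

## The synthetic generator

`wave_model_params()` encodes the study conditions the package is
validated under:

| parameter | default | why |
|---|---|---|
| extension (a, s, o, $e_{l\max}$) | 25 mm, 0.006 d⁻¹, 33.5 d, 38 mm | a first molar initiating ≈ −49 d and approaching 38 mm |
| `secretion_density_frac` | 0.25 | secreted enamel carries ~20–30% of mature mineral |
| `maturation_lag_cuspal` | 40 d | pause between secretion and maturation at the EDJ |
| `lag_depth_gradient` | 25 d per unit depth | the pause shrinks towards the surface |
| `maturation_duration` | 50 d | onset → completion (85% landmark) at a location |
| `max_density` | 2.62 g/cm³ | reference maximum HAp density |
| `apposition_rate` | 0.02 mm/d | ~30 d to full 0.6 mm thickness |
| `noise_frac` | 0.05 | 5% multiplicative grey noise, truncated at ±4σ |

Death ages follow a front-loaded grid (`synthetic_series_ages()`,
$540\,u^{1.7}$, median ≈ 165 d) because natural mortality in such series
concentrates in the first months of life. The maturation ramp is a scaled
logistic (differentiable, two-parameter), anchored so that *completion*
means the 85% landmark: onset → 85% takes exactly `maturation_duration`
days, with the residual mineral accruing in a slow tail. The generator's
rendered sections use a synthetic calibration line spanning 0–2.62 g/cm³
across the 16-bit range; the empirical batch lines (intercepts 1.54/1.49
g/cm³) cannot represent freshly secreted enamel and would clip the early
maturation signal (real out-of-range densities are clipped with a
warning, as the calibration module does for any line).

What the generator does *not* emulate: incremental features (Retzius
lines, cross-striations), mineral phase (ACP vs HAp), 3-D loph torsion
and oblique sectioning, spatially correlated scanner noise, and
between-individual biological variation in maturation geometry. Passing
tests therefore demonstrate the pipeline's correctness under a smooth
two-wave truth with independent pixel noise — not robustness to every
artifact of real scans.

## Numerical choices and study sizes

- Landmark-noise level for the fitter's recovery study: rendering
  sections at 5% density noise and re-measuring landmarks gives an
  empirical positional scatter of ≈ 0.1 mm, which is the noise the
  Monte-Carlo study injects. Naively multiplying positions by 5% noise
  instead (±1.9 mm at the cervix) makes the offset parameter
  unidentifiable to 10% for any estimator — the least-squares fit then
  beats the truth's own residual sum of squares.
- Tests and the acceptance script run the pipeline at reduced size:
  every 6th EDJ distance bin (~310 pixels), 10 depth bins, 10,000–40,000
  MCMC samples per pixel. These sizes were chosen so a full run remains a
  few seconds while every structural property (constraint rates, wave
  geometry, band ordering) is already stable; the sampler defaults
  remain the method's 150,000 × 4 walkers.
- Completion times derived from sparse series carry an interpolation
  bias: the linear chord between bracketing specimen ages lies below the
  concave upper part of the density ramp, so threshold crossings are
  systematically late. With 12 specimens over 0–530 d and a 50-d ramp the
  noise-free floor of this bias is ≈ 13 d RMS; with 45 specimens it drops
  to ≈ 1.5 d. Per-pixel completion times from very small series should be
  read with that floor in mind.
- Degenerate inputs: all-background sections calibrate to an empty mask;
  landmark positions are 0 when no bin qualifies; pixels observed in
  fewer than two specimens are flagged unusable and recorded as absent in
  `age_mask`; `maturation_duration = 0` produces an exact step.

## Known limitations

- Credible bands from the flat monotone prior are anti-conservative on
  density plateaus (see above).
- The EDJ tracer assumes a single connected enamel band with dentin on a
  consistent side (`edj_side`); heavily fragmented masks need manual
  cleaning.
- Wear offsets are estimated by profile alignment against a reference at
  a different developmental stage; the residual mismatch between their
  profiles is absorbed into the offset.
- Second-molar series are supported through `initiation_day = 84`, but no
  cross-tooth model conversion is attempted.
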