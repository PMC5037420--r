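---
title: "Cell-nucleus correlation analysis: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-nucleus correlation analysis: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnmotility)
```

## The model

Mesenchymal-like migration alternates between two subcellular activities:
leading-edge protrusion, during which the cell centroid advances while the
nucleus stays put, and trailing-edge detachment, during which actomyosin
contraction releases rear adhesions and the nucleus translocates coherently
with the cell body. Because the nucleus is mechanically coupled to the
cytoskeleton, the *relative* motion of the two centroids reads out which
activity dominates a given moment.

For each fixed sampling interval $\tau$ we form the cell centroid
displacement vector and its magnitude (CCD, $\mu$m), and project the
concurrent nucleus centroid displacement onto the CCD direction to get the
signed scalar NCD$_{/\!/}$. The pair (NCD$_{/\!/}$, CCD) is one
*CN-correlation point*; its polar angle

$$\theta = \operatorname{atan2}(\mathrm{CCD},\ \mathrm{NCD}_{/\!/}) \in (0^\circ, 180^\circ]$$

classifies the interval:

| Region | $\theta$ | interpretation | color |
|---|---|---|---|
| I | $(0, 45]$ | detachment (nucleus outruns the cell centroid) | red |
| II | $(45, 75]$ | mixed detachment + protrusion | yellow |
| III | $(75, 105]$ | protrusion/retraction (nucleus static) | blue |
| IV | $(105, 180]$ | large-angle side protrusion (nucleus inertia opposes the new heading) | green |
| V | — | stationary mode, assigned only by the noise filter | black |

The taxonomy does not presume event durations: a locomotion event of any
length decomposes into fixed-$\tau$ sub-events that inherit its signature,
which is what makes a fixed-interval analysis valid.

Two deliberate conventions deserve emphasis. First, the angular axis:
NCD$_{/\!/}$ is the abscissa and CCD the ordinate, so pure protrusion
(NCD$_{/\!/}\approx 0$) sits at $90^\circ$ and detachment
(NCD$_{/\!/} >$ CCD $> 0$) below $45^\circ$ — the only orientation
consistent with the region semantics. Second, boundary handling: the
brackets are half-open with a closed upper bound, so $\theta = 45^\circ$ is
Region I, $75^\circ$ Region II, $105^\circ$ Region III. With real
fixed-precision data exact boundary angles are measure-zero; the choice
matters only for reproducibility of synthetic edge cases.

An interval whose CCD is exactly zero (within $10^{-12}\,\mu$m) has no
direction to project onto; it is labeled `UNDEFINED`, drawn as a gap in
barcodes, and excluded from occurrence denominators. Real centroid data
never hit this case; simulated `stationary` events do.

## The migration potential index

With $o_i$ the occurrence fraction of region $i$ over defined intervals and
$\langle \mathrm{NCD}_{/\!/} \rangle_i$ the mean projection within it,

$$\mathrm{CMPI} = \sum_{i \in \{\mathrm{I},\mathrm{II}\}} o_i\,
  \langle \mathrm{NCD}_{/\!/} \rangle_i
  \;=\; \frac{1}{N_{\mathrm{def}}} \sum_{0^\circ < \theta \le 75^\circ}
  \mathrm{NCD}_{/\!/},$$

the effective forward nuclear translocation per interval ($\mu$m per
interval at the stated $\tau$). Regions III–V contribute nothing: nuclear
motion perpendicular to, or against, the cell's heading does not advance
migration. The algebraic identity above is enforced by the
`CMPIResult` validity method and tested to $10^{-12}$.

The index is computed per cell and averaged over cells
($\langle\mathrm{CMPI}\rangle$ with SEM); the per-cell route is what makes
sample-size convergence curves meaningful. A pooled-interval variant of
occurrence rates is available through `poolRegionOccurrence()`, since
population occurrence percentages can be read either way.

Units: CMPI is reported per interval, not per minute, because comparisons
across cell types are made at a fixed $\tau$; divide by $\tau$ (or use the
reported `tau` slot) when comparing across sampling rates. CMPI is
invariant under rotation and translation of both tracks and scales
linearly with the spatial unit — properties the test suite checks
explicitly.

## The stationary-mode filter

A fixed (chemically immobilized) cell imaged through the same pipeline
yields CN points that are pure positioning noise. `fitNoiseDensity()` bins
those points into a 2-D histogram over (NCD$_{/\!/}$, CCD) — default
$32\times 32$ bins over the data hull, piecewise-constant, with a
documented lower-bin tie-break on edges. A histogram rather than a kernel
density: it is deterministic, cheap, and no bandwidth is specified by the
procedure the filter implements.

The normalization is an interpretive choice. The filter needs a value
$p \in [0,1]$ per bin for an acceptance test (draw $u \sim U[0,1]$; keep
the live-cell label if $u > p$, else reassign to Region V), but a
probability *density* can exceed 1. We max-normalize (modal bin
$\mapsto 1$): a live-cell displacement indistinguishable from the most
probable pure-noise outcome is treated as almost surely noise. A
relative-frequency alternative (`normalization = "frequency"`) is exposed;
it reassigns far fewer points and depends on bin count.

The filter consumes exactly one uniform draw per interval in time order
from a single seeded stream, so output is bit-reproducible; original
labels and per-point $p$ travel along in `region_original` and `noise_p`.
Reassignment is calibrated: the expected fraction sent to Region V equals
the mean of $p$ over the series (checked within three Poisson-binomial
standard errors at $n = 10^4$). Only runs of Region V *strictly longer*
than five intervals (`prolongedStationarySegments()`) mark a genuinely
stationary cell; 1–3-interval stationary flickers are part of normal
locomotion. The four-region scheme remains the default for CMPI because
the filtered points concentrate where they contribute little to the index
anyway.

## The persistent-random-walk benchmark

The PRW model summarizes a track by the Fürth MSD
$\langle r^2\rangle(t) = 2S^2P\,[\,t - P(1-e^{-t/P})\,]$ with
root-mean-square speed $S$ and persistence time $P$, and the motility
diffusion coefficient $\mu = S^2P/n$ with $n = 2$ dimensions.
`fitPRW()` performs Levenberg–Marquardt least squares (via `minpack.lm`)
on an MSD curve, initialized at $S_0 = \sqrt{\mathrm{msd}(\tau)}/\tau$
(the short-lag ballistic speed) and $P_0 = 5\tau$; fits are per cell type,
on the pair-count-weighted average of the per-track curves
(`averageMSD()`), with a per-track route available by fitting curves
individually.

Numerical notes, all of which the tests exercise:

* **Lag range.** MSD values are computed to 25% of the track length
  (`maxLagFraction = 0.25`); beyond that the overlapping estimator is
  dominated by correlated noise. Even within the cap, long-lag noise makes
  $P$ markedly harder to estimate than $\mu$: on 15 ten-hour tracks at
  $S=1\,\mu$m/min, $P=10$ min, fitted $\mu$ is reliable to roughly
  $\pm20\%$ while fitted $P$ can err by more, and with very few tracks
  $S$ and $P$ trade off along $S^2P \approx$ const while $\mu$ stays
  comparatively stable. Restricting the fit to a few persistence times
  (smaller `maxLagFraction`) tightens $P$ recovery when $P$ is roughly
  known.
* **Degenerate regimes.** A near-ballistic curve ($P$ beyond the fitted
  lag range) converges but is flagged in the fit message; optimizer
  failure or non-positive estimates return `converged = FALSE` with the
  diagnostic, never a silent `NaN`. `mu` always equals $S^2P/2$ by
  construction.
* **Weighting.** Unweighted least squares on the raw MSD is the default;
  `weights = "npairs"` is available but changes little because long-lag
  errors are correlated, not merely large.

`loglogSlope()` gives the standard motility readout (2 ballistic, 1
diffusive, $<1$ sub-diffusive); `instantaneousSpeed()` returns
$|\Delta x|/\tau$ and agrees with CCD$/\tau$ by the cross-module identity
test.

## What the simulators emulate — and what they do not

`simulateEvents()` realizes the event taxonomy literally: scripted
per-interval kinematics (protrusion, retraction, detachment with nucleus/
cell step ratio $\rho = 1.5$ by default, mixed at ratio $0.5$, turns of
$135^\circ$ with nucleus inertia fraction $0.5$, stationary) plus
isotropic Gaussian positional jitter. The defaults put each noiseless
event unambiguously inside its designated region ($33.7^\circ$,
$63.4^\circ$, $90^\circ$, $109.5^\circ$), which is what makes
ground-truth recovery testable at the 99% level under 2% jitter.

`simulatePRW()` uses the *exact* discretization of the integrated
Ornstein–Uhlenbeck process: per coordinate, velocity relaxation time $P$,
stationary per-component variance $S^2/2$ (so
$\langle|v|^2\rangle = S^2$ in 2-D), and the position increment drawn
jointly with the end-of-step velocity from the exact Gaussian transition.
The Fürth formula is therefore an exact oracle at any step size, not an
Euler-approximation target. `simulateFixedCell()` adds i.i.d. per-frame
Gaussian jitter (default $\sigma = 0.17\,\mu$m, a typical intrinsic
microscope error) to a constant point, independently for cell and nucleus.

These generators reproduce the *kinematic* structure of the data class —
they do not model cell shape, segmentation error autocorrelation, stage
drift, frame drops, or heterogeneity of event kinematics within a cell.
Passing tests therefore demonstrate the correctness and calibration of the
analysis chain on data satisfying its stated assumptions, not performance
on any particular microscope's output.

## Noise robustness machinery

`injectDisplacementNoise()` adds an independent 2-D Gaussian (per-component
sd $\sigma$) to every cell and nucleus *displacement* vector — the default
mode because the robustness procedure perturbs displacement measurements
directly; position-level noise (`injectPositionNoise()`), also provided,
anti-correlates consecutive intervals instead. Per-component sd equal to
$\sigma$ (noise magnitude Rayleigh with mode $\sigma$) is the documented
reading of "Gaussian noise with standard deviation $\sigma$".
`noiseImplementedCMPI()` averages the population CMPI over many seeded
noise realizations; $\sigma = 0$ reproduces the noise-free value
bit-exactly. Under overwhelming noise the region occupancy tends to the
isotropic limit — $\theta$ distributed like the polar angle of a 3-D
isotropic Gaussian, density $\tfrac{1}{2}\sin\theta$ — a useful closed-form
sanity limit. `robustnessGrid()` subsamples base-rate trajectories to
coarser $\tau$ (exactly equivalent to slower acquisition), recomputes the
noise-implemented $\langle\mathrm{CMPI}\rangle$ per cell type and reports
the ordinary intercept-included $R^2$ against the types' PRW diffusion
coefficients.

## Problem sizes and determinism

Every stochastic routine takes an explicit integer seed and restores the
caller's RNG state, so pipelines are bit-reproducible end to end. The
validation suite uses sizes chosen to make its statistical assertions
sharp at interactive cost: $10^4$ random pairs for the classifier oracle,
$10^3$ series for the CMPI identity, $10^4$ OU tracks for the Fürth
comparison (5% band below the persistence time), 15 tracks of 600 steps
for parameter recovery, $10^4$-interval fixed-cell series for filter
calibration, 1000-repeat noise sweeps at $\sigma \in \{0.02, 1\}\,\mu$m,
and a 50-cell pool at between-cell CV 0.35 for convergence (the
closed-form crossing $\mathrm{CV}/\sqrt{s} < 0.1$ puts the flag at the
first sampled size above $s \approx 12$, i.e. 15 on a step-5 grid, with
~20 the visually typical value at slightly wider spreads).

## Known limitations

* 2-D trajectories only; the taxonomy itself would carry over to 3-D but
  none of the code does.
* The $\theta$ autocorrelation diagnostic is linear, not circular;
  angular series near the $0/180^\circ$ wrap would be better served by
  circular statistics, though regions I–IV keep $\theta$ well inside the
  interval in practice.
* The noise filter's max-normalization is an interpretation (see above);
  conclusions that depend on the absolute Region-V rate should be checked
  under both normalizations.
* Absolute CMPI values are tied to $\tau$ and to the imaging pipeline's
  centroid quality; the index is designed for *relative* comparisons
  across cell types measured identically.
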