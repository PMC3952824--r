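---
title: "Models and methods behind resectrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind resectrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resectrack)
```

# The assay and what the package computes

A site-specific endonuclease cuts one chromosomal locus; 5′→3′ resection
then converts the flanking DNA to single strands. Two ParB/*parS*
cassettes downstream of the cut — INT1 (distal end 1231 nt away) and INT2
(distal end 7612 nt away) — carry fluorescent foci that are extinguished
when the resection front reaches their distal ends, because ParB binds
only double-stranded DNA. Movies are acquired in bursts: 50 frames of
200 ms every 2 min (*yku70*) or 5 min (wild type), 65-nm pixels, starting
8 min after induction. The bursts provide sub-second lags for
mean-square-displacement (MSD) analysis and a minutes-scale clock for
focus-loss timing.

`resectrack` implements both halves: a generative model of such movies
with complete ground truth, and the analysis pipeline (detection,
tracking, intensity quantification, loss calling, MSD/diffusion,
kinetics) that recovers the injected biology. Everything the analysis
reports is therefore testable by parameter recovery.

# Generative model

## Event times

Each cell is cut with probability `pCut` (default 0.6). Cleavage times
follow a Gaussian truncated at 10 min (redraw scheme; only the shape near
the floor matters and none of the analyses depend on the tail
convention). Resection starts after a commitment lag, and the front moves
at `vSlow` nt/min up to the phase-switch position (1231 nt, INT1's distal
end) and at `vFast` nt/min beyond it when the fast phase is enabled:

$$t_{loss,1} = t_{onset} + d_1 / v_{slow}, \qquad
  t_{loss,2} = t_{onset} + s/v_{slow} + (d_2 - s)/v_{fast}.$$

Focus amplitude declines linearly while the front traverses a cassette
(ParB binds uniformly along it) and reaches zero exactly at the loss
time; wild type disables the fast phase, so INT2 persists indefinitely.

## Genotype presets

```{r presets}
scenarioPreset("wt")@vSlow
scenarioPreset("yku70")@vSlow
```

The published observables pin the presets only partially, and they are
not mutually consistent: the earliest cleavage (10 min), the earliest
wild-type INT1 loss (25 min) and a ~10-min commitment lag cannot all hold
if the wild-type front moves at the canonical 82 nt/min (10 + 10 +
1231/82 ≈ 35 min). The presets reproduce the *observables*: wild type
uses lag 10 min and `vSlow = 1231/5 ≈ 246` nt/min, so earliest losses
fall at ~25 min and the cohort window at ~25–32 min — and the
earliest-anchor analysis of such cohorts then *returns* 82 nt/min, which
is exactly how the canonical figure arises (it folds the commitment lag
into the apparent resection time). The *yku70* preset uses lag 0,
`vSlow = 300` nt/min and `vFast = 1900` nt/min, giving INT1 losses within
12–19 min and INT2 following ~3.4 min later. Cleavage-time parameters
(wild type 12 ± 2 min, *yku70* 11 ± 1.2 min, floor 10) are free
parameters chosen once to land the loss windows inside the published
ranges; the tighter mutant sd keeps 20-cell cohorts inside 12–19 min in
the large majority of seeds.

## Motion

Chromatin mobility is piecewise: free Brownian diffusion
(`D ≈ 0.019 µm²/s` uncut), a switch to confined motion 5.5 min after
cleavage, and a step back to free diffusion at a per-genotype recovery
time (interpreted as minutes after cleavage: 30 for wild type, 18 for
*yku70*, reflecting the ~12-min-later recovery in wild type). Confinement
is modelled as an Ornstein–Uhlenbeck (OU) process per axis with
short-time coefficient `D` and relaxation time `τ_c` (default 20 s):

$$x' = \mu + (x-\mu)e^{-\Delta t/\tau_c} +
  \sqrt{D\tau_c\left(1-e^{-2\Delta t/\tau_c}\right)}\,\xi .$$

This is the exact discrete update, so irregular timestamp grids are
integrated without discretization error; its MSD,
$4D\tau_c(1-e^{-\tau/\tau_c})$, is linear at short lags (slope $4D$) and
plateaus at $4D\tau_c$ — the two features the first-2-s slope analysis
uses. Sub-diffusion via fractional Brownian motion is deliberately out of
scope: an anomalous exponent is not identifiable from the first-2-s
slope and plateau alone.

Within a burst, positions follow the scheduled model exactly. Across the
minutes between bursts a freely diffusing locus would leave the field of
view (11 µm r.m.s. over an hour at 0.019 µm²/s), which real chromatin
cannot do inside a ~2-µm nucleus; each burst therefore restarts from the
cell's home position plus a small jitter (sd 0.15 µm), emulating
decorrelation within the nuclear territory. Consequently only
within-burst statistics carry the motion model, which is also all the
analysis uses.

## Imaging

The expected image is a uniform background bleaching as
$B_0 e^{-t/\tau_{bleach}}$ plus one pixel-integrated Gaussian PSF per
focus (sd 1.3 px ≈ 85 nm), so a focus's total flux equals its amplitude.
Observation adds Poisson shot noise and Gaussian read noise (sd 3
photons), applies the camera gain and clips to the 16-bit range. Defaults
(4000 photons per intact focus over background 40) give SNR well above
10. Because the background bleaches while foci do not, the normalized
focus/background intensity ratio of an intact focus *rises* during early
acquisition — a signature the quantification tests reproduce. All
randomness derives from one root seed through fixed integer splitting,
so cohorts are reproducible cell by cell.

# Analysis pipeline

## Detection, linking, track filtering

Per frame: boxcar background subtraction (width `2r+1`), Gaussian matched
filter (σ = r/2 — the kernel scale that makes the default radius 4 behave
like the classical particle-detector kernel), local maxima within `r`,
retention of maxima in the top `percentile` % of filtered pixel values
(default 0.1 %) with score above `cutoff` (default 0, i.e. no
discrimination; the score is the filtered peak intensity), then
intensity-weighted centroid refinement in a `(2r+1)²` window. Note the
percentile rule keeps ~n/1000 pixels, so very small fields can hold fewer
retained peaks than true foci; the detection accuracy tests use a
128×128 field for that reason.

Linking is greedy globally-nearest-neighbour per consecutive frame pair
(candidates within 10 px sorted by distance, ties by spot index), with no
gap closing — scored tracks must be strictly consecutive, and only tracks
*longer than* 15 frames are kept. Greedy linking can diverge from the
exhaustive minimal-total-distance assignment when two candidates compete
for crossing partners; the test suite contains the constructed
counterexample, and on well-separated foci (the regime of this assay:
one or two foci per nucleus) the two coincide.

## Intensity traces and loss calling

The intensity ratio sums a horizontal 9-px line through the tracked focus
and divides by an equal line displaced 15 px away (searching eight
compass offsets for a spot-free, in-bounds line), normalized to 100 % at
the first timepoint; after loss the line stays at the last tracked
position. Traces are collapsed to one point per burst (median; bursts
span seconds, kinetics run on minutes).

Loss is called two ways. The intensity method smooths the trace (window
3), estimates the background plateau as the smoothed minimum and the
pre-onset level as the median of the first five points, and calls loss
where the excess ratio stays below `thresholdFraction` (0.5) of the
pre-onset excess for 3 consecutive bursts — gated by a minimum
pre-onset-to-plateau contrast of 25 percentage points so that noise-only
traces (uncut cells) can never qualify. The detection-absence method
calls loss at the start of the first run of ≥ 3 trackless bursts. The
events tables use the detection-absence call as primary: extinction is
gradual (minutes), so a 50 % intensity threshold fires about half a
cassette-traversal early, while the first trackless burst pins the
extinction itself to within one burst interval. Both calls are reported.

## MSD and diffusion

Per track, the time-averaged MSD at lag $k\Delta t$ is
$\frac{1}{N-k}\sum_i |r_{i+k}-r_i|^2$; the ensemble curve is an
unweighted mean over tracks reaching that lag (each cell counts equally;
a pair-count-weighted variant is available). `estimateD` fits ordinary
least squares over lags ≤ 2 s *with an intercept*: localization noise
adds a lag-independent $4\sigma_{loc}^2$ which would otherwise inflate
the slope; `D = slope/4` for 2D tracking. Fitting a line to the OU curve
under-reads its short-time slope by a few percent (the curve saturates
within the window) — visible in the confined-D recovery, and well inside
the stated tolerances. `windowedD` applies this per burst (windows with
no surviving tracks are missing, not zero) and normalizes to the uncut
reference (0.019 µm²/s = 100 %).

## Kinetics

Loss-time distributions are summarized by sample moments (mean, sd with
n−1, range) — the published claim is only Gaussian shape, so no truncated
maximum-likelihood fit is attempted. Durations anchor at the fixed
earliest-cleavage constant (10 min), exactly as the headline calculation
prescribes, with a mean-based variant alongside; per-cell cleavage times
are unobservable in this assay. The fast-phase speed is reported per cell
over cells losing both foci, and cohort-level recovery tests use the
distance over the *mean* INT1→INT2 interval, where burst quantization
approximately cancels (the mean of per-cell ratios is biased when a
~3.4-min interval is quantized to 2-min bursts). The commitment delay is
the difference of mean INT1 loss times between the first two scenarios;
estimating it as an injected-lag recovery requires cohorts differing
only in lag — comparing the wt and yku70 presets as published also mixes
their different slow-phase speeds.

# Numerical choices and problem sizes

Positions are continuous micrometres, origin at the top-left corner;
pixel `(i, j)` spans `[j·px,(j+1)·px) × [i·px,(i+1)·px)` with centres at
`(j+0.5)·px`; pixels appear only at I/O boundaries. Frame indices are
0-based; all kinetic times are minutes on the induction axis, with every
frame of a burst mapped to the burst start (10-s bursts vs a minutes
clock). TIFF output is plain multi-page 16-bit little-endian, one file
per channel, metadata in JSON sidecars.

The tests and the acceptance script scale simulations to desk size as the
package's own choice of problem size: 48–64-px fields (128 px for
detection accuracy), 20-frame bursts for end-to-end runs (still above
the strict 15-frame scoring rule), cohorts of 4–22 cells, and 100–500
tracks for Monte-Carlo recovery. Movies extend far enough past the latest
expected loss for the 3-burst persistence rule to fire.

# What passing tests do and do not show

The generator emulates the features the analysis relies on — burst
acquisition, truncated-Gaussian cleavage, linear focus extinction, step
mobility switches, bleaching background, shot and read noise. It does not
emulate nuclear-envelope geometry, fractional Brownian sub-diffusion,
multi-nucleus fields, z-drift, or focus photobleaching (foci demonstrably
persist over >1500 exposures in this assay). Recovery of injected
parameters therefore validates the estimators and their wiring, not the
biology of real movies; conversely, quantities that are properties of the
biological experiment (the ~60 % cut fraction as measured, the 40 %
INT2-loss fraction, measured mobility curves) are inputs here, not
outputs. Survival-style treatment of never-lost (censored) cells is
limited to reporting the lost fraction.
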