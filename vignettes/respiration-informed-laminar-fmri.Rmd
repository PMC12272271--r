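---
title: "Respiration-informed removal of macrovascular bias in laminar fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiration-informed removal of macrovascular bias in laminar fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminaresp)
```

## The problem

Sub-millimetre fMRI at ultra-high field can resolve signal across cortical
depth, but the measured response is biased toward the cortical surface: large
pial vessels (veins for BOLD, and to a lesser degree arteries for blood-volume
weighted contrasts) respond strongly and sit at the CSF/GM boundary, so the
laminar profile of a task response peaks superficially even when the neural
input targets mid-depth.

Respiration offers an inexpensive handle on this bias. Breath-to-breath
variations in depth, rate and phase modulate arterial CO2 and intrathoracic
pressure, and the resulting signal fluctuations are concentrated at and around
macrovessels. `laminaresp` maps these respiration-related fluctuations
directly from the fMRI series — no belt or CO2 recording is required for the
map itself — and removes the most respiration-responsive voxels before
extracting depth profiles, sharpening laminar specificity.

## The processing chain

The pipeline operates on an interleaved acquisition that alternates
blood-nulled and control volumes (volume TR 6.082 s by default):

1.  **Contrasts** (`split_conditions()`, `compute_vaper()`,
    `compute_mt_anat()`). The control stream is a conventional BOLD series.
    The VAPER (blood volume/perfusion weighted) contrast subtracts the nulled
    from the control signal dynamically; in corrected mode the difference is
    divided by the control signal, removing the shared T2\* weighting and the
    residual BOLD component. An interleaved control/MT-prepared run yields the
    anatomical reference `(S_ctrl − S_mt)/S_mt`.
2.  **Censoring** (`censor_frames()`). Volumes are excluded when the Euclidean
    norm of the backward-difference motion derivatives exceeds 0.4 mm
    (rotations converted to arc length at a 50 mm head radius) or when at
    least 10% of in-mask voxels are outliers from the per-voxel polynomial
    trend.
3.  **Respiration-effect map** (`outlier_fraction()`,
    `select_variation_points()`, `respiration_effect_map()`). The per-volume
    outlier fraction (order-2 polynomial detrend, Gaussian-tail MAD threshold)
    flags the 15% of time points with the strongest transients as
    respiration-variation points; the map is the mean absolute deviation of
    those volumes from the mean image of the remaining, stable-respiration
    volumes.
4.  **Laminar geometry** (`equivolume_depth()`, `build_columns()`,
    `build_roi()`). Equi-volume cortical depth on volumetric segmentations, a
    seeded column parcellation of GM, and the analysis ROI (seed region
    dilated by 2 voxels, re-intersected with GM, restricted to activation at
    uncorrected p < 0.01).
5.  **Profiles** (`fit_block_glm()`, `exclusion_mask_topfrac()`,
    `extract_laminar_profile()`, `superficial_bias()`). Percent-signal-change
    GLMs, exclusion of the top 10% respiration-responsive voxels across the
    brain mask, and depth-binned profiles before/after exclusion with
    peak-depth and surface/mid-ratio summaries.
6.  **Vascular association** (`node_summaries()`, `pooled_correlation()`,
    `histogram2d()`). Node-wise vessel density against respiration-effect
    strength, normalized per brain and pooled across subjects.
7.  **Blurring** (`neighbor_correlation_kernel()`, `kernel_fwhm()`). The mean
    neighbor-correlation kernel of the series and its FWHM per axis, an index
    of effective spatial smoothness, evaluated before and after exclusion.

`run_pipeline()` chains all stages from one `run_config()` and writes every
artifact plus a JSON manifest; `inst/cli/laminaresp.R` is a thin command-line
front-end over it.

## Key modelling and numerical choices

**Dynamic pairing of the streams.** The control signal must be evaluated at
each nulled volume's time. The default pairs each nulled volume with the
nearest preceding control volume — the partner of the acquired pair. The
symmetric alternative (mean of the two adjacent control volumes) is exposed
(`pairing = "two_neighbor"`), but it mixes task and rest volumes at block
transitions: on a noiseless block-design phantom it attenuates the recovered
VAPER beta by about one third, so it is not the default.

**Sign and orientation conventions.** VAPER is reported so that a task-evoked
blood-volume increase is positive (stronger blood suppression lowers the
nulled signal, so control − nulled rises). Cortical depth is 0 at the CSF/GM
boundary and 1 at the GM/WM boundary, so profiles read CSF → mid-GM → WM from
left to right.

**Outlier statistic.** For each voxel the residual from an order-2 ordinary
polynomial fit is compared against `k · median(|residual|)` with
`k = qnorm(1 − q/2) · sqrt(pi/2)` and `q = 0.001` — the MAD rescaled to a
two-sided Gaussian tail. Voxels whose MAD is exactly zero flag any nonzero
residual. The per-volume statistic is the flagged fraction of mask voxels.
Selection of the top 15% happens after censoring, so volumes already censored
(at ≥ 10% outliers) are never variation-point candidates; ties are broken
toward earlier volumes and at least one point is always selected.

**Respiration-map units.** Percent of the stable-period mean is the default
(suitable for pooling across subjects); raw units are available. Maps are
computed per contrast — VAPER on the nulled-pair time grid (raw VAPER by
default, the corrected series optionally), BOLD on the control stream — and
the variation points are detected on the same series the map is computed
from, where the subtraction has already cancelled task and drift components.

**Equi-volume depth.** Distance transforms to the WM and CSF/background
boundaries (half-voxel face offset) give the equidistant depth
`d_csf/(d_csf + d_wm)`. Within each cortical column, voxels sorted by
equidistant depth receive the cumulative volume fraction as their equi-volume
depth — the discrete volume-fraction construction, which corrects the
equidistant coordinate for curvature. For this to work the columns must be
wedge-shaped: `build_columns()` thins the mid-depth band to a locally
one-voxel layer, labels it by geodesically nearest seed (farthest-point
sampling, 6-connected within-GM graph distances so columns do not leak across
sulci), and assigns every GM voxel to its Euclidean-nearest mid-layer voxel
via an exact feature transform — a projection along the cortical normal.
Assigning voxels to the nearest *seed* instead produces near-prismatic
columns whose cumulative-volume depth degenerates to the equidistant depth;
the projection construction recovers the spherical-shell closed form
`(r_csf^3 − r^3)/(r_csf^3 − r_wm^3)` with a mean absolute error of about
0.02 at a 10-voxel shell thickness (the package's analytic acceptance check
requires < 0.03). The internal parcellation used for depth aims at ~500
voxels per column; smaller columns have noisier cross-section profiles. For
node analyses choose K so that nodes keep at least ~30 voxels (the
whole-brain analyses this mirrors use K = 1000; the phantom default is 200).

**Percent signal change.** Each voxel's series is normalized by its temporal
mean before regression; the reported beta is `100 · b_task / b_intercept`
(task coefficient over fitted baseline), which is invariant to the
normalization scale and exactly equals the planted amplitude on noiseless
boxcar data. The default task regressor at a ~6 s TR is the raw boxcar; a
double-gamma convolution is available for BOLD (`hrf = "double_gamma"`).

**Exclusion rule.** The threshold is the `1 − fraction` quantile of the
respiration map over the whole brain mask (not the ROI); ties at the
threshold are all excluded. Exclusion masks are computed per contrast from
that contrast's own map.

**Phase-ROI analysis.** Given one signal-change map per acquisition breath
phase (0/90/180/270 degrees), voxels above the response threshold (default:
80th percentile of the voxelwise maximum positive change — the level is not
prescribed by the method, and the percentile keeps noise voxels from diluting
ROI means) are grouped by their argmax phase; each ROI's mean change per
phase is fitted with `A·cos(theta − phi0)` in closed form (four equally
spaced phases make the least-squares fit a single Fourier bin, `A ≥ 0`,
`phi0 ∈ [0, 360)`).

**Blurring kernel.** Correlations use linearly detrended series; pairs are
symmetric so the kernel is exactly even, the center is exactly 1, and the
half-maximum reference is fixed at 0.5, measured by linear interpolation of
the first crossing (profiles that never cross within the radius are reported
as `2·radius` and flagged). Voxels with numerically zero variance are
excluded from pairs.

**Breathing-challenge windows.** Deep-breath trials use the latter 2/3 of the
six-volume breathing block (the first two volumes carry the transient) and
the latter 2/3 of the six-volume post-task rest; breath-hold blocks use the
five hold volumes (the cued breath-in/out volume is not part of the event)
against volumes 3–8 after the hold ends. Windows are defined in seconds on
the acquisition grid and intersected with the sample times of whatever series
is analysed, so the same rule serves full runs, single streams and contrast
series; trial means are averaged before the task/rest contrast, and trials
whose task or rest window is entirely censored are dropped and counted.

## The synthetic phantom

`phantom_spec()` / `make_phantom_anatomy()` / `make_phantom_timeseries()`
generate every input the pipeline reads, plus ground truth for parameter
recovery: a WM ball inside a GM shell (radii 14 and 24 voxels on a 64³ grid,
0.8 mm isotropic) inside a thin CSF shell; pial vessels as tangential tubes
(radius 1.4 voxels ≈ 1.1 mm) on the GM/CSF interface and thinner penetrating
radial vessels, planted with an azimuthally varying density so that vessel
density genuinely varies across nodes; and a sector ROI about +z with a
mid-depth Gaussian neural response (2% at depth 0.5, width 0.15) plus a
superficial macrovascular response proportional to pial-vessel proximity
(10% at-vessel for BOLD; 3% for the CBV-weighted stream, because blood-volume
imaging is not entirely devoid of large-vessel bias — this small residual is
what exclusion removes from the VAPER profile).

The generative model for the two streams is

    control = B(x) (1 + b_bold(x) g(t) + c(x) h(t) + e)
    nulled  = B(x) kappa (1 + (b_bold(x) − b_cbv(x)) g(t) + c(x) h(t) + e)

with `g` the task boxcar, `h` the per-volume respiration regressor (windowed
belt-amplitude deviation from the run median — an RVT-like simplification;
the detection pipeline itself never uses the belt), `c(x)` the
vessel-coupling field (5% at a vessel, decaying as `exp(−d/1.5 voxels)` to
emulate extravascular spread), and `e` AR(1) Gaussian noise (0.6% of
baseline, coefficient 0.3). The at-vessel coupling of 5% is of the order of
the respiratory fluctuations conspicuous at macrovessels in sub-millimetre 7T
data; at levels near the thermal noise floor no exclusion strategy could
work, which would not emulate the regime the method addresses. Spontaneous
deep breaths (sighs, near-full-scale symmetric cycles) occur about once a
minute on a jittered grid, natural breathing oscillates at ~0.27 Hz with
seeded amplitude/rate jitter, and each voxel inherits a quarter-cycle
respiratory transit lag from its nearest vessel, assigned by azimuthal sector
— this regional delay structure is what makes the four phase-ROIs of the
deep-breath experiment emerge. With `kappa = 0.5` (the blood-nulling
preparation also attenuates tissue signal; 0.5 is in the plausible range) the
corrected-VAPER gain `kappa/(1 − kappa)` is exactly 1, so the recovered
percent signal change equals the planted CBV amplitude, which keeps the
ground truth directly interpretable.

Motion spikes inject a 0.6 mm step into the motion table together with a 3%
global intensity perturbation; outlier spikes perturb intensity only. Both
are scheduled, so censoring can be checked exactly. Every output is
bit-reproducible from the spec and seed.

**What the phantom does not emulate.** EPI distortion and ghosting, k-space
reconstruction, cardiac pulsatility, partial-volume mixtures at tissue
borders, folded cortical geometry (the shell is convex, so the
geodesic-versus-Euclidean distinction in column building is untested on real
sulci), CO2 kinetics (the coupling is belt-driven with fixed regional lags),
and registration error. Passing the phantom tests therefore demonstrates that
the statistics and geometry are implemented correctly and that the
recovery logic works in a controlled regime — not that real acquisitions meet
the model's assumptions.

## Problem sizes used by the tests and the acceptance script

Unit and property tests run on toy arrays (up to 8×8×8×40) and a 32³ phantom;
the acceptance checks run the default 64³ × 120-volume phantom end-to-end,
the analytic depth check on the full shell, the blurring closed form on
32³ × 60 smoothed-noise series, and the four-run deep-breath phase analysis
on the 32³ phantom. These sizes were chosen so the whole suite exercises
every stage at full fidelity while remaining a desk-scale computation.

## Limitations

The respiration map rests on the assumption that, after censoring, transient
deviations from the signal trend are respiratory in origin; tasks that
correlate with breathing, or global arousal fluctuations, violate it. The
exclusion strategy removes voxels rather than modelling them, so it trades
sensitivity for specificity. The equi-volume construction is volumetric and
column-based; on heavily folded cortex at marginal resolution a surface-based
implementation remains preferable. Respiration maps carry no information
about vessel diameter, so the excluded set conflates vessel calibres.
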