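# laminaresp

Respiration-informed removal of macrovascular bias for laminar fMRI.

Sub-millimetre fMRI resolves activity across cortical depth, but task
responses are biased toward the cortical surface: large pial vessels respond
strongly and sit at the CSF/GM boundary, so a laminar profile peaks
superficially even when the neural input targets mid-depth. Breath-to-breath
respiratory variation modulates exactly those macrovascular voxels.
`laminaresp` maps respiration-related signal fluctuations directly from the
fMRI series itself and uses the map to exclude macrovascular-dominated voxels
before depth analysis.

The package implements, for interleaved blood-nulled/control ("VAPER") and
BOLD acquisitions:

- **Contrasts** — dynamic subtraction `C − N` and corrected `(C − N)/C`
  VAPER, the control stream as BOLD, and the MT anatomical contrast
  `(S_ctrl − S_mt)/S_mt`; frame censoring at motion-derivative Euclidean norm
  > 0.4 mm or outlier fraction ≥ 10%.
- **Respiration-effect map** — the per-volume outlier fraction (polynomial
  detrend, Gaussian-tail MAD threshold) marks the top 15% of time points as
  respiration-variation points; the map is the mean absolute deviation of
  those volumes from the stable-respiration mean image. Deep-breath and
  breath-hold block analyses and the four-phase breath-cycle ROI analysis
  (sinusoidal fits `A cos(θ − φ₀)`) are included.
- **Laminar geometry** — equi-volume cortical depth on volumetric
  segmentations (cumulative volume fraction within normal-projected columns),
  seeded column/node parcellation of GM, and ROI construction (dilation + GM
  re-intersection + activation gate at uncorrected p < 0.01).
- **Profiles** — percent-signal-change GLMs, exclusion of the top 10%
  respiration-responsive voxels brain-wide, depth profiles before/after
  exclusion, and superficial-bias metrics (peak depth, surface/mid ratio).
- **Vascular association** — per-node vessel density vs respiration effect,
  per-brain normalization, pooled correlation and 2D histograms.
- **Blurring** — the neighbor-correlation kernel of a series and its FWHM.
- **Synthetic phantom** — a seeded spherical-shell cortex with planted
  vessels, respiration-coupled fluctuations, a mid-depth neural plus
  superficial macrovascular response, motion/outlier spikes and interleaved
  acquisition, providing ground truth for every stage.

## Worked example

Generate a small phantom, censor corrupted frames, build the respiration map
from the raw VAPER series, and compare the BOLD laminar profile before and
after excluding the top-10% respiration-responsive voxels:

```r
library(laminaresp)

spec  <- phantom_spec(seed = 1, dim = 32, r_wm = 7, r_csf = 13,
                      csf_thickness = 2, n_pial = 10, n_penetrating = 14)
truth <- make_phantom_anatomy(spec)
resp  <- make_resp_trace(spec, "natural")
sim   <- make_phantom_timeseries(truth, resp)

outfrac <- rep(NA_real_, spec$n_vol)
for (s in split_conditions(sim$series)) {
  of <- outlier_fraction(s, truth$brain_mask)
  outfrac[of$volume] <- of$fraction
}
series <- censor_frames(sim$series, sim$motion, outfrac = outfrac)
series$meta$censor_log$indices
#> [1] 37 55 83

streams  <- split_conditions(series)
vaper    <- compute_vaper(streams$control, streams$nulled, corrected = FALSE)
sel      <- select_variation_points(outlier_fraction(vaper, truth$brain_mask))
resp_map <- respiration_effect_map(vaper, sel, truth$brain_mask)
resp_map
#> <respiration_effect_map> percent units, 9 variation points, 14328 mask voxels

depth <- equivolume_depth(truth$labels, seed = 1)
glm_b <- fit_block_glm(streams$control, sim$design, truth$brain_mask)
roi   <- build_roi(truth$roi_sector, truth$labels, activation = glm_b)
excl  <- exclusion_mask_topfrac(resp_map, truth$brain_mask, 0.10)
prof  <- extract_laminar_profile(glm_b, depth, roi, exclusion_mask = excl)
superficial_bias(prof)
#> # A tibble: 2 × 3
#>   excluded peak_depth surface_mid_ratio
#>   <lgl>         <dbl>             <dbl>
#> 1 FALSE         0.025             1.13
#> 2 TRUE          0.575             0.639
```

The exact volumes carrying the planted motion/outlier spikes (37, 55, 83) are
censored. Before exclusion the BOLD profile peaks in the most superficial
depth bin (0.025, the pial side) and the mean of the three superficial bins
exceeds the mid-depth mean (ratio 1.13); after removing the top-10%
respiration-responsive voxels the peak sits at mid-depth, where the phantom's
neural response was planted, and the surface/mid ratio drops to 0.64.

The respiration map also tracks the planted vasculature at the node level:

```r
cols  <- build_columns(truth$labels, depth, K = 60, seed = 1)
nodes <- node_summaries(cols, resp_map, truth$vessel_mask)
unlist(pooled_correlation(nodes)[c("r", "n", "slope")])
#>         r         n     slope
#> 0.8037431 60.000000 0.3530302
```

`run_pipeline(run_config(seed = 1, out_dir = "out"))` chains every stage and
writes maps (NIfTI), tables (TSV) and a JSON manifest;
`inst/cli/laminaresp.R` wraps it for shell use.

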