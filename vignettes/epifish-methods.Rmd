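---
title: "Statistical integration of LFP and two-photon calcium imaging: methods"
author: "epifish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical integration of LFP and two-photon calcium imaging: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(epifish)
```

# The problem

In larval zebrafish epilepsy models, a local field potential (LFP)
electrode reports, with millisecond resolution, the summed activity of the
whole small brain — but carries no information about *where* a discharge
originates, and its large low-frequency transients are easily confused
with muscle artifacts from tail flicks. Two-photon Ca²⁺ imaging of a
GCaMP6f line is the mirror image: spatially exact, temporally slow
(~4 Hz), and blind to field oscillations. `epifish` implements a joint
statistical treatment of the two channels so that epileptiform activity is
detected, quantified, localized, and attributed to neuronal cohorts
without an operator drawing regions of interest or deciding by eye what
"looks epileptic".

The package targets paired recordings: one single-channel LFP trace
(5 kHz) and one time-lapse fluorescence stack (e.g. 512×512 at ~4 Hz), optionally with an anatomical label image
assigning pixels to the optic tectum (OT), cerebellum (Cb) and medulla
oblongata (MOb).

# LFP power statistics: Main and Secondary Modes

The trace is band-passed to 30–95 Hz, where epileptiform high-frequency
discharges live and movement artifacts do not. RMS power is computed in a
250 ms window slid 50 ms at a time, and its base-10 logarithm is the
working variable. At rest the log-power is well described by one Gaussian;
discharges add a heavy right tail.

`fit_power_modes()` separates the two by iterative tail trimming
(`trim_gaussian_fit()`): fit a normal by sample mean/SD, and if mean and
median disagree by more than `tol`·SD (default `tol = 0.01`), drop all
samples above mean + 2 SD and refit. The surviving bulk is the **Main
Mode** (MM). The **Secondary Mode** (SM) is every sample of the *original*
series above the final MM mean + 2 SD; its count and its mean distance
from the MM mean (ΔSM-MM) quantify how much high-power activity the
recording contains.

Two numerical choices deserve attention:

* **Convergence is checked before any removal.** On a symmetric sample the
  mean≈median criterion is met immediately and nothing is trimmed, so a
  quiet recording is summarized by its plain moments. Checking *after* a
  first removal instead drives the fit to the fixed point of one-sided
  truncation (MM mean biased by about −0.09 SD on pure noise), which is
  clearly not what a "best-fit normal of the bulk" intends.
* **The SM is a mixture.** Even a pure Gaussian series puts ~2.3% of its
  windows above 2 SD (their mean excess is 2.37 SD — the truncated-normal
  expectation), and windows that straddle a discharge edge carry
  intermediate power. A planted per-window excess δ is therefore
  recovered by ΔSM-MM about 10% low; the property tests use exactly this
  mixture oracle rather than pretending ΔSM-MM equals δ.
* At large event loads the procedure has a genuine blind spot: if
  elevated windows are so numerous that the mixture's mean + 2 SD exceeds
  the discharge level, no sample is ever trimmed and the SM comes back
  empty. Brief quasi-periodic discharges (a few percent to ~15% of
  windows) are the regime the statistic is designed for.

The band-pass itself is applied in the frequency domain with the exact
|H(f)|² magnitude of a 4th-order Butterworth band-pass — the response a
forward–backward IIR pass applies — so it is zero-phase by construction
and burst timing is preserved for the cross-correlation stages.

# Pixel statistics: ΔF/F0, skewness, binarization

After dark subtraction and 2×2 binning, each pixel's fluctuation is
ΔF/F0(t) = (f(t) − ⟨f⟩)/⟨f⟩ with a **global** temporal-mean baseline;
a movable baseline distorts large transients into artifactual negative
lobes and is deliberately not offered. The per-pixel distribution of
ΔF/F0 is symmetric for noise and right-skewed where Ca²⁺ events occur;
Pearson's second coefficient, ∂ = 3(mean − median)/SD (sample SD), maps
activity per pixel and, pooled over the section, per recording.

Binarization reuses the same iterative-trim fit per pixel: samples above
the fitted baseline mean + 2 SD become 1. Two morphological rules then
clean the binary stack, exactly as stated and nothing more: positive runs
shorter than 3 frames are deleted, then positive pixels with fewer than 2
positive 8-neighbors in their frame are removed. The support rule is
iterated to a fixed point — a single pass is not idempotent (removing a
pixel can strip its neighbor below the threshold), and idempotency is the
property that makes the filter a well-defined cleanup rather than an
order-dependent heuristic.

# Spatiotemporal domains

`find_clusters()` groups positive voxels that are topologically connected
in (x, y, t) — 26-connectivity by default, 6 available — into Ca²⁺
domains, each measured by volume (voxels = binned pixel × frame),
duration, maximum per-frame surface, and origin (the centroid of its
first-frame pixels: where the event starts). Components are computed on
the voxel adjacency graph via `igraph`; the test suite checks the
partition against an independently coded brute-force flood fill on random
stacks. Domains larger than 300 voxels (strict inequality) are assigned
to the atlas region containing their origin, and counts are normalized to
the number of classified domains in the session.

"Surface" here is the maximum per-frame area, the quantity plotted
against duration when profiling event footprints; a mesh boundary area
would be a different (and for binned binary masks, noisier) notion.

# Localizing LFP sources

The windowed log-RMS power is linearly interpolated at each frame's mean
exposure time (frame i at (i − 0.5)/frame_rate). The coupling map sums,
over lags |l| ≤ L, the lag-l correlation between the z-scored pixel
fluctuation and the z-scored power, divided by the number of lag terms —
a bounded, correlation-like C(x, y) whose map maximum is 1 after
self-normalization. The raw (unnormalized, scale-dependent) sum is
retained behind `mode = "raw"`; the bounded variant is the default
because maps are read after self-normalization and a bounded quantity
compares across recordings. Lags use truncated overlap (no wrap-around),
each normalized by its own overlap length; negative lag means calcium
leads power. L defaults to the half-width at half maximum of the
whole-field correlogram's central peak (`estimate_L()`, floored at one
frame). Maps restricted to chosen frame windows (`windowed_maps()`)
contrast interictal against ictal sources.

# Two neuronal cohorts around each discharge

Cell bodies are detected on the 3×3-median-filtered median projection by
normalized cross-correlation with zero-mean donut templates (sizes 10 and
7 px; ring peaking at 40% of the outer radius with a smooth roll-off —
hard-edged annuli penalize the soft borders of real somata). Because
normalized correlation is scale-free, featureless noise produces local
maxima of 0.3–0.5 whatever the noise amplitude; accepted candidates must
therefore also show a ring-over-surround contrast exceeding 4 standard
errors, with pixel noise estimated robustly from the median-filter
residual. Detection can be restricted to a brain mask, since tissue
boundaries score like cell edges.

Circular ROIs of radius 3 px (29 pixels) give per-neuron ΔF/F0 traces;
these are standardized to unit SD and decomposed by PCA with neurons as
variables and time points as samples, keeping the first 10 components.
Component signs are fixed so each score's peak cross-correlation with the
log-RMS power is positive.

The **Ep** component is the PC with the largest zero-lag correlation with
the power. The **pre-Ep** component is selected among the remaining PCs
whose correlogram attains its global maximum at a negative lag; because
per-event amplitude jitter spreads genuinely power-correlated residual
variance over many PCs (peaks ~0.1–0.2 at arbitrary lags), a candidate
must also exceed a Bonferroni bound on the maximum noise correlation, 30%
of the strongest component peak, and half of the strongest candidate
peak. Among survivors the peak lag closest to zero wins. When nothing
qualifies — a single-population recording — the pre-Ep slot is flagged
undefined rather than filled with noise.

Loading maps divide each neuron's loading by the component's maximum
loading, drop non-positive loadings, and remove neurons whose normalized
loading exceeds `both_threshold` in **both** classes. The default is 0.5,
not lower: the cohorts' time courses correlate at about exp(−Δt/τ)
through the indicator kernel, so PCA mixes a fraction of the leading
cohort into the Ep component and genuinely exclusive pre-Ep neurons carry
cross-loadings near 0.3; a 0.2 cutoff would delete the entire population
the map exists to show. Rostro-caudal profiles sum normalized loadings in
bins along the image y-axis (configurable). Collective maps rasterize
per-fish maps, register them to a reference mask by a moment-based
similarity transform (translation, rotation, isotropic scale; externally
supplied displacement fields are accepted — non-rigid registration is out
of scope), and take the voxelwise maximum across fish.

# Motion

The larva's per-frame position is the centroid of its supra-threshold
silhouette (threshold by Otsu's split unless given); displacement is the
distance to the median centroid over the sequence. An area-difference reading of "position" is a defensible alternative and
stays available via `position = "area"`.

# The synthetic world

`gen_lfp()`/`gen_movie()`/`gen_condition_suite()` generate paired
recordings with complete ground truth, deterministic under a seed. What
they emulate — and what they do not — bounds what a green test
establishes.

* **LFP**: 1/f-shaped Gaussian background; discharges are 30–95 Hz noise
  packets calibrated so the *analysis-measured* band RMS during a burst
  exceeds baseline by the requested δ in log10 units (packets are
  calibrated after a second pass of the analysis filter, which they will
  traverse). Default bursts: 12 × 5 s per 300 s. Multi-second bursts make
  burst-interior windows dominate the SM; the ~10% dilution by edge and
  baseline-tail windows is intrinsic (above). Movement artifacts are
  smooth half-sine transients with no added band power.
* **Movie**: elliptical "brain" with a three-band OT/Cb/MOb atlas;
  donut-shaped neurons; GCaMP-like transients with instant rise and
  exponential decay (τ = 1.5 s; the kernel is a single
  modeling choice isolated in one function). Ep neurons fire at burst onsets, pre-Ep neurons Δt before,
  silent neurons sparsely at random. Noise is Gaussian with variance
  proportional to the mean (shot-noise approximation); SNR is peak ΔF/F0
  over the per-pixel ΔF/F0 noise SD on the generated (raw) grid, so 2×2
  binning halves the noise exactly as in a real pipeline.
* **Domains** are sustained plateaus occupying exactly their recorded
  voxel set (unions of full bin blocks when a binned analysis is
  declared). A decaying kernel would leave a domain's "true" voxel set
  ill-defined — any cutoff on the tail is arbitrary — whereas a plateau
  models a population discharge sustained for the event's duration and
  makes volume/duration recovery a well-posed question.
* Not emulated: optics (PSF, scattering), photobleaching, neuropil
  contamination, non-rigid tissue deformation, correlated physiological
  noise, and real GCaMP nonlinearity. Recovery rates measured on this
  world are upper bounds for real data.

The four condition presets encode the qualitative structure of the
experimental groups: WT (artifacts, tiny motion-locked domains), PTZ
(strong brief discharges, 300–700-voxel cerebellar domains, one
near-global ictal event), MO (moderate discharges, intermediate
cerebellar domains), MO+VPA (MO with burst rate/amplitude strongly
reduced and only sub-threshold domains). Preset discharges are brief
(1.5–2 s): the trim procedure cannot split modes when elevated windows
are too numerous at moderate separation, and brief quasi-periodic events
are also what the models show between seizures.

# Degenerate inputs and edge behavior

Zero-variance pixels are masked, not errors; an all-identical log-power
series is an error ("zero variance"). Frame times outside the LFP span
are flagged, never clipped. Empty binary stacks yield empty cluster sets;
an empty interval list yields no maps. ROIs that do not fit the image are
dropped and reported. Event windows clipped by the recording edge are
truncated and flagged. All exported tables use 0-based pixel/frame
indices with stated units.

# Known limitations

* The trim fit's large-load blind spot (above) is inherent to the
  trimming procedure itself.
* ΔSM-MM under-reports the planted per-window excess by ~10% through SM
  mixing; comparisons across groups are unaffected (the bias is shared).
* The pre-Ep selection heuristics (significance floor, proportional
  floors) are needed to automate a criterion stated for visual use; very
  weak anticipating populations (coupling below ~30% of the Ep coupling)
  will be flagged undefined rather than found.
* The minimal TIFF codec handles uncompressed single-channel strip-based
  files only — sufficient for scientific interchange, not for compressed
  or tiled variants.
* Registration is similarity-only; non-rigid alignment must be supplied
  as displacement fields.
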