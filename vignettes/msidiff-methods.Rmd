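---
title: "Methods: subfield-resolved differential lipid analysis for MALDI imaging MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subfield-resolved differential lipid analysis for MALDI imaging MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msidiff)
```

## The problem

MALDI imaging mass spectrometry (MALDI-IMS) acquires a full mass spectrum at
every pixel of a tissue raster, so the spatial distribution of hundreds of
lipid species can be mapped in a single section. In neurodegeneration
studies the question is rarely "does lipid X change in the hippocampus" but
"in *which subfield* does it change": the Cornu Ammonis fields (CA1–CA4) and
the dentate gyrus (DG) have distinct functions, connectivity and
vulnerability, and pooled-tissue lipidomics averages their signals away.

`msidiff` implements an open, tested version of the analysis workflow such
studies use: align raw spectra to a control m/z list, remove chemical
baseline, normalize pixel spectra to total ion count (TIC), segment the
section to separate white from gray matter, run a receiver-operator
characteristic (ROC) analysis per region of interest (ROI) for every
matched case–control pair, keep only m/z values whose direction of change
is consistent across **all** pairs, and quantify each retained change as a
mean percent change from control. Because the original human datasets
behind such workflows are generally not deposited, the package ships a
synthetic phantom generator with planted, known changes, so every stage can
be validated against ground truth.

## The statistical model

For one reference m/z $j$, one region $r$, and one matched pair $p$, let
$x_{1}, \dots, x_{n}$ be the case section's pixel intensities in $r$ and
$y_{1}, \dots, y_{m}$ the control section's. The ROC area under the curve
is the Mann–Whitney functional

$$\mathrm{AUC} = \Pr(X > Y) + \tfrac12 \Pr(X = Y),$$

computed exactly by the midrank formula. A pair *calls* the species
increased when $\mathrm{AUC} \ge \theta_{\mathrm{up}}$ and decreased when
$\mathrm{AUC} \le \theta_{\mathrm{down}}$; defaults are
$\theta_{\mathrm{up}} = 0.75$, $\theta_{\mathrm{down}} = 0.25$, a
conventional discriminative-AUC cutoff (the proprietary software such
workflows originally used does not document its threshold; ours is a
configurable assumption). The selection rule is the **all-pairs consistency
filter**: $(j, r)$ is reported only when every pair makes the same
non-neutral call. With six pairs, a null species that flips direction at
random passes with probability $2 \cdot (q/2)^6$ for per-pair tail
probability $q$, which is what controls false positives here — there is
deliberately no additional multiple-testing correction, and the per-test
counts are exposed in the ROC record dump for transparency.

Effect size is reported per pair as
$100 \cdot (\bar{x} - \bar{y}) / \bar{y}$ on the same preprocessed peak
matrix the ROC uses, and summarized as the mean over pairs with its
across-pair standard error.

The unit of observation is the pixel, which is spatially autocorrelated
within a section; the design treats the matched pair, not the pixel, as the
replication unit, which is why per-pair AUCs are never pooled into a single
test.

## Preprocessing chain and its fixed order

1. **Alignment** (`align_to_reference()`): each control-list m/z is mapped
   to the axis window ±`tolerance_da` (default 0.25 Da, TOF mass accuracy
   at lipid masses). Overlapping windows of adjacent references are
   truncated at their midpoint; an apex on a window edge with the signal
   still rising outside does not count as a local maximum; apex ties break
   toward lower m/z.
2. **Top-hat baseline removal** (`tophat_baseline()`): subtraction of the
   morphological opening (erosion then dilation with a flat structuring
   element, default width 1.5 Da — far above the ~0.2 Da peak FWHM, far
   below the baseline scale). Opening is idempotent, so the transform
   annihilates constants and leaves already-corrected spectra unchanged.
3. **TIC normalization** (`tic_normalize()`): every on-tissue pixel is
   scaled to the dataset's mean pre-normalization TIC. Scaling to the mean
   rather than to 1 keeps intensities on an interpretable counts scale;
   percent change is invariant to that choice.
4. **Peak extraction** (`extract_peak_matrix()`): the windowed *integral*
   (sum over the aligned window), not the apex height, which is robust to
   ~0.1 Da apex jitter.

The order is pinned by a regression test: normalizing before baseline
removal rescales the baseline differently per pixel and changes the
result.

## Spatial segmentation

The original workflow's proprietary "group areas with a similar m/z
profile" tool is approximated by k-means over per-pixel peak vectors
(columns scaled to unit variance), after an edge-preserving median filter
on each feature image (`weak` = 3×3, `strong` = 5×5; bilateral filtering
would be the obvious alternative but adds two parameters for little gain at
100 µm pitch). Defaults: `k = 3` (background rim, white, gray), seed 42.
Noiseless phantoms collapse each region to one repeated profile, which
Hartigan–Wong k-means rejects (duplicate centers), so Lloyd's algorithm is
started from distinct pixel profiles instead. The cluster with the highest
mean intensity over sulfatide-like marker species (defaults m/z 906.7,
918.7 — sulfatides are myelin lipids, hence white-matter enriched) is
named `white_matter`. Segmentation is used the way the field uses it — to
differentiate white and gray matter and for QC overlays; the differential
statistics always run on the traced ROI label maps.

## The phantom: what it emulates and what it does not

`phantom_spec()` describes a paired study at the reference acquisition
geometry: 100 µm raster pitch, m/z 400–2000 at 0.1 Da spacing (~16k
channels, chosen to keep a full section under ~300 MB in memory). The
`"subfields"` layout places DG at the centre of a tissue disc wrapped by
CA4, CA2/3, CA1 and an outer white-matter ring; only label identity
matters downstream, not anatomical shape. Each on-tissue pixel spectrum is

$$ s(m) = f_{\mathrm{pix}} \cdot g_{\mathrm{pair}} \left[ \sum_k a_k(\mathrm{region}, \mathrm{role}) \, e^{-(m - m_k)^2 / 2\sigma_k^2} + b_0 e^{-\lambda (m - m_{\min})} \right] + \varepsilon(m), $$

clipped at zero, with $a_k(\cdot, \mathrm{case}) = a_k(\cdot,
\mathrm{control}) \times \mathrm{fold}_k$.

Model choices (the reference workflow documents neither its noise floor
nor its baseline shape, so these are explicit stand-ins):

* **Baseline**: a single decaying exponential (default $b_0 = 150$ counts,
  $\lambda = 0.01\,\mathrm{Da}^{-1}$) — smooth, strictly positive, and
  removable by top-hat.
* **Pixel TIC variability**: a log-normal per-pixel factor
  $f_{\mathrm{pix}}$ with mean 1 and CV `tic_cv` (default 0.15), the
  multiplicative acquisition variability TIC normalization exists to
  remove; log-normal keeps it symmetric in log space.
* **Pair heterogeneity**: a global factor $g_{\mathrm{pair}}$ drawn
  uniformly within ±10%, shared by both members of a pair because each
  matched pair is acquired in one dataset.
* **Channel noise**: Gaussian with signal-dependent variance,
  $\mathrm{sd}(m) = \texttt{noise\_sd} \cdot \sqrt{1 + s(m)}$ (default
  `noise_sd` = 2 counts). This is counting-statistics (shot-noise-like)
  behaviour: quiet off-peak channels, variance growing with signal. A flat
  additive noise floor would be both less physical for TOF detection and
  analytically unworkable here: the morphological opening of a noisy
  baseline sits systematically below it, leaving a positive residual floor
  proportional to the off-peak noise sd on every channel; with flat noise
  that floor and the pixel-level spread that drives the per-pair ROC and
  percent-change dispersion are proportional to the *same* sd, so the
  percent-change attenuation bias stays locked at roughly four times the
  across-pair standard error at any noise level, and no setting recovers
  planted effect sizes within their honest uncertainty. Signal-dependent
  variance decouples the two; the residual floor bias under the defaults is
  well under one percentage point and the pipeline's recovered percent
  changes sit within 3 SE of the planted values.
* **Species panel** (`species_panel_default()`): 40 species — 10 planted
  changes (two per region: one up, one down, folds 0.50–1.75, i.e. |percent
  change| ≥ 30) and 30 null species (10 white-matter-enriched, 10
  gray-enriched, 10 flat, abundances 450–8800 counts). Within every region
  the planted up and down abundance deltas cancel
  ($\sum_k a_k(\mathrm{fold}_k - 1) = 0$), mirroring the mixed
  increase/decrease pattern real subfield studies report per region; this
  also keeps per-pixel TIC comparable between case and control, so TIC
  normalization cannot leak planted effects into null species.

What the phantom does **not** emulate — and hence what passing tests do not
establish about real data: isotope envelopes and adduct chemistry, detector
saturation, mass-calibration drift (spectra are born aligned; the alignment
stage only windows them), histology-driven irregular ROI shapes, spatial
intensity gradients within a region, and biological pair-to-pair
heterogeneity in effect size (the planted fold is identical in all pairs).
Results on real data additionally depend on the quality of the traced ROIs
and of the control m/z list.

## Numerical choices and degenerate inputs

* Intensities are stored as doubles in memory and as 32-bit floats in the
  imzML binary (`.ibd`); statistics run in double precision.
* The top-hat structuring-element half-width is
  $\lfloor \mathrm{window} / 2\,\mathrm{step} \rfloor$ channels (with a
  $10^{-9}$ epsilon against floating-point division artifacts); fewer than
  3 channels is a configuration error.
* Zero-TIC pixels are off-tissue by definition: untouched by
  normalization, excluded from clustering and from region statistics.
* A zero control mean makes a percent change undefined; it is reported as
  missing, never as infinity.
* Processed-mode imzML is resampled by linear interpolation onto a uniform
  axis at the median channel spacing over the union m/z range, with zero
  outside each spectrum's support.
* Hotspot removal clips at the `ceiling(q n)`-th order statistic
  (`type = 1` quantile) of on-tissue values, so the documented behaviour
  "one extreme pixel in a thousand is reduced to the 990th order
  statistic" holds exactly; clipping is monotone and idempotent. The
  colormap scales per image (minimum to clip level); a global scale across
  images is the documented alternative.
* Annotation ties (two lipid-table entries equidistant from a reference)
  resolve to the lower m/z; every reference receives a label or
  `"unassigned"`.

## Problem sizes used in validation

The validation suite runs the study conditions end to end: six pairs of
48×48-pixel sections on the full m/z 400–2000 axis (~16k channels), the
40-species panel above, processed pair by pair so full-resolution spectra
never coexist in memory. Unit tests use 16×16 to 64×64 phantoms on
narrower axes. The ROC implementation is checked against exhaustive
pair-counting on a thousand random tied samples of size up to 50; top-hat
against a brute-force sliding min/max oracle; segmentation against known
phantom labels via the adjusted Rand index (1.0 noiseless, ≥ 0.9 at channel
noise 10% of peak amplitude); and the end-to-end run must recover every
planted change's direction, within 3 SE of the planted percent change, with
zero false positives among the 30 null species.

## Known limitations

* The consistency filter's error control degrades gracefully but
  unquantifiedly when pairs are few; with $n < 4$ pairs the all-pairs rule
  alone is weak.
* Pixel autocorrelation makes per-pair AUCs optimistic as *tests*; they
  are used here only as direction calls, matching the original design, but
  a spatially blocked variant would be the principled extension.
* k-means segmentation is a stand-in for the proprietary tool it
  approximates; agreement on real data is unverifiable without that tool.
* The m/z axis is assumed uniform after import; strongly non-uniform axes
  (e.g. raw TOF bins) should be resampled upstream.
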