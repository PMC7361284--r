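---
title: "Quantifying MICOS assemblies and crista junctions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying MICOS assemblies and crista junctions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cristaequant)
```

# Scope

Mitochondrial cristae are attached to the inner boundary membrane through
crista junctions (CJs), and the MICOS complex — with its Mic60 and Mic10
subcomplexes — organizes where those junctions form. Experiments probing
this machinery produce three kinds of quantitative raw material:
super-resolution (STED) images of immunolabeled Mic60, MINFLUX
single-molecule localization events, and manual annotations of electron
microscopy (EM) sections. `cristaequant` implements the downstream
quantification for all three, together with seeded simulators that
generate data with known ground truth, so that every analysis stage can be
validated without microscope data.

# The clustered-fraction statistic

The central image statistic asks: what fraction of the segmented Mic60
signal sits in *small, punctate* clusters as opposed to extended ring- or
rib-like assemblies? The procedure is:

1. **Filter** the image with a blob-enhancing Laplacian-of-Gaussian (LoG)
   kernel of 80 nm FWHM. We use the *negated* LoG so that bright blobs
   yield positive peaks (the sign convention is not fixed by the procedure
   itself, but a relative threshold on "the brightest value" is only
   meaningful on a blob-positive response), and clamp negative response
   values to zero.
2. **Segment** at 4% of the maximum response value. The comparison is
   `>=`, so the maximum pixel is always foreground. Connected components
   are labeled with 8-connectivity — the conservative choice that does not
   split segments touching diagonally. Border-touching segments are kept;
   excluding them would bias against large assemblies.
3. **Classify** segments by area: a segment strictly smaller than
   0.0225 µm² is a *single cluster*.
4. The **clustered fraction** is the summed single-cluster area divided by
   the total segmented area. It lies in [0, 1]; higher values mean
   smaller assemblies. An image with an empty segmentation yields a
   flagged undefined result, never a silent 0.

Because the threshold is relative, the statistic is invariant under any
positive rescaling of the intensities, which the test suite checks
explicitly. The area cutoff is a plain parameter: a ten-fold smaller
published variant of the cutoff (0.00225 µm², with `<=`) can be requested
by passing a different `single_cluster_area_cutoff_um2`; the package
defaults to the 0.0225 µm² strict-`<` convention and takes no position on
which variant is preferable. An area ratio is computed rather than an
intensity-weighted ratio; the segmentation object carries everything
needed to build intensity-weighted variants externally.

Numerical details that matter:

* FWHM relates to the Gaussian σ by σ = FWHM / (2√(2 ln 2)) everywhere in
  the package (one exported helper, `fwhm_to_sigma()`, used by renderer
  and filter alike).
* The LoG is applied as a separable convolution with **edge-replicated
  padding**. With zero padding, border pixels of even a constant image
  would see a truncated kernel and produce nonzero responses; replication
  makes the response of a constant image exactly zero everywhere and
  avoids spurious border blobs. The sampled second-derivative taps are
  mean-corrected for the same reason.
* The filter refuses to run when σ is below half a pixel — that
  configuration almost always means the pixel-size metadata are wrong,
  and a wrong pixel size silently corrupts every area downstream.

Per-image analysis can be restricted to a binary mask (e.g. one cell's
mitochondria) so that the unit of analysis matches per-cell reporting.
Condition comparisons use the classical one-way ANOVA (below) over
per-cell clustered fractions.

```{r cluster-example}
img <- render_image(simulate_scene(scene_params("scattered_puncta", seed = 11)))
cluster_metric(img)
```

# MINFLUX event filtering

MINFLUX localizations carry five per-event quality scalars. The filter
keeps an event only if **all** of these hold:

| criterion | keep condition | boundary |
|---|---|---|
| background parameter | `p0 < 0.11` | strict |
| relative position | `r_relative < 32 nm` | strict |
| count rate | `rate <= 100 kHz` | 100 kHz is kept |
| photon number | `photons > 1000` | exactly 1000 is removed |
| signal-to-background | `sbr > 0.6` | strict |

The `p0`/`r_relative` pair is stated in the source procedure as the basis
for *removing* false positives; we read it as the retention condition
(events failing either bound are removed), since the opposite reading
would discard precisely the best-localized events. The count-rate bound
removes multi-emitter events (rates strictly above 100 kHz); the photon
and signal-to-background bounds guarantee localization precision. `p0`
and `r_relative` are instrument-defined scalars; the package treats them
as opaque numbers thresholded as stated.

Every failing criterion of a removed event is recorded — the filter does
not short-circuit — so per-criterion counts support QC summaries. Events
with non-finite quality fields are removed and flagged `MALFORMED`,
never dropped silently. The filter is a pure partition: kept plus removed
equals the input, it is idempotent, order-independent, and relaxing any
single threshold can only grow the kept set; all four laws are tested.

# EM morphometry

Annotations are consumed per mitochondrial section: outer-membrane (OM)
length, CJ count, measured CJ diameters, a morphology class, and septum
bookkeeping. On top of these:

* `cj_frequency()` normalizes CJ counts to OM length. The headline number
  is the *pooled* rate (total CJs / total OM length), which is invariant
  to how sections are subdivided; per-section rates with their SEM are
  reported alongside.
* `diameter_summary()` pools all diameters of a condition and reports
  mean, sample SD (n − 1), and n.
* `morphology_fractions()` tabulates class fractions per condition
  against a declared class set. Two vocabularies ship with the package: a
  coarse {wild_type, aberrant} split and a detailed eight-class set. The
  fine-grained class names are package-chosen descriptive labels (the
  two-tier classification itself is standard; the fine vocabulary is
  user-replaceable).
* `junction_septa_accounting()` separates genuine cristae CJs from septum
  junctions: on 2D sections, a septum's connection to the boundary
  membrane mimics a CJ. With junction prevalence p and septum-associated
  fraction s per condition, the cristae-CJ prevalence is p(1 − s) and the
  relative decrease between conditions is 1 − p_t(1 − s_t)/p_c(1 − s_c).
  Accounting is section-level by default (a junction-bearing section
  either is or is not septum-associated), with a per-junction weighting
  mode available — published summaries do not always say which convention
  was used, so both are provided. On summary proportions 0.60/0.15
  (control) versus 0.36/0.50, the relative decrease evaluates to ≈ 0.647,
  i.e. about two thirds once inputs are rounded to two digits.

The one-way ANOVA used throughout (`anova_one_way()`) is the classical
fixed-effects omnibus test, delegated to `stats::oneway.test()` with
equal variances; no post-hoc correction is applied because none is part
of the procedure being implemented. Degenerate inputs are flagged: zero
within-group variance with differing means reports F = ∞ and p at the
distribution limit 0; fully constant data report an undefined F. The
conventional significance tiers (`***` ≤ 0.001 etc.) are exposed via
`significance_tier()`.

`mean_line_profile()` samples intensity profiles along user lines by
bilinear interpolation, normalizes each profile min–max onto [0, 1] (the
only normalization under which profiles of different brightness average
meaningfully; divide-by-max is available as an option), and averages
pointwise with an SD band. Flat profiles cannot be normalized; they are
flagged degenerate and excluded (flatness is judged with a relative 1e-9
tolerance, because bilinear weights leave last-ulp wobble on exactly
constant data).

# The synthetic-data generators

The simulators define the study conditions under which the pipeline is
validated. All of them draw from one root seed with documented child
streams (1: emitter placement, 2: rendering noise, 3: MINFLUX events,
4: morphometry), so partial pipelines reproduce the full run and
identical parameters plus seed give bit-identical output.

**Scenes** (`simulate_scene()`): emitters live on the surface of a
cylinder — radius 150 nm, length 3 µm by default — and are
orthographically projected onto the image plane (2D recordings are
effectively axial projections; no depth attenuation). Four spatial models
mirror the observed Mic60 arrangements: scattered puncta; stripes —
circumferential rings spaced 150 nm, echoing the perpendicular stripe
pattern of wild-type cells; opposite bands — cluster centers confined to
two strips within `band_halfwidth_nm` (default 50 nm) of the projected
tubule edges, the two-sided distribution seen without the Mic10
subcomplex; and extended assemblies — contiguous arcs (default 180°,
5 nm emitter spacing, slight axial spread) standing in for ring/rib
structures. Punctate clusters carry Poisson(8) emitters spread 15 nm
around their center.

**Rendering** (`render_image()`): each emitter contributes an isotropic
Gaussian PSF (default FWHM 60 nm, typical of 2D STED) **integrated
exactly over each pixel** via error-function differences, scaled to a
mean of 500 photons; a uniform background (2 counts/pixel) is added and
per-pixel Poisson noise applied unless disabled. Pixel-integrated
rendering makes photon conservation exact up to PSF truncation at the
4.5 σ kernel window, which the tests exploit. Default pixel size is
20 nm, inside the 15–25 nm range of real STED recordings.

**MINFLUX mixtures** (`simulate_minflux_events()`): valid events are
drawn inside all five thresholds; artifacts cycle round-robin through the
five failure modes so every filter branch is exercised by any artifact
count ≥ 5, and each event records its generating label.

**Morphometry tables** (`simulate_morphometry()`): per section, OM length
is log-normal (median 3 µm by default — section-length statistics are
not published, so this is a package choice and configurable); the CJ
count is Poisson with mean `cj_per_um × OM length`; diameters are normal
truncated at zero **by resampling** (clipping would put a point mass at
zero and bias mean recovery); the septum flag is Bernoulli. Two presence
modes exist: by default junction presence is implied by the Poisson
counts and septum junctions are drawn *on top*, so the pooled CJ rate is
an unbiased estimate of `cj_per_um`; when `p_section_has_junction` is
set, presence is controlled explicitly (used to emulate prevalence
scenarios such as 60% vs 36% of sections bearing a junction) and
`cj_per_um` only shapes within-section counts. Condition presets bundle
the reported phenotypes — diameters around 20 nm (wild type), 28 nm
(Mic10-KO), 32 nm (Mic60-KO); septum association 15% vs 50% — while CJ
rates (1.2, 0.35, 0.05 CJ/µm) and diameter SDs (4, 6, 8 nm) are
package defaults chosen once to be realistic, since per-condition values
for them are not published.

What the simulators deliberately do **not** model: depth attenuation and
3D PSFs, labeling efficiency and fixation artifacts, drift, detector
correlations, non-Gaussian PSF tails, EM imaging itself (annotation
tables are simulated directly), and any within-section correlation of
diameters. Passing tests therefore demonstrate that the *analysis* is
correct and well-calibrated under its stated assumptions — not that those
assumptions exhaust real microscope data.

# Validation strategy and problem sizes

The test suite pairs every operation with an independent oracle or a
forced-arithmetic case: segmentation against a brute-force flood fill
(200 random images up to 64×64, exact equality), the LoG against a direct
2D kernel convolution, the renderer against midpoint quadrature of the
Gaussian density, the ANOVA against explicit sums of squares (100 random
instances, 1e-10), the filter against re-application of the thresholds on
10,000 labeled events (exact), and parameter recovery at 96 diameters /
500 sections (2 SEM coverage over 100 seeds; 3 SE bounds). End-to-end, 20
scattered-puncta scenes against 20 extended-assembly scenes separate
cleanly (mean clustered fractions ≈ 0.86 vs ≈ 0.20 at the default seed
set) with the omnibus test far beyond the 0.1% tier. These sizes were
chosen so the entire suite runs in well under a minute while leaving the
statistical checks overwhelming power.

# Known limitations

* The clustered fraction depends on the relative threshold through the
  image *maximum*; a single extremely bright artifact can therefore
  shrink the segmentation. Masking (or pre-cleaning) is the intended
  remedy and is supported directly.
* 8-connectivity and the strict-`<` area cutoff are conventions; both are
  parameters or documented invariants rather than silently baked in.
* The accounting functions treat proportions as exact inputs; they
  propagate no sampling uncertainty. Confidence statements should come
  from the per-section tables (e.g. via resampling), not from the
  proportion arithmetic.
* `filter_params()` thresholds default to published values that are tied
  to a specific instrument configuration; they are not transferable
  defaults for other MINFLUX setups.
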