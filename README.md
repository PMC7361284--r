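# cristaequant

Quantitative analysis of mitochondrial cristae architecture from
microscopy-derived data, for cell biologists working on the MICOS complex
and inner-membrane remodeling.

Mitochondrial cristae connect to the inner boundary membrane through
crista junctions (CJs), whose formation and placement are organized by the
MICOS complex (Mic60- and Mic10-subcomplexes). Experiments on this
machinery yield three kinds of quantitative data, and this package
implements the downstream analysis for each:

* **Clustered-fraction metric** for STED images of immunolabeled Mic60:
  the image is filtered with a negated Laplacian of Gaussian (80 nm FWHM),
  segmented at 4% of the brightest response value with 8-connected
  components, and segments with area < 0.0225 µm² are classed as single
  clusters. The statistic is

  *clustered fraction* = Σ area(single clusters) / Σ area(all segments),

  a number in [0, 1]; higher values mean smaller (more punctate) Mic60
  assemblies, lower values mean extended ring/rib assemblies.
* **MINFLUX event filter**: post-hoc quality filtering of localization
  events; an event is kept iff p₀ < 0.11, r_relative < 32 nm,
  count rate ≤ 100 kHz, photons > 1,000 and signal-to-background > 0.6,
  with every failing criterion recorded per event.
* **EM morphometry**: CJ frequency normalized to outer-membrane length,
  pooled CJ diameter summaries, morphology-class fractions,
  junction/septum accounting (separating true cristae CJs from
  septum-derived junctions), and the classical one-way ANOVA used for all
  group comparisons. Averaged, normalized fluorescence line profiles are
  included.
* **Seeded simulators** for all three data kinds — emitter point patterns
  on a tubule surface (scattered puncta, perpendicular stripes, opposite
  bands, extended arc assemblies) rendered through a Gaussian PSF with
  Poisson noise; valid/artifact MINFLUX mixtures; morphometry tables with
  condition presets — each with full ground truth, so the entire pipeline
  is testable without microscope data.

## Worked example

```r
library(cristaequant)

# a synthetic STED-like image of punctate Mic60 clusters, 20 nm pixels
p   <- scene_params("scattered_puncta", n_clusters = 30, seed = 11)
img <- render_image(simulate_scene(p))
img
#> <image2d> 33 x 168 px, 20 nm/px, range [0, 550]

cluster_metric(img)
#> clustered fraction: 0.7678  (14/16 segments single, 0.164/0.2136 um^2)
```

Of the 16 segments found at the 4% threshold, 14 are below the 0.0225 µm²
cutoff; they carry 0.164 of the 0.214 µm² total segmented area, so 77% of
the Mic60 signal area sits in single clusters — the punctate phenotype.
An extended-assembly scene scores ≈ 0.1–0.2 on the same scale.

```r
# MINFLUX mixture: 300 valid events, 200 artifacts
ev <- simulate_minflux_events(n_valid = 300, n_artifact = 200, seed = 7)
summary(filter_events(ev))
#> MINFLUX filter: kept 300 / 500 events (60.0%)
#>         P0 R_RELATIVE       RATE    PHOTONS        SBR  MALFORMED
#>         40         40         40         40         40          0

# EM morphometry with the Mic10-knockout preset (CJ diameters ~28 nm)
tab <- simulate_morphometry(morphometry_presets()$mic10_ko,
                            n_sections = 120, seed = 5)
cj_frequency(tab)
#> CJ frequency (per um outer membrane):
#>  condition pooled_rate mean_rate     sem n_sections total_cj total_om_um
#>   mic10_ko      0.3345    0.3523 0.03724        120      137       409.5

# junction/septum accounting on summary proportions
junction_septa_from_rates(0.60, 0.15, 0.36, 0.50)
#> junction prevalence: ctrl 0.600, test 0.360
#> septum-associated fraction: ctrl 0.150, test 0.500
#> cristae-CJ prevalence: ctrl 0.510, test 0.180
#> relative decrease of cristae CJs: 0.647
```

The filter recovers exactly the 300 generated valid events, with the 200
artifacts spread evenly over the five failure modes. The morphometry table
recovers the preset's 0.35 CJ/µm rate (pooled estimate 0.33 ± its SE) and
28 nm diameter mean (27.8 nm over 137 diameters here). The accounting
example shows how 60%→36% junction prevalence combined with 15%→50%
septum association amounts to a ≈ 65% loss of genuine cristae CJs.

A YAML-driven command line covering the same operations
(`simulate-image`, `cluster-metric`, `minflux-filter`, `morphometry`,
`line-profile`, …) is installed at `inst/cli/cristaequant.R`:

```sh
Rscript inst/cli/cristaequant.R --config run.yaml --seed 3 --output-dir out/
```

Each run writes its artifacts plus a `provenance.json` (command, seed,
config checksum, versions) sufficient to reproduce the outputs
byte-identically.

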