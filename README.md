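# dropletmorph

Morphometry of organoids confined in collagen droplets.

Droplet microfluidics encapsulates single pancreatic-cancer (PDAC) cells in
nanolitre collagen-I spheres — small (~370 µm, ~27 nl) or large (~750 µm,
~221 nl) — where each cell can grow into an organoid. The interesting
biology is read out from 2-D projected binary segmentation masks: does a
structure stay a **spheroid** or develop a **branched**, invasive
morphology; how fast does its major axis grow; how homogeneous is the
culture (polydispersity index, PDI); and how strongly does the growing
organoid pull on its droplet (diameter contraction, compactness loss,
boundary proximity). `dropletmorph` implements this readout as a tested R
pipeline, plus the closed-form droplet physics, and a ground-truthed
synthetic mask generator so everything is testable without microscopy data.

## What it computes

* **Region geometry** from 16-bit label TIFFs (label 1 = droplet, ≥ 2 =
  organoid structures): area *A*, perimeter *P* (calibrated chain-code
  estimator: digital disks measure compactness 1.00 ± 0.02), moment-ellipse
  axes *a* ≥ *b*, equivalent diameter 2√(*A*/π); compactness 4π*A*/*P*² and
  shape irregularity index *P*/(2√(π*A*)).
* **Branch census**: Guo–Hall skeleton, spur pruning, geodesic branch
  lengths from tips to junctions or to the structure's body.
* **Classification**: spheroid iff *a* < 60 µm, or *b* > *a*/2, or fewer
  than 2 branches ≥ 30 µm (thresholds configurable); otherwise branched.
* **Population statistics**: PDI = 100·s.d.(*A*)/mean(*A*), branched
  fraction per experiment (mean ± s.d.), per-day growth summaries.
* **Droplet dynamics**: population contraction relative to a baseline day
  with percentile-bootstrap 95% CIs (1000 resamples), per-day compactness,
  normalised minimal organoid–droplet boundary distance, radial position.
* **Encapsulation model**: sphere volumes, production rate (dispersed flow ÷
  droplet volume), Poisson occupancy λ = concentration × volume with
  p(empty)/p(single)/p(multi).
* **Synthetic data**: deterministic phantom generator for both droplet
  regimes with per-structure ground truth (class, branch path lengths,
  boundary distances, Poisson cell counts), dataset writer (TIFF + manifest
  CSV + ground-truth JSON) and a config-driven pipeline/CLI.

## Worked example

```r
library(dropletmorph)

# closed-form physics of the two regimes
droplet_volume_nl(370)                            # 26.5  (prints as 27 nl)
droplet_volume_nl(750)                            # 220.9 (prints as 221 nl)
production_rate_hz(encapsulation_config(750, 5000))  # 1.26 Hz (~1 Hz)
occupancy(encapsulation_config(750, 5000))
#> <occupancy> lambda=1.105 cells/droplet: empty 33.1%, single 36.6%, multi 30.3%

# synthetic large-droplet experiment: 8 droplets, days 2/4/5/6
cfg <- config_large_droplets(seed = 1, n_droplets = 8)
res <- run_pipeline(run_config(mode = "synthetic", synthetic = cfg, seed = 1))
res$day_summary
#>   day n_structures mean_major_axis_um sd_major_axis_um mean_sii pdi_percent branched_percent
#> 1   2            8                101             38.0     1.52        26.7             62.5
#> 2   4            8                203             58.0     1.85       110.1             62.5
#> 3   5            8                266             83.6     2.08       118.9             62.5
#> 4   6            8                297             92.9     2.22       121.6             62.5
res$contraction
#>   day n mean_diameter_um contraction_percent ci_lower ci_upper
#> 1   2 8              767                   0   -5.064     4.74
#> 2   4 8              752                   2   -2.529     6.40
#> 3   5 8              729                   5    0.296     9.61
#> 4   6 8              675                  12    7.503    16.53
```

The day-6 contraction recovers the configured 12% schedule exactly; the
mean major axis follows the growth curve (266 µm at day 5 for large
droplets); the branched percentage reflects the configured 0.59 fraction at
this sample size; the shape irregularity index rises with branching. PDI
values on synthetic data exceed the published ones because a 60/40 mixture
of branched and spheroid phantoms is more area-bimodal than a real culture
(see the methods vignette).

Mask datasets round-trip through disk:

```r
man <- write_dataset(cfg, "dataset/")        # TIFFs + manifest + ground truth
res2 <- run_pipeline(run_config(mode = "masks", manifest = man, seed = 1))
```

A CLI wrapper is installed at `inst/cli/dropletmorph`
(`generate`, `analyze`, `report` subcommands).

## Documentation

The methods vignette (`vignettes/dropletmorph-methods.Rmd`) describes the
model and estimators, the synthetic world and its parameter provenance,
numerical choices, and known limitations.
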