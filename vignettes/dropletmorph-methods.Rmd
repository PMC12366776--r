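---
title: "Methods: droplet-confined organoid morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: droplet-confined organoid morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropletmorph)
```

## The problem

Droplet microfluidics packs single pancreatic-cancer (PDAC) cells into
nanolitre collagen-I spheres, where each cell can grow into an organoid.
Two droplet regimes are of interest: small (~370 um diameter, ~27 nl) and
large (~750 um, ~221 nl). The biology of interest is read out entirely from
2-D projected binary masks: whether a structure is a simple spheroid or a
branched (invasive) organoid, how fast it grows, how homogeneous the culture
is, and how strongly the growing organoid pulls on and contracts its
droplet. `dropletmorph` implements that readout as a tested pipeline, with a
synthetic mask generator standing in for microscopy data.

## Shape descriptors

For every labelled region we compute the projected area $A$ (pixel count
times pixel area), the perimeter $P$, the full major/minor axis lengths
$a \ge b$ of the moment-matched ellipse ($4\sqrt{\lambda_i}$ of the pixel
covariance, with the $1/12$ unit-square correction so that one-pixel-wide
structures keep $b > 0$), the centroid, and the equivalent diameter
$2\sqrt{A/\pi}$.

Two derived quantities matter downstream:

* **compactness** $= 4\pi A/P^2$ (1 for a circle, smaller for deformed
  droplets), and
* **shape irregularity index** $= P/(2\sqrt{\pi A})$, the perimeter relative
  to the equal-area circle. The identity $\mathrm{SII}^2 \times
  \mathrm{compactness} = 1$ holds exactly and is asserted in the tests.

**Perimeter estimator.** Naive pixel-edge counting overestimates $P$ by up
to $\sqrt 2$, which would make compactness useless (a digital disk would
measure ~0.8). We trace the outer contour (Moore neighbour tracing, Jacob's
stopping criterion) and weight chain-code steps with the calibrated
coefficients 0.948 (axial) and 1.340 (diagonal). Digital disks of radius
50-200 px then measure compactness 1.000-1.011, within the frozen +/- 0.02
tolerance. Hole boundaries are added to $P$: organoid lumens are genuine
boundary complexity. Droplet-label holes, by contrast, are segmentation
artifacts and are filled before measurement.

## Branch census

The branch detector reduces a component to its topological skeleton by
Guo-Hall thinning followed by a sequential unit-width cleanup (removing
8-simple pixels with three or more neighbours, using Yokoi's connectivity
number). Guo-Hall was chosen over Zhang-Suen deliberately: Zhang-Suen
erodes the free ends of diagonal strokes, which truncated branch tips by up
to 15 px in testing.

A *branch* is the geodesic path along the skeleton from an endpoint to
where the branch ends: a skeleton junction, or the entry into the *body*,
defined as the region whose local half-width (chamfer 3-4 distance
transform) exceeds 8 um - halfway between typical branch half-widths
(~5 um) and organoid body half-widths (>= 14 um). Because the walk only
detects the body once it is 8 um deep, the measured length is corrected by
the predicted penetration $\sqrt{8^2 - w_h^2}$ (with $w_h$ the tube
half-width estimated near the tip), placing the branch end on the body
surface. Path lengths use the same calibrated chain-code weights as the
perimeter, avoiding the staircase bias for oblique branches. Spurs shorter
than 10 um (default) are pruned first; this is far below the 30 um
qualifying threshold, so pruning cannot remove a real branch. An elongated
structure whose skeleton is a single open path with neither junction nor
body is counted as two half-branches - an invasive, tube-like phenotype.

Against generator ground truth (192 phantoms across both regimes), branch
counts are recovered exactly and the two dominant branch lengths agree with
the constructed path lengths to 3.7% on average (worst 11%); the frozen
test tolerance is 10% on the dedicated census fixtures.

## Classification

A structure is a **spheroid** when *any* of: $a < 60$ um, $b > a/2$, or
fewer than 2 branches of at least 30 um. Everything else is **branched**.
The three criteria are combined with OR by default - the literal reading of
the defining sentence - but the conjunctive combination is available as
`combine = "and"` because the prose is ambiguous. The thresholds are
parameters (`a_max_um`, `axis_ratio`, `min_branch_um`, `min_branches`), not
constants. Structures touching the image border are flagged and excluded
from population summaries, since their area and axes are censored.

## Population statistics

* **PDI** (polydispersity index): $100 \times \mathrm{s.d.}(A)/
  \mathrm{mean}(A)$, population s.d. by default (conventions `"sample"` and
  `"squared"` are switches). The exact printed formula is not recoverable
  from the source figure; coefficient of variation of projected area
  reproduces the qualitative ordering bulk > large > small.
* **Branched fraction**: per-experiment fractions, mean +/- sample s.d.
  across experiments (s.d. 0 for a single experiment).
* **Growth**: per-day mean +/- s.d. of the major axis.

## Droplet dynamics

Contraction is population-level: $100 (1 - \bar d_{day}/\bar d_{baseline})$
with a seeded percentile bootstrap CI (1000 resamples by default,
resampling droplets within day and baseline independently). Ratio of means
rather than mean of ratios, because droplets in a cross-sectional screen
are not individually tracked; a per-droplet mode is trivially available by
grouping on `droplet_id` when ids persist. The baseline day defaults to the
earliest observed day.

Boundary proximity uses exact Euclidean distances between boundary pixel
sets (minimum organoid-boundary to droplet-boundary distance), normalised
by the droplet's equivalent radius - the stable radius choice once droplets
deform. Radial position is the centroid offset over the same radius. With
several organoid components the largest is used. An organoid crossing the
droplet boundary is flagged; the droplet outline is then recovered by
morphological closing (12 px) and the interior part measured.

## Encapsulation model

Volumes are $(\pi/6)d^3$; occupancy is Poisson with
$\lambda = c \times V$: `p_empty` $= e^{-\lambda}$, `p_single`
$= \lambda e^{-\lambda}$, `p_multi` the complement. Production rate divides
the dispersed-phase (collagen) flow by the droplet volume - the oil flow
sets droplet spacing, not volume, which is the standard droplet-microfluidics
accounting and reproduces both printed rates (10 Hz and 1 Hz). Unit
constants: 1 nl = 1e6 um^3, 1 ul = 1e3 nl, 1 ml = 1e6 nl, 1 h = 3600 s.
The bootstrap is the plain percentile method, the simplest consistent with
a one-line description ("1000 bootstrap iterations, 95% CI").

Note an internal tension in the published occupancy numbers: the printed
percentages for large droplets (37/36/27) correspond to $\lambda \approx
1.0$, while the printed mean (1.1 cells/droplet) equals the
concentration-derived $\lambda = 5000\,\mathrm{ml}^{-1} \times 221\,
\mathrm{nl}$. We implement the analytic model anchored to the means
(0.8 and 1.1), and validate it against brute-force Monte-Carlo seeding, not
against the measured histogram.

## The synthetic world

The generator emulates the two published regimes:

| parameter | small | large | why |
|---|---|---|---|
| diameter (um) | 373 +/- 21 | 756 +/- 30 | printed droplet sizes |
| cells/ml | 30 000 | 5000 | printed seeding concentrations |
| branched fraction | 0.44 | 0.59 | printed day-4 screening |
| growth curve (um, day 2/4/5/6) | 40/120/150/170 | 60/200/266/300 | day-5 anchors 150 and 266 printed; other days interpolated/extrapolated |
| contraction (day 2/4/5/6) | 0/.02/.04/.05 | 0/.02/.05/.12 | day-6 anchors 5% and 12% printed; "similar up to day 5" |
| size_cv | 0.14 | 0.25 | chosen so spheroid area CV lands near the printed PDIs (28% and 47%) |
| pixel size | 2 um | 2 um | keeps a 750 um droplet under 512^2 px; ~10x objective scale |

Droplets are rasterised from a continuous boundary $r(\theta) = R_0 (1 +
\sum_{k=2}^{4} a_k \cos(k\theta + \phi_k))$ whose total perturbation
amplitude is half the contraction fraction (undeformed at zero contraction,
increasingly irregular as contraction grows); $R_0$ is rescaled so the
*area-equivalent* diameter matches the schedule exactly, which the tests
verify to 1 px. Organoid phantoms are placed uniformly in area within the
feasible centre region (the placement offset follows the $\sqrt u$ law,
checked by a KS test).

Spheroid phantoms are rotated ellipses with axis ratio drawn from
(0.65, 0.95) - safely above the 1/2 threshold. Branched phantoms are a
circular body (34 um) with two opposed main branches along curvature-capped
random-walk tubes (10 um wide), plus optional extra branches at 50-62
degrees from a main. Several construction rules exist purely to keep
phantoms *unambiguous members of their class* under pixelation, because the
classification thresholds are sharp: branches launch along the body surface
normal (a tube grazing a curved body blurs the body/branch boundary), the
walk is stiff near its root, extra branches keep >= 50 degrees separation
from their main and are dropped when too short (< 38 um) or when their
lateral extent would push the structure's minor axis towards $a/2$. The
circular body was chosen over an elongated one after elongated body tips
(curvature comparable to the tube width) proved inseparable from branch
roots by any local-width criterion.

Every phantom carries a ground-truth record (class, droplet diameter,
branch path lengths, continuous minimal boundary distance, placement
offset, Poisson cell count). Truth distances are computed from the
continuous geometry (dense boundary sampling), independent of the raster
measurement path.

What the generator does **not** emulate: image noise, point-spread blur,
fluorescence texture, 3-D structure, touching/overlapping organoids,
segmentation errors. A green test therefore establishes that the metrics
are correct on clean masks of known geometry - not that any particular
segmenter produces such masks.

## Determinism

All randomness derives from one integer seed via per-(id, day, purpose)
derived streams, so `generate_droplet_mask(cfg, 7, 4)` is identical no
matter what was generated before it, datasets re-written with the same
config are byte-identical, and the pipeline's output tables reproduce
exactly. User RNG state is never touched.

## Known limitations

* Branch lengths carry a ~4% average (10% worst-case) measurement error
  from skeleton discretisation and body-entry localisation; sub-pixel
  accuracy was not attempted.
* The PDI of a mixed spheroid/branched population is dominated by the
  between-class area difference, so synthetic PDI values exceed the
  printed ones (which describe real, less bimodal cultures); only the
  small < large ordering is asserted.
* The chamfer 3-4 distance transform (used for body detection) is exact to
  ~6%; the boundary-distance metrics use exact point-set distances instead.
* `branch_count_range` is honoured as an upper bound: extras that cannot be
  placed unambiguously are dropped, so most phantoms have exactly two
  branches.
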