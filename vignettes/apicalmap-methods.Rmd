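---
title: "Quantifying synaptic input to apical dendrites from skeleton annotations"
author: "apicalmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synaptic input to apical dendrites from skeleton annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apicalmap)
```

## The scientific problem

Pyramidal neurons of cortical layers 2, 3 and 5 all extend an apical
dendrite (AD) towards the pia; almost all of them form the AD's main
bifurcation — a "Y" of two similar daughter branches — in a narrow band at
the layer 1/2 border. Dense 3-D electron microscopy of that band makes it
possible to annotate *every* input synapse on an AD segment and to ask how
the balance of putative inhibitory and excitatory input differs between
pyramidal cell types, how it changes along the dendrite, and whether the
inhibitory axons that supply it choose their AD targets selectively.

`apicalmap` implements that analysis as a reusable pipeline operating on
skeleton annotations (webKnossos NML files) rather than on images:

1. **skeleton I/O** — parse/write NML, convert voxel to physical
   coordinates, place everything in a common frame of cortical depth below
   pia;
2. **morphometry** — spine-pruned shaft path lengths, dendrite diameters,
   surface areas, landmark detection, depth profiles;
3. **synapse quantification** — structural classification of inputs,
   per-dendrite densities and inhibitory fractions, path-distance and
   cortical-depth profiles;
4. **axon analysis** — identity calibration of presynaptic axons, target
   preference, innervation multiplicity, bootstrap specificity testing,
   cross-region consistency;
5. **cell-type models** — layer assignment, L5 thick- vs slender-tufted
   clustering, thick-tuftedness PCA, and the regression models linking
   synaptic composition to morphology;
6. **synthetic data** — a generator that emulates all of the above with
   known ground truth, so that every estimator in the package is covered
   by a recovery test.

## Classification model and its assumptions

Synapses are classified by their structural target: synapses on dendritic
shafts, on spine necks, and secondary innervations of an
already-innervated spine count as **putative inhibitory**; primary spine
innervations count as **excitatory**. Double-innervated spines always
contribute one excitatory and one inhibitory synapse. This is a
*structural proxy*: its error rate is estimated by reconstructing the
presynaptic axons of a seeded synapse sample and classifying each axon by
the fraction of its output made onto single-innervated spines (strict
majority above 50% = excitatory). Where the proxy is poor — shafts of L5
slender-tufted dendrites receive substantial input from spine-preferring
axons — the per-structure excitatory fraction is used to correct densities
(`correctDensity()`), moving that fraction of shaft-synapse mass to the
excitatory side while leaving double-spine contributions untouched.

The **putative inhibitory fraction** of a segment is i/(i+e). Two summary
conventions exist and are both reported by `summarizeDensities()`:
per-dendrite means (mean of ratios, with SEM over dendrites) and pooled
statistics (ratio of sums). They differ whenever composition varies
between dendrites; per-dendrite means match the headline numbers, pooled
values are used for depth-resolved profiles where single segments are
short.

## Key quantities and parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| analysis window around the main bifurcation | ±10 | µm path distance | the complete-mapping window used for all per-cell-type densities |
| distance-profile bin | 10 | µm | path-distance resolution along the trunk |
| minimum synapses per reported bin | 4 | count | avoids extreme ratios in near-empty bins; deficient bins merge into their proximal neighbour (distal only at the proximal end) |
| depth slab | 100 | µm | virtual tangential sections for depth-resolved pooled fractions |
| bootstrap resamples | 10,000 | — | percentile CIs and specificity p-values |
| specificity threshold | 0.05 / 8 | — | Bonferroni across the eight target categories |
| axon classification threshold | 0.5 | spine fraction | strict majority for excitatory; exactly 0.5 resolves to putative inhibitory |
| diameter sampling spacing | 2.5 | µm | diameter is measured every ~2–3 µm along the path |
| bifurcation similarity tolerance | 0.5 | relative | "two daughters of similar total length"; annotated landmarks override |

Shaft path length removes spine necks from the skeleton before summing
edge lengths; surface area uses the open-cylinder model
`π · length · mean diameter`. Soma size uses the equivalent-volume sphere
of the measured ellipsoid axes; synapse interface area uses the ellipse
`π · a/2 · b/2` of the two annotated axes.

## Regression models

Three model families are fitted by least squares
(`fitExponential()`, `fitLinear()`, `fitLinearFraction()`):

* **exponential with offset**, `y = c + a·e^{b·x}`, for the inhibitory
  fraction at the main bifurcation against soma distance. Initialization:
  `c₀ = min(y)` (minus a small margin), `a₀` from the range, `b₀` from a
  log-linear regression of `y − c₀`; several fallback starts guard against
  singular Jacobians; `c` is constrained to `[0, 1]` when the response is
  a fraction.
* **linear**, for synapse densities against thick-tuftedness (PC1).
* **linear fraction**, `y = (a·x + b) / (c·x + d)`, for the inhibitory
  fraction against PC1. The family is invariant to a common rescaling of
  the four parameters, so the package fixes `d = 1` during optimization
  and reports parameters on that scale — the fitted *curve* is the
  identifiable object, and tests compare curves, not raw parameter
  quadruples. Fits whose denominator changes sign over the data range are
  rejected rather than reported.

R² is `1 − SS_res/SS_tot` throughout, and model comparison for the
fraction-prediction exercise (`predictFractionFromDensities()`) computes
the R² of `Î/(Î+Ê)` against the observed fraction with the non-modelled
component held at its sample mean.

## L5 subtype classification

Four morphological features — soma equivalent diameter, main-bifurcation
depth, oblique-dendrite count, trunk diameter — are standardized to unit
variance (they mix µm and counts; an unstandardized cosine distance would
be dominated by the largest-magnitude feature) and clustered by
average-linkage agglomeration. Candidate metrics (cosine, Euclidean,
correlation, city-block) compete on cophenetic correlation; cosine is
expected to win on realistic data and a warning is emitted if it does
not. The two-cluster cut is labelled by soma size (larger mean =
thick-tufted). Thick-tuftedness is the first principal component of the
standardized features, sign-oriented to correlate positively with soma
diameter so scores are deterministic.

## Axonal target preference

Each reconstructed axon is summarized by its fractional innervation of
eight target categories (L2 AD, deep-layer AD, other shafts, single- and
double-innervated spines, L2 somata, axon initial segments, glia), always
excluding the seed synapse. The conditional matrix reports, per seed
group, mean per-axon fractions and the AD-restricted renormalization; the
ratio-of-means variant is reported alongside because the two denominators
differ in general. Multiplicity statistics (synapses per distinct AD
target; monosynaptic connection fraction) and the binarized preference
(each distinct AD counted once) quantify how much multi-synaptic
innervation contributes to the preference.

Specificity between two seed groups is tested by a pooled-resampling
bootstrap: the groups are concatenated, resamples of the original group
sizes are drawn (the resampling unit is the axon, so category fractions
stay coupled), and the two-sided p-value is the fraction of resampled
mean differences at least as extreme as the observed one. Two-sidedness
is the conservative reading of "more extreme"; the +1 convention (adding
the observed statistic to the null set) is reported alongside as `pPlus`.
Cross-region consistency uses the coefficient of variation of per-region
means and a Wilks-lambda MANOVA over the six retained categories (AIS and
glia are excluded: they carry almost no synapses and make the covariance
singular), followed on rejection by Bonferroni-corrected one-way ANOVAs.

## What the synthetic generator emulates

`generatorConfig()` fixes the emulated study conditions:

* **Geometry** — a straight trunk from the soma (or from 60 µm below the
  bifurcation for deep-layer cells without a soma in the volume), a
  Y-bifurcation at 100 ± 10 µm below pia, two straight tuft branches,
  1 µm node spacing, spines as 1.5 µm labelled side branches. Marginal L2
  neurons get an oblique (75°) trunk.
* **Synapse placement** — independent Poisson processes along arc length.
  Main-bifurcation window rates (per µm shaft): L2 shaft 0.42 / spine
  0.84; deep layer 0.22 / 2.16; the L2 spine rate is a calibration choice
  placing the per-dendrite shaft-synapse fraction near its published
  value, not itself a published rate. Distal tuft rates are calibrated so
  the total putative-inhibitory fractions land at the published per-type
  values (e.g. L5tt distal 22.5%) after accounting for double-spine
  (6.4% L2 / 3.5% DL) and spine-neck (2% of spines) contributions. Along
  the trunk the total rate is held at the window total while the
  inhibitory share follows the exponential distance model
  `0.1 + 1.57·e^{−0.047·d}` (clamped to [0.02, 0.9]; the model exceeds 1
  below ~10 µm and is only meaningful over the observed distance range).
  Synapse events are inserted as *exact* skeleton nodes at their sampled
  arc positions, so windowed counts and clipped path lengths are
  consistent and density estimators are unbiased at window boundaries.
* **Axons** — output count Poisson(30) truncated at 6; each synapse
  targets an AD with probability 0.203; AD synapses form connections with
  multiplicities (77/16/5/2% for 1–4) and target the axon's own seed type
  with probability (1+s)/2, s = 0.548 so the AD-restricted own-type
  fraction sits at its published 77.4%; non-AD targets draw from a fixed
  category mix dominated by shafts and somata, as expected for inhibitory
  axons. Identity-mixing groups plant excitatory axons among shaft-seeded
  ones at configurable rates (0.44/0.60 for L5st in L1/L2 contexts).
* **L5 features** — two Gaussian clusters (7 thick-tufted, 11
  slender-tufted) separated in all four features; excitatory density
  follows `0.44·PC1 + 1.4` with 0.25 SD noise and the inhibitory density
  follows the published linear-fraction curve, making the regression
  recovery tests closed-loop.

What it does **not** emulate: realistic 3-D axon trajectories (axon output
is tabular), curved or branching trunks, annotation errors and human QC,
volume boundaries clipping dendrites mid-window, or overdispersed synapse
placement (a negative-binomial hook exists but is off by default).
Passing recovery tests therefore demonstrate that the estimators are
correct and calibrated under Poisson placement on idealized skeletons —
not that the biological conclusions would survive annotation noise.

## Numerical choices and degenerate inputs

* Windows are closed path-distance intervals; `c(-10, 10)` denotes
  "within 10 µm of the landmark" in unsigned arc distance. Binning
  elsewhere is half-open `[lo, hi)`.
* Spine-neck identification prefers explicit labels (node comments);
  a geometric fallback flags terminal branches under 3 µm bearing a
  synapse-tagged tip. Synapses on spine branches inherit the arc position
  of their attachment node.
* Multi-component trees are tolerated at parse time; operations needing
  connectivity fail with named errors.
* Deficient distance bins merge proximally first — a deterministic
  reading of "merged to their immediate neighbour" — and the merge
  provenance is recorded per reported bin.
* Zero shaft length, empty axon output lists, identical feature vectors,
  and sign-changing linear-fraction denominators raise errors instead of
  returning silent zeros.
* All randomness flows through explicit seeds; `runPipeline()` derives
  per-stage sub-seeds from the single run seed.

## Problem sizes

The shipped tests run the full published cohort sizes where they are
cheap (41+41 dendrites, 183 axons, 18 L5 cells, 81 distance points, 16
tuft branches; 100-seed medians for the regression recoveries) and scaled
-down cohorts (4–8 dendrites, a few hundred bootstrap resamples) for
pipeline smoke and determinism checks. The type-I-error simulation of the
specificity test uses 1000 replicates of 30-axon groups at 2000
resamples; coverage of the depth-profile bootstrap uses 120 replicates of
12 dendrites at 300 resamples.

## Worked example

```{r example, eval = FALSE}
cfg <- generatorConfig()
gen <- generateDendrites(cfg, c(L2 = 41, DL = 41), seed = 1)
ads <- extractDendrites(gen$annotation)
res <- lapply(ads, densityResult, window = c(-10, 10))
ct <- vapply(ads, cellType, character(1))
summarizeDensities(res[ct == "L2"])$summary

ax <- generateAxons(cfg, seed = 1)
conditionalMatrix(innervationProfile(ax$table))
```

## Known limitations

* The NML dialect covered is nodes/edges/comments plus retained unknown
  node attributes; branch-point and group elements are not modelled.
* Diameter estimation from node radii subsamples existing nodes rather
  than interpolating along the arc; explicit diameter samples are
  preferred when available.
* The diameter average is unweighted by local arc length (the weighting
  convention is not determined by the published description; the
  sensitivity is small at near-uniform sampling).
* `compareGroups()` follows Kruskal–Wallis with Tukey HSD on
  rank-transformed values, a pragmatic reading of "Tukey's honestly
  significant difference post-hoc test" after a rank-based omnibus.
* The L2/L3/L5 soma-depth boundaries are configuration, not data: real
  datasets require their own layer table.
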