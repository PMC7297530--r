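# apicalmap

Quantitative connectomic analysis of synaptic input to the apical
dendrites (ADs) of cortical pyramidal cells, from skeleton + synapse
annotations (webKnossos NML) to per-cell-type synapse densities,
inhibitory/excitatory balance, axonal target-preference statistics,
cell-type classification and distance-dependence model fits.

**Who it is for.** Connectomics groups annotating dense 3-D EM volumes at
the cortical layer 1/2 border — where nearly all pyramidal cells place
their AD's main bifurcation — who need a tested, reproducible pipeline
from raw skeleton annotations to the quantities that characterize
AD innervation, plus a synthetic-annotation generator with ground truth
for validating every estimator.

## The model in brief

Input synapses on an AD segment are classified structurally:

* **putative inhibitory** — synapses on the dendritic shaft, on spine
  necks, and secondary innervations of a spine,
* **excitatory** — primary spine innervations,

and summarized per dendrite as densities per µm of spine-pruned shaft
path length (and per µm² of surface area, `π·L·d̄`) and as the putative
inhibitory fraction *i/(i+e)*. The structural proxy is calibrated by
reconstructing presynaptic axons and classifying each by its
single-innervated-spine output fraction (strict majority > 50% ⇒
excitatory); per-structure excitatory fractions correct the shaft-synapse
counts where the proxy fails. Distance dependence of the inhibitory
fraction is modelled as a single-term exponential with offset
`I(d) = c + a·e^{b·d}`; L5 subtypes are separated by average-linkage
clustering (cosine distance chosen by cophenetic correlation) of four
morphological features, with "thick-tuftedness" as their first principal
component. Axonal AD-type selectivity is tested with a pooled-resampling
bootstrap over per-axon innervation fraction vectors, Bonferroni-corrected
over eight target categories.

## Worked example

Simulate the two main-bifurcation cohorts (41 layer-2 and 41 deep-layer
dendrites), quantify their ±10 µm windows, and inspect axonal target
preference:

```r
library(apicalmap)
cfg <- generatorConfig()

gen <- generateDendrites(cfg, c(L2 = 41, DL = 41), seed = 11)
ads <- extractDendrites(gen$annotation)
ct  <- vapply(ads, cellType, character(1))
res <- lapply(ads, densityResult, window = c(-10, 10))
s <- summarizeDensities(res[ct == "L2"])$summary
s[s$statistic %in% c("densShaftLen", "densSpineLen", "inhFraction"), ]
#>     statistic      mean        sem  n
#>  densShaftLen 0.4552846 0.02031626 41
#>  densSpineLen 0.8349593 0.02356882 41
#>   inhFraction 0.3879580 0.01281332 41
```

The layer-2 cohort realizes a shaft-synapse (putative inhibitory) density
of 0.46 ± 0.02 per µm and a spine-synapse density of 0.83 ± 0.02 per µm —
the sample means of 41 dendrites generated at rates 0.42 and 0.84 —
yielding a per-dendrite inhibitory fraction around 0.39 once spine-neck
and double-spine synapses are included.

```r
ax <- generateAxons(cfg, seed = 12)   # 92 L2- and 91 DL-seeded axons
cm <- conditionalMatrix(innervationProfile(ax$table))
cm$matrix
#>  seedType  n      L2_AD      DL_AD adFraction
#>        DL 91 0.05392405 0.15766858  0.2115926
#>        L2 92 0.15770063 0.04242913  0.2001298
cm$restricted
#>  seedType nADAxons   restrL2   restrDL
#>        DL       91 0.2559900 0.7440100
#>        L2       92 0.7943315 0.2056685
```

Each axon places about 20% of its output on ADs; restricted to AD
synapses, L2-seeded axons put ~79% of them on L2 ADs and DL-seeded axons
~74% on deep-layer ADs — the planted selectivity (own-type probability
77.4%) recovered from the simulated cohort.

Single noisy draws of the distance model scatter; the median fitted decay
rate over 100 simulated cohorts recovers the generating value:

```r
bs <- vapply(1:100, function(s) {
  d <- generateDistanceSamples(seed = 1000 + s)
  unname(fitExponential(d$distance, d$fraction)$params["b"])
}, numeric(1))
median(bs)
#> [1] -0.04603125
```

`runPipeline(seed = 1)` chains all stages (simulate → quantify → axons →
classify → fit) into one deterministic run and can write every result
table as TSV.

See `vignettes/apicalmap-methods.Rmd` for the full account of the models,
parameter choices and limitations.

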