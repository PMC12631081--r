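# panHRD

Aggregated homologous-recombination-deficiency (HRD) scoring and an
explainable multi-omics model that learns the score back from somatic
data.

HRD tumors — classically those with *BRCA1/2* loss — respond to PARP
inhibitors and platinum agents, but clinical HRD testing reads only a
narrow set of markers. A broader, quantitative readout comes from the
mutational footprints HRD leaves genome-wide: the single-base
substitution signature SBS3, the indel signature ID6, the copy-number
signature CN17 (with CN1 anti-correlated), and the scarHRD index
(LOH + LST + TAI counts). This package is for computational cancer
genomicists who want that readout, and the machinery around it, as
tested, reusable components.

## What it computes

**panHRD score.** For sample *i* of tumor type *t*, with normalized
exposures \(\hat E_{k,i}\) of the four HRD channels
(SBS3 proportion, ID6 proportion, combined CN channel
\(((1-\hat E_{CN1}) + \hat E_{CN17})/2\), max-normalized scarHRD):

\[ s_{t,i} = \sum_{k=1}^{4} \hat w_{k,t}(\varepsilon)\, \hat E_{k,i},
\qquad
w_{k,t}(\varepsilon) = \frac{1}{G_t} \sum_{i \in t}
\mathbf{1}\{\hat E_{k,i} \ge \varepsilon\}, \]

with the weights \(\hat w\) rescaled to sum to 1 per tumor type and
\(\varepsilon = 0.1\) by default. Scores live in [0, 1] and are
discretized at the cohort median.

**Prediction pipeline.** Copy number, expression, methylation and
protein-altering mutation counts are transformed
(`log2(1 + x/2)`, `log(1 + x)`), screened per layer by an all-relevant
shadow-feature (Boruta-style) selection against the panHRD target,
z-scaled on training rows, and fed to a cross-validation-tuned
gradient-boosted tree regression. Interpretation uses exact TreeSHAP
attributions: global importance, per-tumor SHAP/feature correlation
heatmaps with bootstrap-supported clustering, top-N feature ablation,
and waterfall exports. Feature ranks
\( \mathrm{rank}_v = \mathrm{corr}(\mathrm{shap}_v, \mathrm{value}_v)
\cdot 10^{\mathrm{importance}_v} \) feed a from-scratch preranked GSEA.

A seeded synthetic-cohort generator with a known latent HRD level stands
in for protected patient data, so every stage has a parameter-recovery
test.

## Worked example

```r
library(panHRD)

cfg <- syntheticConfig(nSamples = 400,
                       nGenesPerLayer = c(CNV = 60, EXP = 60, MET = 60, MUT = 60),
                       nInformativePerLayer = c(CNV = 6, EXP = 6, MET = 6, MUT = 6),
                       seed = 42)
cohort <- generateCohort(cfg)
scores <- discretizeByMedian(panhrdScores(cohort$exposures))
scores
#> ScoreResult: 400 panHRD scores (epsilon = 0.1)
#>   range: 0.2455 .. 0.7352
#>   discretized at cutoff 0.3426 -> 200 HRD-positive
```

The cutoff is the cohort median; half the cohort is HRD-positive by
construction, and the score range reflects how strongly the four
normalized channels co-vary with the latent deficient/proficient
mixture the generator plants.

The orchestrator runs every stage (it re-derives its own generator seed
from the global one, so its cohort differs from the one above):

```r
man <- runPanHRD(pipelineConfig(synthetic = cfg,
                                borutaMaxIter = 25L, searchDraws = 2L,
                                bootstrapB = 30L, nPerm = 100L,
                                seed = 42),
                 outDir = "panhrd-run")
str(man$metrics)
#> List of 5
#>  $ medianPanHRD     : num 0.358
#>  $ r2               : num 0.781
#>  $ auc              : num 0.951
#>  $ kappa            : num 0.724
#>  $ confirmedFeatures: int 24
```

Read: the shadow-feature race kept 24 of 240 genes (the generator
planted 24 informative ones); on the held-out 20% the model explains
78% of the variance of the true panHRD score and separates
median-thresholded HRD status with AUC 0.95 and kappa 0.72. All
intermediate artifacts (scores, selection summary, SHAP matrix,
correlation heatmap, dendrogram, ablation curve, enrichment table) are
TSVs under `outDir`, with md5 checksums in `manifest.json`.

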