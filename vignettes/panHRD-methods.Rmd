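---
title: "panHRD: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{panHRD: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Homologous recombination deficiency (HRD) — the loss of faithful
double-strand-break repair, classically through *BRCA1/2* inactivation —
leaves characteristic genome-wide scars: the flat single-base-substitution
signature SBS3, the indel signature ID6, the copy-number signature CN17,
and elevated counts of LOH segments, large-scale state transitions and
telomeric allelic imbalance (the scarHRD index, their unweighted sum).
panHRD aggregates these exposures into a single per-sample score in
[0, 1], then treats that score as a quantitative phenotype to be predicted
from four somatic omics layers — gene-level copy number, expression,
methylation and protein-altering mutation counts — so that the fitted
model's attributions can point at genes associated with the HRD state.

## The aggregated score

For each exposure class the package first puts samples on a common scale:

* SBS, ID and CN exposures are divided by the sample's total exposure in
  that class, so each biomarker is the proportion of the sample's
  mutational load it explains;
* scarHRD, a single non-negative index, is divided by the cohort-wide
  maximum.

CN1 (a diploid-like background signature) anti-correlates strongly with
CN17, so the two are folded into one channel,
$\hat{E}_{CN} = ((1-\hat{E}_{CN1}) + \hat{E}_{CN17})/2$.

Tumor types differ wildly in how often they show any HRD signal, so each
channel is weighted per tumor type by the fraction of that tumor's
samples whose normalized exposure reaches a threshold
$\varepsilon$ (inclusive; default 0.1). The four weights of each tumor
are rescaled to sum to one, and the score is the weighted sum of the four
channels. Two conventions the equations leave open are fixed here: a
sample with zero total exposure in a class contributes 0 for that class,
and a tumor type whose four raw weights are all zero falls back to
uniform weights (with a warning) rather than producing undefined scores.
Both choices keep every score inside [0, 1], which the tests assert on
randomized cohorts. Weights are computed on whichever cohort is passed
(an explicit `weights` argument supports train-only weighting).

Scores are discretized at the cohort median with a strict `>` rule, so
ties at the cutoff land in the HRD-negative half; an external cutoff can
be supplied for subsets.

## The synthetic cohort

The generator exists so that every downstream stage has a
parameter-recovery test with known ground truth; it emulates the
statistical shape of a pan-cancer multi-omics cohort, not its biology.
A latent HRD level per sample is drawn from a two-component Beta mixture
(Beta(2, 8) proficient vs Beta(8, 2) deficient, mixing weight 0.35),
giving the bimodal deficient/proficient structure that makes a median
cutoff meaningful. Exposures are Gamma-distributed (non-negative and
overdispersed, like NMF exposure estimates): background signatures use
shape 2; the planted channels (SBS3, ID6, CN17, scarHRD increasing in
the latent level, CN1 decreasing) use shape 12, a coefficient of
variation of about 0.29, chosen once at design time so the aggregated
score tracks the latent level closely (correlation ≈ 0.92 at n = 1000)
while remaining clearly noisy. Omics layers plant the same latent signal
in a configurable number of genes: copy number is Gaussian around the
diploid score 2 with an additive latent shift, expression is log-normal
with a shifted log-mean, methylation is Beta-distributed with a shifted
mean (precision 20, so values stay strictly inside [0, 1]), and
mutations are Poisson with a latent-scaled rate.

Defaults are desk-scale study conditions: 2,000 samples, 3 tumor types,
300 genes per layer with 10 informative each, effect size 2, noise SD
0.5. What the generator does **not** emulate: realistic trinucleotide
catalogs, signature-deconvolution uncertainty, inter-gene correlation
structure, batch effects, or tumor-type-specific marginals. Passing
recovery tests therefore demonstrates that the pipeline's machinery is
correct and well-calibrated, not that real-cohort performance figures
transfer.

## Preprocessing

Expression is transformed with natural `log(1 + x)` (the log base is a
convention; tree models are invariant to monotone rescaling), copy
number with `log2(1 + x/2)` so diploid maps to 1, methylation and
mutation counts pass through. Only HIGH/MODERATE-impact mutations are
counted. Features are z-scaled with mean and sample SD (n − 1) computed
on training rows only and applied to all rows; constant training columns
scale to 0 with a warning. Samples missing an entire layer are retained
with missing values rather than dropped, because the boosted-tree
learner routes missing values through learned default directions.

## Feature selection

Selection is the all-relevant shadow-feature race: each iteration
appends a shuffled copy of every feature, fits a random-forest regressor
(100 trees, depth capped at 8, impurity importance), and scores a hit
for each real feature whose importance beats the best shadow. Hits are
tested two-sided against Binomial(iterations, 0.5) with Bonferroni
correction at level 0.01, confirming persistent winners and rejecting
persistent losers; undecided features after `maxIterations` are
tentative and excluded from the model by default.

Two design points deserve a note. First, shadows are drawn from **all**
original features in every iteration even after real features are
rejected. Shrinking the shadow ensemble alongside the rejected features
looks economical but quietly weakens the null: once only a handful of
shadows remain, a noise feature whose sample-specific spurious
correlation happens to be large beats the shadow maximum in most
iterations and is eventually confirmed. With the full shadow ensemble
the strongest noise feature faces an equally extreme fresh shadow
maximum each round and stalls near a 50% hit rate. Second, the
Bonferroni scope is the constant count of presented features, not the
shrinking set of still-active ones — the shrinking scope relaxes the
test exactly when the race is most selection-biased. Even so, an
extremely persistent spurious winner is occasionally confirmed under a
pure-noise target; the null simulations in the test suite quantify this
at roughly one affected replicate in twenty.

## Model

Samples are split 80/20 stratified by tumor type (singleton tumors go to
training). Hyperparameters are tuned by 5-fold cross-validation
minimizing RMSE over a random search (learning rate log-uniform on
0.01–0.3, depth 3–8, min child weight 1–10, row/column subsampling
0.6–1, boosting rounds by early stopping up to 1,000); ties break toward
fewer rounds, then the earlier candidate. The final squared-error model
is fit on the full training set. Evaluation reports R² and RMSE on the
continuous score and, after thresholding the *true* score at the cohort
median, AUC (rank statistic on the predicted score), Cohen's kappa
(same cutoff applied to predictions), sensitivity, specificity and
precision, plus a per-tumor breakdown; single-class strata report a
missing AUC with a warning.

Leakage is treated as a testable property: scaling statistics, fold
assignment and tuning are functions of training rows only, and the suite
asserts that perturbing test rows changes none of them. Selection runs
on training samples by default (`sampleSubset`), with full-cohort
selection available explicitly.

## Explanation

SHAP values come from the exact tree-path algorithm on the raw margin
scale, where additivity (row sum + base value = prediction) is exact up
to float error; the suite also checks a single depth-2 tree against
brute-force Shapley coalition enumeration. Global importance is the mean
absolute SHAP value. The per-tumor heatmap correlates feature values
with SHAP values within each tumor type (Pearson by default, Spearman by
flag; constant columns are missing, not zero; tumors under 3 samples are
flagged missing). Rows are clustered (average linkage, Euclidean
distance, missing entries imputed by column median) and node support is
the ordinary bootstrap proportion over column resamples — deliberately
not a multiscale-bootstrap AU p-value, which approximates a different
quantity. Top-N ablation masks all but the N most important features
with the missing marker and re-predicts with the same model, so N = all
is bit-identical to the full model and features the trees never use
change nothing.

## Enrichment

Features are ranked by `corr(shap, value) * 10^importance`. The printed
form of this statistic is typographically ambiguous (a lost superscript
would read `corr * 10 * importance`); the exponent reading is the
default because it scales the rank multiplicatively with importance, and
the linear reading is available via `reading = "linear"`. Preranked GSEA
is implemented directly: the classic weighted Kolmogorov–Smirnov running
sum (weight exponent 1 on |rank|; 0 gives the unweighted statistic used
in scale-invariance tests), a null of random same-size gene sets,
sign-stratified permutation p-values with the `(1 + k)/(1 + n)` floor,
NES as ES over the mean same-sign null magnitude, and BH adjustment
across sets. A set spanning the whole universe has no misses to balance
the running sum and is assigned ES 0 by convention. Collection
membership is partitioned UpSet-style with an exclusive Complementary
bucket, and per-tumor score-vs-mutation-carrier associations use the
two-sided Mann–Whitney test with BH adjustment across tumors, skipping
groups under 3 samples.

## Numerical and scale choices

The default test-suite problem sizes — 200–600-sample cohorts for
property checks, one 2,000-sample default cohort for end-to-end
recovery, 100–1,000 randomized cohorts for invariants, 20 replicates
for null calibration — are the package's chosen desk-scale study
conditions and run in minutes on one CPU. The pipeline orchestrator
(`runPanHRD()`) derives per-stage seeds deterministically from one
global seed and writes every artifact with an md5 manifest, so a rerun
under the same config is bit-identical. All stochastic components
(generator, shuffles, forests, boosting, permutations, bootstraps) are
seeded; xgboost and ranger run single-threaded for reproducibility.

## Known limitations

The generator's independence assumptions (genes independent given the
latent level, tumor labels independent of the latent level) are
simplifications; real cohorts confound tumor type with HRD prevalence,
which is exactly what the per-tumor weight rescaling is for but which
the synthetic recovery tests exercise only mildly. Impurity importance
is used inside the selection race for speed and is known to favor
high-cardinality features; permutation importance would be the
conservative alternative on real data. The shadow race retains a small,
quantified false-confirmation rate for extreme spurious correlates.
Enrichment p-values use plain permutation and are floored at
`1/(nPerm+1)`; very small p-values require proportionally many
permutations.
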