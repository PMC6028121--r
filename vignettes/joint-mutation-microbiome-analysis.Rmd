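---
title: "Predicting tumor mutational features from the tumor-adjacent microbiome"
author: "micromut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting tumor mutational features from the tumor-adjacent microbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micromut)
```

## The problem

Colorectal tumors carry heterogeneous somatic mutational profiles, and the
microbial community living on the tumor surface varies between patients.
`micromut` asks whether those two layers are statistically coupled: can the
composition of the tumor-adjacent microbiome predict which genes or pathways
harbour loss-of-function (LoF) mutations in the underlying tumor, or the
tumor's stage group? The package implements the full joint-analysis chain —
from raw OTU tables and per-mutation annotation records to
permutation-tested classifiers and mutation-conditioned co-occurrence
networks — and ships a synthetic-data generator so every stage can be
validated end to end against planted ground truth.

The host side of the analysis is a binary feature matrix: a gene is
"mutated" in a sample if at least one qualifying somatic variant hits it.
Variant annotations are collapsed into three nested scopes: *total* (all
variants), *missense* (amino-acid substitutions) and *lof* (premature stop
gain, stop loss, frameshift). Gene calls are lifted to KEGG and PID pathways
by logical OR over member genes, using a three-column identifier-mapping
file, and features are prevalence-filtered (by default, mutated in at least
10 of 44 patients) to bound the number of hypotheses. Possible confounding
between mutation status and stage group (stages 1–2 versus 3–4) is checked
per feature with a two-sided Fisher's exact test plus Benjamini–Hochberg
correction.

## The discriminant screen

For one binary contrast (mutated vs wildtype tumors, or low vs high stage),
taxa that separate the two classes are found with a two-stage screen in the
style of LDA effect-size biomarker discovery:

1. **Kruskal–Wallis screen.** Each taxon's relative abundances are tested
   between the two classes with the tie-corrected Kruskal–Wallis statistic
   (equivalent to a Wilcoxon rank-sum test for two groups) under the
   chi-square(1) approximation; taxa with `p < kwAlpha` (default 0.05) pass.
   Constant taxa get `p = 1`. The in-package implementation is vectorised
   C++ (it sits inside a permutation loop; see *Performance*) and is tested
   to agree with `stats::kruskal.test` to 1e-12.

2. **Bootstrapped LDA effect size.** On the screened taxa jointly, a
   one-dimensional Fisher discriminant is fitted in each of `nBootstrap`
   (default 30) subsamples drawing `bootstrapFraction` (default 2/3) of each
   class without replacement. The pooled within-class covariance gets a
   small relative ridge (`ridge`, default 1e-6 of the mean diagonal) so that
   collinear compositional features and degenerate subsamples never abort a
   fit; the fallback for a still-singular system adds a near-diagonal
   regulariser and is counted. Per taxon the effect size is the bootstrap
   mean of
   `(|w_t (mu1 - mu0) . w| + |mu1_t - mu0_t|) / 2`
   (`w` the unit discriminant vector), i.e. the average of the taxon's
   contribution to the projected class separation and its raw class-mean
   difference. The reported score is `log10(1 + scaling * effect)` with
   `scaling = 1e6`, which maps proportion-scale effects onto the
   conventional "counts per million" log10 scale; taxa scoring at or above
   `ldaThreshold = 2` are selected, signed by the class with the larger raw
   mean. The threshold is the conventional "log10 LDA score of at least 2";
   the scaling factor is config-exposed so per-million-rescaled inputs
   behave identically.

The selection is deterministic given a seed. Bootstrap subsampling iterates
the two classes in order of first sample occurrence, which makes the RNG
stream — and therefore the selected set and its scores — bit-identical
under relabelling of the classes (only the enrichment signs flip).

## The risk index and its significance

The classifier is deliberately simple: the per-sample **risk index** is the
unweighted sum of arcsine-square-root transformed relative abundances of
taxa enriched in the target class minus the same sum for taxa enriched in
the reference class. The unweighted sum, rather than the LDA coefficients,
keeps the model rigid enough for 44-sample training sets. By construction
`|RI| <= (pi/2) * n_taxa`, and swapping the two taxon sets negates every
index exactly (the implementation accumulates the two sums separately so
the antisymmetry is IEEE-exact).

Out-of-sample behaviour is estimated by **leave-one-out**: for each of the
`n` samples, the entire screen is re-run on the other `n - 1` samples, a
risk model is built, and the held-out sample is scored. Folds whose model
is empty yield missing indices (excluded pairwise downstream); a run with
more than 20% empty folds aborts with a diagnostic, since the labels are
then uninformative for these taxa. Separation of the held-out indices is
summarised by a two-sided Mann–Whitney U test and by the difference in
class means.

Significance is assessed against a **label-permutation null**: the class
labels are permuted `B` times (999 in production use; the calibration
experiments below use 99) and the *complete* leave-one-out pipeline —
including per-fold taxon reselection — is re-run on each permutation. The
empirical p-value uses the add-one convention
`(1 + #{|diff_perm| >= |diff_obs|}) / (B + 1)`, so it is valid and floored
at `1/(B+1)`. The test is two-sided on the absolute mean difference because
the direction of a microbiome shift is not prespecified per feature. A
documented `fastMode` selects taxa once per permutation without the inner
leave-one-out; it is an order of magnitude cheaper but optimistically
biased, and is intended for smoke tests only. Across features, p-values are
Benjamini–Hochberg corrected within each family (genes, KEGG pathways, PID
pathways are separate families in production use; the pipeline corrects
within one run).

### Why the permutation test, not the Mann–Whitney p, carries the inference

The leave-one-out scheme protects each held-out *score* from leakage, but
the *collection* of held-out scores is not exchangeable under the null:
each fold re-selects taxa on labels that are almost the full label vector,
so fold models are correlated with the labels and with each other. Treating
the held-out indices as i.i.d. samples — as the Mann–Whitney test does —
is therefore anticonservative. This is measurable: on null synthetic data
(no planted shifts) the Mann–Whitney p-values on leave-one-out indices
have mean ≈ 0.3 rather than 0.5 and fail a Kolmogorov–Smirnov test against
uniformity decisively. The package still reports the Mann–Whitney p (it is
the conventional descriptive statistic), but calibrated inference comes
from the permutation p, whose null *replicates* the reselection bias: the
acceptance suite verifies that the fraction of null features with
`perm_p < 0.05` stays inside the binomial 95% band around 0.05. The same
reselection bias inflates cross-validated ROC summaries built from
fold-local curves (below).

## Evaluation

ROC analysis uses stratified 10-fold cross-validation: taxa and model are
re-trained on nine folds, the held-out fold is scored, a fold-local ROC
curve is computed, and the fold curves are vertically averaged on a fixed
false-positive-rate grid (the behaviour of the conventional ROC plotting
packages); the headline AUC is the trapezoidal area under the mean curve,
and the rank-statistic AUC of the pooled held-out scores is also reported
(`U/(n1 n2)`, ties at 1/2 — verified against O(n²) pair counting). With
only ~4 samples per fold the interpolated mean curve is upward-biased under
the null (mean ≈ 0.65 across null seeds, versus 0.51 for the pooled AUC);
the pooled AUC is the summary to trust at this cohort size, and the mean
curve is kept for comparability with the conventional presentation. Folds
are stratified by class with a seeded shuffle because unstratified folds on
44 imbalanced samples frequently lose a class; `k` is configurable, with
`k = n` giving leave-one-out.

Operating points come in two flavours: the smallest cutoff whose
specificity reaches a required level (default 80%), reporting accuracy and
sensitivity there (checked against an exhaustive grid search), and a
leave-one-out refined optimal cutoff, where each fold chooses the cutoff
maximising training accuracy — ties resolved deterministically by the
midpoint of the tied cutoff interval — classifies its held-out sample, and
the aggregate held-out sensitivity/specificity/accuracy are reported.

## Mutation-conditioned SparCC networks

Co-occurrence among the discriminant taxa is inferred separately for the
mutated and wildtype strata with a from-scratch SparCC implementation:
per Dirichlet resample (counts + 1 prior, 20 resamples), all pairwise
log-ratio variances `t_ij = var(log x_i / x_j)` are computed, the linear
system for basis variances is solved, correlations
`r_ij = (w_i² + w_j² − t_ij) / (2 w_i w_j)` are clipped to [−1, 1], and the
most correlated pair above 0.1 is iteratively excluded from the system (up
to 10 iterations, never leaving a taxon with fewer than two partners); the
final estimate is the element-wise median across resamples. Negative basis
variances — which occur for small taxon sets — are clipped to the smallest
positive basis variance rather than an absolute epsilon, so correlations do
not saturate at ±1. Pseudo p-values come from 100 shuffled datasets (each
taxon's counts permuted independently, destroying correlation while
preserving marginals) with the same add-one convention as above; each
stratum gets its own shuffle null. Displayed edges require `|r| >= 0.25`
and `p <= 0.05`; node weights are mean relative abundances in the stratum,
and networks serialise to edge-list TSV and GraphML. The system is
underdetermined below 4 taxa, which is an error. Because the Dirichlet
resampling consumes a sequential RNG stream, reordering taxa changes the
draws: taxon-permutation equivariance holds statistically (to resampling
noise), not bit-exactly.

Calibration at `n = 200`, 10 taxa: independent log-normal bases give median
off-diagonal `|r|` ≈ 0.03; a planted basis correlation of 0.8 is recovered
within ±0.15, with recovery error shrinking from `n = 50` to `n = 500`.
Small strata are honest but noisy: at 8 taxa and 18 samples the shuffle
null of `|r|` reaches 0.88, so differential networks need reasonably sized
strata (the tests use 40 samples per stratum).

## Robustness linear models

As an orthogonal check on the discriminant pipeline, each taxon passing the
conventional prevalence/abundance filters (non-zero in ≥ 5 tumors, mean
relative abundance ≥ 0.001) is fitted with ordinary least squares:
arcsine-square-root abundance on feature status plus age and sex, two-sided
t-test on the feature coefficient, Benjamini–Hochberg over taxa. This is a
plain covariate-adjusted per-taxon linear model, not a reimplementation of
any boosting-based multivariate association tool; the transform is
config-exposed because variance-stabilising conventions differ between
tools. Constant taxa get coefficient 0 and `p = 1`; rank-deficient designs
are skipped with a diagnostic; rows with missing covariates are dropped per
taxon with the used sample count reported. `concordance()` counts features
significant under both the permutation-tested risk index and the linear
models.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
at the cohort's scale:

* **44 tumor samples** and **300 taxa** by default, with a single
  log-normal base composition (`sdlog = 2`, giving the realistic regime of
  a few dominant and many rare taxa) shared by all samples;
* **mean depth 120,000 reads** per sample (Poisson-distributed), matching
  the order of magnitude of quality-filtered 16S runs on tissue samples;
* **Dirichlet-multinomial counts** with concentration
  `overdispersion × proportions` (default 200, a moderate 16S
  overdispersion; `Inf` recovers plain multinomial sampling);
* **binary mutation features** at prevalence 0.5, resampled until both
  classes are non-empty, with optional controlled Jaccard overlap between
  features to emulate co-mutation;
* **planted multiplicative shifts**: for positive-labelled samples the
  planted taxa are multiplied by their fold change *before* renormalization,
  so boosting one taxon depresses the rest — the compositional coupling
  real data have. The default plant is 5 taxa at 4-fold, drawn from
  abundance ranks 11–40 of the realised base so the planted signal sits in
  the moderately abundant range the screen targets (rare planted taxa at
  this depth would be undetectable by any method and test nothing).

Everything is deterministic given one integer seed, and `generateDataset()`
emits a truth table for recovery experiments. What the generator does *not*
emulate: phylogenetic correlation between taxa, paired tumor/normal
structure, batch effects, or abundance-dependent sequencing bias — so a
passing recovery experiment demonstrates the statistical machinery, not
robustness to those real-data complications.

## Numerical and design choices

* Proportions are validated to `[0, 1]` with a 1e-12 clip tolerance before
  the arcsine transform; normalized tables must have column sums within
  1e-9 of 1 (taxon subsets of a normalized table keep their proportions
  relative to the original whole, so sums may fall below 1).
* Lineage strings are compared on stripped rank tokens, so spaced
  (`k__Bacteria; p__...`) and unspaced dialects match; collapsing to a rank
  conserves per-sample totals exactly for integer counts; lineages
  shallower than the requested rank fall into explicit unclassified
  buckets.
* The empirical p-value convention is add-one throughout (permutation test
  and SparCC pseudo p-values).
* Stage-missing samples are excluded from stage analyses but retained for
  mutation analyses; metadata readers keep explicit `NA`s rather than
  dropping samples.
* Pathway membership matches ENSEMBL gene ids when present, falling back
  to symbols; mapping misses are reported, never fatal.
* The Kruskal–Wallis chi-square approximation is compared against full
  permutation enumeration at `n = 4 + 4` in the rejection region, where its
  error is < 0.02; mid-range p-values at that sample size are approximated
  more coarsely, which does not affect screening decisions.
* Permutation loops run sequentially with per-permutation child seeds drawn
  from the master seed, so results are independent of any worker count; the
  C++ engine makes parallelism unnecessary at this problem size.

## Performance and problem sizes

The permutation test re-runs the full leave-one-out selection `B` times,
i.e. `B × n` discriminant fits; at the default conditions that is ~4,400
fits per feature. The screen and LDA bootstrap are therefore implemented in
C++ (RcppArmadillo), giving roughly 100 µs per fold at 300 taxa. The
validation experiments use: 40 null features × B = 99 for permutation
calibration (~6 min), 20 seeds × B = 99 for planted-effect power (~3 min),
50 replicates for the Mann–Whitney calibration check, and `n = 200`,
10 taxa for SparCC calibration. Production analyses with `B = 999` scale
linearly.

## Known limitations

* The Mann–Whitney p on leave-one-out indices is anticonservative (see
  above); use the permutation p for inference.
* The vertically averaged 10-fold ROC curve is optimistic at 44 samples;
  prefer the pooled AUC.
* Exact reproduction of any particular published taxon list additionally
  depends on the upstream OTU pipeline and on unstated screening seeds;
  the package promises threshold-level behaviour, which is what the
  synthetic recovery experiments check.
* SparCC estimates on fewer than ~10 taxa or ~20 samples per stratum are
  noisy; the preconditions enforce only the hard identifiability limit
  (4 taxa, 4 samples), so judge small-stratum networks accordingly.
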