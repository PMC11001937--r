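---
title: "Models and methods behind triomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind triomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`triomics` analyses three-generation gut multi-omics cohorts: untargeted
fecal metabolomics acquired in pooled-QC batches, genus-level taxa tables,
and KO functional profiles. This vignette explains the models the package
fits, the choices behind their defaults, and what the synthetic cohort
generator does and does not emulate.

## The batch problem and the QC strategy

A cohort of ~200 fecal samples cannot be measured in one GC-MS sequence.
The package assumes the standard design: the cohort is split into batches
(here one generation per batch), a pooled QC sample — an aliquot of a pool
drawn from all groups — is injected at the start of each batch (equilibrium
QCs, used only to condition the instrument) and then every 9–10 study
samples (interspersed QCs), and blank preparations capture reagent
background. Because every QC injection is chemically identical, any
systematic change in its signal is instrumental, and can be removed.

### QC-SVRC (intra-batch)

For each feature and batch, the interspersed-QC intensities are regressed
on injection order with a radial-basis support-vector regression; every
intensity in the batch is then divided by the fitted curve relative to the
batch QC median. The drift model is multiplicative: MS response changes
(detector fouling, derivatization ageing) scale the signal rather than
shift it, so division is the natural correction (subtraction is the other
defensible reading; we document division as our interpretation).

Hyperparameters are not free: cost is chosen from {1, 10, 100} and the
epsilon tube from {0.02, 0.1} × MAD of the (reference-scaled) QC
intensities, by leave-one-QC-out squared error; the kernel width is fixed
at γ = 1 on the order axis normalized to [0, 1]. With only eight QCs per
batch a larger grid mostly fits noise; the grid covers the qualitative
regimes (stiff-to-interpolating) while leave-one-out guards against
chasing single QCs. A fitted curve must stay strictly positive across the
batch; otherwise the feature falls back to a flat batch-median model and
is flagged. Predictions outside the QC span are clamped to the nearest
edge, so early study injections (before the first interspersed QC) are
corrected with the nearest anchor rather than an extrapolation.

### QC-Norm (inter-batch)

After the batches are fused, each feature is scaled per batch by
(grand median of all interspersed-QC intensities) / (batch QC median).
Medians rather than means keep single outlying QCs from steering the
scale. By construction the per-feature QC medians agree across batches
afterwards; features whose batch QC median is non-positive cannot be
scaled and are excluded with a flag.

### QA filters and their order

Standalone QA (`qa_pipeline()`) runs blank subtraction (a feature is
background if its mean study signal is below 3× its mean blank signal —
the factor is a convention, exposed as `blank_ratio`), then the presence
filter, then the QC-RSD filter, each per batch with "pass in at least one
batch" semantics. The presence rule is read conjunctively: a feature is
kept when it appears in ≥50% of QCs **and** ≥70% of study samples (the
disjunctive reading is available as `mode = "or"`). "Appears" means
non-missing and positive; equilibrium QCs are excluded from every QC
statistic.

The full pipeline (`run_pipeline()`) applies blank and presence filters
before normalization but re-applies the RSD gate *after* QC-SVRC +
QC-Norm, and carries the post-normalization survivors forward. Drift
inflates QC RSD for reasons the correction removes; filtering only before
normalization would discard rescuable features. Both counts are reported,
so the rescue is visible (the all-batch pass count strictly grows on
drifted data).

## Chemometric models

PCA is computed by SVD of the centered, UV-scaled (mean 0, SD 1 per
feature) matrix, with per-component explained-variance fractions R².
PLS-DA uses NIPALS on a dummy-coded class matrix; predictive ability is
Q² = 1 − PRESS/TSS under stratified venetian-blind cross-validation with
7 folds by default (the fold count for the single-omics models is not a
given of the design; 7 is the common chemometrics default, and `folds = n`
gives exact leave-one-out). Centering and scaling are re-estimated inside
every training fold, so Q² is honest. Component signs are fixed
(largest-magnitude loading positive) for run-to-run determinism. A
QC-dispersion ratio — mean squared distance of QC scores to their
centroid over the same for study samples — quantifies the "QCs cluster
tightly" criterion on any score plot.

## Mixed models

Each feature is modelled as

`value = mu + generation + (1 | family) + error`

fitted by REML with `lme4`. Family is the random intercept because the
three generations of one family share genetics and environment; ignoring
it would treat 3 correlated samples as independent. The overall generation
effect is a likelihood-ratio test of maximum-likelihood fits against the
intercept-only model; the three pairwise contrasts are Wald tests with
Satterthwaite degrees of freedom. Singular fits (family variance at zero)
are legitimate boundary estimates and are flagged, not dropped — in that
regime the estimates coincide with ordinary least squares, which the test
suite verifies. BH FDR is applied per contrast across features at 0.05.
Functional (KO / BRITE) tables use an ordinary linear model per column
with BH adjustment at a 0.10 ceiling, on TMM-normalized abundances —
normalized counts rather than proportions, since TMM factors are defined
against effective library sizes.

Metabolite responses enter the model as produced by the normalization
pipeline, without further transformation, matching the convention that
multivariate and univariate models run on UV-scaled / untransformed data
respectively.

## Ecology, functional profiles, associations

Richness is the number of taxa with positive count (no rarefaction —
kept deliberately simple; library sizes are generated narrow). Shannon
diversity uses the natural logarithm, the ecology default. Minor-taxon
lumping for stacked-bar displays collapses a taxon only when its
group-mean relative abundance is below the cut in **all** groups (0.1%
for phyla, 2% for genera); group means of per-sample proportions are used
rather than pooled counts so large libraries cannot dominate a group.

TMM normalization delegates to edgeR's canonical implementation (30%
trim on log-ratios, 5% on abundance, precision weights, upper-quartile
reference); the test suite checks it against a literal transcription of
the trimmed-mean formula. BRITE aggregation sums member KOs; a KO mapped
to several level-C pathways contributes to each, with the duplicated mass
reported so totals reconcile.

Spearman correlations use mid-ranks; for n ≤ 9 the p-value is the exact
permutation tail of rho (ties handled naturally), otherwise the
t-approximation. Pathway over-representation is the hypergeometric upper
tail P(X ≥ k). The background universe is the set of measured, annotated
metabolites — the standard ORA choice; a whole-reference-metabolome
universe can be supplied explicitly via the `universe` argument.
Correlations are pooled across generations (one coefficient per pair),
matching how a single rho per producer–metabolite pair is usually
reported. Topology-weighted pathway scoring is out of scope: it requires
pathway graph structures this package does not ship.

## Multiblock sparse PLS-DA

The integration model seeks, per component, one loading vector per omics
block maximizing the design-weighted sum of covariances among block
scores and the score of the (centered, scaled) class-indicator matrix.
The default design is fully connected with weight 1 — with three blocks
that all discriminate the same phenotype there is no basis for
down-weighting any pair, and the design is exposed as a configuration
matrix for users who have one. Sparsity retains exactly `keepX` (default
25) largest-magnitude entries per block, soft-thresholded at the
(keepX+1)-th magnitude; ties at the threshold resolve by variable order,
so "top 25" is reproducible. Convergence is declared when the largest
loading change drops below 1e-6 (at most 500 alternating iterations;
non-convergence is an error, not a warning). Blocks are deflated by their
own scores, making successive scores orthogonal within a block. Signs are
anchored on block 1 and the remaining blocks aligned to correlate
positively with it, so cross-block score correlations are reported on a
consistent orientation.

Performance is stratified 5-fold cross-validation repeated 10 times;
each block votes by nearest training-class centroid in score space and
the majority wins (ties by smallest mean distance). Per-block one-vs-all
AUROC scores samples along the direction from rest-centroid to
class-centroid and computes the mid-rank Mann–Whitney statistic. The
similarity matrix behind circos displays is the component-sum of products
of variable–score correlations against the averaged block-pair scores,
thresholded at |0.65|; the clustered image map uses Euclidean distance
with complete linkage on both axes, with rows and columns pre-sorted by
id so equal-height merges are reproducible.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults are the study
conditions the rest of the package is validated under. Intensities are
log-normal; generation effects, family intercepts (SD 0.3) and residuals
(SD 0.4) are additive on the log scale. Drift is multiplicative per
feature and batch: amplitude drawn from ±[0.3, 0.8], shape a random mix
of a linear ramp and a half-cosine, so it is always positive, smooth and
slow — the regime QC-SVRC targets. Analytical noise has 2% CV. QC
injections carry the pooled mean of the generation levels, times drift,
batch factor and noise; blanks carry background only, on a designated
contaminant subset (which gives blank subtraction an exact target the
tests check). Missingness is left-censoring below a per-feature detection
limit (on generic features only — the named fatty-acid/amine panel is
generated well above detection, as those abundant metabolites are in
practice) plus the implied dropout. Acetate's base level is set an order
of magnitude above the other SCFAs, reflecting its dominance of the fecal
SCFA pool; this also makes the SCFA/BCFA ratio contrast robust. Taxa are
Dirichlet-multinomial around generation-specific base compositions
(infants concentrated and more overdispersed, concentration 35 vs 90);
KO tables are multinomial draws from taxa-abundance-weighted mixtures of
sparse per-taxon genome profiles, so taxa–function correlation is built
in rather than asserted. The drift magnitude, noise, effect sizes and all
rates are exposed as parameters.

What the generator does **not** emulate: chromatographic peak shapes and
co-elution, retention-index drift, annotation ambiguity, compositional
sequencing artefacts beyond the multinomial, zero-inflation mechanisms
other than censoring, covariates confounded with age (diet, birth mode),
and longitudinal structure. Passing tests therefore demonstrate that the
algorithms recover known structure of this idealized kind, not that any
particular real cohort is free of subtler artefacts.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run the generator at moderate
sizes chosen once: the full 197-sample cohort with 150 features for the
drift-rescue check, 60-sample cohorts for replicated Monte Carlo checks,
1000 null features (60 families) for mixed-model calibration, and
50–150-variable blocks for the integration checks. These sizes keep every
Monte Carlo criterion well-powered while a full validation run stays in
the minutes range on one core. A single seed fans out to fixed per-stage
substreams, and `run_pipeline()` writes a manifest of md5 checksums over
all stage outputs; re-running with the same configuration reproduces the
checksums byte for byte.

## Known limitations

* The drift-correction literature leaves the SVR hyperparameter policy
  open; ours is fixed and documented above, but other grids will give
  slightly different curves.
* With eight QCs per batch, leave-one-QC-out selection has high variance;
  pathological QC outliers can still steer a feature's curve (the flat
  fallback catches only non-positivity).
* The LMM treats generation as the only fixed effect; covariate
  adjustment beyond that is out of scope here.
* The multiblock model fixes `keepX` rather than tuning it by
  cross-validation; 25 per block per component is the convention it
  reproduces deterministically.
* Mother–grandmother discrimination is intrinsically weak in the
  generator (as in the motivating setting), so overall CV error of the
  integration is dominated by adult confusion; per-class errors are
  reported for that reason.
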