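---
title: "Cross-cohort integrative analysis of microbiome and metabolome profiles: methods"
author: "ccia package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-cohort integrative analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Case-control studies of the gut microbiome in inflammatory bowel disease
(IBD) and similar conditions are published one cohort at a time, with
different countries, sequencing centres, extraction kits and recruitment
designs. Pooling cohorts multiplies statistical power but also imports batch
structure: cohort membership shifts every feature's distribution, and the
case:control ratio differs between cohorts, so a naive pooled test confounds
disease with cohort. `ccia` implements a cross-cohort integrative analysis
(CCIA) pipeline for species-level taxonomic profiles, KO gene-family
profiles and metabolite concentration panels: cohort-blocked differential
abundance testing with a robust effect size, multivariate metabolite
selection, classifier-based panel refinement with transfer-style validation,
and a reaction-level map joining the differential features of all three
layers.

# Statistical methods

## Cohort-blocked permutation Wilcoxon test

For a feature with (log-scale) values $x_{ij}$ in cohort $b$, we mid-rank
values within each cohort, sum the case ranks $S_b$, and standardize by the
conditional moments of a within-cohort label permutation:

$$Z = \frac{\sum_b (S_b - E_b)}{\sqrt{\sum_b V_b}},\qquad
E_b = n_{1b}\frac{n_b+1}{2},\qquad
V_b = \frac{n_{1b}n_{2b}}{n_b(n_b-1)}\sum_i\left(r_{bi}-\tfrac{n_b+1}{2}\right)^2,$$

the van Elteren form of the stratified rank-sum statistic with tie-corrected
variance. The null distribution is generated by permuting status labels
independently *within* each cohort, which conditions out arbitrary
cohort-level distribution shifts; the two-sided p-value is
$(1+\#\{|T_{perm}|\ge|T_{obs}|\})/(1+n_{perm})$. When the total number of
within-cohort case assignments is at most 20,000 the null is enumerated
exactly instead. A normal approximation is provided for use cases whose
claimed significance (e.g. $q<10^{-12}$ for KO genes) lies far below any
feasible permutation resolution; the permutation and asymptotic paths agree
closely at moderate sample sizes and the choice is an explicit argument,
never silent.

Why blocking matters: when case fractions differ between cohorts, cohort
batch shifts masquerade as disease signal in a pooled test. Under a
simulated null with one-decade batch offsets and case fractions of 2/3, 1/3
and 1/2 across three cohorts, the blocked test holds its 5% level while the
pooled Wilcoxon rejects about 19% of null features (both numbers are
recomputed by `scripts/acceptance.R` and the test suite).

## Generalized fold change

The generalized fold change (gFC) is the mean difference between the case
and control quantiles of the log abundances over the grid
$0.05, 0.10, \ldots, 0.95$. For a pure location shift it equals the shift
exactly; under heavy zero-inflation it degrades more gracefully than a mean
or median difference. The grid is a configurable argument; positive gFC
means case-enriched.

## FDR and enrichment

P-values are adjusted by Benjamini-Hochberg step-up (missing values are
excluded from the test count). Study defaults for the significance flag
follow the printed thresholds: $q<10^{-4}$ for species and metabolites,
$q<10^{-12}$ for KO genes; both are arguments. KO pathway
over-representation uses the one-sided hypergeometric upper tail against the
tested-KO universe, BH-adjusted across pathways, run separately for
case-enriched and case-depleted query sets.

## OPLS-DA, VIP, and permutation validation

Orthogonal projections to latent structures discriminant analysis is fit
NIPALS-style with one predictive component and a configurable number of
orthogonal components (default 1): the predictive weight vector is the
normalized covariance direction $X^\top y$; each orthogonal component
captures within-$X$ variation orthogonal to it and is deflated before the
predictive component is extracted. Features are centred and unit-variance
scaled inside the model (idempotent for z-scored input); labels are encoded
0/1. $R^2Y$ is the fitted label-variance fraction; $Q^2Y = 1-PRESS/SS$ comes
from 7-fold cross-validation in which the whole pipeline (scaling, filter,
fit) is refit per fold. With zero orthogonal components the model reduces to
single-component PLS1 and reproduces a reference PLS implementation to
machine precision (verified in the test suite against mixOmics).

VIP scores use the predictive component only:
$VIP_j=\sqrt{p}\,|w_j|$ with $\|w\|=1$, so $\sum_j VIP_j^2 = p$ identically.
The candidate-metabolite rule is the intersection
$\{q < 10^{-4}\}\cap\{VIP>1\}$. Model validation refits the pipeline on 200
label permutations (the study's permutation count) and reports
$(1+\#\{Q^2Y_{perm}\ge Q^2Y_{obs}\})/201$.

## Classifier harness

The classifier is a 500-tree random forest (ranger) with $\sqrt p$ features
per split and class-balanced case weights, wrapped so that per-feature
standardization statistics are learned on the training unit and frozen into
the model — no evaluation scheme lets test samples influence preprocessing,
feature ranking or fitting. AUROC uses the Mann-Whitney formulation with
half-credit ties and a stratified percentile bootstrap CI (1000 resamples).

Evaluation schemes: repeated stratified 10-fold CV within cohort (5 repeats
by default, matching the study's mean ± sd over n = 5); leave-one-out CV
(pooled held-out scores); cohort-to-cohort transfer (train on one cohort,
test on each other); leave-one-cohort-out (LOCO; train on all but one).
Iterative feature elimination evaluates the mean stratified 10-fold AUROC,
ranks features by mean impurity importance across the fold models, drops the
lowest 10% (at least one), and repeats to two features; the selected panel is
the iteration with maximal mean AUROC, ties resolved to the smallest set.
Specificity is assessed by calibrating a score threshold to a target false
positive rate on control samples and measuring the above-threshold fraction
in non-target disease sets.

## MOBC maps

The multi-omics biological correlation map joins the three layers at the
reaction level: candidate metabolites are linked to every KO possessing a
reaction whose substrate or product set contains them (undirected
membership, since enzymatic involvement rather than direction is what the
linkage asserts); linked KOs are intersected with the differential-KO set;
and each surviving KO entry carries its reaction(s), the differential status
of every substrate/product (direction, `none` if measured but not
significant, `not_measured` otherwise), a `validated_in_both` flag, and its
top-5 contributing species. The contributor statistic is the mean, over
samples where the KO is detected, of the species' share of the KO's
stratified abundance; the `unclassified` bucket is reported separately and
does not occupy a top-5 slot. KEGG extraction itself is out of scope: the
reaction table is a documented TSV fixture schema
(`ko_id, reaction_id, substrates, products, equation_text`).

# The synthetic cohort generator

Every downstream stage is exercised on seeded synthetic data with a planted
truth table rather than on downloads.

* **Species.** Per-feature baseline $\mu_i \sim N(0, 0.7)$ on the log10
  scale; per-sample values $\mu_i + \epsilon$, $\epsilon\sim N(0,1)$; a
  per-(cohort, feature) batch offset $N(0, \sigma_{batch})$ (default 0.5
  decades); a planted shift of ±1 decade in cases for the differential
  features; zero-inflation (default 10%) applied before renormalization to
  emulate detection limits; columns renormalized to sum one.
* **Planting band.** Differential species are drawn from the 50th-85th
  percentile of the baseline distribution. Shifting a dominant taxon would
  redistribute mass across all other features under compositional closure
  and turn nulls into apparent signals, while rare taxa sit so close to the
  detection floor that the log pseudo-count (1e-5) swallows the planted
  shift; disease markers in real profiles are typically well-detected
  mid-abundance commensals.
* **Direction imbalance.** A planted feature is case-enriched with
  probability 0.15 (most disease-associated species in IBD-type dysbiosis
  are depleted); this also keeps the net compositional mass change of the
  planted set negligible.
* **Cohort design.** Three cohorts of 40 cases and 20 controls by default —
  two cases per control, the centre of the study's 1:2-1:3 control:case
  band.
* **KO layer.** A binary species×KO gene-content matrix (density 5%);
  KO abundance is the content-weighted sum of species abundances,
  renormalized, with the per-species terms kept as a consistent stratified
  store. Differential KOs draw their contributors exclusively from planted
  species of one direction, so their shifts arise through the coupling
  rather than being injected directly.
* **Metabolites.** log2 level = baseline + coupling × (mean z-scored log10
  abundance of 1-3 coupled KOs) + $N(0, 0.5)$, exponentiated to a
  concentration scale (µmol/g). Differential metabolites couple only to
  differential KOs.
* **Metadata.** Age, gender and BMI are drawn independently of status
  (confounder-free by default); `inject_confounding()` adds a
  factor-level-specific log-scale offset to a feature subset for confounder
  studies.

What the generator does *not* emulate: phylogenetic correlation between
species, realistic prevalence-abundance relationships, longitudinal
structure, compositional correlation beyond closure, or instrument-specific
metabolomics noise. Passing tests therefore demonstrate the pipeline's
statistical behaviour under a controlled model, not performance on any real
cohort; the study's printed feature counts and AUROCs depend on the real
data and are deliberately not targets.

# Numerical and design choices

* **Transform constants** follow the printed values: species pseudo-count
  1e-5 (log10), functional pseudo-count 1e-9 with a 1e-6
  maximum-abundance filter (log10), metabolites log2 with no pseudo-count
  and a loud error on zeros. "Maximum abundance cutoff" is implemented as
  drop-if-maximum-below-threshold; capping values at 1e-6 would destroy
  the signal the filter is meant to protect.
* **Z-score scope** is the training split of whatever evaluation is running,
  frozen and applied to held-out data. Whether the original analysis scoped
  standardization per cohort or globally is unstated; the training-split
  scope is the only choice that cannot leak test information, and a global
  scope remains available by passing all samples as the training set.
* **Ratio-band filter**: controls are uniformly subsampled (seeded) down to
  `floor(cases/2)` when they exceed half the case count, i.e. the
  controls:cases band 1:2-1:3 with minimal removal.
* **Exact-enumeration threshold** 20,000 arrangements; above it the sampled
  permutation null (default 10,000 draws) or the normal approximation is
  used. Permutation p-values carry the resolution bound
  $p \ge 1/(n_{perm}+1)$, so claims below that bound must use the
  asymptotic path.
* **Simpson's index** is reported as Gini-Simpson ($1-\sum p_i^2$), with the
  dominance form as an option.
* **PCoA** clamps negative eigenvalues to zero (no Lingoes/Cailliez
  correction); explained fractions are relative to positive inertia.
* **Alpha-diversity comparison** uses a fixed-effect linear model
  (`index ~ status + cohort`, optional covariates) — an explicit stand-in
  for mixed-model meta-analytic tooling, chosen to keep the package
  dependency-light; with three to nine cohorts fixed cohort effects are
  standard practice.
* **Confounder partitioning** uses type-II sums of squares per feature and
  reports each term's share of total variance; aliased designs yield NA with
  a warning.
* **RF hyperparameters** (500 trees, $\sqrt p$ mtry, balanced weights) are
  the field's defaults and all exposed; importance is mean impurity decrease
  across CV folds, with the fold models also supplying the held-out AUROC.
* **Determinism.** Every function with a `seed` argument seeds a local RNG
  stream and restores the caller's state on exit, so seeded components are
  reproducible without freezing surrounding simulations; CLI manifests omit
  timestamps so reruns are byte-identical.

# Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations use 3 cohorts × 60 samples
with 200 species (20 planted) for recovery; 1000 null features × several
seeds for test calibration; 100-400 replicates for the PERMANOVA and OPLS
null distributions; 100 features (5 informative) at n = 180 for feature
elimination; and 200-tree forests in the transfer experiments. These sizes
give stable medians for the properties being checked while keeping the whole
suite rerunnable in minutes on a single core.

# Known limitations

* The blocked test conditions on cohort but not on continuous covariates;
  confounding by age or BMI is assessed (variance partitioning), not
  corrected.
* gFC is a marginal effect size on relative abundances; compositional
  closure can induce small apparent shifts in non-differential features when
  the planted/true signal is direction-imbalanced and abundant.
* OPLS-DA is binary-class only; VIP follows the predictive-component
  convention and values are not comparable across VIP conventions.
* The MOBC linkage is only as complete as the supplied reaction table; no
  attempt is made to infer missing reactions or directionality.
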