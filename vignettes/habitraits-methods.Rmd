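---
title: "Trait-based analysis of host-associated microbial communities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based analysis of host-associated microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`habitraits` studies the functional composition of human-microbiome samples
through a curated trait database rather than gene-content inference. This
vignette documents the models the package implements, the parameters that
matter, the synthetic-data generator that backs its test suite, and the
numerical and design choices a maintainer should know about.

## Data model

A **trait table** holds one row per taxon (species or genus rank) with its
lineage (phylum, class, order, family) and one column per trait. Traits are
typed by a **schema**: continuous (e.g. optimal growth temperature, real,
missing-capable), categorical (e.g. oxygen requirement with levels aerobe /
anaerobe / facultative, missing-capable), or binary (e.g. growth on glucose).
Binary traits are coded 0 when not reported — absence of evidence is treated
as absence of the capability — so a species-rank binary cell is never
missing. Genus-rank consensus records are derived from species rows: a trait
value is kept when every species with a known value agrees, and coded
missing otherwise. By default a missing species value does not break
consensus; requiring complete unanimity (`require_complete = TRUE`) would
empty most genera, but the switch is exposed because the choice is a
convention, not a fact about the data. Disagreement can therefore make a
*genus-rank* binary value missing; downstream encoding handles this through
the missingness mask.

Mixed-type traits enter models through `encode_traits()`: continuous and
binary traits pass through, each k-level categorical trait becomes k dummy
columns that are masked jointly when the value is missing. Matching between
abundance rows and database records is by normalized name (case-folded,
underscores to spaces), species first, then the genus consensus record.

## Abundance-weighted trait profiles

For trait $t$ and sample $s$ the profile cell is
$\sum_i w_i(s,t)\, x_i(t)$, where the weights are relative abundances
renormalized over the taxa whose value of $t$ is known — a taxon with a
missing value simply drops out of that trait's average rather than dragging
it toward an imputed value. Each cell records its *support* (the renormalized
weight that informed it); zero support yields a missing cell. Profiles can
be restricted to one phylum ("phyla-samples"), which is how the leave-one-
phylum-out site classifiers are built.

## Site contrasts

Pairwise site differences use the difference of per-sample profile means as
the test statistic, with site labels permuted (10,000 permutations at
analysis scale; the reduced testing profile uses fewer). We report the
add-one estimator $p = (1 + \#\{|d^\ast| \ge |d|\})/(B+1)$, which cannot be
zero; an exact enumeration mode exists for small groups and is used as its
own oracle in the tests. Repeated samples from a subject are first thinned
to one per (subject, site). BH adjustment is applied within one family per
phylum (all trait × site-pair tests of that phylum); contrasts significant
in ≥ 2 phyla are reported as replicated, with sign conflicts flagged rather
than merged. Subject pairing across sites is not preserved under
permutation; the de-duplicated samples are treated as exchangeable.

## Blocked learning

Cross-validation folds are clade-label equivalence classes — phyla, classes,
or families — so the held-out fold is evolutionarily independent of the
training set; if every unit shares one class the fold builder descends to
families. The learner is a random forest (the `randomForest`
implementation), 5000 trees at analysis scale with stratified per-class
bootstrap sampling equalized to the minority class; the reduced profile uses
500 trees. Classification is scored by Cohen's κ (mean across folds, with
per-fold values and pooled-prediction κ also reported) and by the area under
the precision-recall curve computed from out-of-ensemble vote fractions.
Regression reports RMSE, Pearson (and Spearman) correlation, and the
adjusted $R^2$ of observed-on-predicted with one predictor. Missing encoded
values are imputed with database-wide column means before modelling — the
imputation is a property of the database, not of a training fold.

## Trait network

The co-occurrence network is a sparse Gaussian graphical model of the
mean-imputed, column-standardized profiles. The graphical lasso is solved by
block coordinate descent (compiled code; warm starts along a 100-point
descending λ path from $\lambda_{max}$ to $0.01\lambda_{max}$) and the path
point minimising $\mathrm{EBIC} = -2\,\ell + |E|\log n + 4\gamma|E|\log p$
is selected, $\gamma = 0.5$ by default. Two numerical choices matter:

* the precision diagonal is **not** penalized (the convention of reference
  EBIC-glasso implementations); penalizing it shrinks every partial
  correlation and biases selection toward the empty graph on correlated
  profile data;
* the *reported* graph removes partial correlations smaller than
  $\log\!\big(p(p-1)/2\big)/\sqrt{n}$ in absolute value. At the EBIC
  optimum the de-biasing of strong true edges lets hair-thin spurious
  partners enter with near-zero weight; thresholding at the estimation-error
  scale is the standard high-specificity remedy. Model *selection* always
  uses the unthresholded precision matrix.

Communities minimise a signed Potts energy: positive edge weight is rewarded
within clusters and negative weight between them, each balanced against a
configuration-model null scaled by a coupling γ (default 1). The optimizer
is an in-package simulated annealer (geometric cooling, single-node moves,
greedy finishing descent), seed-reproducible across platforms; equivalence
with a reference signed spin-glass implementation and with exhaustive
partition search on ≤ 8 nodes is asserted in tests, not delegated to a
dependency. The bipartite cluster-site network regresses each site's
membership on all profiles with an L1-penalised logistic model
(`glmnet`, 10-fold CV on misclassification error, minimum-CV rule); an edge
weight is the mean of the cluster's retained coefficients and absent when
none is retained.

## Generalism and phylogenetic logistic regression

A taxon's body-area count uses presence (> 0 relative abundance) in at least
two samples of an area; taxa seen once overall are excluded, as are taxa
with ≥ 2 scattered appearances but no qualifying area (flagged `excluded`
rather than silently dropped — the treatment of such taxa is a convention).
Turning both filters off reproduces the noisier unfiltered labelling used
for degradation checks.

The trait-generalism follow-up model is a logistic regression at the tips of
a phylogeny whose residual correlation decays as $\exp(-\alpha d_{ij})$ in
patristic distance. Estimation is by iterated GEE-style updates with the
signal parameter α profiled on a log-spaced grid (scaled by the mean
pairwise distance, with the independence limit included) against a Gaussian
pseudo-likelihood of the standardized residuals; a large α̂ recovers
ordinary logistic regression, which the star-tree test checks to within
0.05. Inference on the slope is a parametric bootstrap: tips are
re-simulated from the fitted model through a latent-Gaussian threshold whose
marginals match the fitted probabilities exactly, refitted with α held at
α̂ (profiling α inside every replicate would multiply cost for little gain
at these sample sizes), and the two-sided tail of the replicate slope
distribution beyond zero gives the p-value with the add-one correction.
Confidence intervals are *basic* (reflected) bootstrap intervals: the slope
estimator carries a small upward finite-sample bias that percentile
intervals inherit, and the reflected form corrects it — coverage at the
nominal 95 % level is asserted by simulation in the tests. Models are
single-predictor by design (one trait per test), and the 20 phylum × trait
tests form one BH family.

## The synthetic world

`simulate_world()` generates everything the pipelines consume, with ground
truth recorded for recovery tests. Defaults (4 phyla × 75 taxa, 45 subjects
with 4–5 samples over 7 body sites in 5 areas, 8 continuous + 4 categorical
+ 30 binary traits of which 20 are carbon substrates) keep a full pipeline
run to desk scale — the whole test suite runs in a few minutes on one CPU.
Mechanisms, and what they emulate:

* **Phylogenies** are per-phylum coalescent trees (depth scaled to 1);
  classes and families are clades cut from the tree, so clade folds are
  genuinely monophyletic.
* **Binary traits evolve on the tree** through the same latent-threshold
  simulator the bootstrap uses (`alpha_bin` controls signal; 1 by default).
  Each trait has a global baseline prevalence with a small per-phylum
  deviation (logit SD 0.15): prevalences drawn independently per phylum
  would make the same trait mean different things in different phyla and
  destroy any cross-phylum transfer, a pathology real databases do not show
  at that magnitude.
* **Continuous traits** are multivariate normal with a block-diagonal
  precision matrix (3 blocks by default) plus small per-phylum location
  shifts (SD 0.25); categorical traits are per-phylum multinomials.
  Missingness (15 % continuous, 10 % categorical, never binary) follows the
  0-coding convention.
* **Site-trait effects** are planted through habitat filtering plus
  selection: each area has a signature set of traits (1 continuous, 3
  carbon substrates, 1 other binary; no trait shared between areas) and a
  taxon's home area(s) are drawn softmax-proportionally to
  `effect_size × (its standardized signature values)`; residents matching
  the signature are additionally more abundant (`tilt_frac` of the same
  effect). `effect_size = 2` by default; zero gives a world with no planted
  effects.
* **Generalists** (≈ 25 % of taxa) hold 2–3 home areas; the probability of
  being a generalist is boosted by a designated driver trait
  (log-odds +2.5), giving the generalism models a real but noisy target.
  The ground-truth generalist set is defined by the same ≥ 2-appearances
  rule applied to the generated presences, so labeller tests check the rule
  itself while model-recovery tests are not tautological.
* **Abundances** are site-specific Dirichlet draws (concentration 0.3 —
  sparse, realistic communities) over base log-normal carrying capacities,
  with a detection limit of 1e-4 creating true absences; non-home areas
  retain a 1 % leak.

Two derived scenarios are fixed once and used by the calibration and
recovery tests: a **global null** (`effect_size = 0` *and* `area_leak = 1`,
i.e. habitat filtering off — a world where body site truly carries no
compositional information, which is what a permutation-calibration test
needs) and a **recovery scenario** (`effect_size = 3`, `tilt_frac = 1`,
`alpha_bin = 6`, phylum shifts reduced) that isolates the planted
site-trait signal from phylum-location nuisance. On the default,
paper-realistic world the blocked site classifiers behave like their
real-data counterparts: some sites are predictable (κ ≈ 0.3–0.7), mouth
sites are mutually indistinguishable, and per-fold κ varies strongly — which
is precisely why the sharp planted-vs-null assertions run on the dedicated
scenarios instead.

What the generator does **not** emulate: real taxon names, realistic
phylogenetic depth calibration, strain-level trait variability, sequencing
noise, or compositional artefacts of relative abundance estimation. Passing
recovery tests therefore demonstrate that the estimators see what was
planted under the stated noise model, not that real HMP effect sizes are
attainable.

## Limitations

* The spin-glass annealer is stochastic; global optimality is only verified
  exhaustively for small graphs, and large-graph partitions should be
  treated as good local optima (as with any annealing-based detector).
* α and β are estimated jointly but α's sampling uncertainty is not
  propagated into the bootstrap (α fixed at α̂ per replicate); type-I error
  remains slightly conservative in the tested regimes.
* EBIC with γ = 0.5 is conservative on highly collinear profile blocks
  (e.g. complementary category dummies); γ is exposed where a denser
  exploratory graph is wanted.
* Genus-consensus records blur within-genus variation by construction; the
  species-first matching rule limits, but does not remove, this.
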