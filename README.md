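# habitraits

Trait-based functional analysis of human-microbiome communities.

Microbiome samples that look wildly different taxonomically are often
surprisingly similar in what their members *do*. `habitraits` analyses that
functional layer directly, starting from a hand-curated table of microbial
traits (growth conditions, morphology, enzyme assays, gas production, carbon
substrate use) and an HMP-style relative-abundance matrix with body-site
metadata. It answers three linked questions:

1. **Which traits characterise which body sites?** Abundance-weighted mean
   trait profiles per sample; permutation tests for pairwise differences
   between sites with Benjamini-Hochberg FDR control, repeated within each
   major phylum and filtered to contrasts that replicate in at least two
   phyla; one-vs-rest random-forest site classifiers scored by
   phylogenetically *blocked* cross-validation; and a trait co-occurrence
   network (graphical lasso with EBIC selection) clustered by a signed
   spin-glass community detector and linked to sites through L1-penalised
   logistic regressions.
2. **What makes a habitat generalist?** Taxa are labelled specialists or
   generalists from their body-area appearance pattern (an area counts only
   with ≥ 2 sample appearances; singletons are excluded), predicted with
   clade-blocked random forests, and the top-ranked traits are tested with a
   phylogenetic logistic regression whose slope p-value comes from a
   parametric bootstrap on the tree.
3. **What drives metabolic breadth?** Per-sample Shannon entropy of carbon
   source use is decomposed against taxonomic entropy, and the number of
   substrates a taxon uses is regressed on its other traits under
   phylum-blocked cross-validation.

## The statistics at the core

* **Weighted trait profile.** For trait *t* and sample *s*,
  `profile(t, s) = Σ_i w_i x_i(t)` with weights `w_i` the relative abundances
  renormalized over the taxa whose value of *t* is known.
* **Blocked cross-validation.** Folds are monophyletic clades (phyla,
  classes, or families), never random splits, so performance estimates are
  not inflated by shared evolutionary history. Performance is Cohen's
  κ = (p_o − p_e)/(1 − p_e) and the area under the precision-recall curve.
* **Trait network.** Sparse inverse covariance of standardized profiles,
  `EBIC(λ) = −2·loglik + |E|·log n + 4·γ·|E|·log p`, minimised over a
  descending λ path (γ = 0.5 by default). Communities minimise a signed
  Potts energy (positive weight rewarded inside, negative weight between
  clusters) by seeded simulated annealing.
* **Phylogenetic logistic regression.** `logit P(y_i = 1) = β0 + β1 x_i`
  with residual tip correlation `exp(−α d_ij)` in patristic distance, fitted
  by iterated estimating equations with α profiled; inference on β1 by a
  parametric bootstrap on the tree.

Everything is exercisable end-to-end on synthetic data with known ground
truth (`simulate_world()`), including planted site-trait effects, block-
structured trait covariance, a trait-driven generalism rule, and binary
traits evolved on per-phylum coalescent trees.

## Worked example

```r
library(habitraits)

world <- simulate_world(world_config(), seed = 42)
world
#> Synthetic microbiome world: 300 taxa, 207 samples, 42 traits, 4 phyla

cfg  <- run_config(seed = 7, profile = "ci")   # reduced sizes for a quick run
site <- run_site_analysis(world$db, world$ab, world$meta, cfg)

site$kappa_grid
#>                  task mean_kappa phyluma phylumb phylumc phylumd
#>        anterior_nares     -0.040  -0.018  -0.113  -0.029   0.000
#>      posterior_fornix      0.023  -0.009   0.000   0.101   0.000
#> retroauricular_crease      0.716   0.919   0.904   0.594   0.447
#>                 stool      0.069   0.000   0.275   0.000   0.000
#>             mouth_all      0.182   0.000   0.000   0.559   0.170
#> ... (per-site one-vs-rest, one column per held-out phylum)
```

Each row is a body-site prediction task; each phylum column is the κ
obtained when that phylum's phyla-samples are held out and the model is
trained on the other three. In this world the skin site happens to carry a
strongly transferable signature (mean κ 0.72) while the three mouth sites
are mutually indistinguishable (κ ≈ 0), reproducing the qualitative pattern
such grids show on real data: predictability varies sharply across sites and
folds.

```r
head(site$replicated[, c("trait", "siteA", "siteB", "n_phyla", "consensus_sign")], 3)
#>   trait          siteA                siteB n_phyla consensus_sign
#> 1 bin_1 anterior_nares        buccal_mucosa       4              1
#> 2 bin_1 anterior_nares                stool       3              1
#> 3 bin_1 anterior_nares supragingival_plaque       4              1

site$network
#> Partial-correlation network: 50 nodes, 7 edges
#>   lambda = 0.01111  (EBIC gamma = 0.5 , n = 155 )
site$clusters
#> Spin-glass trait clusters: 3 clusters over 8 nodes ( 42 isolated )
```

The replication table lists trait-site-pair contrasts that are
BH-significant with a consistent sign in ≥ 2 phyla. The network output shows
the EBIC-selected partial-correlation graph on the 50 expanded traits and
its spin-glass communities.

```r
met <- run_metabolism_analysis(world$db, world$ab, world$meta, cfg)
aggregate(cbind(carbon_entropy, taxonomic_entropy) ~ body_area,
          met$diversity, function(x) round(mean(x, na.rm = TRUE), 3))
#>   body_area carbon_entropy taxonomic_entropy
#> 1   airways          2.611             2.493
#> 2       gut          2.764             2.699
#> 3     mouth          2.589             2.237
#> 4      skin          2.723             2.865
#> 5    vagina          2.733             2.714

round(unlist(met$regression$metrics), 3)
#>         mean_rmse          mean_rho mean_rho_spearman       mean_adj_r2
#>             2.092            -0.040            -0.036             0.025
```

Carbon-source entropy tracks taxonomic entropy across areas (nats, natural
log). The breadth regression is honest about this world: its substrate
traits evolve independently of the other traits, so the blocked estimate of
predictive correlation is correctly near zero — plant a dependency (see the
tests) and mean ρ rises above 0.9.

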