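#' Run configuration for the study pipelines
#'
#' Defaults mirror the headline analysis settings: 10000 permutations,
#' BH alpha 0.05, 5000-tree forests, 10000 bootstrap replicates, 10-fold
#' lasso CV, sites with at least 10 subjects, replication in at least 2
#' phyla, at least 2 appearances per body area. `profile = "ci"` switches to
#' the reduced fast-testing profile (1000 permutations, 500 trees, 500
#' bootstraps).
#'
#' @param seed master seed; every stochastic stage derives its own seed from
#'   it.
#' @param profile `"full"` or `"ci"`.
#' @param ... overrides of individual fields.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, profile = c("full", "ci"), ...) {
  profile <- match.arg(profile)
  cfg <- list(seed = seed, profile = profile,
              B = 10000L, alpha = 0.05, min_phyla = 2L,
              min_subjects_per_site = 10L, num_trees = 5000L,
              ebic_gamma = 0.5, nlambda = 100L,
              spinglass_gamma = 1, lasso_cv_folds = 10L,
              nboot = 10000L, min_appearances = 2L,
              min_taxa_per_phylum = 50L, top_k = 5L,
              exclude_singletons = TRUE)
  if (profile == "ci") {
    cfg$B <- 1000L; cfg$num_trees <- 500L; cfg$nboot <- 500L
    cfg$nlambda <- 40L
  }
  cfg <- utils::modifyList(cfg, list(...))
  structure(cfg, class = "run_config")
}

# species + genus-consensus records as one matchable database
combined_database <- function(db) {
  gen <- genus_consensus(db)
  out <- rbind(as.data.frame(db), as.data.frame(gen))
  new_trait_table(out, tt_schema(db))
}

# phyla with enough matched taxa to support phylum-specific models
focal_phyla <- function(db, match, min_taxa) {
  m <- match[match$matched, , drop = FALSE]
  phy <- db$phylum[match(m$db_taxon_id, db$taxon_id)]
  tab <- table(phy)
  sort(names(tab)[tab >= min_taxa])
}

#' Site-association pipeline: contrasts, classifiers, networks
#'
#' Executes the complete body-site analysis on one dataset: genus-consensus
#' augmentation of the database, abundance-weighted profiles (pooled and per
#' focal phylum), one-sample-per-subject de-duplication, permutation
#' contrasts per phylum with BH control and the cross-phylum replication
#' filter, phylogenetically blocked one-vs-rest site classifiers on
#' phyla-samples, and the trait network (graphical lasso + EBIC, spin-glass
#' clusters, bipartite cluster-site lasso network).
#'
#' @param db species-rank `trait_table`.
#' @param ab an `abundance_table`.
#' @param meta `sample_metadata`.
#' @param config a [run_config()].
#' @param contrast_traits optional subset of expanded traits to contrast
#'   (default all; reduce for speed).
#' @return list: `profiles` (pooled + per phylum), `contrasts` (per-phylum
#'   tables + `pooled`), `replicated`, `site_models` (per-site metrics +
#'   kappa grid), `network`, `clusters`, `bipartite`, `retained_samples`.
#' @export
run_site_analysis <- function(db, ab, meta, config = run_config(),
                              contrast_traits = NULL) {
  db2 <- combined_database(db)
  enc <- encode_traits(db2)
  match <- match_taxa(ab, db2)
  phyla <- focal_phyla(db2, match, config$min_taxa_per_phylum)
  keep <- subsample_one_per_subject(meta, derive_seed(config$seed, 1L))

  pooled_prof <- weighted_trait_profile(ab, enc, db2, match = match)
  prof_ph <- lapply(stats::setNames(phyla, phyla), function(ph)
    weighted_trait_profile(ab, enc, db2, match = match, restrict_phylum = ph))

  contrasts <- lapply(stats::setNames(phyla, phyla), function(ph)
    site_contrast_table(prof_ph[[ph]], meta, traits = contrast_traits,
                        B = config$B, alpha = config$alpha,
                        seed = derive_seed(config$seed, 2L + match(ph, phyla)),
                        samples = keep))
  pooled_contrasts <- site_contrast_table(pooled_prof, meta,
                                          traits = contrast_traits,
                                          B = config$B, alpha = config$alpha,
                                          seed = derive_seed(config$seed, 2L),
                                          samples = keep)
  replicated <- replicate_across_phyla(contrasts, config$min_phyla)

  # --- blocked site classifiers on phyla-samples -------------------------
  meta2 <- meta[match(colnames(ab$x), meta$sample_id), , drop = FALSE]
  Xl <- list(); fold_lab <- c()
  for (ph in phyla) {
    v <- t(prof_ph[[ph]]$values)
    informative <- rowSums(!is.na(v)) > 0
    v <- v[informative, , drop = FALSE]
    rownames(v) <- paste(ph, rownames(v), sep = "::")
    Xl[[ph]] <- v
    fold_lab <- c(fold_lab, rep(ph, nrow(v)))
  }
  X <- do.call(rbind, Xl)
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[, j], na.rm = TRUE)
  }
  X <- X[, colSums(is.na(X)) == 0, drop = FALSE]
  samp_of <- sub("^.*::", "", rownames(X))
  site_of <- meta2$body_site[match(samp_of, meta2$sample_id)]
  subj_of <- meta2$subject_id[match(samp_of, meta2$sample_id)]
  n_subj <- tapply(subj_of, site_of, function(s) length(unique(s)))
  eligible <- names(n_subj)[n_subj >= config$min_subjects_per_site]
  tasks <- c(stats::setNames(as.list(eligible), eligible))
  mouth_sites <- unique(meta2$body_site[meta2$body_area == "mouth"])
  if (length(intersect(mouth_sites, site_of)) > 0L)
    tasks$mouth_all <- mouth_sites
  folds <- make_clade_folds(rownames(X),
                            data.frame(phylum = fold_lab), level = "phylum")
  site_models <- list()
  for (tn in names(tasks)) {
    y <- ifelse(site_of %in% tasks[[tn]], "site", "rest")
    if (length(unique(y)) < 2L) next
    site_models[[tn]] <- blocked_classify(
      X, y, folds,
      config = list(num_trees = config$num_trees,
                    seed = derive_seed(config$seed, 20L + match(tn, names(tasks)))),
      positive = "site")
  }
  kappa_grid <- do.call(rbind, lapply(names(site_models), function(tn) {
    m <- site_models[[tn]]
    data.frame(task = tn, mean_kappa = m$metrics$mean_kappa,
               t(stats::setNames(m$per_fold$kappa, m$per_fold$fold)),
               stringsAsFactors = FALSE, check.names = FALSE)
  }))

  # --- trait network on de-duplicated pooled profiles --------------------
  net_prof <- pooled_prof$values[, colnames(pooled_prof$values) %in% keep,
                                 drop = FALSE]
  network <- fit_glasso_ebic(t(net_prof), gamma = config$ebic_gamma,
                             nlambda = config$nlambda)
  clusters <- spin_glass_communities(network, gamma = config$spinglass_gamma,
                                     seed = derive_seed(config$seed, 40L))
  bipartite <- site_cluster_network(pooled_prof, meta, clusters,
                                    cv_folds = config$lasso_cv_folds,
                                    seed = derive_seed(config$seed, 41L))

  list(profiles = c(list(pooled = pooled_prof), prof_ph),
       contrasts = c(contrasts, list(pooled = pooled_contrasts)),
       replicated = replicated, site_models = site_models,
       kappa_grid = kappa_grid, network = network, clusters = clusters,
       bipartite = bipartite, retained_samples = keep, phyla = phyla)
}

#' Generalism pipeline: blocked prediction and phylogenetic regression
#'
#' Labels taxa as specialists/generalists from their body-area appearance
#' pattern, fits blocked random-forest classifiers within each phylum
#' (class folds, family fallback) and across phyla (phylum folds), selects
#' each phylum's top-k most important traits, and tests each with a
#' phylogenetic logistic regression, BH-correcting the whole family of
#' phylum x trait tests.
#'
#' @param db species-rank `trait_table`.
#' @param ab an `abundance_table`.
#' @param meta `sample_metadata`.
#' @param trees named list of per-phylum `phylo` trees (tips = taxon ids).
#' @param config a [run_config()].
#' @return list: `labels`, `within` (per-phylum blocked results),
#'   `across` (phylum-fold result), `top_traits` (per phylum),
#'   `phylo_tests` (tidy data frame with BH q-values), `units`.
#' @export
run_generalism_analysis <- function(db, ab, meta, trees,
                                    config = run_config()) {
  labels <- generalism_labels(ab, meta, config$min_appearances,
                              config$exclude_singletons)
  match <- match_taxa(ab, db)
  sp <- match[match$matched & match$rank_used == "species", , drop = FALSE]
  lab <- labels[match(sp$taxon_id, labels$taxon_id), , drop = FALSE]
  use <- lab$label != "excluded"
  units <- sp$db_taxon_id[use]
  y <- stats::setNames(lab$label[use], units)
  enc <- mean_impute(encode_traits(db))
  X <- enc$x[units, , drop = FALSE]
  lin <- as.data.frame(db)[match(units, db$taxon_id),
                           c("phylum", "class", "family")]
  within <- list(); top_traits <- list(); tests <- list()
  for (ph in sort(unique(lin$phylum))) {
    rows <- which(lin$phylum == ph)
    if (length(rows) < 10L || length(unique(y[rows])) < 2L) next
    folds <- tryCatch(make_clade_folds(units[rows], lin[rows, ], level = "class"),
                      error = function(e) NULL)
    if (is.null(folds) || length(folds$folds) < 2L) next
    res <- blocked_classify(X[rows, , drop = FALSE], y[rows], folds,
                            config = list(num_trees = config$num_trees,
                                          seed = derive_seed(config$seed, 60L)),
                            positive = "generalist")
    within[[ph]] <- res
    top <- select_top_traits(res$importance_mean, config$top_k)
    top_traits[[ph]] <- top
    tree <- trees[[ph]]
    if (is.null(tree)) next
    for (tr in top) {
      fit <- tryCatch(
        phylo_logistic(tree,
                       y = stats::setNames(as.integer(y[rows] == "generalist"),
                                           units[rows]),
                       x = stats::setNames(X[rows, tr], units[rows]),
                       nboot = config$nboot,
                       seed = derive_seed(config$seed,
                                          70L + length(tests))),
        error = function(e) NULL)
      if (is.null(fit)) next
      tests[[length(tests) + 1L]] <-
        data.frame(phylum = ph, trait = tr, coefficient = fit$coef["slope"],
                   alpha = fit$alpha, p_boot = fit$p_boot,
                   nboot = fit$nboot, converged = fit$converged,
                   stringsAsFactors = FALSE)
    }
  }
  phfolds <- tryCatch(make_clade_folds(units, lin, level = "phylum"),
                      error = function(e) NULL)
  across <- if (!is.null(phfolds) && length(phfolds$folds) >= 2L)
    blocked_classify(X, y, phfolds,
                     config = list(num_trees = config$num_trees,
                                   seed = derive_seed(config$seed, 61L)),
                     positive = "generalist") else NULL
  phylo_tests <- if (length(tests)) {
    out <- do.call(rbind, tests)
    rownames(out) <- NULL
    adj <- bh_adjust(out$p_boot, config$alpha)
    out$q <- adj$q; out$reject <- adj$reject
    out
  } else NULL
  list(labels = labels, within = within, across = across,
       top_traits = top_traits, phylo_tests = phylo_tests, units = units)
}

#' Metabolic-breadth pipeline: diversity decomposition and regression
#'
#' Computes per-sample taxonomic and carbon-source Shannon entropies, the
#' per-taxon metabolic breadth (carbon substrates used), a phylum-fold
#' blocked random-forest regression of breadth on all non-substrate traits,
#' and per-site substrate-overlap distributions.
#'
#' @inheritParams run_generalism_analysis
#' @return list: `diversity` (per sample, with body site attached),
#'   `breadth` (named per-taxon counts), `regression` (blocked result),
#'   `overlap` (per-site mean shared-substrate counts).
#' @export
run_metabolism_analysis <- function(db, ab, meta, config = run_config()) {
  db2 <- combined_database(db)
  match <- match_taxa(ab, db2)
  div <- sample_diversity(ab, db2, match = match)
  meta2 <- meta[match(div$sample_id, meta$sample_id), , drop = FALSE]
  div$body_site <- meta2$body_site
  div$body_area <- meta2$body_area
  breadth <- metabolic_breadth(db)
  sp <- match[match$matched & match$rank_used == "species", , drop = FALSE]
  units <- sp$db_taxon_id
  enc <- mean_impute(encode_traits(db))
  keep_cols <- enc$map$column[enc$map$category != "carbon_substrate"]
  X <- enc$x[units, intersect(colnames(enc$x), keep_cols), drop = FALSE]
  lin <- as.data.frame(db)[match(units, db$taxon_id),
                           c("phylum", "class", "family")]
  folds <- make_clade_folds(units, lin, level = "phylum")
  regression <- blocked_regress(X, breadth[units], folds,
                                config = list(num_trees = config$num_trees,
                                              seed = derive_seed(config$seed, 80L)))
  sites <- sort(unique(meta2$body_site))
  overlap <- lapply(stats::setNames(sites, sites), function(s) {
    smp <- meta2$sample_id[meta2$body_site == s]
    pres <- rowSums(ab$x[, colnames(ab$x) %in% smp, drop = FALSE] > 0) > 0
    taxa <- sp$db_taxon_id[sp$taxon_id %in% rownames(ab$x)[pres]]
    substrate_overlap(db, taxa)$mean
  })
  list(diversity = div, breadth = breadth, regression = regression,
       overlap = overlap)
}
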