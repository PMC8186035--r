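#' Bipartite cluster-site association network
#'
#' For each body site, site membership (site vs rest) is regressed on all
#' trait profiles with an L1-penalised logistic regression; the penalty is
#' chosen by cross-validated misclassification error (minimum-CV rule). The
#' weight of a (cluster, site) edge is the mean of the retained (nonzero)
#' coefficients of the cluster's traits in that site's model; a cluster none
#' of whose traits is retained has no edge to that site.
#'
#' @param profiles a `trait_profile` (traits x samples).
#' @param meta `sample_metadata` covering the profile's samples.
#' @param clusters a `trait_clusters` partition of the profile's traits.
#' @param cv_folds cross-validation folds (default 10); automatically reduced
#'   with a warning for sites with fewer positive samples than folds.
#' @param seed integer seed (CV fold assignment).
#' @param sites body sites to model (default: every site present with both
#'   positive and negative samples).
#' @return list: `edges` (data frame cluster / site / weight / n_retained),
#'   `lambda` (named per-site selected penalty).
#' @export
site_cluster_network <- function(profiles, meta, clusters, cv_folds = 10L,
                                 seed = 1L, sites = NULL) {
  meta <- meta[match(colnames(profiles$values), meta$sample_id), , drop = FALSE]
  x <- t(profiles$values)
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mean(x[, j], na.rm = TRUE)
  }
  keep_col <- apply(x, 2L, function(v) all(is.finite(v)) && stats::sd(v) > 0)
  x <- x[, keep_col, drop = FALSE]
  if (is.null(sites)) sites <- sort(unique(meta$body_site))
  edges <- list(); lambdas <- c()
  for (site in sites) {
    y <- as.integer(meta$body_site == site)
    npos <- sum(y == 1); nneg <- sum(y == 0)
    if (npos < 2L || nneg < 2L) next
    nf <- cv_folds
    if (npos < cv_folds) {
      nf <- max(3L, npos)
      warning("site '", site, "': only ", npos,
              " positive samples; reducing CV folds to ", nf)
    }
    foldid <- with_seed(derive_seed(seed, match(site, sites)), {
      # stratified fold assignment so every fold sees both classes
      f <- integer(length(y))
      f[y == 1] <- sample(rep_len(seq_len(nf), npos))
      f[y == 0] <- sample(rep_len(seq_len(nf), nneg))
      f
    })
    cv <- glmnet::cv.glmnet(x, y, family = "binomial",
                            type.measure = "class", foldid = foldid)
    lambdas[site] <- cv$lambda.min
    co <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1L, 1L]
    retained <- co[co != 0]
    if (!length(retained)) next
    for (cl in sort(unique(clusters$membership))) {
      traits <- names(clusters$membership)[clusters$membership == cl]
      rc <- retained[names(retained) %in% traits]
      if (!length(rc)) next
      edges[[length(edges) + 1L]] <-
        data.frame(cluster = cl, site = site, weight = mean(rc),
                   n_retained = length(rc), stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(cluster = integer(), site = character(),
                           weight = numeric(), n_retained = integer(),
                           stringsAsFactors = FALSE)
  list(edges = edges, lambda = lambdas)
}
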