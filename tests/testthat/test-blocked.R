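test_that("clade folds are label classes with finer-level fallback", {
  units <- paste0("t", 1:8)
  labels <- data.frame(phylum = rep(c("A", "B"), each = 4),
                       class = rep("onlyclass", 8),
                       family = rep(c("f1", "f2", "f3", "f4"), each = 2))
  f <- make_clade_folds(units, labels, level = "phylum")
  expect_equal(f$level, "phylum")
  expect_length(f$folds, 2L)
  expect_setequal(unlist(f$folds), units)
  # all units share one class -> descend to family (Bacteroidetes-style)
  f2 <- make_clade_folds(units, labels, level = "class")
  expect_equal(f2$level, "family")
  expect_length(f2$folds, 4L)
  # all-distinct labels degenerate to leave-one-out
  f3 <- make_clade_folds(units, data.frame(phylum = units), level = "phylum")
  expect_length(f3$folds, 8L)
  # nothing left to descend to -> error
  expect_error(make_clade_folds(units, data.frame(family = rep("x", 8)),
                                level = "family"), "cannot block")
  # folds are disjoint
  expect_equal(anyDuplicated(unlist(f2$folds)), 0L)
})

test_that("Cohen's kappa matches marginal arithmetic", {
  expect_equal(cohens_kappa(c(1, 0, 1), c(1, 0, 1)), 1)
  # 90% positive observed, predict all positive -> prevalence-only null, 0
  obs <- rep(c("pos", "neg"), c(9, 1))
  expect_equal(cohens_kappa(obs, rep("pos", 10)), 0)
  # TP=45 FN=5 FP=15 TN=35: p_o = 0.8, p_e = 0.5 -> kappa 0.6
  truth <- rep(c("pos", "pos", "neg", "neg"), c(45, 5, 15, 35))
  pred <- rep(c("pos", "neg", "pos", "neg"), c(45, 5, 15, 35))
  expect_equal(cohens_kappa(truth, pred), 0.6)
  expect_error(cohens_kappa(1:3, 1:2), "mismatch")
  # bounded in [-1, 1] on random label pairs
  set.seed(2)
  for (i in 1:20) {
    a <- sample(c("x", "y"), 30, TRUE); b <- sample(c("x", "y"), 30, TRUE)
    k <- cohens_kappa(a, b)
    expect_gte(k, -1); expect_lte(k, 1)
  }
})

test_that("AUPRC equals brute-force threshold enumeration", {
  # perfect separation
  expect_equal(precision_recall_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9), 1), 1)
  # constant scores -> single-point curve at the prevalence
  expect_equal(precision_recall_auc(c(1, 0, 0, 0), rep(0.5, 4), 1), 0.25)
  # 6-point hand example vs independent enumeration oracle
  obs <- c(1, 0, 1, 1, 0, 0)
  sc <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.1)
  oracle <- {
    ths <- sort(unique(sc), decreasing = TRUE)
    auc <- 0; rprev <- 0
    for (t in ths) {
      tp <- sum(obs == 1 & sc >= t); fp <- sum(obs == 0 & sc >= t)
      prec <- tp / (tp + fp); rec <- tp / sum(obs == 1)
      auc <- auc + (rec - rprev) * prec; rprev <- rec
    }
    auc
  }
  expect_equal(precision_recall_auc(obs, sc, 1), oracle)
  # hand arithmetic: recall steps at thresholds 0.9, 0.7, 0.4 with
  # precisions 1, 2/3, 3/4
  expect_equal(oracle, 1/3 * 1 + 1/3 * 2/3 + 1/3 * 3/4, tolerance = 1e-12)
  expect_error(precision_recall_auc(c(1, 1), c(0.5, 0.4), 1), "single-class")
})

test_that("regression metrics match closed forms", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 5))
  expect_equal(m$rmse, sqrt(4 / 3))
  expect_equal(m$rho, cor(c(1, 2, 3), c(1, 2, 5)))
  expect_true(m$adj_r2 <= cor(c(1, 2, 3), c(1, 2, 5))^2 + 1e-12)
  expect_true(is.na(regression_metrics(c(1, 1, 1), c(1, 2, 3))$rho))
})

planted_matrix <- function(n = 80, p = 8, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("u", 1:n), paste0("v", 1:p)))
  X
}

test_that("blocked classification: separable signal gives per-fold kappa 1 and exact fold accounting", {
  X <- planted_matrix()
  # feature 1 determines the label, with a clear margin around the boundary
  X[, 1] <- sign(X[, 1]) * (0.5 + abs(X[, 1]))
  y <- ifelse(X[, 1] > 0, "pos", "neg")
  labels <- data.frame(phylum = rep(c("A", "B", "C", "D"), each = 20))
  folds <- make_clade_folds(rownames(X), labels)
  res <- blocked_classify(X, y, folds, config = list(num_trees = 200, seed = 3),
                          positive = "pos")
  expect_equal(nrow(res$per_fold), 4L)
  expect_true(all(res$per_fold$kappa == 1))
  expect_equal(res$metrics$mean_kappa, 1)
  # every unit predicted exactly once, never inside its own training partition
  expect_setequal(res$predictions$unit, rownames(X))
  expect_equal(anyDuplicated(res$predictions$unit), 0L)
  for (k in seq_along(folds$folds))
    expect_setequal(res$predictions$unit[res$predictions$fold == names(folds$folds)[k]],
                    folds$folds[[k]])
  # the planted feature dominates importance
  expect_equal(res$importance_mean$trait[1], "v1")
  # single-class training partition is skipped and flagged
  y2 <- y; y2[21:80] <- "neg"  # only fold A has positives
  res2 <- blocked_classify(X, y2, folds, config = list(num_trees = 50, seed = 1),
                           positive = "pos")
  expect_true(res2$per_fold$skipped[res2$per_fold$fold == "A"])
})

test_that("blocked classification: labels independent of features give kappa near 0", {
  kappas <- vapply(1:20, function(r) {
    X <- planted_matrix(n = 60, p = 6, seed = 100 + r)
    set.seed(200 + r)
    y <- sample(c("pos", "neg"), 60, TRUE)
    folds <- make_clade_folds(rownames(X),
                              data.frame(phylum = rep(c("A", "B", "C"), each = 20)))
    blocked_classify(X, y, folds, config = list(num_trees = 100, seed = r,
                                                importance = FALSE),
                     positive = "pos")$metrics$mean_kappa
  }, 0)
  expect_lt(abs(mean(kappas)), 0.08)
})

test_that("blocked regression recovers a separable response and nulls out noise", {
  X <- planted_matrix(n = 100, p = 5, seed = 7)
  folds <- make_clade_folds(rownames(X),
                            data.frame(phylum = rep(c("A", "B", "C", "D"), each = 25)))
  res <- blocked_regress(X, X[, 2], folds, config = list(num_trees = 400, seed = 2))
  expect_true(all(res$per_fold$rho > 0.75))
  expect_gt(res$metrics$mean_rho, 0.85)
  expect_true(res$metrics$mean_rmse < 0.7)
  expect_equal(res$importance_mean$trait[1], "v2")
  expect_true(all(res$per_fold$adj_r2 <= 1))
  # independent-noise response: mean rho across replicates near 0
  rhos <- vapply(1:10, function(r) {
    set.seed(300 + r)
    y <- rnorm(100)
    blocked_regress(X, y, folds, config = list(num_trees = 100, seed = r,
                                               importance = FALSE))$metrics$mean_rho
  }, 0)
  expect_lt(abs(mean(rhos)), 0.12)
})

test_that("random splits inflate apparent performance on phylogenetically structured data", {
  # features and labels both evolve on one tree: the only association is
  # shared ancestry, which random splits leak and clade blocking removes
  naive_minus_blocked <- vapply(1:20, function(r) {
    tree <- ape::rcoal(60)
    tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
    tree$tip.label <- paste0("t", 1:60)
    y <- simulate_binary_on_tree(tree, 0, 0, 0, alpha = 0.3, seed = 1000 + r)
    X <- sapply(1:8, function(j)
      simulate_binary_on_tree(tree, 0, 0, 0, alpha = 0.3, seed = 2000 + 10 * r + j))
    rownames(X) <- tree$tip.label
    if (length(unique(y)) < 2) return(NA_real_)
    cls <- cutree(hclust(as.dist(ape::cophenetic.phylo(tree)), "average"), k = 4)
    blocked <- make_clade_folds(tree$tip.label,
                                data.frame(phylum = paste0("c", cls)))
    set.seed(r)
    rand <- structure(list(folds = split(tree$tip.label, sample(rep(1:4, 15))),
                           level = "random"), class = "fold_spec")
    yl <- ifelse(y == 1, "pos", "neg")
    kb <- tryCatch(blocked_classify(X, yl, blocked,
                                    config = list(num_trees = 100, seed = r,
                                                  importance = FALSE),
                                    positive = "pos")$metrics$mean_kappa,
                   error = function(e) NA_real_)
    kr <- tryCatch(blocked_classify(X, yl, rand,
                                    config = list(num_trees = 100, seed = r,
                                                  importance = FALSE),
                                    positive = "pos")$metrics$mean_kappa,
                   error = function(e) NA_real_)
    kr - kb
  }, 0)
  expect_gt(mean(naive_minus_blocked, na.rm = TRUE), 0)
})
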