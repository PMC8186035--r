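#' Build phylogenetically blocked cross-validation folds
#'
#' Folds are clade-label equivalence classes (every unit carrying the same
#' label at the blocking level forms one fold), never random splits, so each
#' held-out fold can be treated as having evolved independently of the
#' training clades. If all units share a single label at the requested level,
#' the next finer level is used instead (e.g. a phylum whose species all
#' belong to one class falls back to family folds).
#'
#' @param units character vector of unit names (taxa or phyla-sample ids).
#' @param labels data frame of clade labels, rows aligned with `units`,
#'   columns named by level (e.g. `phylum`, `class`, `family`).
#' @param level blocking level to start from.
#' @return a `fold_spec`: list with `folds` (named list of unit-name vectors),
#'   `level` (the level actually used).
#' @export
make_clade_folds <- function(units, labels,
                             level = c("phylum", "class", "family")) {
  level <- match.arg(level)
  stopifnot(nrow(labels) == length(units))
  order_levels <- c("phylum", "class", "family")
  cand <- order_levels[seq(match(level, order_levels), length(order_levels))]
  cand <- intersect(cand, names(labels))
  if (!length(cand)) stop("no usable blocking level among label columns")
  for (lv in cand) {
    lab <- as.character(labels[[lv]])
    if (anyNA(lab)) stop("missing ", lv, " label for some units")
    if (length(unique(lab)) >= 2L) {
      folds <- split(units, lab)
      return(structure(list(folds = folds, level = lv), class = "fold_spec"))
    }
  }
  stop("all units share one label at every available level; cannot block")
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between observed and predicted labels:
#' `(p_o - p_e) / (1 - p_e)` with expected agreement `p_e` from the marginal
#' label frequencies. Measures the gain of a classifier over a null model
#' that knows only class prevalences. Returns 0 in the degenerate case
#' `p_e = 1` (both marginals concentrated on a single identical class).
#'
#' @param observed,predicted equal-length label vectors.
#' @return kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) == 0L) stop("empty label vectors")
  lev <- union(unique(as.character(observed)), unique(as.character(predicted)))
  o <- factor(as.character(observed), levels = lev)
  p <- factor(as.character(predicted), levels = lev)
  n <- length(o)
  po <- mean(o == p)
  pe <- sum((table(o) / n) * (table(p) / n))
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(0)
  (po - pe) / (1 - pe)
}

#' Area under the precision-recall curve
#'
#' Step-wise interpolation over unique score thresholds taken in descending
#' order: AUPRC = sum over thresholds of (R_k - R_(k-1)) * P_k. With a
#' constant score the curve has a single point and the area equals the
#' positive-class prevalence.
#'
#' @param observed label vector containing both classes.
#' @param scores numeric classifier scores (higher = more positive).
#' @param positive the positive-class label.
#' @return area in \[0, 1\].
#' @export
precision_recall_auc <- function(observed, scores, positive) {
  y <- as.character(observed) == as.character(positive)
  if (all(y) || !any(y))
    stop("precision-recall curve undefined: observed labels are single-class")
  stopifnot(length(y) == length(scores), !anyNA(scores))
  npos <- sum(y)
  auc <- 0; r_prev <- 0
  for (t in sort(unique(scores), decreasing = TRUE)) {
    sel <- scores >= t
    prec <- sum(y[sel]) / sum(sel)
    rec <- sum(y[sel]) / npos
    auc <- auc + (rec - r_prev) * prec
    r_prev <- rec
  }
  auc
}

#' Impute missing encoded trait values by database-wide column means
#'
#' Every missing cell is replaced by the mean of its column computed over the
#' full database (not the training fold; the imputation is a property of the
#' database, applied before any split). Columns with no observed value are
#' dropped with a warning.
#'
#' @param enc an `encoded_traits` object.
#' @return an `encoded_traits` with complete `x`; the original missingness
#'   mask is retained.
#' @export
mean_impute <- function(enc) {
  x <- enc$x
  mu <- colMeans(x, na.rm = TRUE)
  drop <- !is.finite(mu)
  if (any(drop)) {
    warning("dropping ", sum(drop), " all-missing column(s): ",
            paste(colnames(x)[drop], collapse = ", "))
    x <- x[, !drop, drop = FALSE]
    mu <- mu[!drop]
  }
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mu[j]
  }
  out <- enc
  out$x <- x
  out$mask <- enc$mask[, colnames(x), drop = FALSE]
  out$map <- enc$map[enc$map$column %in% colnames(x), , drop = FALSE]
  out
}

#' Regression-fit metrics
#'
#' RMSE, Pearson and Spearman correlation of predicted against observed, and
#' the adjusted R-squared of the linear fit of observed on predicted (one
#' predictor, n = length of the vectors).
#'
#' @param observed,predicted equal-length numeric vectors.
#' @return list: `rmse`, `rho`, `rho_spearman`, `adj_r2` (correlations NA
#'   when either vector is constant).
#' @export
regression_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 1L)
  out <- list(rmse = sqrt(mean((predicted - observed)^2)),
              rho = NA_real_, rho_spearman = NA_real_, adj_r2 = NA_real_)
  if (stats::sd(observed) > 0 && stats::sd(predicted) > 0) {
    out$rho <- stats::cor(predicted, observed)
    out$rho_spearman <- stats::cor(predicted, observed, method = "spearman")
    n <- length(observed)
    if (n >= 3L) {
      r2 <- summary(stats::lm(observed ~ predicted))$r.squared
      out$adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
    }
  }
  out
}

rf_config <- function(config = list()) {
  defaults <- list(num_trees = 500L, stratify = TRUE, seed = 1L,
                   importance = TRUE)
  utils::modifyList(defaults, config)
}

#' Blocked random-forest classification
#'
#' For each fold of a clade-blocked [make_clade_folds()] specification, a
#' random forest (with stratified per-class bootstrap sampling equalized to
#' the minority class when `config$stratify`) is trained on all other folds
#' and evaluated on the held-out fold. Performance is Cohen's kappa and the
#' area under the precision-recall curve per fold, plus their means and the
#' kappa of the pooled out-of-fold predictions. Variable importances (mean
#' decrease in accuracy) are reported per training configuration and averaged.
#'
#' @param features complete numeric matrix, rownames = unit names.
#' @param labels binary label vector aligned with `features` rows.
#' @param folds a `fold_spec`.
#' @param config list: `num_trees` (default 500), `stratify` (TRUE),
#'   `seed` (master seed fanned out per fold), `importance` (TRUE).
#' @param positive positive-class label for AUPRC/scores (default the rarer
#'   class).
#' @return list: `per_fold` (fold, n_test, kappa, auprc, prevalence,
#'   skipped), `metrics` (mean_kappa, pooled_kappa, mean_auprc),
#'   `predictions` (unit, fold, truth, score, prediction), `importance`
#'   (fold, trait, importance) plus `importance_mean` (trait, importance,
#'   rank).
#' @export
blocked_classify <- function(features, labels, folds, config = list(),
                             positive = NULL) {
  cfg <- rf_config(config)
  stopifnot(inherits(folds, "fold_spec"), length(folds$folds) >= 2L)
  units <- rownames(features)
  stopifnot(!is.null(units), length(labels) == nrow(features))
  y <- factor(as.character(labels))
  if (nlevels(y) != 2L) stop("blocked_classify expects binary labels")
  if (is.null(positive)) positive <- names(sort(table(y)))[1L]
  names(y) <- units
  per_fold <- list(); preds <- list(); imps <- list()
  for (k in seq_along(folds$folds)) {
    fold_name <- names(folds$folds)[k]
    test_units <- intersect(folds$folds[[k]], units)
    train_units <- setdiff(units, folds$folds[[k]])
    row <- data.frame(fold = fold_name, n_test = length(test_units),
                      kappa = NA_real_, auprc = NA_real_,
                      prevalence = NA_real_, skipped = FALSE,
                      stringsAsFactors = FALSE)
    ytr <- droplevels(y[train_units])
    if (length(test_units) == 0L || nlevels(ytr) < 2L) {
      row$skipped <- TRUE
      per_fold[[k]] <- row
      next
    }
    fit <- with_seed(derive_seed(cfg$seed, k), {
      args <- list(x = features[train_units, , drop = FALSE], y = ytr,
                   ntree = cfg$num_trees, importance = cfg$importance)
      if (cfg$stratify) {
        nmin <- min(table(ytr))
        args$strata <- ytr
        args$sampsize <- rep(nmin, nlevels(ytr))
      }
      do.call(randomForest::randomForest, args)
    })
    prob <- predict(fit, features[test_units, , drop = FALSE], type = "prob")
    score <- prob[, as.character(positive)]
    pred <- levels(y)[apply(prob[, levels(y), drop = FALSE], 1L, which.max)]
    truth <- as.character(y[test_units])
    row$kappa <- cohens_kappa(truth, pred)
    row$prevalence <- mean(truth == as.character(positive))
    if (length(unique(truth)) == 2L)
      row$auprc <- precision_recall_auc(truth, score, positive)
    per_fold[[k]] <- row
    preds[[k]] <- data.frame(unit = test_units, fold = fold_name,
                             truth = truth, score = unname(score),
                             prediction = pred, stringsAsFactors = FALSE)
    if (cfg$importance) {
      im <- randomForest::importance(fit, type = 1L, scale = FALSE)
      imps[[k]] <- data.frame(fold = fold_name, trait = rownames(im),
                              importance = unname(im[, 1L]),
                              stringsAsFactors = FALSE)
    }
  }
  per_fold <- do.call(rbind, per_fold)
  predictions <- if (length(preds)) do.call(rbind, preds) else NULL
  importance <- if (length(imps)) do.call(rbind, imps) else NULL
  importance_mean <- NULL
  if (!is.null(importance)) {
    agg <- stats::aggregate(importance ~ trait, importance, mean)
    agg <- agg[order(-agg$importance, agg$trait), ]
    agg$rank <- seq_len(nrow(agg))
    rownames(agg) <- NULL
    importance_mean <- agg
  }
  pooled <- if (!is.null(predictions))
    cohens_kappa(predictions$truth, predictions$prediction) else NA_real_
  list(per_fold = per_fold,
       metrics = list(mean_kappa = mean(per_fold$kappa, na.rm = TRUE),
                      pooled_kappa = pooled,
                      mean_auprc = mean(per_fold$auprc, na.rm = TRUE)),
       predictions = predictions,
       importance = importance,
       importance_mean = importance_mean,
       positive = positive)
}

#' Blocked random-forest regression
#'
#' Clade-blocked analogue of [blocked_classify()] for a numeric response.
#' Per held-out fold: RMSE, Pearson and Spearman correlation between
#' predicted and observed, and the adjusted R-squared of the linear fit of
#' observed on predicted (n = fold test size, 1 predictor).
#'
#' @inheritParams blocked_classify
#' @param response numeric vector aligned with `features` rows.
#' @return list: `per_fold` (fold, n_test, rmse, rho, rho_spearman, adj_r2,
#'   constant_response), `metrics` (means), `predictions`, `importance`,
#'   `importance_mean`.
#' @export
blocked_regress <- function(features, response, folds, config = list()) {
  cfg <- rf_config(config)
  stopifnot(inherits(folds, "fold_spec"), length(folds$folds) >= 2L)
  units <- rownames(features)
  stopifnot(!is.null(units), length(response) == nrow(features))
  yr <- as.numeric(response); names(yr) <- units
  per_fold <- list(); preds <- list(); imps <- list()
  for (k in seq_along(folds$folds)) {
    fold_name <- names(folds$folds)[k]
    test_units <- intersect(folds$folds[[k]], units)
    train_units <- setdiff(units, folds$folds[[k]])
    row <- data.frame(fold = fold_name, n_test = length(test_units),
                      rmse = NA_real_, rho = NA_real_,
                      rho_spearman = NA_real_, adj_r2 = NA_real_,
                      constant_response = FALSE, stringsAsFactors = FALSE)
    if (length(test_units) == 0L || length(train_units) < 2L) {
      per_fold[[k]] <- row
      next
    }
    fit <- with_seed(derive_seed(cfg$seed, k),
      randomForest::randomForest(x = features[train_units, , drop = FALSE],
                                 y = yr[train_units], ntree = cfg$num_trees,
                                 importance = cfg$importance))
    pred <- predict(fit, features[test_units, , drop = FALSE])
    obs <- yr[test_units]
    mm <- regression_metrics(obs, pred)
    row$rmse <- mm$rmse
    if (is.na(mm$rho)) {
      row$constant_response <- TRUE
    } else {
      row$rho <- mm$rho
      row$rho_spearman <- mm$rho_spearman
      row$adj_r2 <- mm$adj_r2
    }
    per_fold[[k]] <- row
    preds[[k]] <- data.frame(unit = test_units, fold = fold_name,
                             truth = unname(obs), score = unname(pred),
                             prediction = unname(pred), stringsAsFactors = FALSE)
    if (cfg$importance) {
      im <- randomForest::importance(fit, type = 1L, scale = FALSE)
      imps[[k]] <- data.frame(fold = fold_name, trait = rownames(im),
                              importance = unname(im[, 1L]),
                              stringsAsFactors = FALSE)
    }
  }
  per_fold <- do.call(rbind, per_fold)
  importance <- if (length(imps)) do.call(rbind, imps) else NULL
  importance_mean <- NULL
  if (!is.null(importance)) {
    agg <- stats::aggregate(importance ~ trait, importance, mean)
    agg <- agg[order(-agg$importance, agg$trait), ]
    agg$rank <- seq_len(nrow(agg))
    rownames(agg) <- NULL
    importance_mean <- agg
  }
  list(per_fold = per_fold,
       metrics = list(mean_rmse = mean(per_fold$rmse, na.rm = TRUE),
                      mean_rho = mean(per_fold$rho, na.rm = TRUE),
                      mean_rho_spearman = mean(per_fold$rho_spearman, na.rm = TRUE),
                      mean_adj_r2 = mean(per_fold$adj_r2, na.rm = TRUE)),
       predictions = if (length(preds)) do.call(rbind, preds) else NULL,
       importance = importance,
       importance_mean = importance_mean)
}
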