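#' Graphical lasso at a single regularization value
#'
#' Estimates a sparse inverse covariance (precision) matrix by maximising
#' `log det(Theta) - tr(S Theta) - lambda * ||Theta||_1(off-diagonal)` with
#' block coordinate descent. Warm starts (`W0`, `B0`) carry the previous
#' solution along a lambda path.
#'
#' @param S empirical covariance/correlation matrix (symmetric, p x p).
#' @param lambda nonnegative L1 penalty.
#' @param W0,B0 optional warm-start covariance estimate and coefficient
#'   matrix from a previous fit.
#' @param penalize_diagonal apply the L1 penalty to the precision diagonal
#'   (default FALSE, matching common EBIC-glasso practice; diagonal
#'   penalization shrinks every partial correlation and biases the
#'   likelihood used for model selection).
#' @param tol,maxit,inner_maxit convergence controls.
#' @return list: `W` (covariance estimate), `Theta` (sparse precision),
#'   `B` (column lasso coefficients), `converged`.
#' @export
glasso_fit <- function(S, lambda, W0 = NULL, B0 = NULL,
                       penalize_diagonal = FALSE,
                       tol = 1e-4, maxit = 200L, inner_maxit = 200L) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), lambda >= 0)
  p <- nrow(S)
  if (is.null(W0)) {
    W0 <- S
    if (penalize_diagonal) diag(W0) <- diag(S) + lambda
  }
  if (is.null(B0)) B0 <- matrix(0, p, p)
  fit <- glasso_cpp(S, lambda, W0, B0, tol, as.integer(maxit),
                    as.integer(inner_maxit))
  dimnames(fit$W) <- dimnames(fit$Theta) <- dimnames(S)
  fit
}

#' Trait co-occurrence network by graphical lasso with EBIC selection
#'
#' Infers conditionally dependent trait-trait interactions from per-sample
#' trait profiles. Profiles are mean-imputed and standardized column-wise
#' (required for comparable penalization across mixed-scale traits), the
#' graphical lasso is fitted along a descending lambda path with warm starts,
#' and the path point minimising the extended Bayesian information criterion
#'
#' `EBIC(lambda) = -2 loglik + |E| log n + 4 |E| gamma log p`
#'
#' is selected, where `|E|` is the number of edges, `n` the sample count and
#' `p` the node count. `gamma = 0` reduces to ordinary BIC.
#'
#' @param x a `trait_profile` (traits x samples; transposed internally) or a
#'   samples x variables numeric matrix.
#' @param gamma EBIC hyperparameter (default 0.5, the conventional choice).
#' @param nlambda number of path points (default 100).
#' @param lambda_min_ratio smallest lambda as a fraction of `lambda_max`,
#'   the smallest lambda yielding an empty graph (default 0.01).
#' @param lambda_path optional explicit descending path (overrides the two
#'   arguments above).
#' @param edge_tol absolute precision-entry threshold defining an edge.
#' @param threshold when TRUE (default), partial correlations smaller in
#'   absolute value than `log(p * (p - 1) / 2) / sqrt(n)` are zeroed in the
#'   returned graph (the high-specificity thresholding rule common in EBIC
#'   glasso implementations). Shrinking the whole path enough to de-bias
#'   strong true edges lets hair-thin spurious partners slip in at the EBIC
#'   optimum; magnitude thresholding at the estimation-error scale is the
#'   standard remedy. Model selection itself always uses the unthresholded
#'   precision matrix.
#' @param ... passed to [glasso_fit()].
#' @return a `pcor_network`: list with `pcor` (signed partial correlations,
#'   zero off the selected graph), `theta`, `lambda`, `gamma`, `n`, `p`,
#'   `nodes`, `dropped` (constant columns excluded), and `path` (data frame
#'   lambda / edges / loglik / ebic / converged).
#' @export
fit_glasso_ebic <- function(x, gamma = 0.5, nlambda = 100L,
                            lambda_min_ratio = 0.01, lambda_path = NULL,
                            edge_tol = 1e-8, threshold = TRUE, ...) {
  if (inherits(x, "trait_profile")) x <- t(x$values)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 samples for network inference")
  # database-free mean imputation: profiles' own column means
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mean(x[, j], na.rm = TRUE)
  }
  sds <- apply(x, 2L, stats::sd)
  dropped <- colnames(x)[!is.finite(sds) | sds == 0]
  x <- x[, is.finite(sds) & sds > 0, drop = FALSE]
  p <- ncol(x)
  if (p < 2L) stop("fewer than 2 non-constant variables")
  x <- scale(x)
  S <- crossprod(x) / (n - 1)
  if (is.null(lambda_path)) {
    lmax <- max(abs(S[upper.tri(S)]))
    if (lmax <= 0) lmax <- 1e-3
    lambda_path <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                           length.out = nlambda))
  }
  lambda_path <- sort(lambda_path, decreasing = TRUE)
  pcor_thr <- if (threshold) log(p * (p - 1) / 2) / sqrt(n) else 0
  W <- NULL; B <- NULL
  path <- list(); fits <- list()
  for (i in seq_along(lambda_path)) {
    lam <- lambda_path[i]
    fit <- tryCatch(glasso_fit(S, lam, W0 = W, B0 = B, ...),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      warning("glasso did not converge at lambda = ", signif(lam, 4),
              "; dropping this path point")
      next
    }
    W <- fit$W; B <- fit$B
    th <- fit$Theta
    d <- sqrt(diag(th))
    pc <- -th / tcrossprod(d)
    # model complexity counts every nonzero precision entry; the magnitude
    # threshold only prunes the reported graph
    n_edges <- sum(abs(th) > edge_tol & upper.tri(th))
    n_reported <- sum(abs(th) > edge_tol & abs(pc) >= pcor_thr & upper.tri(th))
    loglik <- (n / 2) * (as.numeric(determinant(th, logarithm = TRUE)$modulus) -
                           sum(S * th))
    ebic <- -2 * loglik + n_edges * log(n) + 4 * n_edges * gamma * log(p)
    path[[length(path) + 1L]] <- data.frame(lambda = lam, edges = n_edges,
                                            edges_reported = n_reported,
                                            loglik = loglik, ebic = ebic)
    fits[[length(fits) + 1L]] <- th
  }
  if (!length(path)) stop("no converged glasso fit on the lambda path")
  path <- do.call(rbind, path)
  best <- which.min(path$ebic)
  theta <- fits[[best]]
  d <- sqrt(diag(theta))
  pcor <- -theta / tcrossprod(d)
  diag(pcor) <- 0
  pcor[abs(theta) <= edge_tol | abs(pcor) < pcor_thr] <- 0
  dimnames(pcor) <- dimnames(S)
  structure(list(pcor = pcor, theta = theta, lambda = path$lambda[best],
                 gamma = gamma, n = n, p = p, nodes = colnames(S),
                 dropped = dropped, path = path),
            class = "pcor_network")
}

#' @export
print.pcor_network <- function(x, ...) {
  ne <- sum(abs(x$pcor[upper.tri(x$pcor)]) > 0)
  cat("Partial-correlation network:", x$p, "nodes,", ne, "edges\n")
  cat("  lambda =", signif(x$lambda, 4), " (EBIC gamma =", x$gamma,
      ", n =", x$n, ")\n")
  invisible(x)
}

#' Edge list of a partial-correlation network
#' @param net a `pcor_network`.
#' @return data frame: from, to, weight (signed partial correlation).
#' @export
network_edges <- function(net) {
  idx <- which(abs(net$pcor) > 0 & upper.tri(net$pcor), arr.ind = TRUE)
  data.frame(from = net$nodes[idx[, 1L]], to = net$nodes[idx[, 2L]],
             weight = net$pcor[idx], stringsAsFactors = FALSE)
}
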