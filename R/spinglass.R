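#' Signed spin-glass (Potts) energy of a partition
#'
#' The energy rewards positive edge weight inside clusters and negative edge
#' weight between clusters, each part balanced against a configuration-model
#' null scaled by `gamma`:
#' `H = -sum_(i<j) [ (w+_ij - gamma p+_ij) - (w-_ij - gamma p-_ij) ] * delta(c_i, c_j)`
#' with `p±_ij = k±_i k±_j / (2 m±)` from the positive/negative degree
#' sequences. Lower energy = better partition.
#'
#' @param w symmetric signed weight matrix (zero diagonal).
#' @param membership integer community labels per node.
#' @param gamma null-model coupling (default 1).
#' @return the scalar energy.
#' @export
spinglass_energy <- function(w, membership, gamma = 1) {
  M <- spinglass_coupling(w, gamma)
  same <- outer(membership, membership, "==")
  -sum(M[same & upper.tri(M)])
}

# pairwise coupling matrix M: energy is -sum_{i<j, same cluster} M_ij
spinglass_coupling <- function(w, gamma = 1) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  wp <- pmax(w, 0); wn <- pmax(-w, 0)
  diag(wp) <- 0; diag(wn) <- 0
  null_part <- function(a) {
    m2 <- sum(a)
    if (m2 <= 0) return(matrix(0, nrow(a), ncol(a)))
    k <- rowSums(a)
    tcrossprod(k) / m2
  }
  M <- (wp - gamma * null_part(wp)) - (wn - gamma * null_part(wn))
  diag(M) <- 0
  M
}

#' Spin-glass community detection on a signed weighted network
#'
#' Partitions the non-isolated nodes of a partial-correlation network by
#' minimising the signed Potts energy of [spinglass_energy()] with simulated
#' annealing (geometric cooling, single-node relabelling moves) followed by a
#' greedy descent to a local optimum. Deterministic given `seed`.
#'
#' @param net a `pcor_network`, or a symmetric signed weight matrix with
#'   dimnames.
#' @param gamma spin-glass null-model coupling (default 1).
#' @param seed integer seed.
#' @param t0 initial temperature (default 1).
#' @param cooling geometric cooling factor per stage (default 0.9).
#' @param n_stages number of temperature stages (default 60).
#' @param sweeps_per_stage proposal sweeps (times n nodes) per stage.
#' @param max_communities cap on the number of spin states (default: number
#'   of nodes).
#' @return a `trait_clusters`: list with `membership` (named integer vector
#'   over non-isolated nodes), `energy`, `gamma`, `seed`, `isolated`
#'   (nodes with no incident edge; not clustered).
#' @export
spin_glass_communities <- function(net, gamma = 1, seed = 1L, t0 = 1,
                                   cooling = 0.9, n_stages = 60L,
                                   sweeps_per_stage = 20L,
                                   max_communities = NULL) {
  w <- if (inherits(net, "pcor_network")) net$pcor else as.matrix(net)
  stopifnot(nrow(w) == ncol(w))
  if (is.null(rownames(w))) rownames(w) <- colnames(w) <- paste0("n", seq_len(nrow(w)))
  deg <- rowSums(abs(w)) - abs(diag(w))
  isolated <- rownames(w)[deg == 0]
  keep <- deg > 0
  w <- w[keep, keep, drop = FALSE]
  n <- nrow(w)
  if (n == 0L)
    return(structure(list(membership = stats::setNames(integer(), character()),
                          energy = 0, gamma = gamma, seed = seed,
                          isolated = isolated), class = "trait_clusters"))
  M <- spinglass_coupling(w, gamma)
  K <- if (is.null(max_communities)) n else min(n, max_communities)
  with_seed(seed, {
    mem <- sample.int(K, n, replace = TRUE)
    temp <- t0
    for (stage in seq_len(n_stages)) {
      for (s in seq_len(sweeps_per_stage)) {
        order_i <- sample.int(n)
        for (i in order_i) {
          new_c <- sample.int(K, 1L)
          if (new_c == mem[i]) next
          # delta H of moving i: -(aff_new - aff_old)
          old_c <- mem[i]
          a_old <- sum(M[i, mem == old_c]) - M[i, i]
          a_new <- sum(M[i, mem == new_c])
          delta <- a_old - a_new
          if (delta < 0 || stats::runif(1) < exp(-delta / temp)) mem[i] <- new_c
        }
      }
      temp <- temp * cooling
    }
    # greedy descent: move each node to its best community until stable
    repeat {
      moved <- FALSE
      for (i in seq_len(n)) {
        a <- vapply(seq_len(K), function(cc)
          sum(M[i, mem == cc]) - ifelse(mem[i] == cc, M[i, i], 0), 0)
        best <- which.max(a)
        if (a[best] > a[mem[i]] + 1e-12) { mem[i] <- best; moved <- TRUE }
      }
      if (!moved) break
    }
    mem <- as.integer(factor(mem, levels = unique(mem)))
    names(mem) <- rownames(w)
    structure(list(membership = mem,
                   energy = spinglass_energy(w, mem, gamma),
                   gamma = gamma, seed = seed, isolated = isolated),
              class = "trait_clusters")
  })
}

#' @export
print.trait_clusters <- function(x, ...) {
  cat("Spin-glass trait clusters:", length(unique(x$membership)),
      "clusters over", length(x$membership), "nodes (",
      length(x$isolated), "isolated )\n")
  cat("  energy =", signif(x$energy, 6), ", gamma =", x$gamma, "\n")
  invisible(x)
}

#' Exhaustively minimise the spin-glass energy (small graphs)
#'
#' Enumerates every partition of up to `max_nodes` nodes (Bell-number
#' explosion beyond that) and returns the global energy minimiser. Intended
#' as an independent oracle for [spin_glass_communities()].
#'
#' @param w symmetric signed weight matrix.
#' @param gamma null-model coupling.
#' @param max_nodes refuse larger problems (default 10).
#' @return list: `membership`, `energy`.
#' @export
spinglass_exhaustive <- function(w, gamma = 1, max_nodes = 10L) {
  n <- nrow(w)
  if (n > max_nodes) stop("exhaustive search limited to ", max_nodes, " nodes")
  # enumerate set partitions in restricted-growth-string order
  best <- NULL; best_e <- Inf
  rgs <- integer(n)
  recurse <- function(i, maxlab) {
    if (i > n) {
      e <- spinglass_energy(w, rgs, gamma)
      if (e < best_e) { best_e <<- e; best <<- rgs }
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L)) {
      rgs[i] <<- lab
      recurse(i + 1L, max(maxlab, lab))
    }
  }
  recurse(1L, 0L)
  mem <- best
  names(mem) <- rownames(w)
  list(membership = mem, energy = best_e)
}
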