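#' Keep one sample per subject and body site
#'
#' Repeated samples from the same subject at the same site are not
#' statistically independent; before site contrasts one sample is retained
#' per (subject, body_site) pair, chosen uniformly at random.
#'
#' @param meta `sample_metadata`.
#' @param seed integer seed; the selection is deterministic given the seed.
#' @return character vector of retained sample ids.
#' @export
subsample_one_per_subject <- function(meta, seed) {
  with_seed(seed, {
    grp <- interaction(meta$subject_id, meta$body_site, drop = TRUE)
    picked <- vapply(split(meta$sample_id, grp),
                     function(ids) ids[sample.int(length(ids), 1L)], "")
    sort(unname(picked))
  })
}

#' Permutation test for a trait's mean difference between two body sites
#'
#' The test statistic is the difference of means (site A minus site B) of the
#' per-sample weighted trait values. Site labels are permuted `B` times; the
#' two-sided p-value uses the add-one estimator
#' `(1 + #(|perm diff| >= |observed|)) / (B + 1)`, so p is never below
#' `1/(B+1)`.
#'
#' @param profiles a `trait_profile` (see [weighted_trait_profile()]).
#' @param meta `sample_metadata` covering the profile's samples.
#' @param trait expanded-trait row name.
#' @param siteA,siteB body-site labels to contrast.
#' @param B number of permutations (default 10000).
#' @param seed integer seed.
#' @param samples optional sample-id subset (e.g. from
#'   [subsample_one_per_subject()]).
#' @param exact enumerate every label assignment instead of sampling
#'   (feasible only for small groups); the p-value is then the exact
#'   permutation tail without the add-one correction.
#' @return list: `trait`, `siteA`, `siteB`, `diff` (signed observed), `p`,
#'   `B`, `n_A`, `n_B`, `testable` (FALSE when either site has fewer than two
#'   non-missing values; then `p` and `diff` are NA).
#' @export
permutation_site_contrast <- function(profiles, meta, trait, siteA, siteB,
                                      B = 10000L, seed = 1L, samples = NULL,
                                      exact = FALSE) {
  v <- profiles$values[trait, ]
  meta <- meta[match(colnames(profiles$values), meta$sample_id), , drop = FALSE]
  keep <- !is.na(v) & meta$body_site %in% c(siteA, siteB)
  if (!is.null(samples)) keep <- keep & meta$sample_id %in% samples
  v <- v[keep]; site <- meta$body_site[keep]
  nA <- sum(site == siteA); nB <- sum(site == siteB)
  out <- list(trait = trait, siteA = siteA, siteB = siteB,
              diff = NA_real_, p = NA_real_, B = as.integer(B),
              n_A = nA, n_B = nB, testable = nA >= 2L && nB >= 2L)
  if (!out$testable) return(out)
  a <- v[site == siteA]; b <- v[site == siteB]
  obs <- mean(a) - mean(b)
  pool <- c(a, b); n <- length(pool); tot <- sum(pool)
  out$diff <- obs
  if (exact) {
    sets <- utils::combn(n, nA)
    perm <- apply(sets, 2L, function(idx) {
      sa <- sum(pool[idx]); sa / nA - (tot - sa) / nB
    })
    out$B <- ncol(sets)
    out$p <- mean(abs(perm) >= abs(obs) - 1e-12)
  } else {
    perm <- with_seed(seed, vapply(seq_len(B), function(i) {
      sa <- sum(pool[sample.int(n, nA)])
      sa / nA - (tot - sa) / nB
    }, 0))
    out$p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (B + 1)
  }
  out
}

#' All pairwise site contrasts for every trait of a profile
#'
#' Runs [permutation_site_contrast()] for every expanded trait and every
#' unordered pair of the given sites, then applies Benjamini-Hochberg
#' adjustment across all testable results (one family per call; when called
#' per phylum, the family is that phylum's trait x site-pair grid).
#'
#' @inheritParams permutation_site_contrast
#' @param sites body sites to contrast (default: all sites in `meta` with
#'   samples in the profile); pairs are taken in sorted order.
#' @param traits optional subset of expanded traits (default all).
#' @param alpha BH false-discovery level for the `reject` column.
#' @return tidy data frame: trait, siteA, siteB, diff, p, q, reject, n_A,
#'   n_B, testable.
#' @export
site_contrast_table <- function(profiles, meta, sites = NULL, traits = NULL,
                                B = 10000L, seed = 1L, samples = NULL,
                                alpha = 0.05) {
  meta2 <- meta[match(colnames(profiles$values), meta$sample_id), , drop = FALSE]
  if (is.null(sites)) sites <- sort(unique(meta2$body_site))
  if (is.null(traits)) traits <- rownames(profiles$values)
  pairs <- utils::combn(sort(sites), 2L)
  rows <- list(); k <- 0L
  for (j in seq_len(ncol(pairs))) {
    for (tr in traits) {
      k <- k + 1L
      r <- permutation_site_contrast(profiles, meta, tr, pairs[1L, j], pairs[2L, j],
                                     B = B, seed = derive_seed(seed, k),
                                     samples = samples)
      rows[[k]] <- as.data.frame(r, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_; out$reject <- FALSE
  if (any(out$testable)) {
    adj <- bh_adjust(out$p[out$testable], alpha = alpha)
    out$q[out$testable] <- adj$q
    out$reject[out$testable] <- adj$reject
  }
  out[, c("trait", "siteA", "siteB", "diff", "p", "q", "reject",
          "n_A", "n_B", "testable")]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up procedure: with ordered p-values p(1) <= ... <= p(m),
#' q(i) = min over j >= i of m * p(j) / j (capped at 1); the rejection set at
#' level alpha is every test with q <= alpha.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @param alpha false-discovery level (default 0.05).
#' @return list: `q` (adjusted values, input order) and `reject` (logical).
#' @export
bh_adjust <- function(pvalues, alpha = 0.05) {
  m <- length(pvalues)
  if (m == 0L) return(list(q = numeric(), reject = logical()))
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  o <- order(pvalues)
  q_sorted <- pmin(1, rev(cummin(rev(pvalues[o] * m / seq_len(m)))))
  q <- numeric(m); q[o] <- q_sorted
  list(q = q, reject = !is.na(q) & q <= alpha)
}

#' Cross-phylum replication filter for site contrasts
#'
#' A (trait, site pair) contrast is ecologically informative when it is
#' BH-significant independently in at least `min_phyla` phyla. Contrasts
#' whose significant signs disagree across phyla are retained but flagged.
#'
#' @param per_phylum named list of per-phylum [site_contrast_table()] results.
#' @param min_phyla minimum number of phyla (default 2).
#' @return data frame: trait, siteA, siteB, n_phyla, phyla (comma-joined),
#'   consensus_sign (+1/-1, NA under conflict), sign_conflict.
#' @export
replicate_across_phyla <- function(per_phylum, min_phyla = 2L) {
  stopifnot(is.list(per_phylum), !is.null(names(per_phylum)))
  hits <- list()
  for (ph in names(per_phylum)) {
    d <- per_phylum[[ph]]
    d <- d[d$testable & d$reject, , drop = FALSE]
    if (nrow(d)) {
      d$phylum <- ph
      hits[[ph]] <- d[, c("trait", "siteA", "siteB", "diff", "phylum")]
    }
  }
  empty <- data.frame(trait = character(), siteA = character(),
                      siteB = character(), n_phyla = integer(),
                      phyla = character(), consensus_sign = integer(),
                      sign_conflict = logical(), stringsAsFactors = FALSE)
  if (!length(hits)) return(empty)
  all_hits <- do.call(rbind, hits)
  key <- paste(all_hits$trait, all_hits$siteA, all_hits$siteB, sep = "\r")
  rows <- lapply(split(all_hits, key), function(d) {
    if (length(unique(d$phylum)) < min_phyla) return(NULL)
    signs <- unique(sign(d$diff))
    data.frame(trait = d$trait[1], siteA = d$siteA[1], siteB = d$siteB[1],
               n_phyla = length(unique(d$phylum)),
               phyla = paste(sort(unique(d$phylum)), collapse = ","),
               consensus_sign = if (length(signs) == 1L) as.integer(signs) else NA_integer_,
               sign_conflict = length(signs) > 1L,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
          else assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed)
  expr
}
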