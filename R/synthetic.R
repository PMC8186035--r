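#' Configuration for a synthetic microbiome world
#'
#' Bundles every knob of the generator: taxonomy sizes, sample design, trait
#' counts and covariance structure, planted site-trait effects, the
#' generalism-determining rule, and missingness rates. Defaults emulate an
#' HMP-style study at desk scale: 4 phyla x 75 taxa, 45 subjects sampled at
#' 7 body sites across the 5 body areas, 8 continuous traits with
#' block-structured covariance (3 blocks), 4 three-level categorical traits,
#' and 30 binary traits (20 of them carbon substrates) evolved on per-phylum
#' coalescent trees.
#'
#' @param n_phyla,taxa_per_phylum,classes_per_phylum,families_per_class
#'   taxonomy dimensions.
#' @param n_subjects,samples_per_subject sample design (sites are drawn per
#'   sample from `site_weights`).
#' @param n_continuous,cont_blocks,cont_partial continuous-trait count, block
#'   sizes of the precision matrix, and the within-block off-diagonal
#'   precision entry.
#' @param n_categorical,n_cat_levels categorical-trait design.
#' @param n_carbon,n_binary_other binary-trait counts (carbon substrates vs
#'   other assays).
#' @param alpha_bin phylogenetic-signal decay rate for binary-trait evolution
#'   (tree depth is scaled to 1; smaller = stronger signal).
#' @param phylum_shift_sd SD of per-phylum location shifts of continuous
#'   traits (trait units; traits remain comparable across phyla when small).
#' @param phylum_prevalence_sd SD (logit scale) of per-phylum deviation of
#'   binary-trait prevalence around its global baseline.
#' @param effect_size planted site-trait effect in SD units (0 = null world).
#' @param tilt_frac fraction of `effect_size` also applied as a within-sample
#'   abundance tilt (resident taxa whose traits match the area's signature
#'   are proportionally more abundant, not just more likely to reside).
#' @param frac_generalists,generalism_beta,area_leak generalism rule: target
#'   generalist fraction, log-odds boost of the driver trait, and the
#'   relative concentration a taxon keeps outside its home areas.
#' @param dirichlet_conc concentration scale of the per-sample Dirichlet
#'   abundance draws (smaller = sparser communities).
#' @param detection_limit relative abundances below this are zeroed (and the
#'   sample renormalized), creating true absences.
#' @param miss_continuous,miss_categorical missingness rates (binary traits
#'   are never missing, matching the 0-coding convention).
#' @param genus_only_frac fraction of singleton-genus taxa whose abundance
#'   rows carry only the genus name (exercising genus-level matching).
#' @return a `world_config` list.
#' @export
world_config <- function(n_phyla = 4L, taxa_per_phylum = 75L,
                         classes_per_phylum = 3L, families_per_class = 2L,
                         n_subjects = 45L, samples_per_subject = c(4L, 5L),
                         n_continuous = 8L, cont_blocks = c(3L, 3L, 2L),
                         cont_partial = -0.3,
                         n_categorical = 4L, n_cat_levels = 3L,
                         n_carbon = 20L, n_binary_other = 10L,
                         alpha_bin = 1,
                         phylum_shift_sd = 0.25,
                         phylum_prevalence_sd = 0.15,
                         effect_size = 2, tilt_frac = 0.5,
                         frac_generalists = 0.25, generalism_beta = 2.5,
                         area_leak = 0.01,
                         dirichlet_conc = 0.3, detection_limit = 1e-4,
                         miss_continuous = 0.15, miss_categorical = 0.10,
                         genus_only_frac = 0.08) {
  if (sum(cont_blocks) != n_continuous)
    stop("cont_blocks must sum to n_continuous")
  if (length(cont_blocks) > n_continuous)
    stop("infeasible config: more blocks than continuous traits")
  if (n_phyla < 2L) stop("need >= 2 phyla for replication analyses")
  cfg <- as.list(environment())
  cfg$sites <- data.frame(
    site = c("stool", "posterior_fornix", "buccal_mucosa",
             "supragingival_plaque", "tongue_dorsum", "anterior_nares",
             "retroauricular_crease"),
    area = c("gut", "vagina", "mouth", "mouth", "mouth", "airways", "skin"),
    stringsAsFactors = FALSE)
  cfg$site_weights <- c(stool = 0.24, posterior_fornix = 0.13,
                        buccal_mucosa = 0.11, supragingival_plaque = 0.11,
                        tongue_dorsum = 0.13, anterior_nares = 0.14,
                        retroauricular_crease = 0.14)
  structure(cfg, class = "world_config")
}

# default planted effect matrix: each area selects on its own signature set
# of traits (1 continuous, 3 carbon substrates, 1 other binary; signs
# alternate within the set), with no trait shared between areas, mirroring
# the multi-trait site differences real body sites show
default_site_effects <- function(cfg) {
  areas <- unique(cfg$sites$area)
  n_area <- length(areas)
  if (cfg$n_continuous < n_area || cfg$n_carbon < 3L * n_area ||
      cfg$n_binary_other < n_area + 1L)
    stop("default site effects need >= ", n_area, " continuous, ",
         3L * n_area, " carbon and ", n_area + 1L, " other binary traits; ",
         "pass a custom effect table for smaller worlds")
  eff <- list()
  add <- function(area, trait, e)
    eff[[length(eff) + 1L]] <<- data.frame(area = area, trait = trait,
                                           effect = e, stringsAsFactors = FALSE)
  for (i in seq_along(areas)) {
    sgn <- if (i %% 2L == 0L) -1 else 1
    add(areas[i], paste0("cont_", i), sgn * cfg$effect_size)
    for (j in 1:3)
      add(areas[i], paste0("carbon_", 3L * (i - 1L) + j),
          sgn * (-1)^j * cfg$effect_size)
    add(areas[i], paste0("bin_", i + 1L), -sgn * cfg$effect_size)
  }
  do.call(rbind, eff)
}

block_precision <- function(sizes, off) {
  p <- sum(sizes)
  om <- diag(p)
  start <- cumsum(c(1L, sizes))
  for (b in seq_along(sizes)) {
    idx <- seq(start[b], length.out = sizes[b])
    om[idx, idx] <- off
  }
  diag(om) <- 1
  om
}

#' Draw sample profiles from a block-diagonal precision matrix
#'
#' Generates an n x p Gaussian matrix whose precision matrix is block
#' diagonal (within-block off-diagonal entries `off`, diagonal 1), the
#' ground truth for network-recovery tests.
#'
#' @param n samples.
#' @param blocks integer block sizes.
#' @param off within-block precision off-diagonal (default -0.4, i.e.
#'   positive partial correlation 0.4).
#' @param seed integer seed.
#' @return list: `x` (n x p matrix, columns `v1..vp`), `block` (integer
#'   block label per column), `precision` (the true precision matrix).
#' @export
simulate_block_profiles <- function(n, blocks = c(3L, 3L, 2L), off = -0.4,
                                    seed = 1L) {
  om <- block_precision(blocks, off)
  if (min(eigen(om, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("block precision matrix is not positive definite; reduce |off|")
  sig <- solve(om)
  x <- with_seed(seed, MASS::mvrnorm(n, mu = rep(0, sum(blocks)), Sigma = sig))
  colnames(x) <- paste0("v", seq_len(sum(blocks)))
  list(x = x, block = rep(seq_along(blocks), blocks), precision = om)
}

#' Simulate a complete synthetic microbiome world
#'
#' Generates, deterministically given `seed`: per-phylum coalescent
#' phylogenies with clade (class/family) annotations; a species-rank trait
#' database (continuous traits from a block-precision multivariate normal,
#' categorical traits from per-phylum multinomials, binary traits evolved on
#' the trees with phylogenetic signal); planted generalist taxa whose
#' probability of holding multiple home areas is boosted by a driver trait;
#' HMP-style sample metadata; and per-sample relative abundances from
#' site-specific Dirichlet draws whose concentrations favour taxa whose
#' traits match the planted site-trait effects. The ground-truth ledger
#' records everything a recovery test needs to score.
#'
#' @param config a [world_config()].
#' @param seed master integer seed.
#' @return a `synthetic_world`: list with `config`, `schema`, `db` (species
#'   `trait_table`), `ab` (`abundance_table`), `meta` (`sample_metadata`),
#'   `trees` (named list of `phylo` per phylum), and `truth` (site_effects,
#'   cont_blocks, generalists, home_areas, generalism_trait/beta, labels).
#' @export
simulate_world <- function(config = world_config(), seed = 1L) {
  cfg <- config
  with_seed(derive_seed(seed, 0L), {
    phyla <- paste0("phylum", letters[seq_len(cfg$n_phyla)])
    trees <- list(); tax_rows <- list()
    for (pi in seq_along(phyla)) {
      ph <- phyla[pi]
      nt <- cfg$taxa_per_phylum
      # genera of size 1-4 within the phylum
      gsizes <- c()
      while (sum(gsizes) < nt)
        gsizes <- c(gsizes, sample(1:4, 1L))
      gsizes[length(gsizes)] <- gsizes[length(gsizes)] - (sum(gsizes) - nt)
      gsizes <- gsizes[gsizes > 0L]
      genus <- rep(paste0("g", letters[pi], seq_along(gsizes)), gsizes)
      sp_idx <- unlist(lapply(gsizes, seq_len))
      ids <- paste0(genus, " sp", sp_idx)
      tree <- ape::rcoal(nt, tip.label = sample(ids))
      depth <- max(ape::node.depth.edgelength(tree))
      tree$edge.length <- tree$edge.length / depth
      trees[[ph]] <- tree
      D <- ape::cophenetic.phylo(tree)
      hc <- stats::hclust(stats::as.dist(D), method = "average")
      cls <- stats::cutree(hc, k = min(cfg$classes_per_phylum, nt))
      fam <- stats::cutree(hc, k = min(cfg$classes_per_phylum *
                                         cfg$families_per_class, nt))
      tax_rows[[ph]] <- data.frame(
        taxon = ids, genus = genus, phylum = ph,
        class = paste0("class_", ph, "_", cls[ids]),
        order = paste0("order_", ph, "_", cls[ids]),
        family = paste0("family_", ph, "_", fam[ids]),
        stringsAsFactors = FALSE)
    }
    tax <- do.call(rbind, tax_rows)
    rownames(tax) <- NULL
    n_taxa <- nrow(tax)

    # ---- schema ----------------------------------------------------------
    cont_names <- paste0("cont_", seq_len(cfg$n_continuous))
    cat_names <- if (cfg$n_categorical > 0L)
      paste0("cat_", seq_len(cfg$n_categorical)) else character()
    carbon_names <- paste0("carbon_", seq_len(cfg$n_carbon))
    bin_names <- if (cfg$n_binary_other > 0L)
      paste0("bin_", seq_len(cfg$n_binary_other)) else character()
    cat_levels <- paste0("lv", seq_len(cfg$n_cat_levels))
    schema <- trait_schema(
      trait = c(cont_names, cat_names, carbon_names, bin_names),
      kind = c(rep("continuous", length(cont_names)),
               rep("categorical", length(cat_names)),
               rep("binary", length(carbon_names) + length(bin_names))),
      category = c(rep(c("genomic", "growth_condition"),
                       length.out = length(cont_names)),
                   rep(c("morphology", "growth_condition"),
                       length.out = length(cat_names)),
                   rep("carbon_substrate", length(carbon_names)),
                   rep(c("enzyme_assay", "gas_production"),
                       length.out = length(bin_names))),
      levels = c(replicate(length(cont_names), character(), simplify = FALSE),
                 replicate(length(cat_names), cat_levels, simplify = FALSE),
                 replicate(length(carbon_names) + length(bin_names),
                           character(), simplify = FALSE)),
      units = c(rep("unit", length(cont_names)),
                rep("", length(cat_names) + length(carbon_names) +
                      length(bin_names))))

    # ---- trait values ----------------------------------------------------
    om <- block_precision(cfg$cont_blocks, cfg$cont_partial)
    sig <- solve(om)
    cont <- matrix(NA_real_, n_taxa, cfg$n_continuous,
                   dimnames = list(tax$taxon, cont_names))
    cats <- matrix(NA_character_, n_taxa, length(cat_names),
                   dimnames = list(tax$taxon, cat_names))
    bins <- matrix(0L, n_taxa, length(carbon_names) + length(bin_names),
                   dimnames = list(tax$taxon, c(carbon_names, bin_names)))
    # binary traits share a global baseline prevalence with modest
    # phylum-level deviation (logit sd 0.3), so the same trait means the
    # same thing across phyla
    p0_global <- stats::runif(ncol(bins), 0.2, 0.8)
    names(p0_global) <- colnames(bins)
    for (ph in phyla) {
      rows <- which(tax$phylum == ph)
      mu_ph <- stats::rnorm(cfg$n_continuous, 0, cfg$phylum_shift_sd)
      cont[rows, ] <- MASS::mvrnorm(length(rows), mu = mu_ph, Sigma = sig)
      for (cn in cat_names) {
        pr <- stats::rgamma(cfg$n_cat_levels, 2); pr <- pr / sum(pr)
        cats[rows, cn] <- sample(cat_levels, length(rows), TRUE, prob = pr)
      }
      tree <- trees[[ph]]
      norm_ids <- normalize_taxon_id(tax$taxon[rows])
      for (bn in colnames(bins)) {
        b0 <- stats::qlogis(p0_global[bn]) +
          stats::rnorm(1, 0, cfg$phylum_prevalence_sd)
        yb <- simulate_binary_on_tree(tree, b0, 0, 0,
                                      alpha = cfg$alpha_bin,
                                      seed = sample.int(2^30, 1L))
        bins[rows, bn] <- unname(yb[norm_ids])
      }
    }
    # missingness (never on binary traits)
    cont[matrix(stats::runif(length(cont)) < cfg$miss_continuous,
                nrow(cont))] <- NA_real_
    cats[matrix(stats::runif(length(cats)) < cfg$miss_categorical,
                nrow(cats))] <- NA_character_

    raw <- data.frame(taxon = tax$taxon, rank = "species",
                      phylum = tax$phylum, class = tax$class,
                      order = tax$order, family = tax$family,
                      stringsAsFactors = FALSE)
    for (cn in cont_names) raw[[cn]] <- cont[, cn]
    for (cn in cat_names) raw[[cn]] <- cats[, cn]
    for (cn in colnames(bins)) raw[[cn]] <- bins[, cn]
    db <- validate_trait_table(raw, schema)

    # ---- generalism rule and habitat filtering ---------------------------
    areas <- unique(cfg$sites$area)
    driver <- if (length(bin_names)) bin_names[1L] else carbon_names[1L]
    drv <- as.numeric(db[[driver]])
    a0 <- stats::qlogis(cfg$frac_generalists) - cfg$generalism_beta * mean(drv)
    is_gen <- stats::runif(n_taxa) < stats::plogis(a0 + cfg$generalism_beta * drv)

    site_effects <- if (cfg$effect_size != 0) default_site_effects(cfg)
                    else data.frame(area = character(), trait = character(),
                                    effect = numeric())
    # habitat filtering: a taxon's home area(s) are drawn with probability
    # proportional to exp(sum of planted area-trait effects times its
    # standardized trait values), so the taxa resident in an area carry
    # systematically shifted trait values
    enc <- encode_traits(db, schema)
    z <- scale(enc$x)
    z[is.na(z) | is.nan(z)] <- 0
    area_base <- c(gut = 0.3, vagina = 0.15, mouth = 0.25,
                   skin = 0.15, airways = 0.15)[areas]
    logits <- matrix(log(area_base), n_taxa, length(areas), byrow = TRUE,
                     dimnames = list(db$taxon_id, areas))
    if (nrow(site_effects)) for (r in seq_len(nrow(site_effects))) {
      cols <- enc$map$column[enc$map$trait == site_effects$trait[r]]
      if (!length(cols)) stop("effect trait not in encoding: ",
                              site_effects$trait[r])
      logits[, site_effects$area[r]] <- logits[, site_effects$area[r]] +
        site_effects$effect[r] * rowMeans(z[, cols, drop = FALSE])
    }
    home_areas <- lapply(seq_len(n_taxa), function(i) {
      pr <- exp(logits[i, ] - max(logits[i, ]))
      sample(areas, if (is_gen[i]) sample(2:3, 1L) else 1L, prob = pr / sum(pr))
    })
    names(home_areas) <- db$taxon_id
    meta_rows <- list()
    for (s in seq_len(cfg$n_subjects)) {
      k <- sample(seq(cfg$samples_per_subject[1], cfg$samples_per_subject[2]), 1L)
      st <- sample(cfg$sites$site, k, TRUE, prob = cfg$site_weights[cfg$sites$site])
      meta_rows[[s]] <- data.frame(
        sample_id = paste0("subj", s, "_smp", seq_len(k)),
        subject_id = paste0("subj", s),
        body_site = st,
        body_area = cfg$sites$area[match(st, cfg$sites$site)],
        stringsAsFactors = FALSE)
    }
    meta <- validate_sample_metadata(do.call(rbind, meta_rows))

    # ---- abundances ------------------------------------------------------
    base <- exp(stats::rnorm(n_taxa, 0, 1))
    pref <- matrix(cfg$area_leak, n_taxa, length(areas),
                   dimnames = list(db$taxon_id, areas))
    for (i in seq_len(n_taxa)) pref[i, home_areas[[i]]] <- 1
    # within-sample selection: residents matching the area signature are
    # proportionally more abundant (same planted effects, scaled by tilt_frac)
    tilt <- matrix(0, n_taxa, length(areas),
                   dimnames = list(db$taxon_id, areas))
    if (nrow(site_effects) && cfg$tilt_frac > 0)
      tilt <- (logits - matrix(log(area_base), n_taxa, length(areas),
                               byrow = TRUE)) * cfg$tilt_frac
    A <- matrix(0, n_taxa, nrow(meta),
                dimnames = list(db$taxon_id, meta$sample_id))
    for (s in seq_len(nrow(meta))) {
      w <- base * pref[, meta$body_area[s]] * exp(tilt[, meta$body_area[s]])
      shape <- cfg$dirichlet_conc * w / mean(w)
      g <- stats::rgamma(n_taxa, shape = shape, rate = 1)
      x <- g / sum(g)
      x[x < cfg$detection_limit] <- 0
      if (sum(x) == 0) x[which.max(g)] <- 1
      A[, s] <- x / sum(x)
    }

    # some singleton-genus taxa are only identified to genus level
    gtab <- table(tax$genus)
    singletons <- which(tax$genus %in% names(gtab)[gtab == 1L])
    n_gen_only <- floor(cfg$genus_only_frac * length(singletons))
    gen_only <- sort(sample(singletons, n_gen_only))
    ab_labels <- tax$taxon
    ab_labels[gen_only] <- tax$genus[gen_only]
    ab <- new_abundance_table(A, ab_labels)

    structure(list(
      config = cfg, schema = schema, db = db, ab = ab, meta = meta,
      trees = trees,
      truth = list(site_effects = site_effects,
                   cont_blocks = rep(seq_along(cfg$cont_blocks), cfg$cont_blocks),
                   generalists = db$taxon_id[is_gen],
                   home_areas = home_areas,
                   generalism_trait = driver,
                   generalism_beta = cfg$generalism_beta,
                   genus_only = normalize_taxon_id(tax$genus[gen_only]),
                   seed = seed)),
      class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic microbiome world:", nrow(x$db), "taxa,",
      ncol(x$ab$x), "samples,", nrow(x$schema), "traits,",
      length(x$trees), "phyla\n")
  invisible(x)
}

#' Write a synthetic world to disk in the package's input dialects
#'
#' Emits the trait table + schema, the abundance matrix (first column a
#' pipe-delimited lineage string; optionally bz2-compressed), sample
#' metadata, one Newick tree per phylum, and the ground-truth ledger as JSON.
#' Files re-parse (via [read_trait_table()], [read_abundance()],
#' [read_newick()]) to the in-memory objects.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @param bz2 compress the abundance matrix (default FALSE).
#' @return named character vector of the written paths.
#' @export
write_world <- function(world, dir, bz2 = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(traits = file.path(dir, "traits.tsv"),
             schema = file.path(dir, "trait_schema.tsv"),
             abundance = file.path(dir, if (bz2) "abundance.tsv.bz2"
                                        else "abundance.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.json"))
  write_trait_table(world$db, paths["traits"])
  write_trait_schema(world$schema, paths["schema"])
  db <- world$db
  lin_lookup <- function(id) {
    i <- match(id, db$taxon_id)
    if (is.na(i)) {  # genus-only row: lineage from any member species
      j <- which(genus_of(db) == id)[1]
      paste("bacteria", db$phylum[j], db$class[j], db$family[j], id, sep = "|")
    } else paste("bacteria", db$phylum[i], db$class[i], db$family[i],
                 db$taxon[i], sep = "|")
  }
  adf <- data.frame(lineage = vapply(rownames(world$ab$x), lin_lookup, ""),
                    world$ab$x, check.names = FALSE, stringsAsFactors = FALSE)
  if (bz2) {
    con <- bzfile(paths["abundance"], "w")
    utils::write.table(adf, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  } else write_tsv(adf, paths["abundance"])
  write_tsv(world$meta, paths["metadata"])
  for (ph in names(world$trees)) {
    p <- file.path(dir, paste0("tree_", ph, ".nwk"))
    ape::write.tree(world$trees[[ph]], p)
    paths[paste0("tree_", ph)] <- p
  }
  truth <- world$truth
  truth$home_areas <- lapply(truth$home_areas, as.list)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  paths
}
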