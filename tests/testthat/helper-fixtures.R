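# shared fixtures, built once per test run

demo_schema <- function() {
  trait_schema(
    trait = c("optimal_temp", "oxygen", "glucose", "xylose", "catalase"),
    kind = c("continuous", "categorical", "binary", "binary", "binary"),
    category = c("growth_condition", "growth_condition", "carbon_substrate",
                 "carbon_substrate", "enzyme_assay"),
    levels = list(character(), c("aerobe", "anaerobe", "facultative"),
                  character(), character(), character()),
    units = c("C", "", "", "", ""))
}

# write a small trait-table file and return its path
demo_trait_file <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "traits.tsv")
  df <- data.frame(
    taxon = c("Alpha one", "Alpha two", "Beta uno"),
    rank = "species",
    phylum = c("p1", "p1", "p2"), class = "c1", order = "o1", family = "f1",
    optimal_temp = c("37", "NA", "25.5"),
    oxygen = c("aerobe", "facultative", ""),
    glucose = c("1", "", "0"),
    xylose = c("0", "1", "1"),
    catalase = c("1", "1", ""),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small worlds are expensive; build once and memoise across tests
.world_cache <- new.env(parent = emptyenv())

cached_world <- function(key, config, seed) {
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- simulate_world(config, seed = seed)
  .world_cache[[key]]
}

small_world <- function(seed = 101L) {
  cached_world(paste0("small", seed),
               world_config(taxa_per_phylum = 40L, n_subjects = 30L,
                            samples_per_subject = c(3L, 4L)),
               seed)
}

# recovery scenario: strong planted effects, phylum nuisance minimised
recovery_config <- function(effect_size = 3) {
  world_config(effect_size = effect_size, tilt_frac = 1, alpha_bin = 6,
               phylum_shift_sd = 0.1, phylum_prevalence_sd = 0.05)
}

# global null: no planted effects and no habitat filtering, so body site
# carries no information about composition
null_config <- function() {
  world_config(effect_size = 0, area_leak = 1, alpha_bin = 6,
               phylum_shift_sd = 0.1, phylum_prevalence_sd = 0.05)
}

# assemble the phyla-sample feature matrix + site labels for site tasks
phyla_sample_features <- function(world) {
  db2 <- habitraits:::combined_database(world$db)
  enc <- encode_traits(db2)
  m <- match_taxa(world$ab, db2)
  phyla <- sort(unique(world$db$phylum))
  Xl <- list(); fold_lab <- c()
  for (ph in phyla) {
    pr <- weighted_trait_profile(world$ab, enc, db2, match = m,
                                 restrict_phylum = ph)
    v <- t(pr$values)
    v <- v[rowSums(!is.na(v)) > 0, , drop = FALSE]
    rownames(v) <- paste(ph, rownames(v), sep = "::")
    Xl[[ph]] <- v
    fold_lab <- c(fold_lab, rep(ph, nrow(v)))
  }
  X <- do.call(rbind, Xl)
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[, j], na.rm = TRUE)
  }
  samp <- sub("^.*::", "", rownames(X))
  list(X = X, fold_lab = fold_lab,
       site = world$meta$body_site[match(samp, world$meta$sample_id)],
       area = world$meta$body_area[match(samp, world$meta$sample_id)])
}
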