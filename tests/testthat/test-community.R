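test_that("abundance reader round-trips generator output and drops orphan samples", {
  w <- small_world()
  d <- withr::local_tempdir()
  paths <- write_world(w, d)
  r <- read_abundance(paths[["abundance"]], paths[["metadata"]])
  expect_equal(dim(r$ab$x), dim(w$ab$x))
  expect_identical(rownames(r$ab$x), rownames(w$ab$x))
  expect_equal(unname(r$ab$x), unname(w$ab$x), tolerance = 1e-12)
  expect_identical(as.data.frame(r$meta), as.data.frame(w$meta))
  # a sample column missing from the metadata is dropped with a warning
  meta2 <- w$meta[-1, ]
  write.table(meta2, file.path(d, "meta2.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_warning(r2 <- read_abundance(paths[["abundance"]], file.path(d, "meta2.tsv")),
                 "dropping 1")
  expect_equal(ncol(r2$ab$x), ncol(w$ab$x) - 1L)
  # non-numeric abundance cell is a parse error with a location
  lines <- readLines(paths[["abundance"]])
  lines[2] <- sub("\t[0-9.e-]+$", "\toops", lines[2])
  writeLines(lines, file.path(d, "bad_ab.tsv"))
  expect_error(read_abundance(file.path(d, "bad_ab.tsv"), paths[["metadata"]]),
               "parse error")
})

test_that("taxon matching prefers species and falls back to genus consensus", {
  sc <- demo_schema()
  tt <- read_trait_table(demo_trait_file(), sc)
  db <- habitraits:::new_trait_table(
    rbind(as.data.frame(tt), as.data.frame(genus_consensus(tt))), sc)
  ab <- habitraits:::new_abundance_table(
    matrix(0.25, 4, 1, dimnames = list(NULL, "s1")),
    c("Alpha one", "Alpha unknown", "Beta uno", "Gamma thing"))
  m <- match_taxa(ab, db)
  expect_identical(m$rank_used, c("species", "genus", "species", NA))
  expect_identical(m$db_taxon_id[2], "alpha")
  expect_identical(m$matched, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("weighted profiles renormalize over informing taxa", {
  sc <- trait_schema("temp", "continuous", "growth_condition", units = "C")
  raw <- data.frame(taxon = c("A a", "B b", "C c"), rank = "species",
                    phylum = "p", class = "c", order = "o", family = "f",
                    temp = c("10", "20", ""))
  db <- habitraits:::validate_trait_table(raw, sc)
  enc <- encode_traits(db)
  ab <- habitraits:::new_abundance_table(
    matrix(c(0.6, 0.4, 0,   # s1: plain weighted mean
             0.6, 0, 0.4,   # s2: C missing -> renormalize to A alone
             0.2, 0.8, 0), 3, dimnames = list(NULL, c("s1", "s2", "s3"))),
    c("A a", "B b", "C c"))
  pr <- weighted_trait_profile(ab, enc, db)
  expect_equal(pr$values["temp", "s1"], 14)
  expect_equal(pr$values["temp", "s2"], 10)
  # convexity: shared value v is returned for any abundances
  raw2 <- raw; raw2$temp <- "7"
  db2 <- habitraits:::validate_trait_table(raw2, sc)
  pr2 <- weighted_trait_profile(ab, encode_traits(db2), db2)
  expect_equal(unname(pr2$values["temp", ]), rep(7, 3))
  # support records the renormalized weight of informing taxa
  expect_equal(pr$support["temp", "s2"], 0.6)
})

test_that("profiles are invariant to splitting a taxon's abundance across duplicate rows", {
  w <- small_world()
  db2 <- habitraits:::combined_database(w$db)
  enc <- encode_traits(db2)
  pr1 <- weighted_trait_profile(w$ab, enc, db2)
  # duplicate the most abundant taxon, splitting its abundance 30/70;
  # both halves match the same database record
  x <- w$ab$x
  i <- which.max(rowSums(x))
  x2 <- rbind(x, x[i, ] * 0.7)
  x2[i, ] <- x[i, ] * 0.3
  tax2 <- c(w$ab$taxon, paste(w$ab$taxon[i], "dup"))
  ab2 <- structure(list(x = x2, taxon = tax2), class = "abundance_table")
  rownames(ab2$x) <- c(rownames(x), rownames(x)[i])  # same taxon id twice
  m <- match_taxa(w$ab, db2)
  m2 <- rbind(m, m[i, ])
  m2$taxon_id[nrow(m2)] <- rownames(ab2$x)[nrow(x2)]
  pr2 <- weighted_trait_profile(ab2, enc, db2, match = m2)
  expect_equal(pr2$values, pr1$values, tolerance = 1e-10)
})

test_that("cells lie within the range of contributing taxon values and sit NA when unsupported", {
  w <- small_world()
  db2 <- habitraits:::combined_database(w$db)
  enc <- encode_traits(db2)
  pr <- weighted_trait_profile(w$ab, enc, db2)
  rng <- apply(enc$x, 2L, range, na.rm = TRUE)
  for (tr in sample(rownames(pr$values), 10)) {
    v <- pr$values[tr, ]
    expect_true(all(is.na(v) | (v >= rng[1, tr] - 1e-9 & v <= rng[2, tr] + 1e-9)))
  }
  expect_true(all(is.na(pr$values[pr$support == 0])))
})

test_that("generalism labelling follows the two-appearances-per-area rule", {
  meta <- validate_sample_metadata(data.frame(
    sample_id = paste0("s", 1:10), subject_id = paste0("u", 1:10),
    body_site = rep(c("stool", "tongue_dorsum"), each = 5),
    body_area = rep(c("gut", "mouth"), each = 5)))
  x <- matrix(0, 4, 10, dimnames = list(NULL, meta$sample_id))
  x[1, 1:5] <- 0.1          # 5 stool samples only -> specialist
  x[2, c(1:3, 6:7)] <- 0.1  # 3 stool + 2 tongue -> generalist
  x[3, c(1, 6)] <- 0.1      # once in each area -> no qualifying area
  x[4, 1] <- 0.1            # singleton -> excluded
  ab <- habitraits:::new_abundance_table(x, paste("T", 1:4))
  g <- generalism_labels(ab, meta)
  expect_identical(g$label, c("specialist", "generalist", "excluded", "excluded"))
  expect_identical(g$n_areas, c(1L, 2L, 0L, 0L))
  # monotone in min_appearances: raising it never upgrades a label
  g3 <- generalism_labels(ab, meta, min_appearances = 3L)
  rank_of <- function(l) match(l, c("excluded", "specialist", "generalist"))
  expect_true(all(rank_of(g3$label) <= rank_of(g$label)))
  # with filters off, the singleton becomes a specialist
  g1 <- generalism_labels(ab, meta, min_appearances = 1L,
                          exclude_singletons = FALSE)
  expect_identical(g1$label[4], "specialist")
})

test_that("sample diversity matches closed-form Shannon entropies", {
  n_sub <- 4
  sc <- trait_schema(paste0("sub", 1:n_sub), rep("binary", n_sub),
                     rep("carbon_substrate", n_sub))
  raw <- data.frame(taxon = paste("T", 1:4), rank = "species", phylum = "p",
                    class = "c", order = "o", family = "f")
  for (j in 1:n_sub) raw[[paste0("sub", j)]] <- as.character(as.integer(1:4 == j))
  db <- habitraits:::validate_trait_table(raw, sc)  # taxon i uses substrate i only
  ab <- habitraits:::new_abundance_table(
    matrix(c(1, 0, 0, 0,
             1/3, 1/3, 1/3, 0,
             0.5, 0.25, 0.25, 0), 4,
           dimnames = list(NULL, c("one", "uniform", "skew"))),
    paste("T", 1:4))
  div <- sample_diversity(ab, db)
  expect_equal(div$taxonomic_entropy[div$sample_id == "one"], 0)
  expect_equal(div$carbon_entropy[div$sample_id == "one"], 0)
  expect_equal(div$taxonomic_entropy[div$sample_id == "uniform"], log(3))
  expect_equal(div$carbon_entropy[div$sample_id == "uniform"], log(3))
  # -(0.5 log 0.5 + 2 * 0.25 log 0.25) = 1.0397 nats
  expect_equal(div$carbon_entropy[div$sample_id == "skew"], 1.0397, tolerance = 1e-4)
  expect_equal(div$carbon_richness[div$sample_id == "skew"], 3L)
  # bounds on a synthetic world
  w <- small_world()
  db2 <- habitraits:::combined_database(w$db)
  dv <- sample_diversity(w$ab, db2)
  m <- match_taxa(w$ab, db2)
  expect_true(all(dv$carbon_entropy <=
                    log(length(carbon_substrate_traits(w$schema))) + 1e-9,
                  na.rm = TRUE))
  expect_true(all(dv$taxonomic_entropy <= log(sum(m$matched)) + 1e-9, na.rm = TRUE))
  expect_true(all(dv$taxonomic_entropy >= 0, na.rm = TRUE))
})

test_that("substrate overlap equals the brute-force pair intersection", {
  set.seed(12)
  n_sub <- 8
  sc <- trait_schema(paste0("s", 1:n_sub), rep("binary", n_sub),
                     rep("carbon_substrate", n_sub))
  vals <- matrix(rbinom(7 * n_sub, 1, 0.5), 7)
  raw <- data.frame(taxon = paste("T", 1:7), rank = "species", phylum = "p",
                    class = "c", order = "o", family = "f")
  for (j in 1:n_sub) raw[[paste0("s", j)]] <- as.character(vals[, j])
  db <- habitraits:::validate_trait_table(raw, sc)
  ov <- substrate_overlap(db, db$taxon_id)
  # brute-force oracle over explicit set intersections
  for (r in sample(nrow(ov$pairs), 10, replace = TRUE)) {
    i <- match(ov$pairs$taxon_a[r], db$taxon_id)
    j <- match(ov$pairs$taxon_b[r], db$taxon_id)
    expect_equal(ov$pairs$shared[r],
                 length(intersect(which(vals[i, ] == 1), which(vals[j, ] == 1))))
  }
  # identical sets share their full size; disjoint sets share 0
  raw2 <- raw[1:2, ]
  for (j in 1:5) { raw2[[paste0("s", j)]] <- c("1", "1") }
  for (j in 6:8) { raw2[[paste0("s", j)]] <- c("0", "0") }
  db2 <- habitraits:::validate_trait_table(raw2, sc)
  expect_equal(substrate_overlap(db2, db2$taxon_id)$pairs$shared, 5L)
  raw3 <- raw[1:2, ]
  for (j in 1:n_sub) raw3[[paste0("s", j)]] <- c(as.character(as.integer(j <= 4)),
                                                 as.character(as.integer(j > 4)))
  db3 <- habitraits:::validate_trait_table(raw3, sc)
  expect_equal(substrate_overlap(db3, db3$taxon_id)$pairs$shared, 0L)
  # fewer than two taxa -> empty
  expect_equal(nrow(substrate_overlap(db, db$taxon_id[1])$pairs), 0L)
})
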