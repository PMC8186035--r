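test_that("trait schema enforces the levels/kind contract", {
  sc <- demo_schema()
  expect_s3_class(sc, "trait_schema")
  expect_equal(nrow(sc), 5L)
  expect_error(trait_schema("t", "categorical", "other", levels = list(character())),
               "levels")
  expect_error(trait_schema("t", "binary", "other", levels = list(c("a", "b"))),
               "must not declare")
  expect_error(trait_schema(c("a", "a"), rep("binary", 2), rep("other", 2)),
               "unique")
})

test_that("trait table round-trips, normalizes missing markers and 0-codes binaries", {
  sc <- demo_schema()
  tt <- read_trait_table(demo_trait_file(), sc)
  expect_equal(nrow(tt), 3L)
  expect_setequal(tt$taxon_id, c("alpha one", "alpha two", "beta uno"))
  # continuous: "NA" marker becomes missing
  expect_true(is.na(tt$optimal_temp[tt$taxon_id == "alpha two"]))
  # binary cell left empty is 0, never missing
  expect_identical(tt$glucose[tt$taxon_id == "alpha two"], 0L)
  expect_false(anyNA(tt$glucose))
  # categorical empty cell is missing
  expect_true(is.na(tt$oxygen[tt$taxon_id == "beta uno"]))
  # schema round-trips through its sidecar file
  d <- withr::local_tempdir()
  write_trait_schema(sc, file.path(d, "schema.tsv"))
  sc2 <- read_trait_schema(file.path(d, "schema.tsv"))
  expect_equal(sc2$trait, sc$trait)
  expect_equal(sc2$levels, sc$levels)
})

test_that("reader rejects schema violations with informative errors", {
  sc <- demo_schema()
  d <- withr::local_tempdir()
  path <- demo_trait_file(d)
  # categorical value outside levels
  bad <- readLines(path)
  bad[2] <- sub("aerobe", "microaerophile", bad[2])
  writeLines(bad, file.path(d, "bad.tsv"))
  expect_error(read_trait_table(file.path(d, "bad.tsv"), sc),
               "microaerophile")
  # unknown trait column
  df <- read.delim(path, check.names = FALSE)
  df$mystery <- 1
  write.table(df, file.path(d, "extra.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_trait_table(file.path(d, "extra.tsv"), sc),
               "schema error.*mystery")
  # non-numeric continuous value
  df2 <- read.delim(path, check.names = FALSE)
  df2$optimal_temp[1] <- "warm"
  write.table(df2, file.path(d, "nonnum.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_trait_table(file.path(d, "nonnum.tsv"), sc), "warm")
})

make_consensus_fixture <- function() {
  sc <- demo_schema()
  raw <- data.frame(
    taxon = c("Genusa s1", "Genusa s2", "Genusa s3", "Genusb s1", "Genusb s2"),
    rank = "species",
    phylum = "p1", class = "c1", order = "o1", family = "f1",
    optimal_temp = c("37", "", "37", "20", "25"),
    oxygen = c("aerobe", "aerobe", "aerobe", "aerobe", "anaerobe"),
    glucose = c("1", "1", "1", "1", "0"),
    xylose = c("0", "0", "0", "1", "1"),
    catalase = c("1", "", "1", "0", "0"),
    stringsAsFactors = FALSE)
  habitraits:::validate_trait_table(raw, sc)
}

test_that("genus consensus keeps unanimous values and codes disagreement missing", {
  tt <- make_consensus_fixture()
  gc <- genus_consensus(tt)
  expect_setequal(gc$taxon_id, c("genusa", "genusb"))
  a <- gc[gc$taxon_id == "genusa", ]
  b <- gc[gc$taxon_id == "genusb", ]
  # unanimity (binary {1,1,1} and categorical all-aerobe)
  expect_identical(a$glucose, 1L)
  expect_identical(a$oxygen, "aerobe")
  # disagreement -> missing, even for binary traits at genus rank
  expect_true(is.na(b$oxygen))
  expect_true(is.na(b$glucose))
  expect_true(is.na(b$optimal_temp))
  # ignore-missing rule: {37, missing, 37} agrees at 37
  expect_equal(a$optimal_temp, 37)
  # strict rule: any missing species value breaks consensus
  gc_strict <- genus_consensus(tt, require_complete = TRUE)
  expect_true(is.na(gc_strict[gc_strict$taxon_id == "genusa", "optimal_temp"]))
})

test_that("genus consensus is idempotent and never invents values", {
  tt <- make_consensus_fixture()
  gc <- genus_consensus(tt)
  # idempotence: consensus of genus-rank rows re-derived from themselves
  relabel <- as.data.frame(gc)
  relabel$rank <- "species"
  relabel$taxon <- paste(relabel$taxon, "sp")
  tt2 <- habitraits:::new_trait_table(relabel, tt_schema(tt))
  tt2$taxon_id <- normalize_taxon_id(relabel$taxon)
  gc2 <- genus_consensus(tt2)
  for (tr in tt_schema(tt)$trait)
    expect_identical(gc2[[tr]], gc[[tr]])
  # no invented values: every non-missing consensus appears among species
  sp <- as.data.frame(tt)
  for (g in gc$taxon_id) {
    members <- sp[habitraits:::genus_of(tt) == g, ]
    for (tr in tt_schema(tt)$trait) {
      v <- gc[gc$taxon_id == g, tr]
      if (!is.na(v)) expect_true(v %in% members[[tr]])
    }
  }
})

test_that("encoding expands categoricals one-hot and masks jointly", {
  sc <- demo_schema()
  tt <- read_trait_table(demo_trait_file(), sc)
  enc <- encode_traits(tt)
  expect_equal(ncol(enc$x), 4L + 3L)  # 1 continuous + 3 binary + 3 dummies
  fac <- enc$x["alpha two", paste0("oxygen=", c("aerobe", "anaerobe", "facultative"))]
  expect_equal(unname(fac), c(0, 0, 1))
  # missing categorical masks all its dummies
  expect_true(all(enc$mask["beta uno", grepl("^oxygen=", colnames(enc$x))]))
  # dummies of a non-missing value sum to 1
  expect_equal(sum(enc$x["alpha one", grepl("^oxygen=", colnames(enc$x))]), 1)
  # collapsing dummies recovers the assignment where non-missing
  expect_identical(unname(decode_categorical(enc, "oxygen")),
                   c("aerobe", "facultative", NA))
  # binary-only table passes through unchanged
  sc_bin <- trait_schema(c("glucose", "xylose"), rep("binary", 2),
                         rep("carbon_substrate", 2))
  raw <- data.frame(taxon = c("X a", "Y b"), rank = "species", phylum = "p",
                    class = "c", order = "o", family = "f",
                    glucose = c("1", "0"), xylose = c("0", "1"))
  tb <- habitraits:::validate_trait_table(raw, sc_bin)
  eb <- encode_traits(tb)
  expect_equal(unname(eb$x), matrix(c(1, 0, 0, 1), 2))
})

test_that("metabolic breadth counts substrate traits and matches a row-sum oracle", {
  sc <- demo_schema()
  tt <- read_trait_table(demo_trait_file(), sc)
  mb <- metabolic_breadth(tt)
  expect_identical(unname(mb[c("alpha one", "alpha two", "beta uno")]),
                   c(1L, 1L, 1L))
  # random fixture vs independent row-sum oracle
  set.seed(9)
  n_sub <- 6
  sc2 <- trait_schema(c(paste0("s", 1:n_sub), "catalase"),
                      rep("binary", n_sub + 1),
                      c(rep("carbon_substrate", n_sub), "enzyme_assay"))
  vals <- matrix(rbinom(10 * (n_sub + 1), 1, 0.4), 10)
  raw <- data.frame(taxon = paste("T", 1:10), rank = "species", phylum = "p",
                    class = "c", order = "o", family = "f")
  for (j in seq_len(n_sub + 1)) raw[[sc2$trait[j]]] <- as.character(vals[, j])
  tb <- habitraits:::validate_trait_table(raw, sc2)
  oracle <- rowSums(vals[, 1:n_sub])
  expect_equal(unname(metabolic_breadth(tb)), oracle)
  # monotone: planting one more substrate never decreases a count
  raw2 <- raw
  raw2$s1 <- "1"
  tb2 <- habitraits:::validate_trait_table(raw2, sc2)
  expect_true(all(metabolic_breadth(tb2) >= metabolic_breadth(tb)))
  # zero-usage taxon
  raw3 <- raw[1, ]; for (s in paste0("s", 1:n_sub)) raw3[[s]] <- "0"
  expect_identical(unname(metabolic_breadth(
    habitraits:::validate_trait_table(raw3, sc2))), 0L)
})

test_that("database composition summarises ranks and trait kinds", {
  tt <- make_consensus_fixture()
  both <- habitraits:::new_trait_table(
    rbind(as.data.frame(tt), as.data.frame(genus_consensus(tt))), tt_schema(tt))
  comp <- db_composition(both)
  expect_equal(comp$n_species, 5L)
  expect_equal(comp$n_genera, 2L)
  expect_equal(comp$n_traits, 5L)
  expect_equal(comp$n_continuous, 1L)
  expect_equal(comp$n_categorical, 1L)
  expect_equal(comp$n_binary, 3L)
})

test_that("mean imputation fills with database-wide column means", {
  x <- matrix(c(1, NA, 3, 2, 2, 2, NA, NA, NA), 3,
              dimnames = list(paste0("t", 1:3), c("a", "b", "c")))
  enc <- structure(list(x = x, mask = is.na(x),
                        map = data.frame(column = c("a", "b", "c"),
                                         trait = c("a", "b", "c"),
                                         level = NA, kind = "continuous",
                                         category = "other")),
                   class = "encoded_traits")
  expect_warning(out <- mean_impute(enc), "all-missing")
  expect_equal(colnames(out$x), c("a", "b"))
  expect_equal(out$x["t2", "a"], 2)       # (1+3)/2
  expect_equal(unname(out$x[, "b"]), rep(2, 3))  # identity when complete
  # oracle: recompute column means independently on a random mask
  set.seed(4)
  y <- matrix(rnorm(60), 12, 5, dimnames = list(paste0("r", 1:12), paste0("v", 1:5)))
  y[sample(length(y), 15)] <- NA
  ency <- structure(list(x = y, mask = is.na(y),
                         map = data.frame(column = colnames(y), trait = colnames(y),
                                          level = NA, kind = "continuous",
                                          category = "other")),
                    class = "encoded_traits")
  outy <- mean_impute(ency)
  for (j in colnames(y)) {
    mu <- mean(y[, j], na.rm = TRUE)
    expect_equal(unname(outy$x[is.na(y[, j]), j]),
                 rep(mu, sum(is.na(y[, j]))))
  }
})
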