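BODY_AREAS <- c("gut", "vagina", "mouth", "skin", "airways")

#' Read sample metadata
#'
#' TSV/CSV with columns `sample_id`, `subject_id`, `body_site`, `body_area`.
#' Every body site must map to exactly one of the five body areas (gut,
#' vagina, mouth, skin, airways); sample ids must be unique.
#'
#' @param path metadata file path.
#' @return a validated `sample_metadata` data frame.
#' @export
read_sample_metadata <- function(path) {
  raw <- read_delim_auto(path)
  need <- c("sample_id", "subject_id", "body_site", "body_area")
  if (!all(need %in% names(raw)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  validate_sample_metadata(raw[, need])
}

validate_sample_metadata <- function(df) {
  df <- as.data.frame(lapply(df, as.character), stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1])
  bad_area <- !df$body_area %in% BODY_AREAS
  if (any(bad_area))
    stop("unknown body_area '", df$body_area[which(bad_area)[1]],
         "' (must be one of ", paste(BODY_AREAS, collapse = ", "), ")")
  amb <- tapply(df$body_area, df$body_site, function(a) length(unique(a)))
  if (any(amb > 1L))
    stop("body_site '", names(amb)[which(amb > 1L)[1]],
         "' maps to more than one body_area")
  class(df) <- c("sample_metadata", "data.frame")
  df
}

new_abundance_table <- function(x, taxon) {
  stopifnot(is.matrix(x), nrow(x) == length(taxon))
  rownames(x) <- normalize_taxon_id(taxon)
  structure(list(x = x, taxon = taxon), class = "abundance_table")
}

#' Read a relative-abundance matrix with sample metadata
#'
#' The abundance file is TSV (optionally bz2-compressed): first column the
#' taxon lineage string (semicolon- or pipe-delimited ranks accepted; the last
#' field is taken as the taxon name), remaining columns numeric relative
#' abundances per sample. Samples absent from the metadata are dropped with a
#' warning giving the count.
#'
#' @param path abundance matrix file.
#' @param metadata_path sample metadata file (see [read_sample_metadata()]).
#' @return list with elements `ab` (an `abundance_table`: `$x` is the taxa x
#'   samples matrix keyed by normalized taxon id, `$taxon` the original
#'   labels) and `meta` (a `sample_metadata` restricted to retained samples).
#' @export
read_abundance <- function(path, metadata_path) {
  raw <- read_delim_auto(path)
  lineage <- raw[[1L]]
  taxon <- vapply(strsplit(lineage, "[;|]"), function(p) trimws(p[length(p)]), "")
  num <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(num) <- "double")
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("parse error: non-numeric abundance at taxon row ", bad[1L],
         ", sample column '", colnames(num)[bad[2L]], "'")
  }
  if (any(num < 0))
    stop("parse error: negative abundance value")
  tot <- colSums(num)
  if (any(tot > 1 + 1e-6))
    warning(sum(tot > 1 + 1e-6), " sample(s) with abundance total > 1")
  meta <- read_sample_metadata(metadata_path)
  keep <- colnames(num) %in% meta$sample_id
  if (any(!keep))
    warning("dropping ", sum(!keep), " sample(s) without metadata")
  num <- num[, keep, drop = FALSE]
  meta <- meta[match(colnames(num), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  list(ab = new_abundance_table(num, taxon), meta = meta)
}

#' Match abundance-table taxa against the trait database
#'
#' A species-rank database record matching the (normalized) taxon name is
#' preferred; when absent, the genus-rank consensus record for the taxon's
#' genus (its first name component) is used; otherwise the taxon is left
#' unmatched and excluded from trait profiles.
#'
#' @param ab an `abundance_table`.
#' @param db a `trait_table` holding species and/or genus records.
#' @return data frame: `taxon_id`, `matched` (logical), `rank_used`
#'   (`"species"`, `"genus"` or NA), `db_taxon_id`.
#' @export
match_taxa <- function(ab, db) {
  ids <- rownames(ab$x)
  sp <- db$taxon_id[db$rank == "species"]
  gn <- db$taxon_id[db$rank == "genus"]
  genus <- vapply(strsplit(ids, " ", fixed = TRUE), `[`, "", 1L)
  rank_used <- rep(NA_character_, length(ids))
  db_id <- rep(NA_character_, length(ids))
  is_sp <- ids %in% sp
  rank_used[is_sp] <- "species"; db_id[is_sp] <- ids[is_sp]
  try_gn <- !is_sp & genus %in% gn
  rank_used[try_gn] <- "genus"; db_id[try_gn] <- genus[try_gn]
  data.frame(taxon_id = ids, matched = !is.na(rank_used),
             rank_used = rank_used, db_taxon_id = db_id,
             stringsAsFactors = FALSE)
}

#' Abundance-weighted mean trait profiles per sample
#'
#' For each expanded trait t and sample s, the profile cell is the weighted
#' mean of t over the matched taxa present in s, with weights the relative
#' abundances renormalized over the taxa whose value of t is non-missing
#' (taxa with a missing value simply drop out of that trait's average). With
#' `restrict_phylum` set, only matched taxa of that phylum contribute
#' ("phyla-samples"); a sample with no contributing taxa yields an all-missing
#' column.
#'
#' @param ab an `abundance_table`.
#' @param enc an `encoded_traits` matrix of the database (see
#'   [encode_traits()]).
#' @param db the `trait_table` behind `enc` (needed for lineage lookups and
#'   matching).
#' @param match optional precomputed [match_taxa()] result.
#' @param restrict_phylum optional phylum name.
#' @return a `trait_profile` list: `values` (expanded traits x samples, NA
#'   where unsupported), `support` (same shape; summed renormalized weight of
#'   taxa informing each cell), `map` (expanded-trait map), `restrict_phylum`,
#'   `n_taxa` (contributing taxa count).
#' @export
weighted_trait_profile <- function(ab, enc, db, match = NULL,
                                   restrict_phylum = NULL) {
  if (is.null(match)) match <- match_taxa(ab, db)
  keep <- match$matched
  if (!is.null(restrict_phylum)) {
    phy <- db$phylum[match(match$db_taxon_id, db$taxon_id)]
    keep <- keep & !is.na(phy) & phy == restrict_phylum
  }
  rows <- which(keep)
  p <- ncol(enc$x)
  s <- ncol(ab$x)
  vals <- matrix(NA_real_, p, s, dimnames = list(colnames(enc$x), colnames(ab$x)))
  supp <- matrix(0, p, s, dimnames = dimnames(vals))
  if (length(rows)) {
    A <- ab$x[rows, , drop = FALSE]
    tot <- colSums(A)
    ok <- tot > 0
    A[, ok] <- sweep(A[, ok, drop = FALSE], 2L, tot[ok], "/")
    A[, !ok] <- 0
    X <- enc$x[match$db_taxon_id[rows], , drop = FALSE]
    X0 <- X; X0[is.na(X0)] <- 0
    informed <- !is.na(X)
    num <- crossprod(X0, A)        # p x s: sum w_i x_i over non-missing
    den <- crossprod(informed + 0, A)  # summed weight of informing taxa
    vals <- num / den
    vals[den == 0] <- NA_real_
    supp <- den
    dimnames(vals) <- dimnames(supp) <- list(colnames(enc$x), colnames(ab$x))
  }
  structure(list(values = vals, support = supp, map = enc$map,
                 restrict_phylum = restrict_phylum, n_taxa = length(rows)),
            class = "trait_profile")
}

#' Label taxa as habitat specialists or generalists
#'
#' A body area qualifies for a taxon when the taxon is present (relative
#' abundance strictly > 0) in at least `min_appearances` samples from that
#' area. Taxa present in only a single sample overall are excluded, as are
#' taxa with no qualifying area.
#'
#' @param ab an `abundance_table`.
#' @param meta `sample_metadata` covering the table's samples.
#' @param min_appearances minimum per-area sample appearances (default 2).
#' @param exclude_singletons drop taxa seen in at most one sample overall
#'   (default TRUE); turning both filters off (`min_appearances = 1`,
#'   `exclude_singletons = FALSE`) reproduces the noisier unfiltered
#'   labelling.
#' @return data frame: `taxon_id`, `n_samples` (total appearances),
#'   `n_areas` (qualifying areas), `label` in
#'   specialist/generalist/excluded.
#' @export
generalism_labels <- function(ab, meta, min_appearances = 2L,
                              exclude_singletons = TRUE) {
  meta <- meta[match(colnames(ab$x), meta$sample_id), , drop = FALSE]
  pres <- ab$x > 0
  n_samples <- rowSums(pres)
  areas <- unique(meta$body_area)
  per_area <- vapply(areas, function(a)
    rowSums(pres[, meta$body_area == a, drop = FALSE]), numeric(nrow(pres)))
  if (is.null(dim(per_area))) per_area <- matrix(per_area, nrow = nrow(pres))
  n_areas <- rowSums(per_area >= min_appearances)
  single <- if (exclude_singletons) n_samples <= 1L else rep(FALSE, nrow(pres))
  label <- ifelse(single | n_areas == 0L, "excluded",
                  ifelse(n_areas == 1L, "specialist", "generalist"))
  data.frame(taxon_id = rownames(ab$x), n_samples = as.integer(n_samples),
             n_areas = as.integer(n_areas), label = label,
             stringsAsFactors = FALSE)
}

#' Per-sample taxonomic and carbon-source diversity
#'
#' Taxonomic diversity is the Shannon entropy (nats) of the renormalized
#' abundances of database-matched taxa. Carbon-source diversity is the
#' Shannon entropy of the per-sample distribution over carbon substrates,
#' built by allocating each matched taxon's abundance across the substrates
#' it uses; `allocation = "equal"` splits the abundance evenly among the
#' taxon's substrates (maximum-entropy default), `"full"` gives every used
#' substrate the taxon's full weight before renormalizing.
#'
#' @param ab an `abundance_table`.
#' @param db a `trait_table` with carbon-substrate traits.
#' @param schema a [trait_schema()]; defaults to the database's.
#' @param match optional precomputed [match_taxa()] result.
#' @param allocation `"equal"` or `"full"`.
#' @return data frame: `sample_id`, `taxonomic_entropy`, `carbon_entropy`
#'   (NA when no matched taxon uses any substrate), `carbon_richness`.
#' @export
sample_diversity <- function(ab, db, schema = tt_schema(db), match = NULL,
                             allocation = c("equal", "full")) {
  allocation <- match.arg(allocation)
  if (is.null(match)) match <- match_taxa(ab, db)
  rows <- which(match$matched)
  subs <- carbon_substrate_traits(schema)
  B <- as.matrix(as.data.frame(db)[match(match$db_taxon_id[rows], db$taxon_id),
                                   subs, drop = FALSE])
  B[is.na(B)] <- 0
  usage <- B == 1
  n_subs <- rowSums(usage)
  A <- ab$x[rows, , drop = FALSE]
  out <- data.frame(sample_id = colnames(ab$x),
                    taxonomic_entropy = NA_real_,
                    carbon_entropy = NA_real_,
                    carbon_richness = NA_integer_,
                    stringsAsFactors = FALSE)
  for (s in seq_len(ncol(A))) {
    w <- A[, s]
    out$taxonomic_entropy[s] <- if (any(w > 0)) shannon_entropy(w) else NA_real_
    users <- w > 0 & n_subs > 0
    if (!any(users)) next
    alloc_w <- if (allocation == "equal") w[users] / n_subs[users] else w[users]
    sub_w <- colSums(usage[users, , drop = FALSE] * alloc_w)
    out$carbon_entropy[s] <- shannon_entropy(sub_w)
    out$carbon_richness[s] <- sum(sub_w > 0)
  }
  out
}

#' Pairwise shared-substrate counts among taxa
#'
#' For every unordered pair of the given taxa, counts the carbon substrates
#' both are recorded to use.
#'
#' @param db a `trait_table`.
#' @param taxa character vector of taxon_ids present in `db` (length >= 2 for
#'   a non-empty result).
#' @param schema a [trait_schema()]; defaults to the database's.
#' @return list: `pairs` (data frame taxon_a / taxon_b / shared) and `mean`
#'   (mean shared count; NA when fewer than 2 taxa).
#' @export
substrate_overlap <- function(db, taxa, schema = tt_schema(db)) {
  taxa <- intersect(normalize_taxon_id(taxa), db$taxon_id)
  if (length(taxa) < 2L)
    return(list(pairs = data.frame(taxon_a = character(), taxon_b = character(),
                                   shared = integer(), stringsAsFactors = FALSE),
                mean = NA_real_))
  subs <- carbon_substrate_traits(schema)
  B <- as.matrix(as.data.frame(db)[match(taxa, db$taxon_id), subs, drop = FALSE])
  B[is.na(B)] <- 0
  S <- tcrossprod(B == 1)          # shared-substrate counts
  idx <- which(upper.tri(S), arr.ind = TRUE)
  pairs <- data.frame(taxon_a = taxa[idx[, 1L]], taxon_b = taxa[idx[, 2L]],
                      shared = as.integer(S[idx]), stringsAsFactors = FALSE)
  list(pairs = pairs, mean = mean(pairs$shared))
}
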