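LINEAGE_COLS <- c("phylum", "class", "order", "family")

new_trait_table <- function(df, schema) {
  rownames(df) <- NULL
  attr(df, "schema") <- schema
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Schema attached to a trait table
#' @param table a `trait_table`.
#' @return the [trait_schema()] the table was validated against.
#' @export
tt_schema <- function(table) attr(table, "schema")

#' Read and validate a curated trait table
#'
#' The table is delimited text (TSV or CSV, sniffed from the header line) with
#' columns `taxon`, `rank`, `phylum`, `class`, `order`, `family`, followed by
#' one column per trait declared in `schema`. Missing markers (empty cell,
#' `NA`, `NaN`, case-insensitive) are normalized. Binary traits are coded 0
#' when not reported, so a binary cell is never missing on read; continuous
#' and categorical traits stay missing-capable.
#'
#' @param path path to the trait table file.
#' @param schema a [trait_schema()] describing every trait column.
#' @return a `trait_table`: a data frame with columns `taxon_id` (normalized),
#'   `taxon`, `rank`, the four lineage columns, then one column per trait, with
#'   the schema attached (see [tt_schema()]).
#' @details Validation errors name the offending taxon and trait. A trait
#'   column in the file that the schema does not declare is a schema error;
#'   a categorical value outside the declared levels is a validation error.
#' @export
read_trait_table <- function(path, schema) {
  raw <- read_delim_auto(path)
  meta_cols <- c("taxon", "rank", LINEAGE_COLS)
  if (!all(meta_cols %in% names(raw)))
    stop("trait table must have columns: ", paste(meta_cols, collapse = ", "))
  trait_cols <- setdiff(names(raw), meta_cols)
  unknown <- setdiff(trait_cols, schema$trait)
  if (length(unknown))
    stop("schema error: trait column(s) not in schema: ", paste(unknown, collapse = ", "))
  absent <- setdiff(schema$trait, trait_cols)
  if (length(absent))
    stop("schema error: schema trait(s) missing from file: ", paste(absent, collapse = ", "))
  validate_trait_table(raw, schema)
}

# shared by read_trait_table and the synthetic generator's in-memory path
validate_trait_table <- function(raw, schema) {
  df <- data.frame(taxon_id = normalize_taxon_id(raw$taxon),
                   taxon = as.character(raw$taxon),
                   rank = as.character(raw$rank),
                   stringsAsFactors = FALSE)
  for (lc in LINEAGE_COLS) df[[lc]] <- as.character(raw[[lc]])
  bad_rank <- !df$rank %in% c("species", "genus")
  if (any(bad_rank))
    stop("invalid rank for taxon ", df$taxon[which(bad_rank)[1]],
         " (must be 'species' or 'genus')")
  if (anyDuplicated(df$taxon_id))
    stop("duplicate taxon_id after normalization: ",
         df$taxon_id[duplicated(df$taxon_id)][1])
  if (any(is_missing_marker(df$phylum)))
    stop("lineage phylum must always be present")
  for (i in seq_len(nrow(schema))) {
    tr <- schema$trait[i]
    v <- raw[[tr]]
    miss <- is_missing_marker(v)
    if (schema$kind[i] == "continuous") {
      num <- suppressWarnings(as.numeric(v))
      bad <- !miss & is.na(num)
      if (any(bad))
        stop("validation error: non-numeric value '", v[which(bad)[1]],
             "' for continuous trait '", tr, "' in taxon ", df$taxon[which(bad)[1]])
      num[miss] <- NA_real_
      df[[tr]] <- num
    } else if (schema$kind[i] == "binary") {
      val <- trimws(as.character(v))
      bad <- !miss & !val %in% c("0", "1")
      if (any(bad))
        stop("validation error: binary trait '", tr, "' has value '",
             v[which(bad)[1]], "' in taxon ", df$taxon[which(bad)[1]])
      out <- ifelse(miss, 0L, as.integer(val))  # not reported => 0
      df[[tr]] <- out
    } else {
      val <- trimws(as.character(v))
      lev <- schema$levels[[i]]
      bad <- !miss & !val %in% lev
      if (any(bad))
        stop("validation error: value '", val[which(bad)[1]],
             "' of categorical trait '", tr, "' in taxon ",
             df$taxon[which(bad)[1]], " is outside levels {",
             paste(lev, collapse = ", "), "}")
      val[miss] <- NA_character_
      df[[tr]] <- val
    }
  }
  new_trait_table(df, schema)
}

#' Write a trait table back to TSV
#' @param table a `trait_table`.
#' @param path output path.
#' @export
write_trait_table <- function(table, path) {
  df <- as.data.frame(table)[, c("taxon", "rank", LINEAGE_COLS, tt_schema(table)$trait)]
  write_tsv(df, path)
}

#' Genus name of each row (first word of the binomial)
#' @noRd
genus_of <- function(table) vapply(strsplit(table$taxon_id, " ", fixed = TRUE),
                                   `[`, "", 1L)

#' Derive genus-level consensus records from species entries
#'
#' For every genus with at least one species-rank row, a genus record is
#' emitted whose trait values are the consensus across that genus' species:
#' the shared value when all species agree, missing otherwise. By default
#' agreement is evaluated over non-missing values only (a species with a
#' missing value does not break consensus); set `require_complete = TRUE` to
#' demand non-missing unanimity instead, in which case any missing species
#' value also codes the genus value missing.
#'
#' Binary trait values at genus rank CAN be missing (unlike species rows,
#' where absence codes 0): a genus whose species disagree on a binary trait
#' carries no consensus.
#'
#' @param table a `trait_table` containing species-rank rows.
#' @param require_complete logical; see Description.
#' @return a `trait_table` of genus-rank rows (taxon = genus name); lineage
#'   columns take the most frequent value among the genus' species.
#' @export
genus_consensus <- function(table, require_complete = FALSE) {
  schema <- tt_schema(table)
  sp <- table[table$rank == "species", , drop = FALSE]
  if (nrow(sp) == 0L) {
    out <- table[0, , drop = FALSE]
    return(new_trait_table(as.data.frame(out), schema))
  }
  gs <- genus_of(sp)
  rows <- lapply(split(seq_len(nrow(sp)), gs), function(idx) {
    rec <- list(taxon_id = gs[idx[1]], taxon = gs[idx[1]], rank = "genus")
    for (lc in LINEAGE_COLS) {
      v <- sp[[lc]][idx]
      v <- v[!is_missing_marker(v)]
      rec[[lc]] <- if (length(v)) names(sort(table(v), decreasing = TRUE))[1] else NA_character_
    }
    for (i in seq_len(nrow(schema))) {
      tr <- schema$trait[i]
      v <- sp[[tr]][idx]
      obs <- v[!is.na(v)]
      consensus <- if (require_complete && anyNA(v)) {
        NA
      } else if (length(obs) && length(unique(obs)) == 1L) {
        obs[1]
      } else NA
      rec[[tr]] <- if (schema$kind[i] == "continuous") as.numeric(consensus)
                   else if (schema$kind[i] == "binary") as.integer(consensus)
                   else as.character(consensus)
    }
    as.data.frame(rec, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  new_trait_table(out, schema)
}

#' Encode a trait table as a numeric matrix with dummy variables
#'
#' Continuous and binary traits pass through as single columns; each
#' categorical trait with k levels expands to k 0/1 dummy columns (named
#' `trait=level`). Missingness is carried in a logical mask and propagated
#' jointly to all dummies of a missing categorical value.
#'
#' @param table a `trait_table`.
#' @param schema a [trait_schema()]; defaults to the table's own schema.
#' @return an `encoded_traits` list: `x` (taxa x expanded-trait numeric
#'   matrix, NA where masked), `mask` (logical matrix, TRUE = missing), and
#'   `map` (data frame column / trait / level / kind / category).
#' @export
encode_traits <- function(table, schema = tt_schema(table)) {
  n <- nrow(table)
  cols <- list(); map <- list()
  for (i in seq_len(nrow(schema))) {
    tr <- schema$trait[i]; kind <- schema$kind[i]
    if (kind == "categorical") {
      lev <- schema$levels[[i]]
      v <- table[[tr]]
      for (l in lev) {
        cn <- paste0(tr, "=", l)
        x <- as.numeric(v == l)   # NA propagates
        cols[[cn]] <- x
        map[[cn]] <- data.frame(column = cn, trait = tr, level = l,
                                kind = kind, category = schema$category[i],
                                stringsAsFactors = FALSE)
      }
    } else {
      x <- as.numeric(table[[tr]])
      cols[[tr]] <- x
      map[[tr]] <- data.frame(column = tr, trait = tr, level = NA_character_,
                              kind = kind, category = schema$category[i],
                              stringsAsFactors = FALSE)
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- table$taxon_id
  mask <- is.na(x)
  structure(list(x = x, mask = mask, map = do.call(rbind, c(map, list(make.row.names = FALSE)))),
            class = "encoded_traits")
}

#' Collapse dummy columns back to categorical assignments
#'
#' Inverse of the categorical expansion in [encode_traits()] wherever the
#' value was non-missing; used for round-trip checks.
#'
#' @param enc an `encoded_traits` object.
#' @param trait name of a categorical trait.
#' @return character vector of levels (NA where masked).
#' @export
decode_categorical <- function(enc, trait) {
  m <- enc$map[enc$map$trait == trait & enc$map$kind == "categorical", ]
  if (nrow(m) == 0L) stop("no categorical trait '", trait, "' in encoding")
  sub <- enc$x[, m$column, drop = FALSE]
  apply(sub, 1L, function(r) if (anyNA(r)) NA_character_ else m$level[which.max(r)])
}

#' Metabolic breadth: number of carbon substrates a taxon grows on
#'
#' Counts the binary carbon-substrate traits recorded as 1 for each taxon.
#' Genus-rank rows with a missing (no-consensus) substrate value contribute 0
#' for that substrate.
#'
#' @param table a `trait_table`.
#' @param schema a [trait_schema()]; defaults to the table's own.
#' @return named integer vector (by taxon_id) of substrate counts.
#' @export
metabolic_breadth <- function(table, schema = tt_schema(table)) {
  subs <- carbon_substrate_traits(schema)
  if (length(subs) == 0L)
    return(stats::setNames(integer(nrow(table)), table$taxon_id))
  m <- as.matrix(as.data.frame(table)[, subs, drop = FALSE])
  mode(m) <- "integer"
  counts <- rowSums(m == 1L, na.rm = TRUE)
  stats::setNames(as.integer(counts), table$taxon_id)
}

#' Structural composition of a trait database
#'
#' Counts used to sanity-check a parsed database against its published
#' description: species entries, genus entries, and traits by kind.
#'
#' @param table a `trait_table` (species and/or genus rows).
#' @param schema a [trait_schema()]; defaults to the table's own.
#' @return named list: `n_species`, `n_genera`, `n_traits`, `n_continuous`,
#'   `n_categorical`, `n_binary`.
#' @export
db_composition <- function(table, schema = tt_schema(table)) {
  list(n_species = sum(table$rank == "species"),
       n_genera = sum(table$rank == "genus"),
       n_traits = nrow(schema),
       n_continuous = sum(schema$kind == "continuous"),
       n_categorical = sum(schema$kind == "categorical"),
       n_binary = sum(schema$kind == "binary"))
}
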