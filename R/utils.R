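#' Normalize a taxon identifier for cross-file matching
#'
#' Database names, HMP lineage strings and tree tip labels format the same
#' binomial differently (spaces vs underscores, capitalisation). All matching
#' in this package happens on the normalized form: lower-case, underscores
#' replaced by single spaces, surrounding/duplicate whitespace removed.
#'
#' @param x character vector of taxon names.
#' @return character vector of normalized identifiers.
#' @export
#' @examples
#' normalize_taxon_id(c("Escherichia_coli", "  escherichia  COLI "))
normalize_taxon_id <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("_", " ", x, fixed = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Derive a child seed from a master seed
#'
#' Every stochastic stage takes its own seed derived deterministically from
#' one master seed, so whole-pipeline runs are reproducible while stages stay
#' independently re-runnable. Child seeds stay below 2^31 - 1.
#'
#' @param seed master seed (single integer).
#' @param offset stage offset (single non-negative integer).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, offset) {
  stopifnot(length(seed) == 1L, length(offset) == 1L, is.finite(seed), is.finite(offset))
  # LCG-style mix; modulus 2^31 - 1 keeps the result a valid 32-bit R integer
  as.integer((abs(seed) * 48271 + offset * 16807 + 1) %% 2147483647)
}

#' Shannon entropy of a nonnegative weight vector (nats)
#'
#' Weights are renormalized to a probability distribution; zero weights drop
#' out. A single-category distribution has entropy 0.
#'
#' @param w nonnegative numeric weights; NAs removed.
#' @return entropy in nats, or `NA_real_` when no positive weight remains.
#' @export
shannon_entropy <- function(w) {
  w <- w[!is.na(w) & w > 0]
  if (length(w) == 0L) return(NA_real_)
  p <- w / sum(w)
  -sum(p * log(p))
}

# missing-value markers accepted on read: empty cell, NA, NaN (case-insensitive)
is_missing_marker <- function(x) {
  is.na(x) | tolower(trimws(as.character(x))) %in% c("", "na", "nan")
}

# shared writer for tidy TSV outputs
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_delim_auto <- function(path) {
  con <- path
  if (grepl("\\.bz2$", path)) con <- bzfile(path)
  first <- readLines(con, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  con2 <- if (grepl("\\.bz2$", path)) bzfile(path) else path
  utils::read.table(con2, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"", comment.char = "",
                    colClasses = "character")
}
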