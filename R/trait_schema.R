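TRAIT_KINDS <- c("continuous", "categorical", "binary")
TRAIT_CATEGORIES <- c("carbon_substrate", "enzyme_assay", "gas_production",
                      "morphology", "growth_condition", "genomic", "other")

#' Construct a trait schema
#'
#' A schema declares, for every trait column of a trait table, its measurement
#' kind (continuous, categorical or binary), its biological category (carbon
#' substrate use, enzyme assay, gas production, morphology, growth condition,
#' genomic, other), the allowed levels of categorical traits, and optional
#' units for continuous ones.
#'
#' @param trait character vector of trait names (unique).
#' @param kind one of `"continuous"`, `"categorical"`, `"binary"` per trait.
#' @param category one of the recognised trait categories per trait.
#' @param levels list of character vectors: allowed levels per trait. Must be
#'   non-empty exactly for categorical traits.
#' @param units optional character vector of units (continuous traits only).
#' @return a `trait_schema` data frame with one row per trait.
#' @export
#' @examples
#' trait_schema(
#'   trait = c("optimal_temp", "oxygen", "glucose"),
#'   kind = c("continuous", "categorical", "binary"),
#'   category = c("growth_condition", "growth_condition", "carbon_substrate"),
#'   levels = list(character(), c("aerobe", "anaerobe", "facultative"), character())
#' )
trait_schema <- function(trait, kind, category, levels = NULL, units = NULL) {
  trait <- as.character(trait)
  n <- length(trait)
  if (anyDuplicated(trait)) stop("trait names must be unique")
  kind <- match.arg(as.character(kind), TRAIT_KINDS, several.ok = TRUE)
  category <- match.arg(as.character(category), TRAIT_CATEGORIES, several.ok = TRUE)
  stopifnot(length(kind) == n, length(category) == n)
  if (is.null(levels)) levels <- replicate(n, character(), simplify = FALSE)
  stopifnot(is.list(levels), length(levels) == n)
  if (is.null(units)) units <- rep("", n)
  for (i in seq_len(n)) {
    has_levels <- length(levels[[i]]) > 0L
    if (kind[i] == "categorical" && !has_levels)
      stop("categorical trait '", trait[i], "' needs non-empty levels")
    if (kind[i] != "categorical" && has_levels)
      stop("non-categorical trait '", trait[i], "' must not declare levels")
  }
  out <- data.frame(trait = trait, kind = kind, category = category,
                    units = as.character(units), stringsAsFactors = FALSE)
  out$levels <- levels
  class(out) <- c("trait_schema", "data.frame")
  out
}

#' Read a trait schema from a sidecar TSV/CSV file
#'
#' Expected columns: `trait`, `kind`, `category`, `levels` (pipe-separated
#' allowed values, empty unless categorical) and optionally `units`.
#'
#' @param path path to the schema file.
#' @return a [trait_schema()].
#' @export
read_trait_schema <- function(path) {
  raw <- read_delim_auto(path)
  need <- c("trait", "kind", "category", "levels")
  if (!all(need %in% names(raw)))
    stop("schema file must have columns: ", paste(need, collapse = ", "))
  lv <- lapply(raw$levels, function(s) {
    s <- trimws(strsplit(as.character(s), "|", fixed = TRUE)[[1]])
    s[nzchar(s)]
  })
  trait_schema(raw$trait, raw$kind, raw$category, levels = lv,
               units = if ("units" %in% names(raw)) raw$units else NULL)
}

#' @export
write_trait_schema <- function(schema, path) {
  df <- data.frame(trait = schema$trait, kind = schema$kind,
                   category = schema$category,
                   levels = vapply(schema$levels, paste, "", collapse = "|"),
                   units = schema$units, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

schema_traits_of_kind <- function(schema, kind) schema$trait[schema$kind == kind]

#' Carbon substrate traits of a schema
#' @param schema a [trait_schema()].
#' @return character vector of binary carbon-substrate trait names.
#' @export
carbon_substrate_traits <- function(schema) {
  schema$trait[schema$category == "carbon_substrate" & schema$kind == "binary"]
}
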