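#' @keywords internal
#' @import stats
#' @import utils
#' @import graphics
"_PACKAGE"

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Locate rankscore columns
#'
#' Rankscore columns follow the `<algorithm>_rankscore` naming convention used
#' by dbNSFP-style annotation tables. Rankscores rescale each prediction
#' algorithm's raw score to its rank among all possible non-synonymous SNVs,
#' so every algorithm lives on the same \[0, 1\] scale (1 = most deleterious).
#'
#' @param x a data frame (annotation table) or character vector of column names.
#' @return character vector of rankscore column names, in table order.
#' @export
rankscore_columns <- function(x) {
  nm <- if (is.data.frame(x)) names(x) else as.character(x)
  grep("_rankscore$", nm, value = TRUE)
}

#' Algorithm names of an annotation table
#'
#' @param x a data frame with `<algorithm>_rankscore` columns.
#' @return algorithm names with the `_rankscore` suffix stripped.
#' @export
algorithm_names <- function(x) {
  sub("_rankscore$", "", rankscore_columns(x))
}

## cosmic_counts are serialised as "entity:count;entity:count" so the table
## stays a flat TSV; an empty string means no COSMIC overlap.
parse_cosmic <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer(0))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  counts <- vapply(kv, function(p) as.integer(p[[2]]), integer(1))
  names(counts) <- vapply(kv, `[[`, character(1), 1L)
  counts
}

format_cosmic <- function(counts) {
  if (length(counts) == 0L) return("")
  paste(sprintf("%s:%d", names(counts), as.integer(counts)), collapse = ";")
}

## total COSMIC mutation count per row of an annotation table
cosmic_total <- function(tab) {
  vapply(tab$cosmic_counts, function(s) sum(parse_cosmic(s)), numeric(1),
         USE.NAMES = FALSE)
}

variant_key <- function(tab) {
  paste(tab$chrom, tab$start, tab$end, tab$ref, tab$alt, sep = ":")
}

## derive a reproducible stream of sub-seeds from one master seed
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}
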