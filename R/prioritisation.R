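## Filter algebra for variant prioritisation and top-table assembly.
##
## A variant is kept when it is protein changing, passes the germline filter,
## and either clears the score cutoff or is rescued by COSMIC overlap or
## DNA-repair-gene membership. COSMIC/DNA-repair act as rescues (a union with
## the score-passers), not as extra conjunctive filters: including known
## cancer variants must be able to grow the prioritised set.

#' Prioritisation filter configuration
#'
#' @param exclude_1000g drop variants flagged as 1000 Genomes germline
#'   variants (a common artifact of somatic calling pipelines).
#' @param max_1000g_af lenient germline mode: instead of dropping every
#'   flagged variant, keep those with allele frequency at or below this bound
#'   (some bona fide somatic hotspots occur at low frequency in germline
#'   panels). `NA` = strict exclusion.
#' @param rescue_cosmic keep variants overlapping COSMIC regardless of score.
#' @param rescue_ddr keep variants in DNA-repair genes regardless of score.
#' @param score_cutoff minimum score; comparison is inclusive (`>=`) unless
#'   `strict_cutoff`. A cutoff above 1 demands evidence in at least two
#'   algorithm clusters of the combination score.
#' @param protein_changing_only master gate on protein-changing variants.
#' @param strict_cutoff use `>` instead of `>=` at the cutoff.
#' @return a `prioritisation_config` list.
#' @export
prioritisation_config <- function(exclude_1000g = TRUE, max_1000g_af = NA,
                                  rescue_cosmic = FALSE, rescue_ddr = FALSE,
                                  score_cutoff = 0,
                                  protein_changing_only = TRUE,
                                  strict_cutoff = FALSE) {
  if (score_cutoff < 0) stopf("score_cutoff must be >= 0")
  structure(list(exclude_1000g = exclude_1000g,
                 max_1000g_af = as.numeric(max_1000g_af),
                 rescue_cosmic = rescue_cosmic, rescue_ddr = rescue_ddr,
                 score_cutoff = score_cutoff,
                 protein_changing_only = protein_changing_only,
                 strict_cutoff = strict_cutoff),
            class = "prioritisation_config")
}

#' Apply the prioritisation filters
#'
#' @param tab annotation data frame carrying a `score` column (see
#'   [score_variants]); `NA` scores never pass the cutoff but remain
#'   rescue-eligible.
#' @param config a [prioritisation_config].
#' @return list with `keep` (logical vector over rows of `tab`) and `counts`,
#'   the per-stage bookkeeping: total, protein-changing, 1000 Genomes
#'   flagged, COSMIC overlap, DNA-repair, passing the score cutoff, final.
#' @export
apply_filters <- function(tab, config = prioritisation_config()) {
  stopifnot(inherits(config, "prioritisation_config"))
  if (is.null(tab$score)) stopf("tab has no score column; run score_variants first")
  pc <- if (config$protein_changing_only) tab$protein_changing else
    rep(TRUE, nrow(tab))
  germline_pass <- if (!config$exclude_1000g) rep(TRUE, nrow(tab))
    else if (is.na(config$max_1000g_af)) !tab$in_1000g
    else !tab$in_1000g |
      (!is.na(tab$af_1000g) & tab$af_1000g <= config$max_1000g_af)
  score_pass <- if (config$strict_cutoff)
    !is.na(tab$score) & tab$score > config$score_cutoff
  else
    !is.na(tab$score) & tab$score >= config$score_cutoff
  cosmic <- cosmic_total(tab) > 0
  ddr <- tab$is_ddr_gene
  rescued <- (config$rescue_cosmic & cosmic) | (config$rescue_ddr & ddr)
  keep <- pc & germline_pass & (score_pass | rescued)
  counts <- c(total = nrow(tab),
              protein_changing = sum(pc),
              flagged_1000g = sum(tab$in_1000g & pc),
              cosmic_overlap = sum(cosmic & pc),
              ddr = sum(ddr & pc),
              score_pass = sum(score_pass & pc),
              final = sum(keep))
  list(keep = keep, counts = counts)
}

#' Kept-variant counts over a grid of score cutoffs
#'
#' Supports the cutoff-choice plot: how many variants survive as the score
#' cutoff rises (with all other filters as configured). Counts are
#' non-increasing in the cutoff.
#'
#' @param tab scored annotation data frame.
#' @param config a [prioritisation_config]; its `score_cutoff` is replaced by
#'   each grid point in turn.
#' @param cutoffs non-empty numeric grid.
#' @return data frame with columns `cutoff` and `n_kept`.
#' @export
cutoff_curve <- function(tab, config = prioritisation_config(), cutoffs) {
  if (length(cutoffs) == 0L) stopf("cutoff grid must be non-empty")
  n <- vapply(cutoffs, function(x) {
    cfg <- config
    cfg$score_cutoff <- x
    sum(apply_filters(tab, cfg)$keep)
  }, numeric(1))
  data.frame(cutoff = cutoffs, n_kept = n)
}

#' Assemble the prioritised top table
#'
#' Collapses kept rows to one row per unique (gene, protein change, type):
#' patient ids observed for the variant are merged (comma-separated, sorted),
#' the COSMIC entity map is rendered as `entity:count` pairs sorted by count
#' descending, and rows are ordered by score descending then gene ascending.
#' The applied configuration is recorded in the `"provenance"` attribute and
#' written as a comment block by [write_top_table].
#'
#' @param tab scored annotation data frame.
#' @param keep logical vector from [apply_filters].
#' @param config the [prioritisation_config] that produced `keep` (recorded as
#'   provenance).
#' @return data frame of class `top_table` with columns `gene`,
#'   `protein_change`, `type`, `classification`, `score`, `cosmic_entity`,
#'   `patient_ids`.
#' @export
assemble_top_table <- function(tab, keep, config = NULL) {
  kept <- tab[keep, , drop = FALSE]
  if (nrow(kept) == 0L) {
    out <- data.frame(gene = character(0), protein_change = character(0),
                      type = character(0), classification = character(0),
                      score = numeric(0), cosmic_entity = character(0),
                      patient_ids = character(0), stringsAsFactors = FALSE)
  } else {
    id <- paste(kept$gene, kept$protein_change, kept$vtype, sep = "\r")
    grp <- split(seq_len(nrow(kept)), id)
    rows <- lapply(grp, function(ix) {
      r <- kept[ix[1L], ]
      cc <- parse_cosmic(r$cosmic_counts)
      if (length(cc)) cc <- cc[order(-cc, names(cc))]
      sc <- kept$score[ix]
      sc <- if (all(is.na(sc))) NA_real_ else max(sc, na.rm = TRUE)
      data.frame(gene = r$gene, protein_change = r$protein_change,
                 type = r$vtype, classification = r$classification,
                 score = sc,
                 cosmic_entity = format_cosmic(cc),
                 patient_ids = paste(sort(unique(kept$patient_id[ix])),
                                     collapse = ", "),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(-ifelse(is.na(out$score), -Inf, out$score), out$gene), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  prov <- list(n_input = nrow(tab), n_kept = sum(keep))
  if (!is.null(config)) prov <- c(prov, unclass(config))
  attr(out, "provenance") <- prov
  class(out) <- c("top_table", "data.frame")
  out
}

#' @export
print.top_table <- function(x, ...) {
  cat(sprintf("Top table: %d prioritised variant(s)\n", nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}
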