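## Druggability: join prioritised variant genes to a drug-gene interaction
## snapshot and summarise patient-level actionability. Only expert-curated,
## multi-tumour-type interaction sources are used: My Cancer Genome entries
## unconditionally, TEND entries only when the agent is antineoplastic. A
## gene is deemed druggable independent of the tumour entity the drug was
## approved for (off-label reasoning); clinical efficacy is explicitly not
## predicted.

#' Restrict an interaction table to the trusted sources
#'
#' Keeps `MyCancerGenome` rows, and `TEND` rows whose `antineoplastic` flag
#' is `TRUE`. Rows with any other source label are dropped with a warning
#' (the vocabulary is closed).
#'
#' @param interactions data frame from [read_interactions].
#' @return the filtered interaction data frame.
#' @export
filter_interaction_sources <- function(interactions) {
  src <- interactions$source
  unknown <- setdiff(unique(src), c("TEND", "MyCancerGenome"))
  if (length(unknown))
    warnf("dropping interaction source(s) outside the closed vocabulary: %s",
          paste(unknown, collapse = ", "))
  keep <- src == "MyCancerGenome" |
    (src == "TEND" & !is.na(interactions$antineoplastic) &
       interactions$antineoplastic)
  interactions[keep, , drop = FALSE]
}

#' Join prioritised variants to drug-gene interactions
#'
#' Gene-symbol equality join (both sides uppercased at ingest). One hit per
#' (variant, drug_or_class) with the contributing sources merged, mirroring
#' how a drug class listed by both databases is reported once. Variants in
#' genes without interactions are absent from the output.
#'
#' @param top a top table (rows with `gene`, `protein_change`, `patient_ids`,
#'   `score`, `cosmic_entity`).
#' @param interactions a source-filtered interaction data frame (see
#'   [filter_interaction_sources]).
#' @return data frame of hits: `gene`, `protein_change`, `patient_ids`,
#'   `score`, `cosmic_flag`, `drug_or_class`, `sources` (sorted, joined with
#'   `" & "`).
#' @export
join_druggability <- function(top, interactions) {
  hits <- list()
  for (i in seq_len(nrow(top))) {
    g <- top$gene[i]
    m <- interactions[interactions$gene == g, , drop = FALSE]
    if (nrow(m) == 0L) next
    for (drug in unique(m$drug_or_class)) {
      srcs <- sort(unique(m$source[m$drug_or_class == drug]))
      hits[[length(hits) + 1L]] <- data.frame(
        gene = g, protein_change = top$protein_change[i],
        patient_ids = top$patient_ids[i], score = top$score[i],
        cosmic_flag = nzchar(top$cosmic_entity[i]),
        drug_or_class = drug, sources = paste(srcs, collapse = " & "),
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(gene = character(0), protein_change = character(0),
                      patient_ids = character(0), score = numeric(0),
                      cosmic_flag = logical(0), drug_or_class = character(0),
                      sources = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

split_patient_ids <- function(s) {
  ids <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  ids[nzchar(ids)]
}

#' Patient-level druggability summary
#'
#' @param hits data frame from [join_druggability].
#' @param n_patients_total cohort size.
#' @return list: `n_patients_total`; `n_druggable` (distinct patients with at
#'   least one hit); `n_multi` (patients appearing in at least two distinct
#'   (gene, protein change, drug) hits) and `n_exactly_two`; `per_class`
#'   (distinct patient count per drug class, named).
#' @export
patient_summary <- function(hits, n_patients_total) {
  pat_by_hit <- lapply(hits$patient_ids, split_patient_ids)
  all_pat <- unique(unlist(pat_by_hit))
  if (length(all_pat) > n_patients_total)
    stopf("more druggable patients (%d) than cohort size (%d)",
          length(all_pat), n_patients_total)
  hit_id <- paste(hits$gene, hits$protein_change, hits$drug_or_class,
                  sep = "\r")
  pairs <- do.call(rbind, lapply(seq_along(pat_by_hit), function(i) {
    p <- pat_by_hit[[i]]
    if (length(p) == 0L) return(NULL)
    data.frame(patient = p, hit = hit_id[i], stringsAsFactors = FALSE)
  }))
  per_patient <- if (is.null(pairs)) integer(0) else
    table(unique(pairs)$patient)
  per_class <- vapply(split(pat_by_hit, hits$drug_or_class),
                      function(l) length(unique(unlist(l))), integer(1))
  list(n_patients_total = n_patients_total,
       n_druggable = length(all_pat),
       n_multi = sum(per_patient >= 2L),
       n_exactly_two = sum(per_patient == 2L),
       per_class = per_class)
}
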