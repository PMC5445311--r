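## Readers/writers and the canonical in-memory model for variant,
## drug-interaction, expression and trait tables. All genomic coordinates are
## 1-based inclusive (MAF convention). Tables are plain data frames so they
## survive TSV round trips; rankscore columns are recognised by the
## `<algorithm>_rankscore` suffix.

## MAF column aliases accepted by the annotation reader (TCGA MAF names on the
## left, canonical names on the right).
.maf_aliases <- c(
  Hugo_Symbol            = "gene",
  Chromosome             = "chrom",
  Start_position         = "start",
  Start_Position         = "start",
  End_position           = "end",
  End_Position           = "end",
  Reference_Allele       = "ref",
  Tumor_Seq_Allele2      = "alt",
  Variant_Type           = "vtype",
  Variant_Classification = "classification",
  Tumor_Sample_Barcode   = "patient_id",
  Protein_Change         = "protein_change"
)

## GENCODE functional-consequence labels regarded as protein changing
.protein_changing_classes <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
  "Splice_Site", "Translation_Start_Site", "De_novo_Start_OutOfFrame",
  "missense", "nonsense", "frame-shift", "in-frame", "splice-site"
)

infer_vtype <- function(ref, alt) {
  ifelse(ref == "-" | nchar(alt) > nchar(ref), "INS",
  ifelse(alt == "-" | nchar(alt) < nchar(ref), "DEL",
  ifelse(nchar(ref) == 1L, "SNP",
  ifelse(nchar(ref) == 2L, "DNP", "ONP"))))
}

#' Read a minimal pre-annotation variant CSV
#'
#' The minimal input format is a header plus one variant per line with columns
#' `chr,start,end,ref,alt` (1-based inclusive coordinates). Variant type is
#' inferred from the allele lengths (SNP/DNP/DEL/INS).
#'
#' @param path path to the CSV file.
#' @return a data frame with columns `chrom`, `start`, `end`, `ref`, `alt`,
#'   `vtype`, rows in file order.
#' @export
read_variant_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        strip.white = TRUE)
  names(df)[names(df) %in% c("chr", "chromosome")] <- "chrom"
  need <- c("chrom", "start", "end", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("missing mandatory column(s): %s", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    out <- df[, need, drop = FALSE]
    out$start <- integer(0); out$end <- integer(0); out$vtype <- character(0)
    return(out)
  }
  start <- suppressWarnings(as.integer(df$start))
  end <- suppressWarnings(as.integer(df$end))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stopf("unparseable coordinate on line(s) %s",
          paste(bad + 1L, collapse = ", "))  # +1 for the header line
  bad <- which(start > end)
  if (length(bad))
    stopf("start > end on line(s) %s", paste(bad + 1L, collapse = ", "))
  data.frame(chrom = df$chrom, start = start, end = end,
             ref = df$ref, alt = df$alt,
             vtype = infer_vtype(df$ref, df$alt),
             stringsAsFactors = FALSE)
}

#' Read an annotated variant table
#'
#' Reads a TSV of per-variant annotations in the style of an Oncotator/MAF
#' export: one row per (variant, patient), identifying columns, annotation
#' flags and any number of `<algorithm>_rankscore` columns. TCGA MAF column
#' names (`Hugo_Symbol`, `Chromosome`, ...) are accepted as aliases. Gene
#' symbols are uppercased at ingest so downstream gene joins are
#' case-insensitive. Empty rankscore cells become missing values (`NA`),
#' never 0 — conservation scores are genuinely undefined for some variants.
#'
#' @param path path to the TSV file.
#' @return a validated annotation data frame (see [validate_annotation_table]).
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  hit <- names(df) %in% names(.maf_aliases)
  names(df)[hit] <- .maf_aliases[names(df)[hit]]
  need <- c("chrom", "start", "end", "ref", "alt", "gene", "patient_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("missing mandatory column(s): %s", paste(miss, collapse = ", "))
  df$chrom <- as.character(df$chrom)
  df$gene <- toupper(ifelse(is.na(df$gene), "", df$gene))
  df$patient_id <- as.character(df$patient_id)
  if (is.null(df$protein_change)) df$protein_change <- ""
  df$protein_change[is.na(df$protein_change)] <- ""
  if (is.null(df$vtype)) df$vtype <- infer_vtype(df$ref, df$alt)
  if (is.null(df$classification)) df$classification <- ""
  if (is.null(df$protein_changing))
    df$protein_changing <- df$classification %in% .protein_changing_classes
  df$protein_changing <- as.logical(df$protein_changing)
  if (is.null(df$af_1000g)) df$af_1000g <- NA_real_
  df$af_1000g <- as.numeric(df$af_1000g)
  if (is.null(df$in_1000g)) df$in_1000g <- !is.na(df$af_1000g)
  df$in_1000g <- as.logical(df$in_1000g)
  if (is.null(df$is_ddr_gene)) df$is_ddr_gene <- FALSE
  df$is_ddr_gene <- as.logical(df$is_ddr_gene)
  if (is.null(df$cosmic_counts)) df$cosmic_counts <- ""
  df$cosmic_counts[is.na(df$cosmic_counts)] <- ""
  for (col in rankscore_columns(df)) df[[col]] <- as.numeric(df[[col]])
  validate_annotation_table(df)
}

#' Validate an annotated variant table
#'
#' Checks the invariants of the canonical model: coordinates 1-based with
#' `start <= end`, rankscores in \[0, 1\] or missing, an allele-frequency
#' implies the 1000 Genomes flag, no duplicate
#' (chrom, start, end, ref, alt, patient_id) keys, and non-empty gene symbols
#' for protein-changing rows.
#'
#' @param tab annotation data frame.
#' @return `tab`, invisibly unchanged, or an error describing the violation.
#' @export
validate_annotation_table <- function(tab) {
  if (nrow(tab) == 0L) return(tab)
  if (any(tab$start > tab$end))
    stopf("start > end in row(s) %s",
          paste(which(tab$start > tab$end), collapse = ", "))
  for (col in rankscore_columns(tab)) {
    v <- tab[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad))
      stopf("rankscore outside [0,1] in column '%s', row(s) %s",
            col, paste(bad, collapse = ", "))
  }
  if (any(!is.na(tab$af_1000g) & !tab$in_1000g))
    stopf("af_1000g present but in_1000g FALSE in row(s) %s",
          paste(which(!is.na(tab$af_1000g) & !tab$in_1000g), collapse = ", "))
  key <- paste(variant_key(tab), tab$patient_id, sep = "|")
  if (anyDuplicated(key))
    stopf("duplicate (variant, patient) key(s): %s",
          paste(unique(key[duplicated(key)]), collapse = ", "))
  bad <- which(tab$protein_changing & !nzchar(tab$gene))
  if (length(bad))
    stopf("protein-changing row(s) with empty gene symbol: %s",
          paste(bad, collapse = ", "))
  tab
}

#' Write an annotated variant table as TSV
#'
#' @param tab annotation data frame.
#' @param path output path.
#' @export
write_annotation_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write a prioritised top table as TSV
#'
#' Writes the columns `gene`, `protein_change`, `type`, `classification`,
#' `score`, `cosmic_entity`, `patient_ids` preceded by `#`-prefixed metadata
#' comment lines recording the filters and thresholds applied, so a
#' downloaded spreadsheet documents its own provenance.
#'
#' @param top a top table as built by [assemble_top_table].
#' @param path output path.
#' @export
write_top_table <- function(top, path) {
  prov <- attr(top, "provenance")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# prioritised variant top table", con)
  if (!is.null(prov)) {
    for (nm in names(prov)) {
      val <- prov[[nm]]
      writeLines(sprintf("# %s: %s", nm,
                         paste(format(val, trim = TRUE), collapse = ",")), con)
    }
  }
  cols <- c("gene", "protein_change", "type", "classification", "score",
            "cosmic_entity", "patient_ids")
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(top)) {
    body <- top[, cols, drop = FALSE]
    body$score <- formatC(body$score, digits = 12, format = "g")
    utils::write.table(body, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read back a top table written by [write_top_table]
#'
#' @param path path to the TSV.
#' @return data frame with the top-table columns; the parsed metadata comment
#'   block is attached as attribute `"provenance"` (character).
#' @export
read_top_table <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE,
                          colClasses = c(score = "numeric"),
                          na.strings = "NA")
  for (col in c("gene", "protein_change", "type", "classification",
                "cosmic_entity", "patient_ids")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  attr(df, "provenance") <- sub("^# ?", "", meta)
  df
}

#' Read a drug-gene interaction snapshot
#'
#' Expected TSV schema: `gene`, `drug_or_class`, `source`, `antineoplastic`.
#' `source` uses the closed vocabulary `TEND`, `MyCancerGenome`, `other`.
#' This file-based snapshot replaces live interaction-database queries so
#' analyses are hermetic and version-pinned.
#'
#' @param path path to the TSV file.
#' @return data frame with uppercased gene symbols.
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("gene", "drug_or_class", "source")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("missing mandatory column(s): %s", paste(miss, collapse = ", "))
  df$gene <- toupper(df$gene)
  if (is.null(df$antineoplastic)) df$antineoplastic <- NA
  df$antineoplastic <- as.logical(df$antineoplastic)
  df
}

#' Read a gene x sample expression matrix from TSV
#'
#' First column = gene symbol, remaining columns = samples; values are
#' expected on a log scale but this is not enforced.
#'
#' @param path path to the TSV file.
#' @return numeric matrix, genes in rows.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- toupper(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (anyDuplicated(genes)) stopf("duplicate gene labels in %s", path)
  if (anyDuplicated(colnames(m))) stopf("duplicate sample labels in %s", path)
  if (any(rowSums(!is.na(m)) == 0L)) stopf("all-missing gene row in %s", path)
  m
}

#' Write a gene x sample expression matrix as TSV
#' @param m numeric matrix, genes in rows.
#' @param path output path.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample trait table
#'
#' One row per sample: a `sample` column, any number of 0/1 dichotomous trait
#' columns (missing allowed) and optional `survival_time` (non-negative) and
#' `survival_event` (0/1) columns.
#'
#' @param path path to the TSV file.
#' @param expr optional expression matrix; if given, sample labels are checked
#'   to be a subset of its columns.
#' @return data frame keyed by `sample`.
#' @export
read_trait_table <- function(path, expr = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (is.null(df$sample)) stopf("missing mandatory column: sample")
  df$sample <- as.character(df$sample)
  if (!is.null(df$survival_time) && any(df$survival_time < 0, na.rm = TRUE))
    stopf("negative survival_time")
  if (!is.null(expr)) {
    extra <- setdiff(df$sample, colnames(expr))
    if (length(extra))
      stopf("trait sample(s) absent from expression matrix: %s",
            paste(extra, collapse = ", "))
  }
  df
}

#' Read gene sets in GMT format
#'
#' GMT: one set per line, tab-separated `name`, `description`, genes...
#'
#' @param path path to the GMT file.
#' @return named list of uppercase gene character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    toupper(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}
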