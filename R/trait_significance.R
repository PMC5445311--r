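## Gene-significance (GS) measures relate each gene's expression profile to a
## sample trait: GS_i = -log10(p_i), where p_i comes from an unpaired
## two-sided Welch t-test for dichotomous traits or from a univariate Cox
## proportional-hazards model for survival. Module significance (MS) is the
## mean absolute GS over a module's genes. These measures let prioritised
## variant genes be read in their tumour-specific pathway context.

.P_FLOOR <- 1e-300  # p = 0 underflow floor before taking logs

gs_from_p <- function(p) -log10(pmax(p, .P_FLOOR))

.gene_labels <- function(expr) {
  if (is.null(rownames(expr))) sprintf("gene_%d", seq_len(nrow(expr)))
  else rownames(expr)
}

#' Gene significance against a dichotomous trait
#'
#' Per gene: unpaired two-sided Welch t-test between trait groups
#' (Welch-Satterthwaite degrees of freedom), effect size = absolute
#' difference in mean expression, GS = -log10(p).
#'
#' @param expr numeric matrix, genes x samples.
#' @param trait 0/1 vector along the samples (`NA` samples are dropped);
#'   both groups need at least 2 samples with positive variance.
#' @param measure label recorded in the output (e.g. `"lymphocyte_score"`,
#'   `"uv_signature"`, `"primary_vs_met"`).
#' @param adjust optionally Benjamini-Hochberg-adjust the p-values before
#'   the log transform (`"none"` by default: raw per-gene significance).
#' @return data frame with columns `gene`, `p_value`, `gs`, `effect_size`,
#'   `measure`.
#' @export
gs_dichotomous <- function(expr, trait, measure = "dichotomous",
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  ok <- !is.na(trait)
  x <- expr[, ok & trait == 1, drop = FALSE]
  y <- expr[, ok & trait == 0, drop = FALSE]
  if (ncol(x) < 2L || ncol(y) < 2L)
    stopf("each trait group needs at least 2 samples (got %d and %d)",
          ncol(y), ncol(x))
  n1 <- rowSums(!is.na(x)); n0 <- rowSums(!is.na(y))
  m1 <- rowMeans(x, na.rm = TRUE); m0 <- rowMeans(y, na.rm = TRUE)
  v1 <- apply(x, 1L, stats::var, na.rm = TRUE)
  v0 <- apply(y, 1L, stats::var, na.rm = TRUE)
  se2 <- v1 / n1 + v0 / n0
  t_stat <- (m1 - m0) / sqrt(se2)
  df <- se2 ^ 2 / ((v1 / n1) ^ 2 / (n1 - 1) + (v0 / n0) ^ 2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  p[se2 == 0] <- 1  # degenerate: identical constant groups
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  data.frame(gene = .gene_labels(expr), p_value = p, gs = gs_from_p(p),
             effect_size = abs(m1 - m0), measure = measure,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gene significance against survival
#'
#' Per gene: univariate Cox proportional-hazards model (Breslow tie
#' handling), two-sided Wald p, effect size = `max(HR, 1/HR)` — the
#' direction-free hazard-ratio magnitude, so protective associations weigh
#' as much as deleterious ones — and GS = -log10(p). Genes whose fit fails
#' to converge are returned with missing values.
#'
#' @param expr numeric matrix, genes x samples.
#' @param time non-negative survival/censoring times along the samples.
#' @param event 0/1 event indicators (at least one event).
#' @param measure label recorded in the output.
#' @param adjust see [gs_dichotomous].
#' @return data frame with columns `gene`, `p_value`, `gs`, `effect_size`
#'   (direction-free HR), `hazard_ratio` (signed), `coef`, `measure`.
#' @export
gs_survival <- function(expr, time, event, measure = "survival",
                        adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (any(time < 0, na.rm = TRUE)) stopf("negative survival time")
  if (sum(event, na.rm = TRUE) < 1) stopf("no events")
  surv <- survival::Surv(time, event)
  fit1 <- function(x) {
    f <- tryCatch(
      survival::coxph(surv ~ x, ties = "breslow",
                      control = survival::coxph.control(iter.max = 50)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(f) || is.na(stats::coef(f)))
      return(c(NA_real_, NA_real_))
    b <- unname(stats::coef(f))
    se <- sqrt(diag(f$var))[1L]
    c(b, 2 * stats::pnorm(-abs(b / se)))
  }
  res <- t(apply(expr, 1L, fit1))
  b <- res[, 1L]; p <- res[, 2L]
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  hr <- exp(b)
  data.frame(gene = .gene_labels(expr), p_value = p, gs = gs_from_p(p),
             effect_size = pmax(hr, 1 / hr), hazard_ratio = hr, coef = b,
             measure = measure, row.names = NULL, stringsAsFactors = FALSE)
}

#' Load an externally computed gene-significance measure
#'
#' Some GS measures (e.g. drug-resistance signatures from an external
#' cell-line study) arrive precomputed. The file must be a TSV with columns
#' `gene`, `p_value`, `effect_size`.
#'
#' @param path TSV path.
#' @param measure label recorded in the output.
#' @return data frame in the [gs_dichotomous] schema.
#' @export
gs_from_file <- function(path, measure = "external") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "p_value", "effect_size")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("missing mandatory column(s): %s", paste(miss, collapse = ", "))
  data.frame(gene = toupper(df$gene), p_value = df$p_value,
             gs = gs_from_p(df$p_value), effect_size = df$effect_size,
             measure = measure, row.names = NULL, stringsAsFactors = FALSE)
}

#' Module significance
#'
#' Mean absolute gene significance over each module's genes; genes with
#' missing GS are excluded from both numerator and denominator. Module 0 is
#' computed but should be read as background, not as a co-expression module.
#'
#' @param gs data frame from a `gs_*` function.
#' @param modules named integer vector (gene -> module id).
#' @return data frame with columns `module`, `measure`, `ms`, `n_genes`.
#' @export
module_significance <- function(gs, modules) {
  gs <- gs[gs$gene %in% names(modules), , drop = FALSE]
  mod <- modules[gs$gene]
  rows <- lapply(sort(unique(mod)), function(q) {
    v <- gs$gs[mod == q & !is.na(gs$gs)]
    data.frame(module = q, measure = gs$measure[1L],
               ms = if (length(v)) mean(abs(v)) else NA_real_,
               n_genes = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Name modules by gene-set enrichment
#'
#' One-sided hypergeometric over-representation test of each module against
#' user-supplied gene sets (GMT-style), with the network genes as universe.
#' Only sets with fewer than `max_term_size` genes compete, to exclude
#' uninformative high-level terms. The winning name is the smallest-p term
#' (ties: smaller set, then lexicographic); modules with no term below
#' `alpha` fall back to `module_<id>`.
#'
#' @param modules named integer vector (gene -> module id).
#' @param gene_sets named list of gene character vectors (see [read_gmt]).
#' @param max_term_size strict upper bound on competing set sizes.
#' @param alpha significance required for a name to win (default 0.05).
#' @return named character vector, one name per module id (>= 1).
#' @export
name_modules <- function(modules, gene_sets, max_term_size = 100,
                         alpha = 0.05) {
  if (length(gene_sets) == 0L) stopf("gene_sets must be non-empty")
  universe <- names(modules)
  sizes <- lengths(gene_sets)
  gene_sets <- gene_sets[sizes < max_term_size]
  ids <- sort(unique(modules[modules > 0]))
  out <- character(length(ids))
  names(out) <- ids
  for (i in seq_along(ids)) {
    mg <- universe[modules == ids[i]]
    p <- vapply(gene_sets, function(set) {
      set <- intersect(set, universe)
      q <- length(intersect(set, mg))
      stats::phyper(q - 1L, length(set), length(universe) - length(set),
                    length(mg), lower.tail = FALSE)
    }, numeric(1))
    ord <- order(p, lengths(gene_sets), names(gene_sets))
    best <- ord[1L]
    out[i] <- if (length(p) && p[best] < alpha) names(gene_sets)[best]
      else sprintf("module_%d", ids[i])
  }
  out
}

#' Place prioritised variant genes in the co-expression network
#'
#' Maps each top-table gene to its module (or `"not in network"` when the
#' gene is outside the selected top-variance genes), attaching the gene's
#' module membership and, per GS measure, its p-value, effect size and a
#' significance flag at `p_cutoff` (the dashed-line threshold of the
#' module-exploration plot).
#'
#' @param top a top table.
#' @param network a `coexpression_network`.
#' @param gs_list list of GS data frames (one per measure).
#' @param module_names optional named vector from [name_modules].
#' @param p_cutoff significance threshold for the per-measure flag.
#' @return list with `view` (one row per (gene, measure)) and
#'   `module_counts` (distinct prioritised genes per module; genes outside
#'   the network are excluded).
#' @export
variant_module_view <- function(top, network, gs_list, module_names = NULL,
                                p_cutoff = 0.05) {
  genes <- unique(top$gene)
  modules <- network$modules
  K <- network$membership
  rows <- list()
  for (g in genes) {
    in_net <- g %in% names(modules)
    mod <- if (in_net) unname(modules[g]) else NA_integer_
    mod_lab <- if (!in_net) "not in network"
      else if (!is.null(module_names) && as.character(mod) %in% names(module_names))
        module_names[[as.character(mod)]]
      else sprintf("module_%d", mod)
    kk <- if (in_net && !is.na(mod) && mod > 0 &&
              paste0("ME", mod) %in% colnames(K))
      K[g, paste0("ME", mod)] else NA_real_
    for (gs in gs_list) {
      hit <- match(g, gs$gene)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, module = mod, module_name = mod_lab, membership = kk,
        measure = gs$measure[1L],
        p_value = if (is.na(hit)) NA_real_ else gs$p_value[hit],
        effect_size = if (is.na(hit)) NA_real_ else gs$effect_size[hit],
        significant = if (is.na(hit)) NA else
          !is.na(gs$p_value[hit]) & gs$p_value[hit] < p_cutoff,
        stringsAsFactors = FALSE)
    }
  }
  view <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), module = integer(0),
               module_name = character(0), membership = numeric(0),
               measure = character(0), p_value = numeric(0),
               effect_size = numeric(0), significant = logical(0))
  in_net_genes <- genes[genes %in% names(modules)]
  module_counts <- table(modules[in_net_genes])
  list(view = view, module_counts = module_counts)
}
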