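## Deterministic synthetic-data generators for every input the toolkit
## consumes, so the full pipeline is testable without external downloads,
## plus a packaged worked example from a published melanoma druggability
## case study.

#' Names of the 18 dbNSFP-style prediction algorithms
#'
#' The current reference set of variant-effect prediction algorithms whose
#' rankscores the toolkit expects, grouped by working principle
#' (attribute `"category"`): conservation-based, protein-function prediction
#' and ensemble scores.
#'
#' @return character vector of 18 algorithm names.
#' @export
dbnsfp_algorithms <- function() {
  algs <- c("PhastCons100way_vertebrate", "PhastCons46way_placental",
            "PhastCons46way_primate", "PhyloP100way_vertebrate",
            "PhyloP46way_placental", "PhyloP46way_primate",
            "SiPhy_29way_logOdds", "GERP",
            "FATHMM", "LRT", "MutationAssessor", "MutationTaster",
            "Polyphen2_HDIV", "Polyphen2_HVAR", "SIFT",
            "LR", "RadialSVM", "CADD")
  attr(algs, "category") <- rep(c("conservation", "function_prediction",
                                  "ensemble"), c(8L, 7L, 3L))
  algs
}

## split a vector into n contiguous blocks as equal as possible
.blocks <- function(x, n) split(x, rep(seq_len(n), length.out = length(x),
                                       each = ceiling(length(x) / n))[seq_along(x)])

#' Generate a synthetic annotated variant table
#'
#' Rankscores follow a planted algorithm-cluster structure: each cluster
#' shares a per-variant latent deleteriousness, each algorithm adds
#' independent noise, and the Gaussian draw is pushed through the
#' probability-integral transform so marginal rankscores are uniform on
#' \[0, 1\]. A latent within-cluster correlation of 0.85 (the default)
#' yields observed rankscore correlations of about 0.84 after the transform.
#' Annotation flags are drawn at the specified fractions; the same seed gives
#' a byte-identical table.
#'
#' @param n_variants number of distinct variants.
#' @param n_patients cohort size (each variant is observed in 1-3 random
#'   patients; one row per (variant, patient)).
#' @param n_clusters planted algorithm-cluster count.
#' @param algorithms algorithm names (default [dbnsfp_algorithms]); planted
#'   clusters are contiguous blocks of this vector.
#' @param within_cor latent within-cluster correlation.
#' @param frac_1000g fraction of variants flagged as 1000 Genomes germline.
#' @param frac_cosmic fraction of variants with COSMIC overlap.
#' @param frac_ddr fraction of variants in DNA-repair genes.
#' @param frac_silent fraction of non-protein-changing variants.
#' @param frac_missing fraction of rankscore cells set missing.
#' @param seed integer seed (mandatory).
#' @return an annotation data frame passing [validate_annotation_table];
#'   the planted cluster partition is in attribute `"truth"`.
#' @export
make_variant_fixture <- function(n_variants = 100, n_patients = 20,
                                 n_clusters = 4,
                                 algorithms = dbnsfp_algorithms(),
                                 within_cor = 0.85, frac_1000g = 0.05,
                                 frac_cosmic = 0.15, frac_ddr = 0.05,
                                 frac_silent = 0.1, frac_missing = 0.05,
                                 seed) {
  if (missing(seed)) stopf("seed is mandatory")
  for (f in c(frac_1000g, frac_cosmic, frac_ddr, frac_silent, frac_missing))
    if (f < 0 || f > 1) stopf("fractions must lie in [0, 1]")
  if (within_cor < 0 || within_cor >= 1)
    stopf("within_cor must lie in [0, 1)")
  set.seed(seed)
  algorithms <- as.character(algorithms)
  blocks <- .blocks(algorithms, n_clusters)

  ## planted rankscores: shared latent per (cluster, variant) + noise
  w <- within_cor
  rs <- matrix(NA_real_, n_variants, length(algorithms),
               dimnames = list(NULL, paste0(algorithms, "_rankscore")))
  for (b in seq_along(blocks)) {
    z <- stats::rnorm(n_variants)
    for (a in blocks[[b]]) {
      g <- sqrt(w) * z + sqrt(1 - w) * stats::rnorm(n_variants)
      rs[, paste0(a, "_rankscore")] <- stats::pnorm(g)
    }
  }
  if (frac_missing > 0) {
    drop <- which(stats::runif(length(rs)) < frac_missing)
    rs[drop] <- NA_real_
  }

  genes <- sprintf("GENE%04d", sample.int(max(3L, ceiling(n_variants * 0.9)),
                                          n_variants, replace = TRUE))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_variants, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  pos <- sample.int(2e8, n_variants)
  silent <- stats::runif(n_variants) < frac_silent
  aa <- c("A", "R", "N", "D", "C", "E", "G", "H", "K", "V")
  variants <- data.frame(
    chrom = as.character(sample(1:22, n_variants, replace = TRUE)),
    start = pos, end = pos, ref = ref, alt = unname(alt),
    gene = genes,
    protein_change = ifelse(silent, "",
                            sprintf("p.%s%d%s", sample(aa, n_variants, TRUE),
                                    sample.int(900, n_variants, TRUE),
                                    sample(aa, n_variants, TRUE))),
    vtype = "SNP",
    classification = ifelse(silent, "Silent", "Missense_Mutation"),
    protein_changing = !silent,
    stringsAsFactors = FALSE)

  flagged <- stats::runif(n_variants) < frac_1000g
  variants$in_1000g <- flagged
  variants$af_1000g <- ifelse(flagged, round(stats::runif(n_variants, 1e-4, 0.1), 5),
                              NA_real_)
  cosmic <- stats::runif(n_variants) < frac_cosmic
  entities <- c("melanoma", "lung", "colon", "breast")
  variants$cosmic_counts <- ifelse(
    cosmic, sprintf("%s:%d", sample(entities, n_variants, replace = TRUE),
                    sample.int(50, n_variants, replace = TRUE)), "")
  ddr_genes <- sample(unique(genes), max(0L, round(frac_ddr * length(unique(genes)))))
  variants$is_ddr_gene <- variants$gene %in% ddr_genes

  ## expand to one row per (variant, patient)
  n_per <- sample(1:3, n_variants, replace = TRUE)
  idx <- rep(seq_len(n_variants), n_per)
  tab <- cbind(variants[idx, , drop = FALSE],
               as.data.frame(rs[idx, , drop = FALSE]))
  tab$patient_id <- unlist(lapply(n_per, function(k)
    sprintf("P%02d", sort(sample.int(n_patients, k)))))
  rownames(tab) <- NULL
  tab <- validate_annotation_table(tab)
  attr(tab, "truth") <- list(clusters = blocks)
  tab
}

#' Generate a synthetic expression matrix with planted modules and traits
#'
#' Module genes are a scaled latent factor plus independent noise, giving the
#' requested within-module correlation; between-module correlations are ~0.
#' One designated module's factor shifts with a dichotomous trait, and
#' survival times are exponential with log-hazard linear in another module's
#' factor, with administrative censoring at a fixed horizon (the default
#' yields roughly 30% events under the null). Background genes are pure
#' noise. Emulates co-expressed modules with trait and survival
#' associations; it does not emulate heavy-tailed counts, batch effects or
#' correlated background structure of real RNA-seq.
#'
#' @param n_genes total gene count (at least `sum(module_sizes)`).
#' @param n_samples sample count.
#' @param module_sizes planted module sizes.
#' @param within_cor within-module gene-gene correlation.
#' @param trait_effect shift (in latent-factor SD units) of module 1's factor
#'   in trait-positive samples; 0 plants no association.
#' @param surv_log_hr planted log hazard ratio per unit of the survival
#'   module's factor (module 2 if present, else module 1); 0 plants none.
#' @param censor_horizon administrative censoring time.
#' @param seed integer seed (mandatory).
#' @return list with `expr` (genes x samples), `traits` (data frame with
#'   `sample`, `trait`, `survival_time`, `survival_event`) and `truth`
#'   (planted module assignment, factors, designated modules).
#' @export
make_expression_fixture <- function(n_genes = 150, n_samples = 100,
                                    module_sizes = c(50, 50, 50),
                                    within_cor = 0.8, trait_effect = 1,
                                    surv_log_hr = 1,
                                    censor_horizon = 0.357, seed) {
  if (missing(seed)) stopf("seed is mandatory")
  if (within_cor < 0 || within_cor >= 1) stopf("within_cor must lie in [0, 1)")
  if (sum(module_sizes) > n_genes)
    stopf("module sizes (%d) exceed n_genes (%d)", sum(module_sizes), n_genes)
  set.seed(seed)
  n_mod <- length(module_sizes)
  trait <- stats::rbinom(n_samples, 1L, 0.5)
  samples <- sprintf("S%03d", seq_len(n_samples))

  factors <- matrix(stats::rnorm(n_mod * n_samples), n_mod, n_samples)
  trait_module <- if (n_mod >= 1L) 1L else NA_integer_
  surv_module <- if (n_mod >= 2L) 2L else trait_module
  if (!is.na(trait_module) && trait_effect != 0)
    factors[trait_module, ] <- factors[trait_module, ] + trait_effect * trait

  w <- within_cor
  expr <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
  assignment <- integer(n_genes)
  g0 <- 0L
  for (m in seq_len(n_mod)) {
    ix <- g0 + seq_len(module_sizes[m])
    for (i in ix)
      expr[i, ] <- sqrt(w) * factors[m, ] + sqrt(1 - w) * expr[i, ]
    assignment[ix] <- m
    g0 <- g0 + module_sizes[m]
  }
  rownames(expr) <- sprintf("G%04d", seq_len(n_genes))
  colnames(expr) <- samples
  names(assignment) <- rownames(expr)

  if (!is.na(surv_module) && surv_log_hr != 0) {
    rate <- exp(surv_log_hr * factors[surv_module, ])
  } else rate <- rep(1, n_samples)
  t_true <- stats::rexp(n_samples, rate = rate)
  event <- as.integer(t_true <= censor_horizon)
  time <- pmin(t_true, censor_horizon)

  traits <- data.frame(sample = samples, trait = trait,
                       survival_time = time, survival_event = event,
                       stringsAsFactors = FALSE)
  list(expr = expr, traits = traits,
       truth = list(modules = assignment, factors = factors,
                    trait_module = trait_module, surv_module = surv_module))
}

#' Packaged melanoma druggability worked example
#'
#' A published case study of 93 BRAF-wild-type/RAS-wild-type cutaneous
#' melanomas reported 13 prioritised variants with drug-gene interactions
#' from the expert-curated sources (TEND antineoplastic agents and
#' My Cancer Genome). This function loads that printed table and the
#' gene-to-drug interaction snapshot it implies, as shipped under
#' `inst/extdata/`. The `cosmic_entity` column carries only the printed
#' overlap flag (`yes`), not per-entity counts.
#'
#' @return list with `top_table` (13 prioritised variants with patient ids
#'   and scores), `interactions` (drug-gene snapshot) and `n_patients`
#'   (cohort size, 93).
#' @export
melanoma_druggability_example <- function() {
  tt <- read_top_table(system.file("extdata",
                                   "melanoma_druggability_top_table.tsv",
                                   package = "oncoprior", mustWork = TRUE))
  ia <- read_interactions(system.file("extdata",
                                      "melanoma_interactions.tsv",
                                      package = "oncoprior", mustWork = TRUE))
  list(top_table = tt, interactions = ia, n_patients = 93L)
}
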