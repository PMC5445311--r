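## Batch orchestration: one configuration (R list or YAML file) drives the
## chain cluster-scores -> score -> prioritise -> druggability -> network,
## with provenance (tool version, input digests, effective config, seeds)
## propagated into every output directory. Reruns with the same config and
## inputs are bit-identical except for timestamps.

.default_config <- function() list(
  seed = 1L,
  out_dir = "oncoprior_run",
  stages = c("cluster", "score", "prioritise"),
  annotations = NULL,
  interactions = NULL,
  expression = NULL,
  traits = NULL,
  gene_sets = NULL,
  cluster = list(k_min = 2L, k_max = 6L, reps = 100L,
                 p_item = 0.8, p_feature = 0.8),
  score = list(threshold = 0.75, algorithm = NULL),
  prioritise = list(exclude_1000g = TRUE, max_af = NA,
                    rescue_cosmic = FALSE, rescue_ddr = FALSE,
                    cutoff = 0, protein_changing_only = TRUE),
  druggability = list(n_patients = NA),
  network = list(top_n = 5000L, beta = "auto", min_module_size = 30L,
                 cut_height = 0.99)
)

## deep-merge user config over defaults; unknown keys are a config error
merge_config <- function(user, defaults = .default_config()) {
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      merge_config(user[[nm]], defaults[[nm]]) else user[[nm]]
  }
  defaults
}

validate_config <- function(cfg) {
  known <- c("cluster", "score", "prioritise", "druggability", "network")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  if (length(cfg$stages) == 0L) stopf("no stages enabled")
  if (is.null(cfg$annotations))
    stopf("config error: 'annotations' is required")
  if ("druggability" %in% cfg$stages && is.null(cfg$interactions))
    stopf("config error: 'interactions' is required when the druggability stage is enabled")
  if ("network" %in% cfg$stages &&
      (is.null(cfg$expression) || is.null(cfg$traits)))
    stopf("config error: 'expression' and 'traits' are required when the network stage is enabled")
  cfg
}

run_provenance <- function(cfg, inputs) {
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  list(tool = "oncoprior",
       version = as.character(utils::packageVersion("oncoprior")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = cfg$seed,
       input_digests = as.list(tools::md5sum(unlist(inputs))),
       config = cfg)
}

#' Run the prioritisation pipeline from a configuration
#'
#' Stages (any subset, executed in this fixed order): `cluster` (consensus
#' clustering of rankscores), `score` (combination score), `prioritise`
#' (filter algebra + top table), `druggability` (interaction join + patient
#' summary), `network` (co-expression network, gene/module significance and
#' the variant-module view). Outputs are written in a fixed layout under
#' `out_dir` together with `provenance.json`; a failing stage writes a
#' `FAILED` marker naming the stage and aborts.
#'
#' @param config an R list, or path to a YAML file with the same structure;
#'   unknown keys are a config error. See the package vignette for the
#'   schema.
#' @return invisibly, a list of the in-memory stage results plus
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(merge_config(config))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out, "FAILED"))
  prov <- run_provenance(cfg, cfg[c("annotations", "interactions",
                                    "expression", "traits", "gene_sets")])
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res <- list(out_dir = out)
  stage <- "setup"
  run_stage <- function(name, fun) {
    stage <<- name
    fun()
  }
  tryCatch({
    tab <- read_annotation_table(cfg$annotations)
    clusters <- NULL
    if ("cluster" %in% cfg$stages) run_stage("cluster", function() {
      cc <- cfg$cluster
      cons <- consensus_cluster(rankscore_matrix(tab),
                                k_range = cc$k_min:cc$k_max, reps = cc$reps,
                                p_item = cc$p_item, p_feature = cc$p_feature,
                                seed = cfg$seed)
      clusters <<- algorithm_clusters(cons)
      jsonlite::write_json(
        list(chosen_k = as.integer(cons$chosen_k),
             chosen_k_provenance = attr(cons$chosen_k, "provenance"),
             assignments = lapply(cons$assignments, as.list),
             cdf = cons$cdf, params = cons$params),
        file.path(out, "clustering.json"), auto_unbox = TRUE, digits = NA)
      res$clustering <<- cons
    })
    if (any(c("score", "prioritise", "druggability", "network") %in%
            cfg$stages)) run_stage("score", function() {
      if (is.null(clusters) && is.null(cfg$score$algorithm)) {
        ## clustering stage disabled and no single algorithm chosen:
        ## fall back to a round-robin partition into four clusters
        algs <- algorithm_names(tab)
        clusters <<- split(algs, rep_len(seq_len(min(4L, length(algs))),
                                         length(algs)))
      }
      tab <<- score_variants(tab, clusters = clusters,
                             threshold = cfg$score$threshold,
                             algorithm = cfg$score$algorithm)
      write_annotation_table(tab, file.path(out, "scored.tsv"))
    })
    top <- NULL
    if (any(c("prioritise", "druggability", "network") %in% cfg$stages))
      run_stage("prioritise", function() {
        pc <- cfg$prioritise
        pcfg <- prioritisation_config(
          exclude_1000g = pc$exclude_1000g,
          max_1000g_af = if (is.null(pc$max_af)) NA else pc$max_af,
          rescue_cosmic = pc$rescue_cosmic, rescue_ddr = pc$rescue_ddr,
          score_cutoff = pc$cutoff,
          protein_changing_only = pc$protein_changing_only)
        flt <- apply_filters(tab, pcfg)
        top <<- assemble_top_table(tab, flt$keep, pcfg)
        write_top_table(top, file.path(out, "top_table.tsv"))
        utils::write.table(data.frame(stage = names(flt$counts),
                                      n = as.integer(flt$counts)),
                           file.path(out, "filter_counts.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        res$top_table <<- top
        res$counts <<- flt$counts
      })
    if ("druggability" %in% cfg$stages) run_stage("druggability", function() {
      ia <- filter_interaction_sources(read_interactions(cfg$interactions))
      hits <- join_druggability(top, ia)
      n_pat <- cfg$druggability$n_patients
      if (is.na(n_pat))
        n_pat <- length(unique(unlist(lapply(top$patient_ids,
                                             split_patient_ids))))
      summ <- patient_summary(hits, n_pat)
      utils::write.table(hits, file.path(out, "druggability_hits.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(summ, file.path(out, "druggability_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      res$hits <<- hits
      res$druggability <<- summ
    })
    if ("network" %in% cfg$stages) run_stage("network", function() {
      nc <- cfg$network
      expr <- read_expression_matrix(cfg$expression)
      traits <- read_trait_table(cfg$traits, expr)
      net <- coexpression_network(expr, top_n_genes = nc$top_n,
                                  beta = nc$beta,
                                  min_module_size = nc$min_module_size,
                                  cut_height = nc$cut_height)
      utils::write.table(data.frame(gene = names(net$modules),
                                    module = net$modules),
                         file.path(out, "modules.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      if (!is.null(net$eigengenes)) {
        write_expression_matrix(net$eigengenes$eigengenes,
                                file.path(out, "eigengenes.tsv"))
        utils::write.table(
          data.frame(gene = rownames(net$membership), net$membership,
                     check.names = FALSE),
          file.path(out, "membership.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
        if (!is.null(net$eigengenes$dendrogram))
          write_eigengene_newick(net$eigengenes,
                                 file.path(out, "eigengene_dendrogram.nwk"))
      }
      sm <- traits[match(colnames(net$expr), traits$sample), ]
      gs_list <- list()
      trait_cols <- setdiff(names(traits),
                            c("sample", "survival_time", "survival_event"))
      for (tc in trait_cols)
        gs_list[[tc]] <- gs_dichotomous(net$expr, sm[[tc]], measure = tc)
      if (!is.null(traits$survival_time))
        gs_list$survival <- gs_survival(net$expr, sm$survival_time,
                                        sm$survival_event)
      ms <- do.call(rbind, lapply(gs_list, module_significance,
                                  modules = net$modules))
      utils::write.table(ms, file.path(out, "module_significance.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      nm <- NULL
      if (!is.null(cfg$gene_sets)) {
        nm <- name_modules(net$modules, read_gmt(cfg$gene_sets))
        jsonlite::write_json(as.list(nm), file.path(out, "module_names.json"),
                             auto_unbox = TRUE)
      }
      if (!is.null(top)) {
        vmv <- variant_module_view(top, net, gs_list, module_names = nm)
        utils::write.table(vmv$view, file.path(out, "variant_module_view.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      res$network <<- net
      res$gs <<- gs_list
      res$module_significance <<- ms
    })
  }, error = function(e) {
    writeLines(sprintf("stage: %s\n%s", stage, conditionMessage(e)),
               file.path(out, "FAILED"))
    stopf("pipeline failed in stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(res)
}
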