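## The cluster-based combination score. Given a partition of the prediction
## algorithms into m clusters of redundant scores, a variant's combination
## score is
##
##   c = sum_j y_j,   y_j = mean rankscore of cluster j   if that mean >= 0.75
##                    y_j = 0                             otherwise
##
## so each algorithm cluster contributes its per-variant mean rankscore only
## when there is strong evidence in that family (a mean in the upper quartile
## of the theoretical [0,1] rankscore range; the 0.75 gate is inclusive).
## The score lies in [0, m]: values above 1 mean at least two independent
## algorithm families rank the variant as highly deleterious.

#' Combination score for one variant
#'
#' @param rankscores named numeric vector of per-algorithm rankscores in
#'   \[0, 1\], `NA` for missing.
#' @param clusters named list of character vectors partitioning (a subset of)
#'   the algorithm names into clusters; must be disjoint and non-empty.
#' @param threshold gate on the per-cluster mean rankscore (inclusive);
#'   default 0.75.
#' @return list with elements `c` (the score; `NA` when every cluster mean is
#'   undefined), `cluster_means` (named, `NA` when a cluster has no
#'   non-missing rankscore), `contributions` (the `y_j`) and
#'   `all_missing` (logical flag per cluster).
#' @export
combination_score <- function(rankscores, clusters, threshold = 0.75) {
  if (length(clusters) == 0L) stopf("clusters must be non-empty")
  algs <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(algs)) stopf("clusters must be disjoint")
  if (any(lengths(clusters) == 0L)) stopf("clusters must be non-empty")
  extra <- setdiff(names(rankscores), algs)
  if (length(extra))
    warnf("rankscore(s) for algorithm(s) outside the clustering ignored: %s",
          paste(extra, collapse = ", "))
  means <- vapply(clusters, function(a) {
    v <- rankscores[a]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  all_missing <- is.na(means)
  y <- ifelse(!all_missing & means >= threshold, means, 0)
  c_score <- if (all(all_missing)) NA_real_ else sum(y)
  list(c = c_score, cluster_means = means, contributions = y,
       all_missing = all_missing)
}

#' Score every variant of an annotation table
#'
#' Adds a `score` column: either the combination score over `clusters`
#' (default) or, in pass-through mode, the rankscore of one chosen
#' `algorithm`. Variants whose rankscores are all missing get `NA` (they are
#' excluded from score-based filtering but remain eligible for COSMIC/DNA-
#' repair rescue downstream).
#'
#' @param tab annotation data frame.
#' @param clusters named list partitioning algorithm names (e.g. from
#'   [algorithm_clusters]); ignored in pass-through mode.
#' @param threshold numeric gate (default 0.75), or `"empirical"` to gate at
#'   the empirical 75% quantile of all observed rankscores in `tab`.
#' @param algorithm optional single algorithm name for pass-through mode.
#' @return `tab` with a `score` column; scoring settings in attribute
#'   `"scoring"`.
#' @export
score_variants <- function(tab, clusters = NULL, threshold = 0.75,
                           algorithm = NULL) {
  algs <- algorithm_names(tab)
  if (!is.null(algorithm)) {
    if (!algorithm %in% algs) stopf("unknown algorithm: %s", algorithm)
    tab$score <- tab[[paste0(algorithm, "_rankscore")]]
    attr(tab, "scoring") <- list(mode = "single", algorithm = algorithm)
    return(tab)
  }
  if (is.null(clusters)) stopf("either clusters or algorithm must be given")
  if (identical(threshold, "empirical")) {
    all_rs <- unlist(tab[, rankscore_columns(tab)], use.names = FALSE)
    threshold <- stats::quantile(all_rs, 0.75, na.rm = TRUE, names = FALSE)
  }
  rs <- as.matrix(tab[, rankscore_columns(tab), drop = FALSE])
  colnames(rs) <- algs
  known <- intersect(unlist(clusters, use.names = FALSE), algs)
  scores <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    v <- rs[i, ]
    scores[i] <- suppressWarnings(
      combination_score(v[known], clusters, threshold)$c)
  }
  tab$score <- scores
  attr(tab, "scoring") <- list(mode = "combination", threshold = threshold,
                               clusters = clusters)
  tab
}
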