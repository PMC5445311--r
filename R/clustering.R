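## Consensus clustering of prediction-algorithm rankscore profiles.
##
## Different variant-effect prediction algorithms carry overlapping
## information (conservation-based, protein-function-based and ensemble
## scores correlate within their families). Monti-style consensus clustering
## over resampled variants reveals the stable groups of redundant algorithms,
## and the CDF / delta(k) diagnostics suggest how many groups there are. The
## items being clustered are the algorithms; the features resampled are the
## variants.

#' Build an algorithm x variant rankscore matrix
#'
#' Collapses an annotation table to one column per unique variant (first
#' occurrence wins across patients: rankscores are a property of the variant,
#' not of the patient it was observed in).
#'
#' @param tab annotation data frame with `<algorithm>_rankscore` columns.
#' @return numeric matrix, algorithms in rows, variants in columns.
#' @export
rankscore_matrix <- function(tab) {
  rs_cols <- rankscore_columns(tab)
  if (length(rs_cols) < 2L) stopf("need at least 2 rankscore columns")
  key <- variant_key(tab)
  first <- !duplicated(key)
  m <- t(as.matrix(tab[first, rs_cols, drop = FALSE]))
  rownames(m) <- sub("_rankscore$", "", rs_cols)
  colnames(m) <- key[first]
  m
}

## average-linkage partition of items from a distance matrix, robust to the
## degenerate all-zero-distance case (then: a single cluster, since there is
## no structure to split)
.cut_avg <- function(d, k) {
  dm <- as.matrix(d)
  if (max(dm, na.rm = TRUE) <= .Machine$double.eps ^ 0.5)
    return(rep(1L, nrow(dm)))
  stats::cutree(stats::hclust(stats::as.dist(dm), method = "average"), k = k)
}

#' Consensus clustering of algorithm rankscore profiles
#'
#' For each resampling replicate, a fraction `p_item` of algorithms and
#' `p_feature` of variants is drawn without replacement, profiles are
#' clustered by average-linkage agglomeration on distance
#' `1 - Pearson correlation` (pairwise-complete observations), and the tree is
#' cut at every `k` in `k_range`. The consensus index of an algorithm pair at
#' a given `k` is the fraction of replicates in which both were drawn and
#' landed in the same cluster. The final assignment at each `k` clusters the
#' consensus matrix itself (average linkage on `1 - consensus`).
#'
#' @param R rankscore matrix from [rankscore_matrix] (algorithms x variants,
#'   values in \[0,1\] or `NA`).
#' @param k_range integer vector of cluster numbers, within
#'   `[2, nrow(R) - 1]`.
#' @param reps number of resampling replicates.
#' @param p_item fraction of algorithms drawn per replicate.
#' @param p_feature fraction of variants drawn per replicate.
#' @param seed integer seed driving the whole resampling schedule (mandatory;
#'   replicates are generated sequentially so results are reproducible).
#' @param min_delta passed to [select_k] for the automatic choice of `k`.
#' @return an object of class `consensus_result`: consensus matrices and
#'   assignments per `k`, the CDF-area diagnostics, `chosen_k` and the
#'   resampling parameters.
#' @export
consensus_cluster <- function(R, k_range = 2:6, reps = 100, p_item = 0.8,
                              p_feature = 0.8, seed, min_delta = 0.05) {
  if (missing(seed)) stopf("seed is mandatory")
  n <- nrow(R)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2L || max(k_range) > n - 1L)
    stopf("k_range must lie within [2, %d]", n - 1L)
  low <- rowSums(!is.na(R)) < 2L
  if (any(low))
    stopf("algorithm(s) with <2 non-missing rankscores: %s",
          paste(rownames(R)[low], collapse = ", "))

  n_item <- max(2L, round(p_item * n))
  n_feat <- max(2L, round(p_feature * ncol(R)))
  co_cluster <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_cluster) <- as.character(k_range)
  co_sampled <- matrix(0, n, n)

  set.seed(seed)
  for (r in seq_len(reps)) {
    items <- sort(sample.int(n, n_item))
    feats <- sort(sample.int(ncol(R), n_feat))
    sub <- R[items, feats, drop = FALSE]
    cm <- suppressWarnings(stats::cor(t(sub), use = "pairwise.complete.obs"))
    cm[is.na(cm)] <- 0  # no overlapping observations: treat as uncorrelated
    d <- 1 - cm
    co_sampled[items, items] <- co_sampled[items, items] + 1
    if (max(d) <= .Machine$double.eps ^ 0.5) {
      for (kc in names(co_cluster))
        co_cluster[[kc]][items, items] <- co_cluster[[kc]][items, items] + 1
    } else {
      tree <- stats::hclust(stats::as.dist(d), method = "average")
      for (k in k_range) {
        cl <- stats::cutree(tree, k = min(k, n_item))
        same <- outer(cl, cl, "==")
        kc <- as.character(k)
        co_cluster[[kc]][items, items] <- co_cluster[[kc]][items, items] + same
      }
    }
  }

  never <- co_sampled == 0 & upper.tri(co_sampled)
  if (any(never))
    warnf("%d algorithm pair(s) never co-sampled; their consensus is set to 0",
          sum(never))

  consensus <- lapply(co_cluster, function(M) {
    C <- ifelse(co_sampled > 0, M / pmax(co_sampled, 1), 0)
    diag(C) <- 1
    dimnames(C) <- list(rownames(R), rownames(R))
    C
  })
  assignments <- lapply(k_range, function(k) {
    cl <- .cut_avg(1 - consensus[[as.character(k)]], k)
    names(cl) <- rownames(R)
    cl
  })
  names(assignments) <- as.character(k_range)

  cdf <- cdf_and_delta(consensus)
  chosen <- select_k(cdf, min_delta = min_delta)

  structure(list(consensus = consensus, assignments = assignments,
                 cdf = cdf, chosen_k = chosen,
                 params = list(k_range = k_range, reps = reps,
                               p_item = p_item, p_feature = p_feature,
                               seed = seed, min_delta = min_delta)),
            class = "consensus_result")
}

#' CDF areas and relative changes for consensus matrices
#'
#' `A(k)` is the area under the empirical CDF of the upper-triangle consensus
#' indices (exact integral of the step CDF over \[0, 1\]). The relative change
#' follows the Monti convention: `delta(k_min) = A(k_min)` and
#' `delta(k) = (A(k) - A(k-1)) / A(k-1)` for larger `k`. A well-separated
#' clustering pushes consensus indices to 0 and 1, so `A(k)` stops growing
#' once `k` exceeds the true number of clusters.
#'
#' @param consensus named list of consensus matrices keyed by `k` (as from
#'   [consensus_cluster]), for at least two consecutive `k`.
#' @return data frame with columns `k`, `area`, `delta`.
#' @export
cdf_and_delta <- function(consensus) {
  ks <- sort(as.integer(names(consensus)))
  if (length(ks) < 2L) stopf("need consensus matrices for at least 2 values of k")
  area <- vapply(as.character(ks), function(kc) {
    C <- consensus[[kc]]
    consensus_cdf_area(C[upper.tri(C)])
  }, numeric(1))
  delta <- c(area[1L],
             if (length(ks) > 1L) diff(area) / head(area, -1L))
  delta[!is.finite(delta)] <- 0
  data.frame(k = ks, area = unname(area), delta = unname(delta))
}

#' Area under the empirical CDF of consensus indices
#'
#' @param x consensus indices in \[0, 1\].
#' @return the exact integral of the empirical CDF over \[0, 1\].
#' @export
consensus_cdf_area <- function(x) {
  x <- sort(x)
  grid <- unique(c(0, x, 1))
  Fg <- vapply(grid, function(t) mean(x <= t), numeric(1))
  sum(diff(grid) * Fg[-length(grid)])
}

#' Choose the number of algorithm clusters from delta(k)
#'
#' Returns the largest `k` whose relative CDF-area change is at least
#' `min_delta` — i.e. the last `k` at which adding a cluster still markedly
#' increased consensus separation. If no `k` qualifies (degenerate data), the
#' smallest candidate `k` is returned with a warning. An explicit user
#' `override` always wins and is recorded in the `"provenance"` attribute.
#'
#' @param deltas data frame from [cdf_and_delta] (or a vector of deltas named
#'   by `k`).
#' @param min_delta minimum relative change regarded as marked.
#' @param override optional user-chosen `k`.
#' @return integer `k` with attribute `"provenance"` of `"rule"`,
#'   `"fallback_min_k"` or `"user_override"`.
#' @export
select_k <- function(deltas, min_delta = 0.05, override = NULL) {
  if (is.data.frame(deltas)) {
    ks <- deltas$k; dl <- deltas$delta
  } else {
    ks <- as.integer(names(deltas)); dl <- as.numeric(deltas)
  }
  if (length(ks) == 0L) stopf("empty deltas")
  if (!is.null(override)) {
    k <- as.integer(override)
    attr(k, "provenance") <- "user_override"
    return(k)
  }
  ok <- which(dl >= min_delta)
  if (length(ok) == 0L) {
    warnf("no k with delta >= %g; falling back to k = %d", min_delta, min(ks))
    k <- min(ks)
    attr(k, "provenance") <- "fallback_min_k"
    return(k)
  }
  k <- max(ks[ok])
  attr(k, "provenance") <- "rule"
  k
}

#' Cluster partition of a consensus result as a named list
#'
#' @param x a `consensus_result`.
#' @param k cluster number (default: `chosen_k`).
#' @return named list mapping cluster labels (`"cluster_1"`, ...) to
#'   character vectors of algorithm names, as consumed by [score_variants].
#' @export
algorithm_clusters <- function(x, k = NULL) {
  stopifnot(inherits(x, "consensus_result"))
  if (is.null(k)) k <- as.integer(x$chosen_k)
  cl <- x$assignments[[as.character(k)]]
  if (is.null(cl)) stopf("k = %d was not in the clustered range", k)
  split(names(cl), paste0("cluster_", cl))
}

#' @export
print.consensus_result <- function(x, ...) {
  p <- x$params
  cat(sprintf("Consensus clustering of %d algorithms (reps = %d, p_item = %g, p_feature = %g, seed = %d)\n",
              nrow(x$consensus[[1L]]), p$reps, p$p_item, p$p_feature, p$seed))
  cat(sprintf("k range: %s; chosen k = %d (%s)\n",
              paste(range(p$k_range), collapse = "-"),
              as.integer(x$chosen_k), attr(x$chosen_k, "provenance")))
  print(x$cdf, row.names = FALSE)
  invisible(x)
}

#' Plot consensus CDF curves and delta(k)
#'
#' @param x a `consensus_result`.
#' @param ... ignored.
#' @export
plot.consensus_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "consensus index",
       ylab = "CDF", main = "consensus CDFs")
  ks <- x$cdf$k
  for (i in seq_along(ks)) {
    C <- x$consensus[[as.character(ks[i])]]
    v <- sort(C[upper.tri(C)])
    graphics::lines(stats::ecdf(v), col = i, do.points = FALSE)
  }
  graphics::legend("bottomright", legend = paste0("k=", ks),
                   col = seq_along(ks), lty = 1, bty = "n")
  plot(x$cdf$k, x$cdf$delta, type = "b", xlab = "k",
       ylab = expression(Delta(k)), main = "relative CDF-area change")
  invisible(x)
}
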