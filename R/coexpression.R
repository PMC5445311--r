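## Tumour-specific weighted co-expression network. Genes are nodes; the
## adjacency is a soft-thresholded absolute Pearson correlation,
## a_ij = |cor(x_i, x_j)|^beta (an unsigned network). Clustering uses the
## topological overlap dissimilarity 1 - TOM, where the topological overlap
## combines the direct adjacency of a gene pair with the adjacency they share
## through common neighbours. Branches of the average-linkage dendrogram are
## modules; each module is summarised per sample by its eigengene (first
## principal component of the module's standardised expression submatrix).
## Module 0 collects the genes not assigned to any module.

#' Select the most variant genes
#'
#' Restricting the network to the top-variance genes concentrates it on genes
#' with biological signal across samples. Ties at the cut are broken by gene
#' label ascending; sample order is preserved.
#'
#' @param expr numeric matrix, genes x samples.
#' @param n number of genes to keep (at most `nrow(expr)`).
#' @return the reduced expression matrix.
#' @export
select_top_variant_genes <- function(expr, n = 5000) {
  if (n > nrow(expr)) stopf("n (%d) exceeds gene count (%d)", n, nrow(expr))
  v <- apply(expr, 1L, stats::var, na.rm = TRUE)
  vs <- sort(v, decreasing = TRUE)
  if (n < length(v) && vs[n] == vs[n + 1L])
    warnf("variance tie at the selection cut; breaking by gene label")
  ord <- order(-v, rownames(expr))
  expr[sort(ord[seq_len(n)]), , drop = FALSE]
}

#' Pick a soft-thresholding power by the scale-free topology criterion
#'
#' For each candidate power the network connectivity distribution is binned
#' and `log10 p(k)` regressed on `log10 k`; the smallest power whose model
#' fit R-squared reaches `r2_target` is chosen. If none qualifies the
#' conventional default 6 is returned with a warning.
#'
#' @param expr numeric matrix, genes x samples (at least 20 genes).
#' @param powers candidate integer powers.
#' @param r2_target scale-free fit target (default 0.8).
#' @param n_bins connectivity-histogram bins.
#' @return chosen integer power, with the per-power fits in attribute
#'   `"fit"`.
#' @export
pick_soft_power <- function(expr, powers = 1:20, r2_target = 0.8,
                            n_bins = 10) {
  if (nrow(expr) < 20L) stopf("need at least 20 genes")
  ac <- abs(stats::cor(t(expr), use = "pairwise.complete.obs"))
  diag(ac) <- 0
  r2 <- vapply(powers, function(b) {
    k <- rowSums(ac ^ b)
    if (max(k) <= 0) return(0)
    br <- cut(k, breaks = n_bins)
    pk <- tapply(k, br, length) / length(k)
    km <- tapply(k, br, mean)
    ok <- !is.na(pk) & pk > 0 & km > 0
    if (sum(ok) < 3L) return(0)
    stats::cor(log10(km[ok]), log10(pk[ok])) ^ 2
  }, numeric(1))
  fit <- data.frame(power = powers, r_squared = r2)
  hit <- which(r2 >= r2_target)
  if (length(hit) == 0L) {
    warnf("no candidate power reached scale-free R^2 >= %g; using 6", r2_target)
    beta <- 6L
  } else beta <- as.integer(powers[min(hit)])
  attr(beta, "fit") <- fit
  beta
}

#' Adjacency and topological-overlap dissimilarity
#'
#' Unsigned adjacency `a_ij = |cor(x_i, x_j)|^beta` (diagonal 0 for
#' connectivity purposes) and unsigned topological overlap
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivity `k_i = sum_u a_iu`; `TOM_ii = 1`. The returned dissimilarity
#' is `1 - TOM`. Correlations use pairwise-complete observations.
#'
#' @param expr numeric matrix, genes x samples; no constant gene rows.
#' @param beta soft-thresholding power (integer >= 1).
#' @return list with `adjacency`, `tom` and `dissimilarity` matrices.
#' @export
adjacency_and_tom <- function(expr, beta) {
  if (beta < 1) stopf("beta must be >= 1")
  v <- apply(expr, 1L, stats::var, na.rm = TRUE)
  if (any(v == 0 | is.na(v)))
    stopf("constant gene(s): %s",
          paste(rownames(expr)[v == 0 | is.na(v)], collapse = ", "))
  a <- abs(stats::cor(t(expr), use = "pairwise.complete.obs")) ^ beta
  a[is.na(a)] <- 0
  diag(a) <- 0
  tom <- tom_from_adjacency(a)
  list(adjacency = a, tom = tom, dissimilarity = 1 - tom)
}

## unsigned topological overlap of an adjacency matrix (diagonal 0)
tom_from_adjacency <- function(a) {
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2  # enforce exact symmetry against FP noise
  dimnames(tom) <- dimnames(a)
  tom
}

#' Cluster genes and cut the dendrogram into modules
#'
#' Average-linkage hierarchical clustering on the TOM dissimilarity with a
#' static branch cut: branches merging below `cut_height` (an absolute height
#' on the \[0, 1\] dissimilarity scale, the static-cut convention of
#' co-expression practice) form candidate clusters, a documented
#' simplification of adaptive branch cutting. Clusters of at least
#' `min_module_size` genes become modules 1..M, ordered by decreasing size;
#' all remaining genes — including unclustered noise genes, whose mutual
#' dissimilarities sit essentially at 1, above any sensible cut — go to
#' module 0.
#'
#' @param dissimilarity symmetric matrix from [adjacency_and_tom].
#' @param min_module_size minimum genes per module (default 30).
#' @param cut_height absolute dendrogram cut height (default 0.99).
#' @return list with `modules` (named integer vector, 0 = unassigned),
#'   `sizes` (named, modules 1..M) and the `hclust` tree.
#' @export
cluster_and_cut <- function(dissimilarity, min_module_size = 30,
                            cut_height = 0.99) {
  n <- nrow(dissimilarity)
  if (min_module_size > n)
    stopf("min_module_size (%d) exceeds gene count (%d)", min_module_size, n)
  d <- dissimilarity
  diag(d) <- 0
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  raw <- stats::cutree(tree, h = cut_height)
  sizes <- table(raw)
  big <- names(sizes)[sizes >= min_module_size]
  big <- big[order(-sizes[big], as.integer(big))]
  modules <- integer(n)
  for (m in seq_along(big)) modules[raw == as.integer(big[m])] <- m
  names(modules) <- rownames(dissimilarity)
  mod_sizes <- if (length(big)) table(modules[modules > 0]) else table(integer(0))
  list(modules = modules, sizes = mod_sizes, tree = tree)
}

#' Module eigengenes
#'
#' The eigengene of module q is the first principal component of the module's
#' standardised expression submatrix: one value per sample, unit norm, sign
#' oriented so it correlates non-negatively with the module's mean expression
#' profile. Module 0 gets no eigengene. The relationship between modules is
#' summarised by an average-linkage dendrogram on `1 - cor(eigengenes)`.
#'
#' @param expr numeric matrix, genes x samples.
#' @param modules named integer vector from [cluster_and_cut].
#' @return list with `eigengenes` (modules x samples matrix, rows
#'   `ME1..MEM`), `var_explained` (fraction per module), and `dendrogram`
#'   (an `hclust` over modules, `NULL` when fewer than 3 modules).
#' @export
module_eigengenes <- function(expr, modules) {
  ids <- sort(unique(modules[modules > 0]))
  if (length(ids) == 0L) stopf("no modules to summarise")
  E <- matrix(NA_real_, length(ids), ncol(expr),
              dimnames = list(paste0("ME", ids), colnames(expr)))
  ve <- numeric(length(ids))
  for (i in seq_along(ids)) {
    genes <- names(modules)[modules == ids[i]]
    if (length(genes) < 2L) stopf("module %d is a singleton", ids[i])
    X <- t(scale(t(expr[genes, , drop = FALSE])))  # standardise each gene
    p <- stats::prcomp(t(X), center = FALSE, scale. = FALSE)
    e <- p$x[, 1L]
    e <- e / sqrt(sum(e ^ 2))
    mmean <- colMeans(expr[genes, , drop = FALSE])
    if (stats::cor(e, mmean) < 0) e <- -e
    E[i, ] <- e
    ve[i] <- p$sdev[1L] ^ 2 / sum(p$sdev ^ 2)
  }
  names(ve) <- rownames(E)
  dend <- if (length(ids) >= 3L)
    stats::hclust(stats::as.dist(1 - stats::cor(t(E))), method = "average")
  else NULL
  list(eigengenes = E, var_explained = ve, dendrogram = dend)
}

#' Export the eigengene dendrogram as Newick
#'
#' @param eig result of [module_eigengenes] (needs at least 3 modules).
#' @param path output path.
#' @export
write_eigengene_newick <- function(eig, path) {
  if (is.null(eig$dendrogram)) stopf("eigengene dendrogram needs >= 3 modules")
  ape::write.tree(ape::as.phylo(eig$dendrogram), file = path)
  invisible(path)
}

#' Module membership
#'
#' `K(i, q) = |cor(x_i, E_q)|`: how closely gene i tracks module q's
#' eigengene, for every selected gene against every module.
#'
#' @param expr numeric matrix, genes x samples.
#' @param eig result of [module_eigengenes] (or an eigengene matrix).
#' @return genes x modules matrix of absolute correlations in \[0, 1\];
#'   zero-variance genes yield `NA` with a warning.
#' @export
module_membership <- function(expr, eig) {
  E <- if (is.list(eig)) eig$eigengenes else eig
  v <- apply(expr, 1L, stats::var, na.rm = TRUE)
  if (any(v == 0, na.rm = TRUE))
    warnf("zero-variance gene(s) get missing membership: %s",
          paste(rownames(expr)[which(v == 0)], collapse = ", "))
  K <- abs(suppressWarnings(
    stats::cor(t(expr), t(E), use = "pairwise.complete.obs")))
  dimnames(K) <- list(rownames(expr), rownames(E))
  K
}

#' Build a weighted co-expression network end to end
#'
#' Convenience wrapper: gene selection, soft power choice, TOM, tree cut,
#' eigengenes and membership in one call.
#'
#' @param expr numeric matrix, genes x samples.
#' @param top_n_genes number of most-variant genes to keep (capped at the
#'   gene count).
#' @param beta soft power, or `"auto"` for the scale-free criterion.
#' @param min_module_size,cut_height see [cluster_and_cut].
#' @param r2_target see [pick_soft_power].
#' @return object of class `coexpression_network`: the selected expression,
#'   `beta`, `modules`, `sizes`, `tree`, `eigengenes` (list from
#'   [module_eigengenes]) and `membership`.
#' @export
coexpression_network <- function(expr, top_n_genes = 5000, beta = "auto",
                                 min_module_size = 30,
                                 cut_height = 0.99,
                                 r2_target = 0.8) {
  sel <- select_top_variant_genes(expr, min(top_n_genes, nrow(expr)))
  if (identical(beta, "auto"))
    beta <- pick_soft_power(sel, r2_target = r2_target)
  at <- adjacency_and_tom(sel, beta)
  cut <- cluster_and_cut(at$dissimilarity, min_module_size, cut_height)
  eig <- if (any(cut$modules > 0)) module_eigengenes(sel, cut$modules)
  else NULL
  K <- if (!is.null(eig)) module_membership(sel, eig) else NULL
  structure(list(expr = sel, beta = as.integer(beta), modules = cut$modules,
                 sizes = cut$sizes, tree = cut$tree, eigengenes = eig,
                 membership = K),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  n_mod <- sum(unique(x$modules) > 0)
  cat(sprintf("Weighted co-expression network: %d genes x %d samples, beta = %d\n",
              nrow(x$expr), ncol(x$expr), x$beta))
  cat(sprintf("%d module(s); %d gene(s) unassigned (module 0)\n",
              n_mod, sum(x$modules == 0)))
  if (n_mod) print(x$sizes)
  invisible(x)
}

#' Plot the gene dendrogram of a co-expression network
#' @param x a `coexpression_network`.
#' @param ... passed to `plot.hclust`.
#' @export
plot.coexpression_network <- function(x, ...) {
  plot(x$tree, labels = FALSE, hang = -1,
       main = "gene dendrogram (1 - TOM, average linkage)",
       xlab = "", sub = "", ...)
  invisible(x)
}
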