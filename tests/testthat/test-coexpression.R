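# Weighted co-expression network construction.

test_that("top-variance gene selection honours order, identity and ties", {
  set.seed(2)
  base <- as.vector(scale(rnorm(20)))        # unit variance exactly
  expr <- outer(1:10, base)                  # row i has variance i^2
  rownames(expr) <- sprintf("g%02d", 1:10)
  colnames(expr) <- sprintf("s%02d", 1:20)
  sel <- select_top_variant_genes(expr, 3)
  expect_setequal(rownames(sel), c("g08", "g09", "g10"))
  expect_identical(colnames(sel), colnames(expr))
  expect_identical(select_top_variant_genes(expr, 10), expr)
  # exact tie at the cut: lexicographically smaller label wins
  tied <- rbind(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4), C = c(0, 0, 0, 1))
  expect_warning(s2 <- select_top_variant_genes(tied, 1), "tie")
  expect_equal(rownames(s2), "A")
  expect_error(select_top_variant_genes(tied, 5), "exceeds")
})

test_that("TOM matches hand-computed values and the triple-loop oracle", {
  # two perfectly correlated genes at beta 1: overlap 1, dissimilarity 0
  expr <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8))
  at <- adjacency_and_tom(expr, 1)
  expect_equal(at$tom[1, 2], 1)
  expect_equal(at$dissimilarity[1, 2], 0)

  # hand instance: a12 = a13 = 0.5, a23 = 0 -> TOM23 = (0.25+0)/(0.5+1-0)
  a <- matrix(c(0, .5, .5, .5, 0, 0, .5, 0, 0), 3)
  tom <- oncoprior:::tom_from_adjacency(a)
  expect_equal(tom[2, 3], 1 / 6)
  expect_equal(tom, oracle_tom(a), tolerance = 1e-14)

  # orthogonal genes: all off-diagonal overlap 0, dissimilarity 1
  orth <- rbind(g1 = c(1, 1, -1, -1), g2 = c(1, -1, 1, -1))
  at0 <- adjacency_and_tom(orth, 2)
  expect_equal(at0$tom[1, 2], 0)
  expect_equal(at0$dissimilarity[1, 2], 1)

  expect_error(adjacency_and_tom(rbind(g1 = rep(1, 4), g2 = 1:4), 2), "g1")
})

test_that("TOM equals the triple-loop oracle on random 20-gene instances", {
  set.seed(9)
  for (i in 1:5) {
    expr <- matrix(rnorm(20 * 30), 20,
                   dimnames = list(paste0("g", 1:20), paste0("s", 1:30)))
    at <- adjacency_and_tom(expr, sample(1:8, 1))
    expect_lt(max(abs(at$tom - oracle_tom(at$adjacency))), 1e-12)
    expect_true(all(at$adjacency >= 0 & at$adjacency <= 1))
    expect_true(all(at$tom >= 0 & at$tom <= 1))
    expect_identical(at$tom, t(at$tom))
    expect_true(all(at$dissimilarity >= 0 & at$dissimilarity <= 1))
  }
})

test_that("planted blocks are cut into modules; noise stays in module 0", {
  fx <- make_expression_fixture(n_genes = 100, module_sizes = c(50, 50),
                                n_samples = 80, seed = 33,
                                trait_effect = 0, surv_log_hr = 0)
  at <- adjacency_and_tom(fx$expr, 6)
  cut <- cluster_and_cut(at$dissimilarity, min_module_size = 30)
  expect_equal(sort(unique(cut$modules)), c(1L, 2L))
  expect_equal(ari(cut$modules, fx$truth$modules), 1)

  noise_all_grey <- 0
  for (s in 1:10) {
    set.seed(400 + s)
    noise <- matrix(rnorm(50 * 60), 50,
                    dimnames = list(paste0("g", 1:50), paste0("s", 1:60)))
    atn <- adjacency_and_tom(noise, 6)
    cn <- cluster_and_cut(atn$dissimilarity, min_module_size = 30)
    if (all(cn$modules == 0L)) noise_all_grey <- noise_all_grey + 1
  }
  expect_gte(noise_all_grey, 9)

  # degenerate cut: everything becomes one module
  one <- cluster_and_cut(at$dissimilarity, min_module_size = 1,
                         cut_height = 1.0)
  expect_equal(sort(unique(one$modules)), 1L)
  expect_error(cluster_and_cut(at$dissimilarity, min_module_size = 1000),
               "exceeds")
})

test_that("eigengenes summarise modules with fixed orientation and PC1 optimality", {
  # identical profiles: the eigengene is the profile itself (up to sign/scale)
  set.seed(12)
  base <- rnorm(40)
  expr <- matrix(rep(base, 5), 5, byrow = TRUE,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:40)))
  expr <- expr + matrix(rnorm(200, sd = 1e-6), 5)
  mods <- setNames(rep(1L, 5), rownames(expr))
  eig <- module_eigengenes(expr, mods)
  expect_equal(abs(cor(eig$eigengenes[1, ], base)), 1, tolerance = 1e-6)
  expect_equal(sum(eig$eigengenes[1, ]^2), 1)
  expect_gte(cor(eig$eigengenes[1, ], colMeans(expr)), 0)
  # orientation survives wholesale negation of the module
  eig_neg <- module_eigengenes(-expr, mods)
  expect_gte(cor(eig_neg$eigengenes[1, ], colMeans(-expr)), 0)

  # PC1 captures at least as much module variance as 100 random directions
  fx <- make_expression_fixture(seed = 8)
  at <- adjacency_and_tom(fx$expr, 6)
  cut <- cluster_and_cut(at$dissimilarity)
  e2 <- module_eigengenes(fx$expr, cut$modules)
  genes <- names(cut$modules)[cut$modules == 1L]
  X <- t(scale(t(fx$expr[genes, ])))       # genes x samples, standardised
  captured <- function(u) sum((X %*% u)^2)
  pc1 <- captured(e2$eigengenes["ME1", ])
  set.seed(3)
  for (i in 1:100) {
    u <- rnorm(ncol(X)); u <- u / sqrt(sum(u^2))
    expect_gte(pc1, captured(u))
  }
})

test_that("planted module structure is recovered with faithful membership", {
  fx <- make_expression_fixture(seed = 14)
  net <- suppressWarnings(coexpression_network(fx$expr, top_n_genes = 150,
                                               beta = 6))
  expect_equal(sum(unique(net$modules) > 0), 3L)
  expect_gte(ari(net$modules, fx$truth$modules[names(net$modules)]), 0.95)
  # the eigengene tracks the planted factor
  for (m in 1:3) {
    cors <- abs(cor(net$eigengenes$eigengenes[paste0("ME", m), ],
                    t(fx$truth$factors)))
    expect_gt(max(cors), 0.95)
  }
  # membership: gene equal to its eigengene has K = 1; orthogonality gives 0
  E <- net$eigengenes$eigengenes
  probe <- rbind(E, t(matrix(residuals(lm(rnorm(ncol(E)) ~ t(E))))))
  rownames(probe) <- c(rownames(E), "orth")
  K <- module_membership(probe, net$eigengenes)
  expect_equal(unname(diag(K[1:3, 1:3])), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(K["orth", ]), rep(0, 3), tolerance = 1e-10)
  # within-module membership exceeds cross-module membership on average
  Kfull <- net$membership
  within <- mean(sapply(1:3, function(m)
    mean(Kfull[net$modules == m, paste0("ME", m)])))
  cross <- mean(sapply(1:3, function(m)
    mean(Kfull[net$modules != m & net$modules > 0, paste0("ME", m)])))
  expect_gt(within, cross)
})

test_that("the intramodular hub tracks the eigengene at least as well as the median gene", {
  fx <- make_expression_fixture(seed = 25)
  net <- suppressWarnings(coexpression_network(fx$expr, top_n_genes = 150,
                                               beta = 6))
  at <- adjacency_and_tom(net$expr, net$beta)
  for (m in seq_len(sum(unique(net$modules) > 0))) {
    genes <- names(net$modules)[net$modules == m]
    k_in <- rowSums(at$adjacency[genes, genes])
    hub <- genes[which.max(k_in)]
    Km <- net$membership[genes, paste0("ME", m)]
    expect_gte(Km[hub], median(Km))
  }
})

test_that("soft-power selection follows the scale-free criterion with fallback", {
  # a hub-structured network: loadings with heavy-tailed spread give a broad
  # connectivity distribution that fits a power law acceptably
  set.seed(41)
  n <- 120; s <- 80
  load <- runif(n)^3
  expr <- sapply(1:s, function(j) load * rnorm(1) + rnorm(n, sd = 0.6))
  rownames(expr) <- paste0("g", 1:n)
  b <- pick_soft_power(expr, r2_target = 0.8)
  fit <- attr(b, "fit")
  expect_gte(fit$r_squared[fit$power == as.integer(b)], 0.8)
  expect_equal(as.integer(pick_soft_power(expr, r2_target = 0)), 1L)
  set.seed(42)
  noise <- matrix(rnorm(30 * 400), 30)
  rownames(noise) <- paste0("g", 1:30)
  expect_warning(b6 <- pick_soft_power(noise, r2_target = 0.999), "using 6")
  expect_equal(as.integer(b6), 6L)
  expect_error(pick_soft_power(noise[1:5, ]), "20 genes")
})

test_that("the eigengene dendrogram exports as Newick readable by ape", {
  fx <- make_expression_fixture(seed = 5)
  net <- suppressWarnings(coexpression_network(fx$expr, top_n_genes = 150,
                                               beta = 6))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_eigengene_newick(net$eigengenes, f)
  tree <- ape::read.tree(f)
  expect_setequal(tree$tip.label, paste0("ME", 1:3))
})
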