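# Gene/module significance measures against sample traits.

test_that("Welch gene significance reproduces hand and reference values", {
  # identical groups: t = 0, p = 1, gs = 0
  expr <- rbind(g1 = c(1, 2, 3, 1, 2, 3))
  out <- gs_dichotomous(expr, c(0, 0, 0, 1, 1, 1))
  expect_equal(out$p_value, 1)
  expect_equal(out$gs, 0)
  expect_equal(out$effect_size, 0)

  # hand instance: group0 = {1,2,3}, group1 = {4,5,6}
  expr <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
  out <- gs_dichotomous(expr, c(0, 0, 0, 1, 1, 1))
  expect_equal(out$effect_size, 3)
  expect_equal(out$p_value, t.test(4:6, 1:3)$p.value, tolerance = 1e-12)

  # the log identity: p = 0.01 -> gs = 2, to full precision
  expect_equal(oncoprior:::gs_from_p(0.01), 2, tolerance = 1e-12)
  expect_equal(oncoprior:::gs_from_p(0), 300)  # underflow floor

  expect_error(gs_dichotomous(expr, c(0, 1, 1, 1, 1, 1)), "at least 2")
})

test_that("Welch GS matches an independent textbook implementation", {
  set.seed(61)
  worst <- 0
  for (i in 1:250) {
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    expr <- matrix(rnorm(4 * (n1 + n0), sd = runif(1, 0.5, 3)), 4)
    trait <- sample(c(rep(1, n1), rep(0, n0)))
    out <- gs_dichotomous(expr, trait)
    for (g in 1:4) {
      ref <- oracle_welch(expr[g, trait == 1], expr[g, trait == 0])
      worst <- max(worst, abs(out$p_value[g] - ref))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("GS is a monotone transform of p and ignores sample order", {
  p <- sort(runif(20))
  expect_false(is.unsorted(rev(oncoprior:::gs_from_p(p))))
  set.seed(3)
  expr <- matrix(rnorm(5 * 30), 5, dimnames = list(paste0("g", 1:5), NULL))
  trait <- rep(c(0, 1), 15)
  perm <- sample(30)
  expect_equal(gs_dichotomous(expr, trait)$p_value,
               gs_dichotomous(expr[, perm], trait[perm])$p_value,
               tolerance = 1e-12)
})

test_that("Cox GS recovers null and planted survival effects", {
  set.seed(71)
  n <- 120
  x <- rnorm(n)
  # two-group covariate with no hazard difference: coefficient ~ 0
  grp <- rep(c(0, 1), n / 2)
  tm <- rexp(n); ev <- rbinom(n, 1, 0.8)
  out <- gs_survival(matrix(grp, 1), tm, ev)
  expect_lt(abs(out$coef), 0.5)
  expect_equal(out$effect_size, max(out$hazard_ratio, 1 / out$hazard_ratio))
  expect_gte(out$effect_size, 1)

  # grid maximisation of the partial likelihood agrees on small instances
  for (i in 1:5) {
    set.seed(80 + i)
    m <- 25
    xx <- rnorm(m)
    tt <- rexp(m, rate = exp(0.8 * xx))   # continuous times: no ties
    evi <- rbinom(m, 1, 0.85)
    if (sum(evi) < 2) evi[1:2] <- 1
    fit <- gs_survival(matrix(xx, 1), tt, evi)
    expect_lt(abs(fit$coef - oracle_cox_coef(tt, evi, xx)), 1e-3)
  }
  expect_error(gs_survival(matrix(x, 1), tm, rep(0, n)), "no events")
  expect_error(gs_survival(matrix(x, 1), -tm, ev), "negative")
})

test_that("a degenerate covariate is flagged missing rather than fitted", {
  set.seed(5)
  tm <- rexp(20); ev <- rep(1, 20)
  out <- gs_survival(matrix(rep(1, 20), 1), tm, ev)  # constant covariate
  expect_true(is.na(out$coef))
  expect_true(is.na(out$p_value))
})

test_that("module significance is the mean absolute GS with relabel invariance", {
  gs <- data.frame(gene = paste0("g", 1:6),
                   p_value = c(0.01, 0.01, 0.1, 0.001, 1, 0.01),
                   gs = c(2, 2, 1, 3, 0, 2),
                   effect_size = 1, measure = "m")
  mods <- setNames(c(1L, 1L, 2L, 2L, 0L, 0L), gs$gene)
  ms <- module_significance(gs, mods)
  expect_equal(ms$ms[ms$module == 1], 2)         # every gene at p 0.01
  expect_equal(ms$ms[ms$module == 2], 2)         # mean of {1, 3}
  # relabelling other modules leaves a module's ms unchanged
  mods2 <- setNames(c(1L, 1L, 7L, 7L, 0L, 0L), gs$gene)
  ms2 <- module_significance(gs, mods2)
  expect_equal(ms2$ms[ms2$module == 1], ms$ms[ms$module == 1])
  # missing gs drops from numerator and denominator
  gs$gs[4] <- NA
  ms3 <- module_significance(gs, mods)
  expect_equal(ms3$ms[ms3$module == 2], 1)
  expect_equal(ms3$n_genes[ms3$module == 2], 1)
})

test_that("the planted trait module attains the maximal module significance", {
  hits <- 0
  for (s in 1:10) {
    fx <- make_expression_fixture(seed = 100 + s, trait_effect = 1)
    net <- suppressWarnings(coexpression_network(fx$expr, top_n_genes = 150,
                                                 beta = 6))
    trait <- fx$traits$trait[match(colnames(net$expr), fx$traits$sample)]
    gs <- gs_dichotomous(net$expr, trait, measure = "trait")
    ms <- module_significance(gs, net$modules)
    ms <- ms[ms$module > 0, ]
    top_mod <- ms$module[which.max(ms$ms)]
    # identify which detected module carries the planted trait factor
    cors <- abs(cor(t(net$eigengenes$eigengenes),
                    fx$truth$factors[fx$truth$trait_module, ]))
    planted <- as.integer(sub("ME", "", rownames(net$eigengenes$eigengenes)[which.max(cors)]))
    if (top_mod == planted) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("module naming picks the most enriched small term with fallback", {
  mods <- setNames(rep(c(1L, 2L, 0L), times = c(50, 40, 60)),
                   sprintf("g%03d", 1:150))
  sets <- list(
    exact_match = names(mods)[1:50],                # identical to module 1
    too_big = names(mods)[1:110],                   # size >= 100: excluded
    partial = names(mods)[41:80])                   # overlaps module 2
  nm <- name_modules(mods, sets, max_term_size = 100)
  expect_equal(unname(nm["1"]), "exact_match")
  expect_false(any(nm == "too_big"))
  # a term of exactly the bound is excluded even if perfectly enriched
  sets2 <- list(at_bound = names(mods)[1:100])
  nm2 <- name_modules(mods, sets2, max_term_size = 100)
  expect_equal(unname(nm2["1"]), "module_1")

  # one random module against one random term: the raw hypergeometric test
  # rejects at most 5% of the time, so fallback names dominate across seeds
  fallback <- 0
  for (s in 1:100) {
    set.seed(200 + s)
    rmods <- setNames(rep(0L, 200), sprintf("r%03d", 1:200))
    rmods[sample(200, 40)] <- 1L
    rsets <- list(set1 = sample(names(rmods), 30))
    if (grepl("^module_", name_modules(rmods, rsets)[["1"]]))
      fallback <- fallback + 1
  }
  expect_gte(fallback, 95)
})

test_that("prioritised variants map to modules with per-measure flags", {
  fx <- make_expression_fixture(seed = 55)
  net <- suppressWarnings(coexpression_network(fx$expr, top_n_genes = 150,
                                               beta = 6))
  trait <- fx$traits$trait[match(colnames(net$expr), fx$traits$sample)]
  gs <- gs_dichotomous(net$expr, trait, measure = "trait")
  in_mod3 <- names(net$modules)[net$modules == 3L][1:5]
  top <- data.frame(gene = c(in_mod3, "ABSENT1"),
                    protein_change = "p.A1V", type = "SNP",
                    classification = "Missense_Mutation", score = 2,
                    cosmic_entity = "", patient_ids = "1")
  out <- variant_module_view(top, net, list(trait = gs),
                             module_names = c("3" = "immune_response"))
  absent <- out$view[out$view$gene == "ABSENT1", ]
  expect_equal(absent$module_name, "not in network")
  expect_false("ABSENT1" %in% names(out$module_counts))
  expect_equal(unname(out$module_counts["3"]), 5L)
  flagged <- out$view[out$view$gene %in% in_mod3, ]
  expect_equal(unique(flagged$module_name), "immune_response")
  expect_identical(flagged$significant, flagged$p_value < 0.05)
  expect_true(all(flagged$membership >= 0 & flagged$membership <= 1))
})
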