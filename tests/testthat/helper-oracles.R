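# Independent oracles used across the suite. Each is a literal, unoptimised
# transcription of the definition it checks, kept free of the package's own
# code paths.

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# literal transcription of the combination-score definition:
# c = sum_j y_j, y_j = mean rankscore of cluster j if that mean >= threshold
oracle_combination_score <- function(rankscores, clusters, threshold = 0.75) {
  c_val <- 0
  any_defined <- FALSE
  for (j in seq_along(clusters)) {
    vals <- c()
    for (a in clusters[[j]]) {
      v <- rankscores[[a]]
      if (!is.null(v) && !is.na(v)) vals <- c(vals, v)
    }
    if (length(vals) == 0) next
    any_defined <- TRUE
    xbar <- mean(vals)
    y <- if (xbar >= threshold) xbar else 0
    c_val <- c_val + y
  }
  if (!any_defined) NA_real_ else c_val
}

# row-wise brute-force transcription of the prioritisation predicate
oracle_keep_row <- function(row, cfg) {
  pc <- if (cfg$protein_changing_only) row$protein_changing else TRUE
  germ <- if (!cfg$exclude_1000g) TRUE
    else if (is.na(cfg$max_1000g_af)) !row$in_1000g
    else !row$in_1000g ||
      (!is.na(row$af_1000g) && row$af_1000g <= cfg$max_1000g_af)
  sp <- if (cfg$strict_cutoff) !is.na(row$score) && row$score > cfg$score_cutoff
    else !is.na(row$score) && row$score >= cfg$score_cutoff
  cosmic <- sum(oncoprior:::parse_cosmic(row$cosmic_counts)) > 0
  rescue <- (cfg$rescue_cosmic && cosmic) || (cfg$rescue_ddr && row$is_ddr_gene)
  pc && germ && (sp || rescue)
}

oracle_apply_filters <- function(tab, cfg) {
  vapply(seq_len(nrow(tab)), function(i) oracle_keep_row(tab[i, ], cfg),
         logical(1))
}

# triple-loop transcription of the unsigned topological overlap
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    s <- 0
    for (u in seq_len(n)) s <- s + a[i, u] * a[u, j]
    tom[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# textbook Welch t-test: statistic, Welch-Satterthwaite df, two-sided p
oracle_welch <- function(x1, x0) {
  m1 <- mean(x1); m0 <- mean(x0)
  v1 <- var(x1); v0 <- var(x0)
  n1 <- length(x1); n0 <- length(x0)
  se2 <- v1 / n1 + v0 / n0
  t <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  2 * pt(-abs(t), df)
}

# grid maximisation of the Cox partial log-likelihood (single covariate,
# no ties assumed in the fixture)
oracle_cox_coef <- function(time, event, x, grid = seq(-3, 3, by = 5e-4)) {
  logpl <- function(b) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    ll
  }
  vals <- vapply(grid, logpl, numeric(1))
  grid[which.max(vals)]
}

# two uncorrelated base profiles for copy-based clustering fixtures
make_uv_profiles <- function(n_variants, seed) {
  set.seed(seed)
  u <- rnorm(n_variants)
  v <- rnorm(n_variants)
  v <- residuals(lm(v ~ u))        # orthogonalise: cor(u, v) ~ 0
  list(u = pnorm(scale(u)[, 1]), v = pnorm(scale(v)[, 1]))
}
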