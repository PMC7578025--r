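# Independent oracles used to cross-check the package's own numerics.
# These deliberately share no code with the implementation paths they test.

# Dense grid search over the 4PL parameter box followed by quasi-Newton
# polishing of the best grid point (plain SSE, no IRLS, no analytic
# Jacobian) - an independent route to the least-squares optimum.
grid_fit_4pl <- function(x, y) {
  lo <- c(-0.5, -0.5, min(x) - 1, 0.1)
  hi <- c(0.5, 1.5, max(x) + 1, 10)
  grid <- expand.grid(b = seq(lo[1], hi[1], length.out = 5),
                      t = seq(lo[2], hi[2], length.out = 9),
                      a = seq(lo[3], hi[3], length.out = 13),
                      h = c(0.1, 0.25, 0.5, 1, 2, 4, 8, 10))
  sse <- function(p) {
    pred <- p[1] + (p[2] - p[1]) / (1 + 10^((p[3] - x) * p[4]))
    sum((y - pred)^2)
  }
  vals <- apply(as.matrix(grid), 1, sse)
  best <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(best, sse, method = "L-BFGS-B", lower = lo,
                      upper = hi, control = list(factr = 1e2))
  list(theta = opt$par, sse = opt$value)
}

# Brute-force ssGSEA: explicit per-position loops over the ranked list.
ssgsea_brute <- function(expr, sets, alpha = 0.25) {
  genes <- rownames(expr)
  n <- length(genes)
  out <- matrix(NA_real_, length(sets), ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    ord <- order(-expr[, j], genes)
    ranked <- genes[ord]
    for (s in seq_along(sets)) {
      members <- sets[[s]]
      in_set <- ranked %in% members
      denom_in <- 0
      for (i in seq_len(n)) if (in_set[i]) denom_in <- denom_in + (n - i + 1)^alpha
      denom_out <- n - sum(in_set)
      es <- 0; cum_in <- 0; cum_out <- 0
      for (i in seq_len(n)) {
        if (in_set[i]) cum_in <- cum_in + (n - i + 1)^alpha
        else cum_out <- cum_out + 1
        es <- es + cum_in / denom_in - cum_out / denom_out
      }
      out[s, j] <- es
    }
  }
  out
}

# Label-permutation p-value for the one-way ANOVA F statistic.
perm_anova_p <- function(values, groups, n_perm = 10000L, seed = 99L) {
  groups <- as.factor(groups)
  fstat <- function(v) {
    gm <- tapply(v, groups, mean); gn <- tapply(v, groups, length)
    ssb <- sum(gn * (gm - mean(v))^2)
    ssw <- sum((v - gm[groups])^2)
    (ssb / (nlevels(groups) - 1)) / (ssw / (length(v) - nlevels(groups)))
  }
  f0 <- fstat(values)
  set.seed(seed)
  hits <- sum(replicate(n_perm, fstat(sample(values))) >= f0)
  (1 + hits) / (1 + n_perm)
}

# small default-shaped synthetic world used by several test files
small_config <- function(seed = 1L, ...) {
  synth_config(n_drugs = 12L, n_genes = 400L, n_gene_sets = 8L,
               genes_per_set = 20L, seed = seed, ...)
}

# small random expression fixtures shared by pathway and acceptance tests
toy_expr <- function(n_g = 50, n_s = 4, seed = 1) {
  set.seed(seed)
  matrix(2^rnorm(n_g * n_s, 5, 2), n_g, n_s,
         dimnames = list(sprintf("g%03d", 1:n_g), paste0("s", 1:n_s)))
}

random_sets <- function(genes, n_sets = 20, seed = 2) {
  set.seed(seed)
  sets <- lapply(1:n_sets, function(i) sample(genes, sample(5:15, 1)))
  names(sets) <- paste0("S", 1:n_sets)
  sets
}
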