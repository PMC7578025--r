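# One-way ANOVA computed directly so that zero-variance edge cases are
# handled exactly: SSW = 0 with unequal means gives F = Inf, p = 0; a
# completely degenerate layout (SSW = SSB = 0) gives p = 1.
oneway_f <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups); n <- length(values)
  if (k < 2L) stop("need >= 2 groups")
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  grand <- mean(values)
  ssb <- sum(gn * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  df1 <- k - 1L; df2 <- n - k
  if (df2 < 1L) stop("need residual degrees of freedom (n > k)")
  if (ssw <= 1e-300) {
    if (ssb <= 1e-300) return(list(F = 0, p = 1, df1 = df1, df2 = df2))
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Sidak family-wise error correction
#'
#' `p_adj = 1 - (1 - p)^m` for `m` tests, computed stably; non-decreasing
#' in `m` and never below the unadjusted p.
#'
#' @param p unadjusted p-value(s) in [0, 1].
#' @param m family size (number of tests).
#' @return adjusted p-value(s).
#' @export
sidak_adjust <- function(p, m) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(1, -expm1(m * log1p(-p)))
}

#' Per-drug subtype-selectivity ANOVA
#'
#' For every drug, a one-way ANOVA of AUC across molecular subtypes, after
#' excluding named subtypes and any subtype with fewer than `min_n` models
#' (the default `min_n = 2` drops singleton classes such as IM and UNS in
#' the default cohort). Drugs are flagged significant at `p < alpha`.
#'
#' @param mat AUC matrix (models x drugs).
#' @param subtypes data.frame with `model_id`, `subtype`, or named vector.
#' @param exclude subtype labels to drop before testing
#'   (default `c("IM", "UNS")`).
#' @param alpha significance level (default 0.05).
#' @param min_n minimum models per retained subtype (default 2).
#' @return data.frame sorted by F (descending): `drug_id`, `groups`
#'   (comma-joined), `group_n`, `group_means`, `F`, `p`, `significant`.
#' @export
subtype_anova <- function(mat, subtypes, exclude = c("IM", "UNS"),
                          alpha = 0.05, min_n = 2L) {
  st <- if (is.data.frame(subtypes))
    setNames(subtypes$subtype, subtypes$model_id)
  else subtypes
  st <- st[intersect(rownames(mat), names(st))]
  st <- st[!(st %in% exclude)]
  tab <- table(st)
  keep_levels <- names(tab)[tab >= min_n]
  st <- st[st %in% keep_levels]
  if (length(keep_levels) < 2L)
    stop("design error: fewer than 2 retained subtype groups")
  models <- names(st)
  rows <- lapply(colnames(mat), function(d) {
    y <- mat[models, d]
    ok <- is.finite(y)
    res <- oneway_f(y[ok], st[ok])
    gm <- tapply(y[ok], st[ok], mean)
    data.frame(drug_id = d,
               groups = paste(keep_levels, collapse = ","),
               group_n = paste(tapply(y[ok], st[ok], length),
                               collapse = ","),
               group_means = paste(sprintf("%.4f", gm), collapse = ","),
               F = res$F, p = res$p, significant = res$p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$F), , drop = FALSE]
}

#' Pharmacogenomic association screen (drug AUC vs mutation status)
#'
#' For every drug, a two-group ANOVA (equivalently an F-test) of AUC by
#' carrier status for one gene, with Sidak correction over the family of
#' tests. The default family size is the number of drugs screened for the
#' gene, matching a drug-wise screen.
#'
#' @param mat AUC matrix (models x drugs).
#' @param mutations data.frame with `model_id` and one 0/1 column per gene.
#' @param gene gene name (a column of `mutations`).
#' @param family_size Sidak family size `m` (default: number of drugs).
#' @return data.frame sorted by p: `drug_id`, `gene`, `n_carrier`,
#'   `n_noncarrier`, `mean_carrier`, `mean_noncarrier`, `F`, `p`,
#'   `p_sidak`.
#' @export
mutation_association <- function(mat, mutations, gene,
                                 family_size = ncol(mat)) {
  if (!gene %in% names(mutations))
    stop("gene ", gene, " not in mutation table")
  mut <- setNames(mutations[[gene]], mutations$model_id)
  mut <- mut[intersect(rownames(mat), names(mut))]
  if (length(unique(mut)) < 2L)
    stop("single-class mutation vector for ", gene)
  if (min(table(mut)) < 2L)
    stop("need >= 2 models in each of carrier/non-carrier")
  models <- names(mut)
  rows <- lapply(colnames(mat), function(d) {
    y <- mat[models, d]
    ok <- is.finite(y)
    res <- oneway_f(y[ok], mut[ok])
    data.frame(drug_id = d, gene = gene,
               n_carrier = sum(mut[ok] == 1),
               n_noncarrier = sum(mut[ok] == 0),
               mean_carrier = mean(y[ok][mut[ok] == 1]),
               mean_noncarrier = mean(y[ok][mut[ok] == 0]),
               F = res$F, p = res$p,
               p_sidak = sidak_adjust(res$p, family_size),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p), , drop = FALSE]
}
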