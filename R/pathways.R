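#' Read a gene-set collection from GMT
#'
#' Standard tab-delimited GMT: one set per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @return named list of gene-id character vectors, with a `descriptions`
#'   attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("GMT ", path, ": line ", bad[1], " has fewer than 3 fields")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stop("GMT ", path, ": duplicate set names")
  attr(sets, "descriptions") <-
    setNames(vapply(parts, `[[`, "", 2L), names(sets))
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list of gene-id vectors.
#' @param path output path.
#' @param descriptions optional named character vector of descriptions
#'   (defaults to the set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions))
    descriptions <- attr(sets, "descriptions")
  if (is.null(descriptions))
    descriptions <- setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Single-sample GSEA pathway scores
#'
#' Per-sample, rank-weighted enrichment score for each gene set. For sample
#' `j`, genes are sorted by expression descending (ties broken by stable
#' gene-identifier order, with a warning if a sample is entirely tied);
#' the gene at sorted position `i` of `N` carries rank score
#' `r_i = N - i + 1`. The enrichment score is the sum over the ranked list
#' of the difference between the weighted in-set cumulative distribution
#' (weights `r_i^alpha`) and the uniform out-of-set cumulative
#' distribution:
#' \deqn{ES = \sum_k \left[ \frac{\sum_{i \le k, g_i \in S} r_i^\alpha}
#'   {\sum_{i \in S} r_i^\alpha} - \frac{\#\{i \le k, g_i \notin S\}}
#'   {N - |S|} \right]}
#' Raw scores are not rescaled by set size (downstream use z-normalizes
#' per pathway across samples anyway, so only relative values matter).
#'
#' @param expr non-negative expression matrix (genes x samples) with gene
#'   ids as rownames.
#' @param sets named list of gene-id vectors; sets are intersected with the
#'   matrix's genes, and empty intersections dropped with a notice.
#' @param alpha rank-weight exponent (default 0.25).
#' @return object of class `pdx_ssgsea`: `raw` (sets x samples matrix),
#'   `z` (row-wise z-normalized; rows with zero SD are set to 0), `row_sd`
#'   (per-set SD of raw scores), `alpha`.
#' @export
ssgsea_score <- function(expr, sets, alpha = 0.25) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (any(expr < 0)) stop("expression must be non-negative")
  genes <- rownames(expr)
  sets <- lapply(sets, intersect, genes)
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty)) {
    message("dropping gene sets with no genes in the matrix: ",
            paste(empty, collapse = ", "))
    sets <- sets[lengths(sets) > 0L]
  }
  if (!length(sets)) stop("no usable gene sets")
  if (any(lengths(sets) == length(genes)))
    stop("a gene set covers every gene; out-of-set CDF is undefined")
  n <- length(genes)
  raw <- matrix(NA_real_, length(sets), ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  member <- lapply(sets, function(s) genes %in% s)  # in input gene order
  pos_w <- (n - seq_len(n) + 1)^alpha              # rank score weights
  for (j in seq_len(ncol(expr))) {
    v <- expr[, j]
    if (diff(range(v)) == 0)
      warning("sample ", colnames(expr)[j],
              " has all-equal expression; ranking falls back to gene order")
    ord <- order(-v, genes)  # descending, stable gene-id tie-break
    for (s in seq_along(sets)) {
      ins <- member[[s]][ord]
      win <- pos_w * ins
      p_in <- cumsum(win) / sum(win)
      p_out <- cumsum(!ins) / (n - sum(ins))
      raw[s, j] <- sum(p_in - p_out)
    }
  }
  row_sd <- apply(raw, 1, stats::sd)
  z <- (raw - rowMeans(raw)) / ifelse(row_sd > 0, row_sd, 1)
  z[row_sd == 0, ] <- 0
  structure(list(raw = raw, z = z, row_sd = row_sd, alpha = alpha),
            class = "pdx_ssgsea")
}

#' @export
print.pdx_ssgsea <- function(x, ...) {
  cat(sprintf("<pdx_ssgsea> %d gene sets x %d samples (alpha = %g)\n",
              nrow(x$raw), ncol(x$raw), x$alpha))
  invisible(x)
}

#' Cross-sample consistency of a pathway's activity
#'
#' "Consistently active" means a high mean raw enrichment score with low
#' spread across samples. Returns the set's mean and SD of raw scores and
#' the rank of its mean among all scored sets (rank 1 = highest mean).
#'
#' @param scores a `pdx_ssgsea` from [ssgsea_score()] (>= 2 samples).
#' @param set_name the gene set to summarize.
#' @return list: `set`, `mean_raw`, `sd_raw`, `rank_of_mean`, `n_sets`.
#' @export
rank_consistency <- function(scores, set_name) {
  stopifnot(inherits(scores, "pdx_ssgsea"))
  if (ncol(scores$raw) < 2L) stop("need >= 2 samples")
  if (!set_name %in% rownames(scores$raw))
    stop("unknown gene set: ", set_name)
  means <- rowMeans(scores$raw)
  rk <- rank(-means, ties.method = "min")
  list(set = set_name, mean_raw = unname(means[set_name]),
       sd_raw = unname(scores$row_sd[set_name]),
       rank_of_mean = unname(rk[set_name]), n_sets = nrow(scores$raw))
}

# two-sided p for a Pearson correlation via the exact t transform
pearson_p <- function(r, n) {
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), n - 2)
}

#' Correlation screen between one drug's AUC and molecular features
#'
#' Pearson correlation (with its exact two-sided t-distribution p-value)
#' between a drug's per-model AUC and every feature row: ssGSEA pathway
#' scores, or single-gene expression (pass `transform = "log2p1"` for raw
#' TPM). A feature passes the screen when `p < alpha` and `|r| >= r_min`
#' (defaults: 0.05 and 0.70). Zero-variance features are reported with `NA`
#' correlation and a note rather than propagating NaN.
#'
#' @param auc_column named numeric vector: one drug's AUC per model.
#' @param features numeric matrix, features x models (a `pdx_ssgsea`'s
#'   `raw`/`z`, or an expression matrix).
#' @param r_min minimum absolute Pearson r to pass (default 0.70).
#' @param alpha significance level (default 0.05).
#' @param transform "none" or "log2p1" (applied to `features` first).
#' @return data.frame sorted by |r|: `feature`, `n`, `pearson_r`, `p`,
#'   `passes`, `note`.
#' @export
correlate_drug_features <- function(auc_column, features, r_min = 0.70,
                                    alpha = 0.05,
                                    transform = c("none", "log2p1")) {
  transform <- match.arg(transform)
  if (inherits(features, "pdx_ssgsea")) features <- features$raw
  stopifnot(is.matrix(features), !is.null(names(auc_column)))
  common <- intersect(names(auc_column), colnames(features))
  if (length(common) < 3L) stop("need >= 3 paired observations")
  y <- auc_column[common]
  x <- features[, common, drop = FALSE]
  if (transform == "log2p1") x <- log2(x + 1)
  if (stats::sd(y) == 0) stop("AUC vector has zero variance")
  rows <- lapply(rownames(x), function(f) {
    v <- x[f, ]
    ok <- is.finite(v) & is.finite(y)
    n <- sum(ok)
    if (n < 3L || stats::sd(v[ok]) == 0) {
      return(data.frame(feature = f, n = n, pearson_r = NA_real_,
                        p = NA_real_, passes = FALSE,
                        note = if (n < 3L) "too few observations"
                        else "zero-variance feature",
                        stringsAsFactors = FALSE))
    }
    r <- stats::cor(v[ok], y[ok])
    p <- if (abs(r) >= 1) 0 else pearson_p(r, n)
    data.frame(feature = f, n = n, pearson_r = r, p = p,
               passes = p < alpha && abs(r) >= r_min, note = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-abs(out$pearson_r)), , drop = FALSE]
}
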