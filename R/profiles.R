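#' Assemble a models-by-drugs AUC matrix from fit records
#'
#' @param fits data.frame with columns `model_id`, `drug_id`, `auc` (the
#'   output of [fit_screen()]). Exact duplicates are deduplicated;
#'   conflicting duplicates (same pair, different AUC) are an error.
#' @return numeric matrix (rows = models, columns = drugs) with `NA` for
#'   pairs absent from `fits`; values outside [0, 1] are rejected.
#' @export
assemble_matrix <- function(fits) {
  req <- c("model_id", "drug_id", "auc")
  if (!all(req %in% names(fits)) || nrow(fits) < 1L)
    stop("fits must be a non-empty data.frame with model_id, drug_id, auc")
  key <- paste(fits$model_id, fits$drug_id, sep = "\r")
  if (anyDuplicated(key)) {
    spread <- tapply(fits$auc, key, function(v) diff(range(v)))
    if (any(spread > 1e-9))
      stop("conflicting duplicate fits for ",
           sub("\r", " / ", names(spread)[spread > 1e-9][1]))
    fits <- fits[!duplicated(key), ]
  }
  if (any(fits$auc < -1e-9 | fits$auc > 1 + 1e-9, na.rm = TRUE))
    stop("auc values must lie in [0, 1]")
  models <- unique(fits$model_id); drugs <- unique(fits$drug_id)
  m <- matrix(NA_real_, length(models), length(drugs),
              dimnames = list(models, drugs))
  m[cbind(match(fits$model_id, models), match(fits$drug_id, drugs))] <-
    pmin(pmax(fits$auc, 0), 1)
  m
}

#' Bidirectional hierarchical clustering of an AUC matrix
#'
#' Clusters both models (rows) and drugs (columns) by Euclidean distance
#' with Ward linkage ("ward.D2"). The drug tree is cut at `k_drugs`
#' clusters which are named by increasing mean AUC; at the default
#' `k_drugs = 3` the classes are `inactive`, `selective`, `pan_active`
#' (inactive = minimal activity anywhere, pan-active = broad activity,
#' selective = large model-to-model differences in between). The model tree
#' is cut at `k_models` for subtype-enrichment testing.
#'
#' Drugs missing in more than `max_missing` of models are dropped before
#' clustering (then models still carrying missing values), and the drops
#' are reported in the result.
#'
#' @param mat AUC matrix from [assemble_matrix()].
#' @param k_drugs number of drug clusters (default 3).
#' @param k_models number of model clusters (default 3).
#' @param max_missing column missingness fraction above which a drug is
#'   dropped (default 0.2).
#' @return object of class `pdx_biclust`: `drug_class` (data.frame drug_id
#'   / cluster / class), `model_cluster` (data.frame model_id / cluster),
#'   `hc_drugs`, `hc_models` (hclust trees), `dropped` (list), `params`.
#' @export
bicluster <- function(mat, k_drugs = 3L, k_models = 3L, max_missing = 0.2) {
  stopifnot(is.matrix(mat))
  if (k_drugs > ncol(mat)) stop("k_drugs exceeds number of drugs")
  if (k_models > nrow(mat)) stop("k_models exceeds number of models")
  col_miss <- colMeans(is.na(mat))
  drop_drugs <- colnames(mat)[col_miss > max_missing]
  m <- mat[, col_miss <= max_missing, drop = FALSE]
  row_miss <- rowSums(is.na(m)) > 0
  drop_models <- rownames(m)[row_miss]
  m <- m[!row_miss, , drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < k_drugs)
    stop("too few complete rows/columns to cluster")
  hc_models <- stats::hclust(stats::dist(m), method = "ward.D2")
  hc_drugs <- stats::hclust(stats::dist(t(m)), method = "ward.D2")
  drug_cut <- stats::cutree(hc_drugs, k = k_drugs)
  cl_mean <- tapply(colMeans(m)[names(drug_cut)], drug_cut, mean)
  ord <- order(cl_mean)  # ascending mean AUC
  class_names <- if (k_drugs == 3L) c("inactive", "selective", "pan_active")
  else sprintf("class_%d", seq_len(k_drugs))
  class_of <- setNames(class_names, ord)  # cluster id -> ordered name
  drug_class <- data.frame(drug_id = names(drug_cut),
                           cluster = unname(drug_cut),
                           class = unname(class_of[as.character(drug_cut)]),
                           stringsAsFactors = FALSE)
  model_cut <- stats::cutree(hc_models, k = k_models)
  model_cluster <- data.frame(model_id = names(model_cut),
                              cluster = unname(model_cut),
                              stringsAsFactors = FALSE)
  structure(list(drug_class = drug_class, model_cluster = model_cluster,
                 hc_drugs = hc_drugs, hc_models = hc_models,
                 dropped = list(drugs = drop_drugs, models = drop_models),
                 params = list(k_drugs = k_drugs, k_models = k_models,
                               max_missing = max_missing,
                               distance = "euclidean",
                               linkage = "ward.D2")),
            class = "pdx_biclust")
}

#' @export
print.pdx_biclust <- function(x, ...) {
  tab <- table(x$drug_class$class)
  cat(sprintf("<pdx_biclust> %d models in %d clusters | %d drugs: %s\n",
              nrow(x$model_cluster),
              length(unique(x$model_cluster$cluster)),
              nrow(x$drug_class),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Export bicluster dendrograms as newick trees
#'
#' @param bic a `pdx_biclust`.
#' @param dir output directory; writes `drugs.nwk` and `models.nwk`.
#' @return `dir`, invisibly.
#' @export
write_dendrograms <- function(bic, dir) {
  stopifnot(inherits(bic, "pdx_biclust"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(ape::as.phylo(bic$hc_drugs), file.path(dir, "drugs.nwk"))
  ape::write.tree(ape::as.phylo(bic$hc_models), file.path(dir, "models.nwk"))
  invisible(dir)
}

#' Chi-squared enrichment of molecular subtypes in model clusters
#'
#' Tests association between pharmacologic model clusters and molecular
#' subtype labels on the cluster x subtype contingency table (Pearson
#' chi-squared, no continuity correction). Named orphan clusters can be
#' excluded before testing.
#'
#' @param model_clusters data.frame with `model_id`, `cluster` (from
#'   [bicluster()]), or a named vector of cluster ids.
#' @param subtype_labels data.frame with `model_id`, `subtype`, or a named
#'   vector.
#' @param exclude_clusters cluster ids to drop (orphans), or `NULL`.
#' @return list: `statistic`, `df`, `p`, `table`.
#' @export
cluster_subtype_enrichment <- function(model_clusters, subtype_labels,
                                       exclude_clusters = NULL) {
  cl <- if (is.data.frame(model_clusters))
    setNames(model_clusters$cluster, model_clusters$model_id)
  else model_clusters
  st <- if (is.data.frame(subtype_labels))
    setNames(subtype_labels$subtype, subtype_labels$model_id)
  else subtype_labels
  common <- intersect(names(cl), names(st))
  cl <- cl[common]; st <- st[common]
  keep <- !(cl %in% exclude_clusters)
  cl <- cl[keep]; st <- st[keep]
  tab <- table(cluster = cl, subtype = st)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("degenerate table: need >= 2 clusters and >= 2 subtype levels")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}

#' Mechanism-of-action coherence of drug response profiles
#'
#' For each mechanism class with at least two drugs, the mean pairwise
#' Pearson correlation of the drugs' AUC columns, compared against a
#' permutation null in which class labels are shuffled across drugs.
#' Singleton classes are skipped with a notice.
#'
#' @param mat AUC matrix (models x drugs).
#' @param annotations data.frame with `drug_id`, `moa_class`, or a named
#'   vector mapping drug id to class.
#' @param n_perm number of label permutations for the null (default 1000).
#' @param seed RNG seed for the permutations.
#' @return data.frame: `moa_class`, `n_drugs`, `mean_r`, `null_q95`,
#'   `perm_p` (fraction of permuted class means >= observed).
#' @export
moa_coherence <- function(mat, annotations, n_perm = 1000L, seed = 1L) {
  ann <- if (is.data.frame(annotations))
    setNames(annotations$moa_class, annotations$drug_id)
  else annotations
  drugs <- intersect(colnames(mat), names(ann))
  ann <- ann[drugs]
  cors <- stats::cor(mat[, drugs, drop = FALSE],
                     use = "pairwise.complete.obs")
  class_mean_r <- function(labels) {
    vapply(split(names(labels), labels), function(ids) {
      if (length(ids) < 2L) return(NA_real_)
      cc <- cors[ids, ids]
      mean(cc[upper.tri(cc)])
    }, numeric(1))
  }
  obs <- class_mean_r(ann)
  singletons <- names(obs)[is.na(obs)]
  if (length(singletons))
    message("skipping singleton MoA classes: ",
            paste(singletons, collapse = ", "))
  obs <- obs[!is.na(obs)]
  if (!length(obs)) return(data.frame())
  set.seed(seed)
  null_mat <- matrix(NA_real_, n_perm, length(obs),
                     dimnames = list(NULL, names(obs)))
  for (b in seq_len(n_perm)) {
    perm <- setNames(sample(unname(ann)), names(ann))
    null_mat[b, ] <- class_mean_r(perm)[names(obs)]
  }
  data.frame(moa_class = names(obs),
             n_drugs = as.integer(table(ann)[names(obs)]),
             mean_r = unname(obs),
             null_q95 = apply(null_mat, 2, stats::quantile, 0.95,
                              na.rm = TRUE),
             perm_p = vapply(names(obs), function(k) {
               (1 + sum(null_mat[, k] >= obs[k], na.rm = TRUE)) /
                 (1 + sum(is.finite(null_mat[, k])))
             }, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Patient vs PDX transcriptome concordance
#'
#' Selects the `n_top` genes of highest variance across all samples on the
#' log2(TPM+1) scale and returns the Pearson correlation of every patient
#' sample against every PDX sample on those genes, flagging matched pairs
#' (same model id).
#'
#' @param expr non-negative expression matrix (genes x samples, TPM).
#' @param groups data.frame with `sample_id`, `group` ("patient" or "pdx"),
#'   `model_id` (links a PDX to its donor patient).
#' @param n_top number of most-variant transcripts to use (default 1000,
#'   capped at the gene count).
#' @return list: `r` (patients x PDX correlation matrix), `matched`
#'   (logical matrix of the same shape), `genes` (selected gene ids).
#' @export
patient_pdx_concordance <- function(expr, groups, n_top = 1000L) {
  stopifnot(all(c("sample_id", "group", "model_id") %in% names(groups)))
  if (n_top > nrow(expr)) n_top <- nrow(expr)
  pats <- groups$sample_id[groups$group == "patient"]
  pdxs <- groups$sample_id[groups$group == "pdx"]
  if (length(pats) < 2L || length(pdxs) < 2L)
    stop("need >= 2 samples per group")
  le <- log2(expr[, c(pats, pdxs), drop = FALSE] + 1)
  v <- apply(le, 1, stats::var)
  sel <- order(v, decreasing = TRUE)[seq_len(n_top)]
  if (all(v[sel] == 0)) stop("selected gene set has zero variance")
  r <- stats::cor(le[sel, pats, drop = FALSE], le[sel, pdxs, drop = FALSE])
  mid <- setNames(groups$model_id, groups$sample_id)
  matched <- outer(mid[pats], mid[pdxs], "==")
  dimnames(matched) <- dimnames(r)
  list(r = r, matched = matched, genes = rownames(le)[sel])
}
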