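test_that("assemble_matrix builds, masks, dedups and rejects conflicts", {
  fits <- data.frame(model_id = rep(c("m1", "m2"), each = 2),
                     drug_id = rep(c("d1", "d2"), 2),
                     auc = c(0.1, 0.9, 0.2, 0.8))
  m <- assemble_matrix(fits)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["m2", "d2"], 0.8)
  # missing pair stays masked
  m2 <- assemble_matrix(fits[-4, ])
  expect_true(is.na(m2["m2", "d2"]))
  # duplicate with equal auc is accepted
  expect_silent(assemble_matrix(rbind(fits, fits[1, ])))
  # conflicting duplicate errors
  bad <- rbind(fits, data.frame(model_id = "m1", drug_id = "d1", auc = 0.5))
  expect_error(assemble_matrix(bad), "conflicting duplicate")
  expect_error(assemble_matrix(transform(fits, auc = auc + 2)), "\\[0, 1\\]")
})

test_that("bicluster names classes by mean AUC and is permutation invariant", {
  set.seed(5)
  n_m <- 10
  mk <- function(level, k) matrix(level + rnorm(n_m * k, 0, 0.02), n_m, k)
  mat <- cbind(mk(0.05, 4), mk(0.5, 4), mk(0.92, 4))
  mat <- pmin(pmax(mat, 0), 1)
  dimnames(mat) <- list(paste0("m", 1:n_m), paste0("d", 1:12))
  bic <- bicluster(mat)
  cls <- setNames(bic$drug_class$class, bic$drug_class$drug_id)
  expect_true(all(cls[paste0("d", 1:4)] == "inactive"))
  expect_true(all(cls[paste0("d", 5:8)] == "selective"))
  expect_true(all(cls[paste0("d", 9:12)] == "pan_active"))
  # permuting rows and columns leaves the partition unchanged
  perm <- mat[sample(n_m), sample(12)]
  bic2 <- bicluster(perm)
  cls2 <- setNames(bic2$drug_class$class, bic2$drug_class$drug_id)
  expect_identical(cls2[names(cls)], cls)
  expect_error(bicluster(mat, k_drugs = 50), "k_drugs")
})

test_that("bicluster drops high-missingness drugs then incomplete models", {
  set.seed(6)
  mat <- matrix(runif(80), 8, 10,
                dimnames = list(paste0("m", 1:8), paste0("d", 1:10)))
  mat[1:4, "d1"] <- NA      # 50% missing -> dropped drug
  mat["m8", "d5"] <- NA     # residual missing -> dropped model
  bic <- bicluster(mat, k_drugs = 2)
  expect_equal(bic$dropped$drugs, "d1")
  expect_equal(bic$dropped$models, "m8")
  expect_false("d1" %in% bic$drug_class$drug_id)
})

test_that("newick dendrograms are written for both axes", {
  set.seed(7)
  mat <- matrix(runif(48), 6, 8,
                dimnames = list(paste0("m", 1:6), paste0("d", 1:8)))
  bic <- bicluster(mat, k_drugs = 2, k_models = 2)
  d <- withr::local_tempdir()
  write_dendrograms(bic, d)
  tr <- ape::read.tree(file.path(d, "models.nwk"))
  expect_setequal(tr$tip.label, paste0("m", 1:6))
})

test_that("cluster-subtype enrichment: chi-squared value, orphans, errors", {
  # perfectly associated 2x2 table (10,0;0,10): X^2 = 20 uncorrected
  cl <- rep(1:2, each = 10)
  st <- rep(c("A", "B"), each = 10)
  names(cl) <- names(st) <- paste0("m", 1:20)
  res <- cluster_subtype_enrichment(cl, st)
  expect_equal(res$statistic, 20)
  expect_lt(res$p, 1e-4)
  # excluding an orphan cluster drops its row
  cl2 <- c(cl, m21 = 3)
  st2 <- c(st, m21 = "A")
  res2 <- cluster_subtype_enrichment(cl2, st2, exclude_clusters = 3)
  expect_equal(res2$statistic, 20)
  expect_error(cluster_subtype_enrichment(cl[1:10], st[1:10]),
               "degenerate")
})

test_that("enrichment p-values are uniform under independent labels", {
  set.seed(42)
  ps <- replicate(500, {
    cl <- sample(1:3, 120, replace = TRUE)
    st <- sample(c("A", "B", "C", "D"), 120, replace = TRUE)
    names(cl) <- names(st) <- paste0("m", seq_along(cl))
    cluster_subtype_enrichment(cl, st)$p
  })
  d <- suppressWarnings(stats::ks.test(ps, "punif"))$statistic
  expect_lt(d, 0.1)
})

test_that("moa_coherence scores shared-mechanism classes against a null", {
  set.seed(8)
  base <- runif(12)
  mat <- cbind(dupA = base, dupB = base,
               matrix(runif(12 * 6), 12, 6,
                      dimnames = list(NULL, paste0("r", 1:6))))
  rownames(mat) <- paste0("m", 1:12)
  ann <- setNames(c("DUP", "DUP", rep("RAND", 6)), colnames(mat))
  res <- suppressMessages(moa_coherence(mat, ann, n_perm = 200))
  expect_equal(res$mean_r[res$moa_class == "DUP"], 1)
  expect_lt(abs(res$mean_r[res$moa_class == "RAND"]), 0.35)
  # planted shared-profile trio from the generator beats the null
  cfg <- small_config()
  scr <- generate_screen(cfg)
  mat2 <- assemble_matrix(fit_screen(normalize_plates(scr$plates)))
  res2 <- suppressMessages(
    moa_coherence(mat2, scr$truth$drug_meta[, c("drug_id", "moa_class")],
                  n_perm = 500))
  row <- res2[res2$moa_class == "TUBULIN_LIKE", ]
  expect_gt(row$mean_r, row$null_q95)
})

test_that("patient-PDX concordance flags matched pairs and honors n_top", {
  set.seed(9)
  n_g <- 60
  pat <- matrix(2^rnorm(n_g * 4, 5, 2), n_g, 4)
  rownames(pat) <- paste0("g", 1:n_g)
  colnames(pat) <- paste0("PT_", 1:4)
  pdx <- pat  # exact copies
  colnames(pdx) <- paste0("PDX_", 1:4)
  expr <- cbind(pat, pdx)
  groups <- data.frame(sample_id = colnames(expr),
                       group = rep(c("patient", "pdx"), each = 4),
                       model_id = rep(paste0("M", 1:4), 2))
  cc <- patient_pdx_concordance(expr, groups, n_top = 50)
  expect_equal(unname(diag(cc$r)), rep(1, 4))
  expect_true(all(diag(cc$matched)))
  expect_false(any(cc$matched[upper.tri(cc$matched)]))
  # n_top = all genes equals plain correlation of full log2 profiles
  cc2 <- patient_pdx_concordance(expr, groups, n_top = n_g)
  direct <- cor(log2(pat + 1), log2(pdx + 1))
  expect_equal(unname(cc2$r), unname(direct), tolerance = 1e-12)
})

test_that("shared module structure makes matched pairs most concordant", {
  set.seed(10)
  n_g <- 200; n_pair <- 5
  module <- matrix(rnorm(n_g * n_pair, 0, 2), n_g, n_pair)
  pat <- 6 + module + matrix(rnorm(n_g * n_pair, 0, 1), n_g, n_pair)
  pdx <- 6 + module + matrix(rnorm(n_g * n_pair, 0, 1), n_g, n_pair)
  expr <- 2^cbind(pat, pdx)
  rownames(expr) <- paste0("g", 1:n_g)
  colnames(expr) <- c(paste0("PT_", 1:n_pair), paste0("PDX_", 1:n_pair))
  groups <- data.frame(sample_id = colnames(expr),
                       group = rep(c("patient", "pdx"), each = n_pair),
                       model_id = rep(paste0("M", 1:n_pair), 2))
  cc <- patient_pdx_concordance(expr, groups, n_top = 150)
  expect_gt(mean(diag(cc$r)), mean(cc$r[!cc$matched]))
})
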