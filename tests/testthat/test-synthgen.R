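test_that("config invariants are enforced", {
  expect_error(synth_config(doses_uM = c(0.1, 1, 10)), "descending")
  expect_error(synth_config(doses_uM = c(10, 1, -1)), "positive")
  expect_error(synth_config(cv_vehicle = 1.2), "cv_vehicle")
  expect_error(synth_config(poscon_kill_fraction = 0), "poscon_kill")
  expect_error(synth_config(n_replicates = 5L), "3 or 4")
  expect_error(synth_config(n_models = 10L), "sum to n_models")
  expect_error(synth_config(n_gene_sets = 100L, genes_per_set = 100L),
               "config error")
  expect_error(synth_config(planted_mutation_drug_pair =
                              list(gene = "TP53", drug = "DRUG_999",
                                   shift = 0.3)),
               "planted drug ids")
})

test_that("control wells that overfill a plate raise a capacity error", {
  cfg <- small_config()
  cfg$dmso_wells_per_plate <- 200L
  cfg$poscon_wells_per_plate <- 200L
  expect_error(generate_screen(cfg), "capacity error")
})

test_that("same config and seed give byte-identical plate tables", {
  cfg <- small_config(seed = 42L)
  s1 <- generate_screen(cfg)
  s2 <- generate_screen(cfg)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_plates(s1$plates, p1)
  write_plates(s2$plates, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(s1$truth$params, s2$truth$params)
})

test_that("every emitted drug-model pair has exactly one truth record", {
  cfg <- small_config()
  scr <- generate_screen(cfg)
  norm <- normalize_plates(scr$plates)
  seen <- unique(paste(norm$model_id, norm$drug_id))
  truth_keys <- paste(scr$truth$params$model_id, scr$truth$params$drug_id)
  expect_setequal(seen, truth_keys)
  expect_false(anyDuplicated(truth_keys) > 0)
})

test_that("complete-kill positive control gives ~0 RLU wells", {
  cfg <- small_config()
  cfg$poscon_kill_fraction <- 1.0
  scr <- generate_screen(cfg)
  pos <- unlist(lapply(scr$plates,
                       function(p) p$wells$rlu[p$wells$role == "POSCON"]))
  expect_true(all(pos == 0))
})

test_that("truth parameters reproduce noise-free well means", {
  cfg <- small_config()
  cfg$cv_vehicle <- 1e-9
  cfg$cv_poscon <- 1e-9
  cfg$replicate_log10_potency_sd <- 0
  scr <- generate_screen(cfg)
  tr <- scr$truth$params
  key <- paste(tr$model_id, tr$drug_id)
  for (p in scr$plates[c(1, 5)]) {
    w <- p$wells[p$wells$role == "DRUG", ]
    i <- match(paste(w$model_id, w$drug_id), key)
    fa_true <- fa_4pl(log10(w$dose_uM), tr$bottom[i], tr$top[i],
                      tr$log10_ac50[i], tr$hill[i])
    expect_equal(w$rlu,
                 cfg$luminescence_mean_vehicle * (1 - fa_true),
                 tolerance = 1e-6)
  }
  # an inactive curve (top = bottom = 0) leaves wells at the vehicle mean
  flat <- tr[tr$top < 1e-12, ]
  if (nrow(flat) == 0) succeed() else {
    norm <- normalize_plates(scr$plates)
    fa <- norm$FA[paste(norm$model_id, norm$drug_id) %in%
                    paste(flat$model_id, flat$drug_id)]
    expect_lt(max(abs(fa)), 1e-6)
  }
})

test_that("default labels mirror the 16-model cohort census", {
  labs <- generate_labels(synth_config())
  expect_equal(nrow(labs$subtypes), 16L)
  expect_equal(as.vector(table(labs$subtypes$subtype)[c("BL1", "BL2", "IM",
                                                        "LAR", "M", "UNS")]),
               c(2L, 4L, 1L, 4L, 4L, 1L))
  expect_true(all(labs$mutations$TP53 %in% 0:1))
  expect_equal(labs$mutations$model_id, labs$subtypes$model_id)
})

test_that("planted mutation-drug pair shifts true AUC by exactly its effect", {
  cfg <- small_config()
  truth <- generate_screen(cfg)$truth
  pm <- cfg$planted_mutation_drug_pair
  carriers <- truth$mutations$model_id[truth$mutations[[pm$gene]] == 1]
  tr <- truth$params[truth$params$drug_id == pm$drug, ]
  expect_equal(mean(tr$true_auc[tr$model_id %in% carriers]) -
                 mean(tr$true_auc[!tr$model_id %in% carriers]),
               pm$shift, tolerance = 1e-9)
})

test_that("planted selective drug raises true AUC in its target subtype", {
  cfg <- small_config()
  truth <- generate_screen(cfg)$truth
  sel <- cfg$planted_selective_drugs[[1]]
  tgt <- truth$subtypes$model_id[truth$subtypes$subtype == sel$subtype]
  tr <- truth$params[truth$params$drug_id == sel$drug, ]
  expect_equal(mean(tr$true_auc[tr$model_id %in% tgt]) -
                 mean(tr$true_auc[!tr$model_id %in% tgt]),
               sel$effect, tolerance = 1e-9)
})

test_that("expression generator is deterministic and GMT round-trips", {
  cfg <- small_config()
  truth <- generate_screen(cfg)$truth
  e1 <- generate_expression(cfg, truth)
  e2 <- generate_expression(cfg, truth)
  expect_identical(e1$expr, e2$expr)
  expect_true(all(e1$expr >= 0))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(e1$gene_sets, path, e1$set_descriptions)
  back <- read_gmt(path)
  expect_identical(lapply(back, identity)[names(e1$gene_sets)],
                   e1$gene_sets)
})

test_that("planted pathway-drug pair realizes its target correlation", {
  # target r applies to the latent construction; the realized ssGSEA score
  # correlation with the drug's true AUC must land within +/- 0.15
  cfg <- small_config()
  truth <- generate_screen(cfg)$truth
  ex <- generate_expression(cfg, truth)
  sc <- ssgsea_score(ex$expr, ex$gene_sets)
  pp <- cfg$planted_pathway_drug_pairs[[1]]
  ta <- truth$params$true_auc[truth$params$drug_id == pp$drug]
  names(ta) <- truth$params$model_id[truth$params$drug_id == pp$drug]
  r <- cor(sc$raw[pp$set, ], ta[colnames(sc$raw)])
  expect_lt(abs(r - pp$r), 0.15)
})

test_that("a planted r = 0 pair stays decorrelated across seeds", {
  hits <- 0L
  for (s in 1:25) {
    cfg <- synth_config(n_drugs = 8L, n_genes = 300L, n_gene_sets = 6L,
                        genes_per_set = 20L,
                        planted_selective_drugs = list(),
                        planted_mutation_drug_pair = NULL,
                        planted_pathway_drug_pairs = list(
                          list(set = "PW_PLANTED_CORR", drug = "DRUG_003",
                               r = 0)),
                        seed = s)
    truth <- pdxscreen:::build_truth(cfg)
    ex <- generate_expression(cfg, truth)
    sc <- ssgsea_score(ex$expr, ex$gene_sets)
    ta <- truth$params$true_auc[truth$params$drug_id == "DRUG_003"]
    names(ta) <- truth$params$model_id[truth$params$drug_id == "DRUG_003"]
    if (abs(cor(sc$raw["PW_PLANTED_CORR", ], ta[colnames(sc$raw)])) < 0.3)
      hits <- hits + 1L
  }
  expect_gte(hits, 21L)  # ~95% expected rate, 25 seeds
})
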