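#' Configuration for the synthetic PDTC screen generator
#'
#' Describes the simulated world: 16 PDX models screened on 384-well plates
#' against a drug library at three doses (10.0, 1.0, 0.1 uM) in 3-4
#' technical replicates, with on-plate DMSO vehicle wells and anisomycin
#' positive-control wells; a genes-by-models TPM-like expression matrix
#' with gene-set structure; binary mutation labels; and TNBC molecular
#' subtype labels. Ground truth (per drug-model 4PL parameters and every
#' planted association) is emitted alongside the data so downstream
#' recovery can be scored.
#'
#' Default control-well parameters (vehicle mean 10,000 RLU at 5% CV;
#' positive control 95% kill at 10% CV) give an expected plate Z-prime of
#' about 0.83; the default replicate potency jitter of 0.05 log10 units
#' gives an analytic expected MSR of `10^(2 sqrt(2) 0.05) ~ 1.38`. The
#' default subtype census mirrors a 16-model TNBC cohort: 2 BL1, 4 BL2,
#' 1 IM, 4 LAR, 4 M, 1 UNS.
#'
#' @param n_models number of PDX models (must equal `sum(subtype_counts)`).
#' @param n_drugs number of drugs in the simulated library (>= 7 with the
#'   default planted associations; the full-study library is much larger,
#'   but library size does not enter the per-plate / per-drug QC
#'   statistics, so a desk-scale default is used).
#' @param doses_uM dose ladder in uM, strictly positive, sorted descending.
#' @param n_replicates technical replicates per drug-dose (3 or 4).
#' @param dmso_wells_per_plate,poscon_wells_per_plate control wells placed
#'   on every plate.
#' @param luminescence_mean_vehicle mean vehicle-well luminescence (RLU).
#' @param cv_vehicle,cv_poscon coefficient of variation of vehicle and
#'   positive-control wells (fractions in (0,1)).
#' @param poscon_kill_fraction fraction of signal killed by the positive
#'   control, in (0, 1].
#' @param replicate_log10_potency_sd per-replicate jitter (SD, log10 units)
#'   of the true AC50, the planted source of replicate-to-replicate potency
#'   scatter that MSR measures.
#' @param n_genes,n_gene_sets,genes_per_set expression-matrix dimensions;
#'   gene sets are disjoint blocks.
#' @param subtype_counts named integer vector of models per TNBC subtype.
#' @param planted_selective_drugs list of `list(drug=, subtype=, effect=)`:
#'   each drug's true AUC is raised by `effect` (AUC units) in models of
#'   the named subtype.
#' @param planted_pathway_drug_pairs list of `list(set=, drug=, r=)`: the
#'   named gene set's member genes are driven by a latent variable with
#'   exact sample correlation `r` to the drug's true AUC across models.
#' @param planted_mutation_drug_pair `list(gene=, drug=, shift=)`: carrier
#'   models' true AUC for the drug exceeds non-carriers' by exactly
#'   `shift`. `NULL` for no planted pharmacogenomic effect.
#' @param seed integer RNG seed; every generator output is a deterministic
#'   function of (config, seed).
#' @return object of class `pdx_synth_config` (validated list).
#' @export
synth_config <- function(n_models = 16L,
                         n_drugs = 60L,
                         doses_uM = c(10.0, 1.0, 0.1),
                         n_replicates = 3L,
                         dmso_wells_per_plate = 16L,
                         poscon_wells_per_plate = 16L,
                         luminescence_mean_vehicle = 10000,
                         cv_vehicle = 0.05,
                         cv_poscon = 0.10,
                         poscon_kill_fraction = 0.95,
                         replicate_log10_potency_sd = 0.05,
                         n_genes = 1200L,
                         n_gene_sets = 20L,
                         genes_per_set = 25L,
                         subtype_counts = c(BL1 = 2L, BL2 = 4L, IM = 1L,
                                            LAR = 4L, M = 4L, UNS = 1L),
                         planted_selective_drugs = list(
                           list(drug = "DRUG_004", subtype = "M",
                                effect = 0.4)),
                         planted_pathway_drug_pairs = list(
                           list(set = "PW_PLANTED_CORR", drug = "DRUG_003",
                                r = 0.8)),
                         planted_mutation_drug_pair = list(
                           gene = "TP53", drug = "DRUG_002", shift = 0.3),
                         seed = 1L) {
  cfg <- list(n_models = as.integer(n_models), n_drugs = as.integer(n_drugs),
              doses_uM = as.numeric(doses_uM),
              n_replicates = as.integer(n_replicates),
              dmso_wells_per_plate = as.integer(dmso_wells_per_plate),
              poscon_wells_per_plate = as.integer(poscon_wells_per_plate),
              luminescence_mean_vehicle = luminescence_mean_vehicle,
              cv_vehicle = cv_vehicle, cv_poscon = cv_poscon,
              poscon_kill_fraction = poscon_kill_fraction,
              replicate_log10_potency_sd = replicate_log10_potency_sd,
              n_genes = as.integer(n_genes),
              n_gene_sets = as.integer(n_gene_sets),
              genes_per_set = as.integer(genes_per_set),
              subtype_counts = subtype_counts,
              planted_selective_drugs = planted_selective_drugs,
              planted_pathway_drug_pairs = planted_pathway_drug_pairs,
              planted_mutation_drug_pair = planted_mutation_drug_pair,
              seed = as.integer(seed))
  if (any(cfg$doses_uM <= 0)) stop("doses must be strictly positive")
  if (is.unsorted(rev(cfg$doses_uM), strictly = TRUE))
    stop("doses must be sorted descending")
  if (length(cfg$doses_uM) < 3L) stop("need >= 3 doses")
  if (!(cfg$cv_vehicle > 0 && cfg$cv_vehicle < 1))
    stop("cv_vehicle must be in (0,1)")
  if (!(cfg$cv_poscon > 0 && cfg$cv_poscon < 1))
    stop("cv_poscon must be in (0,1)")
  if (!(cfg$poscon_kill_fraction > 0 && cfg$poscon_kill_fraction <= 1))
    stop("poscon_kill_fraction must be in (0,1]")
  counts <- c(cfg$n_models, cfg$n_drugs, cfg$n_replicates,
              cfg$dmso_wells_per_plate, cfg$poscon_wells_per_plate,
              cfg$n_genes, cfg$n_gene_sets, cfg$genes_per_set)
  if (any(counts < 1L)) stop("all counts must be >= 1")
  if (!cfg$n_replicates %in% c(3L, 4L))
    stop("n_replicates must be 3 or 4")
  if (sum(cfg$subtype_counts) != cfg$n_models)
    stop("subtype_counts must sum to n_models")
  if (cfg$n_gene_sets * cfg$genes_per_set > cfg$n_genes)
    stop("config error: gene sets larger than n_genes")
  drug_ids <- sprintf("DRUG_%03d", seq_len(cfg$n_drugs))
  planted_drugs <- c(
    vapply(cfg$planted_selective_drugs, `[[`, "", "drug"),
    vapply(cfg$planted_pathway_drug_pairs, `[[`, "", "drug"),
    if (!is.null(cfg$planted_mutation_drug_pair))
      cfg$planted_mutation_drug_pair$drug)
  if (!all(planted_drugs %in% drug_ids))
    stop("planted drug ids must be among ", drug_ids[1], "..",
         drug_ids[cfg$n_drugs])
  if (length(cfg$planted_pathway_drug_pairs) > cfg$n_gene_sets - 1L)
    stop("too many planted pathway pairs for n_gene_sets")
  structure(cfg, class = "pdx_synth_config")
}

# Planted ground truth: subtype and mutation labels plus per drug-model 4PL
# parameters. All draws come from a stream seeded with config$seed, so
# generate_labels() and generate_screen() agree on the same world.
build_truth <- function(config) {
  stopifnot(inherits(config, "pdx_synth_config"))
  set.seed(config$seed)
  n_m <- config$n_models
  model_ids <- sprintf("PDX_%02d", seq_len(n_m))
  drug_ids <- sprintf("DRUG_%03d", seq_len(config$n_drugs))
  dose_range <- range(config$doses_uM)
  subtype <- rep(names(config$subtype_counts), config$subtype_counts)
  subtypes <- data.frame(model_id = model_ids, subtype = subtype,
                         stringsAsFactors = FALSE)

  # mutation labels: planted gene at ~ TP53-like prevalence, plus null genes
  mut <- data.frame(model_id = model_ids, stringsAsFactors = FALSE)
  pm <- config$planted_mutation_drug_pair
  if (!is.null(pm)) {
    carriers <- sample(model_ids, round(0.47 * n_m))
    mut[[pm$gene]] <- as.integer(model_ids %in% carriers)
  }
  for (g in c("NULLGENE_1", "NULLGENE_2", "NULLGENE_3"))
    mut[[g]] <- stats::rbinom(n_m, 1L, 0.3)

  # drug parameter table: one row per (drug, model)
  sel_ids <- vapply(config$planted_selective_drugs, `[[`, "", "drug")
  pw_ids <- vapply(config$planted_pathway_drug_pairs, `[[`, "", "drug")
  mut_id <- if (is.null(pm)) character(0) else pm$drug
  reserved <- unique(c("DRUG_001", mut_id, pw_ids, sel_ids))
  moa_trio <- setdiff(drug_ids, reserved)
  moa_trio <- utils::head(moa_trio, 3L)
  shared_top <- stats::runif(n_m, 0.2, 0.9)  # profile shared by the trio

  param_rows <- vector("list", config$n_drugs)
  archetype <- character(config$n_drugs)
  moa_class <- character(config$n_drugs)
  names(archetype) <- names(moa_class) <- drug_ids
  for (i in seq_len(config$n_drugs)) {
    d <- drug_ids[i]
    if (d == "DRUG_001") {
      # pan-active anchor (anthracycline-like): near-complete kill, potent
      bottom <- 0; top <- rep(1, n_m); a <- -1; h <- 2
      archetype[d] <- "pan_anchor"; moa_class[d] <- "ANTHRACYCLINE_LIKE"
    } else if (length(mut_id) && d == mut_id) {
      a <- -1; h <- 2; bottom <- 0
      a1 <- auc_4pl_exact(0, 1, a, h, dose_range)
      base_auc <- 0.3
      if (base_auc + pm$shift > a1)
        stop("planted mutation shift too large for the dose window")
      top <- ifelse(mut[[pm$gene]] == 1L,
                    (base_auc + pm$shift) / a1, base_auc / a1)
      archetype[d] <- "mutation_planted"; moa_class[d] <- "PLANTED_PGX"
    } else if (d %in% pw_ids) {
      a <- -0.5; h <- 1.5; bottom <- 0
      top <- stats::runif(n_m, 0.3, 0.9)  # spread so a correlate can exist
      archetype[d] <- "pathway_planted"; moa_class[d] <- "PLANTED_PWCOR"
    } else if (d %in% sel_ids) {
      sel <- config$planted_selective_drugs[[match(d, sel_ids)]]
      a <- -0.5; h <- 2; bottom <- 0
      a1 <- auc_4pl_exact(0, 1, a, h, dose_range)
      base_auc <- 0.25
      if (base_auc + sel$effect > a1)
        stop("planted selective effect too large for the dose window")
      top <- ifelse(subtypes$subtype == sel$subtype,
                    (base_auc + sel$effect) / a1, base_auc / a1)
      archetype[d] <- "selective_planted"; moa_class[d] <- "PLANTED_SEL"
    } else if (d %in% moa_trio) {
      a <- stats::runif(1, -0.8, 0.2); h <- stats::runif(1, 1, 3)
      bottom <- 0
      top <- pmin(pmax(shared_top + stats::rnorm(n_m, 0, 0.03), 0), 1)
      archetype[d] <- "moa_shared"; moa_class[d] <- "TUBULIN_LIKE"
    } else {
      kind <- sample(c("inactive", "moderate", "pan"), 1L,
                     prob = c(0.40, 0.35, 0.25))
      a <- stats::runif(1, -1, 0.5); h <- stats::runif(1, 0.8, 3)
      bottom <- 0
      base <- switch(kind,
                     inactive = stats::runif(1, 0, 0.15),
                     moderate = stats::runif(1, 0.3, 0.7),
                     pan = stats::runif(1, 0.85, 1))
      top <- pmin(pmax(base + stats::rnorm(n_m, 0, 0.05), 0), 1)
      archetype[d] <- kind
      moa_class[d] <- paste0("MOA_", toupper(kind), "_", i)
    }
    param_rows[[i]] <- data.frame(
      drug_id = d, model_id = model_ids, bottom = bottom, top = top,
      log10_ac50 = a, hill = h, stringsAsFactors = FALSE)
  }
  params <- do.call(rbind, param_rows)
  params$true_auc <- auc_4pl_exact(params$bottom, params$top,
                                   params$log10_ac50, params$hill,
                                   dose_range)
  drug_meta <- data.frame(drug_id = drug_ids,
                          archetype = unname(archetype),
                          moa_class = unname(moa_class),
                          stringsAsFactors = FALSE)
  structure(list(params = params, subtypes = subtypes, mutations = mut,
                 drug_meta = drug_meta,
                 planted = list(
                   selective = config$planted_selective_drugs,
                   pathway = config$planted_pathway_drug_pairs,
                   mutation = config$planted_mutation_drug_pair),
                 config = config, seed = config$seed),
            class = "pdx_synth_truth")
}

#' Generate subtype and mutation label tables
#'
#' Subtype counts follow the config census (default: 2 BL1, 4 BL2, 1 IM,
#' 4 LAR, 4 M, 1 UNS over 16 models). The mutation table is binary with the
#' planted mutation-drug pair realized as an exact true-AUC shift in
#' carrier models (see [generate_screen()]), plus independent null genes.
#'
#' @param config a [synth_config()].
#' @return list with `subtypes` (model_id, subtype) and `mutations`
#'   (model_id plus one 0/1 column per gene).
#' @export
generate_labels <- function(config) {
  truth <- build_truth(config)
  list(subtypes = truth$subtypes, mutations = truth$mutations)
}

#' Generate synthetic screening plates with planted ground truth
#'
#' Emits one screen per model: every drug at every dose in `n_replicates`
#' technical replicates, distributed across as many 384-well plates as
#' needed, each plate carrying its own DMSO vehicle and anisomycin-like
#' positive-control wells. Raw luminescence of a drug well is
#' `vehicle_mean * (1 - FA_true(dose)) * lognormal noise`, with `FA_true`
#' from the planted 4PL for that drug-model pair; each technical replicate
#' perturbs the true log10 AC50 by `N(0, replicate_log10_potency_sd)` (all
#' doses of one replicate share the perturbation), giving MSR a known
#' analytic expectation. Positive-control wells kill
#' `poscon_kill_fraction` of the vehicle signal. Multiplicative log-normal
#' noise is mean-one at the stated CV. Deterministic given (config, seed).
#'
#' @param config a [synth_config()].
#' @return list with `plates` (list of [plate()] objects) and `truth`
#'   (`pdx_synth_truth`: per drug-model 4PL parameters and exact AUC,
#'   labels, planted associations, drug metadata).
#' @export
generate_screen <- function(config) {
  truth <- build_truth(config)  # seeds the stream; noise draws continue it
  n_dose <- length(config$doses_uM)
  capacity <- 384L - config$dmso_wells_per_plate -
    config$poscon_wells_per_plate
  if (capacity < 1L)
    stop("capacity error: control wells fill or exceed the 384-well plate")
  wells_per_model <- config$n_drugs * n_dose * config$n_replicates
  n_plates <- ceiling(wells_per_model / capacity)
  if (wells_per_model + n_plates * (384L - capacity) > 384L * n_plates)
    stop("capacity error: wells needed exceed plate capacity")

  sv <- sqrt(log(1 + config$cv_vehicle^2))
  sp <- sqrt(log(1 + config$cv_poscon^2))
  lv <- config$luminescence_mean_vehicle
  all_wells <- valid_wells_384()
  model_ids <- unique(truth$params$model_id)
  drug_ids <- sprintf("DRUG_%03d", seq_len(config$n_drugs))

  plates <- list()
  for (m in model_ids) {
    pm <- truth$params[truth$params$model_id == m, ]
    rownames(pm) <- pm$drug_id
    # long table of drug wells for this screen: drug x replicate x dose
    dw <- expand.grid(dose_uM = config$doses_uM,
                      replicate = seq_len(config$n_replicates),
                      drug_id = drug_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    dw <- dw[, c("drug_id", "dose_uM", "replicate")]
    # one AC50 jitter per (drug, replicate), shared across its doses
    jit <- matrix(stats::rnorm(config$n_drugs * config$n_replicates,
                               0, config$replicate_log10_potency_sd),
                  nrow = config$n_drugs,
                  dimnames = list(drug_ids, NULL))
    p <- pm[dw$drug_id, ]
    a_rep <- p$log10_ac50 +
      jit[cbind(match(dw$drug_id, drug_ids), dw$replicate)]
    fa_true <- fa_4pl(log10(dw$dose_uM), p$bottom, p$top, a_rep, p$hill)
    dw$rlu <- lv * (1 - fa_true) *
      exp(stats::rnorm(nrow(dw), -sv^2 / 2, sv))
    # distribute across plates, each with its own control wells
    for (k in seq_len(n_plates)) {
      idx <- seq.int((k - 1L) * capacity + 1L, min(k * capacity, nrow(dw)))
      block <- dw[idx, , drop = FALSE]
      n_ctrl_d <- config$dmso_wells_per_plate
      n_ctrl_p <- config$poscon_wells_per_plate
      n_used <- n_ctrl_d + n_ctrl_p + nrow(block)
      w <- data.frame(
        well = all_wells[seq_len(384L)],
        role = c(rep("DMSO", n_ctrl_d), rep("POSCON", n_ctrl_p),
                 rep("DRUG", nrow(block)), rep("EMPTY", 384L - n_used)),
        drug_id = c(rep(NA_character_, n_ctrl_d + n_ctrl_p),
                    block$drug_id, rep(NA_character_, 384L - n_used)),
        dose_uM = c(rep(NA_real_, n_ctrl_d + n_ctrl_p), block$dose_uM,
                    rep(NA_real_, 384L - n_used)),
        replicate = c(rep(NA_integer_, n_ctrl_d + n_ctrl_p),
                      block$replicate, rep(NA_integer_, 384L - n_used)),
        rlu = c(lv * exp(stats::rnorm(n_ctrl_d, -sv^2 / 2, sv)),
                lv * (1 - config$poscon_kill_fraction) *
                  exp(stats::rnorm(n_ctrl_p, -sp^2 / 2, sp)),
                block$rlu, rep(0, 384L - n_used)),
        model_id = m, stringsAsFactors = FALSE)
      plates[[length(plates) + 1L]] <-
        plate(sprintf("%s_P%02d", m, k), w)
    }
  }
  list(plates = plates, truth = truth)
}

#' Generate a synthetic expression matrix and gene-set collection
#'
#' Builds a non-negative TPM-like genes-by-models matrix with disjoint
#' gene-set blocks. The first set (`PW_ALWAYS_ACTIVE`) has a strongly
#' elevated baseline in every model, emulating a constitutively active
#' pathway. For each planted (gene set, drug, r) pair, the member genes are
#' driven by a latent variable constructed to have an exact sample Pearson
#' correlation `r` with the drug's true AUC across models, so the realized
#' ssGSEA score tracks the drug's sensitivity profile (attenuated only by
#' the rank transform). Remaining sets are null blocks.
#'
#' @param config a [synth_config()].
#' @param truth the `pdx_synth_truth` from [generate_screen()] (or
#'   [build_truth] via [generate_labels()]); supplies the true AUC profiles
#'   planted correlations refer to.
#' @return list with `expr` (matrix, genes x models), `gene_sets` (named
#'   list of gene-id vectors), `set_descriptions` (named character).
#' @export
generate_expression <- function(config, truth) {
  stopifnot(inherits(config, "pdx_synth_config"),
            inherits(truth, "pdx_synth_truth"))
  set.seed(as.integer((as.numeric(config$seed) + 104729) %% 2147483647))
  n_g <- config$n_genes; n_m <- config$n_models
  model_ids <- unique(truth$params$model_id)
  gene_ids <- sprintf("GENE_%04d", seq_len(n_g))
  size <- config$genes_per_set
  set_names <- c("PW_ALWAYS_ACTIVE",
                 vapply(config$planted_pathway_drug_pairs, `[[`, "", "set"))
  set_names <- c(set_names,
                 sprintf("PW_NULL_%02d",
                         seq_len(config$n_gene_sets - length(set_names))))
  gene_sets <- lapply(seq_len(config$n_gene_sets), function(j) {
    gene_ids[seq.int((j - 1L) * size + 1L, j * size)]
  })
  names(gene_sets) <- set_names

  mu <- stats::rnorm(n_g, 4, 1.5)
  names(mu) <- gene_ids
  mu[gene_sets[["PW_ALWAYS_ACTIVE"]]] <- 9 + stats::rnorm(size, 0, 0.25)
  log2e <- matrix(mu, nrow = n_g, ncol = n_m) +
    matrix(stats::rnorm(n_g * n_m, 0, 0.3), n_g, n_m)
  dimnames(log2e) <- list(gene_ids, model_ids)

  for (pp in config$planted_pathway_drug_pairs) {
    a_vec <- truth$params$true_auc[truth$params$drug_id == pp$drug]
    names(a_vec) <- truth$params$model_id[truth$params$drug_id == pp$drug]
    a_vec <- a_vec[model_ids]
    if (stats::sd(a_vec) == 0)
      stop("planted pathway drug ", pp$drug, " has constant true AUC")
    z <- exact_cor_vector(a_vec, pp$r)
    members <- gene_sets[[pp$set]]
    mu_m <- stats::rnorm(length(members), 5, 0.5)
    log2e[members, ] <- matrix(mu_m, length(members), n_m) +
      2 * matrix(z, length(members), n_m, byrow = TRUE) +
      matrix(stats::rnorm(length(members) * n_m, 0, 0.3),
             length(members), n_m)
  }
  desc <- setNames(paste0("synthetic gene set (", set_names, ")"),
                   set_names)
  list(expr = 2^log2e, gene_sets = gene_sets, set_descriptions = desc)
}

# latent vector with EXACT sample correlation r to target (Gram-Schmidt)
exact_cor_vector <- function(target, r) {
  stopifnot(abs(r) <= 1, length(target) >= 3)
  t_std <- as.numeric(scale(target))
  if (abs(r) == 1) return(sign(r) * t_std)
  e <- stats::rnorm(length(target))
  e_perp <- stats::residuals(stats::lm(e ~ t_std))
  e_std <- as.numeric(scale(e_perp))
  r * t_std + sqrt(1 - r^2) * e_std
}

#' @export
print.pdx_synth_truth <- function(x, ...) {
  cat(sprintf(paste0("<pdx_synth_truth> %d models x %d drugs | seed %d | ",
                     "planted: %d selective, %d pathway, %s mutation\n"),
              length(unique(x$params$model_id)),
              length(unique(x$params$drug_id)), x$seed,
              length(x$planted$selective), length(x$planted$pathway),
              if (is.null(x$planted$mutation)) "no" else "1"))
  invisible(x)
}
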