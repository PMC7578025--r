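#' @importFrom stats median sd mad pf pt cor cutree dist hclust qnorm rnorm runif setNames var
#' @importFrom utils read.csv write.csv read.delim write.table
NULL

WELL_ROLES <- c("DMSO", "POSCON", "DRUG", "EMPTY")

valid_wells_384 <- function() {
  paste0(rep(LETTERS[1:16], each = 24), sprintf("%02d", 1:24))
}

#' Construct a 384-well plate object
#'
#' @param barcode plate barcode string.
#' @param wells data.frame with columns `well` (e.g. "A01".."P24"), `role`
#'   (one of DMSO, POSCON, DRUG, EMPTY), `drug_id`, `dose_uM`, `replicate`,
#'   `rlu` (raw luminescence, >= 0), optionally `model_id`.
#' @return object of class `pdx_plate`.
#' @export
plate <- function(barcode, wells) {
  stopifnot(is.character(barcode), length(barcode) == 1L)
  req <- c("well", "role", "drug_id", "dose_uM", "replicate", "rlu")
  miss <- setdiff(req, names(wells))
  if (length(miss))
    stop("plate ", barcode, ": missing columns ", paste(miss, collapse = ", "))
  bad_well <- setdiff(wells$well, valid_wells_384())
  if (length(bad_well))
    stop("plate ", barcode, ": format error, well coordinates out of range: ",
         paste(utils::head(bad_well, 5), collapse = ", "))
  if (anyDuplicated(wells$well))
    stop("plate ", barcode, ": format error, duplicate well ",
         wells$well[duplicated(wells$well)][1])
  bad_role <- setdiff(unique(wells$role), WELL_ROLES)
  if (length(bad_role))
    stop("plate ", barcode, ": format error, unknown role ", bad_role[1])
  if (any(!is.finite(wells$rlu) | wells$rlu < 0))
    stop("plate ", barcode, ": format error, negative or non-finite RLU")
  if (!any(wells$role == "DMSO"))
    stop("QC-fatal: plate ", barcode, " has no DMSO wells")
  structure(list(barcode = barcode, wells = wells), class = "pdx_plate")
}

#' @export
print.pdx_plate <- function(x, ...) {
  tab <- table(x$wells$role)
  cat(sprintf("<pdx_plate> %s: %d wells (%s)\n", x$barcode, nrow(x$wells),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Read screening plates from CSV
#'
#' The plate CSV dialect has columns `plate_barcode, well, role, drug_id,
#' dose_uM, replicate, rlu` and optionally `model_id`. One file may carry
#' any number of plates. Malformed rows are reported with their line
#' numbers; structural violations (duplicate wells, out-of-range well
#' coordinates, negative RLU, plates without DMSO wells) are errors.
#'
#' @param path path to the CSV file.
#' @return list of [plate()] objects, one per barcode, in file order.
#' @export
read_plates <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("plate_barcode", "well", "role", "drug_id", "dose_uM",
           "replicate", "rlu")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("plate CSV ", path, ": missing columns ",
         paste(miss, collapse = ", "))
  bad <- which(is.na(df$rlu) | !is.numeric(df$rlu) | df$rlu < 0 |
                 !(df$role %in% WELL_ROLES) |
                 !(df$well %in% valid_wells_384()))
  if (length(bad))
    stop("plate CSV ", path, ": malformed rows at lines ",
         paste(utils::head(bad + 1L, 10), collapse = ", "),
         " (header = line 1)")
  if (!"model_id" %in% names(df)) df$model_id <- NA_character_
  barcodes <- unique(df$plate_barcode)
  lapply(barcodes, function(b) {
    w <- df[df$plate_barcode == b,
            c("well", "role", "drug_id", "dose_uM", "replicate", "rlu",
              "model_id")]
    rownames(w) <- NULL
    plate(b, w)
  })
}

#' Write plates to the standard CSV dialect
#'
#' @param plates list of `pdx_plate` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_plates <- function(plates, path) {
  rows <- lapply(plates, function(p) {
    cbind(plate_barcode = p$barcode, p$wells)
  })
  df <- do.call(rbind, rows)
  cols <- c("plate_barcode", "well", "role", "drug_id", "dose_uM",
            "replicate", "rlu")
  if ("model_id" %in% names(df)) cols <- c(cols, "model_id")
  utils::write.csv(df[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize a plate to fraction-affected
#'
#' Applies `FA = 1 - rlu / median(DMSO rlu)` using the median of the
#' on-plate DMSO vehicle wells as the denominator. One record is returned
#' per DRUG well; control and empty wells are consumed, not emitted. FA is
#' deliberately not clipped here (clipping to [0, 1] happens only at the
#' AUC stage) so growth-stimulation signals (FA < 0) remain inspectable.
#'
#' @param plate a `pdx_plate`.
#' @return data.frame with columns `model_id`, `drug_id`, `dose_uM`,
#'   `replicate`, `FA`.
#' @export
normalize_plate <- function(plate) {
  stopifnot(inherits(plate, "pdx_plate"))
  w <- plate$wells
  x_dmso <- stats::median(w$rlu[w$role == "DMSO"])
  if (!is.finite(x_dmso) || x_dmso <= 0)
    stop("degenerate plate ", plate$barcode, ": median DMSO RLU is ", x_dmso)
  d <- w[w$role == "DRUG", , drop = FALSE]
  data.frame(model_id = if ("model_id" %in% names(d)) d$model_id
             else NA_character_,
             drug_id = d$drug_id, dose_uM = d$dose_uM,
             replicate = d$replicate, FA = 1 - d$rlu / x_dmso,
             stringsAsFactors = FALSE)
}

#' Normalize a list of plates
#'
#' @param plates list of `pdx_plate` objects.
#' @return row-bound data.frame of [normalize_plate()] outputs.
#' @export
normalize_plates <- function(plates) {
  out <- do.call(rbind, lapply(plates, normalize_plate))
  rownames(out) <- NULL
  out
}

#' Plate Z-prime factor
#'
#' The Zhang-Chipman-Oldenburg assay-quality statistic computed on raw RLU:
#' \deqn{Z' = 1 - \frac{3(\sigma_{pos} + \sigma_{veh})}{|\mu_{pos} - \mu_{veh}|}}
#' using sample standard deviations of the positive-control (anisomycin)
#' and vehicle (DMSO) wells. Z' is at most 1; values above ~0.5 indicate an
#' excellent assay window.
#'
#' @param plate a `pdx_plate` with at least 2 DMSO and 2 POSCON wells.
#' @return scalar Z-prime.
#' @export
z_prime <- function(plate) {
  stopifnot(inherits(plate, "pdx_plate"))
  w <- plate$wells
  veh <- w$rlu[w$role == "DMSO"]
  pos <- w$rlu[w$role == "POSCON"]
  if (length(veh) < 2L || length(pos) < 2L)
    stop("plate ", plate$barcode,
         ": need >= 2 DMSO and >= 2 POSCON wells for Z'")
  sep <- abs(mean(pos) - mean(veh))
  if (sep == 0)
    stop("plate ", plate$barcode, ": undefined separation (equal means)")
  1 - 3 * (stats::sd(pos) + stats::sd(veh)) / sep
}

#' Minimum significance ratio from replicate potencies
#'
#' The smallest potency fold-change distinguishable from technical
#' replicate noise: `MSR = 10^(2 * sqrt(2) * s)` where `s` is the standard
#' deviation of replicate log10 potencies (log10 AC50). MSR is 1 for
#' perfectly reproducible replicates and grows with replicate scatter; an
#' assay averaging below 2 is conventionally called reproducible.
#'
#' @param replicate_potencies numeric vector of log10 AC50 values across
#'   technical replicates of one drug (length >= 2).
#' @return scalar MSR (fold ratio, >= 1).
#' @export
msr <- function(replicate_potencies) {
  v <- replicate_potencies[is.finite(replicate_potencies)]
  if (length(v) < 2L)
    stop("MSR not estimable: need >= 2 finite replicate potencies")
  10^(2 * sqrt(2) * stats::sd(v))
}

# Per-replicate potency estimates for MSR. Each technical replicate's
# 3-point curve is fitted separately and the potency recorded is the log10
# half-effect concentration (the fitted curve's in-window FA = 0.5
# crossing; identical to the log10 AC50 for a full 0-to-1 curve). Only
# drug-model pairs whose POOLED fit shows a full response curve (converged
# 4PL, top >= `min_top`, in-window crossing) are qualified: potency is not
# a well-conditioned quantity for partial-efficacy curves on a 3-point
# design, and standard MSR practice restricts to qualified potencies.
replicate_potencies <- function(normalized, fits = NULL, dose_range = NULL,
                                min_top = 0.8) {
  if (is.null(dose_range)) dose_range <- range(normalized$dose_uM)
  if (is.null(fits)) fits <- fit_screen(normalized, dose_range = dose_range)
  qual <- fits$fit_kind == "FOUR_PL" & fits$converged &
    !is.na(fits$top) & fits$top >= min_top & fits$ic50_flag == "ok"
  qual_key <- paste(fits$model_id, fits$drug_id)[qual]
  keep <- paste(normalized$model_id, normalized$drug_id) %in% qual_key
  nz <- normalized[keep, , drop = FALSE]
  if (!nrow(nz))
    return(data.frame(model_id = character(0), drug_id = character(0),
                      replicate = integer(0), log10_potency = numeric(0)))
  key <- interaction(nz$model_id, nz$drug_id, nz$replicate, drop = TRUE)
  rows <- lapply(split(nz, key), function(g) {
    fit <- tryCatch(fit_cascade(log10(g$dose_uM), g$FA,
                                dose_range = dose_range),
                    error = function(e) NULL)
    ok <- !is.null(fit) && fit$fit_kind == "FOUR_PL" && fit$converged &&
      identical(fit$ic50_flag, "ok")
    data.frame(model_id = g$model_id[1], drug_id = g$drug_id[1],
               replicate = g$replicate[1],
               log10_potency = if (ok) log10(fit$ic50_uM) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screen-level quality-control report
#'
#' Computes the plate-level Z-prime for every plate and, per (model, drug),
#' the minimum significance ratio of replicate potencies obtained by
#' fitting each technical replicate's dose-response curve separately. The
#' potency entering MSR is the log10 half-effect concentration (the fitted
#' curve's FA = 0.5 crossing within the tested window, equal to the log10
#' AC50 for a full 0-to-1 curve). MSR is only computed for qualified
#' drug-model pairs - pooled fit is a converged 4PL with top >= 0.8 and an
#' in-window crossing, and >= 2 replicates yield a potency - since the
#' potency of a partial-efficacy curve is not identifiable from a 3-point
#' design; unqualified pairs are excluded from the mean, matching standard
#' potency-assay MSR practice.
#'
#' @param plates list of `pdx_plate` objects.
#' @param normalized optional pre-computed [normalize_plates()] table; if
#'   `NULL` it is derived from `plates`.
#' @param fits optional pre-computed [fit_screen()] table (used to qualify
#'   drugs); computed from `normalized` when `NULL`.
#' @return list of class `pdx_qc`: `plate_z` (data.frame barcode /
#'   z_prime), `mean_z_prime`, `drug_msr` (data.frame model_id / drug_id /
#'   n_replicates / msr for qualified pairs), `mean_msr`.
#' @export
qc_report <- function(plates, normalized = NULL, fits = NULL) {
  plate_z <- data.frame(
    barcode = vapply(plates, function(p) p$barcode, character(1)),
    z_prime = vapply(plates, z_prime, numeric(1)),
    stringsAsFactors = FALSE)
  if (is.null(normalized)) normalized <- normalize_plates(plates)
  pots <- replicate_potencies(normalized, fits = fits)
  if (nrow(pots)) {
    key <- interaction(pots$model_id, pots$drug_id, drop = TRUE)
    drug_msr <- do.call(rbind, lapply(split(pots, key), function(g) {
      ok <- is.finite(g$log10_potency)
      data.frame(model_id = g$model_id[1], drug_id = g$drug_id[1],
                 n_replicates = sum(ok),
                 msr = if (sum(ok) >= 2L) msr(g$log10_potency[ok])
                 else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    rownames(drug_msr) <- NULL
  } else {
    drug_msr <- data.frame(model_id = character(0), drug_id = character(0),
                           n_replicates = integer(0), msr = numeric(0))
  }
  structure(list(plate_z = plate_z,
                 mean_z_prime = mean(plate_z$z_prime),
                 drug_msr = drug_msr,
                 mean_msr = mean(drug_msr$msr, na.rm = TRUE)),
            class = "pdx_qc")
}

#' @export
print.pdx_qc <- function(x, ...) {
  cat(sprintf(paste0("<pdx_qc> %d plates | mean Z' = %.3f | mean MSR = %.3f",
                     " (%d/%d drugs with estimable potency)\n"),
              nrow(x$plate_z), x$mean_z_prime, x$mean_msr,
              sum(is.finite(x$drug_msr$msr)), nrow(x$drug_msr)))
  invisible(x)
}

#' Write a QC report as TSV + JSON
#'
#' @param qc a `pdx_qc` from [qc_report()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_qc_report <- function(qc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(qc$plate_z, file.path(dir, "plate_zprime.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(qc$drug_msr, file.path(dir, "drug_msr.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(mean_z_prime = qc$mean_z_prime,
                            mean_msr = qc$mean_msr),
                       file.path(dir, "qc_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Fraction of human DNA from qPCR cycle thresholds (delta-delta-Ct)
#'
#' Relative human:mouse genomic DNA quantification used to validate mouse
#' cell depletion of PDX digests. With a human probe (e.g. RNaseP) and a
#' mouse probe (e.g. Trfc) measured in the sample and in a 50:50 reference:
#' `ddCt = (Ct_human_sample - Ct_mouse_sample) -
#' (Ct_human_ref - Ct_mouse_ref)`; the human:mouse ratio is `2^(-ddCt)` and
#' the reported value is the human fraction `ratio / (1 + ratio)`.
#'
#' @param ct_human_sample,ct_mouse_sample Ct values in the test sample.
#' @param ct_human_ref,ct_mouse_ref Ct values in the calibrator sample.
#' @return scalar fraction of human DNA in (0, 1); monotone decreasing in
#'   `ct_human_sample`.
#' @export
ddct_human_content <- function(ct_human_sample, ct_mouse_sample,
                               ct_human_ref, ct_mouse_ref) {
  cts <- c(ct_human_sample, ct_mouse_sample, ct_human_ref, ct_mouse_ref)
  if (!all(is.finite(cts))) stop("all Ct values must be finite")
  ddct <- (ct_human_sample - ct_mouse_sample) - (ct_human_ref - ct_mouse_ref)
  ratio <- 2^(-ddct)
  ratio / (1 + ratio)
}
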