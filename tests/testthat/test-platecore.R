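make_plate <- function(barcode = "P1", n_dmso = 4, n_pos = 4,
                       dmso_rlu = rep(10000, n_dmso),
                       pos_rlu = rep(500, n_pos),
                       drug = data.frame()) {
  wells <- valid_wells <- pdxscreen:::valid_wells_384()
  n_drug <- nrow(drug)
  n <- n_dmso + n_pos + n_drug
  w <- data.frame(
    well = valid_wells[seq_len(n)],
    role = c(rep("DMSO", n_dmso), rep("POSCON", n_pos),
             rep("DRUG", n_drug)),
    drug_id = c(rep(NA, n_dmso + n_pos),
                if (n_drug) drug$drug_id else character(0)),
    dose_uM = c(rep(NA, n_dmso + n_pos),
                if (n_drug) drug$dose_uM else numeric(0)),
    replicate = c(rep(NA, n_dmso + n_pos),
                  if (n_drug) drug$replicate else integer(0)),
    rlu = c(dmso_rlu, pos_rlu, if (n_drug) drug$rlu else numeric(0)),
    stringsAsFactors = FALSE)
  plate(barcode, w)
}

test_that("plate validation rejects malformed containers", {
  w <- data.frame(well = c("A01", "A01"), role = c("DMSO", "DMSO"),
                  drug_id = NA, dose_uM = NA, replicate = NA,
                  rlu = c(1, 2))
  expect_error(plate("B1", w), "duplicate well")
  w2 <- w; w2$well <- c("A01", "Q01")
  expect_error(plate("B1", w2), "out of range")
  w3 <- w; w3$well <- c("A01", "A02"); w3$rlu <- c(1, -2)
  expect_error(plate("B1", w3), "negative")
  w4 <- w; w4$well <- c("A01", "A02"); w4$role <- c("DRUG", "POSCON")
  expect_error(plate("B1", w4), "QC-fatal.*B1")
})

test_that("plate CSV round-trips synthetic screens losslessly", {
  cfg <- small_config()
  scr <- generate_screen(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_plates(scr$plates, path)
  back <- read_plates(path)
  expect_equal(length(back), length(scr$plates))
  expect_equal(back[[1]]$barcode, scr$plates[[1]]$barcode)
  for (col in c("well", "role", "drug_id", "dose_uM", "replicate")) {
    expect_equal(back[[3]]$wells[[col]], scr$plates[[3]]$wells[[col]])
  }
  expect_equal(back[[3]]$wells$rlu, scr$plates[[3]]$wells$rlu,
               tolerance = 1e-12)
})

test_that("normalize applies FA = 1 - rlu / median(DMSO) without clipping", {
  med <- 10000
  drug <- data.frame(drug_id = "D1", dose_uM = c(10, 1, 0.1),
                     replicate = 1L, rlu = c(med, 0, 2 * med))
  p <- make_plate(drug = drug)
  fa <- normalize_plate(p)
  expect_equal(fa$FA, c(0, 1, -1))
  # invariance to rescaling every RLU on the plate by a constant
  p2 <- p; p2$wells$rlu <- p2$wells$rlu * 37.5
  expect_equal(normalize_plate(p2)$FA, fa$FA, tolerance = 1e-12)
})

test_that("degenerate plates (zero DMSO median) are rejected", {
  p <- make_plate(dmso_rlu = rep(0, 4))
  expect_error(normalize_plate(p), "degenerate plate")
})

test_that("Z-prime reproduces the hand-computed control case", {
  # sample sd of a symmetric pair (m - d, m + d) is d * sqrt(2)
  p <- make_plate(n_dmso = 2, n_pos = 2,
                  dmso_rlu = 10000 + c(-1, 1) * 500 / sqrt(2),
                  pos_rlu = 500 + c(-1, 1) * 50 / sqrt(2))
  expect_equal(z_prime(p), 1 - 3 * 550 / 9500, tolerance = 1e-12)
  # noiseless limit
  p0 <- make_plate(n_dmso = 3, n_pos = 3)
  expect_equal(z_prime(p0), 1)
  # symmetric in the two control populations: swap the role labels
  psw <- p
  psw$wells$role <- c("POSCON", "POSCON", "DMSO", "DMSO")
  expect_equal(z_prime(psw), z_prime(p))
})

test_that("Z-prime is invariant to affine rescaling of RLU", {
  set.seed(3)
  p <- make_plate(n_dmso = 8, n_pos = 8,
                  dmso_rlu = rnorm(8, 10000, 400),
                  pos_rlu = rnorm(8, 600, 60))
  z0 <- z_prime(p)
  p2 <- p; p2$wells$rlu <- 2.5 * p2$wells$rlu + 123
  expect_equal(z_prime(p2), z0, tolerance = 1e-12)
})

test_that("Z-prime preconditions are enforced", {
  p <- make_plate(n_dmso = 1, n_pos = 4)
  expect_error(z_prime(p), ">= 2 DMSO")
  peq <- make_plate(n_dmso = 2, n_pos = 2, dmso_rlu = c(400, 600),
                    pos_rlu = c(300, 700))
  expect_error(z_prime(peq), "undefined separation")
})

test_that("MSR follows 10^(2*sqrt(2)*s) exactly", {
  expect_equal(msr(c(0.3, 0.3, 0.3)), 1)
  # pairs constructed to have exact sample SD 0.1 and 0.2
  m1 <- msr(c(-0.1, 0.1) / sqrt(2))
  expect_equal(m1, 10^(2 * sqrt(2) * 0.1), tolerance = 1e-12)
  m2 <- msr(c(-0.2, 0.2) / sqrt(2))
  expect_equal(m2, m1^2, tolerance = 1e-9)  # log-linearity in s
  expect_error(msr(0.5), "not estimable")
})

test_that("ddCt human-content fraction behaves per definition", {
  # ddCt = 0 -> ratio 1 -> fraction 1/2
  expect_equal(ddct_human_content(20, 20, 25, 25), 0.5)
  # one cycle fewer for human doubles the human:mouse ratio
  f1 <- ddct_human_content(20, 20, 25, 25)
  f2 <- ddct_human_content(19, 20, 25, 25)
  odds <- function(f) f / (1 - f)
  expect_equal(odds(f2), 2 * odds(f1), tolerance = 1e-12)
  # ddCt about -7.37 gives ~99.4% human DNA
  expect_equal(ddct_human_content(20, 27.37, 25, 25), 0.994,
               tolerance = 5e-4)
  # monotone decreasing in the human sample Ct
  cts <- seq(18, 26, by = 0.5)
  fr <- vapply(cts, function(ct) ddct_human_content(ct, 20, 25, 25),
               numeric(1))
  expect_true(all(diff(fr) < 0))
  expect_error(ddct_human_content(NA, 20, 25, 25), "finite")
})

test_that("qc_report summarizes Z-prime and qualified-drug MSR", {
  cfg <- small_config()
  scr <- generate_screen(cfg)
  norm <- normalize_plates(scr$plates)
  fits <- fit_screen(norm)
  qc <- qc_report(scr$plates, norm, fits)
  expect_equal(nrow(qc$plate_z), length(scr$plates))
  expect_true(all(qc$plate_z$z_prime <= 1))
  expect_true(all(qc$drug_msr$msr >= 1, na.rm = TRUE))
  expect_true(is.finite(qc$mean_msr))
  d <- withr::local_tempdir()
  write_qc_report(qc, d)
  expect_true(file.exists(file.path(d, "qc_summary.json")))
  js <- jsonlite::read_json(file.path(d, "qc_summary.json"))
  expect_equal(js$mean_z_prime, qc$mean_z_prime, tolerance = 1e-9)
})
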