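test_that("with no covariates the DOL coefficient is the mean paired diff", {
  co <- generateCohort(cleanConfig(seed = 2, n_participants = 12,
                                   followup_split = c(4, 4, 4),
                                   n_proteins = 25))
  for (d in c(1L, 3L, 7L)) {
    res <- fitPairedLMM(co$pqe, d, covariates = character(0))
    expect_equal(res$log2fc, res$raw_paired_lfc, tolerance = 1e-8)
    expect_true(all(sign(res$log2fc) == sign(res$raw_paired_lfc)))
  }
})

test_that("the calibrated LRT reproduces the exact paired t-test", {
  co <- generateCohort(cleanConfig(seed = 6, n_participants = 24,
                                   followup_split = c(8, 8, 8),
                                   n_proteins = 12, subject_sd = 0.8))
  m <- lfq(co$pqe)
  meta <- sampleMeta(co$pqe)
  for (d in c(1L, 7L)) {
    res <- fitPairedLMM(co$pqe, d, covariates = character(0))
    part <- meta$participant_id[meta$dol == d]
    i0 <- match(paste0(part, "_D0"), meta$sample_id)
    ix <- match(paste0(part, "_D", d), meta$sample_id)
    p_t <- apply(m[, ix] - m[, i0], 1, function(dd)
      t.test(dd)$p.value)
    expect_equal(res$p_lrt, unname(p_t[res$protein]), tolerance = 1e-4)
  }
  # the asymptotic chi-square reference remains available and is more
  # liberal in the tail
  res_c <- fitPairedLMM(co$pqe, 7L, covariates = character(0),
                        p_reference = "chisq")
  res_f <- fitPairedLMM(co$pqe, 7L, covariates = character(0))
  expect_true(all(res_c$p_lrt <= res_f$p_lrt + 1e-12))
})

test_that("constant intensities give zero fold change and p = 1", {
  meta <- pairedMeta(4, 0, 0)
  m <- matrix(25, 3, nrow(meta))
  res <- fitPairedLMM(quickPQE(m, meta), 1L, covariates = character(0))
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$p_lrt, rep(1, 3))
})

test_that("profile and lmer engines agree, with and without holes", {
  co <- generateCohort(tinyConfig(seed = 3, n_participants = 15,
                                  followup_split = c(5, 5, 5),
                                  n_proteins = 8, ig_panel = NULL,
                                  n_genes = 0))
  vv <- filterValidValues(co$pqe, 3L)
  a <- fitPairedLMM(vv$pqe, 3L, engine = "profile")
  b <- fitPairedLMM(vv$pqe, 3L, engine = "lmer")
  expect_equal(a$log2fc, b$log2fc, tolerance = 1e-5)
  expect_equal(a$p_lrt, b$p_lrt, tolerance = 1e-4)
  # complete data exercises the vectorized path
  co2 <- generateCohort(cleanConfig(seed = 4, n_participants = 9,
                                    followup_split = c(3, 3, 3),
                                    n_proteins = 8))
  a2 <- fitPairedLMM(co2$pqe, 7L, covariates = c("sex"),
                     engine = "profile")
  b2 <- fitPairedLMM(co2$pqe, 7L, covariates = c("sex"), engine = "lmer")
  expect_equal(a2$log2fc, b2$log2fc, tolerance = 1e-5)
  expect_equal(a2$p_lrt, b2$p_lrt, tolerance = 1e-3)
})

test_that("a true arm effect is recovered within the expected band", {
  # each protein is an independent replicate of the same effect
  cfg <- cleanConfig(seed = 5, n_participants = 30,
                     followup_split = c(0, 0, 30), n_proteins = 200,
                     residual_sd = 0.3,
                     trajectory_classes = list(
                       increasing = list(fraction = 1,
                                         lfc_range = c(0.8, 0.8))))
  co <- generateCohort(cfg)
  res <- fitPairedLMM(co$pqe, 7L, covariates = character(0))
  expect_gte(mean(abs(res$log2fc - 0.8) <= 0.15), 0.95)
})

test_that("proteins without enough pairs are marked not-testable", {
  meta <- pairedMeta(4, 0, 0)
  m <- matrix(rnorm(2 * nrow(meta), 25), 2)
  colnames(m) <- meta$sample_id
  m[1, meta$dol == 1L][1:3] <- NA       # one complete pair only
  res <- fitPairedLMM(quickPQE(m, meta), 1L, covariates = character(0))
  expect_true(is.na(res$p_lrt[1]))
  expect_equal(res$n_used[1], 1L)
  expect_false(is.na(res$p_lrt[2]))
})

test_that("covariates aliased with the design are dropped with a warning", {
  meta <- pairedMeta(4, 0, 0)
  meta$batch <- ifelse(meta$dol == 0L, "B1", "B2")
  m <- matrix(rnorm(3 * nrow(meta), 25), 3)
  expect_warning(
    res <- fitPairedLMM(quickPQE(m, meta), 1L,
                        covariates = c("batch")),
    "aliased")
  expect_true(all(is.finite(res$p_lrt)))
})

test_that("BH adjustment matches hand-computed and brute-force results", {
  expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustBH(0.37), 0.37)
  expect_error(adjustBH(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(17)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(adjustBH(p), bhOracle(p), tolerance = 1e-12)
  }
})

test_that("BH is monotone: raising one p never lowers any q", {
  set.seed(18)
  p <- runif(12)
  q <- adjustBH(p)
  for (i in seq_along(p)) {
    p2 <- p
    p2[i] <- min(1, p[i] + runif(1, 0, 1 - p[i]))
    expect_true(all(adjustBH(p2) >= q - 1e-12))
  }
})

test_that("the significance gate requires both FDR and fold change", {
  res <- data.frame(protein = c("A", "B", "C"), dol = 7L,
                    log2fc = c(0.19, -0.5, 1.0),
                    p_lrt = c(0.013, 0.013, 0.06),
                    q_value = NA_real_, significant = NA)
  out <- callSignificance(res, fdr = 0.05, lfc = 0.2)
  expect_equal(out$q_value, c(0.0195, 0.0195, 0.06))
  expect_false(out$significant[1])   # q ok, fold change too small
  expect_true(out$significant[2])
  expect_false(out$significant[3])   # fold change ok, q too large
})

test_that("Fisher missingness matches exact enumeration", {
  meta <- pairedMeta(0, 0, 10)
  m <- matrix(rnorm(3 * nrow(meta), 25), 3)
  colnames(m) <- meta$sample_id
  m[1, meta$dol == 7L] <- NA               # 10/10 detected vs 0/10
  m[2, c(1, 3, 12, 15)] <- NA              # arbitrary pattern
  res <- fisherMissingness(quickPQE(m, meta), 7L)
  expect_equal(res$p_fisher[1], 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$p_fisher[1], 1.0824e-5, tolerance = 1e-3)
  expect_equal(res$p_fisher[3], 1)         # identical detection
  for (i in 1:3)
    expect_equal(res$p_fisher[i],
                 fisherOracle(res$det_dol0[i],
                              res$n_dol0[i] - res$det_dol0[i],
                              res$det_dolx[i],
                              res$n_dolx[i] - res$det_dolx[i]),
                 tolerance = 1e-12)
})
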