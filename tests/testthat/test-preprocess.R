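test_that("flag filtering removes each flagged row once, by precedence", {
  meta <- pairedMeta(1, 1, 1)
  m <- matrix(rnorm(5 * nrow(meta), 25), 5,
              dimnames = list(paste0("P", 1:5), NULL))
  pqe <- quickPQE(m, meta)
  rd <- proteinInfo(pqe)
  rd$is_contaminant[1] <- TRUE
  rd$is_reverse[1] <- TRUE          # double-flagged: counts as contaminant
  rd$is_reverse[2] <- TRUE
  rd$only_modified_site[3] <- TRUE
  pqe2 <- ProteinQuantExperiment(lfq(pqe), meta, rowData = rd)
  fl <- filterFlags(pqe2)
  expect_equal(fl$report$n_removed_contaminant, 1L)
  expect_equal(fl$report$n_removed_reverse, 1L)
  expect_equal(fl$report$n_removed_modified_only, 1L)
  expect_equal(nrow(fl$pqe), 2L)
  # identity on unflagged input
  fl0 <- filterFlags(pqe)
  expect_identical(lfq(fl0$pqe), lfq(pqe))
})

test_that("valid-value filter applies the 50% rule per comparison arm", {
  meta <- pairedMeta(10, 0, 0)      # 10 participants, DOL0 + DOL1
  n <- nrow(meta)
  m <- matrix(rnorm(3 * n, 25), 3, dimnames = list(paste0("P", 1:3), NULL))
  colnames(m) <- meta$sample_id
  d1 <- which(meta$dol == 1L)
  m[1, d1[1:6]] <- NA               # 4/10 at DOL1 -> below 50%, removed
  m[2, d1[1:5]] <- NA               # exactly 5/10 -> retained (inclusive)
  m[3, ] <- m[3, ]                  # fully observed -> retained
  pqe <- quickPQE(m, meta)
  vv <- filterValidValues(pqe, 1L)
  kept <- rownames(lfq(vv$pqe))
  expect_false("P1" %in% kept)
  expect_true(all(c("P2", "P3") %in% kept))
  expect_equal(vv$report$n_quantifiable, 2L)
  # never creates values: output entries are a subset of input entries
  expect_true(all(lfq(vv$pqe) %in% m | is.na(lfq(vv$pqe))))
  expect_identical(is.na(lfq(vv$pqe)),
                   is.na(m[kept, colnames(lfq(vv$pqe))]))
  expect_error(filterValidValues(pqe, 3L), "design error")
})

test_that("single-batch correction is the identity", {
  co <- generateCohort(tinyConfig(seed = 2, ig_panel = NULL, n_genes = 0,
                                  batch_effects = data.frame(shift = 0,
                                                             scale = 1)))
  one <- correctBatch(co$pqe, covariates = character(0))
  expect_identical(lfq(one$pqe), lfq(co$pqe))
  expect_true(all(one$model$gamma == 0))
  expect_true(all(one$model$delta2 == 1))
})

test_that("injected batch location/scale effects are removed", {
  cfg <- cleanConfig(seed = 13, n_participants = 30,
                     followup_split = c(10, 10, 10), n_proteins = 200,
                     trajectory_classes = list(flat = list(fraction = 1)),
                     batch_effects = data.frame(shift = c(0, 1.0),
                                                scale = c(1, 1.5)))
  co <- generateCohort(cfg)
  b <- sampleMeta(co$pqe)$batch
  before <- rowMeans(lfq(co$pqe)[, b == "B2"]) -
    rowMeans(lfq(co$pqe)[, b == "B1"])
  expect_gt(mean(before), 0.9)
  # EB shrinkage deliberately leaves per-protein noise in place, so the
  # recovery check targets the systematic (across-protein) residual shift
  bc <- correctBatch(co$pqe, covariates = character(0))
  m <- lfq(bc$pqe)
  diff_after <- rowMeans(m[, b == "B2"]) - rowMeans(m[, b == "B1"])
  expect_lt(abs(mean(diff_after)), 0.05)
  vr <- apply(m[, b == "B2"], 1, var) / apply(m[, b == "B1"], 1, var)
  expect_gt(mean(vr), 0.9)
  expect_lt(mean(vr), 1.1)
  # grand means preserved (balanced design)
  expect_equal(rowMeans(m), rowMeans(lfq(co$pqe)), tolerance = 1e-6)
  # in the non-EB limit the empirical batch means are equalized exactly
  m0 <- lfq(correctBatch(co$pqe, covariates = character(0),
                         eb = FALSE)$pqe)
  d0 <- rowMeans(m0[, b == "B2"]) - rowMeans(m0[, b == "B1"])
  expect_lt(mean(abs(d0)), 1e-10)
})

test_that("non-EB limit matches the direct standardization oracle", {
  cfg <- cleanConfig(seed = 14, n_participants = 10,
                     followup_split = c(4, 3, 3), n_proteins = 30,
                     trajectory_classes = list(flat = list(fraction = 1)),
                     batch_effects = data.frame(shift = c(0, 0.8),
                                                scale = c(1, 1.3)))
  co <- generateCohort(cfg)
  bc <- correctBatch(co$pqe, covariates = character(0), eb = FALSE)
  Y <- lfq(co$pqe)
  b <- factor(sampleMeta(co$pqe)$batch)
  w <- as.numeric(table(b)) / ncol(Y)
  oracle <- Y
  for (i in seq_len(nrow(Y))) {
    mu_b <- tapply(Y[i, ], b, mean)
    alpha <- sum(w * mu_b)
    sig <- sqrt(mean((Y[i, ] - mu_b[b])^2))
    z <- (Y[i, ] - alpha) / sig
    g <- tapply(z, b, mean)
    dl <- tapply(z, b, var)
    oracle[i, ] <- sig * (z - g[b]) / sqrt(dl[b]) + alpha
    oracle[i, ] <- oracle[i, ] + mean(Y[i, ]) - mean(oracle[i, ])
  }
  expect_equal(lfq(bc$pqe), oracle, tolerance = 1e-6)
})

test_that("EB shrinkage agrees with the reference ComBat on complete data", {
  skip_if_not_installed("sva")
  cfg <- cleanConfig(seed = 15, n_participants = 12,
                     followup_split = c(4, 4, 4), n_proteins = 60,
                     batch_effects = data.frame(shift = c(0, 0.6),
                                                scale = c(1, 1.4)))
  co <- generateCohort(cfg)
  Y <- lfq(co$pqe)
  b <- sampleMeta(co$pqe)$batch
  ours <- lfq(correctBatch(co$pqe, covariates = character(0))$pqe)
  ref <- suppressMessages(sva::ComBat(Y, batch = b))
  # identical up to the per-protein grand-mean restoration step
  ours_c <- ours - rowMeans(ours)
  ref_c <- ref - rowMeans(ref)
  # small residual slack: the two ICM loops use different stopping rules
  expect_equal(ours_c, ref_c, tolerance = 1e-4)
})

test_that("confounded batch layouts are rejected with the aliased term", {
  meta <- pairedMeta(4, 0, 0)
  meta$batch <- ifelse(meta$dol == 0L, "B1", "B2")   # batch == day
  m <- matrix(rnorm(5 * nrow(meta), 25), 5,
              dimnames = list(paste0("P", 1:5), NULL))
  pqe <- quickPQE(m, meta)
  expect_error(correctBatch(pqe, covariates = "dol"), "confounded")
})

test_that("global-distribution statistic is zero for identical groups", {
  meta <- pairedMeta(3, 3, 3)
  base_col <- rnorm(20, 25)
  m <- matrix(rep(base_col, nrow(meta)), 20)   # all samples identical
  pqe <- quickPQE(m, meta)
  res <- testGlobalDistributions(pqe, n_perm = 50, seed = 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("a strong global shift in one group is detected", {
  meta <- pairedMeta(4, 4, 4)
  set.seed(8)
  m <- matrix(rnorm(100 * nrow(meta), 25), 100)
  m[, meta$dol == 7L] <- m[, meta$dol == 7L] + 2
  pqe <- quickPQE(m, meta)
  res <- testGlobalDistributions(pqe, n_perm = 1000, seed = 2)
  expect_lte(res$p_value, 0.01)
})
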