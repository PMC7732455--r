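test_that("subclass ratios behave as a change of units", {
  co <- generateCohort(tinyConfig(seed = 7, n_proteins = 5))
  ig2 <- computeIgRatios(co$pqe, ref = "IGHG2")
  expect_true(all(ig2$ratios[, "IGHG2"] == 1))
  expect_true(all(ig2$ratios > 0, na.rm = TRUE))
  ig3 <- computeIgRatios(co$pqe, ref = "IGHG3")
  # re-normalization is exact: r_k^(G3) = r_k^(G2) / r_G3^(G2)
  expect_equal(ig3$ratios,
               ig2$ratios / ig2$ratios[, "IGHG3"], tolerance = 1e-12)
  # subclass mean ordering is reference-invariant
  ord2 <- order(colMeans(ig2$ratios[, paste0("IGHG", 1:4)]))
  ord3 <- order(colMeans(ig3$ratios[, paste0("IGHG", 1:4)]))
  expect_identical(ord2, ord3)
})

test_that("configured subclass abundance ratios are recovered", {
  co <- generateCohort(tinyConfig(seed = 8, n_participants = 30,
                                  followup_split = c(10, 10, 10),
                                  n_proteins = 5))
  ig <- computeIgRatios(co$pqe)
  d0 <- ig$meta$dol == 0
  # configured baseline iBAQ IgG1:IgG2 = 5 (log-normal noise around it)
  gm <- exp(mean(log(ig$ratios[d0, "IGHG1"])))
  expect_gt(gm, 3.5)
  expect_lt(gm, 7)
})

test_that("ratio comparison against an adult panel uses Welch's test", {
  adult <- syntheticAdultIgPanel(n = 30, seed = 1)
  ratios_a <- as.matrix(adult[, c("IGHG1", "IGHG3", "IGHG4")]) /
    adult$IGHG2
  same <- compareIgRatios(ratios_a, ratios_a)
  expect_true(all(abs(same$t) < 1e-12))
  expect_true(all(same$p > 0.999))
  inflated <- ratios_a
  inflated[, "IGHG1"] <- inflated[, "IGHG1"] * 2
  diff <- compareIgRatios(inflated, ratios_a)
  expect_lt(diff$p[diff$subclass == "IGHG1"], 0.01)
  expect_error(compareIgRatios(ratios_a[1, , drop = FALSE], ratios_a),
               "at least 2")
})

test_that("Welch comparison holds its size under unequal variances", {
  set.seed(9)
  hits <- 0
  for (i in 1:1000) {
    a <- rnorm(15, 1, 0.2)
    b <- rnorm(40, 1, 1.0)
    if (t.test(a, b)$p.value < 0.05) hits <- hits + 1
  }
  expect_gt(hits / 1000, 0.03)
  expect_lt(hits / 1000, 0.07)
})

test_that("half-life estimation is exact on noise-free decay", {
  meta <- pairedMeta(3, 3, 3)
  t_half <- 21.1
  m <- matrix(30, 2, nrow(meta))
  colnames(m) <- meta$sample_id
  fup <- meta$dol > 0
  m[1, fup] <- 30 - meta$dol[fup] / t_half
  tr <- computeChanges(quickPQE(m, meta))
  hl <- estimateHalfLife(tr, rownames(tr$delta)[1], boot_n = 0)
  expect_equal(hl$t_half, 21.1, tolerance = 1e-10)
  # no decay at all: flagged infinite
  hl2 <- estimateHalfLife(tr, rownames(tr$delta)[2], boot_n = 0)
  expect_identical(hl2$t_half, Inf)
})

test_that("half-life is exact for any true value and scale-invariant", {
  set.seed(10)
  meta <- pairedMeta(3, 3, 3)
  for (th in runif(10, 5, 60)) {
    m <- matrix(28, 1, nrow(meta))
    colnames(m) <- meta$sample_id
    m[1, meta$dol > 0] <- 28 - meta$dol[meta$dol > 0] / th
    tr <- computeChanges(quickPQE(m, meta))
    hl <- estimateHalfLife(tr, rownames(tr$delta)[1], boot_n = 0)
    expect_equal(hl$t_half, th, tolerance = 1e-9)
    # additive shift of all log2 intensities leaves the estimate unchanged
    tr_shift <- computeChanges(quickPQE(m + 5, meta))
    expect_equal(estimateHalfLife(tr_shift, rownames(tr$delta)[1],
                                  boot_n = 0)$t_half, hl$t_half)
  }
})

test_that("single follow-up day is flagged; bootstrap is seeded", {
  meta <- pairedMeta(0, 0, 6)
  set.seed(11)
  m <- matrix(28, 1, nrow(meta))
  colnames(m) <- meta$sample_id
  m[1, meta$dol > 0] <- 28 - 7 / 21 + rnorm(6, 0, 0.05)
  tr <- computeChanges(quickPQE(m, meta))
  expect_warning(hl <- estimateHalfLife(tr, rownames(tr$delta)[1],
                                        boot_n = 100, seed = 5),
                 "single")
  expect_true(hl$single_day)
  hl2 <- suppressWarnings(estimateHalfLife(tr, rownames(tr$delta)[1],
                                           boot_n = 100, seed = 5))
  expect_identical(hl$ci, hl2$ci)
})

test_that("concentration projection multiplies baseline by fold bounds", {
  proj <- projectConcentration(18.5, c(2.054, 2.919))
  expect_equal(proj, c(38.0, 54.0), tolerance = 1e-3)
  expect_equal(projectConcentration(18.5, 1), 18.5)
  expect_error(projectConcentration(-1, 2), "positive")
  expect_error(projectConcentration(18.5, 0), "positive")
})

test_that("coupled IgM and J chain trajectories correlate strongly", {
  co <- generateCohort(tinyConfig(seed = 12, n_participants = 30,
                                  followup_split = c(10, 10, 10),
                                  n_proteins = 5))
  tr <- computeChanges(co$pqe)
  cp <- correlatePair(tr, "IGHM", "JCHAIN")
  expect_gt(cp$r, 0.6)
  expect_lt(cp$p, 0.001)
  self <- correlatePair(tr, "IGHM", "IGHM")
  expect_equal(self$r, 1)
  # anti-coupled pair
  D <- tr$delta
  D2 <- rbind(D, NEG = -D["IGHM", ])
  tr2 <- list(delta = D2, meta = tr$meta)
  expect_lt(correlatePair(tr2, "IGHM", "NEG")$r, 0)
})
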