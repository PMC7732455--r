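#' Remove flagged protein groups
#'
#' Drops rows flagged as potential contaminants, reversed decoys, or
#' identified only by modified peptides. A row carrying several flags is
#' counted once, with precedence contaminant > reverse > modified-only.
#'
#' @param pqe a [ProteinQuantExperiment-class].
#' @return list with `pqe` (filtered matrix) and `report` (a
#'   `data.frame` of removal counts).
#' @export
filterFlags <- function(pqe) {
  rd <- proteinInfo(pqe)
  con <- rd$is_contaminant
  rev <- rd$is_reverse & !con
  mod <- rd$only_modified_site & !con & !rd$is_reverse
  drop <- con | rev | mod
  report <- data.frame(
    n_input = nrow(rd),
    n_removed_contaminant = sum(con),
    n_removed_reverse = sum(rev),
    n_removed_modified_only = sum(mod),
    n_kept = sum(!drop))
  list(pqe = pqe[!drop, ], report = report)
}

# participants belonging to one comparison arm (those whose follow-up is
# at `dol`), and their sample indices
.armSamples <- function(meta, dol) {
  stopifnot(dol %in% c(1L, 3L, 7L))
  part <- meta$participant_id[meta$dol == dol]
  idx <- which(meta$participant_id %in% part & meta$dol %in% c(0L, dol))
  if (!length(part)) stop("design error: no participants with follow-up ",
                          "at DOL", dol)
  list(participants = part, idx = idx)
}

#' Valid-value filtering for one comparison arm
#'
#' Keeps proteins quantified in at least `min_fraction` of the DOL0
#' samples AND at least `min_fraction` of the follow-up-day samples,
#' restricted to participants in that comparison arm (those with their
#' follow-up at `comparison_dol`). The boundary is inclusive: a protein
#' observed in exactly 50% of each group is retained. No values are
#' imputed or altered.
#'
#' @param pqe a [ProteinQuantExperiment-class].
#' @param comparison_dol follow-up day of the arm, one of 1, 3, 7.
#' @param min_fraction minimum fraction of quantified samples per group.
#' @return list with `pqe` (arm samples only, quantifiable proteins only)
#'   and `report`.
#' @export
filterValidValues <- function(pqe, comparison_dol, min_fraction = 0.5) {
  meta <- sampleMeta(pqe)
  arm <- .armSamples(meta, as.integer(comparison_dol))
  sub <- pqe[, arm$idx]
  m <- lfq(sub)
  d <- sampleMeta(sub)$dol
  ok0 <- rowMeans(!is.na(m[, d == 0L, drop = FALSE])) >= min_fraction
  okx <- rowMeans(!is.na(m[, d == comparison_dol, drop = FALSE])) >=
    min_fraction
  keep <- ok0 & okx
  report <- data.frame(
    comparison_dol = as.integer(comparison_dol),
    n_input = nrow(m),
    n_removed_valid_value = sum(!keep),
    n_quantifiable = sum(keep))
  list(pqe = sub[keep, ], report = report)
}

#' Union valid-value filter across all arms
#'
#' Keeps every protein that passes [filterValidValues()] in at least one
#' comparison arm, over all samples; used before ordination, where the
#' per-arm restriction would discard samples.
#'
#' @inheritParams filterValidValues
#' @export
filterValidValuesUnion <- function(pqe, min_fraction = 0.5) {
  keep <- rep(FALSE, nrow(pqe))
  for (d in c(1L, 3L, 7L)) {
    arm <- filterValidValues(pqe, d, min_fraction)
    keep <- keep | rownames(lfq(pqe)) %in% rownames(lfq(arm$pqe))
  }
  report <- data.frame(n_input = nrow(pqe), n_quantifiable = sum(keep))
  list(pqe = pqe[keep, ], report = report)
}

# design matrix for covariates, with aliased columns detected
.covariateDesign <- function(meta, covariates) {
  if (!length(covariates)) return(NULL)
  fm <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
  model.matrix(fm, data = meta)[, -1, drop = FALSE]
}

#' Empirical-Bayes location/scale batch correction
#'
#' Per-protein location/scale adjustment in the ComBat family, tolerant of
#' missing entries (every mean, variance and residual sum is taken over
#' observed entries only). Data are standardized against an overall model
#' fit that protects biological covariates; per-batch location (`gamma`)
#' and scale (`delta^2`) are estimated and shrunk towards parametric
#' empirical-Bayes priors (normal on `gamma`, inverse-gamma on `delta^2`)
#' by iterated conditional modes. After adjustment each protein's grand
#' mean over observed entries is restored exactly.
#'
#' @param pqe a [ProteinQuantExperiment-class] (log2 scale).
#' @param covariates column names of [sampleMeta()] to protect (e.g.
#'   `c("dol", "sex")`); the batch column itself is taken from
#'   `sampleMeta(pqe)$batch`.
#' @param eb use empirical-Bayes shrinkage (`FALSE` gives the direct
#'   per-batch standardization limit).
#' @param tol,max_iter convergence control for the ICM iterations.
#' @return list with `pqe` (adjusted matrix) and `model` (per-batch
#'   `gamma`/`delta2` estimates and prior hyperparameters).
#' @export
correctBatch <- function(pqe, covariates = c("dol", "sex"), eb = TRUE,
                         tol = 1e-4, max_iter = 100) {
  .assertNotImputed(pqe, "batch correction")
  meta <- sampleMeta(pqe)
  meta$dol <- factor(meta$dol)
  batch <- factor(meta$batch)
  nb <- nlevels(batch)
  Y <- lfq(pqe)
  if (nb < 2) {
    model <- list(gamma = matrix(0, nrow(Y), 1,
                                 dimnames = list(rownames(Y),
                                                 levels(batch))),
                  delta2 = matrix(1, nrow(Y), 1), hyper = NULL)
    return(list(pqe = pqe, model = model))
  }
  if (any(table(batch) < 2))
    stop("each batch needs at least 2 samples")
  B <- model.matrix(~ 0 + batch)
  covariates <- covariates[vapply(covariates, function(cn)
    length(unique(meta[[cn]])) > 1, logical(1))]
  X <- .covariateDesign(meta, covariates)
  if (!is.null(X)) {
    # reduce covariates to full rank among themselves (plus intercept),
    # then demand they stay identifiable next to the batch dummies
    fr_cov <- .fullRankColumns(cbind(`(Intercept)` = 1, X), 1)
    if (length(fr_cov$dropped))
      warning("dropping redundant covariate column(s): ",
              paste(fr_cov$dropped, collapse = ", "))
    X <- X[, intersect(colnames(X),
                       colnames(cbind(`(Intercept)` = 1,
                                      X))[fr_cov$kept]), drop = FALSE]
    if (ncol(X) == 0) X <- NULL
  }
  if (!is.null(X)) {
    fr <- .fullRankColumns(cbind(B, X), ncol(B))
    if (length(fr$dropped))
      stop("batch is confounded with the design; aliased column(s): ",
           paste(fr$dropped, collapse = ", "))
  }
  full <- cbind(B, X)
  n_batch <- as.integer(table(batch))
  w <- n_batch / ncol(Y)

  np <- nrow(Y)
  obs <- !is.na(Y)
  beta <- matrix(NA_real_, np, ncol(full))
  # per-protein OLS over observed entries (missingness patterns differ)
  for (i in seq_len(np)) {
    oi <- obs[i, ]
    fit <- stats::lm.fit(full[oi, , drop = FALSE], Y[i, oi])
    beta[i, ] <- fit$coefficients
  }
  beta[is.na(beta)] <- 0
  batch_means <- beta[, seq_len(nb), drop = FALSE]
  alpha <- as.vector(batch_means %*% w)
  cov_part <- if (is.null(X)) matrix(0, np, ncol(Y)) else
    beta[, -seq_len(nb), drop = FALSE] %*% t(X)
  fitted <- batch_means %*% t(B) + cov_part
  resid <- Y - fitted
  sigma2 <- rowSums(resid^2, na.rm = TRUE) / rowSums(obs)
  sigma2 <- pmax(sigma2, 1e-12)
  sig <- sqrt(sigma2)
  Z <- (Y - alpha - cov_part) / sig

  gamma_star <- matrix(0, np, nb, dimnames = list(rownames(Y),
                                                  levels(batch)))
  delta2_star <- matrix(1, np, nb)
  hyper <- vector("list", nb)
  for (g in seq_len(nb)) {
    sel <- batch == levels(batch)[g]
    Zg <- Z[, sel, drop = FALSE]
    n_obs <- rowSums(!is.na(Zg))
    g_hat <- rowMeans(Zg, na.rm = TRUE)
    d_hat <- apply(Zg, 1, var, na.rm = TRUE)
    # proteins with <2 observed entries in this batch stay unadjusted
    ok <- n_obs >= 2 & is.finite(g_hat) & is.finite(d_hat)
    d_hat <- pmax(d_hat, 1e-8)
    if (!eb) {
      gamma_star[ok, g] <- g_hat[ok]
      delta2_star[ok, g] <- d_hat[ok]
      next
    }
    g_bar <- mean(g_hat[ok])
    t2 <- max(var(g_hat[ok]), 1e-12)
    m_d <- mean(d_hat[ok])
    s2_d <- var(d_hat[ok])
    if (!is.finite(s2_d) || s2_d < 1e-12) {
      # degenerate scale spread: nothing to shrink against
      gamma_star[ok, g] <- g_hat[ok]
      delta2_star[ok, g] <- d_hat[ok]
      next
    }
    a_pr <- (2 * s2_d + m_d^2) / s2_d
    b_pr <- (m_d * s2_d + m_d^3) / s2_d
    hyper[[g]] <- list(gamma_bar = g_bar, tau2 = t2, a = a_pr, b = b_pr)
    g_new <- g_hat[ok]
    d_new <- d_hat[ok]
    gh <- g_hat[ok]
    no <- n_obs[ok]
    Zok <- Zg[ok, , drop = FALSE]
    for (it in seq_len(max_iter)) {
      g_old <- g_new; d_old <- d_new
      g_new <- (no * t2 * gh + d_new * g_bar) / (no * t2 + d_new)
      d_new <- (b_pr + 0.5 * rowSums((Zok - g_new)^2, na.rm = TRUE)) /
        (no / 2 + a_pr - 1)
      d_new <- pmax(d_new, 1e-8)
      if (max(abs(g_new - g_old)) + max(abs(d_new - d_old)) < tol) break
    }
    gamma_star[ok, g] <- g_new
    delta2_star[ok, g] <- d_new
  }
  Z_adj <- Z
  for (g in seq_len(nb)) {
    sel <- batch == levels(batch)[g]
    Z_adj[, sel] <- (Z[, sel, drop = FALSE] - gamma_star[, g]) /
      sqrt(delta2_star[, g])
  }
  Y_adj <- Z_adj * sig + alpha + cov_part
  # restore per-protein grand mean over observed entries
  Y_adj <- Y_adj + (rowMeans(Y, na.rm = TRUE) -
                      rowMeans(Y_adj, na.rm = TRUE))
  out <- ProteinQuantExperiment(Y_adj, sampleMeta(pqe),
                                rowData = proteinInfo(pqe),
                                ibaq = ibaq(pqe), imputed = isImputed(pqe))
  list(pqe = out,
       model = list(gamma = gamma_star, delta2 = delta2_star,
                    hyper = hyper, alpha = alpha, sigma2 = sigma2))
}

# quantile-profile ANOVA-like statistic: between/within mean squared
# deviation of per-sample quantile vectors
.quantileStat <- function(Q, grp) {
  grand <- rowMeans(Q)
  G <- nlevels(grp)
  N <- ncol(Q)
  between <- 0; within <- 0
  for (g in levels(grp)) {
    sel <- grp == g
    qg <- rowMeans(Q[, sel, drop = FALSE])
    between <- between + sum(sel) * sum((qg - grand)^2)
    within <- within + sum((Q[, sel, drop = FALSE] - qg)^2)
  }
  if (between < .Machine$double.eps * N) return(0)
  (between / (G - 1)) / (within / (N - G))
}

#' Permutation test for global distributional differences
#'
#' Tests whether the marginal intensity distributions differ between
#' groups (default: day of life) beyond sample-to-sample variability,
#' which would argue against between-group comparability or for
#' quantile-type normalization. Each sample is summarized by a vector of
#' equally spaced quantiles of its observed values; the statistic is the
#' ratio of between-group to within-group mean squared deviation of those
#' vectors, and the null distribution is built by permuting group labels.
#' The add-one permutation p-value estimator is used, so p is never 0.
#'
#' @param pqe a [ProteinQuantExperiment-class].
#' @param group column of [sampleMeta()] defining groups (default `"dol"`).
#' @param n_perm number of label permutations.
#' @param n_probes number of quantile probes per sample.
#' @param seed integer seed.
#' @return list with `statistic`, `p_value`, `n_perm`, `perm_stats`.
#' @export
testGlobalDistributions <- function(pqe, group = "dol", n_perm = 10000,
                                    n_probes = 100, seed = 1L) {
  meta <- sampleMeta(pqe)
  grp <- factor(meta[[group]])
  if (nlevels(grp) < 2) stop("need at least 2 groups")
  if (any(table(grp) < 2)) stop("every group needs at least 2 samples")
  Y <- lfq(pqe)
  probs <- seq(0, 1, length.out = n_probes)
  Q <- apply(Y, 2, quantile, probs = probs, na.rm = TRUE, names = FALSE)
  stat <- .quantileStat(Q, grp)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i)
    .quantileStat(Q, sample(grp)), numeric(1))
  p <- (1 + sum(perm >= stat)) / (1 + n_perm)
  list(statistic = stat, p_value = p, n_perm = n_perm, perm_stats = perm)
}
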