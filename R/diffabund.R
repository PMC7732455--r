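# ---- random-intercept linear mixed model, profiled maximum likelihood ----
#
# The model y = X beta + u_id + e with u ~ N(0, s2u), e ~ N(0, s2e) has
# covariance s2e * (I + rho Z Z') with rho = s2u/s2e block-diagonal in the
# participant blocks. Profiling beta and s2e leaves a 1-D likelihood in
# rho, maximized numerically; rho = 0 (the OLS boundary) is always
# evaluated so variance-zero fits fall back to ordinary least squares.

# V^{-1} v for block-diagonal V = I + rho J within id blocks
.vinv <- function(v, idx, k_per_obs, rho) {
  bs <- rowsum(v, idx)
  v - (rho / (1 + k_per_obs * rho)) * bs[idx]
}

.profileLL <- function(rho, y, X, idx, k_per_obs, kk, reml = FALSE) {
  WX <- vapply(seq_len(ncol(X)), function(j)
    .vinv(X[, j], idx, k_per_obs, rho), numeric(length(y)))
  WX <- matrix(WX, nrow = length(y))
  XtWX <- crossprod(X, WX)
  beta <- solve(XtWX, crossprod(WX, y))
  r <- y - as.vector(X %*% beta)
  rss <- max(sum(r * .vinv(r, idx, k_per_obs, rho)), 1e-300)
  n <- length(y)
  p <- ncol(X)
  logdetV <- sum(log(1 + kk * rho))
  if (reml) {
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * s2) + (n - p) + logdetV +
                    determinant(XtWX, logarithm = TRUE)$modulus)
  } else {
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) + n + logdetV)
  }
  list(ll = as.numeric(ll), beta = as.vector(beta), sigma2_e = s2,
       sigma2_u = rho * s2)
}

# scalar fit: maximize the profile likelihood over rho >= 0
.lmmFit <- function(y, X, id, reml = FALSE) {
  id <- droplevels(factor(id))
  idx <- as.integer(id)
  kk <- as.numeric(table(id))
  k <- kk[idx]
  obj <- function(lr) .profileLL(exp(lr), y, X, idx, k, kk, reml)$ll
  opt <- optimize(obj, interval = log(c(1e-8, 1e4)), maximum = TRUE,
                  tol = 1e-8)
  at0 <- .profileLL(0, y, X, idx, k, kk, reml)
  if (at0$ll >= opt$objective) at0 else
    .profileLL(exp(opt$maximum), y, X, idx, k, kk, reml)
}

# vectorized fit over many response columns sharing one design: coarse
# grid search over rho, parabolic refinement in log-rho, then one exact
# profile evaluation per protein at its selected rho
.lmmFitMatrix <- function(Y, X, id) {
  id <- droplevels(factor(id))
  idx <- as.integer(id)
  n <- nrow(Y)
  kk <- as.numeric(table(id))
  k <- kk[idx]
  Z <- model.matrix(~ 0 + id)
  lr <- seq(log(1e-6), log(1e4), length.out = 90)
  h <- lr[2] - lr[1]
  rho_grid <- c(0, exp(lr))
  P <- ncol(Y)
  best_ll <- rep(-Inf, P)
  best_idx <- rep(1L, P)
  left_ll <- rep(NA_real_, P)
  right_ll <- rep(NA_real_, P)
  ll_prev <- rep(NA_real_, P)
  for (j in seq_along(rho_grid)) {
    rho <- rho_grid[j]
    Vinv <- diag(n) - Z %*% (diag(rho / (1 + kk * rho),
                                  ncol(Z)) %*% t(Z))
    XtWX <- crossprod(X, Vinv %*% X)
    B <- solve(XtWX, crossprod(X, Vinv))
    M <- Vinv - (Vinv %*% X) %*% B
    logdetV <- sum(log(1 + kk * rho))
    rss <- pmax(colSums(Y * (M %*% Y)), 1e-300)
    ll <- -0.5 * (n * log(2 * pi * rss / n) + n + logdetV)
    was_prev <- best_idx == j - 1L
    upd <- ll > best_ll
    right_ll[was_prev & !upd] <- ll[was_prev & !upd]
    left_ll[upd] <- ll_prev[upd]
    right_ll[upd] <- NA_real_
    best_ll[upd] <- ll[upd]
    best_idx[upd] <- j
    ll_prev <- ll
  }
  out_ll <- numeric(P)
  beta <- matrix(NA_real_, ncol(X), P)
  s2e <- numeric(P)
  s2u <- numeric(P)
  for (i in seq_len(P)) {
    bi <- best_idx[i]
    rho_hat <- rho_grid[bi]
    if (bi > 2L && bi < length(rho_grid) &&
        is.finite(left_ll[i]) && is.finite(right_ll[i])) {
      den <- left_ll[i] - 2 * best_ll[i] + right_ll[i]
      if (is.finite(den) && den < 0) {
        off <- 0.5 * h * (left_ll[i] - right_ll[i]) / den
        off <- max(min(off, h), -h)
        rho_hat <- exp(lr[bi - 1L] + off)
      }
    }
    fit <- .profileLL(rho_hat, Y[, i], X, idx, k, kk)
    if (fit$ll < best_ll[i]) fit <- .profileLL(rho_grid[bi], Y[, i], X,
                                               idx, k, kk)
    out_ll[i] <- fit$ll
    beta[, i] <- fit$beta
    s2e[i] <- fit$sigma2_e
    s2u[i] <- fit$sigma2_u
  }
  list(ll = out_ll, beta = beta, sigma2_e = s2e, sigma2_u = s2u)
}

# p-value for the 1-df likelihood-ratio statistic. In the balanced
# complete-pair case the LRT is a monotone function of the paired t
# statistic, stat = n * log(1 + t^2 / (n - 1)) with n complete pairs, so
# referring the back-transformed t^2 to F(1, n-1) is exact there and a
# far better finite-sample reference in general than the asymptotic
# chi-square, whose heavy far tail inflates the realized FDR at cohort
# sizes of a few dozen pairs.
.pLRT <- function(stat, n_pairs, reference = c("f", "chisq")) {
  reference <- match.arg(reference)
  if (reference == "chisq")
    return(pchisq(stat, df = 1, lower.tail = FALSE))
  n <- pmax(n_pairs, 2)
  nu <- n - 1
  t2 <- nu * (exp(stat / n) - 1)
  stats::pf(t2, 1, nu, lower.tail = FALSE)
}

# greedy full-rank design: keep `keep_first` columns, then add covariate
# columns only while they increase the rank; returns kept column indices
.fullRankColumns <- function(X, keep_first) {
  kept <- seq_len(keep_first)
  r <- qr(X[, kept, drop = FALSE])$rank
  dropped <- character()
  for (j in setdiff(seq_len(ncol(X)), kept)) {
    r2 <- qr(X[, c(kept, j), drop = FALSE])$rank
    if (r2 > r) {
      kept <- c(kept, j)
      r <- r2
    } else dropped <- c(dropped, colnames(X)[j])
  }
  list(kept = kept, dropped = dropped)
}

#' Paired mixed-effects differential abundance for one follow-up day
#'
#' For each protein, fits a linear mixed-effects model of log2 intensity
#' on the comparison arm's samples (participants whose follow-up is at
#' `dol`): fixed effects for the day-of-life contrast plus covariates, and
#' a random participant intercept. The p-value comes from a
#' likelihood-ratio test (1 df, both models refit by maximum likelihood)
#' against the identical model without the DOL term; the reported log2
#' fold change is the DOL coefficient. Remaining missing values are
#' omitted; proteins with fewer than 2 complete pairs are marked
#' not-testable.
#'
#' @param pqe a [ProteinQuantExperiment-class] that passed valid-value
#'   filtering for this arm (never an imputed matrix).
#' @param dol follow-up day, one of 1, 3, 7.
#' @param covariates [sampleMeta()] columns used as fixed covariates
#'   (default sex and batch). Covariates aliased with the design are
#'   dropped with a warning.
#' @param engine `"profile"` (fast profiled-ML fitter; vectorized across
#'   proteins when the arm has no missing entries), `"lmer"`
#'   ([lme4::lmer()], maximum likelihood), or `"auto"` (profile).
#' @param p_reference reference distribution for the 1-df LRT statistic:
#'   `"f"` (default) back-transforms to the paired-t scale and uses
#'   F(1, pairs-1) — exact in the balanced complete-pair case and
#'   calibrated at realistic cohort sizes; `"chisq"` is the asymptotic
#'   chi-square(1).
#' @return a `DiffAbundResult` `data.frame`: `protein`, `dol`, `log2fc`
#'   (DOL coefficient), `raw_paired_lfc` (mean within-participant
#'   difference), `p_lrt`, `q_value` (`NA` until [adjustBH()]),
#'   `significant` (`NA` until [callSignificance()]), `n_used` (complete
#'   pairs), `sigma_u`, `sigma_e`.
#' @export
fitPairedLMM <- function(pqe, dol, covariates = c("sex", "batch"),
                         engine = c("auto", "profile", "lmer"),
                         p_reference = c("f", "chisq")) {
  engine <- match.arg(engine)
  p_reference <- match.arg(p_reference)
  .assertNotImputed(pqe, "differential abundance")
  dol <- as.integer(dol)
  meta <- sampleMeta(pqe)
  arm <- .armSamples(meta, dol)
  if (length(arm$participants) < 3)
    stop("arm at DOL", dol, " has fewer than 3 participants")
  sub <- pqe[, arm$idx]
  Y <- t(lfq(sub))                      # samples x proteins
  am <- sampleMeta(sub)
  x_day <- as.numeric(am$dol == dol)
  id <- factor(am$participant_id)
  Xcov <- NULL
  if (length(covariates)) {
    covariates <- covariates[vapply(covariates, function(cn)
      length(unique(am[[cn]])) > 1, logical(1))]
    if (length(covariates))
      Xcov <- .covariateDesign(am, covariates)
  }
  X_full <- cbind(`(Intercept)` = 1, dol = x_day, Xcov)
  fr <- .fullRankColumns(X_full, keep_first = 2)
  if (length(fr$dropped))
    warning("dropping covariate column(s) aliased with the design: ",
            paste(fr$dropped, collapse = ", "))
  X_full <- X_full[, fr$kept, drop = FALSE]
  X_null <- X_full[, colnames(X_full) != "dol", drop = FALSE]

  prot <- colnames(Y)
  np <- length(prot)
  # complete pairs and raw paired differences
  n_used <- integer(np)
  raw <- rep(NA_real_, np)
  d0 <- am$dol == 0L
  y0 <- Y[d0, , drop = FALSE][match(levels(id), am$participant_id[d0]), ,
                              drop = FALSE]
  yx <- Y[!d0, , drop = FALSE][match(levels(id), am$participant_id[!d0]), ,
                               drop = FALSE]
  dif <- yx - y0
  n_used <- colSums(!is.na(dif))
  raw <- colMeans(dif, na.rm = TRUE)
  raw[n_used == 0] <- NA_real_

  log2fc <- rep(NA_real_, np)
  p_lrt <- rep(NA_real_, np)
  s_u <- rep(NA_real_, np)
  s_e <- rep(NA_real_, np)
  testable <- n_used >= 2

  zero_var <- apply(Y, 2, function(v) var(v[!is.na(v)]) < 1e-12)
  complete <- colSums(is.na(Y)) == 0L
  vec <- engine != "lmer" & complete & testable & !zero_var
  if (any(vec)) {
    ff <- .lmmFitMatrix(Y[, vec, drop = FALSE], X_full, id)
    f0 <- .lmmFitMatrix(Y[, vec, drop = FALSE], X_null, id)
    stat <- pmax(0, 2 * (ff$ll - f0$ll))
    log2fc[vec] <- ff$beta[match("dol", colnames(X_full)), ]
    p_lrt[vec] <- .pLRT(stat, n_used[vec], p_reference)
    s_e[vec] <- sqrt(ff$sigma2_e)
    s_u[vec] <- sqrt(ff$sigma2_u)
  }
  log2fc[zero_var & testable] <- 0
  p_lrt[zero_var & testable] <- 1
  loop_idx <- which(testable & !zero_var & !vec)
  if (length(loop_idx)) {
    for (i in loop_idx) {
      oi <- !is.na(Y[, i])
      yi <- Y[oi, i]
      Xi <- X_full[oi, , drop = FALSE]
      fri <- .fullRankColumns(Xi, keep_first = 2)
      Xi <- Xi[, fri$kept, drop = FALSE]
      X0 <- Xi[, colnames(Xi) != "dol", drop = FALSE]
      idi <- droplevels(id[oi])
      if (engine == "lmer") {
        df_i <- data.frame(y = yi, Xi[, -1, drop = FALSE],
                           check.names = FALSE, pid = idi)
        fixed <- paste0("`", setdiff(colnames(Xi), "(Intercept)"), "`",
                        collapse = " + ")
        ffit <- lme4::lmer(stats::as.formula(
          paste("y ~", fixed, "+ (1|pid)")), data = df_i, REML = FALSE,
          control = lme4::lmerControl(check.conv.singular = "ignore"))
        nfit <- lme4::lmer(stats::as.formula(paste(
          "y ~", if (ncol(X0) > 1) paste0("`",
            setdiff(colnames(X0), "(Intercept)"), "`", collapse = " + ")
          else "1", "+ (1|pid)")), data = df_i, REML = FALSE,
          control = lme4::lmerControl(check.conv.singular = "ignore"))
        stat <- max(0, 2 * (as.numeric(logLik(ffit)) -
                              as.numeric(logLik(nfit))))
        log2fc[i] <- lme4::fixef(ffit)[["dol"]]
        vc <- as.data.frame(lme4::VarCorr(ffit))
        s_u[i] <- vc$sdcor[vc$grp == "pid"]
        s_e[i] <- vc$sdcor[vc$grp == "Residual"]
      } else {
        ffit <- .lmmFit(yi, Xi, idi)
        nfit <- .lmmFit(yi, X0, idi)
        stat <- max(0, 2 * (ffit$ll - nfit$ll))
        log2fc[i] <- ffit$beta[match("dol", colnames(Xi))]
        s_u[i] <- sqrt(ffit$sigma2_u)
        s_e[i] <- sqrt(ffit$sigma2_e)
      }
      p_lrt[i] <- .pLRT(stat, n_used[i], p_reference)
    }
  }
  log2fc[!testable] <- NA_real_
  p_lrt[!testable] <- NA_real_
  data.frame(protein = prot, dol = dol, log2fc = log2fc,
             raw_paired_lfc = raw, p_lrt = p_lrt, q_value = NA_real_,
             significant = NA, n_used = as.integer(n_used),
             sigma_u = s_u, sigma_e = s_e,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated wrapper around the standard step-up procedure:
#' `q_(i) = min_(j >= i) p_(j) * m / j` with monotonicity enforced; `NA`
#' p-values are excluded from `m` and stay `NA`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
adjustBH <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("validation error: p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Apply the dual significance gate
#'
#' A protein is called significantly differentially regulated when its
#' q-value is below `fdr` AND its |log2 fold change| exceeds `lfc`.
#' Fills `q_value` (per-day BH across proteins, unless `pool_days`) and
#' `significant`.
#'
#' @param result `DiffAbundResult` rows from [fitPairedLMM()] (possibly
#'   several days stacked).
#' @param fdr FDR threshold (default 0.05).
#' @param lfc absolute log2 fold-change threshold (default 0.2).
#' @param pool_days adjust across all days jointly instead of per day.
#' @return `result` with `q_value` and `significant` filled in.
#' @export
callSignificance <- function(result, fdr = 0.05, lfc = 0.2,
                             pool_days = FALSE) {
  if (pool_days) {
    result$q_value <- adjustBH(result$p_lrt)
  } else {
    for (d in unique(result$dol)) {
      sel <- result$dol == d
      result$q_value[sel] <- adjustBH(result$p_lrt[sel])
    }
  }
  result$significant <- !is.na(result$q_value) &
    result$q_value < fdr & abs(result$log2fc) > lfc
  result
}

#' Fisher's exact missingness analysis
#'
#' Complements the valid-value-filtered differential test: run on the
#' matrix *prior* to valid-value filtering (flags removed), it asks per
#' protein whether detection itself differs between DOL0 and the
#' follow-up day, via a two-sided exact test on the 2x2
#' detected/undetected table for the comparison arm. This recovers
#' DOL-unique proteins that strict filtering would discard.
#'
#' @param pqe pre-filter [ProteinQuantExperiment-class] (flags removed,
#'   valid-value filter NOT applied).
#' @param dol follow-up day, one of 1, 3, 7.
#' @return `data.frame`: per protein the table cells (`det_dol0`,
#'   `n_dol0`, `det_dolx`, `n_dolx`) and the two-sided `p_fisher`.
#' @export
fisherMissingness <- function(pqe, dol) {
  .assertNotImputed(pqe, "missingness analysis")
  dol <- as.integer(dol)
  meta <- sampleMeta(pqe)
  arm <- .armSamples(meta, dol)
  sub <- pqe[, arm$idx]
  m <- lfq(sub)
  d <- sampleMeta(sub)$dol
  n0 <- sum(d == 0L)
  nx <- sum(d == dol)
  det0 <- rowSums(!is.na(m[, d == 0L, drop = FALSE]))
  detx <- rowSums(!is.na(m[, d == dol, drop = FALSE]))
  key <- paste(det0, detx)
  p_by_key <- vapply(unique(key), function(k) {
    ab <- as.integer(strsplit(k, " ")[[1]])
    tab <- matrix(c(ab[1], n0 - ab[1], ab[2], nx - ab[2]), 2)
    fisher.test(tab)$p.value
  }, numeric(1))
  data.frame(protein = rownames(m), dol = dol,
             det_dol0 = as.integer(det0), n_dol0 = n0,
             det_dolx = as.integer(detx), n_dolx = nx,
             p_fisher = unname(p_by_key[key]),
             stringsAsFactors = FALSE, row.names = NULL)
}
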