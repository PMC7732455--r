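#' Left-censored Gaussian imputation for ordination
#'
#' Replaces missing entries with draws that simulate signals from
#' low-abundance proteins, in the QRILC style: per sample, the mean and
#' standard deviation of the complete (uncensored) intensity distribution
#' are estimated by regressing the observed order statistics on standard
#' normal quantiles with censoring-aware plotting positions (the missing
#' fraction occupies the lower tail); each missing value is then drawn
#' from a normal with that mean and `sd * tune_sigma`, truncated above at
#' the fitted distribution's `q`-quantile. Observed values are never
#' modified, and the result is flagged so that statistical stages refuse
#' it ([isImputed()]).
#'
#' @param pqe a [ProteinQuantExperiment-class] on log2 scale.
#' @param q tail quantile bounding the imputed values from above.
#' @param tune_sigma shrink factor on the fitted standard deviation.
#' @param seed integer seed; draws are reproducible.
#' @return an imputed `ProteinQuantExperiment` with `imputed = TRUE`.
#' @export
imputeLeftCensored <- function(pqe, q = 0.01, tune_sigma = 0.3, seed = 1L) {
  stopifnot(q > 0, q < 1, tune_sigma > 0)
  Y <- lfq(pqe)
  if (!anyNA(Y)) {
    out <- ProteinQuantExperiment(Y, sampleMeta(pqe),
                                  rowData = proteinInfo(pqe),
                                  ibaq = ibaq(pqe), imputed = TRUE)
    return(out)
  }
  set.seed(seed)
  n_tot <- nrow(Y)
  for (s in seq_len(ncol(Y))) {
    ys <- Y[, s]
    miss <- is.na(ys)
    n_obs <- sum(!miss)
    if (!any(miss)) next
    if (n_obs < 10)
      stop("sample '", colnames(Y)[s], "' has fewer than 10 observed ",
           "values; censored-normal fit is unstable")
    srt <- sort(ys[!miss])
    # plotting positions assuming the missing entries fill the lower tail
    pp <- (sum(miss) + seq_len(n_obs) - 0.5) / n_tot
    fit <- stats::lm.fit(cbind(1, qnorm(pp)), srt)
    mu <- fit$coefficients[1]
    sdev <- max(fit$coefficients[2], 1e-8)
    upper <- mu + sdev * qnorm(q)
    sd_draw <- sdev * tune_sigma
    # inverse-CDF draw from N(mu, sd_draw) truncated above at `upper`
    # exact inverse-CDF sampling, in log space for far-tail stability
    log_pmax <- pnorm((upper - mu) / sd_draw, log.p = TRUE)
    log_u <- log(runif(sum(miss))) + log_pmax
    Y[miss, s] <- mu + sd_draw * qnorm(log_u, log.p = TRUE)
  }
  ProteinQuantExperiment(Y, sampleMeta(pqe), rowData = proteinInfo(pqe),
                         ibaq = ibaq(pqe), imputed = TRUE)
}

#' Principal component analysis of a complete intensity matrix
#'
#' Protein-wise mean-centered PCA via singular value decomposition;
#' intensities are left on their common log2 scale by default (no
#' unit-variance scaling).
#'
#' @param pqe a complete (imputed) [ProteinQuantExperiment-class].
#' @param n_components number of components to return.
#' @param center,scale. passed to [stats::prcomp()]; centering is per
#'   protein.
#' @return list with `scores` (samples x components), `loadings`
#'   (proteins x components) and `explained_variance_fraction`.
#' @export
runPCA <- function(pqe, n_components = 5, center = TRUE, scale. = FALSE) {
  Y <- lfq(pqe)
  if (anyNA(Y))
    stop("matrix has missing entries; run imputeLeftCensored() first")
  pc <- prcomp(t(Y), center = center, scale. = scale.)
  k <- min(n_components, ncol(pc$x))
  ev <- pc$sdev^2
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained_variance_fraction = (ev / sum(ev))[seq_len(k)])
}
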