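#' Per-participant change versus DOL0
#'
#' Builds the trajectory matrix Delta = log2(intensity at follow-up) -
#' log2(intensity at the same participant's DOL0 sample), one column per
#' follow-up sample, `NA` wherever either endpoint is missing.
#' Participants without a DOL0 sample are excluded with a warning.
#'
#' @param pqe a [ProteinQuantExperiment-class] (unimputed).
#' @return list with `delta` (proteins x follow-up samples), `meta`
#'   (annotation of the follow-up samples, including `days` elapsed).
#' @export
computeChanges <- function(pqe) {
  .assertNotImputed(pqe, "trajectory computation")
  meta <- sampleMeta(pqe)
  m <- lfq(pqe)
  f_idx <- which(meta$dol > 0L)
  base_col <- match(meta$participant_id[f_idx],
                    meta$participant_id[meta$dol == 0L])
  no_base <- is.na(base_col)
  if (any(no_base)) {
    warning("excluding participant(s) without DOL0 sample: ",
            paste(meta$participant_id[f_idx][no_base], collapse = ", "))
    f_idx <- f_idx[!no_base]
    base_col <- base_col[!no_base]
  }
  b_idx <- which(meta$dol == 0L)[base_col]
  delta <- m[, f_idx, drop = FALSE] - m[, b_idx, drop = FALSE]
  colnames(delta) <- meta$sample_id[f_idx]
  fmeta <- meta[f_idx, , drop = FALSE]
  fmeta$days <- fmeta$dol
  rownames(fmeta) <- NULL
  list(delta = delta, meta = fmeta)
}

# Pearson correlation with exact t-transform p-value
.corTest <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0)
    return(c(r = NA_real_, p = NA_real_, n = n))
  r <- cor(x[ok], y[ok])
  tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
  p <- 2 * pt(-abs(tt), df = n - 2)
  c(r = r, p = p, n = n)
}

#' Clustered protein-protein correlation matrix of changes
#'
#' Pairwise-complete Pearson correlations between protein trajectories
#' (rows of the Delta matrix), with entries backed by fewer than
#' `min_pairs` complete pairs marked undefined, and average-linkage
#' hierarchical clustering on distance 1 - R (undefined distances set to
#' the maximum, 2). Leaf order is deterministic (ties broken by index
#' order).
#'
#' @param traj result of [computeChanges()].
#' @param min_pairs minimum complete pairs per correlation.
#' @return list with `r` (symmetric correlation matrix), `n_pairs`,
#'   `order` (leaf order), `hclust`.
#' @export
correlationMatrix <- function(traj, min_pairs = 6) {
  D <- traj$delta
  obs <- !is.na(D)
  npair <- obs %*% t(obs)
  R <- suppressWarnings(cor(t(D), use = "pairwise.complete.obs"))
  R[npair < min_pairs] <- NA
  diag(R) <- 1
  dmat <- 1 - R
  dmat[is.na(dmat)] <- 2
  hc <- hclust(as.dist(dmat), method = "average")
  list(r = R, n_pairs = npair, order = hc$order, hclust = hc)
}

#' Correlation screen against one target protein
#'
#' Correlates every protein's change trajectory against the target
#' protein's (pairwise-complete Pearson, two-sided p from the exact
#' t-transform) and returns proteins with p below `alpha`, sorted by R
#' descending. p-values are intentionally not multiple-testing corrected.
#'
#' @param traj result of [computeChanges()].
#' @param target_protein row name of the target.
#' @param alpha retention threshold on the raw p-value.
#' @return `data.frame` with `protein`, `r`, `p`, `n_pairs`.
#' @export
screenAgainst <- function(traj, target_protein, alpha = 0.05) {
  D <- traj$delta
  if (!target_protein %in% rownames(D))
    stop("target protein '", target_protein,
         "' absent from trajectory matrix")
  tv <- D[target_protein, ]
  res <- t(apply(D, 1, .corTest, y = tv))
  out <- data.frame(protein = rownames(D), r = res[, "r"], p = res[, "p"],
                    n_pairs = as.integer(res[, "n"]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[!is.na(out$p) & out$p < alpha, , drop = FALSE]
  out[order(-out$r), , drop = FALSE]
}
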