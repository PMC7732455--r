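#' Median-of-ratios normalization of RNA counts
#'
#' Size factors are the per-sample medians of count ratios against the
#' geometric-mean reference gene profile (genes with a zero count in any
#' sample are excluded from the reference); normalized values are
#' `log2(count / size_factor + 1)`.
#'
#' @param counts integer gene-by-sample count matrix.
#' @return list with `log2` (normalized matrix) and `size_factors`.
#' @export
normalizeCounts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(colSums(counts) == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  logmeans <- rowMeans(log(counts))
  use <- is.finite(logmeans)
  if (!any(use))
    stop("no gene is observed in every sample; cannot form the reference")
  sf <- apply(counts, 2, function(col)
    exp(median(log(col[use]) - logmeans[use])))
  norm <- log2(sweep(counts, 2, sf, "/") + 1)
  list(log2 = norm, size_factors = sf)
}

#' Gene-level change versus DOL0
#'
#' Mirrors [computeChanges()] on normalized log2 RNA values: per
#' follow-up sample, the change against the same participant's DOL0.
#'
#' @param norm_log2 normalized log2 matrix from [normalizeCounts()].
#' @param meta sample metadata (paired design, validated).
#' @return list with `delta` (genes x follow-up samples) and `meta`.
#' @export
rnaChanges <- function(norm_log2, meta) {
  validateSampleMeta(meta)
  meta <- meta[match(colnames(norm_log2), meta$sample_id), , drop = FALSE]
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
  delta <- norm_log2[, f_idx, drop = FALSE] -
    norm_log2[, b_idx, drop = FALSE]
  colnames(delta) <- meta$sample_id[f_idx]
  fmeta <- meta[f_idx, , drop = FALSE]
  fmeta$days <- fmeta$dol
  rownames(fmeta) <- NULL
  list(delta = delta, meta = fmeta)
}

#' Protein-mRNA concordance of change trajectories
#'
#' For each gene-protein pair, correlates change-vs-DOL0 at two levels:
#' across individual matched follow-up samples (`r_individual`, with an
#' exact-t p-value), and across the three per-DOL mean changes
#' (`r_dol_average`). Classification as concordant uses the DOL-average
#' correlation against `threshold`; with only three points that
#' correlation is unstable, which the output flags in `n_dol_points`
#' rather than attaching a p-value.
#'
#' @param protein_traj result of [computeChanges()].
#' @param rna_traj result of [rnaChanges()].
#' @param pairs `data.frame` with columns `gene` and `protein`.
#' @param threshold concordance threshold on the DOL-average R.
#' @return `ConcordanceResult` `data.frame`.
#' @export
concordance <- function(protein_traj, rna_traj, pairs, threshold = 0.3) {
  shared <- intersect(colnames(protein_traj$delta),
                      colnames(rna_traj$delta))
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$gene[i]; p <- pairs$protein[i]
    if (!g %in% rownames(rna_traj$delta) ||
        !p %in% rownames(protein_traj$delta)) next
    pv <- protein_traj$delta[p, shared]
    gv <- rna_traj$delta[g, shared]
    ok <- !is.na(pv) & !is.na(gv)
    if (sum(ok) < 3) {
      warning("pair ", g, "/", p, " has fewer than 3 shared samples; ",
              "skipped")
      next
    }
    ind <- .corTest(pv, gv)
    dols <- protein_traj$meta$dol[match(shared,
                                        protein_traj$meta$sample_id)]
    pm <- tapply(pv[ok], dols[ok], mean)
    gm <- tapply(gv[ok], dols[ok], mean)
    r_avg <- if (length(pm) >= 2 && sd(pm) > 0 && sd(gm) > 0)
      cor(pm, gm) else NA_real_
    out[[length(out) + 1]] <- data.frame(
      gene = g, protein = p,
      r_individual = ind[["r"]], p_individual = ind[["p"]],
      r_dol_average = r_avg,
      concordant = !is.na(r_avg) & r_avg > threshold,
      n_pairs = as.integer(ind[["n"]]),
      n_dol_points = length(pm),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene = character(), protein = character(),
                      r_individual = numeric(), p_individual = numeric(),
                      r_dol_average = numeric(), concordant = logical(),
                      n_pairs = integer(), n_dol_points = integer()))
  do.call(rbind, out)
}
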