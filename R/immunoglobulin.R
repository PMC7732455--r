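#' Per-sample immunoglobulin iBAQ panel and subclass ratios
#'
#' Extracts linear-scale iBAQ values for the immunoglobulin genes and
#' forms per-sample subclass ratios normalized to a reference subclass
#' (default IgG2, which compensates for differing experimental designs
#' when comparing against an external cohort). iBAQ values should derive
#' from unique peptides only; protein rows are located by gene name with
#' a user-overridable mapping.
#'
#' @param pqe a [ProteinQuantExperiment-class] carrying an `ibaq` assay.
#' @param ref reference subclass gene (default `"IGHG2"`).
#' @param genes Ig genes to extract.
#' @return list with `ibaq` (samples x genes, linear scale), `ratios`
#'   (samples x genes, each gene divided by the reference; reference
#'   column identically 1 where defined), `meta`, `ref`.
#' @export
computeIgRatios <- function(pqe, ref = "IGHG2",
                            genes = c("IGHG1", "IGHG2", "IGHG3", "IGHG4",
                                      "IGHM", "JCHAIN")) {
  ib <- ibaq(pqe)
  if (is.null(ib)) stop("matrix carries no iBAQ assay")
  gn <- proteinInfo(pqe)$gene_name
  idx <- match(genes, gn)
  found <- genes[!is.na(idx)]
  if (!ref %in% found) stop("reference subclass '", ref, "' not found")
  if (!all(c("IGHG1", "IGHG2", "IGHG3", "IGHG4") %in% found))
    stop("all four IgG subclass rows (IGHG1-IGHG4) must be present")
  panel <- t(ib[idx[!is.na(idx)], , drop = FALSE])
  colnames(panel) <- found
  refv <- panel[, ref]
  if (anyNA(refv))
    message("reference subclass missing in ", sum(is.na(refv)),
            " sample(s); their ratios are undefined")
  ratios <- panel / refv
  list(ibaq = panel, ratios = ratios, meta = sampleMeta(pqe), ref = ref)
}

#' Compare subclass ratios between two panels
#'
#' Welch two-sample t-test per subclass ratio, e.g. newborn versus an
#' adult reference panel.
#'
#' @param panel_a,panel_b results of [computeIgRatios()], or matrices of
#'   per-sample ratios with subclasses in columns.
#' @return `data.frame` per subclass: group means, Welch `t`, `p`.
#' @export
compareIgRatios <- function(panel_a, panel_b) {
  ra <- if (is.list(panel_a)) panel_a$ratios else as.matrix(panel_a)
  rb <- if (is.list(panel_b)) panel_b$ratios else as.matrix(panel_b)
  shared <- intersect(colnames(ra), colnames(rb))
  out <- do.call(rbind, lapply(shared, function(g) {
    a <- ra[, g]; b <- rb[, g]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2)
      stop("need at least 2 samples per group for subclass ", g)
    if (sd(a) == 0 && sd(b) == 0) {
      return(data.frame(subclass = g, mean_a = mean(a), mean_b = mean(b),
                        t = 0, p = 1, stringsAsFactors = FALSE))
    }
    tt <- t.test(a, b)
    data.frame(subclass = g, mean_a = mean(a), mean_b = mean(b),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Apparent plasma half-life from paired log2 changes
#'
#' Under first-order decay, `C(t) = C(0) * 2^(-t / t_half)`, so the
#' participant-level paired change satisfies `Delta(t) = -t / t_half` on
#' log2 scale with `Delta(0) = 0` by construction. The slope `k` is
#' estimated by zero-intercept least squares of the paired Delta values on
#' elapsed days, and `t_half = -1/k`. A non-negative slope is flagged as
#' no measurable decay (`t_half = Inf`). The confidence interval comes
#' from a nonparametric bootstrap over participants.
#'
#' @param traj result of [computeChanges()].
#' @param protein row name of the protein (e.g. the IGHG1 group).
#' @param boot_n bootstrap resamples (0 disables the interval).
#' @param conf confidence level.
#' @param seed integer seed for the bootstrap.
#' @return list with `slope` (log2/day), `t_half` (days), `ci` (days),
#'   `n_pairs`, `single_day` flag.
#' @export
estimateHalfLife <- function(traj, protein, boot_n = 2000, conf = 0.95,
                             seed = 1L) {
  if (!protein %in% rownames(traj$delta))
    stop("protein '", protein, "' absent from trajectory matrix")
  d <- traj$delta[protein, ]
  t <- traj$meta$days
  ok <- !is.na(d)
  d <- d[ok]; t <- t[ok]
  if (length(d) < 3) stop("need at least 3 paired changes")
  single_day <- length(unique(t)) < 2
  if (single_day)
    warning("all changes at a single follow-up day; the slope relies ",
            "entirely on the origin constraint")
  slope <- sum(t * d) / sum(t * t)
  t_half <- if (slope < 0) -1 / slope else Inf
  ci <- c(NA_real_, NA_real_)
  if (boot_n > 0) {
    set.seed(seed)
    n <- length(d)
    bs <- vapply(seq_len(boot_n), function(b) {
      ii <- sample.int(n, n, replace = TRUE)
      s <- sum(t[ii] * d[ii]) / sum(t[ii]^2)
      if (s < 0) -1 / s else Inf
    }, numeric(1))
    ci <- unname(quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE))
  }
  list(slope = slope, t_half = t_half, ci = ci, n_pairs = length(d),
       single_day = single_day)
}

#' Project a plasma concentration through a fold-change interval
#'
#' Multiplies a baseline concentration by a linear fold change (or an
#' interval of fold changes), e.g. projecting a DOL7 IgM concentration
#' from the average DOL0 level.
#'
#' @param baseline_conc baseline concentration (e.g. mg/dl), positive.
#' @param fold_change linear fold change, scalar or interval bounds.
#' @return projected concentration(s), same units as `baseline_conc`.
#' @export
projectConcentration <- function(baseline_conc, fold_change) {
  if (any(baseline_conc <= 0) || any(fold_change <= 0))
    stop("baseline and fold change must be positive")
  baseline_conc * fold_change
}

#' Pearson correlation between two proteins' change trajectories
#'
#' @param traj result of [computeChanges()].
#' @param protein_a,protein_b row names of the two proteins.
#' @return list with `r`, `p` (exact t-transform, two-sided), `n_pairs`;
#'   `r` is `NA` with a message for degenerate (zero-variance) input.
#' @export
correlatePair <- function(traj, protein_a, protein_b) {
  D <- traj$delta
  for (p in c(protein_a, protein_b))
    if (!p %in% rownames(D))
      stop("protein '", p, "' absent from trajectory matrix")
  res <- .corTest(D[protein_a, ], D[protein_b, ])
  if (res[["n"]] < 3)
    stop("need at least 3 complete pairs")
  if (is.na(res[["r"]]))
    message("degenerate (zero-variance) trajectories; R undefined")
  list(r = res[["r"]], p = res[["p"]], n_pairs = as.integer(res[["n"]]))
}
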