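#' Configuration for the synthetic paired cohort generator
#'
#' Builds the parameter set of [generateCohort()]. Defaults emulate the
#' study design the pipeline targets: 30 newborns, each with a DOL0
#' baseline and exactly one follow-up sample at DOL 1, 3 or 7 (10
#' participants per follow-up day, 60 samples), ~200 quantifiable plasma
#' proteins with log-normal LFQ intensities, participant random effects,
#' day-of-life trajectory classes, two batches with location/scale effects,
#' intensity-dependent left-censored missingness, an immunoglobulin panel
#' with maternal IgG decay and IgM/J-chain growth, and RNA counts with
#' tunable protein-mRNA concordance.
#'
#' @param n_participants number of participants.
#' @param followup_split integer triple: participants with follow-up at
#'   DOL 1, 3 and 7; must sum to `n_participants`.
#' @param n_proteins number of (non-immunoglobulin) proteins.
#' @param trajectory_classes named list over classes `flat`, `increasing`,
#'   `decreasing`, `acute_dol1`; each element a list with `fraction` and,
#'   for non-flat classes, `lfc_range` (magnitude of the log2 fold change
#'   reached at DOL7, or at DOL1 for the acute class).
#' @param subject_sd,residual_sd participant random-effect and residual
#'   standard deviations, log2 units.
#' @param sex_effect additive log2 shift for male samples (default 0).
#' @param baseline_mean,baseline_sd distribution of per-protein log2
#'   baseline intensity.
#' @param batch_effects `data.frame` with columns `shift` (additive log2
#'   location per batch) and `scale` (multiplier on the residual standard
#'   deviation); one row per batch. Samples are assigned to batches in a
#'   balanced rotation.
#' @param censor_quantile,censor_steepness MNAR left-censoring: an entry
#'   goes missing with probability `plogis(steepness * (tau - y))` where
#'   `tau` is the `censor_quantile` of all intensities. Set
#'   `censor_quantile = 0` to disable.
#' @param ig_panel `data.frame` describing the immunoglobulin panel, with
#'   columns `gene`, `baseline_ibaq`, `half_life_days` (`Inf` for
#'   non-decaying), `growth` (log2 units/day), `synthesis` (additive log2
#'   units/day on top of decay) and `couple_to` (gene whose per-participant
#'   latent growth rate is shared; `NA` for none). Set to `NULL` to omit
#'   the panel.
#' @param ig_subject_sd,ig_residual_sd,growth_sd variability of the Ig
#'   panel: participant baseline spread, residual noise, and
#'   between-participant spread of latent growth rates.
#' @param n_genes number of RNA genes (0 disables the RNA arm).
#' @param rna_target_r per-gene target protein-mRNA concordance
#'   correlations at the DOL-average level (recycled to `n_genes`);
#'   defaults mix strongly concordant and near-null genes.
#' @param rna_base_mean,rna_nb_size negative-binomial mean and size
#'   (dispersion) for counts.
#' @param gene_amp amplitude (log2) of the engineered gene trajectory.
#' @param seed integer seed fixing all randomness.
#' @return object of class `simConfig` (a validated list).
#' @export
simConfig <- function(n_participants = 30,
                      followup_split = c(10, 10, 10),
                      n_proteins = 200,
                      trajectory_classes = list(
                        flat = list(fraction = 0.70),
                        increasing = list(fraction = 0.10,
                                          lfc_range = c(0.2, 1.5)),
                        decreasing = list(fraction = 0.10,
                                          lfc_range = c(0.2, 1.5)),
                        acute_dol1 = list(fraction = 0.10,
                                          lfc_range = c(0.2, 1.5))),
                      subject_sd = 0.5,
                      residual_sd = 0.3,
                      sex_effect = 0,
                      baseline_mean = 25,
                      baseline_sd = 2,
                      batch_effects = data.frame(shift = c(0, 0.4),
                                                 scale = c(1, 1.25)),
                      censor_quantile = 0.15,
                      censor_steepness = 2,
                      ig_panel = defaultIgPanel(),
                      ig_subject_sd = 0.4,
                      ig_residual_sd = 0.2,
                      growth_sd = 0.05,
                      n_genes = 30,
                      rna_target_r = c(0.88, 0.86, 0.90, 0.85, 0.74, 0.79,
                                       0.49,
                                       seq(-0.4, 0.1, length.out = 23)),
                      rna_base_mean = 500,
                      rna_nb_size = 50,
                      gene_amp = 1,
                      seed = 1L) {
  cfg <- as.list(environment())
  fr <- vapply(cfg$trajectory_classes, function(z) z$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-8)
    stop("config error: trajectory class fractions must sum to 1")
  if (length(cfg$followup_split) != 3 ||
      sum(cfg$followup_split) != cfg$n_participants)
    stop("config error: followup_split must be 3 counts summing to ",
         "n_participants")
  if (cfg$residual_sd < 0 || cfg$subject_sd < 0)
    stop("config error: standard deviations must be non-negative")
  if (!is.null(cfg$ig_panel) && any(cfg$ig_panel$half_life_days <= 0))
    stop("config error: half_life_days must be positive")
  if (cfg$n_genes > 0 &&
      any(abs(rep_len(cfg$rna_target_r, cfg$n_genes)) > 1))
    stop("config error: infeasible concordance target (|R| > 1)")
  class(cfg) <- "simConfig"
  cfg
}

#' Default immunoglobulin panel specification
#'
#' Maternal IgG1-4 decay first-order with subclass-specific half-lives
#' (IgG1 at the apparent 21.1 d observed in neonatal plasma; IgG3 much
#' shorter), with no endogenous IgG synthesis in the first week; IgM and
#' J chain grow, sharing a per-participant latent growth rate so their
#' trajectories correlate.
#'
#' @return `data.frame` consumed by [simConfig()]'s `ig_panel`.
#' @export
defaultIgPanel <- function() {
  data.frame(
    gene = c("IGHG1", "IGHG2", "IGHG3", "IGHG4", "IGHM", "JCHAIN"),
    baseline_ibaq = c(5e9, 1e9, 5e8, 2.5e8, 8e8, 2e8),
    half_life_days = c(21.1, 28, 7.1, 21, Inf, Inf),
    growth = c(0, 0, 0, 0, 0.17, 0.17),
    synthesis = c(0, 0, 0, 0, 0, 0),
    couple_to = c(NA, NA, NA, NA, NA, "IGHM"),
    stringsAsFactors = FALSE)
}

# per-class log2FC profile at DOL 1, 3, 7
.classProfile <- function(class, theta) {
  switch(class,
         flat = c(0, 0, 0),
         increasing = theta * c(1, 3, 7) / 7,
         decreasing = -theta * c(1, 3, 7) / 7,
         acute_dol1 = c(theta, theta / 4, 0),
         stop("unknown trajectory class: ", class))
}

#' Generate a synthetic paired cohort with known ground truth
#'
#' Simulates log2 LFQ intensities as
#' `baseline + subject effect + class-specific DOL effect + sex effect +
#' batch location + batch-scaled residual noise`, then censors entries to
#' missing with probability `logistic(steepness * (threshold - intensity))`
#' (intensity-dependent, MNAR). The immunoglobulin panel follows
#' `C(t) = C(0) * 2^(-t / t_half)` for decaying species (optionally plus a
#' linear-in-log2 synthesis term) and linear-in-log2 growth for IgM and
#' J chain. RNA counts are drawn negative-binomially around means
#' engineered so that each gene's DOL-average change correlates with its
#' partner protein's change at the configured target correlation.
#'
#' @param config a [simConfig()].
#' @return list with elements `pqe` ([ProteinQuantExperiment-class] with
#'   `lfq` and `ibaq` assays), `rna_counts` (integer matrix or `NULL`),
#'   `meta` (sample table) and `truth` (ground-truth sidecar: per-protein
#'   class and true log2FC per DOL, batch effects, Ig kinetics, per-gene
#'   target concordance and gene-protein map, censor threshold).
#' @export
generateCohort <- function(config = simConfig()) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  fdays <- c(1L, 3L, 7L)
  pid <- sprintf("P%03d", seq_len(config$n_participants))
  fup <- rep(fdays, times = config$followup_split)
  meta <- data.frame(
    sample_id = c(paste0(pid, "_D0"), paste0(pid, "_D", fup)),
    participant_id = c(pid, pid),
    dol = c(rep(0L, length(pid)), fup),
    stringsAsFactors = FALSE)
  sex <- setNames(sample(c("F", "M"), length(pid), replace = TRUE), pid)
  meta$sex <- unname(sex[meta$participant_id])
  nb <- nrow(config$batch_effects)
  meta <- meta[order(meta$participant_id, meta$dol), ]
  # balanced batch rotation within each DOL group, so batch is never
  # confounded with day of life
  meta$batch <- NA_character_
  for (d in unique(meta$dol)) {
    sel <- meta$dol == d
    meta$batch[sel] <- paste0("B", rep_len(seq_len(nb), sum(sel)))
  }
  meta$cohort <- "synthetic"
  rownames(meta) <- NULL

  np <- config$n_proteins
  cls_names <- names(config$trajectory_classes)
  frac <- vapply(config$trajectory_classes, function(z) z$fraction,
                 numeric(1))
  n_per <- floor(np * frac)
  n_per[1] <- np - sum(n_per[-1])
  classes <- rep(cls_names, times = n_per)
  theta <- vapply(seq_len(np), function(i) {
    cl <- config$trajectory_classes[[classes[i]]]
    if (is.null(cl$lfc_range)) 0 else runif(1, cl$lfc_range[1],
                                            cl$lfc_range[2])
  }, numeric(1))
  profiles <- t(vapply(seq_len(np),
                       function(i) .classProfile(classes[i], theta[i]),
                       numeric(3)))
  colnames(profiles) <- paste0("lfc_dol", fdays)
  baseline <- rnorm(np, config$baseline_mean, config$baseline_sd)
  u <- matrix(rnorm(np * length(pid), 0, config$subject_sd), np,
              dimnames = list(NULL, pid))

  ns <- nrow(meta)
  bidx <- match(meta$batch, paste0("B", seq_len(nb)))
  shift <- config$batch_effects$shift[bidx]
  scl <- config$batch_effects$scale[bidx]
  day_col <- match(meta$dol, fdays)          # NA for DOL0
  eff <- matrix(0, np, ns)
  has_f <- !is.na(day_col)
  eff[, has_f] <- profiles[, day_col[has_f], drop = FALSE]
  y <- baseline + u[, meta$participant_id, drop = FALSE] + eff +
    matrix(rep(config$sex_effect * (meta$sex == "M") + shift, each = np),
           np, ns) +
    matrix(rnorm(np * ns, 0, config$residual_sd), np, ns) *
      matrix(rep(scl, each = np), np, ns)
  colnames(y) <- meta$sample_id
  rownames(y) <- sprintf("SP%04d", seq_len(np))

  censor_threshold <- NA_real_
  if (config$censor_quantile > 0) {
    censor_threshold <- quantile(y, config$censor_quantile, names = FALSE)
    pmiss <- plogis(config$censor_steepness * (censor_threshold - y))
    y[matrix(runif(length(y)), np, ns) < pmiss] <- NA
  }

  # immunoglobulin panel (iBAQ-scale kinetics, appended as extra rows)
  ig <- config$ig_panel
  ig_lfq <- NULL
  ig_ibaq <- NULL
  if (!is.null(ig) && nrow(ig)) {
    t_s <- meta$dol
    lam <- matrix(NA_real_, nrow(ig), length(pid),
                  dimnames = list(ig$gene, pid))
    for (g in seq_len(nrow(ig)))
      lam[g, ] <- rnorm(length(pid), ig$growth[g], config$growth_sd)
    for (g in which(!is.na(ig$couple_to)))
      lam[g, ] <- lam[ig$couple_to[g], ] + ig$growth[g] - ig$growth[
        match(ig$couple_to[g], ig$gene)]
    ui <- matrix(rnorm(nrow(ig) * length(pid), 0, config$ig_subject_sd),
                 nrow(ig), dimnames = list(NULL, pid))
    ig_lfq <- matrix(NA_real_, nrow(ig), ns,
                     dimnames = list(ig$gene, meta$sample_id))
    for (g in seq_len(nrow(ig))) {
      decay <- if (is.finite(ig$half_life_days[g]))
        -t_s / ig$half_life_days[g] + ig$synthesis[g] * t_s else
          lam[g, meta$participant_id] * t_s
      ig_lfq[g, ] <- log2(ig$baseline_ibaq[g]) +
        ui[g, meta$participant_id] + decay +
        rnorm(ns, 0, config$ig_residual_sd)
    }
    ig_ibaq <- 2^ig_lfq
  }

  lfq_all <- rbind(y, ig_lfq)
  ibaq_all <- rbind(matrix(NA_real_, np, ns), ig_ibaq)
  dimnames(ibaq_all) <- dimnames(lfq_all)
  rd <- data.frame(
    protein_group_id = rownames(lfq_all),
    gene_name = c(rep(NA_character_, np),
                  if (is.null(ig_lfq)) NULL else ig$gene),
    is_reverse = FALSE, is_contaminant = FALSE,
    only_modified_site = FALSE,
    unique_peptides = 2L,
    stringsAsFactors = FALSE)
  pqe <- ProteinQuantExperiment(lfq_all, meta, rowData = rd,
                                ibaq = ibaq_all)

  # RNA: engineer DOL-average concordance with partner proteins
  rna_counts <- NULL
  rna_truth <- NULL
  if (config$n_genes > 0) {
    targ <- rep_len(config$rna_target_r, config$n_genes)
    nonflat <- which(classes != "flat")
    partner <- rep_len(c(nonflat, which(classes == "flat")),
                       config$n_genes)
    gmu <- matrix(NA_real_, config$n_genes, ns)
    gene_prof <- matrix(0, config$n_genes, 3)
    for (g in seq_len(config$n_genes)) {
      v <- profiles[partner[g], ]
      if (sd(v) < 1e-12) v <- c(1, 3, 7) / 7   # fallback axis for flat partners
      vs <- (v - mean(v)) / sd(v)
      e <- rnorm(3)
      e <- e - mean(e) - vs * sum(e * vs) / sum(vs * vs)
      if (sd(e) < 1e-12) e <- c(-1, 0, 1) - vs * sum(c(-1, 0, 1) * vs) /
          sum(vs * vs)
      es <- (e - mean(e)) / sd(e)
      w <- targ[g] * vs + sqrt(max(0, 1 - targ[g]^2)) * es
      gene_prof[g, ] <- w * config$gene_amp
    }
    bi <- matrix(rnorm(config$n_genes * length(pid), 0, 0.3),
                 config$n_genes, dimnames = list(NULL, pid))
    base_g <- log2(config$rna_base_mean) +
      rnorm(config$n_genes, 0, 1)
    for (s in seq_len(ns)) {
      dprof <- if (is.na(day_col[s])) 0 else gene_prof[, day_col[s]]
      gmu[, s] <- base_g + bi[, meta$participant_id[s]] + dprof
    }
    rna_counts <- matrix(
      rnbinom(length(gmu), mu = 2^gmu, size = config$rna_nb_size),
      config$n_genes, ns,
      dimnames = list(sprintf("G%04d", seq_len(config$n_genes)),
                      meta$sample_id))
    storage.mode(rna_counts) <- "integer"
    rna_truth <- data.frame(gene = rownames(rna_counts),
                            protein = rownames(y)[partner],
                            target_r = targ,
                            stringsAsFactors = FALSE)
  }

  truth <- list(
    protein = data.frame(protein = rownames(y), class = classes,
                         theta = theta, profiles,
                         stringsAsFactors = FALSE),
    batch = data.frame(batch = paste0("B", seq_len(nb)),
                       config$batch_effects, stringsAsFactors = FALSE),
    ig = if (is.null(ig)) NULL else ig,
    rna = rna_truth,
    censor_threshold = censor_threshold,
    config = config)
  list(pqe = pqe, rna_counts = rna_counts, meta = meta, truth = truth)
}

#' Append flagged contaminant/decoy rows to a matrix
#'
#' Adds rows mimicking MaxQuant's handling artefacts: potential
#' contaminants (keratin-like), reversed-decoy hits and
#' only-identified-by-site entries, with intensities resampled from the
#' observed distribution. The injected IDs are recorded in
#' `metadata(pqe)$injected` so downstream filtering can be checked against
#' the bookkeeping.
#'
#' @param pqe a [ProteinQuantExperiment-class].
#' @param n_contaminants,n_reverse,n_modified_only row counts to inject.
#' @param seed integer seed.
#' @return the augmented `ProteinQuantExperiment`.
#' @export
injectFlagRows <- function(pqe, n_contaminants = 0, n_reverse = 0,
                           n_modified_only = 0, seed = 1L) {
  set.seed(seed)
  m <- lfq(pqe)
  n_new <- n_contaminants + n_reverse + n_modified_only
  if (n_new == 0) return(pqe)
  obs <- m[!is.na(m)]
  newm <- matrix(sample(obs, n_new * ncol(m), replace = TRUE),
                 n_new, ncol(m), dimnames = list(NULL, colnames(m)))
  ids <- c(if (n_contaminants) sprintf("CON__KRT%d", seq_len(n_contaminants)),
           if (n_reverse) sprintf("REV__Q%05d", seq_len(n_reverse)),
           if (n_modified_only) sprintf("MOD__Q%05d",
                                        seq_len(n_modified_only)))
  rd_new <- data.frame(
    protein_group_id = ids,
    gene_name = NA_character_,
    is_reverse = rep(c(FALSE, TRUE, FALSE),
                     c(n_contaminants, n_reverse, n_modified_only)),
    is_contaminant = rep(c(TRUE, FALSE, FALSE),
                         c(n_contaminants, n_reverse, n_modified_only)),
    only_modified_site = rep(c(FALSE, FALSE, TRUE),
                             c(n_contaminants, n_reverse, n_modified_only)),
    unique_peptides = 1L,
    stringsAsFactors = FALSE)
  rownames(newm) <- ids
  rd <- rbind(proteinInfo(pqe)[, colnames(rd_new)], rd_new)
  lfq_all <- rbind(m, newm)
  ib <- ibaq(pqe)
  ib_all <- if (is.null(ib)) NULL else
    rbind(ib, matrix(NA_real_, n_new, ncol(m)))
  out <- ProteinQuantExperiment(lfq_all, sampleMeta(pqe), rowData = rd,
                                ibaq = ib_all, imputed = isImputed(pqe))
  S4Vectors::metadata(out)$injected <- ids
  out
}

#' Write a cohort in the MaxQuant proteinGroups dialect
#'
#' Emits the tab-separated schema read by [readProteinGroups()]: LFQ
#' intensities de-logged, missing entries serialized as 0, flags as "+",
#' iBAQ columns present iff the matrix carries an iBAQ assay.
#'
#' @param pqe a [ProteinQuantExperiment-class].
#' @param path output path.
#' @export
writeMaxQuantLike <- function(pqe, path) {
  m <- lfq(pqe)
  rd <- proteinInfo(pqe)
  lin <- 2^m
  lin[is.na(m)] <- 0
  tab <- data.frame(
    `Protein IDs` = rd$protein_group_id,
    `Gene names` = ifelse(is.na(rd$gene_name), "", rd$gene_name),
    Reverse = ifelse(rd$is_reverse, "+", ""),
    `Potential contaminant` = ifelse(rd$is_contaminant, "+", ""),
    `Only identified by site` = ifelse(rd$only_modified_site, "+", ""),
    `Razor + unique peptides` = rd$unique_peptides,
    check.names = FALSE, stringsAsFactors = FALSE)
  lfq_block <- as.data.frame(lin)
  colnames(lfq_block) <- paste0("LFQ intensity ", colnames(m))
  tab <- cbind(tab, lfq_block)
  ib <- ibaq(pqe)
  if (!is.null(ib)) {
    ibl <- ib
    ibl[is.na(ibl)] <- 0
    ib_block <- as.data.frame(ibl)
    colnames(ib_block) <- paste0("iBAQ ", colnames(m))
    tab <- cbind(tab, ib_block)
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMaxQuantLike
#' @param meta sample metadata `data.frame`.
#' @export
writeSampleMeta <- function(meta, path) {
  write.table(meta, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMaxQuantLike
#' @param counts integer gene-by-sample count matrix.
#' @export
writeRnaCounts <- function(counts, path) {
  tab <- data.frame(gene_id = rownames(counts), counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Synthetic adult immunoglobulin reference panel
#'
#' Stand-in for an external adult plasma cohort used as reference in the
#' subclass-ratio comparison: iBAQ values with the literature-like adult
#' subclass ordering IgG1 > IgG2 > IgG3 ~ IgG4 and adult-level IgM. This
#' panel is synthetic and only supports tests and examples.
#'
#' @param n number of adult reference samples.
#' @param seed integer seed.
#' @return `data.frame`: one row per sample, one column per Ig gene,
#'   linear-scale iBAQ.
#' @export
syntheticAdultIgPanel <- function(n = 30, seed = 42L) {
  set.seed(seed)
  base <- c(IGHG1 = 6e9, IGHG2 = 2.4e9, IGHG3 = 5e8, IGHG4 = 4e8,
            IGHM = 5e9, JCHAIN = 1.5e9)
  out <- vapply(base, function(b) b * 2^rnorm(n, 0, 0.4), numeric(n))
  out <- as.data.frame(out)
  out$sample_id <- sprintf("AD%03d", seq_len(n))
  out[, c("sample_id", names(base))]
}
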