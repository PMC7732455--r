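#' Pipeline configuration
#'
#' Collects every stage parameter, with defaults matching the analysis
#' conventions of the package (50% valid-value rule, q = 0.01 /
#' tune.sigma = 0.3 imputation for PCA only, 5% FDR and 0.2 log2
#' fold-change gate, 10000 permutations for the global-distribution
#' test). All randomness derives from `seed` via fixed per-stage offsets.
#'
#' @param min_fraction valid-value fraction per group.
#' @param impute_q,tune_sigma left-censored imputation parameters.
#' @param n_components principal components to report.
#' @param fdr,lfc significance gate.
#' @param n_perm permutations for the global-distribution test.
#' @param bootstrap_n bootstrap resamples for half-life intervals.
#' @param concordance_threshold DOL-average R threshold.
#' @param covariates fixed covariates of the mixed model.
#' @param run_pca,run_global_test,run_ig,run_integration stage toggles.
#' @param halflife_protein protein row used for half-life estimation
#'   (`NULL` = the row whose gene name is IGHG1).
#' @param seed root seed.
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(min_fraction = 0.5, impute_q = 0.01,
                           tune_sigma = 0.3, n_components = 5,
                           fdr = 0.05, lfc = 0.2, n_perm = 10000,
                           bootstrap_n = 2000,
                           concordance_threshold = 0.3,
                           covariates = c("sex", "batch"),
                           run_pca = TRUE, run_global_test = TRUE,
                           run_ig = TRUE, run_integration = TRUE,
                           halflife_protein = NULL, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipelineConfig()]; unknown keys are an
#' error, missing keys take the defaults.
#'
#' @param path YAML file path.
#' @return a `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipelineConfig, vals)
}

#' Run the full analysis pipeline
#'
#' Stages in dependency order: flag filtering; then two branches from the
#' flag-filtered matrix: the ordination branch (union valid-value filter,
#' left-censored imputation, PCA) and the testing branch (per-arm
#' valid-value filter, batch correction, paired mixed-model differential
#' abundance with BH correction and the dual significance gate, plus
#' Fisher missingness on the pre-filter matrix); trajectory correlations;
#' immunoglobulin ratios and IgG1 half-life; protein-mRNA concordance.
#' Imputed values never reach any statistical stage (enforced by the
#' `imputed` provenance flag).
#'
#' @param pqe a [ProteinQuantExperiment-class].
#' @param rna_counts optional gene-by-sample count matrix.
#' @param gene_protein_pairs optional `data.frame` (`gene`, `protein`)
#'   for concordance.
#' @param config a [pipelineConfig()].
#' @return list of stage results plus a `manifest` recording the config,
#'   seeds, package version and per-stage row counts.
#' @export
runPipeline <- function(pqe, rna_counts = NULL, gene_protein_pairs = NULL,
                        config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  validateSampleMeta(sampleMeta(pqe))
  res <- list()
  fl <- filterFlags(pqe)
  res$filter_report <- fl$report
  base <- fl$pqe

  if (config$run_global_test) {
    res$global_test <- testGlobalDistributions(
      base, n_perm = config$n_perm, seed = config$seed + 101L)
  }

  if (config$run_pca) {
    un <- filterValidValuesUnion(base, config$min_fraction)
    imp <- imputeLeftCensored(un$pqe, q = config$impute_q,
                              tune_sigma = config$tune_sigma,
                              seed = config$seed + 202L)
    res$pca <- runPCA(imp, n_components = config$n_components)
    res$pca_n_proteins <- nrow(un$pqe)
  }

  da <- list()
  miss <- list()
  vv_reports <- list()
  for (d in c(1L, 3L, 7L)) {
    vv <- filterValidValues(base, d, config$min_fraction)
    vv_reports[[as.character(d)]] <- vv$report
    bc <- correctBatch(vv$pqe, covariates = "dol")
    da[[as.character(d)]] <- fitPairedLMM(bc$pqe, d,
                                          covariates = config$covariates)
    miss[[as.character(d)]] <- fisherMissingness(base, d)
  }
  res$valid_value_reports <- do.call(rbind, vv_reports)
  res$diffabund <- callSignificance(do.call(rbind, da),
                                    fdr = config$fdr, lfc = config$lfc)
  res$missingness <- do.call(rbind, miss)

  traj <- computeChanges(base)
  res$trajectories <- traj
  res$correlation <- correlationMatrix(traj)

  if (config$run_ig && !is.null(ibaq(pqe))) {
    res$ig_ratios <- computeIgRatios(pqe)
    hl_protein <- config$halflife_protein
    if (is.null(hl_protein)) {
      gi <- proteinInfo(pqe)
      hl_protein <- gi$protein_group_id[match("IGHG1", gi$gene_name)]
    }
    traj_all <- computeChanges(pqe)
    if (!is.na(hl_protein))
      res$half_life <- estimateHalfLife(traj_all, hl_protein,
                                        boot_n = config$bootstrap_n,
                                        seed = config$seed + 303L)
  }

  if (config$run_integration && !is.null(rna_counts) &&
      !is.null(gene_protein_pairs)) {
    norm <- normalizeCounts(rna_counts)
    rtraj <- rnaChanges(norm$log2, sampleMeta(pqe))
    res$concordance <- concordance(computeChanges(pqe), rtraj,
                                   gene_protein_pairs,
                                   threshold = config$concordance_threshold)
  }

  res$manifest <- list(
    package_version = as.character(packageVersion("pairedLFQ")),
    config = unclass(config),
    seed = config$seed,
    n_samples = ncol(pqe),
    n_proteins_input = nrow(pqe),
    n_proteins_flag_filtered = nrow(base),
    timestamp = format(Sys.time(), tz = "UTC"))
  res
}
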