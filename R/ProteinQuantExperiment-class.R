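#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata 'metadata<-'
#' @importFrom stats coef complete.cases cor fisher.test lm median optimize
#'   pchisq plogis pnorm prcomp pt qnorm quantile rbinom rnbinom rnorm runif
#'   sd setNames t.test var model.matrix hclust as.dist p.adjust logLik anova
#'   aggregate
#' @importFrom utils read.delim write.table packageVersion head
NULL

#' Container for a protein quantification experiment
#'
#' `ProteinQuantExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment] and is the central data
#' object of the pipeline: a proteins-by-samples matrix of log2 LFQ
#' intensities (assay `"lfq"`, `NA` marking not-quantified entries),
#' optionally accompanied by a linear-scale iBAQ matrix of the same shape
#' (assay `"ibaq"`). Row metadata carries the MaxQuant quality flags
#' (`is_reverse`, `is_contaminant`, `only_modified_site`) together with
#' protein-group and gene identifiers; column metadata carries the sample
#' annotation of the paired design (`participant_id`, `dol`, `sex`,
#' `batch`, `cohort`).
#'
#' The `imputed` flag in [S4Vectors::metadata()] records whether missing
#' entries were ever filled in. Imputation is quarantined to ordination:
#' statistical stages refuse matrices with `imputed = TRUE`.
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#'
#' @seealso [readProteinGroups()], [generateCohort()], [lfq()], [ibaq()],
#'   [sampleMeta()]
#' @export
setClass("ProteinQuantExperiment",
         contains = "SummarizedExperiment")

.validPQE <- function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!"lfq" %in% an)
    msg <- c(msg, "assay 'lfq' is required")
  else {
    m <- SummarizedExperiment::assay(object, "lfq")
    if (!is.numeric(m))
      msg <- c(msg, "'lfq' assay must be numeric")
    else if (any(!is.finite(m[!is.na(m)])))
      msg <- c(msg, "all present 'lfq' values must be finite")
  }
  if ("ibaq" %in% an) {
    b <- SummarizedExperiment::assay(object, "ibaq")
    bb <- b[!is.na(b)]
    if (length(bb) && any(bb <= 0))
      msg <- c(msg, "present 'ibaq' values must be strictly positive")
  }
  rd <- SummarizedExperiment::rowData(object)
  need_rd <- c("protein_group_id", "is_reverse", "is_contaminant",
               "only_modified_site")
  miss <- setdiff(need_rd, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  if ("protein_group_id" %in% colnames(rd) &&
      any(!nzchar(as.character(rd$protein_group_id))))
    msg <- c(msg, "protein_group_id must be non-empty")
  cd <- SummarizedExperiment::colData(object)
  need_cd <- c("participant_id", "dol", "sex", "batch", "cohort")
  missc <- setdiff(need_cd, colnames(cd))
  if (length(missc))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(missc, collapse = ", ")))
  if ("dol" %in% colnames(cd) && !all(cd$dol %in% c(0L, 1L, 3L, 7L)))
    msg <- c(msg, "dol must be one of 0, 1, 3, 7")
  if (length(msg)) msg else TRUE
}
setValidity("ProteinQuantExperiment", .validPQE)

#' Construct a ProteinQuantExperiment
#'
#' @param lfq numeric matrix of log2 LFQ intensities, proteins in rows,
#'   samples in columns; `NA` marks not-quantified entries.
#' @param meta `data.frame` of sample annotation with columns `sample_id`,
#'   `participant_id`, `dol`, `sex`, `batch`, `cohort`, one row per column
#'   of `lfq` (matched by `sample_id` against `colnames(lfq)`).
#' @param rowData `data.frame`/`DataFrame` of per-protein annotation; if it
#'   lacks the quality-flag columns these default to `FALSE` and
#'   `unique_peptides` to `NA`.
#' @param ibaq optional linear-scale iBAQ matrix, same shape as `lfq`.
#' @param imputed logical; whether missing entries were filled in.
#' @return A [ProteinQuantExperiment-class] object.
#' @export
ProteinQuantExperiment <- function(lfq, meta, rowData = NULL, ibaq = NULL,
                                   imputed = FALSE) {
  lfq <- as.matrix(lfq)
  if (is.null(colnames(lfq)))
    stop("'lfq' must have sample IDs as column names")
  meta <- as.data.frame(meta)
  if (!"sample_id" %in% colnames(meta))
    stop("'meta' must contain a sample_id column")
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample IDs in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "))
  if (!setequal(colnames(lfq), meta$sample_id))
    stop("sample IDs of 'lfq' and 'meta' do not match")
  meta <- meta[match(colnames(lfq), meta$sample_id), , drop = FALSE]
  meta$dol <- as.integer(meta$dol)
  if (is.null(rowData)) {
    rowData <- data.frame(
      protein_group_id = if (is.null(rownames(lfq)))
        sprintf("P%04d", seq_len(nrow(lfq))) else rownames(lfq),
      gene_name = NA_character_,
      is_reverse = FALSE, is_contaminant = FALSE,
      only_modified_site = FALSE, unique_peptides = NA_integer_)
  }
  rowData <- as.data.frame(rowData)
  for (fl in c("is_reverse", "is_contaminant", "only_modified_site"))
    if (!fl %in% colnames(rowData)) rowData[[fl]] <- FALSE
  if (!"protein_group_id" %in% colnames(rowData))
    rowData$protein_group_id <- if (is.null(rownames(lfq)))
      sprintf("P%04d", seq_len(nrow(lfq))) else rownames(lfq)
  if (!"gene_name" %in% colnames(rowData))
    rowData$gene_name <- NA_character_
  if (!"unique_peptides" %in% colnames(rowData))
    rowData$unique_peptides <- NA_integer_
  rownames(lfq) <- rowData$protein_group_id
  assays <- list(lfq = lfq)
  if (!is.null(ibaq)) {
    ibaq <- as.matrix(ibaq)
    dimnames(ibaq) <- dimnames(lfq)
    assays$ibaq <- ibaq
  }
  cd <- S4Vectors::DataFrame(meta, row.names = meta$sample_id)
  rownames(rowData) <- rownames(lfq)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = S4Vectors::DataFrame(rowData), colData = cd)
  obj <- methods::new("ProteinQuantExperiment", se)
  S4Vectors::metadata(obj)$imputed <- isTRUE(imputed)
  methods::validObject(obj)
  obj
}

#' @describeIn ProteinQuantExperiment log2 LFQ intensity matrix
#' @param x,object a `ProteinQuantExperiment`
#' @export
setGeneric("lfq", function(x) standardGeneric("lfq"))

#' @rdname ProteinQuantExperiment-class
#' @export
setMethod("lfq", "ProteinQuantExperiment", function(x)
  SummarizedExperiment::assay(x, "lfq"))

#' @describeIn ProteinQuantExperiment linear-scale iBAQ matrix (or `NULL`)
#' @export
setGeneric("ibaq", function(x) standardGeneric("ibaq"))

#' @rdname ProteinQuantExperiment-class
#' @export
setMethod("ibaq", "ProteinQuantExperiment", function(x) {
  if (!"ibaq" %in% SummarizedExperiment::assayNames(x)) return(NULL)
  SummarizedExperiment::assay(x, "ibaq")
})

#' @describeIn ProteinQuantExperiment sample annotation as a `data.frame`
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' @rdname ProteinQuantExperiment-class
#' @export
setMethod("sampleMeta", "ProteinQuantExperiment", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @describeIn ProteinQuantExperiment per-protein annotation as a `data.frame`
#' @export
setGeneric("proteinInfo", function(x) standardGeneric("proteinInfo"))

#' @rdname ProteinQuantExperiment-class
#' @export
setMethod("proteinInfo", "ProteinQuantExperiment", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @describeIn ProteinQuantExperiment has the matrix been imputed?
#' @export
setGeneric("isImputed", function(x) standardGeneric("isImputed"))

#' @rdname ProteinQuantExperiment-class
#' @export
setMethod("isImputed", "ProteinQuantExperiment", function(x)
  isTRUE(S4Vectors::metadata(x)$imputed))

setMethod("show", "ProteinQuantExperiment", function(object) {
  m <- lfq(object)
  cat("ProteinQuantExperiment:", nrow(m), "proteins x", ncol(m), "samples\n")
  cat("  missing lfq entries:", sum(is.na(m)),
      sprintf("(%.1f%%)", 100 * mean(is.na(m))), "\n")
  cat("  iBAQ assay:", if (is.null(ibaq(object))) "absent" else "present",
      "| imputed:", isImputed(object), "\n")
  dol <- SummarizedExperiment::colData(object)$dol
  cat("  samples per DOL:",
      paste(sprintf("DOL%d:%d", as.integer(names(table(dol))),
                    as.integer(table(dol))), collapse = " "), "\n")
  invisible(NULL)
})

# internal: stop if the matrix carries imputed values (quarantine rule)
.assertNotImputed <- function(x, stage) {
  if (isImputed(x))
    stop(stage, " must not be run on an imputed matrix; ",
         "imputation is reserved for PCA (use the unimputed matrix)")
  invisible(TRUE)
}
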