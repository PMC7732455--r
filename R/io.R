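#' Read a MaxQuant-style proteinGroups table
#'
#' Parses the tab-separated `proteinGroups.txt` dialect: quality flags are
#' "+"/"" columns (`Reverse`, `Potential contaminant`, `Only identified by
#' site`), and `LFQ intensity <label>` / `iBAQ <label>` columns hold linear
#' intensities with 0 meaning not-quantified. LFQ values are log2-transformed
#' on import; iBAQ values stay linear (ratios are taken on linear scale).
#'
#' @param path path to a tab-separated proteinGroups-style file.
#' @param meta sample metadata `data.frame` (see [readSampleMeta()]).
#' @param sample_map optional named character vector mapping the column
#'   labels used in the file (the `<label>` part of `LFQ intensity <label>`)
#'   to sample IDs in `meta`. Default: labels are already sample IDs. No
#'   fuzzy matching is attempted.
#' @return A [ProteinQuantExperiment-class].
#' @export
readProteinGroups <- function(path, meta, sample_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  lfq_cols <- grep("^LFQ intensity ", colnames(tab), value = TRUE)
  if (!length(lfq_cols))
    stop("format error: no 'LFQ intensity <sample>' columns found")
  for (cn in c("Protein IDs", "Reverse", "Potential contaminant",
               "Only identified by site")) {
    if (!cn %in% colnames(tab))
      stop("format error: mandatory column '", cn, "' is missing")
  }
  labels <- sub("^LFQ intensity ", "", lfq_cols)
  ids <- if (is.null(sample_map)) labels else {
    unmapped <- setdiff(labels, names(sample_map))
    if (length(unmapped))
      stop("sample_map lacks entries for: ", paste(unmapped, collapse = ", "))
    unname(sample_map[labels])
  }
  if (anyDuplicated(ids))
    stop("duplicate sample IDs after mapping: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lin <- as.matrix(tab[, lfq_cols, drop = FALSE])
  storage.mode(lin) <- "double"
  lfq <- ifelse(lin > 0, log2(lin), NA_real_)
  colnames(lfq) <- ids
  ibaq <- NULL
  ibaq_cols <- paste0("iBAQ ", labels)
  if (all(ibaq_cols %in% colnames(tab))) {
    ib <- as.matrix(tab[, ibaq_cols, drop = FALSE])
    storage.mode(ib) <- "double"
    ibaq <- ifelse(ib > 0, ib, NA_real_)
    colnames(ibaq) <- ids
  }
  flag <- function(col) !is.na(tab[[col]]) & tab[[col]] == "+"
  rd <- data.frame(
    protein_group_id = as.character(tab[["Protein IDs"]]),
    gene_name = if ("Gene names" %in% colnames(tab)) {
      gn <- as.character(tab[["Gene names"]])
      ifelse(is.na(gn) | !nzchar(gn), NA_character_, gn)
    } else NA_character_,
    is_reverse = flag("Reverse"),
    is_contaminant = flag("Potential contaminant"),
    only_modified_site = flag("Only identified by site"),
    unique_peptides = if ("Razor + unique peptides" %in% colnames(tab))
      as.integer(tab[["Razor + unique peptides"]]) else NA_integer_,
    stringsAsFactors = FALSE)
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("metadata lacks rows for sample(s): ",
         paste(setdiff(ids, meta$sample_id), collapse = ", "))
  ProteinQuantExperiment(lfq, meta, rowData = rd, ibaq = ibaq)
}

#' Read and validate sample metadata
#'
#' Expects columns `sample_id`, `participant_id`, `dol`, `sex`, `batch`,
#' `cohort` and enforces the paired design: every participant has exactly
#' one DOL0 baseline and at most one follow-up sample at exactly one of
#' DOL 1, 3 or 7. Missing fields are errors, not defaults.
#'
#' @param path path to a comma- or tab-separated metadata table.
#' @return `data.frame`, one row per sample.
#' @export
readSampleMeta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  meta <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  validateSampleMeta(meta)
  meta
}

#' Validate the paired sampling design
#'
#' @param meta sample metadata `data.frame`.
#' @return invisibly `TRUE`; stops with participant IDs on violation.
#' @export
validateSampleMeta <- function(meta) {
  need <- c("sample_id", "participant_id", "dol", "sex", "batch", "cohort")
  miss <- setdiff(need, colnames(meta))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  for (cn in need)
    if (anyNA(meta[[cn]]))
      stop("metadata column '", cn, "' contains missing values")
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample IDs: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "))
  dol <- as.integer(meta$dol)
  if (any(is.na(dol)) || !all(dol %in% c(0L, 1L, 3L, 7L)))
    stop("unknown DOL value(s): ",
         paste(unique(meta$dol[!meta$dol %in% c(0, 1, 3, 7)]),
           collapse = ", "))
  n0 <- tapply(dol == 0L, meta$participant_id, sum)
  bad0 <- names(n0)[n0 != 1L]
  if (length(bad0))
    stop("design error: participant(s) without exactly one DOL0 sample: ",
         paste(bad0, collapse = ", "))
  nf <- tapply(dol > 0L, meta$participant_id, sum)
  badf <- names(nf)[nf > 1L]
  if (length(badf))
    stop("design error: participant(s) with more than one follow-up sample: ",
         paste(badf, collapse = ", "))
  invisible(TRUE)
}

#' Read a gene-level RNA count matrix
#'
#' Reads a tab-separated genes-by-samples table of integer read counts and
#' applies the standard pre-filters: globin transcripts (or any gene ID
#' matching a drop pattern) are removed, as are genes with fewer than
#' `min_count` counts in `min_samples` or more samples.
#'
#' @param path path to TSV with gene IDs in the first column.
#' @param drop_genes character vector of regular expressions; matching gene
#'   IDs are removed (default drops hemoglobin genes).
#' @param min_count,min_samples low-count filter: drop genes with
#'   `< min_count` reads in `>= min_samples` samples.
#' @return list with `counts` (integer matrix, genes x samples) and
#'   `gene_ids`.
#' @export
readRnaCounts <- function(path, drop_genes = "^HB[ABGDEQMZ]",
                          min_count = 10, min_samples = 9) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  cnt <- as.matrix(tab[, -1, drop = FALSE])
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("validation error: counts must be non-negative integers")
  storage.mode(cnt) <- "integer"
  rownames(cnt) <- genes
  filterRnaCounts(cnt, drop_genes = drop_genes, min_count = min_count,
                  min_samples = min_samples)
}

#' @rdname readRnaCounts
#' @param counts integer matrix of counts, genes in rows.
#' @export
filterRnaCounts <- function(counts, drop_genes = "^HB[ABGDEQMZ]",
                            min_count = 10, min_samples = 9) {
  keep <- rep(TRUE, nrow(counts))
  for (pat in drop_genes)
    keep <- keep & !grepl(pat, rownames(counts))
  low <- rowSums(counts < min_count) >= min_samples
  keep <- keep & !low
  out <- counts[keep, , drop = FALSE]
  list(counts = out, gene_ids = rownames(out))
}

#' Write a results table to TSV
#'
#' Tab-separated, one row per protein (or gene), stable column order,
#' missing values as empty strings, numbers at full precision so that the
#' table round-trips through [readResultsTable()].
#'
#' @param result a `data.frame` of results.
#' @param path output path.
#' @export
writeResultsTable <- function(result, path) {
  result <- as.data.frame(result)
  write.table(result, path, sep = "\t", quote = FALSE, na = "",
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeResultsTable
#' @export
readResultsTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, na.strings = "", stringsAsFactors = FALSE)
}
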