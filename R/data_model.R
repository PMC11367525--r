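#' Expression matrix with sample metadata and missingness mask
#'
#' The central container for per-gene per-sample quantities. Counts may not be
#' missing; protein log-intensities may be, and the mask travels with the
#' values so that imputation and quantification rules can be applied later.
#'
#' @param values Numeric gene x sample matrix with rownames (gene ids) and
#'   colnames (sample ids).
#' @param samples Data frame describing the columns; see [sample_table()].
#'   Must contain one row per column of `values`, in the same order.
#' @param value_kind One of `"raw_count"`, `"log_intensity"`, `"fraction"`,
#'   `"logFC"`, `"ratio"`.
#' @param missing Optional logical matrix of the same shape flagging missing
#'   cells; defaults to `is.na(values)`.
#' @return An object of class `omic_matrix`: a list with elements `values`,
#'   `samples`, `value_kind`, `missing`.
#' @export
omic_matrix <- function(values, samples, value_kind, missing = NULL) {
  value_kind <- match.arg(value_kind,
    c("raw_count", "log_intensity", "fraction", "logFC", "ratio"))
  .check(is.matrix(values) && is.numeric(values),
         "'values' must be a numeric matrix")
  .check(!is.null(rownames(values)) || nrow(values) == 0L,
         "'values' must have gene ids as rownames")
  .check(anyDuplicated(rownames(values)) == 0L, "duplicate gene ids")
  .check(is.data.frame(samples) && nrow(samples) == ncol(values),
         "sample table must have one row per matrix column")
  .check(identical(as.character(samples$sample_id), colnames(values)),
         "matrix colnames must equal samples$sample_id, in order")
  if (is.null(missing)) missing <- is.na(values)
  .check(identical(dim(missing), dim(values)), "mask dimension mismatch")
  dimnames(missing) <- dimnames(values)
  if (value_kind == "raw_count") {
    ok <- values[!missing]
    .check(!any(missing), "raw counts may not be missing")
    .check(all(ok >= 0) && all(ok == floor(ok)),
           "raw counts must be non-negative integers")
  }
  structure(list(values = values, samples = samples,
                 value_kind = value_kind, missing = missing),
            class = "omic_matrix")
}

#' @export
print.omic_matrix <- function(x, ...) {
  cat(sprintf("<omic_matrix> %d genes x %d samples [%s], %d missing cells\n",
              nrow(x$values), ncol(x$values), x$value_kind, sum(x$missing)))
  invisible(x)
}

#' @export
dim.omic_matrix <- function(x) dim(x$values)

#' Build and validate a sample table
#'
#' @param sample_id Character vector of unique sample ids.
#' @param modality `"transcript"` or `"protein"` per sample.
#' @param time_h Numeric time in hours post starvation.
#' @param replicate Replicate label.
#' @param plate Plate pairing key; `NA` for unpaired samples. A plate key may
#'   be shared by at most one sample per modality — this is what makes
#'   RNA/protein pairs from the same plate identifiable.
#' @return A validated data frame of class `c("sample_table","data.frame")`.
#' @export
sample_table <- function(sample_id, modality, time_h, replicate, plate = NA) {
  df <- data.frame(sample_id = as.character(sample_id),
                   modality = as.character(modality),
                   time_h = as.numeric(time_h),
                   replicate = as.character(replicate),
                   plate = as.character(plate),
                   stringsAsFactors = FALSE)
  .check(all(df$modality %in% c("transcript", "protein")),
         "modality must be 'transcript' or 'protein'")
  .check(anyDuplicated(df$sample_id) == 0L, "duplicate sample ids")
  key <- paste(df$modality, df$time_h, df$replicate)
  .check(anyDuplicated(key) == 0L,
         "(modality, time_h, replicate) must be unique")
  pk <- paste(df$modality, df$plate)[!is.na(df$plate)]
  .check(anyDuplicated(pk) == 0L,
         "a plate key may appear at most once per modality")
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Paired transcriptomics/proteomics dataset
#'
#' @param counts `omic_matrix` of raw transcript counts.
#' @param intensities `omic_matrix` of protein log2-intensities (may contain
#'   missing values).
#' @param genes Gene annotation data frame with at least `gene_id`,
#'   `is_protein_coding`, `protein_group`.
#' @param truth Optional data frame of simulation ground truth.
#' @param config Optional simulation configuration used to generate the data.
#' @return Object of class `paired_omics`.
#' @export
paired_omics <- function(counts, intensities, genes, truth = NULL,
                         config = NULL) {
  .check(inherits(counts, "omic_matrix") && counts$value_kind == "raw_count",
         "'counts' must be a raw_count omic_matrix")
  .check(inherits(intensities, "omic_matrix") &&
           intensities$value_kind == "log_intensity",
         "'intensities' must be a log_intensity omic_matrix")
  .check(all(c("gene_id", "is_protein_coding", "protein_group") %in%
               names(genes)), "gene annotation columns missing")
  structure(list(counts = counts, intensities = intensities, genes = genes,
                 truth = truth, config = config), class = "paired_omics")
}

#' @export
print.paired_omics <- function(x, ...) {
  cat(sprintf(paste0("<paired_omics> %d genes; %d RNA samples, %d protein ",
                     "samples; %d plate pairs\n"),
              nrow(x$counts$values), ncol(x$counts$values),
              ncol(x$intensities$values), length(plate_pairs(x)$plate)))
  invisible(x)
}

#' Identify plate-paired RNA/protein sample columns
#'
#' @param dataset A `paired_omics` object.
#' @return Data frame with columns `plate`, `rna_sample`, `protein_sample`,
#'   `time_h`, one row per plate shared by both modalities.
#' @export
plate_pairs <- function(dataset) {
  rs <- dataset$counts$samples
  ps <- dataset$intensities$samples
  common <- intersect(rs$plate[!is.na(rs$plate)], ps$plate[!is.na(ps$plate)])
  ri <- match(common, rs$plate)
  pi <- match(common, ps$plate)
  data.frame(plate = common,
             rna_sample = rs$sample_id[ri],
             protein_sample = ps$sample_id[pi],
             time_h = rs$time_h[ri],
             stringsAsFactors = FALSE)
}

# ---- readers / writers ------------------------------------------------------

.write_matrix_tsv <- function(mat, path, missing = NULL) {
  vals <- mat
  if (!is.null(missing)) vals[missing] <- NA
  df <- data.frame(gene_id = rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

.read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE,
                          na.strings = "")
  .check(names(df)[1] == "gene_id", "%s: first column must be gene_id", path)
  .check(anyDuplicated(df$gene_id) == 0L, "%s: duplicate gene ids", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!vapply(df[-1], is.numeric, logical(1)))
  .check(length(bad) == 0L, "%s: non-numeric values in column(s) %s", path,
         paste(names(df)[-1][bad], collapse = ", "))
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$gene_id)
  m
}

#' Write a paired dataset as a TSV bundle
#'
#' Writes `counts.tsv`, `intensities.tsv` (missing cells as empty fields),
#' `samples.tsv`, `genes.tsv` and, when truth is attached, `truth.tsv` into
#' `dir`. The bundle round-trips losslessly through [read_dataset()].
#'
#' @param dataset A `paired_omics` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_matrix_tsv(dataset$counts$values, file.path(dir, "counts.tsv"))
  .write_matrix_tsv(dataset$intensities$values,
                    file.path(dir, "intensities.tsv"),
                    missing = dataset$intensities$missing)
  samples <- rbind(dataset$counts$samples, dataset$intensities$samples)
  utils::write.table(samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(dataset$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(dataset$truth))
    utils::write.table(dataset$truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  invisible(dir)
}

#' Read a paired dataset from a TSV bundle
#'
#' @param dir Directory written by [write_dataset()].
#' @return A `paired_omics` object.
#' @export
read_dataset <- function(dir) {
  need <- c("counts.tsv", "intensities.tsv", "samples.tsv", "genes.tsv")
  missing_files <- need[!file.exists(file.path(dir, need))]
  .check(length(missing_files) == 0L, "missing input file(s): %s",
         paste(missing_files, collapse = ", "))
  samples <- utils::read.table(file.path(dir, "samples.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE,
                               na.strings = "")
  samples <- sample_table(samples$sample_id, samples$modality,
                          samples$time_h, samples$replicate, samples$plate)
  cmat <- .read_matrix_tsv(file.path(dir, "counts.tsv"))
  imat <- .read_matrix_tsv(file.path(dir, "intensities.tsv"))
  rs <- samples[samples$modality == "transcript", , drop = FALSE]
  ps <- samples[samples$modality == "protein", , drop = FALSE]
  .check(setequal(colnames(cmat), rs$sample_id) &&
           setequal(colnames(imat), ps$sample_id),
         "matrix headers do not match the sample table")
  cmat <- cmat[, rs$sample_id, drop = FALSE]
  imat <- imat[, ps$sample_id, drop = FALSE]
  rownames(rs) <- rownames(ps) <- NULL
  genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE,
                             na.strings = "")
  truth <- NULL
  if (file.exists(file.path(dir, "truth.tsv")))
    truth <- utils::read.table(file.path(dir, "truth.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE,
                               na.strings = "")
  paired_omics(omic_matrix(cmat, rs, "raw_count"),
               omic_matrix(imat, ps, "log_intensity"),
               genes, truth = truth)
}

# ---- preprocessing filters --------------------------------------------------

#' Sum transcript counts to protein-coding gene level
#'
#' Counts from transcripts encoding the same protein are summed; transcripts
#' that do not encode a protein are discarded. This is the fixed first step of
#' the pipeline, before the expression filter.
#'
#' @param counts `omic_matrix` of raw counts (rows = transcripts).
#' @param annot Gene annotation with `gene_id`, `is_protein_coding`,
#'   `protein_group`.
#' @return `omic_matrix` with one row per protein group.
#' @export
collapse_to_protein_coding <- function(counts, annot) {
  idx <- match(rownames(counts$values), annot$gene_id)
  .check(!anyNA(idx), "transcripts absent from annotation")
  coding <- which(as.logical(annot$is_protein_coding[idx]))
  vals <- counts$values[coding, , drop = FALSE]
  grp <- as.character(annot$protein_group[idx][coding])
  out <- rowsum(vals, group = grp, reorder = FALSE)
  omic_matrix(out, counts$samples, "raw_count")
}

#' Keep genes with evidence of expression
#'
#' A gene is considered expressed when it has more than one read in at least
#' one sample (maximum count over all samples > 1).
#'
#' @param counts `omic_matrix` of raw counts.
#' @return Filtered `omic_matrix`.
#' @export
filter_expressed <- function(counts) {
  keep <- apply(counts$values, 1L, max) > 1
  omic_matrix(counts$values[keep, , drop = FALSE], counts$samples,
              "raw_count")
}

#' Partition proteins by quantification completeness
#'
#' Splits proteins into those quantified everywhere (`directly_quantified`),
#' those quantified in all replicates of at least one time point but missing
#' elsewhere (`imputable` — these are eligible for MinProb imputation), and
#' the remainder (`unquantified`, dropped from analysis).
#'
#' @param intensities `omic_matrix` of log-intensities with missing mask.
#' @return List of three character vectors of gene ids.
#' @export
select_quantified_proteins <- function(intensities) {
  obs <- !intensities$missing
  tp <- intensities$samples$time_h
  complete_tp <- vapply(unique(tp), function(t)
    rowSums(obs[, tp == t, drop = FALSE]) == sum(tp == t),
    logical(nrow(obs)))
  if (nrow(obs) == 1L) complete_tp <- matrix(complete_tp, nrow = 1L)
  all_obs <- rowSums(obs) == ncol(obs)
  any_complete <- rowSums(complete_tp) > 0
  g <- rownames(intensities$values)
  list(directly_quantified = g[all_obs],
       imputable = g[!all_obs & any_complete],
       unquantified = g[!any_complete & !all_obs])
}

#' Read gene sets from a GMT file
#'
#' Standard tab-delimited GMT: set name, description, then member genes.
#' Duplicate genes within a line are removed.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(structure(list(), names = character(0)))
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    .check(length(f) >= 3L, "malformed GMT line: %s", substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
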