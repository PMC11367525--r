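#' Accounting summary from raw counts
#'
#' The arithmetic core of the summary table: given the seven counts, compute
#' the six percentages (expressed / quantified / both-quantified out of all
#' protein-coding genes; DE out of the expressed / quantified / both
#' totals), rounded half-up to one decimal.
#'
#' @param n_coding All annotated protein-coding genes.
#' @param n_expressed Expressed transcripts.
#' @param n_quantified Quantified proteins (direct + imputed).
#' @param n_both Genes quantified in both modalities.
#' @param n_de_rna,n_de_prot,n_de_both Differentially expressed counts.
#' @return Data frame of class `summary_table` with `description`,
#'   `transcripts`, `proteins`, `both` columns.
#' @export
summarize_counts <- function(n_coding, n_expressed, n_quantified, n_both,
                             n_de_rna, n_de_prot, n_de_both) {
  .check(n_de_both <= min(n_de_rna, n_de_prot),
         "both-DE cannot exceed either modality's DE count")
  pct <- function(a, b) if (b > 0) round_half_up(100 * a / b, 1) else 0
  out <- data.frame(
    description = c("all_protein_coding", "expressed_or_quantified",
                    "pct_of_protein_coding", "differentially_expressed",
                    "pct_de_of_expressed_or_quantified"),
    transcripts = c(n_coding, n_expressed, pct(n_expressed, n_coding),
                    n_de_rna, pct(n_de_rna, n_expressed)),
    proteins = c(n_coding, n_quantified, pct(n_quantified, n_coding),
                 n_de_prot, pct(n_de_prot, n_quantified)),
    both = c(n_coding, n_both, pct(n_both, n_coding),
             n_de_both, pct(n_de_both, n_both)),
    stringsAsFactors = FALSE)
  class(out) <- c("summary_table", "data.frame")
  out
}

#' Summarise a paired analysis
#'
#' Derives the accounting counts from a dataset and its two DE results and
#' delegates to [summarize_counts()]. "Quantified" proteins are those
#' retained after the imputation rule (directly quantified + imputable);
#' "both" means quantified in both modalities.
#'
#' @param dataset A `paired_omics` dataset (pre-filtering).
#' @param de_rna `de_result` from [nb_lrt()] on the expressed transcripts.
#' @param de_prot `de_result` from [moderated_f_test()] on the imputed
#'   proteins.
#' @return A `summary_table`.
#' @export
summarize <- function(dataset, de_rna, de_prot) {
  coding <- unique(dataset$genes$protein_group[
    as.logical(dataset$genes$is_protein_coding)])
  expressed <- de_rna$gene_id
  quantified <- de_prot$gene_id
  both <- intersect(expressed, quantified)
  de_r <- de_rna$gene_id[de_rna$is_DE]
  de_p <- de_prot$gene_id[de_prot$is_DE]
  summarize_counts(length(coding), length(expressed), length(quantified),
                   length(both), length(de_r), length(de_p),
                   length(intersect(de_r, de_p)))
}

#' Run the whole pipeline on a generated (or loaded) dataset
#'
#' simulate/load -> collapse and filter -> DE on both modalities ->
#' clustering -> concordance (lag matrix, per-gene r, matched vs mismatched)
#' -> protein:mRNA ratios with Dunnett contrasts -> multi-view factors ->
#' summary table. Results are written as TSVs plus a JSON manifest recording
#' seeds and parameters; deterministic stages replay bit-identically from
#' the same manifest.
#'
#' @param config A [sim_config()]; ignored when `input_dir` is given.
#' @param out_dir Output directory.
#' @param input_dir Optional directory with an existing TSV bundle.
#' @param k_clusters Clusters for the RNA logFC heatmap grouping.
#' @param n_factors Factors for the multi-view decomposition.
#' @param alpha DE threshold on adjusted p.
#' @return Invisibly, a list with all intermediate results.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, input_dir = NULL,
                         k_clusters = 4, n_factors = 3, alpha = 0.01) {
  t0 <- Sys.time()
  stage <- function(msg) message(sprintf("[omiclag +%5.1fs] %s",
                                         as.numeric(Sys.time() - t0,
                                                    units = "secs"), msg))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage("dataset")
  ds <- if (is.null(input_dir)) generate_paired_dataset(config)
        else read_dataset(input_dir)
  write_dataset(ds, file.path(out_dir, "dataset"))

  stage("preprocess")
  counts <- filter_expressed(
    collapse_to_protein_coding(ds$counts, ds$genes))
  sets <- select_quantified_proteins(ds$intensities)
  imput <- impute_minprob(ds$intensities,
                          imputation_params(seed = config$seed))

  stage("differential expression")
  de_rna <- nb_lrt(counts, alpha = alpha)
  de_prot <- moderated_f_test(imput, alpha = alpha)
  utils::write.table(de_rna, file.path(out_dir, "de_rna.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(de_prot, file.path(out_dir, "de_prot.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  stage("clustering")
  clust <- if (sum(de_rna$is_DE) >= k_clusters)
    cluster_logfc(de_rna, k = k_clusters) else NULL
  if (!is.null(clust))
    utils::write.table(
      data.frame(gene_id = names(clust$clusters), cluster = clust$clusters),
      file.path(out_dir, "clusters_rna.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)

  stage("concordance")
  rna_frac <- fraction_of_total(counts)
  prot_frac <- fraction_of_total(imput, delog2 = TRUE)
  lag <- lag_matrix(rna_frac, prot_frac)
  pg <- per_gene_correlations(rna_frac, prot_frac)
  mm <- matched_vs_mismatched(rna_frac, prot_frac, seed = config$seed)
  utils::write.table(as.data.frame(lag$lag_matrix),
                     file.path(out_dir, "lag_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = TRUE)
  utils::write.table(pg, file.path(out_dir, "per_gene_r.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  stage("ratios")
  cls <- classify_regulation(de_rna)
  rr <- ratio_matrix(rna_frac, prot_frac)
  ratio_tests <- lapply(c(up = "up", down = "down"), function(cl) {
    g <- intersect(names(cls)[cls == cl], rownames(rr$log2_ratio))
    if (length(g) < 2) return(NULL)
    vals <- stats::setNames(lapply(seq_along(rr$time_h), function(j)
      rr$log2_ratio[g, j]), rr$time_h)
    dunnett_vs_baseline(vals, seed = config$seed)
  })

  stage("factors")
  fm <- fit_multiview_factors(log_transform(counts), imput, K = n_factors)
  utils::write.table(
    data.frame(factor = rownames(fm$var_explained), fm$var_explained),
    file.path(out_dir, "factor_variance_explained.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)

  stage("summary")
  summary <- summarize(ds, de_rna, de_prot)
  utils::write.table(summary, file.path(out_dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(package = "omiclag",
                   version = as.character(utils::packageVersion("omiclag")),
                   seed = config$seed, alpha = alpha,
                   k_clusters = k_clusters, n_factors = n_factors,
                   n_genes = config$n_genes,
                   estimated_lag_h = lag$estimated_lag_h,
                   matched_median_r = mm$matched_median_r,
                   matched_vs_mismatched_p = mm$p)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage("done")
  invisible(list(dataset = ds, counts = counts, imputed = imput,
                 de_rna = de_rna, de_prot = de_prot, clusters = clust,
                 lag = lag, per_gene_r = pg, matched = mm,
                 ratios = rr, ratio_tests = ratio_tests, factors = fm,
                 summary = summary, manifest = manifest))
}
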