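#' Hierarchically cluster DE genes on their fold-change profiles
#'
#' Euclidean distance between logFC vectors, agglomerative clustering
#' (Ward by default), tree cut into `k` groups. Clusters are relabelled by
#' descending mean logFC at the final time point, so cluster 1 is always the
#' most upregulated — matching how heatmap cluster numbering is usually read.
#'
#' @param de `de_result`; only genes with `is_DE` are clustered.
#' @param k Number of clusters.
#' @param linkage `hclust` method; default `"ward.D2"`.
#' @return List of class `cluster_result`: `clusters` (named integer vector),
#'   `k`, `linkage`, `profile_quartiles` (per cluster x time point 25/50/75%
#'   logFC quantiles).
#' @export
cluster_logfc <- function(de, k, linkage = "ward.D2") {
  lfc <- as.matrix(de[de$is_DE, grep("^logFC_", names(de)), drop = FALSE])
  rownames(lfc) <- de$gene_id[de$is_DE]
  .check(k >= 1 && k <= nrow(lfc),
         "k must be between 1 and the number of DE genes (%d)", nrow(lfc))
  hc <- stats::hclust(stats::dist(lfc), method = linkage)
  raw <- stats::cutree(hc, k = k)
  final <- tapply(lfc[, ncol(lfc)], raw, mean)
  relabel <- match(names(sort(final, decreasing = TRUE)), names(final))
  clusters <- match(raw, as.integer(names(final)[relabel]))
  names(clusters) <- rownames(lfc)
  qs <- do.call(rbind, lapply(seq_len(k), function(cl) {
    sub <- lfc[clusters == cl, , drop = FALSE]
    do.call(rbind, lapply(colnames(sub), function(tc) data.frame(
      cluster = cl, timepoint = sub("logFC_", "", tc),
      q25 = stats::quantile(sub[, tc], 0.25, names = FALSE),
      median = stats::median(sub[, tc]),
      q75 = stats::quantile(sub[, tc], 0.75, names = FALSE))))
  }))
  structure(list(clusters = clusters, k = k, linkage = linkage,
                 profile_quartiles = qs), class = "cluster_result")
}

#' Fisher-exact gene-set enrichment of a gene cluster
#'
#' One-sided (enrichment) Fisher exact test per term: with `a` term members
#' inside the cluster, the p-value is the upper hypergeometric tail
#' P[X >= a]. Fold enrichment is (a / cluster size) / (term size /
#' background size). Terms with fewer than `min_term_size` annotated genes in
#' the background are skipped.
#'
#' @param cluster_genes Character vector of cluster member gene ids.
#' @param background_genes Character vector of the gene universe (all
#'   expressed / quantified genes for the modality, not the genome).
#' @param gene_sets Named list from [read_gene_sets()].
#' @param min_term_size Minimum annotated-in-background term size.
#' @return Data frame sorted by p: `term`, `a`, `b`, `c`, `d`, `p`,
#'   `fold_enrichment`.
#' @export
go_fisher <- function(cluster_genes, background_genes, gene_sets,
                      min_term_size = 3) {
  cluster_genes <- intersect(cluster_genes, background_genes)
  N <- length(background_genes)
  n <- length(cluster_genes)
  rows <- lapply(names(gene_sets), function(term) {
    members <- intersect(gene_sets[[term]], background_genes)
    K <- length(members)
    if (K < min_term_size) return(NULL)
    a <- length(intersect(members, cluster_genes))
    p <- if (a == 0) 1 else
      stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, a = a, b = K - a, c = n - a,
               d = N - K - (n - a), p = p,
               fold_enrichment = if (n > 0 && K > 0) (a / n) / (K / N) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), p = numeric(0),
                      fold_enrichment = numeric(0)))
  out <- out[order(out$p, -out$fold_enrichment), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the strongest terms per cluster
#'
#' Smallest p first, ties broken by larger fold enrichment.
#'
#' @param enrichment Result of [go_fisher()].
#' @param n_top Number of terms to keep (default 4).
#' @return The `n_top` leading rows.
#' @export
top_terms <- function(enrichment, n_top = 4) {
  utils::head(enrichment[order(enrichment$p, -enrichment$fold_enrichment), ,
                         drop = FALSE], n_top)
}

#' PCA on the most variable genes
#'
#' Selects the `n_top` genes with the largest variance of (log-scale)
#' values, centres each gene, and computes sample scores by SVD. Typical
#' choices are the 500 most variable transcripts and the 300 most variable
#' proteins.
#'
#' @param mat `omic_matrix` of log-scale values, or a plain matrix.
#' @param n_top Number of top-variance genes.
#' @return List: `scores` (sample x PC), `var_explained` (percent per PC,
#'   summing to 100), `genes` (ids used).
#' @export
pca_top_variable <- function(mat, n_top = 500) {
  y <- if (inherits(mat, "omic_matrix")) mat$values else mat
  v <- apply(y, 1L, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_top, nrow(y)))]
  yc <- y[keep, , drop = FALSE] - rowMeans(y[keep, , drop = FALSE])
  sv <- svd(yc)
  scores <- t(yc) %*% sv$u
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  ve <- 100 * sv$d^2 / sum(sv$d^2)
  list(scores = scores, var_explained = ve, genes = rownames(y)[keep])
}

#' Per-gene z-score trajectories over time
#'
#' For each gene, expression is averaged over replicates within each time
#' point and standardised across time points: z = (x - mean) / sd. Genes with
#' a constant trajectory get an all-zero z profile and are flagged.
#'
#' @param mat `omic_matrix` of log-scale values.
#' @param samples Optional sample table.
#' @param gene_sets Optional named list (e.g. milestone classes); when given,
#'   only member genes are returned, with a `set` column.
#' @return List: `z` (gene x time point matrix), `constant` (logical flag per
#'   gene), `time_h`.
#' @export
milestone_zscores <- function(mat, samples = NULL, gene_sets = NULL) {
  y <- if (inherits(mat, "omic_matrix")) mat$values else mat
  if (is.null(samples) && inherits(mat, "omic_matrix")) samples <- mat$samples
  tps <- sort(unique(samples$time_h))
  m <- vapply(tps, function(t)
    rowMeans(y[, samples$time_h == t, drop = FALSE]), numeric(nrow(y)))
  if (nrow(y) == 1L) m <- matrix(m, nrow = 1L)
  dimnames(m) <- list(rownames(y), sprintf("%gh", tps))
  mu <- rowMeans(m)
  sd_ <- apply(m, 1L, stats::sd)
  constant <- sd_ < 1e-12
  z <- (m - mu) / ifelse(constant, 1, sd_)
  z[constant, ] <- 0
  if (!is.null(gene_sets)) {
    keep <- unlist(gene_sets, use.names = FALSE)
    z <- z[rownames(z) %in% keep, , drop = FALSE]
    constant <- constant[rownames(z)]
  }
  list(z = z, constant = constant, time_h = tps)
}
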