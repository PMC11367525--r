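#' Scale each sample to fractions of its total
#'
#' Divides each sample column by its total so the scaled values sum to 1,
#' putting counts and (de-logged) intensities on a common relative scale.
#'
#' @param mat `omic_matrix` or matrix of non-negative, complete values.
#' @param delog2 Set `TRUE` to first undo a log2 transform (for protein
#'   log-intensities).
#' @return `omic_matrix` of kind `fraction` (or a plain matrix for matrix
#'   input).
#' @export
fraction_of_total <- function(mat, delog2 = FALSE) {
  y <- if (inherits(mat, "omic_matrix")) mat$values else mat
  .check(!anyNA(y), "matrix must be complete")
  if (delog2) y <- 2^y
  .check(all(y >= 0), "values must be non-negative")
  tot <- colSums(y)
  .check(all(tot > 0), "every sample must have a positive total")
  out <- sweep(y, 2L, tot, "/")
  if (inherits(mat, "omic_matrix"))
    omic_matrix(out, mat$samples, "fraction") else out
}

# replicate means per time point: gene x time matrix
.tp_means <- function(mat, samples = NULL) {
  y <- if (inherits(mat, "omic_matrix")) mat$values else mat
  if (is.null(samples) && inherits(mat, "omic_matrix")) samples <- mat$samples
  tps <- sort(unique(samples$time_h))
  m <- vapply(tps, function(t)
    rowMeans(y[, samples$time_h == t, drop = FALSE]), numeric(nrow(y)))
  if (nrow(y) == 1L) m <- matrix(m, nrow = 1L)
  dimnames(m) <- list(rownames(y), sprintf("%g", tps))
  attr(m, "time_h") <- tps
  m
}

#' Across-gene Spearman correlation at a pair of time points
#'
#' Mean fractions over replicates at `t_rna` (mRNA) and `t_prot` (protein)
#' are correlated across the common genes, with average ranks for ties.
#'
#' @param rna_frac,prot_frac Fraction-scale `omic_matrix` objects.
#' @param t_rna,t_prot Time points in hours.
#' @param genes Optional gene subset (e.g. genes DE in both modalities).
#' @return Spearman rho (scalar).
#' @export
across_gene_correlation <- function(rna_frac, prot_frac, t_rna, t_prot,
                                    genes = NULL) {
  mr <- .tp_means(rna_frac)
  mp <- .tp_means(prot_frac)
  common <- intersect(rownames(mr), rownames(mp))
  if (!is.null(genes)) common <- intersect(common, genes)
  .check(length(common) >= 3L, "need >= 3 common genes")
  x <- mr[common, as.character(t_rna)]
  y <- mp[common, as.character(t_prot)]
  stats::cor(rank(x), rank(y), method = "pearson")
}

#' Full mRNA-time x protein-time correlation (lag) matrix
#'
#' Computes the across-gene Spearman correlation for every pair of an RNA
#' time point and a protein time point. The estimated translation lag is the
#' protein-minus-RNA offset maximising the mean correlation, among offsets
#' represented by at least two time-point pairs (a single pair is too noisy
#' to define a lag; with only one shared time point the lag is 0 by
#' convention).
#'
#' @inheritParams across_gene_correlation
#' @return List of class `concordance_lag`: `lag_matrix` (RNA x protein),
#'   `per_timepoint_rho` (shared time points), `estimated_lag_h`,
#'   `offsets` (data frame offset / mean rho / #pairs).
#' @export
lag_matrix <- function(rna_frac, prot_frac, genes = NULL) {
  t_rna <- sort(unique(rna_frac$samples$time_h))
  t_prot <- sort(unique(prot_frac$samples$time_h))
  lm_ <- matrix(NA_real_, length(t_rna), length(t_prot),
                dimnames = list(sprintf("rna_%gh", t_rna),
                                sprintf("prot_%gh", t_prot)))
  for (i in seq_along(t_rna)) for (j in seq_along(t_prot))
    lm_[i, j] <- across_gene_correlation(rna_frac, prot_frac, t_rna[i],
                                         t_prot[j], genes)
  shared <- intersect(t_rna, t_prot)
  per_tp <- stats::setNames(
    vapply(shared, function(t)
      lm_[match(t, t_rna), match(t, t_prot)], numeric(1)),
    sprintf("%gh", shared))
  off <- outer(t_rna, t_prot, function(a, b) b - a)
  offs <- sort(unique(as.vector(off)))
  tab <- data.frame(offset_h = offs,
                    mean_rho = vapply(offs, function(d)
                      mean(lm_[off == d]), numeric(1)),
                    n_pairs = vapply(offs, function(d)
                      sum(off == d), numeric(1)))
  eligible <- tab[tab$n_pairs >= 2, , drop = FALSE]
  lag <- if (nrow(eligible))
    eligible$offset_h[which.max(eligible$mean_rho)] else 0
  structure(list(lag_matrix = lm_, per_timepoint_rho = per_tp,
                 estimated_lag_h = lag, offsets = tab),
            class = "concordance_lag")
}

#' Ranged major axis (model II) regression
#'
#' Both variables are scaled by their ranges, the major-axis (orthogonal)
#' slope is computed on the scaled data, and the slope is transformed back;
#' the intercept passes through the means. Symmetric under exchange of x and
#' y (the slope inverts), appropriate when both variables carry error.
#'
#' @param x,y Numeric vectors (log mean fractions, typically).
#' @return List with `slope` and `intercept`.
#' @export
rma_regression <- function(x, y) {
  .check(length(x) == length(y) && length(x) >= 3L, "need >= 3 points")
  rx <- diff(range(x))
  ry <- diff(range(y))
  .check(rx > 0 && ry > 0, "x and y must each have positive range")
  xs <- x / rx
  ys <- y / ry
  sxx <- stats::var(xs)
  syy <- stats::var(ys)
  sxy <- stats::cov(xs, ys)
  b_scaled <- if (abs(sxy) < 1e-300) sqrt(syy / sxx) else
    (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  slope <- b_scaled * ry / rx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Per-gene Pearson correlations over plate-paired samples
#'
#' For each gene, the Pearson correlation between its RNA fractions and its
#' protein fractions over the plate-paired samples (only samples with both
#' modalities from the same plate enter). Genes with zero variance in either
#' modality are undefined and flagged.
#'
#' @param rna_frac,prot_frac Fraction-scale `omic_matrix` objects.
#' @return Data frame: `gene_id`, `r`, `defined`.
#' @export
per_gene_correlations <- function(rna_frac, prot_frac) {
  pairs <- .frac_pairs(rna_frac, prot_frac)
  x <- rna_frac$values[pairs$genes, pairs$rna, drop = FALSE]
  y <- prot_frac$values[pairs$genes, pairs$prot, drop = FALSE]
  r <- .row_pearson(x, y)
  data.frame(gene_id = pairs$genes, r = r, defined = !is.na(r),
             stringsAsFactors = FALSE)
}

# shared plate bookkeeping for paired-sample operations
.frac_pairs <- function(rna_frac, prot_frac) {
  rs <- rna_frac$samples
  ps <- prot_frac$samples
  plates <- intersect(rs$plate[!is.na(rs$plate)], ps$plate[!is.na(ps$plate)])
  .check(length(plates) >= 3L, "need >= 3 plate-paired samples")
  ri <- match(plates, rs$plate)
  pi <- match(plates, ps$plate)
  list(genes = intersect(rownames(rna_frac$values),
                         rownames(prot_frac$values)),
       rna = rs$sample_id[ri], prot = ps$sample_id[pi],
       time_h = rs$time_h[ri], plates = plates)
}

# vectorised per-row Pearson correlation of two aligned matrices
.row_pearson <- function(x, y) {
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  sx <- sqrt(rowSums(xc^2))
  sy <- sqrt(rowSums(yc^2))
  r <- rowSums(xc * yc) / (sx * sy)
  r[sx < 1e-300 | sy < 1e-300] <- NA
  r
}

#' Matched versus mismatched plate pairing
#'
#' Tests whether sampling RNA and protein from the same plate buys
#' correlation: the median per-gene Pearson r under the true plate pairing is
#' compared with the medians obtained when protein samples are shuffled
#' across plates *within* each time point (the identity permutation is
#' excluded). The permutation p-value is the fraction of permuted medians at
#' least as large as the matched one.
#'
#' @param rna_frac,prot_frac Fraction-scale `omic_matrix` objects.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the permutation draws.
#' @return List: `matched_median_r`, `mismatched_median_r` (mean over
#'   permutations), `perm_medians`, `p`.
#' @export
matched_vs_mismatched <- function(rna_frac, prot_frac, n_perm = 1000,
                                  seed = 1) {
  pairs <- .frac_pairs(rna_frac, prot_frac)
  tp <- pairs$time_h
  .check(any(table(tp) >= 2),
         "no time point has >= 2 replicates: no valid permutation exists")
  x <- rna_frac$values[pairs$genes, pairs$rna, drop = FALSE]
  y <- prot_frac$values[pairs$genes, pairs$prot, drop = FALSE]
  matched <- stats::median(.row_pearson(x, y), na.rm = TRUE)
  with_seed(seed, {
    perm_medians <- vapply(seq_len(n_perm), function(i) {
      repeat {
        idx <- seq_len(ncol(y))
        for (t in unique(tp)) {
          j <- which(tp == t)
          if (length(j) > 1) idx[j] <- j[sample.int(length(j))]
        }
        if (!identical(idx, seq_len(ncol(y)))) break
      }
      stats::median(.row_pearson(x, y[, idx, drop = FALSE]), na.rm = TRUE)
    }, numeric(1))
    list(matched_median_r = matched,
         mismatched_median_r = mean(perm_medians),
         perm_medians = perm_medians,
         p = mean(perm_medians >= matched))
  })
}

#' Abundance share of the top k genes
#'
#' Sum of the `k` largest mean fractions — e.g. "the top two proteins
#' encompass 10% of total protein abundance".
#'
#' @param frac Fraction-scale `omic_matrix` or matrix.
#' @param k Number of top genes.
#' @return Scalar share in \[0, 1\].
#' @export
top_k_share <- function(frac, k = 2) {
  y <- if (inherits(frac, "omic_matrix")) frac$values else frac
  m <- rowMeans(y)
  sum(sort(m, decreasing = TRUE)[seq_len(min(k, length(m)))])
}
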