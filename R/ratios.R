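#' Protein:mRNA ratio trajectories
#'
#' Replicate-averaged fractions per time point are divided element-wise:
#' ratio = protein fraction / mRNA fraction. A pseudo-fraction of 1e-12
#' guards zeros, so ratios are strictly positive; log2 ratios are returned
#' alongside. The ratios are relative quantities only — they say nothing
#' about absolute molecule numbers.
#'
#' @param rna_frac,prot_frac Fraction-scale `omic_matrix` objects.
#' @param genes Optional gene subset; default: genes present in both.
#' @return List of class `ratio_result`: `ratio` and `log2_ratio`
#'   (gene x shared time point matrices), `time_h`.
#' @export
ratio_matrix <- function(rna_frac, prot_frac, genes = NULL) {
  mr <- .tp_means(rna_frac)
  mp <- .tp_means(prot_frac)
  common <- intersect(rownames(mr), rownames(mp))
  if (!is.null(genes)) common <- intersect(common, genes)
  shared <- intersect(colnames(mr), colnames(mp))
  .check(length(shared) >= 1L, "no shared time points")
  eps <- 1e-12
  ratio <- (mp[common, shared, drop = FALSE] + eps) /
    (mr[common, shared, drop = FALSE] + eps)
  colnames(ratio) <- sprintf("%sh", shared)
  structure(list(ratio = ratio, log2_ratio = log2(ratio),
                 time_h = as.numeric(shared)), class = "ratio_result")
}

#' Classify genes by their 10h mRNA fold change
#'
#' DE genes whose fitted fold change at the final time point versus baseline
#' exceeds 2 are `up`; DE genes below 0.5 are `down`; everything else
#' (including all non-DE genes, whatever their fold change) is `other`.
#'
#' @param de_rna `de_result` from [nb_lrt()].
#' @param t_final Final time point (default: the last fitted one).
#' @return Named character vector (`up` / `down` / `other`) per gene.
#' @export
classify_regulation <- function(de_rna, t_final = NULL) {
  tps <- attr(de_rna, "timepoints")
  if (is.null(t_final)) t_final <- tps[length(tps)]
  col <- sprintf("logFC_%gh", t_final)
  .check(col %in% names(de_rna), "no logFC column for t = %g h", t_final)
  fc <- 2^de_rna[[col]]
  cls <- ifelse(de_rna$is_DE & fc > 2, "up",
                ifelse(de_rna$is_DE & fc < 0.5, "down", "other"))
  stats::setNames(cls, de_rna$gene_id)
}

#' Dunnett many-to-one contrasts against the baseline time point
#'
#' One-way layout of (log2) ratios by time point: pooled-variance t
#' statistics of each later time point against baseline, with family-wise
#' adjustment from the Monte-Carlo distribution of the maximum |t| under the
#' contrast correlation structure (multivariate t draws, so the k = 1 case
#' reduces to an ordinary two-sample pooled t-test). Two-sided. Time points
#' with fewer than 2 observations are excluded with a warning.
#'
#' @param values List of numeric vectors, one per time point, named by the
#'   time in hours (baseline = smallest), or a `ratio_result` (its log2
#'   ratios, pooling genes within each time point).
#' @param n_mc Monte-Carlo draws for the max-|t| null (default 20000).
#' @param seed Seed for the Monte-Carlo draws.
#' @return Data frame: `time_h`, `estimate` (mean difference vs baseline),
#'   `t`, `p_unadjusted`, `p_adjusted` (>= unadjusted by construction).
#' @export
dunnett_vs_baseline <- function(values, n_mc = 20000, seed = 1) {
  if (inherits(values, "ratio_result"))
    values <- stats::setNames(
      lapply(seq_along(values$time_h),
             function(j) values$log2_ratio[, j]),
      values$time_h)
  tps <- as.numeric(names(values))
  .check(!anyNA(tps), "time-point names must be numeric hours")
  sizes <- lengths(values)
  if (any(sizes < 2)) {
    warning("excluding time point(s) with < 2 observations: ",
            paste(names(values)[sizes < 2], collapse = ", "))
    values <- values[sizes >= 2]
    tps <- tps[sizes >= 2]
  }
  .check(length(values) >= 2L, "need >= 2 usable time points")
  ord <- order(tps)
  values <- values[ord]
  tps <- tps[ord]
  n <- lengths(values)
  k <- length(values) - 1L
  means <- vapply(values, mean, numeric(1))
  df <- sum(n) - length(values)
  s2 <- sum(vapply(values, function(v)
    sum((v - mean(v))^2), numeric(1))) / df
  se <- sqrt(s2 * (1 / n[-1] + 1 / n[1]))
  tstat <- (means[-1] - means[1]) / se
  # contrast correlation: corr(t_i, t_j) = lambda_i*lambda_j,
  # lambda_i = sqrt(n_i / (n_i + n_0))
  lam <- sqrt(n[-1] / (n[-1] + n[1]))
  R <- outer(lam, lam)
  diag(R) <- 1
  p_un <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_mc * k), n_mc, k) %*% chol(R)
    W <- sqrt(stats::rchisq(n_mc, df) / df)
    maxt <- apply(abs(Z / W), 1L, max)
    p_adj <- vapply(abs(tstat), function(tv) mean(maxt >= tv), numeric(1))
  })
  data.frame(time_h = tps[-1], estimate = means[-1] - means[1], t = tstat,
             p_unadjusted = p_un, p_adjusted = pmax(p_adj, p_un),
             row.names = NULL)
}
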