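#' Parameters for probabilistic-minimum imputation
#'
#' @param q Low quantile of the observed distribution at which imputed draws
#'   are centred (default 0.01).
#' @param sigma_scale Multiplier on the observed standard deviation.
#' @param per_sample Impute from each sample's own observed distribution
#'   (default) or from the pooled distribution.
#' @param seed Optional seed for the imputation draws.
#' @return List of class `imputation_params`.
#' @export
imputation_params <- function(q = 0.01, sigma_scale = 1, per_sample = TRUE,
                              seed = NULL) {
  .check(q > 0 && q < 0.5, "q must be in (0, 0.5)")
  .check(sigma_scale > 0, "sigma_scale must be > 0")
  structure(list(q = q, sigma_scale = sigma_scale, per_sample = per_sample,
                 seed = seed), class = "imputation_params")
}

#' Impute censored protein intensities with a probabilistic minimum
#'
#' Implements left-censored (missing-not-at-random) imputation: missing cells
#' are drawn from Normal(mu_s, (sigma_scale*sd_s)^2), where mu_s is the
#' `q`-quantile and sd_s the standard deviation of the observed values of
#' that sample. Only proteins quantified in all replicates of at least one
#' time point qualify (see [select_quantified_proteins()]); the rest are
#' dropped, so the output is complete.
#'
#' @param intensities `omic_matrix` of log-intensities with missing mask.
#' @param params [imputation_params()].
#' @param sets Optional precomputed result of [select_quantified_proteins()].
#' @return Complete `omic_matrix`; per-gene imputation counts are attached as
#'   attribute `n_imputed`, the seed as `imputation_seed`.
#' @export
impute_minprob <- function(intensities, params = imputation_params(),
                           sets = NULL) {
  if (is.null(sets)) sets <- select_quantified_proteins(intensities)
  keep <- c(sets$directly_quantified, sets$imputable)
  x <- intensities$values[rownames(intensities$values) %in% keep, ,
                          drop = FALSE]
  miss <- intensities$missing[rownames(intensities$values) %in% keep, ,
                              drop = FALSE]
  pooled <- x[!miss]
  with_seed(params$seed, {
    for (s in seq_len(ncol(x))) {
      mi <- which(miss[, s])
      if (!length(mi)) next
      obs <- x[!miss[, s], s]
      if (!params$per_sample || length(obs) < 10L) {
        if (params$per_sample && length(obs) < 10L)
          warning(sprintf(
            "sample %s has %d observed values; using pooled parameters",
            colnames(x)[s], length(obs)))
        obs <- pooled
      }
      mu <- stats::quantile(obs, params$q, names = FALSE)
      sd_s <- stats::sd(obs) * params$sigma_scale
      x[mi, s] <- stats::rnorm(length(mi), mu, sd_s)
    }
    out <- omic_matrix(x, intensities$samples, "log_intensity",
                       missing = matrix(FALSE, nrow(x), ncol(x)))
    attr(out, "n_imputed") <- rowSums(miss)
    attr(out, "imputation_seed") <- params$seed
    out
  })
}

#' Moderated residual variance
#'
#' The posterior variance of the hierarchical scaled-inverse-chi-square
#' model: `(d0*s0_sq + d*s2) / (d0 + d)`; for `d0 = Inf` it is `s0_sq`.
#'
#' @param s2 Per-gene residual variances.
#' @param d Residual degrees of freedom.
#' @param d0 Prior degrees of freedom (may be `Inf`).
#' @param s0_sq Prior variance.
#' @return Moderated variances.
#' @export
moderated_variance <- function(s2, d, d0, s0_sq) {
  if (is.infinite(d0)) return(rep_len(s0_sq, length(s2)))
  (d0 * s0_sq + d * s2) / (d0 + d)
}

#' Estimate empirical-Bayes variance hyperparameters
#'
#' Moment-matching on log s^2: with s^2 ~ s0^2 * (chisq_d/d) * (d0/chisq_d0)
#' marginally, E[log s^2] and Var[log s^2] have closed forms in digamma /
#' trigamma, which are inverted here. If the excess variance of log s^2 is
#' non-positive (all variances essentially equal) the prior is degenerate:
#' `d0 = Inf`.
#'
#' @param s2 Per-gene residual variances (positive).
#' @param d Residual degrees of freedom (scalar).
#' @return List with `d0` and `s0_sq`.
#' @export
estimate_eb_hyperparams <- function(s2, d) {
  .check(all(s2 > 0), "residual variances must be positive")
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  ev <- stats::var(e) - trigamma(d / 2)
  if (!is.finite(ev) || ev <= 0)
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  d0 <- 2 * trigamma_inverse(ev)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderated F-test on protein log-intensities
#'
#' Per gene, ordinary least squares with one mean per time point gives the
#' residual variance s^2 on d = n - T degrees of freedom. The hyperparameters
#' (d0, s0^2) of a scaled-inverse-chi-square prior are estimated across genes
#' by [estimate_eb_hyperparams()], each gene's denominator variance is
#' moderated, and F = between-group mean square / moderated variance is
#' referred to F(T-1, d0+d). p-values are BH-adjusted; log2 fold changes
#' versus the baseline time point come from the fitted means (the data are
#' already log2).
#'
#' @param intensities Complete `omic_matrix` of log-intensities
#'   (post-imputation) or a plain matrix.
#' @param samples Optional sample table.
#' @param alpha Adjusted-p threshold for the DE flag.
#' @param d0,s0_sq Optional forced hyperparameters (0 disables moderation,
#'   `Inf` shrinks fully to the prior variance); estimated when `NULL`.
#' @return A `de_result` data frame (columns as [nb_lrt()], with `F_stat`
#'   in place of the LRT statistic and `s2`, `s2_moderated` alongside).
#' @export
moderated_f_test <- function(intensities, samples = NULL, alpha = 0.01,
                             d0 = NULL, s0_sq = NULL) {
  if (inherits(intensities, "omic_matrix")) {
    .check(!any(intensities$missing),
           "intensity matrix must be complete (impute first)")
    if (is.null(samples)) samples <- intensities$samples
    y <- intensities$values
  } else y <- intensities
  tps <- sort(unique(samples$time_h))
  .check(length(tps) >= 2L, "need at least 2 time points")
  group <- factor(samples$time_h, levels = tps)
  nt <- table(group)
  .check(all(nt >= 2L), "need >= 2 replicates per time point")
  n <- ncol(y)
  T_ <- length(tps)
  d <- n - T_

  means <- vapply(tps, function(t)
    rowMeans(y[, group == t, drop = FALSE]), numeric(nrow(y)))
  if (nrow(y) == 1L) means <- matrix(means, nrow = 1L)
  colnames(means) <- sprintf("%gh", tps)
  fitted <- means[, as.integer(group), drop = FALSE]
  rss <- rowSums((y - fitted)^2)
  s2 <- pmax(rss / d, 1e-300)
  grand <- as.vector(means %*% (as.integer(nt) / n))
  msb <- as.vector(((means - grand)^2) %*% as.integer(nt)) / (T_ - 1)

  if (is.null(d0)) {
    hyp <- estimate_eb_hyperparams(s2, d)
    d0 <- hyp$d0
    if (is.null(s0_sq)) s0_sq <- hyp$s0_sq
  } else if (is.null(s0_sq)) {
    s0_sq <- if (d0 > 0) estimate_eb_hyperparams(s2, d)$s0_sq else 1
  }
  s2_mod <- moderated_variance(s2, d, d0, s0_sq)
  f_stat <- msb / s2_mod
  df2 <- d0 + d
  p <- stats::pf(f_stat, T_ - 1, df2, lower.tail = FALSE)
  p_adj <- stats::p.adjust(p, method = "BH")
  lfc <- means[, -1, drop = FALSE] - means[, 1]
  colnames(lfc) <- sprintf("logFC_%gh", tps[-1])
  out <- data.frame(gene_id = rownames(y), F_stat = f_stat, p = p,
                    p_adj = p_adj, s2 = s2, s2_moderated = s2_mod, lfc,
                    is_DE = p_adj < alpha, stringsAsFactors = FALSE,
                    check.names = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("de_result", "data.frame"),
            fitted_means = means, timepoints = tps, baseline = tps[1],
            alpha = alpha, d0 = d0, s0_sq = s0_sq, df_residual = d,
            modality = "protein")
}
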