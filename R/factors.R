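#' Multi-view factor decomposition by truncated SVD
#'
#' A deterministic stand-in for probabilistic multi-omics factor analysis:
#' the two views (mRNA and protein, replicate-averaged per time point and
#' restricted to common genes) are centred per gene, scaled so each view
#' contributes equal total variance, stacked gene-wise, and decomposed by
#' truncated SVD. Factor values are the right singular vectors scaled by the
#' singular values; per-view loadings are the corresponding rows of the left
#' singular vectors, rescaled so the maximum |loading| per factor and view
#' is 1 (which is the scale on which the loading threshold is applied).
#' Variance explained of factor k in a view is
#' 100 * ||d_k u_{k,view} v_k'||^2 / ||Y_view||^2. Signs are fixed by
#' making each factor's value at the last time point non-negative.
#'
#' @param rna_mat,prot_mat Gene x sample (or gene x time) matrices, or
#'   `omic_matrix` objects; replicate-averaged per time point internally
#'   when a sample table is available.
#' @param K Number of factors.
#' @param average_replicates Average columns within time points first
#'   (default `TRUE`).
#' @return Object of class `factor_model`: `factors` (sample x K),
#'   `loadings` (list rna / protein, gene x K, scaled to \[-1, 1\]),
#'   `raw_loadings`, `var_explained` (K x 2 matrix, percent), `d` (singular
#'   values), `time_h`.
#' @export
fit_multiview_factors <- function(rna_mat, prot_mat, K = 3,
                                  average_replicates = TRUE) {
  get_view <- function(m) {
    if (inherits(m, "omic_matrix")) {
      if (average_replicates) .tp_means(m)
      else {
        v <- m$values
        attr(v, "time_h") <- m$samples$time_h
        v
      }
    } else m
  }
  yr <- get_view(rna_mat)
  yp <- get_view(prot_mat)
  common <- intersect(rownames(yr), rownames(yp))
  .check(length(common) >= 2L, "need >= 2 common genes")
  tr <- attr(yr, "time_h")
  tp <- attr(yp, "time_h")
  if (!is.null(tr) && !is.null(tp) && !identical(tr, tp)) {
    shared <- intersect(tr, tp)  # e.g. drop the RNA-only 6h time point
    .check(length(shared) >= 2L, "views share fewer than 2 time points")
    yr <- yr[, tr %in% shared, drop = FALSE]
    yp <- yp[, tp %in% shared, drop = FALSE]
    tr <- tr[tr %in% shared]
  }
  .check(ncol(yr) == ncol(yp), "views must share the sample grid")
  time_h <- tr %||% seq_len(ncol(yr))
  yr <- yr[common, , drop = FALSE]
  yp <- yp[common, , drop = FALSE]
  center_scale <- function(y) {
    yc <- y - rowMeans(y)
    ss <- sum(yc^2)
    .check(ss > 0, "a view has zero variance")
    yc / sqrt(ss)  # equal total variance per view
  }
  yr_s <- center_scale(yr)
  yp_s <- center_scale(yp)
  Y <- rbind(yr_s, yp_s)
  .check(K >= 1 && K <= min(dim(Y)), "K exceeds the rank bound")
  sv <- svd(Y, nu = K, nv = K)
  d <- sv$d[seq_len(K)]
  u <- sv$u
  v <- sv$v
  # sign convention: factor value at the last time point non-negative
  last <- which.max(time_h)
  flip <- ifelse(v[last, ] * d < 0, -1, 1)
  u <- sweep(u, 2L, flip, "*")
  v <- sweep(v, 2L, flip, "*")
  factors <- sweep(v, 2L, d, "*")
  dimnames(factors) <- list(colnames(yr), paste0("Factor", seq_len(K)))
  nr <- length(common)
  u_rna <- u[seq_len(nr), , drop = FALSE]
  u_prot <- u[nr + seq_len(nr), , drop = FALSE]
  scale_load <- function(m) {
    mx <- apply(abs(m), 2L, max)
    sweep(m, 2L, ifelse(mx > 0, mx, 1), "/")
  }
  ve <- cbind(rna = 100 * d^2 * colSums(u_rna^2) / sum(yr_s^2),
              protein = 100 * d^2 * colSums(u_prot^2) / sum(yp_s^2))
  rownames(ve) <- paste0("Factor", seq_len(K))
  name_load <- function(m) {
    dimnames(m) <- list(common, paste0("Factor", seq_len(K)))
    m
  }
  structure(list(factors = factors,
                 loadings = list(rna = name_load(scale_load(u_rna)),
                                 protein = name_load(scale_load(u_prot))),
                 raw_loadings = list(rna = name_load(u_rna),
                                     protein = name_load(u_prot)),
                 var_explained = ve, d = d, time_h = time_h, K = K),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> %d factors, %d genes, %d samples\n",
              x$K, nrow(x$loadings$rna), nrow(x$factors)))
  print(round(x$var_explained, 1))
  invisible(x)
}

#' Select genes strongly loading a factor in both views
#'
#' Genes whose scaled |loading| reaches `threshold` in *both* the mRNA and
#' the protein view, classified by sign agreement: `concordant_up` (both
#' positive), `concordant_down` (both negative), `discordant` (opposite
#' signs — mRNA and protein regulation opposing one another).
#'
#' @param model A `factor_model`.
#' @param factor_index Which factor (default 1).
#' @param threshold Loading threshold on the max-|loading|-scaled factors
#'   (default 0.45).
#' @return Data frame: `gene_id`, `loading_rna`, `loading_protein`, `class`.
#' @export
select_factor_genes <- function(model, factor_index = 1, threshold = 0.45) {
  lr <- model$loadings$rna[, factor_index]
  lp <- model$loadings$protein[, factor_index]
  sel <- abs(lr) >= threshold & abs(lp) >= threshold
  cls <- ifelse(lr > 0 & lp > 0, "concordant_up",
                ifelse(lr < 0 & lp < 0, "concordant_down", "discordant"))
  data.frame(gene_id = names(lr)[sel], loading_rna = lr[sel],
             loading_protein = lp[sel], class = cls[sel],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Permutation GSEA on factor loadings
#'
#' Statistic: mean loading of the set's members in the chosen view and
#' factor. Null: `n_perm` random gene sets of the same size drawn from the
#' view's gene universe. Two-sided p with the add-one correction
#' (1 + #\{|null| >= |obs|\}) / (n_perm + 1), so the minimum attainable p is
#' 1/(n_perm+1). Invariant to affine rescaling of the loadings.
#'
#' @param model A `factor_model`.
#' @param view `"rna"` or `"protein"`.
#' @param factor_index Which factor.
#' @param gene_sets Named list of gene id vectors.
#' @param n_perm Number of permutations.
#' @param seed Seed.
#' @return Data frame: `term`, `size`, `mean_weight`, `p`.
#' @export
gsea_factor_weights <- function(model, view = c("rna", "protein"),
                                factor_index = 2, gene_sets,
                                n_perm = 10000, seed = 1) {
  view <- match.arg(view)
  w <- model$loadings[[view]][, factor_index]
  universe <- names(w)
  with_seed(seed, {
    rows <- lapply(names(gene_sets), function(term) {
      members <- intersect(gene_sets[[term]], universe)
      m <- length(members)
      if (m == 0) return(NULL)
      obs <- mean(w[members])
      if (m == length(universe)) {
        p <- 1  # the whole universe: no permutation varies the statistic
      } else {
        null <- vapply(seq_len(n_perm), function(i)
          mean(w[sample.int(length(universe), m)]), numeric(1))
        p <- (1 + sum(abs(null - mean(w)) >= abs(obs - mean(w)))) /
          (n_perm + 1)
      }
      data.frame(term = term, size = m, mean_weight = obs, p = p,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(term = character(0), size = integer(0),
                        mean_weight = numeric(0), p = numeric(0))
    out[order(out$p), , drop = FALSE]
  })
}
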