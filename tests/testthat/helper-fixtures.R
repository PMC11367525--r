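# shared fixtures and independent oracles for the test suite

# quick sample table: one modality, tps x reps, optional plate keys
st_fix <- function(tps, reps, modality = "transcript", plates = FALSE) {
  g <- expand.grid(r = seq_len(reps), t = tps)
  prefix <- if (modality == "transcript") "rna" else "prot"
  sample_table(sprintf("%s_%02dh_r%d", prefix, g$t, g$r), modality, g$t,
               paste0("r", g$r),
               plate = if (plates) sprintf("plate_%02dh_r%d", g$t, g$r)
                       else NA)
}

# named count/intensity matrix with given dims
mat_fix <- function(values, st, genes = NULL) {
  m <- matrix(values, ncol = nrow(st))
  rownames(m) <- genes %||% sprintf("g%03d", seq_len(nrow(m)))
  colnames(m) <- st$sample_id
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles -----------------------------------------------------

# Spearman via explicit average ranks + Pearson product-moment formula
spearman_bf <- function(x, y) {
  rk <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- sum(v < v[i]) + (1 + sum(v == v[i])) / 2
    r
  }
  pearson_bf(rk(x), rk(y))
}

# Pearson from the raw covariance sums
pearson_bf <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# hypergeometric upper tail P[X >= a] by explicit enumeration with choose()
hyper_tail_bf <- function(a, K, N, n) {
  lo <- max(0, n - (N - K))
  hi <- min(K, n)
  terms <- vapply(lo:hi, function(x)
    choose(K, x) * choose(N - K, n - x), numeric(1))
  sum(terms[(lo:hi) >= a]) / choose(N, n)
}

# ranged major axis slope, independently coded: scale by ranges, eigenvector
# of the 2x2 covariance matrix, back-transform
rma_bf <- function(x, y) {
  xs <- x / diff(range(x))
  ys <- y / diff(range(y))
  S <- stats::cov(cbind(xs, ys))
  ev <- eigen(S)$vectors[, 1]
  b <- ev[2] / ev[1]
  if (sign(b) != sign(stats::cov(xs, ys)) && abs(stats::cov(xs, ys)) > 0)
    b <- -1 / b  # eigen may return the minor-axis-orthogonal orientation
  b * diff(range(y)) / diff(range(x))
}

# NB log-likelihood from the raw pmf via lgamma (no dnbinom)
nb_loglik_bf <- function(y, mu, phi) {
  r <- 1 / phi
  sum(lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
        r * log(r / (r + mu)) + y * log(mu / (r + mu)))
}

# closed-form solution of dP/dt = a*M0*exp(k t) - d*P, P(0) = p0
ode_closed_form <- function(t, M0, k, a, d, p0) {
  part <- a * M0 / (d + k) * exp(k * t)
  C <- p0 - a * M0 / (d + k)
  part + C * exp(-d * t)
}

# adjusted Rand index between two partitions
ari_bf <- function(a, b) {
  tab <- table(a, b)
  sc <- function(x) sum(choose(x, 2))
  nij <- sc(tab)
  ai <- sc(rowSums(tab))
  bj <- sc(colSums(tab))
  nn <- choose(sum(tab), 2)
  (nij - ai * bj / nn) / ((ai + bj) / 2 - ai * bj / nn)
}

# standard generated dataset + preprocessing used by several files
prep_dataset <- function(cfg) {
  ds <- generate_paired_dataset(cfg)
  counts <- filter_expressed(collapse_to_protein_coding(ds$counts, ds$genes))
  imp <- impute_minprob(ds$intensities, imputation_params(seed = cfg$seed))
  list(ds = ds, counts = counts, imp = imp,
       rna_frac = fraction_of_total(counts),
       prot_frac = fraction_of_total(imp, delog2 = TRUE))
}
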