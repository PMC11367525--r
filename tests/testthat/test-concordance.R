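# fraction scaling, correlations, lag matrix, RMA, matched pairing, shares

test_that("fraction-of-total columns sum to one", {
  st <- st_fix(0, 3)
  y <- matrix(c(2, 3, 5, 1, 1, 2, 7, 2, 1), 3,
              dimnames = list(c("a", "b", "c"), st$sample_id))
  f <- fraction_of_total(y)
  expect_equal(f[, 1], c(a = 0.2, b = 0.3, c = 0.5))
  expect_equal(unname(colSums(f)), rep(1, 3), tolerance = 1e-12)
  # n equal genes -> 1/n each
  f2 <- fraction_of_total(matrix(7, 4, 3,
                                 dimnames = list(letters[1:4],
                                                 st$sample_id)))
  expect_true(all(f2 == 0.25))
  expect_error(fraction_of_total(y * NA), "complete")
})

test_that("correlations agree with brute-force rank/covariance oracles", {
  # worked examples (rank formula: 1 - 6*sum(d^2)/(n(n^2-1)), d^2 sums to 4)
  expect_equal(spearman_bf(1:5, c(2, 1, 4, 3, 5)), 1 - 6 * 4 / (5 * 24))
  expect_equal(stats::cor(1:5, c(2, 1, 4, 3, 5), method = "spearman"),
               spearman_bf(1:5, c(2, 1, 4, 3, 5)))
  expect_equal(pearson_bf(c(1, 2, 3), c(1, 3, 2)), 0.5)

  # exhaustive small-case equivalence against the package's machinery,
  # via across_gene_correlation / per_gene_correlations on crafted inputs
  set.seed(4)
  st1 <- st_fix(0, 1)
  stp <- st_fix(0, 1, "protein")
  for (i in 1:20) {
    n <- sample(4:6, 1)
    x <- sample(100, n)  # distinct values
    y <- sample(100, n)
    gx <- sprintf("g%d", seq_len(n))
    mr <- omic_matrix(matrix(x / sum(x), n, 1,
                             dimnames = list(gx, st1$sample_id)),
                      st1, "fraction")
    mp <- omic_matrix(matrix(y / sum(y), n, 1,
                             dimnames = list(gx, stp$sample_id)),
                      stp, "fraction")
    expect_equal(across_gene_correlation(mr, mp, 0, 0),
                 spearman_bf(x, y), tolerance = 1e-12)
  }

  # per-gene Pearson over paired samples: affine protein = r = 1
  st3 <- st_fix(c(0, 2, 4), 1, plates = TRUE)
  st3p <- st_fix(c(0, 2, 4), 1, "protein", plates = TRUE)
  xr <- matrix(c(1, 2, 3, 2, 4, 1), 2, byrow = TRUE,
               dimnames = list(c("gA", "gB"), st3$sample_id))
  fr <- omic_matrix(xr, st3, "fraction")
  as_prot <- function(v) {
    colnames(v) <- st3p$sample_id
    omic_matrix(v, st3p, "fraction")
  }
  r <- per_gene_correlations(fr, as_prot(3 * xr + 1))
  expect_equal(r$r, c(1, 1))
  expect_equal(per_gene_correlations(fr, as_prot(-xr + 10))$r, c(-1, -1))
  # x=[1,2,3], y=[1,3,2] -> r = 0.5; zero-variance gene flagged
  r2 <- per_gene_correlations(fr, as_prot(rbind(gA = c(1, 3, 2),
                                                gB = c(5, 5, 5))))
  expect_equal(r2$r[1], 0.5)
  expect_false(r2$defined[2])
})

test_that("the lag matrix diagonal matches per-time-point correlations", {
  prep <- prep_dataset(sim_config(n_genes = 300, seed = 9))
  lag <- lag_matrix(prep$rna_frac, prep$prot_frac)
  shared <- intersect(unique(prep$rna_frac$samples$time_h),
                      unique(prep$prot_frac$samples$time_h))
  for (t in shared) {
    expect_identical(unname(lag$per_timepoint_rho[sprintf("%gh", t)]),
                     across_gene_correlation(prep$rna_frac, prep$prot_frac,
                                             t, t))
  }
  # self-match: RNA against itself peaks on the diagonal at lag 0
  rs <- prep$rna_frac
  stf <- st_fix(c(0, 2, 4, 6, 8, 10), 4, "protein")
  vals <- rs$values
  colnames(vals) <- stf$sample_id
  self <- lag_matrix(rs, omic_matrix(vals, stf, "fraction"))
  expect_equal(self$estimated_lag_h, 0)
  expect_equal(unname(diag(self$lag_matrix)),
               rep(1, 6), tolerance = 1e-12)
})

test_that("ranged-major-axis regression matches its oracle and symmetry", {
  # exact line
  x <- c(0, 1, 2, 5)
  fit <- rma_regression(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)

  # swap symmetry and oracle equivalence on a Gaussian cloud
  set.seed(5)
  xg <- rnorm(200)
  yg <- 1.5 * xg + rnorm(200, 0, 0.7)
  f1 <- rma_regression(xg, yg)
  f2 <- rma_regression(yg, xg)
  expect_equal(f1$slope, 1 / f2$slope, tolerance = 1e-10)
  expect_equal(f1$slope, rma_bf(xg, yg), tolerance = 1e-10)

  expect_error(rma_regression(rep(1, 5), 1:5), "positive range")
})

test_that("matched plate pairing beats mismatched permutations", {
  prep <- prep_dataset(sim_config(n_genes = 600, plate_effect_sd = 0.3,
                                  seed = 10))
  mm <- matched_vs_mismatched(prep$rna_frac, prep$prot_frac, n_perm = 200,
                              seed = 10)
  expect_gt(mm$matched_median_r, mm$mismatched_median_r)
  expect_lt(mm$p, 0.05)

  # exchangeable world: no plate effect, matched is nothing special
  prep0 <- prep_dataset(sim_config(n_genes = 600, plate_effect_sd = 0,
                                   seed = 11))
  mm0 <- matched_vs_mismatched(prep0$rna_frac, prep0$prot_frac,
                               n_perm = 200, seed = 11)
  expect_gt(mm0$p, 0.05)
  expect_lt(abs(mm0$matched_median_r - mm0$mismatched_median_r), 0.05)

  # single replicate per time point: no permutation exists
  one <- sim_config(n_genes = 50, n_reps_rna = 1, n_reps_protein = 1,
                    seed = 12)
  prep1 <- prep_dataset(one)
  expect_error(matched_vs_mismatched(prep1$rna_frac, prep1$prot_frac,
                                     n_perm = 10, seed = 1),
               "no valid permutation")
})

test_that("top-k abundance share matches a sort-and-sum oracle", {
  st <- st_fix(0, 1)
  f <- matrix(c(0.5, 0.3, 0.2), 3,
              dimnames = list(c("a", "b", "c"), st$sample_id))
  expect_equal(top_k_share(f, 2), 0.8)
  expect_equal(top_k_share(matrix(0.1, 10, 1,
                                  dimnames = list(letters[1:10], "s")), 2),
               0.2)
  set.seed(6)
  x <- rgamma(50, 0.3)
  fr <- matrix(x / sum(x), dimnames = list(sprintf("g%d", 1:50), "s"))
  expect_equal(top_k_share(fr, 5), sum(rev(sort(x / sum(x)))[1:5]))
})
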