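# multi-view SVD factors, gene selection, loading GSEA

# planted two-view world: a shared factor and an optional mRNA-only factor,
# with component strengths set as fractions of total variance
plant_views <- function(n = 400, share_shared = 0.6, share_rna_only = 0,
                        noise = 1, seed = 1, tps = c(0, 2, 4, 6, 8, 10)) {
  set.seed(seed)
  nt <- length(tps)
  unitize <- function(v) {
    v <- v - mean(v)
    v / sqrt(sum(v^2))
  }
  lin <- unitize(tps)
  dip <- unitize(-exp(-(tps - 5)^2 / 6))
  w1 <- rnorm(n)
  w2 <- rnorm(n)
  base <- matrix(rnorm(n * nt, 0, noise), n, nt)
  base2 <- matrix(rnorm(n * nt, 0, noise), n, nt)
  # amplitude making the planted component carry `share` of total variance:
  # |a*(w %o% lin)|^2 = a^2*n, noise carries ~ n*nt*noise^2
  amp <- function(share) sqrt(share / (1 - share)) * sqrt(nt) * noise
  a1 <- amp(share_shared)
  rna <- a1 * (w1 %o% lin) + base
  prot <- a1 * (w1 %o% lin) + base2
  if (share_rna_only > 0)
    rna <- rna + amp(share_rna_only) * (w2 %o% dip)
  gn <- sprintf("g%03d", seq_len(n))
  dimnames(rna) <- dimnames(prot) <- list(gn, sprintf("c%d", seq_len(nt)))
  attr(rna, "time_h") <- attr(prot, "time_h") <- tps
  list(rna = rna, prot = prot, w1 = w1, tps = tps)
}

test_that("a planted shared factor is recovered with its variance share", {
  pv <- plant_views(share_shared = 0.6, seed = 1,
                    tps = rep(c(0, 2, 4, 8, 10), each = 3))
  fm <- fit_multiview_factors(pv$rna, pv$prot, K = 3)
  expect_lt(abs(fm$var_explained["Factor1", "rna"] - 60), 10)
  expect_lt(abs(fm$var_explained["Factor1", "protein"] - 60), 10)
  # factor 1 tracks time monotonically (replicate-averaged trajectory)
  fbar <- tapply(fm$factors[, 1], rep(c(0, 2, 4, 8, 10), each = 3), mean)
  expect_true(all(diff(fbar) > 0) || all(diff(fbar) < 0))
  # sign convention: non-negative value at the last time point
  expect_gte(fm$factors[nrow(fm$factors), 1], 0)
})

test_that("a pure-noise protein view loads almost nothing on factor 1", {
  # replicate-level columns (15 plate-aligned samples), so a random
  # direction can only soak up ~1/15 of a white-noise view
  reps <- rep(c(0, 2, 4, 8, 10), each = 3)
  pv <- plant_views(share_shared = 0.6, seed = 2, tps = reps)
  set.seed(22)
  noise_prot <- matrix(rnorm(length(pv$prot)), nrow(pv$prot),
                       dimnames = dimnames(pv$prot))
  attr(noise_prot, "time_h") <- reps
  fm <- fit_multiview_factors(pv$rna, noise_prot, K = 3)
  expect_lt(fm$var_explained["Factor1", "protein"], 10)
})

test_that("full-rank decomposition accounts for all variance per view", {
  pv <- plant_views(n = 40, seed = 3)
  fm <- fit_multiview_factors(pv$rna, pv$prot, K = 6)
  expect_equal(unname(colSums(fm$var_explained)), c(100, 100),
               tolerance = 1e-8)
  expect_true(all(fm$var_explained >= 0))
  expect_true(all(abs(fm$loadings$rna) <= 1 + 1e-12))
  expect_error(fit_multiview_factors(pv$rna, pv$prot, K = 20), "rank")
})

test_that("the mRNA-only dip factor reproduces the variance asymmetry", {
  pv <- plant_views(share_shared = 0.35, share_rna_only = 0.3, seed = 4,
                    tps = rep(c(0, 2, 4, 8, 10), each = 3))
  fm <- fit_multiview_factors(pv$rna, pv$prot, K = 3)
  ve <- fm$var_explained
  # protein variance concentrates in factor 1; the dip factor is mRNA-only
  expect_gt(ve["Factor1", "protein"], ve["Factor2", "protein"] + 10)
  expect_gt(ve["Factor2", "rna"], 15)
  expect_lt(ve["Factor2", "protein"], 10)
})

test_that("factor gene selection applies the both-view threshold and signs", {
  fm <- list(loadings = list(
    rna = matrix(c(0.5, 0.5, 0.3, -0.6), 4, 1,
                 dimnames = list(c("a", "b", "c", "d"), "Factor1")),
    protein = matrix(c(0.5, -0.5, 0.9, -0.7), 4, 1,
                     dimnames = list(c("a", "b", "c", "d"), "Factor1"))))
  class(fm) <- "factor_model"
  sel <- select_factor_genes(fm, 1, threshold = 0.45)
  expect_equal(sel$gene_id, c("a", "b", "d"))  # c fails the rna threshold
  expect_equal(sel$class,
               c("concordant_up", "discordant", "concordant_down"))
})

test_that("loading GSEA is calibrated, extreme on top sets, and affine-safe", {
  pv <- plant_views(n = 200, seed = 5)
  fm <- fit_multiview_factors(pv$rna, pv$prot, K = 2)
  w <- fm$loadings$rna[, 1]
  top <- names(sort(abs(w), decreasing = TRUE))  # by signed value below
  top_pos <- names(sort(w, decreasing = TRUE))[1:10]
  res <- gsea_factor_weights(fm, "rna", 1,
                             list(top = top_pos,
                                  all = names(w)), n_perm = 499, seed = 6)
  expect_equal(res$p[res$term == "top"], 1 / 500)
  expect_equal(res$p[res$term == "all"], 1)
  expect_equal(res$mean_weight[res$term == "all"], mean(w))

  # affine rescaling of the loadings leaves p untouched
  fm2 <- fm
  fm2$loadings$rna <- 3 * fm$loadings$rna + 0.2
  res2 <- gsea_factor_weights(fm2, "rna", 1, list(top = top_pos),
                              n_perm = 499, seed = 6)
  expect_equal(res2$p, res$p[res$term == "top"])

  # null calibration: random sets give uniform p
  set.seed(7)
  null_sets <- lapply(1:150, function(i) sample(names(w), 15))
  names(null_sets) <- sprintf("ns%03d", 1:150)
  resn <- gsea_factor_weights(fm, "rna", 2, null_sets, n_perm = 199,
                              seed = 8)
  expect_gt(suppressWarnings(stats::ks.test(resn$p, "punif")$p.value), 0.01)
})
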