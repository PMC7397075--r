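# Summarization, normalization, variance filter and PCA.

test_that("single-probe genes pass through as log2", {
  probes <- list(
    intensities = matrix(c(4, 8), 1, 2,
                         dimnames = list("gA_p1", c("s1", "s2"))),
    probe_map = data.frame(probe_id = "gA_p1", gene_id = "gA"))
  expect_equal(unname(summarize_probes(probes)["gA", ]), c(2, 3))
})

test_that("median polish recovers column effects of an additive matrix", {
  set.seed(1)
  col_eff <- rnorm(6)
  row_eff <- rnorm(3)
  lx <- outer(row_eff, col_eff, `+`) + 5
  probes <- list(
    intensities = 2^lx,
    probe_map = data.frame(probe_id = paste0("p", 1:3), gene_id = "g1"))
  rownames(probes$intensities) <- probes$probe_id
  colnames(probes$intensities) <- paste0("s", 1:6)
  out <- summarize_probes(probes)["g1", ]
  # equal to the true column effects up to one additive constant
  expect_lt(diff(range(out - col_eff)), 1e-6)
})

test_that("summarization is invariant to probe row order", {
  ds <- make_small_dataset(n_genes = 20, seed = 11)
  pm <- ds$probes
  perm <- sample(nrow(pm$intensities))
  pm2 <- pm
  pm2$intensities <- pm$intensities[perm, ]
  pm2$probe_map <- pm$probe_map[perm, ]
  out1 <- summarize_probes(pm)
  out2 <- summarize_probes(pm2)
  expect_equal(out1, out2[rownames(out1), ])
})

test_that("probe replication of a gene matrix is identity up to log2", {
  set.seed(2)
  gm <- matrix(2^rnorm(40, 8), 10, 4,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  probes <- list(
    intensities = gm[rep(1:10, each = 3), ],
    probe_map = data.frame(probe_id = paste0("g", rep(1:10, each = 3),
                                             "_p", 1:3),
                           gene_id = paste0("g", rep(1:10, each = 3))))
  rownames(probes$intensities) <- probes$probe_map$probe_id
  expect_equal(summarize_probes(probes), log2(gm))
})

test_that("non-positive intensities are rejected with the probe named", {
  probes <- list(
    intensities = matrix(c(1, -2, 3, 4), 2, 2,
                         dimnames = list(c("pa", "pb"), c("s1", "s2"))),
    probe_map = data.frame(probe_id = c("pa", "pb"),
                           gene_id = c("g1", "g1")))
  expect_error(summarize_probes(probes), "pb")
})

test_that("quantile normalization matches the sorted-mean contract", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))

  set.seed(3)
  x <- matrix(rnorm(60, 8), 15, 4,
              dimnames = list(paste0("g", 1:15), paste0("s", 1:4)))
  qn <- quantile_normalize(x)
  # identical sorted multiset in every column, equal column means
  for (j in 2:4) expect_equal(sort(qn[, j]), sort(qn[, 1]),
                              ignore_attr = TRUE)
  expect_equal(unname(colMeans(qn)), rep(mean(qn[, 1]), 4))
  # rank preservation and idempotence
  for (j in 1:4) expect_equal(rank(qn[, j]), rank(x[, j]))
  expect_equal(quantile_normalize(qn), qn)
  # identical columns are a fixed point
  same <- cbind(s1 = x[, 1], s2 = x[, 1])
  expect_equal(quantile_normalize(same), same)
  expect_warning(out <- quantile_normalize(x[, 1, drop = FALSE]), "no-op|unchanged")
  expect_equal(out, x[, 1, drop = FALSE])
})

test_that("quantile normalization agrees with limma on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(4)
  x <- matrix(rnorm(200, 10, 2), 50, 4)
  expect_equal(unname(quantile_normalize(x)),
               unname(limma::normalizeQuantiles(x)), tolerance = 1e-12)
})

test_that("variance filter ranks genes by sigma/sigma-max", {
  m <- rbind(g1 = c(0, 1, 2) * sqrt(3 / 2),   # sd 1.0 (up to scaling)
             g2 = c(0, 0.8, 1.6) * sqrt(3 / 2),
             g3 = c(0, 0.5, 1.0) * sqrt(3 / 2))
  colnames(m) <- paste0("s", 1:3)
  vf <- variance_filter(m, threshold = 0.7)
  expect_equal(round(vf$report$sigma_ratio, 10), c(1.0, 0.8, 0.5))
  expect_equal(vf$report$kept, c(TRUE, TRUE, FALSE))
  expect_equal(rownames(vf$matrix), c("g1", "g2"))

  # constant gene removed whenever any non-constant gene is present
  m2 <- rbind(flat = c(5, 5, 5), varying = c(1, 5, 9))
  colnames(m2) <- paste0("s", 1:3)
  expect_equal(variance_filter(m2, 0.7)$report$kept, c(FALSE, TRUE))
  # threshold 0 keeps everything; max-sigma gene always kept
  expect_true(all(variance_filter(m2, 0)$report$kept))
  expect_true(variance_filter(m2, 1)$report$kept[2])
  # monotone in threshold
  set.seed(5)
  m3 <- matrix(rnorm(100), 20, 5)
  rownames(m3) <- paste0("g", 1:20); colnames(m3) <- paste0("s", 1:5)
  for (pair in list(c(0.2, 0.5), c(0.5, 0.9))) {
    k1 <- variance_filter(m3, pair[1])$report$kept
    k2 <- variance_filter(m3, pair[2])$report$kept
    expect_true(all(which(k2) %in% which(k1)))
  }
  # empty input
  empty <- variance_filter(m3[0, , drop = FALSE], 0.7)
  expect_equal(nrow(empty$matrix), 0)
  expect_equal(nrow(empty$report), 0)
})

test_that("variance filter can exclude/include the tetraploid sample", {
  design <- generate_design(2, 1, 2, 2)
  m <- matrix(5, 2, nrow(design),
              dimnames = list(c("g1", "g2"), design$sample_id))
  # g1 varies only in the tetraploid; g2 varies in diploids
  m["g1", design$sample_id[design$ploidy == 4]] <- c(9, 1)
  m["g2", design$sample_id[design$ploidy == 2][1:2]] <- c(9, 1)
  r_excl <- variance_filter(m, 0.5, design)$report
  expect_equal(r_excl$sigma[r_excl$gene_id == "g1"], 0)
  r_incl <- variance_filter(m, 0.5, design, include_tetraploid = TRUE)$report
  expect_gt(r_incl$sigma[r_incl$gene_id == "g1"], 0)
})

test_that("PCA scores separate planted structure and behave numerically", {
  set.seed(6)
  base <- rnorm(30)
  grp1 <- sapply(1:4, function(i) base + rnorm(30, 0, 0.1))
  grp2 <- sapply(1:4, function(i) base + 5 + rnorm(30, 0, 0.1))
  m <- cbind(grp1, grp2)
  dimnames(m) <- list(paste0("g", 1:30), paste0("s", 1:8))
  pc <- pca_scores(m, 2)
  expect_equal(mean(pc$scores$PC1), 0, tolerance = 1e-10)
  expect_equal(mean(pc$scores$PC2), 0, tolerance = 1e-10)
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  expect_lte(sum(pc$var_explained), 1)
  # PC1 splits the two offset groups with consistent signs
  s1 <- pc$scores$PC1[1:4]; s2 <- pc$scores$PC1[5:8]
  expect_true(all(s1 < 0) && all(s2 > 0) || all(s1 > 0) && all(s2 < 0))
  expect_error(pca_scores(m, 8), "smaller")
  expect_error(pca_scores(m[, 1, drop = FALSE]), "2 samples")
})

test_that("samples cluster by ploidy in PCA on simulated data", {
  skip_if_not_installed("cluster")
  ds <- make_small_dataset(n_genes = 300, seed = 12)
  nm <- quantile_normalize(ds$expr)
  pc <- pca_scores(nm, 2)
  xy <- as.matrix(pc$scores[, c("PC1", "PC2")])
  lab <- as.integer(factor(ds$design$ploidy))
  sil <- cluster::silhouette(lab, dist(xy))
  expect_gt(mean(sil[, "sil_width"]), 0)
})
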