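two_cluster_matrix <- function(n_genes = 20L, shift = 0.3, seed = 51) {
  set.seed(seed)
  base <- matrix(stats::runif(n_genes * 8L, 0.3, 0.6), n_genes, 8L)
  base[1:(n_genes / 2), 5:8] <- base[1:(n_genes / 2), 5:8] + shift
  dimnames(base) <- list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%d", 1:8))
  mm(pmin(base, 1))
}

test_that("PCA embeds duplicated samples at coincident points", {
  values <- matrix(stats::runif(30L), 10L, 3L,
                   dimnames = list(paste0("g", 1:10), c("a", "b", "c")))
  values <- cbind(values, a2 = values[, "a"])
  emb <- pca_embed(mm(values), k = 2L)
  expect_equal(emb$coordinates["a", ], emb$coordinates["a2", ],
               tolerance = 1e-10)
  expect_true(all(emb$variance_explained >= 0 &
                    emb$variance_explained <= 1))
  expect_true(all(diff(emb$variance_explained) <= 1e-12))
  expect_lte(sum(emb$variance_explained), 1 + 1e-12)
})

test_that("PCA separates constructed clusters on PC1", {
  mat <- two_cluster_matrix()
  emb <- pca_embed(mat, k = 2L)
  labels <- stats::setNames(rep(c("g1", "g2"), each = 4L),
                            emb$sample_ids)
  pc1 <- emb$coordinates[, 1L]
  expect_true(max(pc1[1:4]) < min(pc1[5:8]) ||
                min(pc1[1:4]) > max(pc1[5:8]))
  expect_gt(separation_score(emb, labels), 0.5)
})

test_that("PCA is invariant to gene order and per-gene constant shifts", {
  mat <- two_cluster_matrix()
  emb <- pca_embed(mat, k = 2L)
  perm <- sample(nrow(mat$values))
  emb_perm <- pca_embed(mm(mat$values[perm, , drop = FALSE]), k = 2L)
  # identical up to per-axis sign
  for (j in 1:2) {
    expect_true(isTRUE(all.equal(emb$coordinates[, j],
                                 emb_perm$coordinates[, j])) ||
                  isTRUE(all.equal(emb$coordinates[, j],
                                   -emb_perm$coordinates[, j])))
  }
  shifted <- mat$values
  shifted[3L, ] <- shifted[3L, ] - min(shifted[3L, ])  # stays in [0,1]
  emb_shift <- pca_embed(mm(shifted), k = 2L)
  for (j in 1:2) {
    expect_true(isTRUE(all.equal(emb$coordinates[, j],
                                 emb_shift$coordinates[, j])) ||
                  isTRUE(all.equal(emb$coordinates[, j],
                                   -emb_shift$coordinates[, j])))
  }
})

test_that("genes with missing values are dropped before ordination", {
  mat <- two_cluster_matrix()
  holed <- mat$values
  holed[2L, 1L] <- NA
  emb <- pca_embed(mm(holed), k = 2L)
  expect_equal(emb$n_genes_dropped, 1L)
  expect_equal(emb$n_genes_used, nrow(holed) - 1L)
  expect_error(pca_embed(mat, k = 10L), "rank")
})

test_that("classical MDS reproduces Euclidean geometry", {
  # three equidistant samples form an equilateral triangle
  values <- matrix(c(1, 0, 0,
                     0, 1, 0,
                     0, 0, 1), nrow = 3L,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  emb <- mds_embed(mm(values / 2), k = 2L)
  d <- stats::dist(emb$coordinates)
  expect_equal(max(d), min(d), tolerance = 1e-9)

  # full-dimensional embedding reproduces the input distances
  mat <- two_cluster_matrix()
  full <- mds_embed(mat, k = ncol(mat$values) - 1L)
  expect_equal(as.numeric(stats::dist(full$coordinates)),
               as.numeric(stats::dist(t(mat$values))),
               tolerance = 1e-8)

  # identical samples land on the same point
  dup <- cbind(mat$values, s1b = mat$values[, 1L])
  emb_dup <- mds_embed(mm(dup), k = 2L)
  expect_equal(emb_dup$coordinates["s1", ], emb_dup$coordinates["s1b", ],
               tolerance = 1e-9)
})

test_that("MDS on Euclidean distances equals PCA scores up to rotation", {
  set.seed(52)
  for (i in 1:5) {
    values <- matrix(stats::runif(15L * 7L), 15L, 7L,
                     dimnames = list(sprintf("g%02d", 1:15),
                                     sprintf("s%d", 1:7)))
    pca <- pca_embed(mm(values), k = 2L)
    mds <- mds_embed(mm(values), k = 2L)
    expect_lt(procrustes_residual(pca$coordinates, mds$coordinates),
              1e-6)
  }
})

test_that("separation score is high for tight clusters, near zero for noise", {
  set.seed(53)
  # two tight far-apart clusters: within/between spread ratio ~ 1:100
  coords <- rbind(matrix(stats::rnorm(10L, 0, 0.01), 5L, 2L),
                  matrix(stats::rnorm(10L, 2, 0.01), 5L, 2L))
  rownames(coords) <- paste0("s", 1:10)
  emb <- structure(list(sample_ids = rownames(coords),
                        coordinates = coords,
                        variance_explained = c(1, 0), method = "pca"),
                   class = "embedding")
  labels <- stats::setNames(rep(c("a", "b"), each = 5L), rownames(coords))
  expect_gt(separation_score(emb, labels), 0.9)

  # duplicated points per group approach the score-1 limit
  dup_coords <- rbind(matrix(0, 4L, 2L), matrix(5, 4L, 2L))
  rownames(dup_coords) <- paste0("s", 1:8)
  emb_dup <- structure(list(sample_ids = rownames(dup_coords),
                            coordinates = dup_coords,
                            variance_explained = c(1, 0),
                            method = "pca"), class = "embedding")
  dup_labels <- stats::setNames(rep(c("a", "b"), each = 4L),
                                rownames(dup_coords))
  expect_equal(separation_score(emb_dup, dup_labels), 1)

  # random labels on one Gaussian cloud: |score| < 0.15 across seeds
  scores <- vapply(1:10, function(s) {
    set.seed(s)
    cloud <- matrix(stats::rnorm(40L), 20L, 2L,
                    dimnames = list(paste0("s", 1:20), NULL))
    e <- structure(list(sample_ids = rownames(cloud),
                        coordinates = cloud,
                        variance_explained = c(0.5, 0.5),
                        method = "pca"), class = "embedding")
    l <- stats::setNames(sample(rep(c("a", "b"), each = 10L)),
                         rownames(cloud))
    separation_score(e, l)
  }, numeric(1L))
  expect_lt(max(abs(scores)), 0.15)

  one_group <- stats::setNames(rep("a", 10L), paste0("s", 1:10))
  expect_error(separation_score(emb, one_group), "at least 2 groups")
})

test_that("chi-square enrichment matches the 2x2 formula and chisq.test", {
  res <- chisq_enrichment(10L, 90L, 20L, 80L)
  expect_equal(res$chi2, oracle_chisq_2x2(10, 90, 20, 80))
  expect_equal(res$chi2, 3.921569, tolerance = 1e-6)
  expect_equal(res$fold_enrichment, 0.5)

  eq <- chisq_enrichment(10L, 30L, 20L, 60L)
  expect_equal(eq$chi2, 0)
  expect_equal(eq$fold_enrichment, 1)

  # transposition symmetry of the chi-square statistic
  expect_equal(chisq_enrichment(7L, 13L, 5L, 25L)$chi2,
               chisq_enrichment(7L, 5L, 13L, 25L)$chi2)

  set.seed(54)
  for (i in 1:50) {
    tab <- matrix(sample(1:30, 4L, replace = TRUE), 2L)
    res <- chisq_enrichment(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(res$chi2, ref$statistic[[1L]], tolerance = 1e-12)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(res$chi2, oracle_chisq_2x2(tab[1, 1], tab[1, 2],
                                            tab[2, 1], tab[2, 2]),
                 tolerance = 1e-12)
  }

  expect_error(chisq_enrichment(0L, 0L, 5L, 5L), "zero margin")
  expect_error(chisq_enrichment(-1L, 2L, 3L, 4L), "non-negative")
})

test_that("welch t statistic matches the formula and t.test", {
  ident <- welch_t_compare(c(0.2, 0.4, 0.6), c(0.6, 0.2, 0.4))
  expect_equal(ident$t, 0)
  expect_equal(ident$p_value, 1)

  jit <- welch_t_compare(c(0, 0, 0, 0) + 1e-6 * (1:4),
                         c(1, 1, 1, 1) + 1e-6 * (1:4))
  expect_lt(jit$p_value, 1e-6)

  set.seed(55)
  for (i in 1:40) {
    a <- stats::rnorm(sample(3:10, 1L))
    b <- stats::rnorm(sample(3:10, 1L), mean = stats::runif(1L))
    ours <- welch_t_compare(a, b)
    ref <- stats::t.test(a, b)
    expect_equal(ours$t, ref$statistic[[1L]], tolerance = 1e-12)
    expect_equal(ours$df, ref$parameter[[1L]], tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }

  deg <- welch_t_compare(c(1, 1), c(1, 1))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  expect_error(welch_t_compare(1, c(1, 2)), "at least 2")
})
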