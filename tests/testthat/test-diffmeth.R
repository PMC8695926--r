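test_that("wilcoxon rank-sum matches hand-derived and enumerated values", {
  res <- wilcoxon_rank_sum(1:3, 4:6)
  expect_equal(res$statistic, 6)
  expect_equal(res$p_value, 0.1)   # 2 / choose(6, 3)
  expect_equal(res$method, "exact")

  same <- wilcoxon_rank_sum(c(1, 5, 9), c(9, 1, 5))
  expect_gte(same$p_value, 0.9)

  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "nonempty")
})

test_that("exact wilcoxon p equals the independent oracle on random instances", {
  set.seed(101)
  for (i in 1:120) {
    nx <- sample(2:8, 1L); ny <- sample(2:8, 1L)
    v <- sample(1000L, nx + ny)   # tie-free
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    ours <- wilcoxon_rank_sum(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$method, "exact")
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, ref$statistic[[1L]] + nx * (nx + 1) / 2)
  }
})

test_that("tied or large samples use the tie-corrected normal approximation", {
  set.seed(102)
  for (i in 1:40) {
    x <- sample(1:5, 12L, replace = TRUE)
    y <- sample(2:6, 15L, replace = TRUE)
    ours <- wilcoxon_rank_sum(x, y)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(ours$method, "normal")
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  # all values identical: no evidence of a shift
  expect_equal(wilcoxon_rank_sum(rep(1, 25), rep(1, 3))$p_value, 1)
})

test_that("kruskal-wallis reproduces the hand-computed H and kruskal.test", {
  res <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(res$statistic, 7.2)
  expect_equal(res$df, 2L)
  ref <- stats::kruskal.test(list(1:3, 4:6, 7:9))
  expect_equal(res$statistic, ref$statistic[[1L]])
  expect_equal(res$p_value, ref$p.value)

  set.seed(103)
  for (i in 1:25) {
    g <- replicate(3, sample(1:6, 7L, replace = TRUE), simplify = FALSE)
    ours <- kruskal_wallis(g)
    ref <- stats::kruskal.test(g)
    expect_equal(ours$statistic, ref$statistic[[1L]], tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }

  # invariant to group order
  a <- kruskal_wallis(list(c(1, 4, 2), c(3, 8), c(5, 5, 9)))
  b <- kruskal_wallis(list(c(5, 5, 9), c(1, 4, 2), c(3, 8)))
  expect_equal(a$statistic, b$statistic)

  deg <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)

  expect_error(kruskal_wallis(list(1:3)), "at least 2")
})

test_that("two-group kruskal-wallis equals the squared-z wilcoxon", {
  set.seed(104)
  for (i in 1:20) {
    x <- round(stats::runif(9L), 2L); y <- round(stats::runif(7L), 2L)
    kw <- kruskal_wallis(list(x, y))
    wz <- wilcoxon_rank_sum(x, y, exact_max_n = 0L, correct = FALSE)
    expect_equal(kw$p_value, wz$p_value, tolerance = 1e-9)
  }
})

test_that("benjamini-hochberg implements the step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04, 0.05)),
               rep(0.05, 5L))
  expect_equal(benjamini_hochberg(0.037), 0.037)
  expect_equal(benjamini_hochberg(rep(1, 4L)), rep(1, 4L))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(105)
  for (i in 1:60) {
    m <- sample(1:40, 1L)
    p <- stats::runif(m)^sample(1:3, 1L)
    q <- benjamini_hochberg(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p))
    # order invariance after mapping back
    perm <- sample(m)
    expect_equal(benjamini_hochberg(p[perm]), q[perm], tolerance = 1e-12)
    # monotone: sorting p sorts q
    expect_equal(benjamini_hochberg(sort(p)), sort(q), tolerance = 1e-12)
  }
})

test_that("differential_genes tests per gene and adjusts across tested genes", {
  values <- rbind(
    gA = c(0.1, 0.12, 0.11, 0.52, 0.55, 0.5),
    gB = c(0.4, 0.41, 0.42, 0.40, 0.41, 0.43),
    gC = c(0.3, NA, NA, 0.31, 0.29, 0.33))   # group 1 has 1 value: skipped
  colnames(values) <- paste0("s", 1:6)
  labels <- stats::setNames(rep(c("hep", "mus"), each = 3L),
                            colnames(values))
  res <- differential_genes(mm(values), labels, "wilcoxon", alpha = 0.05)
  expect_equal(res$gene_id, c("gA", "gB"))
  expect_equal(attr(res, "skipped"), "gC")
  expect_equal(res$q_value, benjamini_hochberg(res$p_value))
  expect_true(all(c("mean_hep", "mean_mus") %in% names(res)))
  expect_equal(res$mean_hep[1L], mean(values["gA", 1:3]))

  # single tested gene: q = p, significant iff p < alpha
  one <- differential_genes(mm(values["gA", , drop = FALSE]), labels,
                            "wilcoxon", alpha = 0.05)
  expect_equal(one$q_value, one$p_value)

  # alpha = 1 flags every tested gene
  all_sig <- differential_genes(mm(values), labels, "wilcoxon", alpha = 1)
  expect_true(all(all_sig$significant))

  expect_error(differential_genes(mm(values), labels[1:3], "wilcoxon"),
               "labeled")
  expect_error(differential_genes(mm(values), labels, "nope"))
})

test_that("gene-set overlap is a plain set operation", {
  ov <- overlap_genes(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(ov$intersection, c("B", "C"))
  expect_equal(ov$n_a_only, 1L)
  expect_equal(ov$n_b_only, 1L)
  expect_length(overlap_genes("A", "B")$intersection, 0L)
  expect_equal(overlap_genes(c("A", "B"), c("B", "A"))$intersection,
               c("A", "B"))
})

make_profile_tables <- function() {
  pos <- c(10L, 20L, 30L, 40L, 50L, 60L)
  make <- function(ratios) {
    data.table::data.table(scaffold = "sc1", position = pos, strand = "+",
                           context = "CpG",
                           meth_count = as.integer(round(ratios * 10)),
                           total_count = 10L, ratio = ratios)
  }
  list(h1 = make(c(0.0, 0.1, 0.8, 0.9, 0.8, 0.1)),
       h2 = make(c(0.1, 0.1, 0.9, 1.0, 0.7, 0.0)),
       m1 = make(c(0.0, 0.2, 0.1, 0.2, 0.1, 0.1)),
       m2 = make(c(0.1, 0.0, 0.2, 0.1, 0.0, 0.2)))
}

test_that("per-CpG profiles are group means over qualifying sites", {
  tabs <- make_profile_tables()
  gene <- data.frame(gene_id = "g", scaffold = "sc1",
                     start = 1L, end = 100L)
  labels <- c(h1 = "hep", h2 = "hep", m1 = "mus", m2 = "mus")
  prof <- per_cpg_profile(gene, tabs, labels)
  expect_equal(nrow(prof), 6L)
  expect_equal(prof$hep, (tabs$h1$ratio + tabs$h2$ratio) / 2)
  expect_equal(prof$mus, (tabs$m1$ratio + tabs$m2$ratio) / 2)

  # single group / single sample
  solo <- per_cpg_profile(gene, tabs["h1"], labels)
  expect_equal(solo$hep, tabs$h1$ratio)

  off <- data.frame(gene_id = "off", scaffold = "sc1",
                    start = 900L, end = 950L)
  expect_error(per_cpg_profile(off, tabs, labels), "no qualifying CpGs")
})

test_that("the DMR scanner segments runs of discriminating CpGs", {
  prof <- data.frame(scaffold = "sc1", position = 10L * (1:12),
                     cpg_index = 1:12,
                     hep = c(0.1, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4, 0.1,
                             0.1, 0.1, 0.1, 0.1),
                     mus = 0.1)
  regions <- scan_dmrs(prof, min_sites = 5L, min_delta = 0.1,
                       max_gap = 2L)
  expect_equal(nrow(regions), 1L)
  expect_equal(regions$n_cpgs, 6L)
  expect_equal(regions$start, 20L)
  expect_equal(regions$end, 70L)
  expect_equal(regions$mean_abs_difference, 0.3)

  # all differences below threshold: no region
  flat <- prof; flat$hep <- flat$mus + 0.05
  expect_equal(nrow(scan_dmrs(flat)), 0L)

  # two runs separated by more than max_gap: two regions
  two <- data.frame(scaffold = "sc1", position = 10L * (1:16),
                    cpg_index = 1:16,
                    hep = c(rep(0.5, 5L), rep(0, 6L), rep(0.5, 5L)),
                    mus = 0)
  r2 <- scan_dmrs(two, min_sites = 5L, min_delta = 0.1, max_gap = 2L)
  expect_equal(nrow(r2), 2L)
  expect_equal(r2$n_cpgs, c(5L, 5L))
  # regions never overlap
  expect_true(all(r2$start[-1L] > head(r2$end, -1L)))

  # a short interruption within max_gap does not split the run
  gap <- data.frame(scaffold = "sc1", position = 10L * (1:10),
                    cpg_index = 1:10,
                    hep = c(0.5, 0.5, 0.5, 0, 0.5, 0.5, 0.5, 0, 0, 0),
                    mus = 0)
  rg <- scan_dmrs(gap, min_sites = 5L, min_delta = 0.1, max_gap = 2L)
  expect_equal(nrow(rg), 1L)
  expect_equal(rg$n_cpgs, 6L)

  # orientation reversal mirrors the regions
  rev_two <- two[rev(seq_len(nrow(two))), ]
  rev_two$position <- 10L * (1:16)
  rev_two$cpg_index <- 1:16
  rr <- scan_dmrs(rev_two, min_sites = 5L, min_delta = 0.1, max_gap = 2L)
  expect_equal(nrow(rr), 2L)
  expect_equal(rr$n_cpgs, c(5L, 5L))
})

test_that("capture/amplicon concordance is computed on shared positions", {
  cap <- data.frame(position = 10L * (1:6),
                    ratio = c(0.1, 0.3, 0.5, 0.7, 0.9, 0.2))
  ident <- amplicon_concordance(cap, cap)
  expect_equal(ident$pearson_r, 1)
  expect_equal(ident$mean_abs_diff, 0)
  expect_equal(ident$n_shared_cpgs, 6L)

  shifted <- cap; shifted$ratio <- shifted$ratio + 0.1
  sh <- amplicon_concordance(cap, shifted)
  expect_equal(sh$pearson_r, 1)
  expect_equal(sh$mean_abs_diff, 0.1)

  anti <- cap; anti$ratio <- 1 - cap$ratio
  expect_equal(amplicon_concordance(cap, anti)$pearson_r, -1)

  # only overlapping positions count
  partial <- data.frame(position = 10L * (4:9),
                        ratio = c(0.6, 0.8, 0.3, 0.5, 0.5, 0.5))
  expect_equal(amplicon_concordance(cap, partial)$n_shared_cpgs, 3L)
  expect_error(amplicon_concordance(cap[1:2, ], cap[1:2, ]),
               "at least 3")
})
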