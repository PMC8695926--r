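#' Wilcoxon rank-sum test (two-sided)
#'
#' The statistic is the rank sum W of the first group, computed with
#' midranks for ties. The p-value is exact -- by full enumeration of the
#' rank-sum distribution -- when the pooled sample is tie-free and no
#' larger than `exact_max_n`, and otherwise uses the normal approximation
#' with tie-corrected variance and (optionally) a continuity correction.
#'
#' @param x,y numeric value vectors for the two groups (NAs dropped).
#' @param exact_max_n largest pooled sample size for the exact path.
#' @param correct apply the continuity correction in the normal
#'   approximation.
#' @return list with `statistic` (W), `p_value`, `method`
#'   (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 20L, correct = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be nonempty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  ties <- anyDuplicated(c(x, y)) > 0L

  if (!ties && n <= exact_max_n) {
    sums <- colSums(utils::combn(n, nx))
    p_le <- sum(sums <= w) / length(sums)
    p_ge <- sum(sums >= w) / length(sums)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = w, p_value = p, method = "exact"))
  }

  mu <- nx * (n + 1) / 2
  tie_tab <- table(r)
  sigma2 <- nx * ny / 12 *
    ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) {  # all values identical
    return(list(statistic = w, p_value = 1, method = "normal"))
  }
  d <- w - mu
  cc <- if (correct) sign(d) * 0.5 else 0
  z <- (d - cc) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = w, p_value = p, method = "normal")
}

#' Kruskal-Wallis rank test
#'
#' H statistic with midranks and tie correction; the p-value comes from
#' the chi-square distribution with k - 1 degrees of freedom. When all
#' values are identical the tie-correction denominator vanishes; the
#' test then returns H = 0, p = 1 with `degenerate = TRUE`.
#'
#' @param groups list of two or more numeric vectors (NAs dropped).
#' @return list with `statistic` (H), `p_value`, `df`, `degenerate`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[lengths(groups) > 0L]
  k <- length(groups)
  if (k < 2L) stop("need at least 2 nonempty groups")
  n_i <- lengths(groups)
  n <- sum(n_i)
  if (n < 3L) stop("need at least 3 values in total")
  r <- rank(unlist(groups))
  grp <- rep(seq_len(k), n_i)
  rbar <- tapply(r, grp, mean)
  h <- 12 / (n * (n + 1)) * sum(n_i * (rbar - (n + 1) / 2)^2)
  tie_tab <- table(r)
  correction <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
  if (correction <= 0) {
    return(list(statistic = 0, p_value = 1, df = k - 1L, degenerate = TRUE))
  }
  h <- h / correction
  list(statistic = h,
       p_value = stats::pchisq(h, df = k - 1L, lower.tail = FALSE),
       df = k - 1L, degenerate = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Step-up false discovery rate adjustment: with p-values sorted
#' ascending, `q_(i) = min over j >= i of p_(j) * m / j`, clamped to 1,
#' returned in the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  o <- order(p_values)
  q_sorted <- p_values[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  # guard against one-ulp rounding below p in p * (m/j) at j = m
  pmax(q, p_values)
}

#' Per-gene rank-based differential methylation
#'
#' Runs the chosen rank test per gene over its non-missing values,
#' grouped by `labels`, then adjusts p-values across the tested genes
#' with [benjamini_hochberg()]. A gene is skipped (and reported in the
#' `skipped` attribute) when any group retains fewer than 2 non-missing
#' values; skipped genes do not enter the multiple-testing family.
#'
#' @param matrix a `methylation_matrix`.
#' @param labels named character vector mapping every sample id of the
#'   matrix to its group.
#' @param test `"wilcoxon"` (exactly 2 groups) or `"kruskal_wallis"`.
#' @param alpha significance level applied to the q-values.
#' @return data frame with one row per tested gene: `gene_id`, `test`,
#'   `statistic`, `p_value`, `q_value`, `significant`, and one
#'   `mean_<group>` column per group. Attributes: `skipped` (gene ids),
#'   `alpha`.
#' @export
differential_genes <- function(matrix, labels,
                               test = c("kruskal_wallis", "wilcoxon"),
                               alpha = 0.05) {
  test <- match.arg(test)
  stopifnot(inherits(matrix, "methylation_matrix"))
  values <- matrix$values
  if (!all(colnames(values) %in% names(labels))) {
    stop("every sample must be labeled")
  }
  grp <- labels[colnames(values)]
  group_levels <- sort(unique(grp))
  if (length(group_levels) < 2L) stop("need at least 2 groups")
  if (test == "wilcoxon" && length(group_levels) != 2L) {
    stop("wilcoxon requires exactly 2 groups")
  }

  rows <- vector("list", nrow(values))
  skipped <- character(0)
  for (i in seq_len(nrow(values))) {
    v <- values[i, ]
    by_group <- split(v[!is.na(v)], grp[!is.na(v)])
    by_group <- by_group[group_levels[group_levels %in% names(by_group)]]
    if (length(by_group) < length(group_levels) ||
        any(lengths(by_group) < 2L)) {
      skipped <- c(skipped, rownames(values)[i])
      next
    }
    res <- if (test == "wilcoxon") {
      wilcoxon_rank_sum(by_group[[1L]], by_group[[2L]])
    } else {
      kruskal_wallis(by_group)
    }
    means <- vapply(by_group, mean, numeric(1L))
    rows[[i]] <- data.frame(gene_id = rownames(values)[i], test = test,
                            statistic = res$statistic,
                            p_value = res$p_value,
                            t(means), check.names = FALSE,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) {
    out <- data.frame(gene_id = character(), test = character(),
                      statistic = numeric(), p_value = numeric(),
                      q_value = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    names(out)[-(1:4)] <- paste0("mean_", names(out)[-(1:4)])
    out$q_value <- benjamini_hochberg(out$p_value)
    out$significant <- out$q_value < alpha | alpha >= 1
    out <- out[, c("gene_id", "test", "statistic", "p_value", "q_value",
                   "significant",
                   grep("^mean_", names(out), value = TRUE))]
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped
  attr(out, "alpha") <- alpha
  out
}

#' Overlap between two gene sets
#'
#' @param set_a,set_b character vectors of gene ids.
#' @return list with `intersection` (sorted ids), `n_a_only`, `n_b_only`.
#' @export
overlap_genes <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  list(intersection = sort(intersect(set_a, set_b)),
       n_a_only = length(setdiff(set_a, set_b)),
       n_b_only = length(setdiff(set_b, set_a)))
}

#' Per-CpG group-mean methylation profile of one gene
#'
#' For each qualifying CpG inside the gene (coverage at least
#' `min_coverage` in every supplied sample), the mean methylation ratio
#' within each group, in genomic order.
#'
#' @param gene one gene-model row.
#' @param tables named list of per-sample methylation-call tables.
#' @param labels named character vector mapping sample ids to groups.
#' @param min_coverage per-sample coverage threshold (default 5).
#' @return data frame with `scaffold`, `position`, `cpg_index` and one
#'   column per group holding the group-mean ratio.
#' @export
per_cpg_profile <- function(gene, tables, labels, min_coverage = 5L) {
  if (!all(names(tables) %in% names(labels))) {
    stop("every sample must be labeled")
  }
  qualified <- qualifying_cpg_sites(tables, min_coverage)
  in_gene <- qualified[qualified$scaffold == gene$scaffold &
                       qualified$position >= gene$start &
                       qualified$position <= gene$end]
  if (nrow(in_gene) == 0L) stop("no qualifying CpGs in gene ", gene$gene_id)
  data.table::setorder(in_gene, position)

  groups <- sort(unique(labels[names(tables)]))
  prof <- data.frame(scaffold = in_gene$scaffold,
                     position = in_gene$position,
                     cpg_index = seq_len(nrow(in_gene)),
                     stringsAsFactors = FALSE)
  ratio_by_sample <- vapply(names(tables), function(s) {
    tab <- tables[[s]][tables[[s]]$scaffold == gene$scaffold, ]
    tab$ratio[match(in_gene$position, tab$position)]
  }, numeric(nrow(in_gene)))
  if (is.null(dim(ratio_by_sample))) {
    ratio_by_sample <- matrix(ratio_by_sample, nrow = nrow(in_gene),
                              dimnames = list(NULL, names(tables)))
  }
  for (g in groups) {
    members <- names(tables)[labels[names(tables)] == g]
    prof[[g]] <- rowMeans(ratio_by_sample[, members, drop = FALSE],
                          na.rm = TRUE)
  }
  prof
}

#' Scan per-CpG profiles for differentially methylated regions
#'
#' A simplified run-based scanner: a CpG is "discriminating" when the
#' largest pairwise difference between group means reaches `min_delta`.
#' Maximal runs of discriminating CpGs -- allowing interruptions of at
#' most `max_gap` non-discriminating CpGs -- are reported as regions when
#' they contain at least `min_sites` discriminating CpGs.
#'
#' @param profile a per-CpG profile as returned by [per_cpg_profile()]
#'   (columns `scaffold`, `position`, `cpg_index`, one per group), or a
#'   named list of per-group tracks sharing identical `position`s.
#' @param min_sites minimum discriminating CpGs per region (default 5).
#' @param min_delta minimum between-group mean difference (default 0.1).
#' @param max_gap maximum run interruption, in CpGs (default 2).
#' @return data frame of regions: `scaffold`, `start`, `end`
#'   (1-based inclusive), `n_cpgs`, `mean_abs_difference`.
#' @export
scan_dmrs <- function(profile, min_sites = 5L, min_delta = 0.1,
                      max_gap = 2L) {
  if (!is.data.frame(profile)) {
    positions <- lapply(profile, function(t) t$position)
    if (length(unique(lapply(positions, as.integer))) != 1L) {
      stop("misaligned tracks: positions differ between groups")
    }
    prof <- data.frame(scaffold = profile[[1L]]$scaffold,
                       position = profile[[1L]]$position,
                       cpg_index = seq_along(profile[[1L]]$position))
    for (g in names(profile)) prof[[g]] <- profile[[g]]$ratio
    profile <- prof
  }
  group_cols <- setdiff(names(profile),
                        c("scaffold", "position", "cpg_index"))
  if (length(group_cols) < 2L) stop("need tracks for at least 2 groups")
  tracks <- as.matrix(profile[, group_cols, drop = FALSE])
  delta <- apply(tracks, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) NA_real_ else max(v) - min(v)
  })
  above <- which(!is.na(delta) & delta >= min_delta)
  empty <- data.frame(scaffold = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      mean_abs_difference = numeric(),
                      stringsAsFactors = FALSE)
  if (length(above) == 0L) return(empty)

  run_id <- cumsum(c(1L, diff(above) - 1L > max_gap))
  regions <- lapply(split(above, run_id), function(idx) {
    if (length(idx) < min_sites) return(NULL)
    data.frame(scaffold = profile$scaffold[idx[1L]],
               start = profile$position[idx[1L]],
               end = profile$position[idx[length(idx)]],
               n_cpgs = length(idx),
               mean_abs_difference = mean(delta[idx]),
               stringsAsFactors = FALSE)
  })
  regions <- regions[!vapply(regions, is.null, logical(1L))]
  if (length(regions) == 0L) return(empty)
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}

#' Write DMR regions to a BED file
#'
#' Converts the 1-based inclusive regions back to 0-based half-open BED.
#'
#' @param regions output of [scan_dmrs()].
#' @param path output path.
#' @export
write_dmr_bed <- function(regions, path) {
  out <- data.frame(regions$scaffold, regions$start - 1L, regions$end,
                    sprintf("dmr%03d", seq_len(nrow(regions))),
                    regions$n_cpgs,
                    round(regions$mean_abs_difference, 4L))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Concordance between capture-based and amplicon per-CpG tracks
#'
#' Compares methylation ratios of position-matched CpGs between two
#' measurement tracks (e.g. subgenome capture vs targeted amplicon
#' bisulfite sequencing of the same region).
#'
#' @param capture_track,amplicon_track data frames with `position` and
#'   `ratio` columns.
#' @return list with `pearson_r`, `mean_abs_diff`, `n_shared_cpgs`.
#' @export
amplicon_concordance <- function(capture_track, amplicon_track) {
  m <- merge(capture_track[, c("position", "ratio")],
             amplicon_track[, c("position", "ratio")],
             by = "position", suffixes = c("_capture", "_amplicon"))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) stop("need at least 3 shared CpG positions")
  list(pearson_r = stats::cor(m$ratio_capture, m$ratio_amplicon),
       mean_abs_diff = mean(abs(m$ratio_capture - m$ratio_amplicon)),
       n_shared_cpgs = nrow(m))
}
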