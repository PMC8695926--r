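#' PCA embedding of sample methylation profiles
#'
#' Principal component analysis of samples over a gene set, on
#' gene-centered, unscaled methylation levels (all features already
#' share the `[0, 1]` scale). Genes with any missing entry are dropped
#' first; the count is recorded in the `n_genes_dropped` attribute.
#'
#' @param matrix a `methylation_matrix`.
#' @param gene_ids gene subset to use (default: all genes).
#' @param k number of components (default 2).
#' @param scale. also scale genes to unit variance (default FALSE).
#' @return an `embedding` object: list with `sample_ids`, `coordinates`
#'   (sample x k), `variance_explained`, `method`.
#' @export
pca_embed <- function(matrix, gene_ids = NULL, k = 2L, scale. = FALSE) {
  values <- complete_submatrix(matrix, gene_ids)
  n <- ncol(values)
  rank_bound <- min(n - 1L, nrow(values))
  if (k > rank_bound) stop("k exceeds the rank of the centered matrix")
  pc <- stats::prcomp(t(values), center = TRUE, scale. = scale.)
  coords <- pc$x[, seq_len(k), drop = FALSE]
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(sample_ids = colnames(values),
                 coordinates = coords,
                 variance_explained = ve[seq_len(k)],
                 method = "pca",
                 n_genes_used = nrow(values),
                 n_genes_dropped = attr(values, "n_dropped")),
            class = "embedding")
}

#' Classical metric MDS embedding of sample methylation profiles
#'
#' Classical (Torgerson) multidimensional scaling on pairwise Euclidean
#' distances between samples. For Euclidean input this reproduces PCA
#' scores up to sign and rotation, and the full-dimensional embedding
#' reproduces the input distances.
#'
#' @inheritParams pca_embed
#' @return an `embedding` object (`method = "mds"`); variance explained
#'   is the positive-eigenvalue fraction per retained axis.
#' @export
mds_embed <- function(matrix, gene_ids = NULL, k = 2L) {
  values <- complete_submatrix(matrix, gene_ids)
  n <- ncol(values)
  if (k > n - 1L) stop("k exceeds the rank of the centered matrix")
  d <- stats::dist(t(values))
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  coords <- fit$points
  rownames(coords) <- colnames(values)
  pos <- fit$eig[fit$eig > 0]
  structure(list(sample_ids = colnames(values),
                 coordinates = coords,
                 variance_explained = (fit$eig / sum(pos))[seq_len(k)],
                 method = "mds",
                 n_genes_used = nrow(values),
                 n_genes_dropped = attr(values, "n_dropped")),
            class = "embedding")
}

complete_submatrix <- function(matrix, gene_ids = NULL) {
  stopifnot(inherits(matrix, "methylation_matrix"))
  values <- matrix$values
  if (!is.null(gene_ids)) {
    missing_ids <- setdiff(gene_ids, rownames(values))
    if (length(missing_ids) > 0L) {
      stop("gene(s) not in matrix: ", paste(head(missing_ids, 3L),
                                            collapse = ", "))
    }
    values <- values[gene_ids, , drop = FALSE]
  }
  complete <- stats::complete.cases(values)
  out <- values[complete, , drop = FALSE]
  if (nrow(out) == 0L) stop("no genes without missing values")
  attr(out, "n_dropped") <- sum(!complete)
  out
}

#' @export
print.embedding <- function(x, ...) {
  cat(toupper(x$method), "embedding:", length(x$sample_ids), "samples,",
      ncol(x$coordinates), "axes,", x$n_genes_used, "genes used\n")
  invisible(x)
}

#' Write an embedding to TSV
#'
#' @param embedding an `embedding` object.
#' @param path output path.
#' @param sample_sheet optional sample sheet to join group columns from.
#' @export
write_embedding <- function(embedding, path, sample_sheet = NULL) {
  df <- data.frame(sample_id = embedding$sample_ids,
                   embedding$coordinates, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[-1L] <- paste0("dim", seq_len(ncol(embedding$coordinates)))
  if (!is.null(sample_sheet)) {
    df <- merge(df, sample_sheet, by = "sample_id", sort = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Silhouette-based group separation score
#'
#' Mean silhouette coefficient of the samples in the embedding, using
#' Euclidean distance and the supplied group labels as the clustering.
#' +1 means tight, well-separated groups; values near 0 mean no
#' separation beyond chance.
#'
#' @param embedding an `embedding` object.
#' @param labels named character vector mapping sample ids to groups.
#' @return mean silhouette width in `[-1, 1]`.
#' @export
separation_score <- function(embedding, labels) {
  stopifnot(inherits(embedding, "embedding"))
  grp <- labels[embedding$sample_ids]
  if (any(is.na(grp))) stop("every sample must be labeled")
  if (length(unique(grp)) < 2L) stop("need at least 2 groups")
  sil <- cluster::silhouette(as.integer(factor(grp)),
                             stats::dist(embedding$coordinates))
  mean(sil[, "sil_width"])
}

#' Chi-square enrichment of a binary annotation in a gene set
#'
#' Pearson chi-square on the 2x2 table (set vs background, flagged vs
#' not), without continuity correction, plus the fold enrichment of the
#' flag proportion in the set relative to the background.
#'
#' @param in_set_with,in_set_without flagged / unflagged counts in the
#'   gene set.
#' @param background_with,background_without flagged / unflagged counts
#'   in the background.
#' @return list with `chi2`, `p_value`, `fold_enrichment`.
#' @export
chisq_enrichment <- function(in_set_with, in_set_without,
                             background_with, background_without) {
  counts <- c(in_set_with, in_set_without,
              background_with, background_without)
  if (any(counts < 0)) stop("counts must be non-negative")
  tab <- matrix(counts, nrow = 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin: enrichment undefined")
  }
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expected)^2 / expected)
  set_prop <- in_set_with / (in_set_with + in_set_without)
  bg_prop <- background_with / (background_with + background_without)
  list(chi2 = chi2,
       p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
       fold_enrichment = set_prop / bg_prop)
}

#' Welch's unequal-variance t test (two-sided)
#'
#' t statistic with the Welch-Satterthwaite degrees of freedom. When both
#' groups have zero variance and equal means the statistic is degenerate;
#' t = 0, p = 1 is returned with `degenerate = TRUE`.
#'
#' @param values_a,values_b numeric vectors, each with at least 2 values.
#' @return list with `t`, `df`, `p_value`, `degenerate`.
#' @export
welch_t_compare <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]; b <- values_b[!is.na(values_b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values")
  }
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  se2 <- va + vb
  if (se2 == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = NA_real_, p_value = 1, degenerate = TRUE))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_,
                p_value = 0, degenerate = TRUE))
  }
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (length(a) - 1L) + vb^2 / (length(b) - 1L))
  list(t = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df),
       degenerate = FALSE)
}
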