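#' Cross-sample methylation variance of one gene
#'
#' Sample variance (n - 1 denominator) over non-missing values.
#'
#' @param row numeric vector of per-sample gene methylation levels.
#' @return variance, a non-negative real.
#' @export
gene_variance <- function(row) {
  v <- row[!is.na(row)]
  if (length(v) < 2L) stop("need at least 2 non-missing values")
  stats::var(v)
}

new_filter_report <- function() {
  structure(list(stages = data.frame(stage = character(),
                                     criterion = character(),
                                     n_before = integer(),
                                     n_after = integer(),
                                     stringsAsFactors = FALSE),
                 removed = list()),
            class = "filter_report")
}

add_stage <- function(report, stage, criterion, before_ids, after_ids) {
  report$stages <- rbind(report$stages, data.frame(
    stage = stage, criterion = criterion,
    n_before = length(before_ids), n_after = length(after_ids),
    stringsAsFactors = FALSE))
  report$removed[[stage]] <- setdiff(before_ids, after_ids)
  report
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter cascade:\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Write a filter report to TSV
#'
#' Writes the per-stage counts as a TSV and, next to it, one
#' `<path>.removed.<stage>.txt` file per stage listing removed gene ids.
#'
#' @param report a `filter_report`.
#' @param path output TSV path.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report$stages, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (stage in names(report$removed)) {
    ids <- report$removed[[stage]]
    writeLines(ids, paste0(path, ".removed.", stage, ".txt"))
  }
  invisible(path)
}

#' Discover variably methylated genes
#'
#' Two-stage discovery on a gene x sample methylation matrix: keep genes
#' whose cross-sample variance exceeds `var_cutoff`, then exclude the
#' consistently methylated or unmethylated ones, i.e. genes whose
#' cross-sample mean ratio is strictly above `band[2]` or strictly below
#' `band[1]`. A gene with mean exactly at a band edge is retained.
#'
#' @param matrix a `methylation_matrix` (from samples of the discovery
#'   dataset, typically WGBS).
#' @param var_cutoff variance threshold, exceeded strictly (default
#'   0.006).
#' @param band mean-ratio retention band `c(low, high)` (default
#'   `c(0.2, 0.8)`).
#' @return list with `variable` (retained gene ids), `consistent`
#'   (band-excluded gene ids) and `report` (a `filter_report`).
#' @export
discover_variable_genes <- function(matrix, var_cutoff = 0.006,
                                    band = c(0.2, 0.8)) {
  stopifnot(inherits(matrix, "methylation_matrix"))
  if (band[1L] >= band[2L]) stop("degenerate band: low >= high")
  if (ncol(matrix$values) < 2L) stop("need at least 2 samples")
  values <- matrix$values
  all_ids <- rownames(values)

  n_obs <- rowSums(!is.na(values))
  variance <- rep(NA_real_, nrow(values))
  variance[n_obs >= 2L] <- apply(values[n_obs >= 2L, , drop = FALSE], 1L,
                                 gene_variance)
  pass_var <- !is.na(variance) & variance > var_cutoff
  var_ids <- all_ids[pass_var]

  means <- rowMeans(values, na.rm = TRUE)[pass_var]
  consistent <- var_ids[means > band[2L] | means < band[1L]]
  variable <- setdiff(var_ids, consistent)

  report <- new_filter_report()
  report <- add_stage(report, "variance",
                      sprintf("cross-sample variance > %g", var_cutoff),
                      all_ids, var_ids)
  report <- add_stage(report, "mean_band",
                      sprintf("mean ratio not > %g and not < %g",
                              band[2L], band[1L]),
                      var_ids, variable)
  list(variable = variable, consistent = consistent, report = report)
}

#' Core-set filter cascade for pre-selected variable genes
#'
#' Applies, in order: (a) drop genes whose sequence is more than
#' `max_n_fraction` Ns; (b) drop genes without a computable average in
#' every sample (coverage qualification is already encoded as
#' missingness, and variance needs at least 2 observed values); (c) drop
#' genes in the bottom `bottom_variance_quantile` of cross-sample
#' variance among the genes remaining; (d) drop genes whose overall mean
#' level is outside the open interval `(level_band[1], level_band[2])`.
#'
#' The bottom-quantile boundary uses the nearest-rank definition
#' (`ceiling(q * n)`), and ties at the boundary variance are all removed,
#' which makes the stage deterministic and order-independent.
#'
#' @param matrix a `methylation_matrix` restricted to the pre-selected
#'   variable gene set.
#' @param genes gene-model data frame covering the matrix genes.
#' @param max_n_fraction maximum tolerated N fraction (default 0.5).
#' @param bottom_variance_quantile variance quantile to drop (default
#'   0.10).
#' @param level_band retained mean-level open interval (default
#'   `c(0.1, 0.9)`).
#' @return list with `core` (surviving gene ids) and `report`.
#' @export
core_set_filter <- function(matrix, genes, max_n_fraction = 0.5,
                            bottom_variance_quantile = 0.10,
                            level_band = c(0.1, 0.9)) {
  stopifnot(inherits(matrix, "methylation_matrix"))
  values <- matrix$values
  ids <- rownames(values)
  if (length(ids) == 0L) stop("empty input gene set")
  if (!all(ids %in% genes$gene_id)) {
    stop("gene models missing for some matrix genes")
  }
  report <- new_filter_report()

  ## (a) N-content
  n_frac <- genes$n_fraction[match(ids, genes$gene_id)]
  keep_a <- ids[n_frac <= max_n_fraction]
  report <- add_stage(report, "n_content",
                      sprintf("n_fraction <= %g", max_n_fraction),
                      ids, keep_a)

  ## (b) computable average: no missing cell, >= 2 values for variance
  sub <- values[keep_a, , drop = FALSE]
  ok_b <- rowSums(!is.na(sub)) == ncol(sub) & ncol(sub) >= 2L
  keep_b <- keep_a[ok_b]
  report <- add_stage(report, "coverage_qualified",
                      "average computable in every sample",
                      keep_a, keep_b)
  if (length(keep_b) == 0L) {
    return(list(core = character(), report = report))
  }

  ## (c) bottom variance quantile among remaining genes
  vb <- apply(values[keep_b, , drop = FALSE], 1L, gene_variance)
  m <- ceiling(bottom_variance_quantile * length(keep_b))
  if (m >= 1L && bottom_variance_quantile > 0) {
    threshold <- sort(vb)[m]
    keep_c <- keep_b[vb > threshold]
  } else {
    keep_c <- keep_b
  }
  report <- add_stage(report, "variance_decile",
                      sprintf("not in bottom %g variance quantile",
                              bottom_variance_quantile),
                      keep_b, keep_c)

  ## (d) mean-level band
  mc <- rowMeans(values[keep_c, , drop = FALSE])
  keep_d <- keep_c[mc >= level_band[1L] & mc <= level_band[2L]]
  report <- add_stage(report, "level_band",
                      sprintf("mean level not < %g and not > %g",
                              level_band[1L], level_band[2L]),
                      keep_c, keep_d)

  list(core = keep_d, report = report)
}
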