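#' CpG sites covered in every sample of an analysis set
#'
#' A site qualifies when its coverage is at least `min_coverage` in
#' every sample supplied -- the analysis set. Adding a sample can only
#' shrink the qualifying set.
#'
#' @param tables named list of per-sample methylation-call tables
#'   (see [read_methylation_table()]), already restricted to the
#'   analysis set of interest.
#' @param min_coverage minimum per-sample coverage (default 5).
#' @return a `data.table` of qualifying sites with columns `scaffold`,
#'   `position`.
#' @export
qualifying_cpg_sites <- function(tables, min_coverage = 5L) {
  if (length(tables) == 0L) stop("no sample tables supplied")
  n_samples <- length(tables)
  long <- data.table::rbindlist(lapply(tables, function(t) {
    data.table::setDT(t)[t$total_count >= min_coverage,
                         c("scaffold", "position"), with = FALSE]
  }))
  qualified <- long[, list(n_ok = .N), by = c("scaffold", "position")]
  qualified <- qualified[qualified$n_ok == n_samples,
                         c("scaffold", "position"), with = FALSE]
  data.table::setorder(qualified, scaffold, position)
  qualified[]
}

#' Gene-body average methylation for one sample
#'
#' Unweighted arithmetic mean of per-CpG ratios at qualifying sites
#' inside the gene interval (1-based inclusive; boundary CpGs count).
#' Returns `NA` when fewer than `min_sites` qualifying CpGs fall in the
#' gene, so sparsely covered genes are reported as missing rather than
#' as unstable estimates.
#'
#' @param sites one sample's methylation-call table restricted to the
#'   qualifying site set.
#' @param gene one gene-model row (`scaffold`, `start`, `end`).
#' @param min_sites minimum qualifying CpGs per gene (default 5).
#' @return mean ratio in `[0, 1]`, or `NA_real_`.
#' @export
gene_average_methylation <- function(sites, gene, min_sites = 5L) {
  in_gene <- sites$scaffold == gene$scaffold &
    sites$position >= gene$start & sites$position <= gene$end
  r <- sites$ratio[in_gene]
  r <- r[!is.na(r)]
  if (length(r) < min_sites) return(NA_real_)
  mean(r)
}

#' Build a gene-by-sample methylation matrix
#'
#' Applies the joint coverage qualification ([qualifying_cpg_sites()])
#' across the supplied analysis set, then computes the gene-body average
#' per gene and sample. Genes with fewer than `min_sites` qualifying
#' CpGs get an all-missing row. The number of qualifying CpGs per gene is
#' recorded (it is shared across samples by construction).
#'
#' @param tables named list of per-sample methylation-call tables; names
#'   are sample ids.
#' @param genes gene-model data frame (see [read_gene_bed()]).
#' @param min_coverage per-sample coverage threshold (default 5).
#' @param min_sites minimum qualifying CpGs per gene (default 5).
#' @return a `methylation_matrix` object: list with `values` (gene x
#'   sample numeric matrix), `n_cpgs_used` (named integer vector),
#'   `gene_ids`, `sample_ids`.
#' @export
build_matrix <- function(tables, genes, min_coverage = 5L, min_sites = 5L) {
  if (length(tables) == 0L) stop("no sample tables supplied")
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("tables must be a named list (names are sample ids)")
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  qualified <- qualifying_cpg_sites(tables, min_coverage)

  ## assign qualifying sites to genes (interval overlap, inclusive)
  gene_dt <- data.table::data.table(
    gene_id = genes$gene_id, scaffold = genes$scaffold,
    start = genes$start, end = genes$end)
  site_dt <- data.table::copy(qualified)
  site_dt[, "start" := site_dt$position]
  site_dt[, "end" := site_dt$position]
  data.table::setkeyv(gene_dt, c("scaffold", "start", "end"))
  assigned <- data.table::foverlaps(site_dt, gene_dt,
                                    type = "within", nomatch = NULL)
  assigned <- assigned[, c("gene_id", "scaffold", "position"), with = FALSE]

  n_cpgs_used <- stats::setNames(integer(nrow(genes)), genes$gene_id)
  if (nrow(assigned) > 0L) {
    cnt <- assigned[, list(n = .N), by = "gene_id"]
    n_cpgs_used[cnt$gene_id] <- cnt$n
  }

  sample_ids <- names(tables)
  values <- matrix(NA_real_, nrow = nrow(genes), ncol = length(sample_ids),
                   dimnames = list(genes$gene_id, sample_ids))
  for (s in sample_ids) {
    tab <- data.table::setDT(tables[[s]])
    m <- merge(assigned, tab[, c("scaffold", "position", "ratio"),
                             with = FALSE],
               by = c("scaffold", "position"))
    avg <- m[, list(value = if (sum(!is.na(ratio)) >= min_sites)
                      mean(ratio, na.rm = TRUE) else NA_real_,
                    n = sum(!is.na(ratio))),
             by = "gene_id"]
    values[avg$gene_id, s] <- avg$value
  }

  methylation_matrix(values, n_cpgs_used)
}

#' Construct a methylation_matrix object
#'
#' @param values gene x sample numeric matrix with dimnames; entries in
#'   `[0, 1]` or `NA`.
#' @param n_cpgs_used named integer vector of qualifying CpGs per gene
#'   (optional).
#' @return a `methylation_matrix` object.
#' @export
methylation_matrix <- function(values, n_cpgs_used = NULL) {
  stopifnot(is.matrix(values))
  if (nrow(values) > 0L && is.null(rownames(values))) {
    stop("values must have gene row names")
  }
  if (ncol(values) > 0L && is.null(colnames(values))) {
    stop("values must have sample column names")
  }
  v <- values[!is.na(values)]
  if (any(v < 0 | v > 1)) stop("methylation values must lie in [0, 1]")
  if (is.null(n_cpgs_used)) {
    n_cpgs_used <- stats::setNames(rep(NA_integer_, nrow(values)),
                                   rownames(values))
  }
  structure(list(values = values,
                 n_cpgs_used = n_cpgs_used,
                 gene_ids = rownames(values),
                 sample_ids = colnames(values)),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat("methylation_matrix:", nrow(x$values), "genes x",
      ncol(x$values), "samples;",
      sum(stats::complete.cases(x$values)), "genes fully observed\n")
  invisible(x)
}

#' Restrict a methylation matrix to a gene and/or sample subset
#'
#' @param x a `methylation_matrix`.
#' @param gene_ids,sample_ids subsets to keep (default: all).
#' @return a `methylation_matrix`.
#' @export
subset_matrix <- function(x, gene_ids = NULL, sample_ids = NULL) {
  stopifnot(inherits(x, "methylation_matrix"))
  g <- if (is.null(gene_ids)) x$gene_ids else intersect(x$gene_ids, gene_ids)
  s <- if (is.null(sample_ids)) x$sample_ids else
    intersect(x$sample_ids, sample_ids)
  methylation_matrix(x$values[g, s, drop = FALSE], x$n_cpgs_used[g])
}
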