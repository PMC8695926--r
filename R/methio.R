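#' @importFrom data.table fread fwrite data.table setDT setorder := .N .SD
#' @importFrom stats var setNames
NULL

# required columns of a methylation-call table (methratio-style dialect)
.meth_cols <- c("scaffold", "position", "strand", "context",
                "meth_count", "total_count")

#' Read a per-CpG methylation-call table
#'
#' Reads a tab-separated methylation-call table in the methratio-style
#' dialect: one row per cytosine with columns `scaffold`, `position`
#' (1-based coordinate of the C on the plus strand), `strand` (`+`/`-`),
#' `context` (`CpG`, `CHG` or `CHH`), `meth_count` and `total_count`.
#' A `ratio` column (`meth_count / total_count`, `NA` at zero coverage)
#' is computed after reading; any ratio column on disk is ignored.
#'
#' Symmetric CpG dyads are reported twice by callers, once per strand.
#' With `merge_strands = TRUE` (default) a minus-strand CpG record at
#' position p+1 is folded into the plus-strand record at p by summing
#' counts, so each CpG site yields a single ratio.
#'
#' @param path path to a tab-separated file with a header line.
#' @param context contexts to keep, e.g. `"CpG"`; `NULL` keeps all rows.
#' @param merge_strands merge minus-strand CpG counts into the
#'   plus-strand dyad position (CpG context only).
#' @return a `data.table` with the columns above plus `ratio`.
#' @export
read_methylation_table <- function(path, context = "CpG",
                                   merge_strands = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "scaffold"))
  missing_cols <- setdiff(.meth_cols, names(dt))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  dt <- dt[, .meth_cols, with = FALSE]
  validate_cpg_records(dt, path)
  if (!is.null(context)) {
    ctx <- context
    dt <- dt[dt$context %in% ctx]
  }
  if (merge_strands) dt <- merge_cpg_strands(dt)
  dt[, "ratio" := ifelse(dt$total_count > 0,
                         dt$meth_count / dt$total_count, NA_real_)]
  data.table::setorder(dt, scaffold, position)
  dt[]
}

validate_cpg_records <- function(dt, path = "<table>") {
  bad_int <- which(!is.finite(dt$meth_count) | !is.finite(dt$total_count) |
                   dt$meth_count != floor(dt$meth_count) |
                   dt$total_count != floor(dt$total_count) |
                   dt$meth_count < 0 | dt$total_count < 0)
  if (length(bad_int) > 0L) {
    stop("malformed counts in ", path, " at data row ", bad_int[1L])
  }
  bad <- which(dt$meth_count > dt$total_count)
  if (length(bad) > 0L) {
    stop("inconsistent counts (meth_count > total_count) in ", path,
         " at data row ", bad[1L])
  }
  bad_pos <- which(!is.finite(dt$position) | dt$position < 1)
  if (length(bad_pos) > 0L) {
    stop("invalid position in ", path, " at data row ", bad_pos[1L])
  }
  invisible(TRUE)
}

#' Merge plus/minus strand records of symmetric CpG dyads
#'
#' Minus-strand CpG records at position p+1 are moved to position p and
#' counts are summed with any plus-strand record there. Non-CpG contexts
#' are left untouched.
#'
#' @param dt a methylation-call `data.table` (see [read_methylation_table()]).
#' @return a `data.table` with one record per CpG site.
#' @export
merge_cpg_strands <- function(dt) {
  dt <- data.table::copy(data.table::setDT(dt))
  is_minus_cpg <- dt$context == "CpG" & dt$strand == "-"
  if (any(is_minus_cpg)) {
    dt[is_minus_cpg, "position" := dt$position[is_minus_cpg] - 1L]
    dt[is_minus_cpg, "strand" := "+"]
  }
  merged <- dt[, list(meth_count = sum(meth_count),
                      total_count = sum(total_count)),
               by = c("scaffold", "position", "strand", "context")]
  if ("ratio" %in% names(dt)) {
    merged[, "ratio" := ifelse(merged$total_count > 0,
                               merged$meth_count / merged$total_count,
                               NA_real_)]
  }
  merged[]
}

#' Read gene intervals from a BED-like file
#'
#' BED intervals are 0-based half-open on disk; they are converted to the
#' internal 1-based inclusive convention (`start = bed_start + 1`,
#' `end = bed_end`). Columns are: chrom, start, end, name, and optionally
#' score, strand, `n_fraction` (fraction of Ns in the gene sequence),
#' `is_housekeeping` (0/1) and `te_overlap` (0/1); absent optional
#' columns default to 0 / FALSE.
#'
#' @param path path to a BED-like file (no header).
#' @return a `data.frame` of gene models with columns `gene_id`,
#'   `scaffold`, `start`, `end`, `strand`, `n_fraction`,
#'   `is_housekeeping`, `te_overlap`.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = FALSE, fill = TRUE,
                          colClasses = list(character = 1L))
  if (ncol(dt) < 4L) stop("BED file needs at least 4 columns: ", path)
  bad <- which(dt[[3L]] <= dt[[2L]])
  if (length(bad) > 0L) {
    stop("empty or inverted interval in ", path, " at line ", bad[1L])
  }
  n <- nrow(dt)
  # optional columns may be absent entirely or only on some lines
  get_col <- function(i, default) {
    col <- if (ncol(dt) >= i) dt[[i]] else rep(default, n)
    col[is.na(col) | col == ""] <- default
    col
  }
  genes <- data.frame(
    gene_id  = as.character(dt[[4L]]),
    scaffold = as.character(dt[[1L]]),
    start    = as.integer(dt[[2L]]) + 1L,
    end      = as.integer(dt[[3L]]),
    strand   = as.character(get_col(6L, ".")),
    n_fraction = as.numeric(get_col(7L, 0)),
    is_housekeeping = as.integer(get_col(8L, 0L)) > 0L,
    te_overlap      = as.integer(get_col(9L, 0L)) > 0L,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene ids in ", path)
  }
  if (any(genes$n_fraction < 0 | genes$n_fraction > 1)) {
    stop("n_fraction outside [0,1] in ", path)
  }
  genes
}

#' Write gene intervals to a BED-like file
#'
#' Inverse of [read_gene_bed()]: converts 1-based inclusive intervals back
#' to the 0-based half-open disk convention.
#'
#' @param genes a gene-model `data.frame` (see [read_gene_bed()]).
#' @param path output path.
#' @export
write_gene_bed <- function(genes, path) {
  out <- data.frame(genes$scaffold, genes$start - 1L, genes$end,
                    genes$gene_id, 0L, genes$strand,
                    genes$n_fraction, as.integer(genes$is_housekeeping),
                    as.integer(genes$te_overlap))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated with a header; requires `sample_id` plus any of
#' `tissue`, `location`, `condition`, `dataset`, `path`.
#'
#' @param path path to the sample sheet TSV.
#' @return a `data.frame`, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(ss)) stop("sample sheet lacks sample_id column")
  if (anyDuplicated(ss$sample_id)) stop("duplicate sample_id in sample sheet")
  ss
}

#' Bisulfite conversion rate from non-CpG cytosines
#'
#' Non-CpG cytosines (CHG/CHH) are assumed unmethylated, so any
#' methylated call there reflects failed bisulfite conversion. The rate
#' is pooled over sites -- `1 - sum(meth_count) / sum(total_count)` --
#' rather than averaged per site, so low-coverage sites cannot
#' destabilise the estimate. Values above ~0.98 indicate a
#' well-converted library.
#'
#' @param records a methylation-call table including CHG/CHH rows
#'   (CpG rows, if present, are ignored).
#' @return conversion rate in `[0, 1]`.
#' @export
compute_conversion_rate <- function(records) {
  non_cpg <- records[records$context %in% c("CHG", "CHH"), , drop = FALSE]
  tot <- sum(as.numeric(non_cpg$total_count))
  if (!is.finite(tot) || tot <= 0) {
    stop("no non-CpG coverage: conversion rate undefined")
  }
  1 - sum(as.numeric(non_cpg$meth_count)) / tot
}

#' Write a methylation matrix to TSV
#'
#' Genes as rows, samples as columns, first column `gene_id`, missing
#' values written as `NA`. Values are written at 6 decimals and
#' round-trip with [read_methylation_matrix()] to that precision.
#'
#' @param matrix a [methylation_matrix] object or a plain numeric matrix
#'   with gene row names and sample column names.
#' @param path output path.
#' @export
write_methylation_matrix <- function(matrix, path) {
  values <- if (inherits(matrix, "methylation_matrix")) matrix$values else matrix
  if (is.null(values) || nrow(values) == 0L || ncol(values) == 0L) {
    stop("empty matrix")
  }
  df <- data.frame(gene_id = rownames(values),
                   round(values, 6L), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a methylation matrix from TSV
#'
#' @param path path written by [write_methylation_matrix()].
#' @return a numeric matrix, genes in rows, samples in columns.
#' @export
read_methylation_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}
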