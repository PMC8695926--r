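# Independent brute-force oracles and fixture builders used across tests.

# literal O(m^2) transcription of the BH step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    candidates <- vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1L))
    q[ord[i]] <- min(1, min(candidates))
  }
  q
}

# textbook 2x2 Pearson chi-square via the shortcut formula
oracle_chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# plain-loop re-implementation of the core-set cascade, kept deliberately
# naive and separate from the package's vectorised version
oracle_core_filter <- function(values, n_fraction, max_n_fraction = 0.5,
                               q_bottom = 0.10, level_band = c(0.1, 0.9)) {
  ids <- rownames(values)
  keep <- ids[n_fraction[ids] <= max_n_fraction]
  keep <- keep[vapply(keep, function(g) {
    all(!is.na(values[g, ])) && ncol(values) >= 2
  }, logical(1L))]
  if (length(keep) == 0L) return(character())
  vars <- vapply(keep, function(g) stats::var(values[g, ]), numeric(1L))
  m <- ceiling(q_bottom * length(keep))
  threshold <- sort(vars)[m]
  keep <- keep[vars > threshold]
  keep[vapply(keep, function(g) {
    mu <- mean(values[g, ])
    mu >= level_band[1L] && mu <= level_band[2L]
  }, logical(1L))]
}

# deterministic gene x sample fixture exercising every cascade stage:
# 30 genes, 8 samples; genes 1-3 N-rich, genes 4-5 with missing cells,
# genes 6-8 lowest-variance, genes 9-10 extreme mean level
make_cascade_fixture <- function() {
  alt <- rep(c(-1, 1), 4L)
  spec <- data.frame(
    gene_id = sprintf("g%02d", 1:30),
    mean = c(rep(0.5, 8L), 0.95, 0.05, rep(0.5, 20L)),
    amp = c(rep(0.05, 5L), 0.005, 0.006, 0.007, 0.02, 0.02,
            0.03 + 0.002 * (0:19)),
    n_fraction = c(0.6, 0.7, 0.9, rep(0.02, 27L)),
    stringsAsFactors = FALSE)
  values <- t(vapply(seq_len(30L),
                     function(i) spec$mean[i] + spec$amp[i] * alt,
                     numeric(8L)))
  dimnames(values) <- list(spec$gene_id, sprintf("s%d", 1:8))
  values["g04", 3L] <- NA
  values["g05", c(1L, 6L)] <- NA
  list(values = values,
       n_fraction = stats::setNames(spec$n_fraction, spec$gene_id),
       genes = data.frame(gene_id = spec$gene_id, scaffold = "sc1",
                          start = 1L, end = 10L, strand = "+",
                          n_fraction = spec$n_fraction,
                          is_housekeeping = FALSE, te_overlap = FALSE,
                          stringsAsFactors = FALSE))
}

# small hand-checkable methylation-call tables for aggregation tests:
# two genes on sc1 (positions 10-90 and 200-260), three samples
make_small_tables <- function() {
  pos <- c(10L, 30L, 50L, 70L, 90L, 200L, 220L, 240L, 260L)
  make <- function(meth, total) {
    data.table::data.table(scaffold = "sc1", position = pos,
                           strand = "+", context = "CpG",
                           meth_count = meth, total_count = total,
                           ratio = ifelse(total > 0, meth / total,
                                          NA_real_))
  }
  list(sampA = make(c(0L, 2L, 5L, 6L, 10L, 1L, 2L, 3L, 4L),
                    c(10L, 10L, 10L, 10L, 10L, 10L, 10L, 10L, 10L)),
       sampB = make(c(1L, 3L, 4L, 5L, 9L, 0L, 1L, 2L, 3L),
                    c(10L, 10L, 10L, 10L, 10L, 10L, 10L, 10L, 10L)),
       sampC = make(c(2L, 2L, 6L, 7L, 8L, 2L, 3L, 4L, 5L),
                    c(10L, 10L, 10L, 10L, 10L, 10L, 10L, 10L, 10L)))
}

small_genes <- function() {
  data.frame(gene_id = c("geneA", "geneB"), scaffold = "sc1",
             start = c(1L, 150L), end = c(100L, 300L), strand = "+",
             n_fraction = 0, is_housekeeping = FALSE, te_overlap = FALSE,
             stringsAsFactors = FALSE)
}

# methylation_matrix from a plain matrix
mm <- function(values) methylation_matrix(values)

# orthogonal Procrustes residual between two configurations
procrustes_residual <- function(a, b) {
  a <- scale(a, center = TRUE, scale = FALSE)
  b <- scale(b, center = TRUE, scale = FALSE)
  s <- svd(crossprod(b, a))
  rot <- s$u %*% t(s$v)
  sqrt(sum((b %*% rot - a)^2))
}

write_meth_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}
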