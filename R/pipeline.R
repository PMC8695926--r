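#' Assemble a pipeline configuration
#'
#' Bundles the input paths, analysis-set definitions and all thresholds
#' of the analysis cascade. Defaults reproduce the standard settings:
#' coverage >= 5X in every sample, >= 5 qualifying CpGs per gene,
#' discovery variance cutoff 0.006 with a (0.2, 0.8) mean-ratio band,
#' core-set level band (0.1, 0.9), 50% N-content ceiling, bottom-decile
#' variance removal, and q < 0.05 significance.
#'
#' @param sample_sheet path to a sample sheet TSV with a `path` column
#'   locating each sample's methylation-call table.
#' @param gene_bed path to the gene BED file.
#' @param out_dir output directory (created if absent).
#' @param min_coverage,min_sites,var_cutoff,band,level_band,
#'   max_n_fraction,bottom_variance_quantile,alpha cascade thresholds;
#'   see [build_matrix()], [discover_variable_genes()],
#'   [core_set_filter()] and [differential_genes()].
#' @param location_tissue tissue within which the location contrast is
#'   run (`NULL`: the tissue with most samples).
#' @param tissue_stratum location within which the tissue contrast is
#'   run (`NULL`: the location with most samples; `NA`: skip the tissue
#'   contrast).
#' @param seed integer seed recorded in the manifest.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sample_sheet, gene_bed, out_dir,
                            min_coverage = 5L, min_sites = 5L,
                            var_cutoff = 0.006, band = c(0.2, 0.8),
                            level_band = c(0.1, 0.9),
                            max_n_fraction = 0.5,
                            bottom_variance_quantile = 0.10,
                            alpha = 0.05,
                            location_tissue = NULL,
                            tissue_stratum = NULL,
                            seed = 1L) {
  cfg <- list(sample_sheet = sample_sheet, gene_bed = gene_bed,
              out_dir = out_dir, min_coverage = as.integer(min_coverage),
              min_sites = as.integer(min_sites), var_cutoff = var_cutoff,
              band = band, level_band = level_band,
              max_n_fraction = max_n_fraction,
              bottom_variance_quantile = bottom_variance_quantile,
              alpha = alpha, location_tissue = location_tissue,
              tissue_stratum = tissue_stratum, seed = as.integer(seed))
  stopifnot(cfg$min_coverage >= 0L, cfg$min_sites >= 1L,
            cfg$var_cutoff >= 0, cfg$band[1L] < cfg$band[2L],
            cfg$level_band[1L] < cfg$level_band[2L],
            cfg$max_n_fraction >= 0, cfg$max_n_fraction <= 1,
            cfg$bottom_variance_quantile >= 0,
            cfg$bottom_variance_quantile < 1,
            cfg$alpha > 0, cfg$alpha <= 1)
  structure(cfg, class = "pipeline_config")
}

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form `key = value`; vector values are comma-separated;
#' `#` starts a comment. Unknown keys are rejected.
#'
#' @param path path to the config file.
#' @param ... overrides passed on to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1L]])
  keys <- vapply(kv, `[`, character(1L), 1L)
  vals <- vapply(kv, `[`, character(1L), 2L)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  parse_val <- function(key, val) {
    parts <- trimws(strsplit(val, ",")[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num) &&
        !key %in% c("sample_sheet", "gene_bed", "out_dir",
                    "location_tissue", "tissue_stratum")) num else parts
  }
  args <- stats::setNames(Map(parse_val, keys, vals), keys)
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(pipeline_config, args)
}

config_as_text <- function(cfg) {
  fmt <- function(v) paste(as.character(v), collapse = ", ")
  set <- !vapply(cfg, is.null, logical(1L))
  paste0(names(cfg)[set], " = ",
         vapply(unclass(cfg)[set], fmt, character(1L)))
}

#' Run the full analysis pipeline
#'
#' Executes aggregation, variable-gene discovery, core-set filtering,
#' the stratified differential contrasts, and ordination of the samples
#' on the significant genes, writing every artifact plus a run manifest
#' to `out_dir`. Identical config and inputs yield identical outputs.
#'
#' Contrasts are stratified to avoid confounding: the tissue contrast
#' (Wilcoxon) is run within a single sampling location, and the location
#' contrast (Kruskal-Wallis) within a single tissue. Coverage
#' qualification is recomputed within each contrast's analysis set.
#'
#' @param config a `pipeline_config`.
#' @return invisibly, a list with the matrix, gene sets, filter reports,
#'   differential tables, embedding and separation scores.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(config$out_dir, "run.log")
  logger <- function(...) {
    msg <- paste0(...)
    message(msg)
    cat(msg, "\n", file = log_file, append = TRUE, sep = "")
  }
  cat("", file = log_file)

  samples <- read_sample_sheet(config$sample_sheet)
  if (!"path" %in% names(samples)) {
    stop("pipeline stage [input]: sample sheet needs a path column")
  }
  genes <- read_gene_bed(config$gene_bed)
  tables <- lapply(stats::setNames(samples$path, samples$sample_id),
                   read_methylation_table)
  logger("loaded ", length(tables), " samples, ", nrow(genes), " genes")

  ## aggregation over the full sample set
  mat <- build_matrix(tables, genes, config$min_coverage, config$min_sites)
  write_methylation_matrix(mat, file.path(config$out_dir, "matrix.tsv"))

  ## discovery + core-set cascade
  disc <- discover_variable_genes(mat, config$var_cutoff, config$band)
  logger("variable genes: ", length(disc$variable),
         " (", length(disc$consistent), " consistently methylated excluded)")
  core <- core_set_filter(subset_matrix(mat, gene_ids = disc$variable),
                          genes, config$max_n_fraction,
                          config$bottom_variance_quantile,
                          config$level_band)
  logger("core set: ", length(core$core), " genes")
  write_filter_report(disc$report,
                      file.path(config$out_dir, "discovery_report.tsv"))
  write_filter_report(core$report,
                      file.path(config$out_dir, "core_set_report.tsv"))

  results <- list(matrix = mat, discovery = disc, core = core)

  ## location contrast: KW across locations within one tissue
  loc_tissue <- config$location_tissue
  if (is.null(loc_tissue)) {
    loc_tissue <- names(sort(table(samples$tissue), decreasing = TRUE))[1L]
  }
  loc_samples <- samples[samples$tissue == loc_tissue, ]
  if (length(unique(loc_samples$location)) >= 2L &&
      length(core$core) > 0L) {
    loc_mat <- build_matrix(tables[loc_samples$sample_id],
                            genes[genes$gene_id %in% core$core, ],
                            config$min_coverage, config$min_sites)
    labels <- stats::setNames(loc_samples$location, loc_samples$sample_id)
    loc_diff <- differential_genes(loc_mat, labels, "kruskal_wallis",
                                   config$alpha)
    utils::write.table(loc_diff,
                       file.path(config$out_dir,
                                 "differential_location.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sig <- loc_diff$gene_id[loc_diff$significant]
    logger("location contrast (", loc_tissue, "): ", length(sig),
           " significant of ", nrow(loc_diff), " tested")
    results$location <- loc_diff
    if (length(sig) >= 2L) {
      emb <- pca_embed(loc_mat, gene_ids = sig,
                       k = min(2L, length(sig), ncol(loc_mat$values) - 1L))
      write_embedding(emb, file.path(config$out_dir,
                                     "embedding_location.tsv"), samples)
      results$location_embedding <- emb
      results$location_separation <- separation_score(emb, labels)
      logger("location separation score: ",
             round(results$location_separation, 3L))
    }
  }

  ## tissue contrast: Wilcoxon between tissues within one location
  stratum <- config$tissue_stratum
  if (is.null(stratum)) {
    stratum <- names(sort(table(samples$location), decreasing = TRUE))[1L]
  }
  if (!is.na(stratum) && length(core$core) > 0L) {
    tis_samples <- samples[samples$location == stratum, ]
    if (length(unique(tis_samples$tissue)) == 2L) {
      tis_mat <- build_matrix(tables[tis_samples$sample_id],
                              genes[genes$gene_id %in% core$core, ],
                              config$min_coverage, config$min_sites)
      labels <- stats::setNames(tis_samples$tissue, tis_samples$sample_id)
      tis_diff <- differential_genes(tis_mat, labels, "wilcoxon",
                                     config$alpha)
      utils::write.table(tis_diff,
                         file.path(config$out_dir,
                                   "differential_tissue.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      logger("tissue contrast (", stratum, "): ",
             sum(tis_diff$significant), " significant of ",
             nrow(tis_diff), " tested")
      results$tissue <- tis_diff
    }
  }

  ## manifest
  cfg_path <- file.path(config$out_dir, "config.txt")
  writeLines(config_as_text(config), cfg_path)
  manifest <- c(
    paste0("methvar_version = ",
           as.character(utils::packageVersion("methvar"))),
    paste0("config_md5 = ", unname(tools::md5sum(cfg_path))),
    paste0("seed = ", config$seed))
  writeLines(manifest, file.path(config$out_dir, "manifest.txt"))
  invisible(results)
}

#' Write a simulated dataset to disk
#'
#' Materialises a [simulate_dataset()] result in the on-disk formats the
#' pipeline reads: per-sample methylation-call TSVs under `tables/`, a
#' gene BED, a sample sheet with a `path` column, and the ground-truth
#' tables.
#'
#' @param sim a `simulated_methylome`, or a [simulation_params()] object
#'   (simulated on the fly).
#' @param dir output directory.
#' @return invisibly, the sample sheet path.
#' @export
write_simulated_dataset <- function(sim, dir) {
  if (inherits(sim, "simulation_params")) sim <- simulate_dataset(sim)
  stopifnot(inherits(sim, "simulated_methylome"))
  dir.create(file.path(dir, "tables"), showWarnings = FALSE,
             recursive = TRUE)
  paths <- character(length(sim$tables))
  for (i in seq_along(sim$tables)) {
    paths[i] <- file.path(dir, "tables",
                          paste0(names(sim$tables)[i], ".tsv"))
    data.table::fwrite(sim$tables[[i]], paths[i], sep = "\t", na = "NA")
  }
  write_gene_bed(sim$genes, file.path(dir, "genes.bed"))
  ss <- sim$samples
  ss$path <- paths
  utils::write.table(ss, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  data.table::fwrite(sim$truth$cpg_ratios,
                     file.path(dir, "truth_cpg_ratios.tsv"), sep = "\t")
  invisible(file.path(dir, "samples.tsv"))
}
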