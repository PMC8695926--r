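#' Shift a methylation ratio on the logit scale
#'
#' Returns `plogis(qlogis(r) + delta)`: the ratio moved by `delta` on the
#' log-odds scale, which keeps the result strictly inside (0, 1) and makes
#' effect sizes comparable across baseline levels.
#'
#' @param r ratio strictly inside (0, 1).
#' @param delta log-odds shift (positive raises methylation).
#' @return shifted ratio in (0, 1).
#' @export
logit_shift <- function(r, delta) {
  if (any(r <= 0 | r >= 1)) stop("r must be strictly inside (0, 1)")
  stats::plogis(stats::qlogis(r) + delta)
}

#' Parameters for the synthetic methylome generator
#'
#' Defaults describe a capture-style experiment: a gene panel measured in
#' two tissues across several sampling locations, with a bimodal-plus-
#' intermediate baseline methylome, negative-binomial sequencing coverage
#' around 30X and a small bisulfite non-conversion error.
#'
#' @param n_genes number of genes on the synthetic scaffold.
#' @param cpgs_per_gene_mean Poisson mean of CpGs per gene (a floor of 5
#'   CpGs per gene is enforced).
#' @param baseline_weights weights of the low / intermediate / high
#'   baseline mixture components (must sum to 1).
#' @param baseline_shapes list of three `c(shape1, shape2)` beta parameter
#'   pairs for the mixture components.
#' @param frac_tissue_genes fraction of genes carrying a tissue effect.
#' @param frac_location_genes fraction carrying a location effect.
#' @param effect_delta logit-scale shift applied in the affected groups.
#' @param dmr_width number of contiguous CpGs carrying the effect
#'   (truncated to the gene's CpG count where necessary).
#' @param coverage_mean mean per-CpG sequencing coverage.
#' @param coverage_dispersion negative-binomial size parameter; the
#'   default equals `coverage_mean`, giving variance about twice the mean.
#' @param non_conversion bisulfite non-conversion rate in `[0, 1)`:
#'   an unmethylated C is read as methylated with this probability, so
#'   observed ratios are inflated to `r + (1 - r) * non_conversion`.
#' @param samples_per_group samples per tissue-by-location cell.
#' @param n_locations number of sampling locations.
#' @param tissues tissue labels; the first is the one affected by tissue
#'   effects.
#' @param frac_high_n fraction of genes with N-rich sequence
#'   (`n_fraction > 0.5`).
#' @param hk_background,hk_effect probability that a non-effect / effect
#'   gene is flagged as housekeeping.
#' @param te_rate probability of transposable-element overlap per gene.
#' @param chh_sites number of unmethylated CHH sites emitted per sample
#'   for conversion-rate QC.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return a `simulation_params` list.
#' @export
simulation_params <- function(n_genes = 200,
                              cpgs_per_gene_mean = 30,
                              baseline_weights = c(0.45, 0.20, 0.35),
                              baseline_shapes = list(c(0.5, 5),
                                                     c(2, 2),
                                                     c(5, 0.5)),
                              frac_tissue_genes = 0.10,
                              frac_location_genes = 0.10,
                              effect_delta = 1.0,
                              dmr_width = 10L,
                              coverage_mean = 30,
                              coverage_dispersion = 30,
                              non_conversion = 0.02,
                              samples_per_group = 12L,
                              n_locations = 4L,
                              tissues = c("hepatopancreas",
                                          "abdominal_muscle"),
                              frac_high_n = 0.05,
                              hk_background = 0.10,
                              hk_effect = 0.30,
                              te_rate = 0.15,
                              chh_sites = 200L,
                              seed = 1L) {
  p <- list(n_genes = as.integer(n_genes),
            cpgs_per_gene_mean = cpgs_per_gene_mean,
            baseline_weights = baseline_weights,
            baseline_shapes = baseline_shapes,
            frac_tissue_genes = frac_tissue_genes,
            frac_location_genes = frac_location_genes,
            effect_delta = effect_delta,
            dmr_width = as.integer(dmr_width),
            coverage_mean = coverage_mean,
            coverage_dispersion = coverage_dispersion,
            non_conversion = non_conversion,
            samples_per_group = as.integer(samples_per_group),
            n_locations = as.integer(n_locations),
            tissues = tissues,
            frac_high_n = frac_high_n,
            hk_background = hk_background,
            hk_effect = hk_effect,
            te_rate = te_rate,
            chh_sites = as.integer(chh_sites),
            seed = as.integer(seed))
  validate_simulation_params(p)
  structure(p, class = "simulation_params")
}

validate_simulation_params <- function(p) {
  if (abs(sum(p$baseline_weights) - 1) > 1e-9) {
    stop("baseline_weights must sum to 1")
  }
  if (length(p$baseline_weights) != 3L || length(p$baseline_shapes) != 3L) {
    stop("baseline mixture needs exactly three components")
  }
  if (p$samples_per_group < 1L) stop("samples_per_group must be >= 1")
  if (p$dmr_width < 1L) stop("dmr_width must be >= 1")
  if (p$non_conversion < 0 || p$non_conversion >= 1) {
    stop("non_conversion must be in [0, 1)")
  }
  if (p$n_genes < 1L) stop("n_genes must be >= 1")
  if (p$n_locations < 1L) stop("n_locations must be >= 1")
  if (p$coverage_mean <= 0 || p$coverage_dispersion <= 0) {
    stop("coverage parameters must be positive")
  }
  if (p$frac_tissue_genes + p$frac_location_genes > 1) {
    stop("effect gene fractions must sum to at most 1")
  }
  invisible(TRUE)
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a per-CpG methylation-count dataset with ground truth
#'
#' Generates a gene panel on one synthetic scaffold. Each gene receives a
#' Poisson number of CpGs (minimum 5) and a baseline methylation level
#' drawn from a three-component beta mixture (low / intermediate / high).
#' A minority of genes carries a tissue or location effect: a contiguous
#' window of `dmr_width` CpGs is shifted by `effect_delta` on the logit
#' scale in the affected groups (the first tissue, or one randomly chosen
#' location). Effect genes draw their baseline from the intermediate
#' mixture component, since a log-odds shift at a near-0 or near-1
#' baseline is invisible at count level; non-effect genes follow the full
#' mixture.
#'
#' Per sample and CpG, coverage is negative binomial
#' (`mu = coverage_mean`, `size = coverage_dispersion`) and the
#' methylated count is binomial with success probability
#' `r_true + (1 - r_true) * non_conversion`. A block of unmethylated CHH
#' sites is appended to every sample so the bisulfite conversion rate can
#' be estimated downstream.
#'
#' @param params a [simulation_params()] object.
#' @return a `simulated_methylome` list with elements `tables` (named
#'   list of per-sample methylation-call `data.table`s), `genes` (gene
#'   models), `samples` (sample sheet), `truth` (per-gene truth table and
#'   per-CpG per-group true ratios) and `params`.
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  validate_simulation_params(params)
  with_seed(params$seed, .simulate_dataset_impl(params))
}

.simulate_dataset_impl <- function(p) {
  n <- p$n_genes
  gene_ids <- sprintf("gene%04d", seq_len(n))

  n_cpgs <- pmax(5L, stats::rpois(n, p$cpgs_per_gene_mean))

  ## gene and CpG coordinates: CpGs every 20 bp, genes 500 bp apart
  cpg_span <- (n_cpgs - 1L) * 20L + 20L
  gene_start <- cumsum(c(1L, head(cpg_span + 500L, -1L)))
  gene_end <- gene_start + cpg_span - 1L

  ## effect assignment
  n_tissue <- round(p$frac_tissue_genes * n)
  n_location <- round(p$frac_location_genes * n)
  effect_class <- rep("none", n)
  idx <- sample.int(n, n_tissue + n_location)
  if (n_tissue > 0) effect_class[idx[seq_len(n_tissue)]] <- "tissue"
  if (n_location > 0) effect_class[idx[n_tissue + seq_len(n_location)]] <- "location"
  is_effect <- effect_class != "none"

  ## baseline levels: effect genes from the intermediate component
  component <- integer(n)
  component[!is_effect] <- sample.int(3L, sum(!is_effect), replace = TRUE,
                                      prob = p$baseline_weights)
  component[is_effect] <- 2L
  baseline <- numeric(n)
  for (k in 1:3) {
    sel <- component == k
    if (any(sel)) {
      sh <- p$baseline_shapes[[k]]
      baseline[sel] <- stats::rbeta(sum(sel), sh[1L], sh[2L])
    }
  }
  baseline <- pmin(pmax(baseline, 0.01), 0.99)  # keep logit finite

  locations <- paste0("loc", seq_len(p$n_locations))
  effect_sign <- ifelse(is_effect, sample(c(-1, 1), n, replace = TRUE), 0)
  affected_location <- ifelse(effect_class == "location",
                              sample(locations, n, replace = TRUE), NA)
  dmr_w <- pmin(p$dmr_width, n_cpgs)
  dmr_start <- ifelse(is_effect,
                      vapply(seq_len(n), function(i) {
                        sample.int(n_cpgs[i] - dmr_w[i] + 1L, 1L)
                      }, integer(1L)),
                      NA_integer_)
  dmr_end <- ifelse(is_effect, dmr_start + dmr_w - 1L, NA_integer_)

  ## gene annotation flags
  high_n <- stats::runif(n) < p$frac_high_n
  n_fraction <- ifelse(high_n, stats::runif(n, 0.55, 0.95),
                       stats::runif(n, 0, 0.05))
  hk_prob <- ifelse(is_effect, p$hk_effect, p$hk_background)
  is_housekeeping <- stats::runif(n) < hk_prob
  te_overlap <- stats::runif(n) < p$te_rate

  genes <- data.frame(gene_id = gene_ids, scaffold = "scaf1",
                      start = gene_start, end = gene_end, strand = "+",
                      n_fraction = round(n_fraction, 4L),
                      is_housekeeping = is_housekeeping,
                      te_overlap = te_overlap,
                      stringsAsFactors = FALSE)

  ## samples: tissue x location x replicate
  grid <- expand.grid(replicate = seq_len(p$samples_per_group),
                      location = locations, tissue = p$tissues,
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("%s_%s_r%02d",
                        abbreviate_tissue(grid$tissue), grid$location,
                        grid$replicate),
    tissue = grid$tissue, location = grid$location,
    condition = "wild", dataset = "capture",
    stringsAsFactors = FALSE)
  samples$group <- paste(samples$tissue, samples$location, sep = ":")
  groups <- unique(samples$group)

  ## per-CpG layout and true ratios per group
  cpg <- data.table::data.table(
    gene_id = rep(gene_ids, n_cpgs),
    cpg_index = unlist(lapply(n_cpgs, seq_len)),
    position = unlist(lapply(seq_len(n), function(i) {
      gene_start[i] + (seq_len(n_cpgs[i]) - 1L) * 20L
    })))
  gi <- match(cpg$gene_id, gene_ids)
  cpg_base <- baseline[gi]
  in_window <- is_effect[gi] & cpg$cpg_index >= dmr_start[gi] &
    cpg$cpg_index <= dmr_end[gi]

  true_ratio <- matrix(rep(cpg_base, length(groups)), ncol = length(groups),
                       dimnames = list(NULL, groups))
  group_tissue <- sub(":.*$", "", groups)
  group_location <- sub("^.*:", "", groups)
  for (g in seq_along(groups)) {
    affected <- in_window & (
      (effect_class[gi] == "tissue" & group_tissue[g] == p$tissues[1L]) |
      (effect_class[gi] == "location" &
         group_location[g] == affected_location[gi]))
    if (any(affected)) {
      true_ratio[affected, g] <- logit_shift(cpg_base[affected],
                                             effect_sign[gi][affected] *
                                               p$effect_delta)
    }
  }

  ## observed counts per sample
  n_cpg_rows <- nrow(cpg)
  chh_pos <- max(gene_end) + 1000L + seq_len(p$chh_sites) * 7L
  tables <- vector("list", nrow(samples))
  names(tables) <- samples$sample_id
  for (s in seq_len(nrow(samples))) {
    r_true <- true_ratio[, samples$group[s]]
    p_obs <- r_true + (1 - r_true) * p$non_conversion
    coverage <- stats::rnbinom(n_cpg_rows, size = p$coverage_dispersion,
                               mu = p$coverage_mean)
    meth <- stats::rbinom(n_cpg_rows, coverage, p_obs)
    tab <- data.table::data.table(
      scaffold = "scaf1", position = cpg$position, strand = "+",
      context = "CpG", meth_count = meth, total_count = coverage)
    if (p$chh_sites > 0L) {
      chh_cov <- stats::rnbinom(p$chh_sites, size = p$coverage_dispersion,
                                mu = p$coverage_mean)
      chh_meth <- stats::rbinom(p$chh_sites, chh_cov, p$non_conversion)
      tab <- rbind(tab, data.table::data.table(
        scaffold = "scaf1", position = chh_pos, strand = "+",
        context = "CHH", meth_count = chh_meth, total_count = chh_cov))
    }
    tab[, "ratio" := ifelse(tab$total_count > 0,
                            tab$meth_count / tab$total_count, NA_real_)]
    tables[[s]] <- tab
  }

  truth_genes <- data.frame(
    gene_id = gene_ids, baseline_level = baseline,
    baseline_component = component, effect_class = effect_class,
    effect_sign = effect_sign, affected_tissue =
      ifelse(effect_class == "tissue", p$tissues[1L], NA),
    affected_location = ifelse(effect_class == "location",
                               affected_location, NA),
    dmr_start_index = dmr_start, dmr_end_index = dmr_end,
    n_cpgs = n_cpgs, stringsAsFactors = FALSE)

  cpg_truth <- data.table::data.table(
    gene_id = rep(cpg$gene_id, length(groups)),
    cpg_index = rep(cpg$cpg_index, length(groups)),
    position = rep(cpg$position, length(groups)),
    group = rep(groups, each = n_cpg_rows),
    true_ratio = as.vector(true_ratio))

  structure(list(tables = tables, genes = genes, samples = samples,
                 truth = list(genes = truth_genes, cpg_ratios = cpg_truth),
                 params = p),
            class = "simulated_methylome")
}

abbreviate_tissue <- function(x) {
  vapply(x, function(t) switch(t,
    hepatopancreas = "hep", abdominal_muscle = "mus",
    substr(t, 1L, 3L)), character(1L))
}

#' @export
print.simulated_methylome <- function(x, ...) {
  cat("simulated_methylome:", nrow(x$genes), "genes,",
      nrow(x$samples), "samples,",
      sum(x$truth$genes$effect_class == "tissue"), "tissue-effect and",
      sum(x$truth$genes$effect_class == "location"),
      "location-effect genes\n")
  invisible(x)
}

#' Precision and recall of a called gene set against simulation truth
#'
#' @param called_genes character vector of called gene ids.
#' @param truth the `truth$genes` data frame of a simulated dataset (or
#'   the `simulated_methylome` itself).
#' @param effect_class which true effect class to score against
#'   (`"tissue"` or `"location"`).
#' @return named numeric vector with `precision` (1 when nothing is
#'   called) and `recall`.
#' @export
recovery_scores <- function(called_genes, truth,
                            effect_class = c("location", "tissue")) {
  effect_class <- match.arg(effect_class)
  if (inherits(truth, "simulated_methylome")) truth <- truth$truth$genes
  unknown <- setdiff(called_genes, truth$gene_id)
  if (length(unknown) > 0L) {
    stop("called gene(s) absent from truth table: ",
         paste(head(unknown, 3L), collapse = ", "))
  }
  true_set <- truth$gene_id[truth$effect_class == effect_class]
  hits <- length(intersect(called_genes, true_set))
  precision <- if (length(called_genes) == 0L) 1.0 else
    hits / length(unique(called_genes))
  recall <- if (length(true_set) == 0L) NA_real_ else hits / length(true_set)
  c(precision = precision, recall = recall)
}
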