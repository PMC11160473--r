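#' Pipeline configuration
#'
#' A validated flat key-value store of every tunable the pipeline uses.
#' \code{defaultConfig()} carries the reference analysis parameters: the
#' two-stage QC cutoffs (stage 1: fewer than 750 detected genes, more than
#' 12,500 UMIs or more than 2.5\% mitochondrial reads removed; stage 2
#' additionally removes cells with more than 2750 detected genes, 9500 UMIs
#' or 1.25\% mitochondrial reads), CP10k depth scaling, 2000 highly variable
#' genes, Leiden resolution 5, a background of 100 WT nonneuronal cells,
#' the 0.05 p-value cutoff for receptor calls, and 750-gene PC-loading
#' stage sets. \code{deskConfig()} rescales the size-dependent values to the
#' synthetic desk-scale datasets produced by \code{\link{simulateAntennalSn}}
#' (about 160 detected genes and 350 UMIs per cell; see the vignette).
#'
#' @param ... named overrides of individual keys.
#' @return a \code{PipelineConfig} object (a validated named list).
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    # stage-1 (lenient) cell filters
    qc1_min_genes = 750, qc1_max_umis = 12500, qc1_max_pct_mito = 2.5,
    # stage-2 (stringent) additional filters
    qc2_max_genes = 2750, qc2_max_umis = 9500, qc2_max_pct_mito = 1.25,
    qc_stage = "stringent",
    cp10k_scale = 10000,
    n_hvg = 2000,
    n_pcs = NA_integer_,        # NA: use the explained-variance elbow
    n_neighbors = 15,
    cluster_resolution = 5,
    background_size = 100,
    alpha = 0.05,
    loading_set_size = 750,
    fc_cutoff_sn = -1,
    fc_cutoff_bulk = -1,
    gap_penalty = 40,
    min_identity = 60,
    # synthetic-data study conditions
    sim_n_cells_per_genotype = 2000,
    sim_neuron_mass_wt = 0.67,
    sim_neuron_mass_mut = NA_real_, # NA: derived from program survival
    sim_dispersion = 0.3,
    sim_depth_sdlog = 0.35,
    sim_batch_sdlog = 0.15,
    sim_baseline_noise = 0.005,
    bulk_n_per_program = 400,
    bulk_n_flat = 1100,
    bulk_replicates = 3,
    bulk_dispersion = 0.1,
    bulk_depth_sdlog = 0.25,
    rng_seed = 1L)
  cfg <- utils::modifyList(cfg, list(...))
  validateConfig(cfg)
}

#' @rdname defaultConfig
#' @export
deskConfig <- function(...) {
  over <- list(
    qc1_min_genes = 75, qc1_max_umis = 1500, qc1_max_pct_mito = 2.5,
    qc2_max_genes = 350, qc2_max_umis = 1200, qc2_max_pct_mito = 1.25,
    n_hvg = 800,
    n_pcs = 30L,
    loading_set_size = 400)
  do.call(defaultConfig, utils::modifyList(over, list(...)))
}

#' Validate a configuration list
#'
#' @param cfg named list of configuration values.
#' @return the list with class \code{"PipelineConfig"}; errors on any
#'   invalid value (all thresholds positive, \code{alpha} in (0, 1),
#'   stage-2 bounds strictly inside stage-1 bounds where comparable).
#' @export
validateConfig <- function(cfg) {
  stopifnot(is.list(cfg))
  miss <- setdiff(CONFIG_KEYS, names(cfg))
  if (length(miss)) stop("config is missing keys: ", paste(miss, collapse = ", "))
  pos <- c("qc1_min_genes", "qc1_max_umis", "qc1_max_pct_mito",
           "qc2_max_genes", "qc2_max_umis", "qc2_max_pct_mito",
           "cp10k_scale", "n_hvg", "n_neighbors", "cluster_resolution",
           "background_size", "loading_set_size", "gap_penalty",
           "min_identity", "sim_n_cells_per_genotype", "sim_depth_sdlog",
           "bulk_n_per_program", "bulk_replicates", "bulk_depth_sdlog")
  for (k in pos) if (!is.numeric(cfg[[k]]) || is.na(cfg[[k]]) || cfg[[k]] <= 0)
    stop("config value '", k, "' must be positive")
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("config value 'alpha' must lie strictly in (0, 1)")
  if (cfg$qc2_max_umis >= cfg$qc1_max_umis)
    stop("stage-2 UMI bound must be strictly inside the stage-1 bound")
  if (cfg$qc2_max_pct_mito >= cfg$qc1_max_pct_mito)
    stop("stage-2 mito bound must be strictly inside the stage-1 bound")
  if (!cfg$qc_stage %in% c("lenient", "stringent"))
    stop("qc_stage must be 'lenient' or 'stringent'")
  structure(cfg, class = "PipelineConfig")
}

CONFIG_KEYS <- c(
  "qc1_min_genes", "qc1_max_umis", "qc1_max_pct_mito",
  "qc2_max_genes", "qc2_max_umis", "qc2_max_pct_mito",
  "qc_stage", "cp10k_scale", "n_hvg", "n_pcs", "n_neighbors",
  "cluster_resolution", "background_size", "alpha", "loading_set_size",
  "fc_cutoff_sn", "fc_cutoff_bulk", "gap_penalty", "min_identity",
  "sim_n_cells_per_genotype", "sim_neuron_mass_wt", "sim_neuron_mass_mut",
  "sim_dispersion", "sim_depth_sdlog", "sim_batch_sdlog",
  "sim_baseline_noise", "bulk_n_per_program", "bulk_n_flat",
  "bulk_replicates", "bulk_dispersion", "bulk_depth_sdlog", "rng_seed")

#' Read / write a pipeline configuration file
#'
#' Flat YAML key-value serialization; \code{readConfig} validates on load so
#' an invalid file is rejected before any computation.
#'
#' @param path file path.
#' @param cfg a \code{PipelineConfig}.
#' @return \code{readConfig}: a validated \code{PipelineConfig};
#'   \code{writeConfig}: the path, invisibly.
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateConfig(utils::modifyList(unclass(defaultConfig()), cfg))
}

#' @rdname readConfig
#' @export
writeConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
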