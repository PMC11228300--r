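# End-to-end orchestration: synthesize or load a cohort, run the density
# comparison and the co-activation network analysis, and write every
# table the analysis produces plus a JSON run report.

#' Assemble a run configuration
#'
#' A run is fully reproducible from its configuration (which includes the
#' seed). Either set `preset = TRUE` to simulate the built-in WT/KO
#' cohort, or point `counts` at a TSV cohort table.
#'
#' @param outdir output directory (created if needed).
#' @param seed integer seed.
#' @param thresholds sweep thresholds, ascending.
#' @param tau edge threshold.
#' @param mode edge selection mode, `"abs_rho"` or `"fdr_p"`.
#' @param alpha FDR level.
#' @param bin_width behavior bin width, seconds.
#' @param preset logical: simulate the preset cohort.
#' @param region_table path to a region table (default: shipped fixture).
#' @param networks path to network definitions (default: shipped file).
#' @param counts optional path to a cohort counts TSV (used when
#'   `preset = FALSE`).
#' @return List of class `run_config`.
#' @export
run_config <- function(outdir, seed = 1L, thresholds = c(0.7, 0.8, 0.9),
                       tau = 0.8, mode = "abs_rho", alpha = 0.05,
                       bin_width = 60, preset = TRUE,
                       region_table = NULL, networks = NULL,
                       counts = NULL) {
  structure(list(outdir = outdir, seed = as.integer(seed),
                 thresholds = thresholds, tau = tau, mode = mode,
                 alpha = alpha, bin_width = bin_width, preset = preset,
                 region_table = region_table, networks = networks,
                 counts = counts),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with the fields of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$outdir)) stop("config must state outdir")
  do.call(run_config, cfg)
}

#' Run the full co-activation analysis pipeline
#'
#' Stages: cohort (simulate preset or load counts) -> densities ->
#' per-region group comparison -> per-genotype correlation, adjacency,
#' threshold sweep and subnetwork edge lists -> written tables and a JSON
#' report. Any stage error aborts with the stage name. Re-running the
#' same config reproduces all numeric outputs bit for bit.
#'
#' @param config a `run_config` (or path to a YAML one).
#' @return The report list, invisibly. Side effect: files under
#'   `config$outdir` (densities.tsv, group_comparison.tsv, per-genotype
#'   correlation/adjacency TSVs, density_sweep.tsv, one edge-list TSV per
#'   genotype x network, run_config.yaml, report.json).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  ont <- stage("regions", load_region_table(
    if (is.null(config$region_table)) default_region_table()
    else config$region_table))
  nets <- stage("networks", load_network_definitions(
    if (is.null(config$networks)) default_network_definitions()
    else config$networks, ont))
  cohort <- stage("cohort", {
    if (isTRUE(config$preset)) {
      generate_cohort(preset_cohort_spec(ont, nets, seed = config$seed))
    } else {
      if (is.null(config$counts))
        stop("preset = FALSE requires a counts table path")
      read_counts_table(config$counts, ont)
    }
  })
  dens <- stage("densities", compute_density(cohort))
  cmp <- stage("group_comparison", compare_groups(dens, config$alpha))
  fit <- stage("network", cofos_network(
    dens, tau = config$tau, thresholds = config$thresholds,
    mode = config$mode, alpha = config$alpha, networks = nets))

  out <- function(...) file.path(config$outdir, ...)
  write_counts_table(cohort, out("counts.tsv"))
  write.table(data.frame(animal_id = dens$animal_id,
                         genotype = as.character(dens$genotype),
                         dens$values, check.names = FALSE),
              out("densities.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_group_comparison(cmp, out("group_comparison.tsv"))
  files <- c("counts.tsv", "densities.tsv", "group_comparison.tsv")
  for (g in names(fit$correlations)) {
    write_matrix_tsv(fit$correlations[[g]], out(paste0("corr_", g, ".tsv")))
    write_matrix_tsv(fit$adjacency[[g]], out(paste0("adjacency_", g, ".tsv")))
    files <- c(files, paste0(c("corr_", "adjacency_"), g, ".tsv"))
    for (nm in names(fit$subnetworks[[g]])) {
      f <- paste0("edges_", g, "_", nm, ".tsv")
      write_edge_list(fit$subnetworks[[g]][[nm]], out(f))
      files <- c(files, f)
    }
  }
  write.table(fit$sweep, out("density_sweep.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  files <- c(files, "density_sweep.tsv")
  cfg_path <- out("run_config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  report <- list(
    package_version = as.character(utils::packageVersion("cofosnet")),
    config = unclass(config),
    config_md5 = unname(tools::md5sum(cfg_path)),
    genotypes = names(fit$density),
    network_density = as.list(fit$density),
    n_regions = nrow(ont),
    files = files)
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
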