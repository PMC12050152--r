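## End-to-end pipeline: (optional) simulation -> morphological networks ->
## functional networks -> coupling -> group statistics, with every artifact
## written as TSV plus a JSON metadata sidecar. All randomness flows from the
## single configured seed.

#' Pipeline run configuration
#'
#' Validates the knobs of [run_pipeline()]. Unknown arguments are an error,
#' not a warning.
#'
#' @param input_dir Directory with the input tables (`voxel_samples.tsv`,
#'   `timeseries/`, `cohort.tsv`, `partition.tsv`, `centroids.tsv`), or
#'   `NULL` when `simulate` is given.
#' @param output_dir Output directory.
#' @param simulate Optional [cohort_config()] used to generate the inputs.
#' @param grid_size KDE grid size per region pair (>= 8; default `2^7`).
#' @param covariates Covariate names for harmonization / residualization.
#' @param fdr_threshold FDR significance threshold in (0, 1).
#' @param n_perm Spin permutations for the group-difference map versus
#'   control-mean map correspondence (0 disables).
#' @param seed Integer seed for the whole run.
#' @return A validated list of class `mfc_run_config`.
#' @export
run_config <- function(input_dir = NULL, output_dir, simulate = NULL,
                       grid_size = 128L,
                       covariates = c("age", "sex", "education", "mean_fd"),
                       fdr_threshold = 0.05, n_perm = 0L, seed = 1L) {
  if (!is_count(grid_size, 8L)) stop_mfc("grid_size must be an integer >= 8")
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    stop_mfc("fdr_threshold must lie in (0, 1)", class = "mfc_config_error")
  if (!is_count(n_perm, 0L)) stop_mfc("n_perm must be a non-negative integer")
  if (!is_count(seed, 0L)) stop_mfc("seed must be a non-negative integer")
  if (is.null(input_dir) && is.null(simulate))
    stop_mfc("either input_dir or simulate must be given", class = "mfc_config_error")
  if (!is.null(simulate) && !inherits(simulate, "mfc_cohort_config"))
    stop_mfc("simulate must be a cohort_config()", class = "mfc_config_error")
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 simulate = simulate, grid_size = as.integer(grid_size),
                 covariates = covariates, fdr_threshold = fdr_threshold,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "mfc_run_config")
}

#' Load a pipeline configuration from JSON
#'
#' Reads a flat JSON object with the fields of [run_config()] (the
#' `simulate` field may itself be an object of [cohort_config()] arguments).
#' Unknown keys are an error.
#'
#' @param path Path to the JSON file.
#' @return An `mfc_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop_mfc("unknown configuration keys: ", paste(unknown, collapse = ", "),
             class = "mfc_config_error")
  if (!is.null(cfg$simulate)) {
    sim_known <- names(formals(cohort_config))
    sim_unknown <- setdiff(names(cfg$simulate), sim_known)
    if (length(sim_unknown))
      stop_mfc("unknown simulate keys: ", paste(sim_unknown, collapse = ", "),
               class = "mfc_config_error")
    cfg$simulate <- do.call(cohort_config, cfg$simulate)
  }
  do.call(run_config, cfg)
}

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

pipeline_log <- function(...) message("[mfcoupling] ", ...)

#' Run the full coupling pipeline
#'
#' Executes simulate (optional) -> morphological networks -> functional
#' networks -> regional/global coupling -> group statistics, writing every
#' stage's artifacts under `config$output_dir`: per-subject MSN and FCN
#' matrices, a long coupling table, group-comparison tables
#' (`regional_comparison.tsv`, `network_comparison.tsv`,
#' `global_comparison.tsv`, `symptom_correlations.tsv`), an optional
#' spin-test table, and a `run_metadata.json` sidecar recording seed and
#' configuration. Rerunning with the same configuration and seed reproduces
#' every table byte for byte.
#'
#' @param config An [run_config()] (or path to a JSON configuration).
#' @return Invisibly, a list with the cohort-mean map and the `mfc_group`
#'   result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "mfc_run_config")) stop_mfc("config must be a run_config()")
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulate)) {
    pipeline_log("simulating cohort (", config$simulate$n_regions, " regions, ",
                 2 * config$simulate$n_subjects_per_group, " subjects)")
    cohort_obj <- simulate_cohort(config$simulate, seed = config$seed)
    input_dir <- file.path(out, "inputs")
    write_cohort_inputs(cohort_obj, input_dir)
    voxels <- cohort_obj$voxels
    timeseries <- cohort_obj$timeseries
    cohort <- cohort_obj$cohort
    partition <- cohort_obj$partition
    centroids <- cohort_obj$centroids
  } else {
    pipeline_log("reading inputs from ", config$input_dir)
    voxels <- read_voxel_samples(file.path(config$input_dir, "voxel_samples.tsv"))
    ts_dir <- file.path(config$input_dir, "timeseries")
    timeseries <- lapply(names(voxels), function(sid)
      read_timeseries(file.path(ts_dir, paste0(sid, ".tsv"))))
    names(timeseries) <- names(voxels)
    cohort <- read_cohort_table(file.path(config$input_dir, "cohort.tsv"))
    partition <- read_partition(file.path(config$input_dir, "partition.tsv"))
    cent_path <- file.path(config$input_dir, "centroids.tsv")
    centroids <- if (file.exists(cent_path)) read_centroids(cent_path) else NULL
  }

  msn_dir <- file.path(out, "msn"); dir.create(msn_dir, showWarnings = FALSE)
  fcn_dir <- file.path(out, "fcn"); dir.create(fcn_dir, showWarnings = FALSE)
  subjects <- names(voxels)
  pipeline_log("building networks for ", length(subjects), " subjects")
  coupling <- matrix(NA_real_, length(subjects),
                     length(voxels[[1]]$samples),
                     dimnames = list(subjects, names(voxels[[1]]$samples)))
  global <- stats::setNames(numeric(length(subjects)), subjects)
  for (sid in subjects) {
    msn <- build_msn(voxels[[sid]], n_grid = config$grid_size)
    fcn <- build_fcn(timeseries[[sid]])
    write_matrix(msn, file.path(msn_dir, paste0(sid, ".tsv")))
    write_matrix(fcn, file.path(fcn_dir, paste0(sid, ".tsv")))
    coupling[sid, ] <- regional_coupling(msn, fcn)
    global[sid] <- as.numeric(global_coupling(msn, fcn))
  }

  pmap <- as_partition(partition, colnames(coupling))
  long <- data.frame(
    subject_id = rep(subjects, each = ncol(coupling)),
    region = rep(colnames(coupling), length(subjects)),
    network = rep(pmap[colnames(coupling)], length(subjects)),
    value = as.numeric(t(coupling)), stringsAsFactors = FALSE)
  long$value <- as.numeric(fmt_num(long$value))
  ctab <- long
  ctab$value <- fmt_num(ctab$value)
  utils::write.table(ctab, file.path(out, "coupling.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  pipeline_log("group statistics")
  fit <- mfc_group_analysis(coupling, cohort, partition,
                            covariates = config$covariates,
                            global_values = global,
                            fdr_threshold = config$fdr_threshold)
  write_df <- function(df, name) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], fmt_num)
    utils::write.table(df, file.path(out, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_df(fit$regional, "regional_comparison.tsv")
  write_df(fit$network, "network_comparison.tsv")
  write_df(fit$global, "global_comparison.tsv")
  if (!is.null(fit$symptom)) write_df(fit$symptom, "symptom_correlations.tsv")

  spin <- NULL
  if (config$n_perm > 0 && !is.null(centroids)) {
    pipeline_log("spin test (", config$n_perm, " permutations)")
    zmap <- stats::setNames(fit$regional$z, fit$regional$unit)
    is_control <- cohort$group[match(rownames(coupling), cohort$subject_id)] == "control"
    control_mean <- colMeans(coupling[is_control, , drop = FALSE])
    spin <- spin_null_pvalue(zmap, control_mean[names(zmap)], centroids,
                             n_perm = config$n_perm, seed = config$seed + 1L)
    write_df(data.frame(observed = spin$observed, p_spin = spin$p_spin,
                        n_perm = spin$n_perm, method = spin$method),
             "spin_test.tsv")
  }

  write_sidecar(file.path(out, "run"), list(
    seed = config$seed, grid_size = config$grid_size,
    covariates = config$covariates, fdr_threshold = config$fdr_threshold,
    n_perm = config$n_perm, n_subjects = length(subjects),
    n_regions = ncol(coupling),
    package_version = as.character(utils::packageVersion("mfcoupling"))))
  pipeline_log("done: ", out)
  invisible(list(coupling = coupling, global = global,
                 mean_map = colMeans(coupling), fit = fit, spin = spin))
}
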