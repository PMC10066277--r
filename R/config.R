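#' Analysis run configuration
#'
#' Collects every tunable parameter of the phenotype-and-connectedness
#' pipeline in one validated object.  The defaults reproduce the reference
#' analysis settings: 1000 label permutations, unit SVM regularization, a
#' composite cutoff of 0.5 (a composite strictly below 0.5 predicts the
#' case group), the six-level descending voxelwise threshold ladder
#' 0.005, 0.001, 0.0005, 0.0001, 0.00005, 0.00001, and Bonferroni
#' correction over 3 region tests.
#'
#' @param seed master seed; every stochastic stage derives a named
#'   substream from it via [substream_seed()].
#' @param n_permutations number of label permutations for the classifier
#'   significance test.
#' @param regularization_strength SVM cost parameter C (> 0).
#' @param composite_cutoff composite-score cutoff in `[0, 1]`; composites
#'   strictly below it are classified as the case group.
#' @param voxelwise_thresholds strictly decreasing vector of nodewise
#'   significance levels used by the robustness map.
#' @param cluster_calibration_iters permutation iterations for cluster
#'   extent calibration.
#' @param bonferroni_n number of region tests the interaction alpha is
#'   divided by.
#' @param fisher_z_averaging if `TRUE`, connectedness averages Fisher
#'   z-transformed correlations (values reported on the z scale).
#' @param case_group label of the case group (the autism-analog group);
#'   `NULL` means "first group level encountered".
#' @param paths optional named list of input/output paths carried into the
#'   run manifest.
#' @return An object of class `phenoconn_config` (a validated list).
#' @export
#' @examples
#' cfg <- run_config(seed = 42)
#' cfg$voxelwise_thresholds
run_config <- function(seed = 1L,
                       n_permutations = 1000L,
                       regularization_strength = 1.0,
                       composite_cutoff = 0.5,
                       voxelwise_thresholds = c(0.005, 0.001, 0.0005,
                                                0.0001, 0.00005, 0.00001),
                       cluster_calibration_iters = 1000L,
                       bonferroni_n = 3L,
                       fisher_z_averaging = FALSE,
                       case_group = NULL,
                       paths = list()) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    err_validation("`seed` must be a single integer")
  if (!is.numeric(n_permutations) || n_permutations < 1)
    err_validation("`n_permutations` must be a positive integer")
  if (!is.numeric(regularization_strength) || regularization_strength <= 0)
    err_validation("`regularization_strength` must be > 0")
  if (!is.numeric(composite_cutoff) ||
      composite_cutoff < 0 || composite_cutoff > 1)
    err_validation("`composite_cutoff` must lie in [0, 1]")
  th <- as.numeric(voxelwise_thresholds)
  if (length(th) < 1L || any(th <= 0) || any(th >= 1))
    err_validation("`voxelwise_thresholds` must be probabilities in (0, 1)")
  if (length(th) > 1L && any(diff(th) >= 0))
    err_validation("`voxelwise_thresholds` must be strictly decreasing")
  if (!is.numeric(cluster_calibration_iters) || cluster_calibration_iters < 1)
    err_validation("`cluster_calibration_iters` must be a positive integer")
  if (!is.numeric(bonferroni_n) || bonferroni_n < 1)
    err_validation("`bonferroni_n` must be a positive integer")

  structure(list(
    seed = as.integer(seed),
    n_permutations = as.integer(n_permutations),
    regularization_strength = as.numeric(regularization_strength),
    composite_cutoff = as.numeric(composite_cutoff),
    voxelwise_thresholds = th,
    cluster_calibration_iters = as.integer(cluster_calibration_iters),
    bonferroni_n = as.integer(bonferroni_n),
    fisher_z_averaging = isTRUE(fisher_z_averaging),
    case_group = case_group,
    paths = paths
  ), class = "phenoconn_config")
}

#' @exportS3Method base::print
print.phenoconn_config <- function(x, ...) {
  cat("phenoconn run configuration\n")
  cat("  seed:", x$seed, "\n")
  cat("  permutations:", x$n_permutations, "\n")
  cat("  SVM cost:", x$regularization_strength, "\n")
  cat("  composite cutoff:", x$composite_cutoff, "\n")
  cat("  voxelwise thresholds:",
      paste(format(x$voxelwise_thresholds, scientific = FALSE), collapse = ", "),
      "\n")
  cat("  extent calibration iters:", x$cluster_calibration_iters, "\n")
  cat("  bonferroni n:", x$bonferroni_n, "\n")
  cat("  fisher-z averaging:", x$fisher_z_averaging, "\n")
  invisible(x)
}

#' Read a run configuration from a JSON or YAML file
#'
#' @param path file whose extension selects the parser (`.json` via
#'   jsonlite, `.yaml`/`.yml` via the yaml package).
#' @return A `phenoconn_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) err_format(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      err_capability("YAML configs require the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  do.call(run_config, lst[intersect(names(lst), known)])
}
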