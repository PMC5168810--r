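#' Write detection results as TSV plus a JSON sidecar
#'
#' The TSV holds one row per feature (feature id, attribute values, up/down
#' discriminant values, call). The JSON sidecar records the models, FDR
#' estimates, effective permutation counts, configuration, seed and package
#' version, so a run is reproducible from the sidecar alone.
#'
#' @param result a [detect()] result.
#' @param path output TSV path; the sidecar is written next to it with a
#'   \code{.json} suffix.
#' @return invisibly, the two paths written.
#' @export
write_results <- function(result, path) {
  utils::write.table(result$calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- list(
    package_version = as.character(utils::packageVersion("discut")),
    config = unclass(result$config),
    effective_B = as.list(result$effective_B),
    status = as.list(result$status),
    models = lapply(Filter(Negate(is.null),
                           list(up = result$model_up, down = result$model_down)),
                    unclass),
    fdr_estimates = lapply(result$fdr_estimates, function(pp)
      lapply(Filter(Negate(is.null), pp), unclass)))
  json_path <- paste0(sub("\\.tsv$", "", path), ".json")
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(path, json_path))
}

#' Write a simulated dataset (counts, labels, truth, config)
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts_path <- file.path(dir, "counts.tsv")
  write_matrix(sim$data$values, counts_path)
  labels_path <- file.path(dir, "labels.tsv")
  utils::write.table(data.frame(sample_id = sim$data$sample_ids,
                                condition = as.character(sim$data$labels)),
                     labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(list(N = sim$N, n_up = sim$n_up, n_down = sim$n_down,
                            sigma_N = sim$sigma_N, seed = sim$seed,
                            package_version = as.character(utils::packageVersion("discut"))),
                       cfg_path, auto_unbox = TRUE, digits = NA)
  invisible(c(counts_path, labels_path, truth_path, cfg_path))
}

#' Write an evaluation report as JSON (and optionally the FDC table)
#'
#' @param report list as returned by [true_fdr()] or [aggregate_replicates()].
#' @param path output JSON path.
#' @param fdc optional data.frame (e.g. from [sweep_psi()]) written as TSV
#'   next to the JSON.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, path, fdc = NULL) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  paths <- path
  if (!is.null(fdc)) {
    fdc_path <- paste0(sub("\\.json$", "", path), "_fdc.tsv")
    utils::write.table(fdc, fdc_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, fdc_path)
  }
  invisible(paths)
}
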