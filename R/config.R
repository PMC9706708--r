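#' Read an experiment configuration file
#'
#' YAML file whose top-level keys mirror the arguments of
#' [experiment_config()]; nested sections `chain_settings`, `tree_params` and
#' `models` are passed through. Unknown keys are rejected so typos fail
#' loudly.
#'
#' @param path YAML file path.
#' @return A config list as produced by [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  raw <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$chain_settings))
    raw$chain_settings <- do.call(chain_settings, raw$chain_settings)
  do.call(experiment_config, raw)
}

#' Write a run log
#'
#' Records the master seed, a hash of the configuration, and per-stage wall
#' times, one key-value line each.
#'
#' @param result result of [run_experiment()].
#' @param path output file.
#' @export
write_run_log <- function(result, path) {
  cfg_hash <- sum(utf8ToInt(paste(deparse(result$config), collapse = "")))
  lines <- c(sprintf("seed: %d", result$config$seed),
             sprintf("config_hash: %d", cfg_hash),
             sprintf("stage_seconds_%s: %.2f", names(result$timings),
                     unlist(result$timings)))
  writeLines(lines, path)
  invisible(path)
}
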