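#' Read a pipeline configuration from YAML or JSON
#'
#' The file mirrors the structure of \code{\link{demoConfig}}: a `sim` block
#' of \code{\link{simConfig}} fields plus top-level `adapter`, `min_len`,
#' `max_len`, `max_mismatch`, `lfc_threshold`, `fdr_threshold` and a `scan`
#' block. Missing fields take their defaults.
#'
#' @param path path to a .yaml/.yml or .json file.
#' @return a configuration list for \code{\link{runPipeline}}.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  base <- demoConfig()
  if (!is.null(raw$sim)) {
    sim_args <- raw$sim
    if (!is.null(sim_args$class_mix)) sim_args$class_mix <- unlist(sim_args$class_mix)
    base$sim <- do.call(simConfig, sim_args)
  }
  for (k in setdiff(names(raw), "sim")) {
    if (identical(k, "scan")) {
      for (j in names(raw$scan)) base$scan[[j]] <- raw$scan[[j]]
    } else base[[k]] <- raw[[k]]
  }
  base
}
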