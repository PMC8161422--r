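# Run manifests: every analysis stage records its resolved parameters,
# seed and package version so outputs can be reproduced.

#' Write a run manifest
#'
#' @param command Stage label (e.g. `"balance"`, `"simulate"`).
#' @param params Named list of resolved parameters (must be
#'   JSON-serializable).
#' @param path Output JSON file.
#' @param seed Seed used by the stage (or `NA` for deterministic stages).
#' @return The manifest list, invisibly.
#' @export
run_manifest <- function(command, params, path, seed = NA_integer_) {
  manifest <- list(
    command = command,
    parameters = params,
    seed = seed,
    package = "pkashift",
    version = as.character(utils::packageVersion("pkashift")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
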