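#' Write a run manifest
#'
#' Every command-line run records exactly one JSON manifest: the command,
#' the fully resolved configuration, the master seed, the package version,
#' digests of the input files, the output paths, and a wall-clock stamp.
#' Re-running with identical manifest inputs reproduces identical outputs
#' under the package's determinism contracts.
#'
#' @param command Command name.
#' @param config Named list: the resolved configuration snapshot.
#' @param seed Master seed of the run.
#' @param inputs Character vector of input paths (digested if they exist).
#' @param outputs Character vector of output paths.
#' @param path Manifest destination (JSON).
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(command, config, seed, inputs = character(),
                               outputs = character(),
                               path = "run_manifest.json") {
  digests <- vapply(inputs, function(f) {
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
  }, character(1))
  manifest <- list(command = command, config = config, seed = seed,
                   package_version = as.character(utils::packageVersion("vestgait")),
                   input_digests = as.list(digests),
                   outputs = as.list(outputs),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
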