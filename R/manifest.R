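#' Build a run manifest
#'
#' Analysis steps record what they did — command label, parameters, input
#' and output paths, seed, package version, and document counts — so a run
#' can be reproduced from its manifest alone.
#'
#' @param command Short label for the step.
#' @param inputs,outputs Named character vectors of paths.
#' @param seed Integer seed used (or `NA`).
#' @param counts Named list/vector of document counts (read, scored,
#'   skipped, ...).
#' @param params Named list of parameter values.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(command, inputs = character(0),
                         outputs = character(0), seed = NA_integer_,
                         counts = list(), params = list()) {
  structure(
    list(
      command = command,
      package_version = as.character(utils::packageVersion("scireadability")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = seed,
      inputs = as.list(inputs),
      outputs = as.list(outputs),
      counts = as.list(counts),
      params = params
    ),
    class = "run_manifest"
  )
}

#' Write a run manifest as JSON
#'
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
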