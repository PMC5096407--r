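# Machine-readable run reports for the analysis drivers: every
# artifact-producing step records its command, configuration, seed, input
# digests and outputs so a run can be reproduced from the report alone.

file_digest <- function(path) unname(tools::md5sum(path))

object_digest <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2L)
  file_digest(tmp)
}

#' Build a run report
#'
#' @param command short name of the step.
#' @param config configuration object (echoed verbatim).
#' @param seed integer seed of the run (NA for deterministic steps).
#' @param inputs named list of input file paths or R objects (digested).
#' @param outputs named list of result values and file paths.
#' @param warnings character vector of caveats (for example
#'   convention-dependent tree counts).
#' @return list of class `run_report`.
#' @export
run_report <- function(command, config = NULL, seed = NA_integer_,
                       inputs = list(), outputs = list(),
                       warnings = character(0)) {
  digests <- lapply(inputs, function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) file_digest(x)
    else object_digest(x)
  })
  structure(list(command = command,
                 config = if (is.null(config)) NULL else unclass(config),
                 seed = seed,
                 input_digests = digests,
                 outputs = outputs,
                 warnings = warnings,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_report")
}

#' Write a run report as JSON
#' @param report a `run_report`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
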