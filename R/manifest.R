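## Run provenance: config snapshot, seeds, input digests, timings.

#' Create a run manifest
#'
#' @param config named list (configuration snapshot)
#' @param seeds named integer vector of every seed used
#' @param inputs character vector of input file paths (digested with md5)
#' @param outputs character vector of produced files
#' @param timings named numeric vector (seconds per stage)
#' @return [RunManifest-class]
#' @export
runManifest <- function(config = list(), seeds = integer(), inputs = character(),
                        outputs = character(), timings = numeric()) {
  digests <- if (length(inputs)) tools::md5sum(inputs) else character()
  new("RunManifest", fields = list(
    package = "rnatopo",
    version = as.character(utils::packageVersion("rnatopo")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config, seeds = as.list(seeds),
    inputs = as.list(digests), outputs = outputs, timings = timings))
}

#' Write a manifest as JSON (jsonlite) or dput text
#' @param manifest [RunManifest-class]; @param file path
#' @export
writeManifest <- function(manifest, file) {
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest@fields, file, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    dput(manifest@fields, file)
  }
  invisible(file)
}
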