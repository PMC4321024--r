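#' Write a run manifest
#'
#' Every command-line run records what it did: the subcommand, a snapshot
#' of the configuration, md5 digests of the input files, the seed, the
#' package version and the output paths, so a run can be audited and
#' reproduced byte-for-byte.
#'
#' @param path Output JSON path.
#' @param subcommand Name of the stage that ran.
#' @param inputs Named character vector of input file paths (digested).
#' @param outputs Named character vector of output file paths.
#' @param config Configuration list to snapshot (e.g. a [screen_config()]).
#' @param seed Integer seed in force.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, subcommand, inputs = character(),
                               outputs = character(), config = NULL,
                               seed = NA_integer_) {
  digests <- if (length(inputs) > 0) {
    as.list(tools::md5sum(unname(inputs)))
  } else {
    list()
  }
  manifest <- list(
    subcommand = subcommand,
    tool = "ovascreen",
    version = as.character(packageVersion("ovascreen")),
    seed = seed,
    config = if (is.null(config)) NULL else unclass(config),
    inputs = as.list(inputs),
    input_md5 = digests,
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
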