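#' Write a JSON run manifest next to an output file
#'
#' Records everything needed to reproduce a run: the subcommand or function
#' name, the full parameter set, the seed (if any), MD5 checksums of the
#' input files and the package version. The command-line interface writes
#' one manifest per output file.
#'
#' @param path Output file the manifest describes; the manifest is written
#'   to `<path>.manifest.json`.
#' @param subcommand Name of the operation.
#' @param params Named list of parameters.
#' @param inputs Character vector of input file paths (checksummed).
#' @param seed Seed used, or `NULL`.
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(path, subcommand, params = list(),
                               inputs = character(), seed = NULL) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    tool = "amplisnv",
    version = as.character(utils::packageVersion("amplisnv")),
    subcommand = subcommand,
    output = basename(path),
    params = params,
    seed = seed,
    input_md5 = as.list(tools::md5sum(inputs))
  )
  out <- paste0(path, ".manifest.json")
  jsonlite::write_json(manifest, out, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(out)
}
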