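# Machine-readable run manifests for reproducibility.

#' Write a run manifest
#'
#' Records the command, configuration snapshot, input file checksums,
#' seed, package and R versions into `manifest.json` inside the output
#' directory. Re-running a deterministic command with the same manifest
#' inputs reproduces its outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param command the command or function name being run.
#' @param config named list of configuration values.
#' @param inputs character vector of input file paths (checksummed with
#'   md5).
#' @param seed the seed used for any randomness.
#' @return the manifest path, invisibly.
#' @export
write_run_manifest <- function(out_dir, command, config = list(),
                               inputs = character(0), seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  checksums <- if (length(inputs))
    stats::setNames(as.character(tools::md5sum(inputs)), inputs)
  else NULL
  manifest <- list(
    command = command,
    config = config,
    inputs = as.list(checksums),
    seed = seed,
    package = "prestor",
    package_version = as.character(utils::packageVersion("prestor")),
    r_version = R.version.string,
    solver = "prestor bounded-variable simplex",
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
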