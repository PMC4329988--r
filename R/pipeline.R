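#' Run the full classification pipeline
#'
#' Convenience wrapper chaining the standard analysis order:
#' peptide filter -> ratio orientation -> per-experiment distribution
#' statistics -> significance calls -> cross-resin classification ->
#' confidence ranking (-> beadome flagging when a beadome is supplied).
#'
#' @param records Protein-group tibble ([read_protein_groups()] or
#'   [simulate_dataset()] output).
#' @param design Experiment design.
#' @param k Significance threshold in scale units.
#' @param min_peptides Quantification peptide floor.
#' @param robust Use the MAD-based scale for significance.
#' @param config An [ipac_config()].
#' @param beadome Optional beadome for [beadome_flag()].
#' @param min_stats_n Minimum quantified proteins per experiment.
#' @return List: `calls`, `stats`, `verdicts`.
#' @export
ipac_pipeline <- function(records, design, k = 1, min_peptides = 2L,
                          robust = FALSE, config = ipac_config(),
                          beadome = NULL, min_stats_n = 10L) {
  filtered <- quantification_filter(records, min_peptides)
  oriented <- orient_ratios(filtered, design,
                            exclusive_min_peptides = min_peptides)
  stats <- distribution_stats(oriented, min_stats_n = min_stats_n)
  calls <- call_significance(oriented, stats, k = k, robust = robust)
  verdicts <- ipac_classify(calls, design, config)
  if (!is.null(beadome)) verdicts <- beadome_flag(verdicts, beadome, config)
  list(calls = calls, stats = stats, verdicts = verdicts)
}

#' Write a run manifest
#'
#' Every output directory gets exactly one `manifest.json` recording the
#' command, the configuration snapshot, md5 checksums of the inputs, the
#' seed, the package version and a timestamp, so published lists are
#' reproducible and self-describing.
#'
#' @param dir Output directory.
#' @param command Subcommand or function name.
#' @param config Named list of parameters used.
#' @param inputs Character vector of input file paths (checksummed).
#' @param seed Integer seed or `NULL`.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, command, config = list(),
                           inputs = character(0), seed = NULL) {
  sums <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else {
    stats::setNames(list(), character(0))
  }
  manifest <- list(
    command = command,
    config = config,
    input_checksums = sums,
    seed = seed,
    tool_version = as.character(utils::packageVersion("ipac")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
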