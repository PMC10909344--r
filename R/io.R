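#' Derive a child seed from a seed and integer keys
#'
#' Keyed spawning of per-run and per-stage seeds from the master seed: each
#' key advances a Lehmer-style mix modulo the Mersenne prime 2^31 - 1, so
#' every (run, stage) pair maps to a reproducible 31-bit seed and adding a
#' stage never perturbs earlier ones.
#'
#' @param seed Integer seed.
#' @param ... Integer keys (e.g. run index, stage index).
#' @return A single integer seed in \[1, 2^31 - 2\].
#' @export
child_seed <- function(seed, ...) {
  m <- 2147483647
  s <- as.double(seed %% m)
  for (k in c(...)) {
    s <- (s * 48271 + as.double(k)) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

# stage indices used by run_single; fixed so manifests are replayable
STAGES <- c(founders = 1L, parent_infection = 2L, pairing = 3L,
            reproduction = 4L, offspring_infection = 5L,
            sampling_control = 6L, sampling_increased = 7L,
            sampling_decreased = 8L)

#' Write / read an experiment run table
#'
#' CSV with a fixed header; numeric columns are serialized with 17
#' significant digits so the round trip is lossless, and missing metrics
#' (e.g. an undefined relative risk) survive as empty cells.
#'
#' @param table Run table from [run_experiment()].
#' @param path File path.
#' @return `path` invisibly (write) or the table (read).
#' @export
write_run_table <- function(table, path) {
  out <- table
  for (nm in names(out)) {
    if (is.double(out[[nm]]))
      out[[nm]] <- ifelse(is.na(out[[nm]]), "",
                          sprintf("%.17g", out[[nm]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_run_table
#' @export
read_run_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  logical_cols <- grep("^converged_", names(tab), value = TRUE)
  for (nm in logical_cols) tab[[nm]] <- as.logical(tab[[nm]])
  tab
}

#' Write a run manifest
#'
#' JSON snapshot of the configuration, experiment labels, master seed and
#' output paths; re-running [run_experiment()] from the manifest reproduces
#' the table exactly.
#'
#' @param cfg A [scenario_config()].
#' @param outcome,scheme Experiment labels.
#' @param table_path Path of the persisted run table.
#' @param path Manifest output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cfg, outcome, scheme, table_path, path) {
  jsonlite::write_json(list(
    package_version = as.character(utils::packageVersion("capturebias")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    outcome = outcome,
    scheme = scheme,
    master_seed = cfg$seed,
    stage_indices = as.list(STAGES),
    config = unclass(cfg),
    table_path = table_path
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
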