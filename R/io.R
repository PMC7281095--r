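#' Read and write delimited trace tables
#'
#' Traces are plain CSV with a `time_s` column plus value columns
#' (`alpha`/`beta`, `I_mean`, `U_mms`, ...), sampled on a uniform grid.
#'
#' @param path CSV file path.
#' @return [read_trace_csv()] returns a tibble.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) abort("trace CSV must have a `time_s` column.")
  as_tibble(df)
}

#' @rdname read_trace_csv
#' @param trace A data frame to write.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' The YAML document has `geometry`, `protocol`, `fluids`, `compliance` and
#' optional `analysis` blocks; fields mirror the constructor arguments of
#' [channel_geometry()], [pump_protocol()], [fluid_pair()] and
#' [compliance_pack()]. Missing fields fall back to the constructor
#' defaults.
#'
#' @param path YAML file path.
#' @return A list with elements `geometry`, `protocol`, `fluids`,
#'   `compliance`, `analysis` (a plain list).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  build <- function(block, ctor) do.call(ctor, cfg[[block]] %||% list())
  list(
    geometry = build("geometry", channel_geometry),
    protocol = build("protocol", pump_protocol),
    fluids = build("fluids", fluid_pair),
    compliance = build("compliance", compliance_pack),
    analysis = cfg$analysis %||% list()
  )
}

#' Write run metadata (thresholds and defaults actually used) to YAML
#'
#' @param config A named list of settings to echo.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build a synthetic scenario from a YAML document
#'
#' Blocks `protocol`, `compliance`, `fluids`, `aggregation`, `noise` and
#' scalars `seed`, `calibration_slope` mirror [synthetic_scenario()].
#'
#' @param path YAML file path.
#' @return A [synthetic_scenario()].
#' @export
scenario_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) abort("scenario YAML must define `seed`.")
  synthetic_scenario(
    seed = cfg$seed,
    protocol = do.call(pump_protocol, cfg$protocol %||% list()),
    compliance = do.call(compliance_pack, cfg$compliance %||% list()),
    fluids = do.call(fluid_pair, cfg$fluids %||% list()),
    aggregation = cfg$aggregation %||% list(),
    calibration_slope = cfg$calibration_slope %||% 2.0732,
    noise = cfg$noise %||% list()
  )
}
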