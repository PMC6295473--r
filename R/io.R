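#' Load and validate a full simulation configuration
#'
#' Reads a YAML file with up to four sections — `geometry`, `params`,
#' `solver`, `protocol` — each holding overrides of the corresponding
#' constructor defaults ([geometry_config()], [sim_params()],
#' [solver_config()], [pacing_protocol()]).  Unknown sections or keys are
#' rejected with a message naming the offending key; all values pass the
#' constructors' range validation.  Units are fixed package-wide (um, ms,
#' uM, mV).
#'
#' @param path YAML file path.
#' @return A `sim_config` list with validated `geometry`, `params`,
#'   `solver`, `protocol` elements.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("geometry", "params", "solver", "protocol")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  build <- function(section, fun) {
    over <- raw[[section]]
    if (is.null(over)) over <- list()
    ok <- names(formals(fun))
    unknown <- setdiff(names(over), ok)
    if (length(unknown))
      stop(sprintf("unknown key(s) in '%s': %s", section,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    do.call(fun, over)
  }
  cfg <- list(geometry = build("geometry", geometry_config),
              params = do.call(sim_params, if (is.null(raw$params)) list()
                               else raw$params),
              solver = build("solver", solver_config),
              protocol = build("protocol", pacing_protocol))
  class(cfg) <- "sim_config"
  cfg
}

#' Save a simulation configuration
#'
#' Writes a [load_config()]-compatible YAML snapshot; a save/load
#' round-trip reproduces the configuration exactly.
#'
#' @param config A `sim_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  out <- list(geometry = drop_null(unclass(config$geometry)),
              params = drop_null(unclass(config$params)),
              solver = drop_null(unclass(config$solver)),
              protocol = drop_null(unclass(config$protocol)))
  yaml::write_yaml(out, path)
  invisible(path)
}

drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

#' Write a recording bundle to disk
#'
#' Writes plain-text outputs (CSV time series and tables; documented units:
#' concentrations uM, time ms, positions um), an `.rds` container for any
#' snapshot arrays, and a JSON run manifest listing the configuration
#' snapshot, seed, package version, timestamps, warning counters and the
#' file inventory.
#'
#' @param recording A `pacing_recording` (or compatible list) from the
#'   protocol drivers; `NULL` fields are skipped.
#' @param out_dir Output directory (created if needed).
#' @param config Optional `sim_config` to embed in the manifest.
#' @param extra Optional named list of extra tables (data frames) to write
#'   as CSV.
#' @return The manifest (invisibly), written as `manifest.json`.
#' @export
write_outputs <- function(recording, out_dir, config = NULL, extra = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  inventory <- character(0)
  put_csv <- function(df, name) {
    f <- file.path(out_dir, name)
    write.csv(df, f, row.names = FALSE)
    inventory <<- c(inventory, name)
  }
  if (!is.null(recording$time)) {
    put_csv(data.frame(time_ms = recording$time, ci_avg_uM = recording$ci_avg,
                       csr_avg_uM = recording$csr_avg, V_mV = recording$V),
            "averages.csv")
  }
  if (!is.null(recording$fluxes)) put_csv(recording$fluxes, "fluxes.csv")
  if (!is.null(recording$strips) && length(recording$strips))
    put_csv(cbind(data.frame(time_ms = recording$time), recording$strips),
            "strips.csv")
  if (!is.null(recording$tprofile))
    put_csv(as.data.frame(recording$tprofile), "transversal_linescan.csv")
  if (!is.null(recording$lprofile))
    put_csv(as.data.frame(recording$lprofile), "longitudinal_linescan.csv")
  for (nm in names(extra)) put_csv(extra[[nm]], paste0(nm, ".csv"))
  if (!is.null(recording$snapshots)) {
    f <- file.path(out_dir, "snapshots.rds")
    saveRDS(list(movie = recording$snapshots, t_ms = recording$snapshot_t),
            f)
    inventory <- c(inventory, "snapshots.rds")
  }
  manifest <- list(
    package = "atriasim",
    version = as.character(utils::packageVersion("atriasim")),
    seed = recording$seed,
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    units = list(length = "um", time = "ms", concentration = "uM",
                 voltage = "mV"),
    warnings = list(clips = as.list(recording$clips)),
    config = if (!is.null(config))
      jsonlite::fromJSON(jsonlite::toJSON(
        list(geometry = drop_null(unclass(config$geometry)),
             params = drop_null(unclass(config$params)),
             solver = drop_null(unclass(config$solver)),
             protocol = drop_null(unclass(config$protocol))),
        auto_unbox = TRUE)) else NULL,
    inventory = inventory,
    complete = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

#' Export the CaRU table for a geometry
#'
#' Plain-text CSV of the functional release units: id, centre coordinates,
#' RyR count and occupied area.
#'
#' @param geom A `cell_geometry`.
#' @param path Output CSV path.
#' @return The table, invisibly.
#' @export
write_caru_table <- function(geom, path) {
  tab <- identify_carus(geom)
  write.csv(tab[, c("caru_id", "center_x_um", "center_y_um", "n_ryr",
                    "area_um2")], path, row.names = FALSE)
  invisible(tab)
}
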