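# On-disk fixture bundles: manifest + spike trains (+ optional raw traces).

#' Write spike trains to CSV
#'
#' Tabular text format with header `unit_id,repetition_index,phase_label,
#' spike_time_ms`; times are written with 17 significant digits so the
#' round-trip through [read_spike_trains()] is bit-exact for doubles.
#'
#' @param spikes A `spike_train_set` (or compatible data frame).
#' @param path Output CSV path.
#' @export
write_spike_trains <- function(spikes, path) {
  df <- data.frame(
    unit_id = spikes$unit_id,
    repetition_index = spikes$repetition_index,
    phase_label = spikes$phase_label,
    spike_time_ms = formatC(spikes$spike_time_ms, digits = 17, format = "g"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spike trains written by [write_spike_trains()]
#' @param path CSV path.
#' @return A data frame with the spike-train columns.
#' @export
read_spike_trains <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(unit_id = "character",
                                       repetition_index = "integer",
                                       phase_label = "character",
                                       spike_time_ms = "numeric"))
  class(df) <- c("spike_train_set", class(df))
  df
}

#' Generate and write a complete synthetic fixture bundle
#'
#' Generates a population and its spike trains (and optionally raw traces)
#' and writes everything to `dir`: `manifest.json` (protocol, seed, per-unit
#' ground truth), `spike_trains.csv`, and `raw.bin`/`raw.json` when
#' `with_raw`. The write is atomic: files are staged in a temporary sibling
#' directory and moved into place only on success, so a failure leaves no
#' stale bundle.
#'
#' @param dir Target directory (created; must not already contain a bundle).
#' @param spec A [population_spec()].
#' @param protocol A [stimulus_protocol()].
#' @param geometry A [geometry_spec()].
#' @param with_raw Also synthesize and store raw voltage traces.
#' @param noise_sd Raw-trace noise SD, volts.
#' @return `dir`, invisibly.
#' @export
make_fixture_bundle <- function(dir, spec, protocol, geometry = geometry_spec(),
                                with_raw = FALSE, noise_sd = 1e-5) {
  staging <- paste0(dir, ".staging")
  if (dir.exists(staging)) unlink(staging, recursive = TRUE)
  dir.create(staging, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(staging, recursive = TRUE), add = TRUE)

  units <- generate_population(spec, geometry)
  spikes <- if (spec$n_units > 0)
    simulate_spike_trains(units, protocol, seed = spec$seed)
  else NULL

  manifest <- list(
    seed = spec$seed,
    protocol = unclass(protocol),
    n_units = spec$n_units,
    empty = is.null(spikes) || nrow(spikes) == 0,
    units = units[, setdiff(names(units), "axon_path")]
  )
  jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  write_spike_trains(if (is.null(spikes)) {
    data.frame(unit_id = character(), repetition_index = integer(),
               phase_label = character(), spike_time_ms = numeric())
  } else spikes, file.path(staging, "spike_trains.csv"))

  if (with_raw) {
    rec <- synthesize_raw_recording(spikes, units, protocol, geometry,
                                    noise_sd = noise_sd, seed = spec$seed)
    write_raw_recording(rec, file.path(staging, "raw"))
  }

  if (dir.exists(dir)) unlink(dir, recursive = TRUE)
  if (!file.rename(staging, dir))
    stop("make_fixture_bundle: could not move staged bundle into place", call. = FALSE)
  ok <- TRUE
  invisible(dir)
}

#' Read a fixture bundle written by [make_fixture_bundle()]
#' @param dir Bundle directory.
#' @return List with `manifest`, `units` (data frame), `spike_trains`, and
#'   `raw` (`raw_recording` or `NULL`).
#' @export
read_fixture_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  spikes <- read_spike_trains(file.path(dir, "spike_trains.csv"))
  raw <- if (file.exists(file.path(dir, "raw.bin")))
    read_raw_recording(file.path(dir, "raw")) else NULL
  units <- as.data.frame(manifest$units, stringsAsFactors = FALSE)
  list(manifest = manifest, units = units, spike_trains = spikes, raw = raw)
}
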