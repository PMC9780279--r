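# Raw multi-channel voltage trace synthesis and binary container IO.

#' Synthesize a raw MEA recording from spike trains
#'
#' Builds channels x samples voltage traces as the sum of (in volts):
#' Gaussian sensor noise, a biphasic spike waveform per spike on the channels
#' near the unit position (amplitude decaying with a Gaussian spatial
#' profile), plus the modality-specific stimulation artifact. Electrical mode
#' adds the sinusoidal carrier inside each phase window with an amplitude
#' decaying with the channel's distance to the active electrode columns.
#' Optogenetic mode adds a slow sensor drift ramp that is reset every 400 ms
#' by a 200 us high-amplitude reset transient; reset sample indices are
#' recorded exactly in the returned object.
#'
#' Noise is drawn first from `seed` with dimensions independent of content,
#' so synthesis is additive: with the same seed, the difference between a
#' recording with and without spikes is exactly the spike component.
#'
#' @param spike_trains A `spike_train_set` (may have zero rows).
#' @param units The `unit_population` the trains came from (positions used for
#'   waveform placement); may be `NULL` when `spike_trains` is empty.
#' @param protocol A [stimulus_protocol()].
#' @param geometry A [geometry_spec()].
#' @param noise_sd Sensor noise SD, volts.
#' @param seed Integer seed for the noise.
#' @param sampling_rate Sampling rate, Hz.
#' @param n_channel_side Channels are laid out on an
#'   `n_channel_side x n_channel_side` grid spanning the array.
#' @param template_amplitude Negative-peak spike amplitude at the unit
#'   position, volts.
#' @param spatial_sd Gaussian spatial decay of the spike waveform, um.
#' @param artifact_amplitude Carrier artifact amplitude at an active
#'   electrode, volts (electrical mode).
#' @param artifact_space_constant Exponential decay of the artifact with
#'   distance to the nearest active column, um.
#' @param drift_amplitude Drift accumulated over one 400 ms reset interval,
#'   volts (optogenetic mode).
#' @param reset_amplitude Amplitude of the 200 us reset transient, volts.
#' @return An object of class `raw_recording`: list with `traces`
#'   (channels x samples), `sampling_rate`, `channel_positions`,
#'   `reset_times` (1-based sample indices), `reset_duration_us`, `modality`.
#' @export
synthesize_raw_recording <- function(spike_trains, units, protocol,
                                     geometry = geometry_spec(),
                                     noise_sd = 1e-5, seed = 1L,
                                     sampling_rate = 20000,
                                     n_channel_side = 4L,
                                     template_amplitude = 1e-4,
                                     spatial_sd = 30,
                                     artifact_amplitude = 5e-3,
                                     artifact_space_constant = 100,
                                     drift_amplitude = 5e-3,
                                     reset_amplitude = 8e-3) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  reset_interval_ms <- 400
  reset_duration_us <- 200
  if (protocol$modality == "optogenetic" &&
      sampling_rate * reset_duration_us * 1e-6 < 2)
    stop("synthesize_raw_recording: sampling_rate too low to represent a 200 us reset",
         call. = FALSE)

  duration_ms <- protocol$n_repetitions * protocol$repetition_duration
  n_samples <- round(duration_ms / 1000 * sampling_rate)
  pos <- as.matrix(expand.grid(
    x = seq(0, geometry$array_extent[1], length.out = n_channel_side),
    y = seq(0, geometry$array_extent[2], length.out = n_channel_side)))
  n_ch <- nrow(pos)

  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  traces <- matrix(stats::rnorm(n_ch * n_samples, 0, noise_sd), nrow = n_ch)

  # biphasic spike template, ~1.2 ms
  tt <- seq(0, 1.2e-3, by = 1 / sampling_rate)
  template <- -sin(2 * pi * tt / 1.2e-3) * exp(-tt / 4e-4)
  template <- template / max(abs(template))

  if (nrow(spike_trains) > 0) {
    stopifnot(!is.null(units))
    uix <- match(spike_trains$unit_id, units$unit_id)
    t_abs <- (spike_trains$repetition_index - 1) * protocol$repetition_duration +
      spike_trains$spike_time_ms
    s0 <- round(t_abs / 1000 * sampling_rate) + 1L
    for (k in seq_along(s0)) {
      i <- s0[k]:(s0[k] + length(template) - 1L)
      keep <- i <= n_samples
      if (!any(keep)) next
      d2 <- (pos[, 1] - units$x[uix[k]])^2 + (pos[, 2] - units$y[uix[k]])^2
      amp <- template_amplitude * exp(-d2 / (2 * spatial_sd^2))
      traces[, i[keep]] <- traces[, i[keep]] +
        outer(amp, template[keep])
    }
  }

  reset_times <- integer(0)
  t_ms <- (seq_len(n_samples) - 1) / sampling_rate * 1000

  if (protocol$modality == "electrical") {
    # active stimulation columns alternate between phases
    col_x <- seq(0, by = geometry$stim_pitch, length.out = geometry$n_stim_cols)
    width_cols <- max(1L, round(protocol$bar_width / geometry$stim_pitch))
    band <- ((seq_along(col_x) - 1) %/% width_cols) %% 2  # 0 = phase1, 1 = phase2
    in_rep_ms <- t_ms %% protocol$repetition_duration
    for (ph in c("phase1", "phase2")) {
      w <- phase_window(protocol, ph)
      active <- in_rep_ms >= w[1] & in_rep_ms < w[2]
      if (!any(active)) next
      ax <- col_x[band == (if (ph == "phase1") 0 else 1)]
      d <- vapply(pos[, 1], function(cx) min(abs(cx - ax)), numeric(1))
      amp <- artifact_amplitude * exp(-d / artifact_space_constant)
      carrier <- sin(2 * pi * protocol$carrier_frequency *
                       (in_rep_ms[active] - w[1]) / 1000)
      traces[, active] <- traces[, active] + outer(amp, carrier)
    }
  } else {
    # slow drift ramp resetting every 400 ms, with a reset transient
    ramp <- drift_amplitude * ((t_ms %% reset_interval_ms) / reset_interval_ms)
    traces <- traces + matrix(ramp, nrow = n_ch, ncol = n_samples, byrow = TRUE)
    n_resets <- floor((duration_ms - 1e-6) / reset_interval_ms) + 1L
    reset_starts_ms <- seq(0, by = reset_interval_ms, length.out = n_resets)
    reset_times <- as.integer(round(reset_starts_ms / 1000 * sampling_rate)) + 1L
    reset_len <- max(2L, round(reset_duration_us * 1e-6 * sampling_rate))
    for (r in reset_times) {
      i <- r:min(r + reset_len - 1L, n_samples)
      transient <- reset_amplitude * rep_len(c(1, -1), length(i))
      traces[, i] <- traces[, i] +
        matrix(transient, nrow = n_ch, ncol = length(i), byrow = TRUE)
    }
  }

  structure(list(
    traces = traces,
    sampling_rate = sampling_rate,
    channel_positions = pos,
    reset_times = reset_times,
    reset_duration_us = reset_duration_us,
    modality = protocol$modality
  ), class = "raw_recording")
}

#' Write a raw recording to a flat binary container with JSON header
#'
#' Traces are stored channel-major as little-endian 32-bit floats in
#' `<prefix>.bin`; metadata (sampling rate, channel count and positions,
#' reset times) goes to `<prefix>.json`.
#'
#' @param rec A `raw_recording`.
#' @param prefix File path prefix (without extension).
#' @return `prefix`, invisibly.
#' @export
write_raw_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "raw_recording"))
  header <- list(
    sampling_rate = rec$sampling_rate,
    n_channels = nrow(rec$traces),
    n_samples = ncol(rec$traces),
    channel_positions = unname(as.matrix(rec$channel_positions)),
    reset_times = rec$reset_times,
    reset_duration_us = rec$reset_duration_us,
    modality = rec$modality
  )
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(t(rec$traces)), con, size = 4, endian = "little")
  jsonlite::write_json(header, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a raw recording written by [write_raw_recording()]
#' @param prefix File path prefix (without extension).
#' @return A `raw_recording`.
#' @export
read_raw_recording <- function(prefix) {
  header <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con), add = TRUE)
  v <- readBin(con, what = "numeric", n = header$n_channels * header$n_samples,
               size = 4, endian = "little")
  traces <- t(matrix(v, nrow = header$n_samples, ncol = header$n_channels))
  structure(list(
    traces = traces,
    sampling_rate = header$sampling_rate,
    channel_positions = matrix(unlist(header$channel_positions),
                               ncol = 2, byrow = FALSE,
                               dimnames = list(NULL, c("x", "y"))),
    reset_times = as.integer(header$reset_times),
    reset_duration_us = header$reset_duration_us,
    modality = header$modality
  ), class = "raw_recording")
}
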