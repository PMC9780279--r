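# Stimulus protocol and array geometry descriptions.

#' High-density MEA geometry
#'
#' Describes the recording/stimulation array: a dense grid of recording sites
#' with a coarser grid of capacitive stimulation electrodes inside the same
#' 1 x 1 mm footprint.
#'
#' @param n_recording_rows,n_recording_cols Number of recording-site rows/columns.
#' @param recording_pitch Center-to-center recording site distance, micrometres.
#' @param n_stim_rows,n_stim_cols Number of stimulation electrode rows/columns.
#' @param stim_pitch Center-to-center stimulation electrode distance, micrometres.
#' @return An object of class `geometry_spec`.
#' @export
geometry_spec <- function(n_recording_rows = 65L, n_recording_cols = 65L,
                          recording_pitch = 16,
                          n_stim_rows = 32L, n_stim_cols = 32L,
                          stim_pitch = 32) {
  if (recording_pitch <= 0 || stim_pitch <= 0)
    stop("geometry_spec: pitches must be positive", call. = FALSE)
  extent <- c((n_recording_cols - 1) * recording_pitch,
              (n_recording_rows - 1) * recording_pitch)
  stim_extent <- c((n_stim_cols - 1) * stim_pitch,
                   (n_stim_rows - 1) * stim_pitch)
  if (any(stim_extent > extent))
    stop("geometry_spec: stimulation grid does not fit inside the recording grid",
         call. = FALSE)
  structure(list(
    n_recording_rows = as.integer(n_recording_rows),
    n_recording_cols = as.integer(n_recording_cols),
    recording_pitch = recording_pitch,
    n_stim_rows = as.integer(n_stim_rows),
    n_stim_cols = as.integer(n_stim_cols),
    stim_pitch = stim_pitch,
    array_extent = extent
  ), class = "geometry_spec")
}

#' Grating pattern-reversal stimulation protocol
#'
#' Defines the timing of the two spatial grating phases within one repetition.
#' In the electrical modality each repetition presents four 40 Hz cosine
#' cycles to the "phase 1" electrode columns between 0 and 100 ms and to the
#' complementary "phase 2" columns between 350 and 450 ms, followed by an
#' inter-stimulus gap. In the optogenetic modality the projected grating is
#' reversed every half period of the reversal frequency, so each phase lasts
#' `1000 / (2 * reversal_frequency)` ms with no gap.
#'
#' @param modality `"electrical"` or `"optogenetic"`.
#' @param bar_width Grating bar width, micrometres.
#' @param reversal_frequency Pattern reversal frequency, Hz (optogenetic only;
#'   2.5 or 10 in the experiments this emulates).
#' @param n_repetitions Number of stimulus repetitions (each containing both
#'   phases).
#' @param carrier_frequency Sinusoidal carrier of the electrical stimulus, Hz.
#' @param carrier_amplitude Peak-to-peak carrier amplitude, volts.
#' @param inter_stimulus_gap Gap after the second electrical phase, ms.
#' @param charge_density Stimulation charge density, uC/cm^2 (metadata only).
#' @param grating_orientation Whether grating bars run along `"columns"` or
#'   `"rows"` of the array.
#' @return An object of class `stimulus_protocol` with `phase1_window` and
#'   `phase2_window` (ms, relative to repetition start) and
#'   `repetition_duration` (ms).
#' @export
stimulus_protocol <- function(modality = c("electrical", "optogenetic"),
                              bar_width = 32,
                              reversal_frequency = 2.5,
                              n_repetitions = 60L,
                              carrier_frequency = 40,
                              carrier_amplitude = 2.5,
                              inter_stimulus_gap = 250,
                              charge_density = 15,
                              grating_orientation = c("columns", "rows")) {
  modality <- match.arg(modality)
  grating_orientation <- match.arg(grating_orientation)
  if (bar_width <= 0) stop("stimulus_protocol: bar_width must be positive", call. = FALSE)
  if (n_repetitions < 1) stop("stimulus_protocol: n_repetitions must be >= 1", call. = FALSE)
  if (modality == "electrical") {
    phase1 <- c(0, 100)
    phase2 <- c(350, 450)
    rep_dur <- 450 + inter_stimulus_gap
  } else {
    if (reversal_frequency <= 0)
      stop("stimulus_protocol: reversal_frequency must be positive", call. = FALSE)
    half <- 1000 / (2 * reversal_frequency)
    phase1 <- c(0, half)
    phase2 <- c(half, 2 * half)
    rep_dur <- 2 * half
  }
  if (diff(phase1) <= 0 || diff(phase2) <= 0)
    stop("stimulus_protocol: zero-duration phase window", call. = FALSE)
  structure(list(
    modality = modality,
    bar_width = bar_width,
    reversal_frequency = if (modality == "optogenetic") reversal_frequency else NA_real_,
    phase1_window = phase1,
    phase2_window = phase2,
    repetition_duration = rep_dur,
    inter_stimulus_gap = if (modality == "electrical") inter_stimulus_gap else 0,
    carrier_frequency = if (modality == "electrical") carrier_frequency else NA_real_,
    carrier_amplitude = if (modality == "electrical") carrier_amplitude else NA_real_,
    charge_density = if (modality == "electrical") charge_density else NA_real_,
    n_repetitions = as.integer(n_repetitions),
    grating_orientation = grating_orientation
  ), class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> %s grating, bar width %g um\n", x$modality, x$bar_width))
  cat(sprintf("  phase 1: %g-%g ms, phase 2: %g-%g ms, %d repetitions\n",
              x$phase1_window[1], x$phase1_window[2],
              x$phase2_window[1], x$phase2_window[2], x$n_repetitions))
  invisible(x)
}

phase_window <- function(protocol, phase) {
  if (phase == "phase1") protocol$phase1_window else protocol$phase2_window
}

phase_duration_ms <- function(protocol, phase) {
  diff(phase_window(protocol, phase))
}
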