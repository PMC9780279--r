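# Phase-locked spike train simulation.

#' Simulate spike trains for a unit population under a grating protocol
#'
#' Spike counts per repetition and phase are Poisson with the unit's expected
#' phase rate times the phase-window duration. In the optogenetic modality
#' spike times are uniform within the phase window (homogeneous Poisson). In
#' the electrical modality spikes are locked to the carrier: each spike is
#' assigned to one of the carrier cycles of the active phase window and
#' jittered around a fixed within-cycle latency, reproducing the
#' spiking-per-cycle structure of sinusoidal capacitive stimulation.
#'
#' @param units A `unit_population` from [generate_population()].
#' @param protocol A [stimulus_protocol()].
#' @param seed Integer seed.
#' @param cycle_latency_ms Latency of locked spikes after each carrier cycle
#'   onset (electrical modality), ms.
#' @param cycle_jitter_ms Gaussian jitter SD around the locked latency, ms.
#' @return A data frame of class `spike_train_set` with columns `unit_id`,
#'   `repetition_index`, `phase_label`, `spike_time_ms` (relative to
#'   repetition start), carrying the protocol as attribute `"protocol"`.
#' @export
simulate_spike_trains <- function(units, protocol, seed = 1L,
                                  cycle_latency_ms = 5, cycle_jitter_ms = 1) {
  stopifnot(inherits(units, "unit_population"), inherits(protocol, "stimulus_protocol"))
  if (nrow(units) == 0) stop("simulate_spike_trains: empty unit population", call. = FALSE)
  for (ph in c("phase1", "phase2"))
    if (phase_duration_ms(protocol, ph) <= 0)
      stop("simulate_spike_trains: zero-duration phase window", call. = FALSE)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  n_rep <- protocol$n_repetitions
  grid <- expand.grid(unit = seq_len(nrow(units)),
                      repetition_index = seq_len(n_rep),
                      phase_label = c("phase1", "phase2"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rate <- ifelse(grid$phase_label == "phase1",
                 units$rate_phase1[grid$unit],
                 units$rate_phase2[grid$unit])
  dur_s <- vapply(grid$phase_label, phase_duration_ms, numeric(1),
                  protocol = protocol) / 1000
  counts <- stats::rpois(nrow(grid), rate * dur_s)

  idx <- rep.int(seq_len(nrow(grid)), counts)
  phase <- grid$phase_label[idx]
  w_lo <- ifelse(phase == "phase1", protocol$phase1_window[1], protocol$phase2_window[1])
  w_hi <- ifelse(phase == "phase1", protocol$phase1_window[2], protocol$phase2_window[2])

  if (protocol$modality == "electrical" && length(idx) > 0) {
    cycle_ms <- 1000 / protocol$carrier_frequency
    n_cycles <- max(1L, floor((w_hi[1] - w_lo[1]) / cycle_ms))
    cyc <- sample.int(n_cycles, length(idx), replace = TRUE) - 1L
    t <- w_lo + cyc * cycle_ms + cycle_latency_ms +
      stats::rnorm(length(idx), 0, cycle_jitter_ms)
    t <- pmin(pmax(t, w_lo), w_hi - 1e-6)
  } else {
    t <- stats::runif(length(idx), w_lo, w_hi)
  }

  out <- data.frame(
    unit_id = units$unit_id[grid$unit[idx]],
    repetition_index = grid$repetition_index[idx],
    phase_label = phase,
    spike_time_ms = t,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$unit_id, out$repetition_index, out$phase_label, out$spike_time_ms), ]
  rownames(out) <- NULL
  attr(out, "protocol") <- protocol
  attr(out, "unit_ids") <- units$unit_id
  class(out) <- c("spike_train_set", class(out))
  out
}
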