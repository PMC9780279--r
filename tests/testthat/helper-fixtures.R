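# Shared fixture builders: everything is generated in code at test time.

empty_spike_set <- function() {
  df <- data.frame(unit_id = character(), repetition_index = integer(),
                   phase_label = character(), spike_time_ms = numeric(),
                   stringsAsFactors = FALSE)
  class(df) <- c("spike_train_set", class(df))
  df
}

# hand-built unit population with prescribed true RFR values
make_units <- function(true_rfr, base_rate = 8, x = NULL, y = NULL,
                       isoibg = 0.5, separability = 3, snr = 8) {
  n <- length(true_rfr)
  out <- data.frame(
    unit_id = sprintf("u%03d", seq_len(n)),
    x = if (is.null(x)) seq(100, 900, length.out = n) else x,
    y = if (is.null(y)) rep(500, n) else y,
    true_rfr = true_rfr,
    rate_phase1 = base_rate * (1 + true_rfr),
    rate_phase2 = base_rate * (1 - true_rfr),
    isoibg = rep_len(isoibg, n),
    separability = rep_len(separability, n),
    snr = rep_len(snr, n),
    stringsAsFactors = FALSE
  )
  out$axon_path <- replicate(n, cbind(x = c(0, 0), y = c(0, 0)), simplify = FALSE)
  class(out) <- c("unit_population", class(out))
  out
}

# zero-selectivity decoding dataset: equal Poisson rates in both phases
chance_dataset <- function(n_units = 40, n_rep = 60, rate = 8, seed = 1) {
  units <- make_units(rep(0, n_units), base_rate = rate)
  prot <- stimulus_protocol("optogenetic", bar_width = 30, n_repetitions = n_rep)
  spk <- simulate_spike_trains(units, prot, seed = seed)
  build_rate_matrix(spk, prot, unit_ids = units$unit_id)
}

# mean f1 of the decoder on a population with selectivity magnitude r
decode_f1_at_r <- function(r, n_units = 40, n_rep = 60, seed = 1,
                           weights = c(0, 0.5, 0.5)) {
  spec <- population_spec(n_units = n_units, mixture_weights = weights,
                          selectivity = r, seed = seed)
  units <- generate_population(spec)
  prot <- stimulus_protocol("optogenetic", bar_width = 30, n_repetitions = n_rep)
  spk <- simulate_spike_trains(units, prot, seed = seed + 1)
  frm <- build_rate_matrix(spk, prot, unit_ids = units$unit_id)
  cross_validated_decode(frm, seed = seed + 2)$f1_mean
}
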