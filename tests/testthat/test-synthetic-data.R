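# Ground-truth population generation and spike-train simulation.

test_that("phase rates invert the RFR definition at the stated base rate", {
  units0 <- generate_population(
    population_spec(n_units = 20, mixture_weights = c(1, 0, 0), seed = 1))
  expect_equal(units0$rate_phase1, units0$rate_phase2)

  units1 <- generate_population(
    population_spec(n_units = 20, mixture_weights = c(0, 1, 0),
                    selectivity = 1, seed = 1))
  expect_true(all(units1$rate_phase2 == 0))
  expect_true(all(units1$rate_phase1 == 2 * 8))

  # general consistency: (FR1 - FR2)/(FR1 + FR2) == true_rfr
  units <- generate_population(population_spec(n_units = 50, seed = 3))
  expect_equal((units$rate_phase1 - units$rate_phase2) /
                 (units$rate_phase1 + units$rate_phase2),
               units$true_rfr)
  expect_true(all(units$rate_phase1 >= 0 & units$rate_phase2 >= 0))
})

test_that("population generation is deterministic and respects the array extent", {
  spec <- population_spec(n_units = 50, seed = 7)
  geom <- geometry_spec()
  a <- generate_population(spec, geom)
  b <- generate_population(spec, geom)
  expect_identical(a, b)
  expect_true(all(a$x >= 0 & a$x <= geom$array_extent[1]))
  expect_true(all(a$y >= 0 & a$y <= geom$array_extent[2]))
})

test_that("invalid mixture weights are a configuration error", {
  expect_error(population_spec(mixture_weights = c(0.5, 0.5, 0.5)), "summing to 1")
  expect_error(population_spec(selectivity = 1.5), "selectivity")
})

test_that("degenerate rates produce the expected spike trains", {
  prot <- stimulus_protocol("optogenetic", bar_width = 30, n_repetitions = 1000)
  # (40 Hz, 0 Hz): every spike in phase 1, empirical RFR exactly 1
  u <- make_units(1, base_rate = 20)  # rates (40, 0)
  spk <- simulate_spike_trains(u, prot, seed = 2)
  expect_true(all(spk$phase_label == "phase1"))
  rfr <- compute_rfr(build_rate_matrix(spk, prot, unit_ids = u$unit_id))
  expect_equal(rfr$rfr, 1)

  # all-zero rates: no spikes at all
  u0 <- make_units(0, base_rate = 0)
  spk0 <- simulate_spike_trains(u0, prot, seed = 2)
  expect_equal(nrow(spk0), 0)
})

test_that("empirical RFR converges to true RFR across the selectivity grid", {
  # Poisson counts with rates r1 = b(1+rfr), r2 = b(1-rfr); the mean-rate
  # estimator converges to true_rfr. SE bound from the delta method at b = 8,
  # 2000 repetitions, 200 ms windows.
  grid <- c(-1, -0.5, 0, 0.5, 1)
  u <- make_units(grid, base_rate = 8)
  prot <- stimulus_protocol("optogenetic", bar_width = 30, n_repetitions = 2000)
  spk <- simulate_spike_trains(u, prot, seed = 4)
  rfr <- compute_rfr(build_rate_matrix(spk, prot, unit_ids = u$unit_id))
  # per-phase expected counts per repetition: lambda_k = rate_k * 0.2 s
  l1 <- u$rate_phase1 * 0.2; l2 <- u$rate_phase2 * 0.2
  se <- sqrt((4 * (l2^2 * l1 + l1^2 * l2)) / ((l1 + l2)^4) / 2000)
  se[l1 + l2 == 0] <- 0
  expect_true(all(abs(rfr$rfr - grid) <= pmax(3 * se, 1e-12)))
})

test_that("spike counts are independent across repetitions (lag-1 check)", {
  units <- make_units(rep(0, 40), base_rate = 10)
  prot <- stimulus_protocol("optogenetic", bar_width = 30, n_repetitions = 200)
  spk <- simulate_spike_trains(units, prot, seed = 6)
  frm <- build_rate_matrix(spk, prot, unit_ids = units$unit_id)
  counts <- frm$values[frm$phase_labels == "phase1", ]
  z <- apply(counts, 2, function(x) {
    r <- stats::cor(x[-1], x[-length(x)])
    r * sqrt(length(x) - 1)
  })
  # under independence z ~ N(0,1); at alpha = 0.01 expect ~0.4 rejections in 40
  expect_lt(mean(abs(z) > stats::qnorm(0.995)), 0.15)
})

test_that("electrical spikes are locked to carrier cycles of the active phase", {
  u <- make_units(0.5, base_rate = 30)
  prot <- stimulus_protocol("electrical", bar_width = 32, n_repetitions = 200)
  spk <- simulate_spike_trains(u, prot, seed = 8)
  p1 <- spk[spk$phase_label == "phase1", ]
  expect_true(all(p1$spike_time_ms >= 0 & p1$spike_time_ms < 100))
  # within-cycle times concentrate near the 5 ms locking latency
  within_cycle <- p1$spike_time_ms %% 25
  expect_gt(mean(within_cycle > 2 & within_cycle < 8), 0.95)
  p2 <- spk[spk$phase_label == "phase2", ]
  expect_true(all(p2$spike_time_ms >= 350 & p2$spike_time_ms < 450))
})

test_that("spike-train simulation rejects bad configuration", {
  u <- make_units(0)
  expect_error(simulate_spike_trains(u[0, ], stimulus_protocol("electrical")),
               "empty")
})

test_that("raw synthesis is additive and counts resets at 400 ms spacing", {
  geom <- geometry_spec()
  prot <- stimulus_protocol("optogenetic", bar_width = 30, n_repetitions = 5) # 2 s
  u <- make_units(0.5, base_rate = 10)
  spk <- simulate_spike_trains(u, prot, seed = 1)
  rec_sa <- synthesize_raw_recording(spk, u, prot, geom, noise_sd = 1e-6, seed = 11)
  rec_a <- synthesize_raw_recording(empty_spike_set(), NULL, prot, geom,
                                    noise_sd = 1e-6, seed = 11)
  rec_s <- synthesize_raw_recording(spk, u, prot, geom, noise_sd = 1e-6, seed = 11,
                                    drift_amplitude = 0, reset_amplitude = 0)
  rec_0 <- synthesize_raw_recording(empty_spike_set(), NULL, prot, geom,
                                    noise_sd = 1e-6, seed = 11,
                                    drift_amplitude = 0, reset_amplitude = 0)
  expect_equal(rec_sa$traces - rec_a$traces, rec_s$traces - rec_0$traces,
               tolerance = 1e-12)
  expect_length(rec_a$reset_times, 5)
  expect_equal(diff(rec_a$reset_times),
               rep(0.4 * rec_a$sampling_rate, 4))
})

test_that("a pure electrical artifact lives only inside phase windows", {
  prot <- stimulus_protocol("electrical", bar_width = 32, n_repetitions = 2)
  rec <- synthesize_raw_recording(empty_spike_set(), NULL, prot,
                                  noise_sd = 0, seed = 1)
  t_ms <- (seq_len(ncol(rec$traces)) - 1) / rec$sampling_rate * 1000
  in_rep <- t_ms %% prot$repetition_duration
  outside <- in_rep >= 100 & in_rep < 350 | in_rep >= 450
  expect_true(all(rec$traces[, outside] == 0))
  inside <- in_rep >= 10 & in_rep < 90
  expect_gt(max(abs(rec$traces[, inside])), 0)
})

test_that("a single spike's filtered peak lands at the spike time", {
  geom <- geometry_spec()
  prot <- stimulus_protocol("optogenetic", bar_width = 30, n_repetitions = 3)
  u <- make_units(0, base_rate = 0, x = 0, y = 0)  # on top of channel 1
  spk <- data.frame(unit_id = u$unit_id, repetition_index = 2L,
                    phase_label = "phase1", spike_time_ms = 50,
                    stringsAsFactors = FALSE)
  class(spk) <- c("spike_train_set", class(spk))
  rec <- synthesize_raw_recording(spk, u, prot, geom, noise_sd = 0, seed = 1,
                                  drift_amplitude = 0, reset_amplitude = 0)
  # brute-force argmax of the (band-filtered) trace vs the known spike sample
  f <- filter_optogenetic_chain(rec)
  s_spike <- round(450 / 1000 * rec$sampling_rate) + 1
  peak <- which.max(abs(f$traces[1, ]))
  # template trough is ~a third of the way into the 1.2 ms waveform
  trough_offset <- which.max(abs(-sin(2 * pi * seq(0, 1.2e-3, by = 1 / rec$sampling_rate) / 1.2e-3) *
                                   exp(-seq(0, 1.2e-3, by = 1 / rec$sampling_rate) / 4e-4))) - 1
  expect_lte(abs(peak - (s_spike + trough_offset)), 1)
})

test_that("too-low sampling rate for the sensor reset is rejected", {
  prot <- stimulus_protocol("optogenetic", bar_width = 30, n_repetitions = 1)
  expect_error(synthesize_raw_recording(empty_spike_set(), NULL, prot,
                                        sampling_rate = 5000),
               "200 us reset")
})

test_that("fixture bundles round-trip bit-exactly and are seed-stable", {
  spec <- population_spec(n_units = 5, seed = 3)
  prot <- stimulus_protocol("electrical", bar_width = 32, n_repetitions = 4)
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  make_fixture_bundle(d1, spec, prot)
  make_fixture_bundle(d2, spec, prot)
  b1 <- read_fixture_bundle(d1)
  units <- generate_population(spec)
  spk <- simulate_spike_trains(units, prot, seed = spec$seed)
  expect_identical(b1$spike_trains$spike_time_ms, spk$spike_time_ms)
  expect_identical(b1$spike_trains$unit_id, spk$unit_id)
  # same seed, byte-identical manifests
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("an empty bundle is valid and flagged in the manifest", {
  spec <- population_spec(n_units = 0, seed = 1)
  prot <- stimulus_protocol("optogenetic", bar_width = 30, n_repetitions = 2)
  d <- file.path(tempdir(), "bundle0")
  make_fixture_bundle(d, spec, prot)
  b <- read_fixture_bundle(d)
  expect_true(b$manifest$empty)
  expect_equal(nrow(b$spike_trains), 0)
  unlink(d, recursive = TRUE)
})

test_that("raw recordings round-trip through the binary container", {
  prot <- stimulus_protocol("optogenetic", bar_width = 30, n_repetitions = 2)
  rec <- synthesize_raw_recording(empty_spike_set(), NULL, prot,
                                  noise_sd = 1e-5, seed = 2)
  prefix <- tempfile()
  write_raw_recording(rec, prefix)
  back <- read_raw_recording(prefix)
  expect_equal(dim(back$traces), dim(rec$traces))
  expect_equal(back$traces, rec$traces, tolerance = 1e-6)  # float32 storage
  expect_identical(back$reset_times, rec$reset_times)
  expect_equal(back$sampling_rate, rec$sampling_rate)
})
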