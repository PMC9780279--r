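# Filter design and the modality-specific preprocessing chains.
#
# Analog prototypes are realized as digital IIR filters via the bilinear
# transform with frequency pre-warping and applied forward-backward
# (zero-phase), so spike timing relative to the stimulus phase windows is
# never shifted. The stated filter orders refer to the designed filter; the
# forward-backward pass squares its magnitude response.

#' Bessel analog lowpass prototype
#'
#' Poles of the reverse Bessel polynomial, scaled so the magnitude response
#' is -3 dB at angular frequency 1.
#'
#' @param order Filter order (>= 1).
#' @return List with `pole` (complex vector) and `gain`.
#' @keywords internal
bessel_prototype <- function(order) {
  stopifnot(order >= 1)
  n <- order
  k <- 0:n
  a <- factorial(2 * n - k) / (2^(n - k) * factorial(k) * factorial(n - k))
  poles <- polyroot(a)
  gain <- a[1]
  mag2 <- function(w) Mod(gain / sum(a * (1i * w)^k))^2
  w3 <- stats::uniroot(function(w) mag2(w) - 0.5, c(1e-3, 10), tol = 1e-12)$root
  list(pole = poles / w3, gain = gain / w3^n)
}

#' Design a digital Bessel filter
#'
#' @param order Filter order.
#' @param cutoff -3 dB cutoff frequency, Hz.
#' @param fs Sampling rate, Hz.
#' @param type `"low"` or `"high"`.
#' @return A `signal::Arma` filter.
#' @export
design_bessel <- function(order, cutoff, fs, type = c("low", "high")) {
  type <- match.arg(type)
  check_nyquist(cutoff, fs)
  TT <- 2
  Ww <- 2 / TT * tan(pi * (cutoff / (fs / 2)) / TT)
  proto <- bessel_prototype(order)
  zpg <- signal::Zpg(zero = numeric(0), pole = proto$pole, gain = proto$gain)
  zpg <- signal::sftrans(zpg, W = Ww, stop = (type == "high"))
  signal::as.Arma(signal::bilinear(zpg, T = TT))
}

#' Design a digital Butterworth filter
#'
#' @inheritParams design_bessel
#' @return A `signal::Arma` filter.
#' @export
design_butterworth <- function(order, cutoff, fs, type = c("low", "high")) {
  type <- match.arg(type)
  check_nyquist(cutoff, fs)
  signal::butter(order, cutoff / (fs / 2), type = type)
}

check_nyquist <- function(cutoff, fs) {
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop(sprintf("cutoff %g Hz violates the Nyquist limit at fs = %g Hz", cutoff, fs),
         call. = FALSE)
  invisible(TRUE)
}

#' Magnitude response of a designed filter
#'
#' Single-pass magnitude at the requested frequencies; square it for the
#' zero-phase (forward-backward) application the chains use.
#'
#' @param flt A `signal::Arma` filter.
#' @param f Frequencies, Hz.
#' @param fs Sampling rate, Hz.
#' @return Magnitude (linear) at each frequency.
#' @export
filter_magnitude <- function(flt, f, fs) {
  w <- 2 * pi * f / fs
  num <- vapply(w, function(wi) Mod(sum(flt$b * exp(-1i * wi * (seq_along(flt$b) - 1)))), numeric(1))
  den <- vapply(w, function(wi) Mod(sum(flt$a * exp(-1i * wi * (seq_along(flt$a) - 1)))), numeric(1))
  num / den
}

apply_zero_phase <- function(traces, flt) {
  out <- traces
  for (ch in seq_len(nrow(traces)))
    out[ch, ] <- signal::filtfilt(flt, traces[ch, ])
  out
}

filtered_recording <- function(rec, traces, provenance, reset_samples_replaced = FALSE) {
  structure(list(
    traces = traces,
    sampling_rate = rec$sampling_rate,
    channel_positions = rec$channel_positions,
    reset_times = rec$reset_times,
    reset_duration_us = rec$reset_duration_us,
    modality = rec$modality,
    provenance = provenance,
    reset_samples_replaced = reset_samples_replaced
  ), class = c("filtered_recording", "raw_recording"))
}

#' Optogenetic band filter chain
#'
#' Second-order highpass Bessel at 200 Hz followed by a second-order lowpass
#' Bessel at 5 kHz, both zero-phase. Run [remove_sensor_reset_artifacts()]
#' first; this band filtering is the last preprocessing step.
#'
#' @param rec A `raw_recording`.
#' @return A `filtered_recording` (same shape, provenance recorded).
#' @export
filter_optogenetic_chain <- function(rec) {
  if (rec$sampling_rate <= 10000)
    stop("filter_optogenetic_chain: sampling_rate must exceed 10 kHz", call. = FALSE)
  hp <- design_bessel(2, 200, rec$sampling_rate, "high")
  lp <- design_bessel(2, 5000, rec$sampling_rate, "low")
  out <- apply_zero_phase(apply_zero_phase(rec$traces, hp), lp)
  prov <- c(rec$provenance,
            list(list(family = "bessel", order = 2, kind = "highpass", cutoff = 200),
                 list(family = "bessel", order = 2, kind = "lowpass", cutoff = 5000)))
  filtered_recording(rec, out, prov, isTRUE(rec$reset_samples_replaced))
}

#' Electrical band filter chain
#'
#' Fourth-order highpass Butterworth at 1 kHz followed by a second-order
#' lowpass Bessel at 3 kHz, both zero-phase. Suppresses the 40 Hz carrier
#' artifact far below the spike band while retaining 1-3 kHz spike content.
#'
#' @param rec A `raw_recording`.
#' @return A `filtered_recording`.
#' @export
filter_electrical_chain <- function(rec) {
  if (rec$sampling_rate <= 6000)
    stop("filter_electrical_chain: sampling_rate must exceed 6 kHz", call. = FALSE)
  hp <- design_butterworth(4, 1000, rec$sampling_rate, "high")
  lp <- design_bessel(2, 3000, rec$sampling_rate, "low")
  out <- apply_zero_phase(apply_zero_phase(rec$traces, hp), lp)
  prov <- c(rec$provenance,
            list(list(family = "butterworth", order = 4, kind = "highpass", cutoff = 1000),
                 list(family = "bessel", order = 2, kind = "lowpass", cutoff = 3000)))
  filtered_recording(rec, out, prov, isTRUE(rec$reset_samples_replaced))
}

#' Remove sensor-reset and drift artifacts from an optogenetic recording
#'
#' Per channel: the trace is split at the recorded reset times; within each
#' inter-reset segment a drift curve (second-order Savitzky-Golay smoother,
#' 800 us window rounded to the nearest odd sample count) is subtracted; the
#' drift-subtracted trace is highpass filtered (second-order Butterworth,
#' 100 Hz, zero-phase); finally the samples inside each 200 us reset window
#' are replaced by noise resampled (with replacement, seeded) from the 50 ms
#' stretch of the same channel with the lowest variance - a quiescent stretch
#' of the same recorded data.
#'
#' @param rec A `raw_recording` with `reset_times`.
#' @param seed Seed for the noise resampling.
#' @return A `raw_recording` (class `filtered_recording`) with
#'   `reset_samples_replaced = TRUE` when resets were present.
#' @export
remove_sensor_reset_artifacts <- function(rec, seed = 1L) {
  fs <- rec$sampling_rate
  n <- ncol(rec$traces)
  sg_n <- round(800e-6 * fs)
  if (sg_n %% 2 == 0) sg_n <- sg_n + 1L
  reset_len <- max(2L, round(rec$reset_duration_us * 1e-6 * fs))
  resets <- sort(rec$reset_times)
  if (is.unsorted(rec$reset_times))
    stop("remove_sensor_reset_artifacts: reset_times must be sorted", call. = FALSE)

  # inter-reset segment boundaries (sample ranges excluding reset windows)
  bounds <- if (length(resets) == 0) {
    list(c(1L, n))
  } else {
    starts <- c(if (resets[1] > 1) 1L, resets + reset_len)
    ends <- c(resets - 1L, if (resets[length(resets)] + reset_len <= n) n)
    if (resets[1] == 1) ends <- ends[-1]
    Map(c, starts, ends)
  }
  bounds <- Filter(function(b) b[2] >= b[1], bounds)

  hp <- design_butterworth(2, 100, fs, "high")
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  out <- rec$traces
  for (ch in seq_len(nrow(out))) {
    x <- out[ch, ]
    for (b in bounds) {
      seg <- x[b[1]:b[2]]
      if (length(seg) <= sg_n) {
        warning(sprintf("segment of %d samples shorter than the %d-sample smoother window; drift step skipped",
                        length(seg), sg_n), call. = FALSE)
        next
      }
      drift <- signal::sgolayfilt(seg, p = 2, n = sg_n)
      x[b[1]:b[2]] <- seg - drift
    }
    x <- signal::filtfilt(hp, x)
    if (length(resets) > 0) {
      # quietest 50 ms stretch of this channel as the noise donor
      win <- max(2L, min(round(0.05 * fs), length(x)))
      n_win <- floor(length(x) / win)
      vars <- vapply(seq_len(n_win), function(k)
        stats::var(x[((k - 1) * win + 1):(k * win)]), numeric(1))
      k0 <- which.min(vars)
      donor <- x[((k0 - 1) * win + 1):(k0 * win)]
      for (r in resets) {
        i <- r:min(r + reset_len - 1L, n)
        x[i] <- donor[sample.int(length(donor), length(i), replace = TRUE)]
      }
    }
    out[ch, ] <- x
  }
  prov <- c(rec$provenance,
            list(list(family = "savitzky_golay", order = 2, kind = "smoother",
                      window_us = 800),
                 list(family = "butterworth", order = 2, kind = "highpass",
                      cutoff = 100)))
  filtered_recording(rec, out, prov, reset_samples_replaced = length(resets) > 0)
}

#' Full preprocessing for one modality
#'
#' Optogenetic: sensor-reset/drift removal, then the 200 Hz - 5 kHz Bessel
#' band chain. Electrical: the 1 kHz - 3 kHz Butterworth/Bessel chain.
#'
#' @param rec A `raw_recording`.
#' @param modality Overrides `rec$modality` if given.
#' @param seed Seed for reset-noise resampling.
#' @return A `filtered_recording`.
#' @export
preprocess_recording <- function(rec, modality = rec$modality, seed = 1L) {
  if (identical(modality, "optogenetic"))
    filter_optogenetic_chain(remove_sensor_reset_artifacts(rec, seed = seed))
  else
    filter_electrical_chain(rec)
}
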