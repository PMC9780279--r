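# Unit curation, per-phase firing-rate matrix, and the RFR selectivity index.

#' Curate sorted units by spike-sorting quality metrics
#'
#' Keeps units with a numerical (non-missing) IsoIBG, separability at or
#' above the threshold, and - in the electrical modality only - SNR inside
#' the accepted range. All boundaries are inclusive. Counts removed per
#' criterion are attached as attribute `"curation_log"` and reported via
#' `message()`.
#'
#' @param units A data frame with columns `isoibg`, `separability`, `snr`
#'   (e.g. a `unit_population`).
#' @param modality `"electrical"` or `"optogenetic"`; the SNR range is only
#'   enforced for electrical recordings.
#' @param separability_min Minimum separability (default 2.5).
#' @param snr_range Accepted SNR range (default `c(3.3, 14)`).
#' @return The surviving subset, original order preserved. An empty survivor
#'   set is returned with a warning, not an error.
#' @export
curate_units <- function(units, modality = c("electrical", "optogenetic"),
                         separability_min = 2.5, snr_range = c(3.3, 14)) {
  modality <- match.arg(modality)
  iso_ok <- !is.na(units$isoibg) & is.finite(units$isoibg)
  sep_ok <- !is.na(units$separability) & units$separability >= separability_min
  snr_ok <- if (modality == "electrical")
    !is.na(units$snr) & units$snr >= snr_range[1] & units$snr <= snr_range[2]
  else rep(TRUE, nrow(units))
  keep <- iso_ok & sep_ok & snr_ok
  log <- c(removed_isoibg = sum(!iso_ok),
           removed_separability = sum(iso_ok & !sep_ok),
           removed_snr = sum(iso_ok & sep_ok & !snr_ok),
           kept = sum(keep))
  message(sprintf("curate_units: kept %d of %d units (isoibg: -%d, separability: -%d, snr: -%d)",
                  log[["kept"]], nrow(units), log[["removed_isoibg"]],
                  log[["removed_separability"]], log[["removed_snr"]]))
  if (!any(keep)) warning("curate_units: no units survive curation", call. = FALSE)
  out <- units[keep, , drop = FALSE]
  attr(out, "curation_log") <- log
  out
}

#' Build the repetitions-by-units firing-rate matrix
#'
#' One row per (repetition, phase): the entry for unit u is its spike count
#' inside that repetition's phase window divided by the window duration
#' (Hz). Spikes in inter-stimulus intervals are excluded by construction.
#' Units with no spikes keep an all-zero column.
#'
#' @param spikes A `spike_train_set` (columns `unit_id`, `repetition_index`,
#'   `phase_label`, `spike_time_ms`).
#' @param protocol The [stimulus_protocol()] defining the phase windows.
#' @param unit_ids Column order; defaults to the spike-train attribute or the
#'   sorted unique unit ids present.
#' @return An object of class `firing_rate_matrix`: list with `values`
#'   (rows = repetition-phase, cols = units, Hz), `phase_labels`,
#'   `repetition_index`, `unit_ids`.
#' @export
build_rate_matrix <- function(spikes, protocol, unit_ids = NULL) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (is.null(unit_ids)) unit_ids <- attr(spikes, "unit_ids")
  if (is.null(unit_ids)) unit_ids <- sort(unique(spikes$unit_id))
  bad <- !spikes$phase_label %in% c("phase1", "phase2")
  if (any(bad))
    stop("build_rate_matrix: repetition rows with undefined phase label", call. = FALSE)

  reps <- seq_len(protocol$n_repetitions)
  rows <- expand.grid(repetition_index = reps,
                      phase_label = c("phase1", "phase2"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  values <- matrix(0, nrow = nrow(rows), ncol = length(unit_ids),
                   dimnames = list(NULL, unit_ids))
  # keep only spikes inside their labelled phase window
  w_lo <- ifelse(spikes$phase_label == "phase1",
                 protocol$phase1_window[1], protocol$phase2_window[1])
  w_hi <- ifelse(spikes$phase_label == "phase1",
                 protocol$phase1_window[2], protocol$phase2_window[2])
  inwin <- spikes$spike_time_ms >= w_lo & spikes$spike_time_ms < w_hi
  sp <- spikes[inwin, , drop = FALSE]
  if (nrow(sp) > 0) {
    ri <- match(paste(sp$repetition_index, sp$phase_label),
                paste(rows$repetition_index, rows$phase_label))
    ci <- match(sp$unit_id, unit_ids)
    keep <- !is.na(ri) & !is.na(ci)
    tab <- table(factor(ri[keep], levels = seq_len(nrow(rows))),
                 factor(ci[keep], levels = seq_along(unit_ids)))
    values <- values + matrix(as.numeric(tab), nrow = nrow(rows),
                              ncol = length(unit_ids))
  }
  dur_s <- vapply(rows$phase_label, phase_duration_ms, numeric(1),
                  protocol = protocol) / 1000
  values <- values / dur_s

  structure(list(values = values,
                 phase_labels = rows$phase_label,
                 repetition_index = rows$repetition_index,
                 unit_ids = unit_ids),
            class = "firing_rate_matrix")
}

#' Relative firing rate (RFR) per unit
#'
#' For each unit, mean firing rate per phase across repetitions and the
#' selectivity index RFR = (FR1 - FR2) / (FR1 + FR2), bounded in `[-1, 1]`.
#' When both phase means are zero the ratio is undefined; it is reported as 0
#' with `undefined = TRUE` so downstream matrices stay dense.
#'
#' @param frm A `firing_rate_matrix`.
#' @return Data frame with `unit_id`, `fr_phase1`, `fr_phase2`, `rfr`,
#'   `undefined`.
#' @export
compute_rfr <- function(frm) {
  stopifnot(inherits(frm, "firing_rate_matrix"))
  if (length(frm$unit_ids) == 0) stop("compute_rfr: empty rate matrix", call. = FALSE)
  p1 <- frm$phase_labels == "phase1"
  fr1 <- colMeans(frm$values[p1, , drop = FALSE])
  fr2 <- colMeans(frm$values[!p1, , drop = FALSE])
  denom <- fr1 + fr2
  undefined <- denom == 0
  rfr <- ifelse(undefined, 0, (fr1 - fr2) / ifelse(undefined, 1, denom))
  data.frame(unit_id = frm$unit_ids,
             fr_phase1 = unname(fr1), fr_phase2 = unname(fr2),
             rfr = unname(rfr), undefined = unname(undefined),
             stringsAsFactors = FALSE)
}
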