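# Ground-truth RGC population generation.

#' Specification of a synthetic RGC population
#'
#' True phase selectivity (RFR) is drawn from a three-component mixture: a
#' point mass at 0 (unmodulated cells) and symmetric point masses at +r and
#' -r (cells preferring phase 1 or phase 2). This reproduces the
#' non-unimodal, roughly symmetric RFR distributions seen in grating-reversal
#' recordings without asserting unpublished parameters.
#'
#' Per-phase expected firing rates follow from the RFR definition
#' RFR = (FR1 - FR2) / (FR1 + FR2) inverted at a fixed mean rate:
#' FR1 = base_rate * (1 + RFR), FR2 = base_rate * (1 - RFR).
#'
#' @param n_units Number of units.
#' @param mixture_weights Weights of the (0, +r, -r) mixture components; must
#'   sum to 1.
#' @param selectivity Selectivity magnitude r in `[0, 1]`.
#' @param base_rate Mean per-phase firing rate, Hz.
#' @param qc_separability_range,qc_isoibg_range Ranges the spike-sorting QC
#'   metrics are drawn from (sorting itself is upstream of this package, so
#'   its quality metrics are simulated metadata).
#' @param qc_snr_range Range the per-unit SNR metadata is drawn from when no
#'   raw traces are synthesized (with raw traces SNR follows template
#'   amplitude / noise SD).
#' @param isoibg_missing_fraction Fraction of units whose IsoIBG is NaN
#'   (single-cluster units, which curation removes).
#' @param seed Integer seed; the generator is fully reproducible.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_units = 50L,
                            mixture_weights = c(0.4, 0.3, 0.3),
                            selectivity = 0.8,
                            base_rate = 8,
                            qc_separability_range = c(2.5, 6),
                            qc_isoibg_range = c(0.1, 1),
                            qc_snr_range = c(3.3, 14),
                            isoibg_missing_fraction = 0,
                            seed = 1L) {
  if (n_units < 0) stop("population_spec: n_units must be >= 0", call. = FALSE)
  if (length(mixture_weights) != 3 || any(mixture_weights < 0) ||
      abs(sum(mixture_weights) - 1) > 1e-8)
    stop("population_spec: mixture_weights must be 3 non-negative values summing to 1",
         call. = FALSE)
  if (selectivity < 0 || selectivity > 1)
    stop("population_spec: selectivity must lie in [0, 1]", call. = FALSE)
  if (base_rate < 0) stop("population_spec: base_rate must be >= 0", call. = FALSE)
  structure(list(
    n_units = as.integer(n_units),
    mixture_weights = mixture_weights,
    selectivity = selectivity,
    base_rate = base_rate,
    qc_separability_range = qc_separability_range,
    qc_isoibg_range = qc_isoibg_range,
    qc_snr_range = qc_snr_range,
    isoibg_missing_fraction = isoibg_missing_fraction,
    seed = as.integer(seed)
  ), class = "population_spec")
}

#' Generate a ground-truth RGC population
#'
#' Places units uniformly on the array, draws each unit's true RFR from the
#' mixture in `spec`, derives the per-phase expected rates by inverting the
#' RFR definition at `spec$base_rate`, assigns simulated sorting-QC metadata,
#' and attaches a straight axon polyline running to the nearest array edge
#' (axons never contribute spikes: selectivity is somatic by construction).
#'
#' @param spec A [population_spec()].
#' @param geometry A [geometry_spec()].
#' @return A data frame of class `unit_population` with one row per unit:
#'   `unit_id`, `x`, `y` (um), `true_rfr`, `rate_phase1`, `rate_phase2` (Hz),
#'   `isoibg`, `separability`, `snr`, and a list column `axon_path`.
#' @export
generate_population <- function(spec, geometry = geometry_spec()) {
  stopifnot(inherits(spec, "population_spec"), inherits(geometry, "geometry_spec"))
  n <- spec$n_units
  rng <- local_rng(spec$seed)
  on.exit(rng(), add = TRUE)

  comp <- sample.int(3L, n, replace = TRUE, prob = spec$mixture_weights)
  true_rfr <- c(0, spec$selectivity, -spec$selectivity)[comp]
  x <- stats::runif(n, 0, geometry$array_extent[1])
  y <- stats::runif(n, 0, geometry$array_extent[2])

  rate1 <- spec$base_rate * (1 + true_rfr)
  rate2 <- spec$base_rate * (1 - true_rfr)

  isoibg <- stats::runif(n, spec$qc_isoibg_range[1], spec$qc_isoibg_range[2])
  if (spec$isoibg_missing_fraction > 0) {
    n_miss <- round(spec$isoibg_missing_fraction * n)
    if (n_miss > 0) isoibg[sample.int(n, n_miss)] <- NA_real_
  }
  separability <- stats::runif(n, spec$qc_separability_range[1], spec$qc_separability_range[2])
  snr <- stats::runif(n, spec$qc_snr_range[1], spec$qc_snr_range[2])

  # straight axon polyline toward the nearest vertical edge
  edge_x <- ifelse(x < geometry$array_extent[1] / 2, 0, geometry$array_extent[1])
  axon_path <- lapply(seq_len(n), function(i) {
    cbind(x = c(x[i], edge_x[i]), y = c(y[i], y[i]))
  })

  out <- data.frame(
    unit_id = sprintf("u%03d", seq_len(n)),
    x = x, y = y,
    true_rfr = true_rfr,
    rate_phase1 = rate1,
    rate_phase2 = rate2,
    isoibg = isoibg,
    separability = separability,
    snr = snr,
    stringsAsFactors = FALSE
  )
  out$axon_path <- axon_path
  class(out) <- c("unit_population", class(out))
  out
}

# Run code under a private RNG state restored on exit; returns the restore fn.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
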