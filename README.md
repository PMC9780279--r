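# retinacuity

Inferring the spatial resolution of artificial retinal stimulation from the
spiking of retinal ganglion cell (RGC) populations.

## Scientific problem

Retinal prostheses (electrical microstimulation) and optogenetic therapies
aim to restore vision by driving RGCs directly, bypassing lost
photoreceptors. A central question for either approach is its *effective
spatial resolution*: how fine a stimulation pattern can the retina still
transmit as a distinguishable population response?

A standard assay presents a reversing grating — alternating bright/dark (or
stimulated/unstimulated) bars that swap every half cycle — at a series of bar
widths, records the RGC population on a multielectrode array, and asks
whether a decoder can tell the two grating phases apart from the population
firing rates. As bars shrink below the resolution limit, both phases
activate every cell equally and decoding falls to chance. The smallest bar
width that still supports reliable decoding, converted to cycles per degree
(cpd) of visual angle, is an estimate of the restored acuity.

This package implements that entire analysis chain, together with a
ground-truth synthetic data generator so that every stage can be validated
against known answers:

1. **Synthetic data** — RGC populations with controlled phase selectivity,
   Poisson spike trains (carrier-locked for electrical stimulation), and raw
   multichannel traces with realistic stimulation artifacts.
2. **Signal processing** — modality-specific zero-phase filter chains
   (Bessel 200 Hz–5 kHz for optogenetic recordings; 4th-order Butterworth
   1 kHz highpass + Bessel 3 kHz lowpass for electrical recordings, which
   suppresses the 40 Hz stimulation carrier) and removal of sensor-reset
   transients and slow drift via per-segment Savitzky–Golay subtraction.
3. **Unit analysis** — spike-sorting quality curation, firing-rate matrices
   (one rate per unit × repetition × phase window), the response-phase ratio
   RFR = (FR1 − FR2)/(FR1 + FR2) as a per-unit selectivity index, and a
   hand-implemented Hartigan dip test for bimodality of the RFR
   distribution.
4. **Decoding** — per-feature standardization (fit on training folds only),
   an RBF-kernel SVM (C = 1), stratified 10-fold cross-validation scored by
   the f1 measure, plus permutation feature importance to identify which
   units carry the phase information.
5. **Acuity report** — the f1-versus-bar-width curve, the acuity threshold
   (smallest width with sustained f1 ≥ 0.75), conversion to cpd at a retinal
   magnification of 35 µm/degree, and machine-readable JSON/CSV/PNG reports.

## The synthetic model

Each unit's true selectivity is drawn from a three-point mixture: a mass at
RFR = 0 (unmodulated cells) and symmetric masses at ±r (cells preferring one
phase). The per-phase expected rates invert the RFR definition at a fixed
mean rate b: FR1 = b(1 + RFR), FR2 = b(1 − RFR). Spike counts per phase
window are Poisson; electrical spikes lock to the 40 Hz carrier cycles with
a 5 ms latency. Raw traces add a biphasic spike template with Gaussian
spatial decay, white noise, and modality-specific artifacts (a 40 Hz
sinusoid inside stimulation windows for electrical; a drift ramp with 200 µs
sensor resets every 400 ms for optogenetic). The selectivity magnitude r can
depend on bar width through `selectivity_profile()`, so the pipeline's
threshold estimate can be checked against a known ground-truth resolution.

## Worked example

```r
library(retinacuity)

cfg <- pipeline_config(modality = "optogenetic",
                       widths = c(5, 10, 20, 30, 50, 100, 500),
                       n_units = 20, n_repetitions = 40,
                       selectivity = selectivity_profile("saturating",
                                                         r_max = 0.6,
                                                         w_half = 40),
                       seed = 42)
curve <- run_pipeline(cfg)
print(curve)
```

```
<acuity_curve>
 bar_width   f1_mean      f1_sd n_units
         5 0.5416955 0.22204964      20
        10 0.5770635 0.12360951      20
        20 0.7940476 0.14216285      20
        30 0.6601082 0.18801160      20
        50 0.8556349 0.06700850      20
       100 0.9550000 0.09559754      20
       500 0.9888889 0.03513642      20
  acuity threshold (f1 >= 0.75): 50 um (0.35 cpd)
```

Narrow bars decode near chance (0.5), wide bars near perfectly, and the
threshold is the smallest width whose f1 stays above criterion for all
larger widths. The RFR dip test at 500 µm confirms the bimodal selectivity
structure:

```r
d <- curve$dip_tests[["500"]]
cat(sprintf("dip = %.4f, p = %.4f (n = %d)\n", d$dip_statistic, d$p_value, d$n))
#> dip = 0.1067, p = 0.0398 (n = 20)
```

Write a full report (JSON + CSV + optional PNG figures):

```r
write_report(curve, "report", plots = TRUE)
```

The same pipeline is scriptable from the shell:

```sh
Rscript inst/cli/retinacuity.R run --modality optogenetic \
    --widths 10,30,100 --n-units 20 --n-repetitions 40 --seed 42 --out report
```

## Reproduction

The chance-level decoding target (mean cross-validated f1 on populations
with zero phase selectivity: 40 units at equal 8 Hz Poisson rates in both
phases, 60 repetitions per phase, standardize + RBF SVM (C = 1) + stratified
10-fold CV, averaged over 50 seed replicates) is reproduced by:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

which writes `{"t2": {"value": 0.4845..., "n": 50}}` — within ±0.05 of the
theoretical chance level of 0.5. The statistic is stochastic across seeds
but fully deterministic for a given `--seed`. The script uses only the
installed package; no external data are required (all recordings are
synthesized in code).

The methods vignette (`vignettes/acuity-pipeline.Rmd`) documents the model,
the numerical choices in the filter designs and the dip statistic, and the
design decisions behind the decoder configuration.
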