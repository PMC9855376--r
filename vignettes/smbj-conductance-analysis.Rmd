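---
title: "Methods: simulating and analysing SMBJ conductance traces for DNA conformations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing SMBJ conductance traces for DNA conformations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement being modelled

In a single-molecule break-junction (SMBJ) experiment a gold STM tip is
driven into a gold substrate until the current preamplifier saturates and
then retracted at a constant speed (~80 nm/s) while the current is recorded
at a fixed bias, down to the preamplifier noise floor (~10 pA).  When no
molecule bridges the shrinking gap the conductance decays exponentially
with distance — a straight line on a semi-log plot.  When a molecule binds
between the electrodes the trace instead holds a *plateau* at a
molecule-specific conductance before breaking down to the floor.
Accumulating the samples of thousands of plateau-bearing traces into a
histogram over `log10(G/G0)` (`G0 = 2e^2/h ≈ 77.48 µS`) produces peaks at
the most-probable junction conductances.

For guanine-rich DNA the same solution can contain two conformations with
very different conductances: the B-form duplex (~1.6–3.4 × 10⁻⁴ G0,
sequence dependent) and the G-quadruplex (~3.5–3.8 × 10⁻³ G0).  The
package simulates such mixtures, reproduces the experimental trace-selection
and peak-fitting chain, assigns peaks to conformations, and titrates the
two species against each other to read out the quadruplex/duplex
peak-height ratio.

## The synthetic trace model

`simulate_trace()` draws, per retraction event:

1. with probability `1 − p_junction`, a pure tunneling decay
   `log10 G(d) = log10(ceiling) − β·d` plus per-sample Gaussian noise in
   decades (multiplicative in linear conductance);
2. otherwise a species from `capture_weights()`, a plateau level from
   `Normal(µ, σ_between)`, and a plateau length from the species' truncated
   normal; the trace decays to the level, holds it for
   `round(L · sampling_rate / retraction_rate)` samples, and then decays to
   the floor.

The trace ends at the first sample at or below the floor and every sample
is clamped to `[floor, ceiling]`, emulating the preamplifier limits.

Default study conditions (all configurable in `generator_config()` and
`mixture_spec()`):

| parameter | default | unit | why |
|---|---|---|---|
| bias | 0.1 | V | typical SMBJ bias; makes the 10 pA floor ≈ 1.29 × 10⁻⁶ G0, just below the histogram window |
| β (tunneling decay) | 6 | decades/nm | typical gold-gap decay; sets the in-window decay length |
| ceiling | 0.1 | G0 | saturation, one decade above the analysis window |
| floor | 1.29 × 10⁻⁶ | G0 | 10 pA / 0.1 V expressed in G0, computed not hard-coded |
| sampling rate | 40 000 | s⁻¹ | with 80 nm/s retraction: 2 pm/sample |
| retraction rate | 80 | nm/s | as in the experiments |
| plateau length | 0.3 ± 0.1 | nm | sub-nm plateaus; 150 ± 50 samples |
| plateau tilt | −0.3 | decades/nm | plateaus sag slightly as the junction strains |
| σ_between | 0.15 | decades | trace-to-trace plateau spread; dominates composite peak width |
| per-sample noise | 0.05 | decades | current noise above the floor |
| p_junction | 0.125 | — | centres the selected fraction in the experimental 10–15% band |

These defaults put composite-histogram peak widths at ~0.16 decades, a few
tenths of a decade as in published semi-log SMBJ histograms.

One deliberate geometric choice: the plateau tilt is **centred** on the
drawn level (`log g = level + slope·(d − d_mid)`), so the drawn level is the
plateau's mean log-conductance.  Anchoring the tilt at the plateau entry
instead would shift every plateau's centroid by `slope·L/2 ≈ −0.045`
decades and bias all recovered peak positions by almost the full recovery
tolerance the package holds itself to (0.05 decades).

### The capture model

No functional form for junction-formation probability versus concentration
is established for these systems, yet titrations show both conformations
remain detectable over ~16 orders of magnitude of concentration ratio.  We
therefore use a deliberately compressive power law: the probability that a
junction event captures species *i* is proportional to
`(affinity_i · c_i)^α` with `α = 0.08` by default.  At a concentration
ratio of 4.4 × 10⁻⁹ the minor species still receives ≈ 18% of junction
events.  `α` is a modelling assumption exposed in `mixture_spec()`, not a
physical claim; conclusions that depend on the shape of the titration curve
(beyond monotonicity and detectability) should not be drawn from it.

### The environment switch

`apply_environment()` implements the potassium control: in 100 mM KCl the
antiparallel quadruplex topology converts to parallel.  With both thiol
linkers on one end, the parallel form cannot bridge two electrodes, so its
capture weight is zero — a quadruplex-only KCl mixture yields tunneling-only
ensembles and an empty histogram.  Duplexes that declare a KCl-condition
conductance (the B-form geometry shifts slightly with the cation) have
their plateau position replaced by it.

## Trace screening

`screen_ensemble()` applies the experimental two-criterion filter:

1. **Residual criterion** — ordinary least squares of `log10 G` against
   distance over the analysis window `[−5.5, −1)` (RMSE in decades); traces
   below the threshold are tunneling decays and are rejected.
2. **Spike criterion** — the tallest bin of the per-trace histogram
   (40 bins/decade, same binning as the composite histogram) must reach a
   count threshold, demanding an in-window plateau.

The thresholds are calibrated against the generator defaults so that the
end-to-end selected fraction of a default ensemble lands inside the
experimental 10–15% band with ≥ 90% recall of junction-labelled traces and
(with the default noise) no false positives: `residual_threshold = 0.15`
decades and `amplitude_threshold = 15` counts.  At the default sampling
geometry a mean plateau spreads its ~150 samples over ~0.2 decades
(tilt ⊕ noise), so the tallest bin of a junction trace is ~25–35 counts
while a pure decay yields ~6; a threshold of 15 separates the two
populations cleanly.  Raising either threshold can only shrink the selected
set (monotonicity), which the tests check pointwise.

## Histogramming and peak fitting

`build_histogram()` adds all in-window samples of the selected traces into
half-open bins (`[edge, edge)` convention shared with the per-trace
histograms; total counts always equal total in-window samples).
`fit_gaussian_peaks()` then fits a sum of *k* Gaussians in
`(log10 G, counts)` space by Levenberg–Marquardt least squares
(`minpack.lm`), initialised from the *k* most prominent local maxima of a
lightly smoothed copy of the histogram, requiring ≥ 0.5 decades separation;
peaks return sorted by position.

Two numerical choices deserve explanation:

* **Constant baseline (default on).**  Every selected trace contributes its
  decay segments to the histogram — about
  `sampling_rate / (retraction_rate · β · bins_per_decade) ≈ 2.1` counts
  per bin per trace, a nearly uniform background of ~20% of a typical peak
  height.  An unmodelled background of that size makes a multi-peak
  fit absorb it into the Gaussians and misplace centres by several tenths
  of a decade.  The default model is therefore `baseline + Σ Gaussians`;
  `baseline = FALSE` remains available for background-free histograms, and
  a Poisson-weighted objective is available via `weighting = "poisson"`.
* **Peak presence.**  Downstream detection claims need a criterion for
  "this fitted component is a real population".  We declare a peak present
  when its height above background exceeds 5 Poisson standard deviations of
  the background level (estimated by the median nonzero bin count) and its
  width is below 0.6 decades (a plateau population, not a background
  artefact).  A rule that compares the raw amplitude to a multiple of the
  median bin count cannot work here: the decay background scales the median
  with the same `N` as the peaks, so no peak could ever clear a 5× median
  bar under these study conditions.

`summarize_repeats()` reproduces the experimental error convention: peak
positions from several independent (differently seeded) measurements are
matched by nearest log-conductance and the quoted value is the mean ±
sample standard deviation of the matched peak's conductance.

## Conformation assignment and titration

`assign_conformations()` labels fitted peaks against `reference_table()`
(duplex 3.03 × 10⁻⁴ G0, G-quadruplex 3.77 × 10⁻³ G0 — the
single-conformation controls), nearest-in-log within a tolerance of 0.35
decades, one-to-one with ties broken toward the lower-conductance entry.
The tolerance spans the sequence-to-sequence duplex spread
(1.63–3.36 × 10⁻⁴ G0) while keeping the two conformation bands (1.1 decades
apart) unambiguous.

`run_titration()` sweeps each species from 2 fM to 0.45 µM against 0.45 µM
of the other (9 log-spaced points per direction by default, 17 distinct
points, ratio span ≈ 16.7 orders of magnitude), runs the full
simulate → screen → histogram → fit(k = 2) → assign chain at every point
with 2 independent seeded repeats (per-point seeds derived from one master
seed via `derive_seed()`), and reports the quadruplex/duplex amplitude
ratio where both peaks pass the presence test in every repeat.  Stage
failures are flagged per point without aborting the grid.

## Problem sizes

Desk-scale defaults keep every analysis reproducible in minutes on one
core: 5000 traces for headline ensembles (matching the experimental
collection size), 1500–2000 traces per titration point or repeat, and 2–3
repeats where repeat statistics are quoted.  At these sizes the selected
fraction of a default ensemble is estimated to ±0.5% and fitted peak
positions to well under 0.05 decades.

## What the generator does and does not emulate

The synthetic ensembles reproduce the *statistical structure* the analysis
chain relies on: semi-log-linear tunneling decays, species-specific plateau
levels with trace-to-trace spread, plateau length dispersion, the noise
floor and saturation clamps, the junction-formation rate, and
concentration-dependent species capture.  They do **not** emulate: multiple
sequential plateaus per trace, conductance switching within a plateau,
stochastic snap-back ("ringing") at plateau exit, 1/f current noise,
drift in the decay constant, contamination events, or any physical
transport model connecting structure to conductance.  Passing tests
therefore validate the analysis pipeline's behaviour on data with the
assumed structure — they do not certify performance on instrument data
with artefacts outside that structure, and the screening thresholds would
need recalibration for a different instrument geometry.

## Worked example

```{r example}
library(smbjr)

cfg <- smbj_config(list(
  mixture = list(species = c("ds_CG3x3", "CG3x3_quad"),
                 concentrations = c(1e-6, 1e-6)),
  seed = 5, n_traces = 2000, repeats = 2))
run_pipeline(cfg)

tit <- run_titration(titration_grid(n_per_direction = 5),
                     n_traces = 900, repeats = 2, seed = 8)
tit[, c("ratio", "peak_height_ratio", "both_detected")]
```

## Known limitations

* The capture exponent `α` and the screening thresholds are calibrated to
  the default generator geometry; they are configuration, not physics.
* The Gaussian-plus-constant model ignores the slight window-edge taper of
  the decay background; with peaks close to a window edge a linear
  baseline would fit better than a constant.
* `summarize_repeats()` requires the same number of peaks in every repeat;
  borderline-presence peaks near the detection floor can make repeats
  unmatchable, which the titration handles by flagging the point rather
  than guessing.
* Concentrations enter only through the capture weights; absolute junction
  rates (`p_junction`) are held constant across titration points because
  per-point selection rates are not modelled.
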