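# smbjr

Single-molecule break-junction (SMBJ) conductance analysis for DNA
conformation sensing.

## The problem

In an SMBJ experiment a gold STM tip is repeatedly pulled out of contact
with a gold substrate in a solution of thiolated DNA while the current is
recorded at fixed bias.  Most retraction traces are bare tunneling decays;
in a minority (typically 10–15%) a molecule bridges the electrodes and the
trace holds a conductance *plateau*.  Accumulating the samples of the
plateau-bearing traces into a histogram over `log10(G/G0)` (with
`G0 = 2e²/h ≈ 77.48 µS`) reveals the most-probable junction conductances.

Guanine-rich sequences complicate the readout: the same solution can hold
both the B-form duplex (conductance ~1.6–3.4 × 10⁻⁴ G0, sequence
dependent) and the G-quadruplex (~3.5–3.8 × 10⁻³ G0), producing two
histogram peaks.  `smbjr` provides the full analysis chain for such
mixtures, plus a seeded synthetic trace generator so every stage is
testable at desk scale without instrument data:

- `simulate_ensemble()` — synthetic retraction traces: exponential
  tunneling decays, species-specific plateaus with spread, noise floor and
  saturation, concentration-dependent species capture;
- `screen_ensemble()` — the experimental two-criterion trace screen
  (semi-log line-fit residual, then a spike in the per-trace histogram);
- `build_histogram()` / `fit_gaussian_peaks()` — composite semi-log
  conductance histogram and Gaussian peak fitting in log scale (with a
  constant-baseline term for the tunneling background);
- `assign_conformations()` — peak labelling against reference
  conductances of the single-conformation controls;
- `apply_environment()` — the KCl control: potassium flips antiparallel
  G-quadruplexes to the parallel topology, which cannot bridge the
  electrodes, suppressing the quadruplex peak;
- `run_titration()` — concentration-ratio titration of the two
  conformations, read out as the quadruplex/duplex peak-height ratio;
- `run_pipeline()` — the whole chain under one master seed, with repeat
  statistics quoted as mean ± sd over independent seeded measurements.

## Worked example

A mixture of the duplex and quadruplex forms of (CG₃)₃ at 1 µM each, 2000
traces, two independent repeats:

```r
library(smbjr)

cfg <- smbj_config(list(
  mixture = list(species = c("ds_CG3x3", "CG3x3_quad"),
                 concentrations = c(1e-6, 1e-6)),
  seed = 5, n_traces = 2000, repeats = 2))
run_pipeline(cfg)
#> <smbj_report> 2000 traces x 2 repeat(s)
#>   selection fraction: 11.9%, 12.6%
#>   peak 1: 0.000163 G0 (0.01261 uS), sigma 0.15 dec, amp 1380 -> duplex
#>   peak 2: 0.0033 G0 (0.2558 uS), sigma 0.16 dec, amp 1082 -> G-quadruplex
#>   repeat stats peak 1: 0.000158 +/- 6.8e-06 G0 (n=2)
#>   repeat stats peak 2: 0.00346 +/- 0.00022 G0 (n=2)
```

Reading the report: 11.9% and 12.6% of the simulated traces passed the
two-criterion screen (inside the experimental 10–15% band); the composite
histogram resolves two peaks, assigned to the duplex (1.63 × 10⁻⁴ G0, i.e.
0.0126 µS) and the G-quadruplex (3.3 × 10⁻³ G0); and across the two
repeats the quoted conductances are 1.58 ± 0.07 × 10⁻⁴ G0 and
3.46 ± 0.22 × 10⁻³ G0 — recovering the generator's ground truth
(1.63 × 10⁻⁴ and 3.50 × 10⁻³) within the measured spread.

A command-line wrapper over the same functions is installed at
`inst/scripts/smbj-run.R` with `simulate`, `screen`, `report` and
`titrate` subcommands, all taking `--config` (a sectioned key=value file),
`--seed` and `--out`.

See `vignettes/smbj-conductance-analysis.Rmd` for the model, parameter
defaults and numerical choices.

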