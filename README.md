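# biflow

Burst-integrated fluorescence lifetime (BIFL) analysis for time-domain
fluorescence lifetime flow cytometry.

## The problem

A time-domain lifetime flow cytometer streams cells through a pulsed-laser
illumination volume and records every detected fluorescence photon with a
time-correlated single photon counting (TCSPC) card in FIFO mode. Each
photon carries a **macro time** (lab-frame arrival, microsecond scale, used
to find the cell) and a **micro time** (delay after the laser sync pulse,
nanosecond scale, whose histogram is the fluorescence decay). A passing
cell produces a **burst** of 500–10,000 photons over a ~ms transit.

`biflow` implements the complete data path from raw photon records to
cytometry-style per-cell parameters:

1. **Burst search** — macro times are histogrammed into 20 µs bins,
   median-filtered, and thresholded; each maximal run of bins above the
   threshold is one burst, characterised by burst duration (BD), photon
   count (PC) and mean count rate (MCR = PC/BD).
2. **Lifetime fitting** — each burst's micro-time histogram is fitted with
   an exponential decay truncated to the sync window *T*: the maximum
   likelihood estimate solves `mean(t) = τ − T/(e^{T/τ} − 1)`;
   Levenberg–Marquardt weighted least squares is available as an
   alternative. A **global bi-exponential analysis** fits
   `I(t) = A₁e^{−t/τ₁} + A₂e^{−t/τ₂}` with lifetimes shared across all
   cells and non-negative per-cell amplitudes, reporting fractional
   intensities `f_k = A_k τ_k / ΣA_j τ_j` — the route to resolving two
   photophysical states (e.g. membrane lipid order probes) from bursts too
   small for unconstrained two-component fits.
3. **FRET from donor lifetime** — per-cell efficiency
   `E_i = 1 − τ_i/τ̄_D` against a donor-only control population, with two
   refinements for expression-dependent donor lifetimes: an
   intensity-matched control subset (the 5% of controls closest in
   intensity), and a recursive variant that matches on the estimated
   unquenched intensity `I_i/(1 − E_i)`, iterated until the mean relative
   change in E drops below 1%.
4. **Ratiometric (three-cube) FRET** — for conventional-cytometer data:
   background correction, bleed-through factors S₁–S₃ from single-
   fluorophore controls (medians of `I_DA/I_DD`, `I_DA/I_AA`, `I_AA/I_DD`),
   sensitized emission `F_c = I_DA − S₁I_DD − S₂(I_AA − S₃I_DD)`, α
   calibration by regressing per-construct `F_c/I_AA` on `I_DD/I_AA`
   across FRET standards, and per-cell `E = F_c/(F_c − k·I_DD)` with
   10%-outlier-trimmed population summaries.
5. **Cytometry outputs** — mean/SEM/STD/n summaries with the
   round-to-SEM reporting convention, percentile gates, a two-sample 2D
   Kolmogorov–Smirnov test (Fasano–Franceschini quadrant statistic), and
   FCS 3.1 list-mode output readable by standard cytometry software.

Because no public instrument data exist, the package ships a **photon
stream simulator** (`simulate_stream()` and friends) that generates FIFO
records from particles with known lifetimes, brightness distributions,
transit profiles and background — every stage of the pipeline is tested
against this ground truth.

## Worked example

```r
library(biflow)

cfg  <- acquisition_config()                 # 80 MHz sync, 12.5 ns window, 20 µs bins
spec <- population_spec(n_cells = 50, lifetime_mean = 2.5, lifetime_sd = 0.15,
                        intensity_median = 2000, arrival_rate = 20,
                        background_rate = 1000)
stream <- simulate_stream(spec, cfg, seed = 1)
stream
#> TCSPC photon stream: 102424 records over 2.476 s, 50 truth particles

cells <- analyze_stream(stream)              # bin -> filter -> threshold -> gate -> fit
nrow(cells)
#> [1] 48                                     # 2 transits overlapped and were gated out
summarize_population(cells$tau[!is.na(cells$tau)])
#> mean 2.53  SEM 0.02  STD 0.149  n 48
```

The recovered population mean matches the simulated 2.5 ns lifetime with
the 0.15 ns cell-to-cell spread; each burst of ~2000 photons contributes a
lifetime estimate with ~0.06 ns shot-noise error.

FRET efficiency against a donor-only control, with the recursive
quenching-corrected estimator:

```r
donor  <- simulate_cell_table(population_spec(2000, 2.593, lifetime_sd = 0.13,
                                              intensity_sdlog = 1.15,
                                              arrival_rate = 50), seed = 2)
constr <- simulate_cell_table(population_spec(2000, 2.593, lifetime_sd = 0.13,
                                              intensity_sdlog = 1.15,
                                              arrival_rate = 50), seed = 3)
constr$tau       <- constr$tau * (1 - 0.21)        # a 21%-transfer construct:
constr$intensity <- constr$intensity * (1 - 0.21)  # lifetime and donor quenched

tab <- fret_table(constr, donor)                   # E1 (basic), E2 (matched), E3 (recursive)
#> mean E3 = 21.20% (SEM 0.09, STD 4.0, n = 2000), 3 recursion passes
```

A command-line front end over the same functions lives at
`system.file("cli", "biflow-cli.R", package = "biflow")` with subcommands
`simulate | segment | fit | fret | report`, YAML configs and a global
`--seed`.

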