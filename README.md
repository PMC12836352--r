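# wgmsense

Whispering-gallery-mode (WGM) sensing of intracellular lipid droplets.

Lipid droplets in live adipocytes (refractive index n_LD ≈ 1.47, embedded
in cytoplasm at n_cell ≈ 1.33–1.40) act as natural optical microcavities:
dye emission circulating at the droplet surface produces a comb of sharp
WGM resonances.  Because every resonance wavelength is pinned to the
optical path π·n_LD·d, the comb is an exquisitely sensitive ruler for the
droplet diameter d — nanometre-scale changes of a 60 µm droplet are
resolvable from picometre line shifts, two orders of magnitude below the
optical resolution of a microscope.  `wgmsense` is for biophotonics and
cell-metabolism researchers who want to turn such spectra into
quantitative lipolysis kinetics and cell-state diagnostics.

The package implements the full chain:

* **Forward optics** — TE/TM resonance positions of a dielectric sphere
  from the first-order radial asymptotic expansion
  (π·n_LD·d/λ = ν + 2^(−1/3)α_q ν^(1/3) − P/√(ρ²−1) + …, with ν = ℓ+1/2,
  ρ = n_LD/n_cell, P = ρ for TE and 1/ρ for TM), an exact Mie
  characteristic-equation oracle, the free spectral range
  FSR = 1/(π·n_eff·d), the TE/TM splitting parameter S = √(ρ²−1)/ρ and
  its inversion n_cell = n_LD√(1−S²), index-perturbation sensitivity and
  evanescent penetration depth.
* **Spectrum I/O and fitting** — CSV/ASCII spectra and time-series
  manifests; baseline subtraction, normalization, SNR estimation; peak
  extraction by Lorentzian-superposition fitting at high SNR or by two
  empirical sinusoid models (chirped in wavelength, or periodic in inverse
  wavelength) at low SNR, with per-peak position uncertainties.
* **Inference** — absolute diameter from the FSR (Eq-4-style telescoped
  inverse-wavelength spacings) or from full mode assignment; nanometre
  diameter tracking across time with FSR-rollover resolution; cytoplasm
  refractive-index time series from TE/TM mode splitting; the resolution
  floor (Δd)_min = d·w_s/λ.
* **Metabolic metrics** — volumetric rate, molecules/s (V_TG = 2 nm³),
  molar flux, lipolytic efficiency; Welch t and Levene group comparisons.
* **Viability diagnostics** — lasing-transition scores, rupture flags
  from n_cell drops, static-droplet flags.
* **Synthetic data** — a physically grounded generator (control /
  lipolysis / rupture scenarios) with exact ground truth, so every stage
  is testable without instrument data.

## Worked example

Simulate one cell undergoing a lipolytic burst, fit every spectrum, and
track its diameter:

```r
library(wgmsense)

sc    <- synth_config(d0 = 60, snr = 20, seed = 1, scenario = "lipolysis")
ts    <- generate_timeseries(sc)
peaks <- lapply(ts$spectra, function(s) fit_spectrum(preprocess(s)))
track <- track_diameter_change(peaks, ts$truth$t_min, cell_id = "cell1")
track[c(1, 5, 6, 7, 13), ]
#>    cell_id t_min  d_um    dd_nm dd_sigma_nm rate_um_per_h n_matched
#> 1    cell1     0 59.97     0.00       0.000            NA        NA
#> 5    cell1    60 59.87   -99.88       1.063      -0.09996        60
#> 6    cell1    75 59.62  -349.75       3.710      -0.99949        56
#> 7    cell1    90 59.37  -599.65       6.359      -0.99960        57
#> 13   cell1   180 58.92 -1049.30      11.126      -0.29981        58
```

The generator imposed a 0.1 µm/h baseline, a 30-minute burst at 1 µm/h
(rows 6–7) and a 0.3 µm/h tail; the tracker recovers the per-interval
rates to a fraction of a percent and the cumulative −1050 nm change to
within 1 nm.  For a stable droplet the resolvable change is
`min_resolvable_change(60, 0.04, 620)` ≈ 3.9 nm.

Convert the burst interval into flux metrics:

```r
molecule_and_molar_flux(d = 59.6, rate = -1)
#> LD flux report (diameter convention): dV/dt = -93 um^3/min,
#> 7.76e+08 molecules/s, 1.15e-07 mol/m^2/s, efficiency -0.0083 um^3/min/um^2
```

A 60 µm droplet changing at 1 µm/h transports ~10⁹ triglyceride molecules
per second across its surface.  Absolute size and cytoplasm index from a
noiseless TE+TM mode assignment:

```r
g  <- generate_spectrum(synth_config(d0 = 60, n_cell = 1.367, snr = Inf))
pk <- fit_lorentzian_superposition(preprocess(g$spectrum))
diameter_from_mode_fit(pk, optical_config(n_cell = 1.36), fit_ncell = TRUE)
#> LD diameter: 59.9981 +/- 0.0001 um (mode-fit), n_cell = 1.3678
```

## Command line

A thin wrapper over the same functions is installed as `exec/wgmsense`:

```sh
wgmsense simulate --scenario lipolysis --output run1 --seed 1
wgmsense fit      --output run1
wgmsense track    --output run1
wgmsense metrics  --output run1
wgmsense report   --output run1     # report.json with config hash + seed
```

Exit codes: 0 success, 2 config error, 3 data error, 4 ambiguity
(e.g. a degenerate mode assignment that needs a user decision).

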