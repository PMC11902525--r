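# secstream

Analysis of multi-detector size-exclusion chromatography (md-SEC) runs in
R. A single injection recorded with a differential refractometer (RI),
dual-angle static light scattering (LALS at 7°, RALS at 90°) and a
capillary-bridge differential viscometer yields, slice by slice, absolute
molecular weight, intrinsic viscosity and radius of gyration — without a
column calibration curve. `secstream` covers the whole chain:

* **raw I/O** — read/write delimited `RawSignals.txt`, `InitData.txt`,
  adjusted-chromatogram and detector-constant files (`#` key = value
  headers plus a numeric table; tab, space or comma separated),
* **preprocess** — elution-region selection, quiet-window baseline
  fitting and subtraction, specific viscosity from the bridge
  (`eta_sp = 4 DP / IP`, with IP used baseline-retained), noise-level
  estimation, optional per-detector volume shifts,
* **optics** — scattering vector, angular (reciprocal form factor) term
  `1 + q^2 Rg^2 / 3`, low-angle validity checks,
* **calibrate** — RI constant by mass balance; LS constants by the
  peak-slice and peak-averaged estimators; RALS angular correction for a
  standard of known Rg; classic log-linear column calibration and
  universal-calibration coordinates,
* **analyze** — per-slice concentrations (mass-balance and calibrated
  routes, with a concordance check), molecular weights per LS detector,
  Rg from the two-angle ratio, Solomon–Ciuta or ratio intrinsic
  viscosity, weight/number distributions, Mn/Mw/Mz/PDI, bulk [η],
  noise-weighted Mark–Houwink–Sakurada fit, MWD table and a
  MultiHydFit-style export,
* **simulate** — a forward instrument model (log-linear column, Gaussian
  bands, baseline offset/drift, additive noise) so every stage can be
  validated against known ground truth,
* **cli** — `exec/secstream` with `simulate`, `prepare`, `calibrate`
  and `analyze` subcommands.

## Quick start

```r
library(secstream)

dir <- tempfile(); dir.create(dir)
fx  <- make_fixture("pul71", dir, seed = 1)      # synthetic pullulan standard
raw <- read_raw_signals(fx$paths$raw)
inj <- read_init(fx$paths$init)

adj <- prepare_chromatogram(raw, min(raw$vel), max(raw$vel))
cal <- calibrate_detectors(adj, inj, m = 70768)
cal$peak
#> Detector constants (peak)
#>   Q_RI   : 8.921000e+06
#>   Q_LALS : 3.319000e+01
#>   Q_RALS : 5.750000e+01

res <- analyze_sample(adj, cal$peak, inj = inj)
res$summary$mw     # 70768 (monodisperse standard, exact round trip)
res$summary$pdi    # 1
```

Or from the shell:

```sh
exec/secstream simulate  --preset pul48_805 --out run --seed 7
exec/secstream prepare   --in run/RawSignals.txt --out run/AdjustedData.txt
exec/secstream calibrate --in run/AdjustedData.txt --init run/InitData.txt \
                         --standard-mw 70768 --out run/constants.txt
exec/secstream analyze   --in run/AdjustedData.txt --constants run/constants.txt \
                         --init run/InitData.txt --out run/results
```

`analyze` writes `slices.tsv`, `mwd.tsv`, `summary.txt`,
`multihydfit.dat` and `run.log` into the results directory.

## Tests

```r
testthat::test_dir("tests/testthat", package = "secstream",
                   load_package = "installed")
```

The suite is fully self-contained: all inputs are generated by the
package's own simulator, and the oracles are closed-form detector
equations, conservation laws and published optical/viscometric reference
values. `tests/testthat/test-acceptance.R` holds the acceptance
criteria; `scripts/acceptance.R` recomputes the headline reference
quantities and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/md-sec-methods.Rmd`) describes the
measurement model, unit conventions, default parameters and the
numerical design decisions — in particular the baseline-retained IP
channel, the always-on low-signal mask floor, and the noise-weighted,
attenuation-corrected MHS fit — plus what the simulator deliberately
does not model.
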