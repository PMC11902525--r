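---
title: "Methods: multi-detector SEC analysis with secstream"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-detector SEC analysis with secstream}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secstream)
```

# The measurement model

Multi-detector size-exclusion chromatography (md-SEC) separates dissolved
macromolecules by hydrodynamic size and records, at each elution volume
$V_{el}$ (mL), five raw signals in mV:

* **RI** — differential refractometer, $RI_j = Q_{RI}\,(dn/dc)\,c_j$,
* **LALS / RALS** — static light scattering at 7° and 90°,
  $LS_j = Q_{LS}\, n_1^2 (dn/dc)^2\, c_j M_j \,/\, [1 + q^2 R_g^2/3]$,
  where the angular (reciprocal form factor) term is 1 for the low-angle
  detector to excellent approximation,
* **IVDP / IVIP** — differential and inlet pressure of a Wheatstone-bridge
  capillary viscometer, giving the specific viscosity
  $\eta_{sp,j} = 4\,DP_j / IP_j$.

Each chromatographic slice $j$ is treated as an effectively monodisperse,
very dilute fraction. From the three detector families the analysis
recovers, per slice, the concentration $c_j$ (g/mL), molecular weight
$M_j$ (g/mol), intrinsic viscosity $[\eta]_j$ (mL/g) and optionally the
radius of gyration $R_{g,j}$ (nm), and from these the molecular weight
distribution, the averages $M_n \le M_w \le M_z$, the polydispersity
index, the bulk intrinsic viscosity and the Mark–Houwink–Sakurada (MHS)
relation $[\eta] = K M^a$.

## Units contract

All conversions happen at the I/O boundary; internally the package uses
one fixed convention: $V_{el}$ in mL, $c$ in g/mL, $M$ in g/mol, $[\eta]$
and $dn/dc$ in mL/g, $\lambda_0$ and $R_g$ in nm, $q$ in nm$^{-1}$,
signals in mV. The light-scattering constants $Q_{LALS}, Q_{RALS}$
therefore carry units of mV per $(\mathrm{g/mL})(\mathrm{g/mol})(\mathrm{mL/g})^2$.

# Workflow

```{r workflow}
# 1. simulate a synthetic standard run (or read a real RawSignals.txt)
fx <- make_fixture("pul71", tempdir(), seed = 1)
raw <- read_raw_signals(fx$paths$raw)
inj <- read_init(fx$paths$init)

# 2. preprocess: region selection, baselines, specific viscosity
adj <- prepare_chromatogram(raw, min(raw$vel), max(raw$vel))

# 3. calibrate detector constants on the standard of known M
cal <- calibrate_detectors(adj, inj, m = 70768)
cal$peak

# 4. analyze a problem sample with those constants
res <- analyze_sample(adj, cal$peak, inj = inj)
res$summary
```

The same stages are available from the shell through `exec/secstream`
(`simulate`, `prepare`, `calibrate`, `analyze`), each writing delimited
result tables and a machine-readable log.

# Key parameters and defaults

| Parameter | Default | Rationale |
|---|---|---|
| quiet windows | first/last 5% of the region | flat solute-free flanks after region selection |
| baseline | line through window medians | robust to residual spikes; estimator unspecified upstream |
| low-signal mask | 2% of the RI peak | tail slices are dominated by detector noise |
| `[eta]` estimator | Solomon–Ciuta | stays accurate at moderate dilution; `ratio` available |
| LA validity cutoff | $q^2R_g^2/3 < 0.5$ | conventional range of the small-$qR_g$ expansion |
| $\lambda_0$, $n$ | 670 nm, 1.33 | instrument class modelled; aqueous solvent |
| column model | log-linear, 10–26 mL, $5\times10^7$–$10^3$ g/mol | typical aqueous SEC column |

# Numerical design decisions

**IP channel is used baseline-retained.** The bridge relation divides the
solute-induced differential pressure by the *absolute* solvent pressure.
DP is baseline-subtracted; subtracting a baseline from IP would zero its
physical level, so IP is used raw. This is flagged here because detector
manuals rarely state it.

**Always-on mask floor.** Baseline subtraction leaves floating-point
residues of order $10^{-13}$ mV. In gap regions of a fully resolved
chromatogram these residues would otherwise enter ratio quantities, so
slices with adjusted RI below $10^{-12}$ of the RI peak are always masked
even when the user-facing mask threshold is 0.

**Noise-weighted, attenuation-corrected MHS fit.** Per-slice $M_j$ and
$[\eta]_j$ are ratios of noisy signals. A plain log–log least-squares fit
then suffers twice: low-signal slices with huge log-scale scatter dominate
the residual, and noise in $\log M$ (the *regressor*) biases the slope
toward zero — classical errors-in-variables attenuation, which the long
extrapolation to $M = 1$ amplifies into a large error on $K$. The
preprocessing stage therefore estimates each detector's noise level from
the quiet-window residuals (`estimate_noise_sd()`, carried through the
adjusted-file metadata), and `mhs_fit()` weights slices by inverse total
log-variance and applies the method-of-moments attenuation correction,
including the covariance induced by the shared RI denominator of both
coordinates. On synthetic data with 1% per-channel noise this reduces the
typical error on $K$ from tens of percent to a few percent while leaving
exact data essentially untouched.

**Calibration estimators under noise.** The peak-based LS constant uses a
single slice and therefore inherits roughly $\sqrt{2}\times$ the
per-channel relative noise (~1.4% at 1% noise); the average-based
constant pools the whole peak and is the appropriate choice for noisy
runs. Both are always computed and reported.

**Two instrument configurations for end-to-end validation.** The
generator/analyzer round trip is checked in two regimes because they
probe different claims. With a *fully resolving* column (band width far
below the component spacing) every slice is exactly monodisperse, so all
slice-level identities must hold to numerical precision — this validates
the algebra. With *realistic band broadening* and 1% noise the
chromatogram is continuous and the statistical estimators are exercised —
this validates robustness. A single configuration cannot test both:
slice-wise identity is undefined under band mixing, and noise robustness
is meaningless on delta-like bands.

# The forward simulator, and what it does not show

`simulate_run()` places each component as a Gaussian band centered at the
elution volume given by the log-linear column model, scaled so the band
integral equals the injected mass, then generates the five detector
responses from the same relations the analysis inverts, plus per-detector
baseline offset/drift and additive, independent Gaussian noise.

Passing round-trip tests against this simulator demonstrates internal
consistency of the implementation, **not** fidelity to real instruments.
Real chromatograms add effects deliberately omitted here: band asymmetry
(tailing), inter-detector dead volume, correlated and non-Gaussian noise,
concentration-dependent (non-dilute) viscosity, the second virial
coefficient, and pressure fluctuations of the viscometer bridge. Results
on experimental data depend on those effects and on the true column
behavior, none of which the simulator constrains.

# Resolved ambiguities

* Raw data file naming differs between upstream descriptions
  (`RawData.txt` vs `RawSignals.txt`); one format is used, with optional
  in-file metadata.
* Inter-detector delay: no correction is applied by default (the
  instrument class shows none); `prepare_chromatogram(shifts = ...)`
  exposes an optional per-detector volume shift.
* The slice mask renormalizes weight fractions over the kept slices — a
  deliberate truncation estimator; the discarded mass fraction is
  reported in the summary.
* Published reference tables for the angular term and the pullulan MHS
  relation mix rounding and truncation and contain cells inconsistent
  with their stated formulas; the package reproduces the formulas, and
  the test suite documents the discrepant cells instead of fitting to
  them.
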