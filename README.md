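# odnptraj

Trajectory analysis for **scalar Overhauser dynamic nuclear polarization
(ODNP)** in radical–substrate complexes.

Scalar ODNP transfers electron polarization to nuclei through the
fluctuating Fermi-contact hyperfine interaction. At high field (9.4 T) the
electron–¹³C zero-quantum transition sits near 0.263 THz, so the efficiency
of the transfer is governed by sub-picosecond dynamics of the electron spin
density at the nuclear positions — dynamics that QM/MM molecular-dynamics
trajectories expose as femtosecond-sampled time series. This package turns
such columnar series (time + spin densities + geometric observables) into
the quantities that diagnose ODNP:

* normalized autocorrelation functions
  `g(t) = ⟨ρ(t₀)ρ(t₀+t)⟩ / ⟨ρ(t₀)²⟩` and inter-channel covariances;
* the memory kernel of the Volterra equation
  `∂g/∂t = −∫₀ᵗ K(τ) g(t−τ) dτ`, solved lag-by-lag in its differentiated
  second-kind form with an arbitrary-precision (default 100 decimal digits)
  contract, a separated δ-mass `a = −g′(0)/g(0)` for Markovian components,
  and an always-on forward-reconstruction round-trip diagnostic;
* one-sided cosine-transform spectral densities
  `J(ω) = 2∫₀^∞ g(t)cos(ωt)dt`, evaluated at the zero-quantum frequency
  `ω_ZQ = 2π(ν_e − ν_C)`, with the scalar cross-relaxation rate estimate
  `R_ZQ = ¼(2π a_iso)² J(ω_ZQ)` under a pinned convention;
* correlation-time spectra by CONTIN-style regularized inverse Laplace
  transform (nonnegative least squares + second-difference smoothing);
* autoregressive models with AIC order selection, where `p · dt` is the
  time-point memory of the process (e.g. 6 fs for an AR(6) fit at 1 fs);
* ODNP bookkeeping: enhancement factors
  `ε = (I_DNP/I_Boltzmann)(n_Boltzmann/n_DNP) − 1` with Gaussian error
  propagation (`ΔI = 1/SNR`), molar-free paramagnetic shifts (slope of
  shift vs. radical concentration), two-state complex lifetimes
  `τ = K_a/k_on`, and capillary-resonator sample volumes.

A synthetic-data module (Ornstein–Uhlenbeck, telegraph "pulse model",
autoregressive, damped-oscillation, titration generators) reproduces the
statistical structure the analysis assumes, so the full pipeline is
testable without a QM/MM engine. It targets spectroscopists and
simulators who have trajectory extractions or NMR integrals in hand and
want the analysis layer between them.

## Worked example

Surrogate spin-density trajectory with the measured phenomenology — fast
0.05 ps decay carrying a 0.3 ps-period wave plus a slower 0.7 ps
component — pushed through the pipeline:

```r
library(odnptraj)

trj <- gen_damped_osc(
  damped_osc_spec(data.frame(decay_ps     = c(0.05, 0.7),
                             omega_rad_ps = c(2 * pi / 0.3, 0),
                             weight       = c(0.7, 0.3))),
  n = 20000, dt_fs = 1, seed = 1)

acf1 <- compute_acf(trj, "x", run_config(max_lag_fraction = 0.1))
ker  <- solve_memory_kernel(acf1, run_config(precision_digits = 100,
                                             max_lag_fraction = 0.1))
glance(ker)[, c("n_lags", "delta_mass", "roundtrip_error")]
#> # A tibble: 1 × 3
#>   n_lags delta_mass roundtrip_error
#>    <int>      <dbl>           <dbl>
#> 1   1999     0.0158       1.80e-106

summarize_components(ilt_acf(compute_acf(trj, "x"), lambda = 1e-2),
                     min_mass = 0.05)
#> # A tibble: 2 × 2
#>   tau_ps  mass
#>    <dbl> <dbl>
#> 1 0.0316 0.916
#> 2 0.736  0.177

zqp <- zq_params(nu_e_ghz = 263, nu_c_ghz = 0.1006, a_iso_mhz = 1)
zq  <- zq_frequency(zqp)
Jz  <- spectral_density_at(compute_acf(trj, "x"), zq$omega_rad_ps)
c(omega_zq_rad_ps = zq$omega_rad_ps, J_zq_ps = Jz,
  R_zq_per_s = estimate_zq_rate(Jz * 1e-12, zqp)$rate_per_s)
#> omega_zq_rad_ps         J_zq_ps      R_zq_per_s
#>        1.651846        0.423717        4.181920

enhancement(51, 1, snr_dnp = 120, snr_boltz = 15)[, c("epsilon", "delta_epsilon")]
#> # A tibble: 1 × 2
#>   epsilon delta_epsilon
#>     <dbl>         <dbl>
#> 1      50          3.40

complex_lifetime(K_a = 1)    # H-bonded complex, diffusion-limited k_on
#> [1] 100
```

Reading the output: the round-trip error of ~1e-106 confirms the 100-digit
recursion is arithmetic-error free over these 2000 lags; the
correlation-time spectrum resolves the sub-0.1 ps decay (dominant mass)
from the ~0.7 ps component; the spectral density at the zero-quantum
frequency (1.65 rad/ps, i.e. 0.263 THz) with a 1 MHz hyperfine coupling
gives a scalar cross-relaxation rate of ~4 s⁻¹, the order of magnitude that
sizable ¹³C enhancements imply; and a 51:1 integral ratio is a 50-fold
enhancement with a ±3.4 uncertainty at those signal-to-noise ratios.

A thin command-line wrapper over the same functions ships at
`inst/cli/odnptraj.R` (subcommands `simulate`, `acf`, `cov`, `memory`,
`spectrum`, `ilt`, `arfit`, `enhance`, `parashift`), reading/writing the
TSV trajectory format and JSON result files with configuration echo and
checksums.

## Acceptance script

`scripts/acceptance.R` recomputes the package's analytic acceptance
targets from scratch against the installed package — currently the
two-state dissociation lifetime of an H-bonded radical–substrate complex
at the upper end of the H-bond binding-constant range with a
diffusion-limited association rate — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
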