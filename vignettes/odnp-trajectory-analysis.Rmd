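---
title: "Dissecting scalar ODNP from spin-density trajectories: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting scalar ODNP from spin-density trajectories: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odnptraj)
```

## The scientific problem

Scalar Overhauser dynamic nuclear polarization (ODNP) transfers electron spin
polarization to nuclei through the *fluctuating* Fermi-contact (scalar
hyperfine) interaction in transient or long-lived radical–substrate
complexes. At high magnetic field (9.4 T; 263 GHz electron Larmor frequency)
the electron–carbon-13 zero-quantum (flip–flop) transition sits near
0.263 THz, so only molecular motions on the sub-picosecond scale can drive
the cross-relaxation. Whether a given complex supports scalar ODNP is
therefore a question about the *dynamics* of the electron spin density at
the nuclear positions.

Those dynamics are accessible from QM/MM molecular-dynamics trajectories
that record, every femtosecond, the atomic spin densities and the geometry
of the complex (hydrogen-bond length and angle, radical–solvent distance,
methyl rotation). This package implements the analysis chain from such a
columnar time series to ODNP-relevant quantities:

1. normalized autocorrelation functions (ACFs) `g(t)` and inter-channel
   covariances (`compute_acf()`, `compute_covariance()`),
2. the memory kernel `K(τ)` of the generalized-Langevin/Volterra equation
   `∂g/∂t = −∫₀ᵗ K(τ) g(t−τ) dτ` (`solve_memory_kernel()`,
   `reconstruct_acf()`, `precision_drift_report()`),
3. spectral densities `J(ω)` and their value at the zero-quantum frequency,
   with a convention-pinned cross-relaxation-rate estimate
   (`acf_to_spectral_density()`, `zq_frequency()`, `estimate_zq_rate()`),
4. correlation-time spectra by regularized inverse Laplace transform
   (`ilt_acf()`, `summarize_components()`),
5. autoregressive models with order selection, the order × step being the
   process "memory" in physical time (`fit_ar()`, `select_order()`),
6. ODNP bookkeeping: enhancement factors with propagated errors, molar-free
   paramagnetic shifts from titrations, complex lifetimes, resonator sample
   volumes (`enhancement()`, `molar_free_shift()`, `complex_lifetime()`,
   `capillary_volume()`).

Because ab-initio trajectories are expensive (10 ps of QM/MM dynamics costs
on the order of 10⁴ CPU hours), a synthetic-data module (`gen_ou()`,
`gen_pulse_model()`, `gen_ar()`, `gen_damped_osc()`, `gen_titration()`)
generates surrogate series with the statistical structure the analysis
assumes, so every stage is testable without the simulation engine.

## The ACF estimator and the centering question

For a channel `ρ(t)` sampled at `N` points the estimator is

```
g(k·dt) = [ Σᵢ ρᵢ ρᵢ₊ₖ / (N−k) ] / [ Σᵢ ρᵢ² / N ]
```

with all admissible time origins used (overlapping windows). The numerator
is unbiased per lag; the denominator is the lag-0 variance, so `g[0] = 1`
exactly. Lags stop at `max_lag_fraction × N` samples (default 0.5): sample
ACFs of finite series converge artificially to zero near the full length,
and half the duration is the conventional guard.

The defining formula uses raw products, but applied to a series with a
nonzero mean it never decays to zero and breaks every downstream stage
(the memory solver needs `g → 0`; the ILT needs a decaying target). The
"fluctuation" reading implies mean removal. Both policies are implemented;
`centering = "mean"` is the default, and the policy used is recorded in
every result. The per-lag band of this estimator on white noise is
`3/√(N−k)`, not `3/√N` — the tail lags average fewer products.

High precision is *not* needed at this stage: double- and 100-decimal ACFs
agree to ≥ 12 significant digits (tested). Precision matters in the
memory-kernel recursion, which is why `precision_digits` (default 100)
is consumed there.

## The memory kernel: formulation, stability, and the precision contract

The Volterra memory equation above is, for the unknown kernel, a first-kind
problem. Discretizing it literally (time derivative of `g` on the left,
Gregory-corrected trapezoid on the right, solve for `K` lag by lag) is
exponentially unstable: the recursion loses ~0.2–0.3 decimal digits *per
lag step*, so even 100-decimal arithmetic is exhausted after a few hundred
lags — no precision budget reaches half of a 10⁴-point trajectory. That
instability, not sloppiness, is why kernel extraction is notorious for
error propagation.

We therefore differentiate once and solve the *second-kind* form
(the setting of Day's quadrature method):

```
−g''(t) − a·g'(t) = K(t)·g(0) + h Σⱼ wⱼ K(tⱼ) g'(t−tⱼ)
```

whose pivot `g(0) + h·wₙ·g'(0) ≈ 1` makes the recursion stable. Two
numerical choices deserve explanation:

**The δ-mass split.** ACFs with `g'(0) ≠ 0` — the memory-free
Ornstein–Uhlenbeck ACF `e^(−γt)`, the telegraph/pulse-model ACF, any
exponential-times-cosine — correspond to kernels with a singular component
`a·δ(τ)`, `a = −g'(0)/g(0)`. A grid function cannot represent a δ;
absorbing it into `K[0]` contaminates the first lags and destabilizes the
tail. The solver instead splits `a` off analytically and reports it as
`delta_mass` (fs⁻¹) next to the regular kernel `K` (fs⁻²). For an OU input
the result is clean: `delta_mass ≈ γ` and `K ≈ 0` everywhere — the
operational meaning of "memory-free". Exponential-cosine inputs give
`delta_mass ≈ λ` and `K ≈ ω²e^(−λτ)`, matching the Laplace-domain oracle
`K̂(s) = 1/ĝ(s) − s`.

**Derivative order and Gregory order.** With second-order central
differences and the plain first Gregory correction, the discretization
residual on a sampled cosine resonates with the kernel recursion and the
extracted `K` drifts by up to 200% over 2000 lags — quantitatively useless
for smooth-kernel work. The shipped defaults are therefore Gregory order 3
and a `deriv_order` switch:

* `deriv_order = 2` (default): 3-point stencils everywhere. This scheme is
  *exactly invertible* by stable forward marching — `reconstruct_acf()`
  undoes `solve_memory_kernel()` to within arithmetic precision at any
  length, so its round-trip diagnostic measures precisely the rounding-error
  propagation the `precision_digits` contract is about (double: ~1e-12;
  100 digits: below 1e-80 on kilolag ACFs, monotone in digits).
* `deriv_order = 4`: 5-point stencils, accurate to < 1e-3 relative on the
  cosine→ω² and damped-cosine oracles over 2000 lags. The price is that the
  exact inverse marching carries a parasitic root of ≈ 13.9 per step
  (the wide stencil solved at its weak edge), so the round-trip check is
  evaluated on a stability-limited prefix: about `0.8·digits/log₁₀(13.9)`
  lags. Use order 4 to *extract* smooth kernels, order 2 when the
  round-trip diagnostic itself is the object of study.

Both backends — C++ doubles for speed, Python's stdlib `decimal` for
arbitrary precision (R ships no big-float arithmetic in this environment) —
implement the identical scheme and agree to ~1e-12 relative; this is
enforced by tests.

```{r kernel-example}
g <- exp(-0.05 * (0:500))                    # Markovian ACF, gamma = 0.05/fs
ker <- solve_memory_kernel(acf_result(g, dt_fs = 1),
                           run_config(precision_digits = NA))
glance(ker)[, c("delta_mass", "roundtrip_error", "support_fs")]
```

## Spectral densities and the zero-quantum rate

`acf_to_spectral_density()` uses the one-sided cosine transform
`J(ω) = 2∫₀^∞ g(t) cos(ωt) dt` with trapezoid end-correction, on an angular
grid up to the Nyquist frequency `π/dt`. The convention (one-sided,
factor 2) is pinned and printed in every output because normalizations vary
across the NMR literature; with it `e^(−t/τ) ↦ 2τ/(1+ω²τ²)` and
`J(0) = 2τ`, and Parseval consistency `∫J dω/π = variance` holds within 1%.
No apodization is applied by default (ACFs are transformed directly); an
optional half-cosine taper for noisy ACFs is recorded in the result when
used.

The scalar cross-relaxation rate estimate is
`R_ZQ = ¼ (2π a_iso)² J(ω_ZQ)` with the hyperfine coupling `a_iso` in Hz
and `J` in seconds. The ¼(2πa)² prefactor is an explicit convention of this
package — treatments differ in how they fold the transition multiplicity
into the spectral density — and every output carries the convention string.
With `a_iso` of a few MHz and `J(ω_ZQ)` around 1e-13–1e-12 s, rates land in
the 0.1–10 s⁻¹ range relevant to observed carbon-13 enhancements.

## Correlation-time spectra (ILT)

`ilt_acf()` solves the CONTIN-style problem: nonnegative weights over a
log-spaced correlation-time grid (default 60 points/decade over
10⁻³–10² ps, spanning sub-0.1 ps initial decays and 0.5–1 ps slow
components with margin), fitted to the ACF with a second-difference
smoothness penalty, by a hand-implemented Lawson–Hanson nonnegative
least-squares solver (no NNLS package ships in this environment). `λ` is
chosen at the L-curve corner (maximum curvature) unless given. Exponential
bases cannot represent negative ACF lobes, so lags after the first zero
crossing are dropped and the truncation is recorded. `summarize_components()`
integrates watershed regions around local maxima carrying ≥ 1% of the mass.
A 0.7/0.3 mixture of 0.05 ps and 0.7 ps exponentials is recovered with both
positions inside one octave and masses within 0.1 — the resolution limit a
user should expect at ACF noise below ~1e-3.

## Autoregressive memory

`fit_ar()` uses conditional least squares (finite-sample bias is smaller
than Yule–Walker's; the `ar.ols` cross-check agrees to 1e-8). The reported
AIC is `n_eff·ln(σ̂²) + 2(p+1)` — Gaussian conditional likelihood, noise
counted as a parameter. Absolute AIC values are software-convention
dependent; only differences and the argmin carry meaning, which is why the
convention string is embedded in the fit. `select_order()` scans
`p = 0..p_max` on a common conditioning window, reports the AIC-minimal
order, its stationarity (companion-matrix spectral radius < 1), and a
coefficient-convergence report: the first order whose shared coefficients
change by < 1% when the order grows. `memory_time = p·dt` converts the
order to physical time — an order-6 model at 1 fs sampling means 6 fs of
time-point memory, the non-Markovian signature that a delta-kernel (OU)
picture cannot produce.

A known property of argmin-AIC selection, inherited here deliberately: it
overselects with asymptotic probability ~15–30% over a scan of several
orders above the truth (the classical `P(χ²₁ > 2) = 0.157` per extra
candidate). Exact-order recovery rates around 70–85% are therefore the
*correct* behavior of this estimator, not a defect; underselection, by
contrast, essentially never occurs when the top coefficient is several
standard errors from zero. The moving-average comparison (`compare_arma`)
only reports ARMA(p,1) AICs side by side; MA terms are never selected
automatically because they have no direct reading as time-point memory.

## What the generators emulate — and what they do not

* `gen_ou()`: exact discrete OU update (`x_{k+1} = x_k e^(−dt/τ) +
  σ√(1−e^(−2dt/τ)) ξ`), stationary start. Emulates memory-free relaxation.
* `gen_pulse_model()`: alternating renewal (telegraph) process —
  exponential off-intervals at the encounter rate, exponential on-intervals
  at the mean contact duration, rectangular amplitude. This is the minimal
  faithful reading of the "pulse" picture of scalar ODNP (contact switches
  on during transient encounters); it does not model any amplitude
  variation within an encounter.
* `gen_ar()`: exact AR(p) recursion with Gaussian innovations, ≥ 10·p
  burn-in, stationarity enforced at spec construction.
* `gen_damped_osc()`: each component `w·e^(−t/τ)cos(ωt)` is realized as a
  rotated pair of independent OU amplitudes
  (`A(t)cos(ωt) − B(t)sin(ωt)`), which has *exactly* the target ACF — the
  same goal as matching AR(2) components, without discretization mismatch.
  Defaults follow the measured phenomenology: sub-0.1 ps initial decay,
  slower 0.5–1.0 ps component, sub-ps oscillation.
* `gen_titration()`: linear-in-concentration paramagnetic shifts with
  Gaussian noise over the 0–200 mM range typical of radical titrations.

All surrogates are Gaussian (or two-valued); real spin-density fluctuations
need not be. A green test therefore establishes that the *estimators* do
what their contracts say on processes with known truth — not that any
particular physical complex behaves like a surrogate. Statistical tests use
3-standard-error bands with batch-means or analytic SEs that account for
serial correlation.

## Numerical choices and degenerate inputs

* Non-finite samples abort every stage (no silent masking).
* Constant channels are a zero-variance error under mean centering.
* `acf_result()` enforces `g[0] = 1` exactly and `|g| ≤ 1 + 1e-9`;
  reconstructed ACFs relax the bound (forward marching carries O(dt²)
  error and may overshoot 1 slightly).
* The kernel recursion checks its pivot against `10^(−digits/2)` and
  aborts with the offending lag index on singularity.
* ILT weights are clamped at 0 by construction (active-set NNLS); an
  all-zero solution with large residual flags a non-decaying input.
* Volumes and lifetimes are returned at full precision; rounding to
  integer nL happens only in display.

## Known limitations

* Kernel extraction from *noisy* sample ACFs amplifies noise like any
  deconvolution; the precision contract controls arithmetic error, not
  statistical error. Use long trajectories or analytic/fitted ACFs for
  quantitative kernel work.
* The order-4 scheme's inverse is usable only on short prefixes (see
  above); this is a property of wide-stencil marching, not of the
  implementation.
* The ZQ-rate prefactor is a declared convention; comparisons across
  software must normalize conventions first.
* The two-state lifetime model takes the association rate constant as
  user input (default diffusion-limited 1e10 M⁻¹s⁻¹); it does not infer
  it from data.
* The saturation factor of the microwave pumping is out of scope: it
  requires coupling/leakage factors that are not part of this package's
  inputs.
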