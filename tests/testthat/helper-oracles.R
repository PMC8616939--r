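# shared fixtures and brute-force oracles, all built in code at test time

# batch-means standard error of the sample ACF at one lag: split the series
# into blocks, estimate the normalized ACF per block, take the SE of the
# block mean; independent of the estimator under test
block_se_acf <- function(x, lag, blocks = 20L) {
  n <- length(x)
  bs <- floor(n / blocks)
  vals <- vapply(seq_len(blocks), function(b) {
    xb <- x[((b - 1L) * bs + 1L):(b * bs)]
    xb <- xb - mean(xb)
    sum(xb[1:(bs - lag)] * xb[(1 + lag):bs]) / (bs - lag) / (sum(xb^2) / bs)
  }, numeric(1))
  sd(vals) / sqrt(blocks)
}

# damped-oscillation world mirroring the measured spin-density ACF shape:
# fast sub-0.1 ps decay plus a slower 0.5-1 ps component
ref_two_tau_spec <- function() {
  damped_osc_spec(data.frame(
    decay_ps = c(0.05, 0.7),
    omega_rad_ps = c(0, 0),
    weight = c(0.7, 0.3)
  ))
}

# oscillatory world: initial decay with a sub-ps wave
ref_wave_spec <- function() {
  damped_osc_spec(data.frame(
    decay_ps = c(0.05, 0.7),
    omega_rad_ps = c(2 * pi / 0.3, 0),
    weight = c(0.7, 0.3)
  ))
}

# reference AR(6) world: Yule-Walker projection of a damped-oscillator fit
# with structure at the few-fs scale (3 fs decay, 10 fs wave period), the
# regime where a 6-step memory at 1 fs sampling is physically meaningful
ref_ar6_spec <- function() {
  ar_spec_from_damped_osc(
    damped_osc_spec(data.frame(
      decay_ps = c(0.003, 0.02),
      omega_rad_ps = c(2 * pi / 0.010, 0),
      weight = c(0.7, 0.3)
    )),
    p = 6L, dt_fs = 1
  )
}

# analytic two-component ACF sampled on an fs grid
bi_exp_acf <- function(n_lags = 3000L, dt_fs = 1) {
  t_fs <- (0:(n_lags - 1L)) * dt_fs
  acf_result(0.7 * exp(-t_fs / 50) + 0.3 * exp(-t_fs / 700), dt_fs)
}

double_cfg <- function(...) run_config(precision_digits = NA, ...)
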