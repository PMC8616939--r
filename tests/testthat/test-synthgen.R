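test_that("generators are seed-deterministic and emit valid trajectories", {
  gens <- list(
    function(s) gen_ou(ou_spec(0.1), n = 500, seed = s),
    function(s) gen_pulse_model(pulse_spec(10, 0.05), n = 500, seed = s),
    function(s) gen_ar(ar_spec(c(0.5, -0.2)), n = 500, seed = s),
    function(s) gen_damped_osc(ref_wave_spec(), n = 500, seed = s)
  )
  for (gen in gens) {
    a <- gen(7L); b <- gen(7L); c3 <- gen(8L)
    expect_identical(a$x, b$x)
    expect_false(identical(a$x, c3$x))
    expect_s3_class(a, "odnp_traj")
    expect_equal(nrow(a), 500L)
  }
})

test_that("zero-noise limits are exact", {
  expect_equal(gen_ou(ou_spec(0.1, sigma = 0, mean = 0.3), n = 100, seed = 1)$x,
               rep(0.3, 100))
  expect_equal(gen_pulse_model(pulse_spec(1, 0.1, amplitude = 0),
                               n = 100, seed = 1)$x, rep(0, 100))
})

test_that("OU sample ACF matches the closed form within 3 batch-means SE", {
  # tau = 0.1 ps, dt = 1 fs: g(0.1 ps) = e^-1
  trj <- gen_ou(ou_spec(0.1), n = 1e5, dt_fs = 1, seed = 42)
  a <- compute_acf(trj, "x", double_cfg(max_lag_fraction = 0.01))
  se <- block_se_acf(trj$x, lag = 100L)
  expect_lt(abs(a$g[101] - exp(-1)), 3 * se)
})

test_that("pulse-model occupancy matches renewal theory within 3 SE", {
  # rate 1/ps, duration 0.1 ps: on-fraction = 0.1/(1 + 0.1) = 1/11
  spec <- pulse_spec(1, 0.1)
  trj <- gen_pulse_model(spec, n = 1e6, dt_fs = 1, seed = 3)
  p_on <- 1 / 11
  t_total_ps <- 1e6 * 1e-3
  tau_mix <- 1 / (spec$rate + 1 / spec$duration)
  # variance of the time average of a two-state Markov process
  se <- sqrt(2 * p_on * (1 - p_on) * tau_mix / t_total_ps)
  expect_lt(abs(mean(trj$x > 0) - p_on), 3 * se)
})

test_that("pulse-model ACF decays on the telegraph mixing time scale", {
  spec <- pulse_spec(1, 0.1)
  trj <- gen_pulse_model(spec, n = 1e6, dt_fs = 1, seed = 3)
  a <- compute_acf(trj, "x", double_cfg(max_lag_fraction = 3e-4))
  fit <- lm(log(pmax(a$g[2:80], 1e-8)) ~ a$lag_fs[2:80])
  tau_fit_ps <- -1 / coef(fit)[2] / 1000
  tau_mix <- 1 / (spec$rate + 1 / spec$duration)   # 0.0909 ps
  expect_lt(abs(tau_fit_ps - tau_mix) / tau_mix, 0.3)
})

test_that("AR(1) generators have the theoretical lag-1 correlation", {
  n <- 1e4
  white <- gen_ar(ar_spec(0), n = n, seed = 5)
  aw <- compute_acf(white, "x", double_cfg(max_lag_fraction = 0.001))
  expect_lt(abs(aw$g[2]), 3 / sqrt(n))
  trj <- gen_ar(ar_spec(0.9), n = n, seed = 6)
  a <- compute_acf(trj, "x", double_cfg(max_lag_fraction = 0.001))
  se <- block_se_acf(trj$x, lag = 1L)
  expect_lt(abs(a$g[2] - 0.9), 3 * se)
})

test_that("non-stationary AR specs are rejected naming the spectral radius", {
  expect_error(ar_spec(c(0.9, 0.2)), "spectral radius")
  expect_error(ar_spec(1.01), "spectral radius")
})

test_that("damped-oscillation surrogate reduces to OU at omega = 0", {
  spec <- damped_osc_spec(data.frame(decay_ps = 0.1, omega_rad_ps = 0,
                                     weight = 1))
  trj <- gen_damped_osc(spec, n = 1e5, dt_fs = 1, seed = 9)
  a <- compute_acf(trj, "x", double_cfg(max_lag_fraction = 0.01))
  se <- block_se_acf(trj$x, lag = 100L)
  expect_lt(abs(a$g[101] - exp(-1)), 3 * se)
})

test_that("oscillatory surrogate ACF has its first negative lobe at the closed-form position", {
  # g(t) = e^{-t/tau} cos(om t): minimum at t* = (pi - atan(om tau)) / om
  tau <- 0.05; om <- 2 * pi / 0.3
  spec <- damped_osc_spec(data.frame(decay_ps = tau, omega_rad_ps = om,
                                     weight = 1))
  trj <- gen_damped_osc(spec, n = 2e5, dt_fs = 1, seed = 10)
  a <- compute_acf(trj, "x", double_cfg(max_lag_fraction = 0.002))
  t_star_fs <- (pi - atan(om * tau)) / om * 1000
  lobe_fs <- a$lag_fs[which.min(a$g)]
  expect_lt(abs(lobe_fs - t_star_fs), 20)
  expect_lt(min(a$g), 0)   # the lobe is genuinely negative
})

test_that("damped-oscillation specs validate weights and decay times", {
  expect_error(damped_osc_spec(data.frame(decay_ps = c(0.1, -1),
                                          omega_rad_ps = c(0, 0),
                                          weight = c(0.5, 0.5))), "> 0")
  expect_error(damped_osc_spec(data.frame(decay_ps = c(0.1, 0.2),
                                          omega_rad_ps = c(0, 0),
                                          weight = c(0.5, 0.6))), "sum to 1")
})

test_that("titration generator is exact at zero noise and unbiased otherwise", {
  tt <- gen_titration(2, intercept_ppm = 1, conc_M = c(0, 0.1, 0.2),
                      noise_sd_ppm = 0, seed = 1)
  expect_equal(tt$C1, 1 + 2 * tt$conc_M)
  # slope-0 series: estimate within 3 fit SE of 0
  t0 <- gen_titration(0, conc_M = c(0, 0.05, 0.1, 0.2),
                      noise_sd_ppm = 0.01, seed = 2)
  fit <- molar_free_shift(t0)
  expect_lt(abs(fit$delta_para_bar), 3 * fit$fit_error)
})
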