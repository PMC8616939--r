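test_that("exponential ACF transforms to the Lorentzian closed form", {
  tau <- 0.1                              # ps
  g <- exp(-(0:9999) / 100)               # dt = 1 fs
  a <- acf_result(g, 1)
  om <- 10^seq(-1, 2, length.out = 200)   # omega * tau from 0.01 to 10
  J <- spectral_density_at(a, om)
  Jex <- 2 * tau / (1 + om^2 * tau^2)
  expect_lt(max(abs(J - Jex) / Jex), 1e-3)
  expect_lt(abs(spectral_density_at(a, 0) - 2 * tau) / (2 * tau), 1e-3)
})

test_that("Lorentzian agreement holds across four decades of omega", {
  tau <- 0.1
  g <- exp(-(0:19999) / 100)
  a <- acf_result(g, 1)
  om <- 10^seq(-2, 2, length.out = 100)
  J <- spectral_density_at(a, om)
  Jex <- 2 * tau / (1 + om^2 * tau^2)
  expect_lt(max(abs(J - Jex) / Jex), 5e-3)
})

test_that("damped-oscillator ACF peaks near omega0 with Lorentzian half-width", {
  # closed form: J(w) = lam/(lam^2 + (w - w0)^2) + lam/(lam^2 + (w + w0)^2)
  lam <- 5; om0 <- 20                     # ps^-1, rad/ps
  t_ps <- (0:7999) / 1000
  g <- exp(-lam * t_ps) * cos(om0 * t_ps)
  a <- acf_result(g, 1)
  sd_ <- acf_to_spectral_density(a, n_omega = 4096)
  Jex <- function(om) lam / (lam^2 + (om - om0)^2) +
    lam / (lam^2 + (om + om0)^2)
  peak_ex <- optimize(Jex, c(10, 30), maximum = TRUE)$maximum
  peak <- sd_$omega_rad_ps[which.max(sd_$J)]
  grid_step <- diff(sd_$omega_rad_ps[1:2])
  expect_lt(abs(peak - peak_ex), grid_step)
  expect_lt(abs(peak - om0), 2 * lam / om0 + grid_step)  # shift ~ lam^2/om0
  # half-width at half-maximum against the closed form (~ lam)
  Jmax <- max(sd_$J)
  above <- sd_$omega_rad_ps[sd_$J > Jmax / 2]
  hwhm <- (max(above) - min(above)) / 2
  half <- function(om) Jex(om) - Jex(peak_ex) / 2
  hw_ex <- (uniroot(half, c(peak_ex, 200))$root -
            uniroot(half, c(0.01, peak_ex))$root) / 2
  expect_lt(abs(hwhm - hw_ex) / hw_ex, 0.1)
  expect_lt(abs(hwhm - lam) / lam, 0.25)
})

test_that("Parseval: int J domega / pi returns the lag-0 covariance within 1%", {
  trj <- gen_damped_osc(ref_two_tau_spec(), n = 40000, seed = 14)
  a <- compute_acf(trj, "x", double_cfg(max_lag_fraction = 0.25))
  sd_ <- acf_to_spectral_density(a, normalized = FALSE, n_omega = 4096)
  integ <- sum((sd_$J[-1] + sd_$J[-nrow(sd_)]) / 2 *
               diff(sd_$omega_rad_ps)) / pi
  expect_lt(abs(integ - attr(a, "variance")) / attr(a, "variance"), 0.01)
})

test_that("negative excursions from truncation are small and reported", {
  t_ps <- (0:2999) / 1000
  g <- damped_osc_acf(ref_wave_spec(), t_ps)
  sd_ <- acf_to_spectral_density(acf_result(g, 1))
  expect_gt(attr(sd_, "min_J"), -0.02 * max(sd_$J))
  expect_equal(attr(sd_, "windowing"), "none")
})

test_that("ZQ frequency reproduces the 9.4 T value of 0.263 THz (1.65e12 rad/s)", {
  zq <- zq_frequency(zq_params(nu_e_ghz = 263, nu_c_ghz = 0.1006))
  expect_equal(zq$nu_thz, 0.263, tolerance = 2e-3)
  expect_equal(zq$omega_thz, 1.65, tolerance = 2e-3)
  expect_equal(zq$omega_rad_ps, 2 * pi * 0.2629, tolerance = 1e-3)
})

test_that("ZQ frequency degenerates and scales by gyromagnetic arithmetic", {
  expect_error(zq_params(1, 1), "nu_e > nu_c")
  pc <- physical_constants()
  # X-band: 9.2 GHz electron; the 13C Larmor frequency follows from the
  # gyromagnetic ratio quotient
  nu_c <- 9.2 * abs(pc$gamma_c13 / pc$gamma_e)
  expect_equal(nu_c * 1000, 3.52, tolerance = 0.01)   # MHz
  zq <- zq_frequency(zq_params(9.2, nu_c))
  expect_equal(zq$nu_thz * 1000, 9.196, tolerance = 0.01)  # ~9.2 GHz
})

test_that("ZQ rate follows the declared (1/4)(2 pi a)^2 J convention", {
  p0 <- zq_params(263, 0.1006, a_iso_mhz = 0)
  expect_equal(estimate_zq_rate(1e-13, p0)$rate_per_s, 0)
  p1 <- zq_params(263, 0.1006, a_iso_mhz = 1)
  r1 <- estimate_zq_rate(1e-13, p1)
  expect_equal(r1$rate_per_s, 0.25 * (2 * pi * 1e6)^2 * 1e-13)
  expect_equal(r1$rate_per_s, 0.9870, tolerance = 1e-3)
  p2 <- zq_params(263, 0.1006, a_iso_mhz = 2)
  expect_equal(estimate_zq_rate(1e-13, p2)$rate_per_s / r1$rate_per_s, 4)
  # monotone in J
  expect_gt(estimate_zq_rate(2e-13, p1)$rate_per_s, r1$rate_per_s)
  expect_warning(rneg <- estimate_zq_rate(-1e-13, p1), "clamped")
  expect_equal(rneg$rate_per_s, 0)
  expect_true(rneg$clamped)
})
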