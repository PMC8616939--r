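# Laplace-domain oracles: for g with transform ghat(s), the memory kernel is
# Khat(s) = 1/ghat(s) - s.  cos(om t) -> K = om^2 constant;
# e^{-lam t} cos(om t) -> K = lam delta(tau) + om^2 e^{-lam tau};
# e^{-gam t} (Markovian) -> K = gam delta(tau) only.

test_that("cosine ACF yields a constant om^2 kernel (order 4, < 1e-3)", {
  om <- 2 * pi / 100
  g <- cos(om * (0:2100))
  ker <- solve_memory_kernel(acf_result(g, 1),
                             double_cfg(deriv_order = 4))
  dev <- abs(ker$K - om^2) / om^2
  expect_lt(max(dev[4:2000]), 1e-3)
  expect_lt(abs(attr(ker, "delta_mass")), 1e-6)
})

test_that("exponentially damped cosine splits into delta mass and decaying kernel", {
  lam <- 0.005; om <- 2 * pi / 80
  t <- 0:2100
  g <- exp(-lam * t) * cos(om * t)
  ker <- solve_memory_kernel(acf_result(g, 1), double_cfg(deriv_order = 4))
  expect_lt(abs(attr(ker, "delta_mass") - lam) / lam, 1e-2)
  oracle <- om^2 * exp(-lam * ker$lag_fs)
  expect_lt(max(abs(ker$K[6:1500] - oracle[6:1500])) / om^2, 1e-3)
})

test_that("a Markovian (OU) ACF has a pure delta kernel: regular part negligible", {
  gam <- 0.05
  g <- exp(-gam * (0:2000))
  ker <- solve_memory_kernel(acf_result(g, 1), double_cfg())
  a <- attr(ker, "delta_mass")
  expect_lt(abs(a - gam) / gam, 1e-2)
  # operationalizes "memory-free": regular kernel beyond 3 dt is < 1e-3 of
  # the spike's grid density a/dt
  expect_lt(max(abs(ker$K[-(1:3)])), 1e-3 * a / 1)
})

test_that("zero kernel reconstructs a constant ACF exactly", {
  g <- reconstruct_acf(memory_kernel(rep(0, 400), 1))
  expect_equal(g$g, rep(1, nrow(g)))
})

test_that("constant kernel om^2 reconstructs cos(om t) to 1e-6 over 10 periods", {
  spp <- 12800L                      # steps per period; error scales as dt^2
  om <- 2 * pi / spp
  g <- reconstruct_acf(memory_kernel(rep(om^2, 10L * spp), 1))
  expect_lt(max(abs(g$g - cos(om * (0:(nrow(g) - 1))))), 1e-6)
})

test_that("solve and reconstruct are mutual inverses on both sides (order 2)", {
  om <- 2 * pi / 100
  g <- cos(om * (0:1200))
  ker <- solve_memory_kernel(acf_result(g, 1), double_cfg())
  # g side: stored round trip
  expect_lt(attr(ker, "roundtrip_error"), 1e-10)
  # K side: reconstruct then re-solve
  g_rec <- reconstruct_acf(ker)
  ker2 <- solve_memory_kernel(acf_result(g_rec$g, 1, tolerance = Inf),
                              double_cfg())
  expect_lt(max(abs(ker2$K[-1] - ker$K[-1][seq_along(ker2$K[-1])])), 1e-8)
  expect_lt(abs(attr(ker2, "delta_mass") - attr(ker, "delta_mass")), 1e-10)
})

test_that("1000-lag exponential ACF round-trips below 1e-10 at 100 digits", {
  g <- exp(-0.02 * (0:999))
  ker <- solve_memory_kernel(acf_result(g, 1),
                             run_config(precision_digits = 100))
  expect_lt(attr(ker, "roundtrip_error"), 1e-10)
})

test_that("round-trip error shrinks monotonically with precision, lag by lag", {
  t <- 0:400
  g <- damped_osc_acf(ref_wave_spec(), t / 1000)
  a <- acf_result(g, 1)
  rep_tbl <- precision_drift_report(a, digits_list = c(NA, 30L, 50L, 100L))
  s <- attr(rep_tbl, "summary")
  err <- setNames(s$max_err, s$precision)
  expect_lt(err[["100"]], err[["50"]])
  expect_lt(err[["50"]], err[["30"]])
  expect_lt(err[["30"]], err[["double"]])
  # elementwise: 100-digit error never exceeds the 50-digit error (both are
  # far below any physical scale; the 1e-100 slack covers lags where one
  # reconstruction lands exactly on the stored double)
  wide <- tidyr::pivot_wider(rep_tbl, names_from = "precision",
                             values_from = "abs_err")
  expect_true(all(wide[["100"]] <= wide[["50"]] + 1e-100))
})

test_that("double and decimal backends implement the same discretization", {
  g <- cos(2 * pi * (0:400) / 100)
  kd <- solve_memory_kernel(acf_result(g, 1), double_cfg())
  ks <- solve_memory_kernel(acf_result(g, 1), run_config(precision_digits = 30))
  expect_lt(max(abs(kd$K - ks$K)) / max(abs(ks$K)), 1e-11)
  expect_lt(abs(attr(kd, "delta_mass") - attr(ks, "delta_mass")), 1e-12)
})

test_that("kernel support is tens of fs, far shorter than the ACF decay", {
  # surrogate with correlation structure at 5 fs and 50 fs: the kernel of a
  # two-exponential mixture decays at the weight-mixed rate, here ~110/ps
  spec <- damped_osc_spec(data.frame(decay_ps = c(0.005, 0.05),
                                     omega_rad_ps = c(0, 0),
                                     weight = c(0.5, 0.5)))
  g <- damped_osc_acf(spec, (0:400) / 1000)
  ker <- solve_memory_kernel(acf_result(g, 1), double_cfg())
  support <- kernel_support_fs(ker)
  expect_gt(support, 5)
  expect_lt(support, 100)
  # the ACF itself needs ~196 fs to fall to 1% of g(0)
  acf_1pc_fs <- (0:400)[which(g < 0.01)[1]]
  expect_lt(support, acf_1pc_fs)
})

test_that("order-4 kernels report a stability-limited round-trip prefix", {
  g <- cos(2 * pi * (0:600) / 100)
  ker <- solve_memory_kernel(acf_result(g, 1), double_cfg(deriv_order = 4))
  rt <- attr(ker, "roundtrip")
  expect_lt(nrow(rt), 20)            # double precision: ~8 usable lags
  expect_lt(attr(ker, "roundtrip_error"), 1e-4)
  ker_hp <- solve_memory_kernel(acf_result(g, 1),
                                run_config(precision_digits = 60,
                                           deriv_order = 4))
  expect_gt(nrow(attr(ker_hp, "roundtrip")), nrow(rt))
  expect_lt(attr(ker_hp, "roundtrip_error"), 1e-8)
})

test_that("too-short ACFs are rejected", {
  expect_error(solve_memory_kernel(acf_result(c(1, 0.9, 0.8), 1),
                                   double_cfg()), "too short")
})
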