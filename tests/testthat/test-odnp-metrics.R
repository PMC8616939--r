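test_that("enhancement factor follows the scan-normalized ratio convention", {
  expect_equal(enhancement(1, 1)$epsilon, 0)
  expect_equal(enhancement(51, 1)$epsilon, 50)        # imidazole-scale gain
  expect_equal(enhancement(-10, 1)$epsilon, -11)      # carboxylate-type sign
  expect_equal(enhancement(10, 2, n_dnp = 4, n_boltz = 8)$epsilon,
               (10 / 2) * (8 / 4) - 1)
})

test_that("enhancement is invariant under common rescaling and consistent scan swap", {
  base <- enhancement(17, 3, n_dnp = 8, n_boltz = 4)$epsilon
  expect_equal(enhancement(17 * 5, 3 * 5, n_dnp = 8, n_boltz = 4)$epsilon, base)
  # swapping scan counts on both channels consistently rescales integrals too
  expect_equal(enhancement(17 / 8, 3 / 4, n_dnp = 1, n_boltz = 1)$epsilon, base)
})

test_that("the symmetric null case gives delta_epsilon = sqrt(2)/SNR exactly", {
  rec <- enhancement(1, 1, snr_dnp = 100, snr_boltz = 100)
  expect_equal(rec$epsilon, 0)
  expect_equal(rec$delta_epsilon, sqrt(2) / 100)
})

test_that("analytic error propagation matches Monte-Carlo within 5% at SNR >= 10", {
  cases <- list(
    list(i_dnp = 51, i_boltz = 1, snr_dnp = 120, snr_boltz = 15),
    list(i_dnp = 5, i_boltz = 2, snr_dnp = 10, snr_boltz = 10),
    list(i_dnp = -10, i_boltz = 1, snr_dnp = 30, snr_boltz = 20)
  )
  set.seed(99)
  for (cs in cases) {
    rec <- enhancement(cs$i_dnp, cs$i_boltz,
                       snr_dnp = cs$snr_dnp, snr_boltz = cs$snr_boltz)
    n_mc <- 1e5
    id <- rnorm(n_mc, cs$i_dnp, 1 / cs$snr_dnp)
    ib <- rnorm(n_mc, cs$i_boltz, 1 / cs$snr_boltz)
    mc_sd <- sd(id / ib - 1)
    expect_lt(abs(rec$delta_epsilon - mc_sd) / mc_sd, 0.05)
  }
})

test_that("degenerate enhancement inputs are rejected", {
  expect_error(enhancement(1, 0), "nonzero")
  expect_error(enhancement(1, 1, snr_dnp = -1), "> 0")
  expect_error(enhancement(Inf, 1), "finite")
})

test_that("molar-free shifts recover exact lines with zero fit error", {
  tt <- gen_titration(2, intercept_ppm = 0.5, conc_M = c(0, 0.1, 0.2),
                      noise_sd_ppm = 0, seed = 1)
  fit <- molar_free_shift(tt)
  expect_equal(fit$delta_para_bar, 2, tolerance = 1e-10)
  expect_lt(fit$fit_error, 1e-10)
  # concentration-independent shifts
  flat <- tibble::tibble(conc_M = c(0, 0.1, 0.2), C1 = rep(3, 3))
  expect_equal(molar_free_shift(flat)$delta_para_bar, 0)
})

test_that("the slope estimator is unbiased over seeded titrations", {
  slopes <- vapply(1:100, function(s) {
    tt <- gen_titration(5, conc_M = c(0, 0.05, 0.1, 0.15, 0.2),
                        noise_sd_ppm = 0.02, seed = 200 + s)
    molar_free_shift(tt)$delta_para_bar
  }, numeric(1))
  se_mean <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 5), 3 * se_mean)
})

test_that("overlapping carbons get a pooled slope standard deviation", {
  tt <- gen_titration(5, conc_M = c(0, 0.05, 0.1, 0.2), seed = 3)
  tt$C2 <- gen_titration(5.4, conc_M = c(0, 0.05, 0.1, 0.2), seed = 4)$C1
  fit <- molar_free_shift(tt, overlap = c("C1", "C2"))
  expect_equal(fit$overlap_sd[1], sd(fit$delta_para_bar))
  expect_error(molar_free_shift(tt, overlap = "C9"), "unknown overlap")
  expect_error(molar_free_shift(tibble::tibble(conc_M = c(1, 1, 1),
                                               C1 = c(1, 2, 3))),
               "rank-deficient")
})

test_that("complex lifetimes follow the two-state dissociation model", {
  expect_equal(complex_lifetime(K_a = 1, k_on = 1e10), 100)    # H-bond regime
  expect_equal(complex_lifetime(K_a = 0.01, k_on = 1e10), 1)   # halogen-bond
  expect_equal(complex_lifetime(K_a = 5, k_on = 1e10),
               5 * complex_lifetime(K_a = 1, k_on = 1e10))
  expect_error(complex_lifetime(K_a = -1), "> 0")
})

test_that("capillary volumes reproduce the resonator bookkeeping", {
  v100 <- capillary_volume(100, 4.5)
  v50 <- capillary_volume(50, 4.5)
  expect_equal(round(v100), 35)
  expect_equal(round(v50), 9)
  expect_equal(v100, 35.34, tolerance = 1e-3)
  expect_equal(v50, 8.836, tolerance = 1e-3)
  expect_equal(capillary_volume(100, 0), 0)
})

test_that("gyromagnetic ratios round to the canonical -658 and -2617", {
  pc <- physical_constants()
  expect_equal(round(pc$gamma_e_over_h1), -658)
  expect_equal(round(pc$gamma_e_over_c13), -2617)
})
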