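#' ODNP enhancement factor with propagated error
#'
#' The Overhauser enhancement is
#' `epsilon = (I_dnp / I_boltz) * (n_boltz / n_dnp) - 1`,
#' the microwave-on signal integral referenced to the thermal (Boltzmann)
#' integral after scan-count normalization. Its uncertainty follows from
#' Gaussian error propagation over the two integrals,
#' `delta_epsilon = sqrt((d eps/d I_dnp)^2 dI_dnp^2 +
#' (d eps/d I_boltz)^2 dI_boltz^2)`, with each integral error taken as the
#' reciprocal of that spectrum's signal-to-noise ratio.
#'
#' @param i_dnp,i_boltz signal integrals with and without microwave
#'   irradiation (arbitrary units; `i_boltz != 0`).
#' @param n_dnp,n_boltz scan counts (>= 1).
#' @param snr_dnp,snr_boltz signal-to-noise ratios (> 0).
#' @param label optional site label.
#' @return An `enhancement_record` tibble row with `epsilon` and
#'   `delta_epsilon` alongside the inputs.
#' @examples
#' enhancement(51, 1, snr_dnp = 120, snr_boltz = 15)   # 50-fold enhancement
#' @export
enhancement <- function(i_dnp, i_boltz, n_dnp = 1L, n_boltz = 1L,
                        snr_dnp = Inf, snr_boltz = Inf, label = NA_character_) {
  if (!all(is.finite(c(i_dnp, i_boltz)))) abort("integrals must be finite")
  if (any(i_boltz == 0)) abort("I_boltzmann must be nonzero (undefined reference)")
  if (any(c(n_dnp, n_boltz) < 1)) abort("scan counts must be >= 1")
  if (any(c(snr_dnp, snr_boltz) <= 0)) abort("signal-to-noise ratios must be > 0")
  scan_ratio <- n_boltz / n_dnp
  eps <- (i_dnp / i_boltz) * scan_ratio - 1
  di_dnp <- 1 / snr_dnp
  di_boltz <- 1 / snr_boltz
  d_eps <- sqrt((scan_ratio / i_boltz)^2 * di_dnp^2 +
                (scan_ratio * i_dnp / i_boltz^2)^2 * di_boltz^2)
  new_tibble(
    tibble(label = label, i_dnp = i_dnp, i_boltz = i_boltz,
           n_dnp = n_dnp, n_boltz = n_boltz,
           snr_dnp = snr_dnp, snr_boltz = snr_boltz,
           epsilon = eps, delta_epsilon = d_eps),
    class = "enhancement_record"
  )
}

#' Molar-free paramagnetic shift from a titration series
#'
#' Fits observed chemical shift versus radical concentration per carbon by
#' ordinary least squares; the slope is the molar-free paramagnetic shift
#' (ppm/M), the error its fit standard error. For carbons whose signals
#' overlap in the DNP spectra, the standard deviation of their slopes is
#' reported as a pooled `overlap_sd`.
#'
#' @param series data frame with `conc_M` in the first column and one shift
#'   column (ppm) per carbon.
#' @param overlap optional character vector of carbon labels whose signals
#'   overlap.
#' @return A `para_shift_result` tibble: per carbon `delta_para_bar`
#'   (ppm/M), `fit_error` (ppm/M), `intercept_ppm`, `overlap_sd`.
#' @examples
#' tt <- gen_titration(5, conc_M = c(0, 0.05, 0.1, 0.2), seed = 2)
#' molar_free_shift(tt)
#' @export
molar_free_shift <- function(series, overlap = NULL) {
  series <- as_tibble(series)
  names(series)[1L] <- "conc_M"
  conc <- series$conc_M
  if (length(conc) < 3L) abort("need at least 3 concentrations")
  if (length(unique(conc)) < 2L) {
    abort("all concentrations identical: slope is rank-deficient")
  }
  carbons <- names(series)[-1L]
  sxx <- sum((conc - mean(conc))^2)
  out <- purrr::map_dfr(carbons, function(cb) {
    fit <- lm(series[[cb]] ~ conc)
    # slope SE computed directly so an exact line gives 0 without noise
    s2 <- sum(stats::residuals(fit)^2) / (length(conc) - 2L)
    tibble(
      carbon = cb,
      delta_para_bar = unname(coef(fit)[2L]),
      fit_error = sqrt(s2 / sxx),
      intercept_ppm = unname(coef(fit)[1L])
    )
  })
  out$overlap_sd <- NA_real_
  if (!is.null(overlap)) {
    bad <- setdiff(overlap, carbons)
    if (length(bad)) abort(sprintf("unknown overlap carbon(s): %s",
                                   paste(bad, collapse = ", ")))
    sd_ov <- sd(out$delta_para_bar[out$carbon %in% overlap])
    out$overlap_sd[out$carbon %in% overlap] <- sd_ov
  }
  new_tibble(out, class = "para_shift_result")
}

#' @export
autoplot.para_shift_result <- function(object, ...) {
  ggplot2::ggplot(as_tibble(as.data.frame(object)),
                  ggplot2::aes(.data$carbon, .data$delta_para_bar)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$delta_para_bar - .data$fit_error,
      ymax = .data$delta_para_bar + .data$fit_error), width = 0.3) +
    ggplot2::labs(x = NULL, y = expression(bar(delta)[para] ~ (ppm / M)))
}

#' Radical-substrate complex lifetime from binding parameters
#'
#' Two-state dissociation model: `k_off = k_on / K_a` and the complex
#' lifetime is `1 / k_off = K_a / k_on`. H-bonded radical-substrate
#' complexes have binding constants of order 0.1-1 per molar, halogen-bonded
#' ones of order 0.01 per molar; with a diffusion-limited association rate
#' constant (default 1e10 per molar per second) these translate to
#' lifetimes of 10-100 ps versus about 1 ps -- the former mismatching the
#' sub-ps fluctuations that high-field ODNP needs, which is why
#' intra-complex dynamics rather than complex formation-dissociation must
#' drive scalar ODNP in long-living H-bonded complexes.
#'
#' @param K_a association constant, per molar (> 0).
#' @param k_on association rate constant, per molar per second (> 0);
#'   default diffusion-limited 1e10.
#' @return lifetime in ps.
#' @examples
#' complex_lifetime(K_a = 1)      # 100 ps
#' complex_lifetime(K_a = 0.01)   # 1 ps, halogen-bond regime
#' @export
complex_lifetime <- function(K_a, k_on = 1e10) {
  if (any(K_a <= 0) || any(k_on <= 0)) abort("K_a and k_on must be > 0")
  (K_a / k_on) * 1e12
}

#' Active sample volume of a capillary resonator section
#'
#' Cylinder volume `pi (d/2)^2 l` for a capillary of inner diameter `d`
#' inside a microwave cavity of active length `l`. Reported exactly in nL;
#' round for display (a 100 um capillary in a 4.5 mm cavity holds 35 nL,
#' a 50 um one 9 nL).
#'
#' @param inner_diameter_um capillary inner diameter, micrometers.
#' @param length_mm active (cavity) length, millimeters.
#' @return volume in nL (full precision; not rounded).
#' @export
capillary_volume <- function(inner_diameter_um, length_mm) {
  if (any(inner_diameter_um < 0) || any(length_mm < 0)) {
    abort("dimensions must be nonnegative")
  }
  r_mm <- inner_diameter_um / 2 / 1000
  pi * r_mm^2 * length_mm * 1000   # mm^3 -> uL -> nL
}

#' Physical constants for ODNP bookkeeping
#'
#' CODATA gyromagnetic ratios of the free electron, proton and carbon-13,
#' and the derived electron/nucleus ratios that set the ceiling of
#' Overhauser enhancements: about -658 for protons and -2617 for
#' carbon-13.
#'
#' @return list with `gamma_e`, `gamma_h1`, `gamma_c13` (rad s^-1 T^-1)
#'   and the ratios `gamma_e_over_h1`, `gamma_e_over_c13`.
#' @export
physical_constants <- function() {
  gamma_e <- -1.76085963023e11   # rad s^-1 T^-1 (CODATA 2018)
  gamma_h1 <- 2.6752218744e8
  gamma_c13 <- 6.728284e7
  list(
    gamma_e = gamma_e,
    gamma_h1 = gamma_h1,
    gamma_c13 = gamma_c13,
    gamma_e_over_h1 = gamma_e / gamma_h1,
    gamma_e_over_c13 = gamma_e / gamma_c13
  )
}
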