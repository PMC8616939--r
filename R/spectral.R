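#' Spectral density of an ACF (one-sided cosine transform)
#'
#' Transforms a normalized ACF to the spectral density
#' `J(omega) = 2 * integral_0^inf g(t) cos(omega t) dt`
#' by discrete cosine transform with trapezoid end-correction. This
#' one-sided, factor-2 convention is pinned here and recorded in every
#' output because spectral-density normalizations differ across the NMR
#' literature; with it, an exponential ACF `exp(-t/tau)` maps to the
#' Lorentzian `2 tau / (1 + omega^2 tau^2)` and `J(0) = 2 tau`.
#' The unnormalized variant multiplies by the stored lag-0 variance
#' (units au^2 ps); the normalized variant has units ps.
#'
#' @param acf an `acf_result`.
#' @param normalized if `FALSE`, scales `J` by the ACF's variance attribute.
#' @param n_omega number of angular-frequency grid points; the grid spans
#'   0 to `pi/dt` (rad/ps), the Nyquist angular frequency.
#' @param window `"none"` (default; ACFs are transformed directly) or
#'   `"cosine"` (half-cosine taper for noisy ACFs); recorded in the result.
#' @return A `spectral_density`: tibble with `omega_rad_ps` and `J`, plus
#'   attributes `convention`, `normalized`, `windowing`, `variance`.
#' @examples
#' g <- exp(-(0:4999) / 100)        # tau = 0.1 ps at dt = 1 fs
#' J <- acf_to_spectral_density(acf_result(g, dt_fs = 1))
#' J$J[1]                           # ~ 2 * 0.1 ps
#' @export
acf_to_spectral_density <- function(acf, normalized = TRUE, n_omega = 1024L,
                                    window = c("none", "cosine")) {
  stopifnot(inherits(acf, "acf_result"))
  window <- match.arg(window)
  dt_ps <- attr(acf, "dt_fs") / 1000
  t_ps <- acf$lag_fs / 1000
  g <- acf$g
  K <- length(g)
  if (window == "cosine") {
    g <- g * cos(pi * seq(0, K - 1) / (2 * (K - 1)))
  }
  omega <- seq(0, pi / dt_ps, length.out = n_omega)
  wts <- rep(1, K)
  wts[c(1L, K)] <- 0.5
  # J(omega) = 2 dt sum'' g_k cos(omega t_k); outer product kept as a
  # matrix-vector product for speed
  J <- 2 * dt_ps * as.numeric(cos(outer(omega, t_ps)) %*% (wts * g))
  v <- attr(acf, "variance")
  if (!normalized) {
    if (is.na(v)) abort("ACF carries no variance; cannot unnormalize")
    J <- J * v
  }
  neg <- min(J)
  new_tibble(
    tibble(omega_rad_ps = omega, J = J),
    convention = "one-sided cosine transform, J(w) = 2 Int_0^Inf g(t) cos(wt) dt",
    normalized = normalized,
    windowing = window,
    variance = v,
    min_J = neg,
    config = attr(acf, "config", exact = TRUE),
    class = "spectral_density"
  )
}

#' Evaluate a spectral density at given angular frequencies
#'
#' Recomputes the cosine transform exactly at `omega` (rad/ps) rather than
#' interpolating the stored grid.
#'
#' @param acf an `acf_result`.
#' @param omega_rad_ps angular frequencies, rad/ps.
#' @param normalized as in [acf_to_spectral_density()].
#' @return numeric vector of `J` values (ps, or au^2 ps if unnormalized).
#' @export
spectral_density_at <- function(acf, omega_rad_ps, normalized = TRUE) {
  stopifnot(inherits(acf, "acf_result"))
  dt_ps <- attr(acf, "dt_fs") / 1000
  t_ps <- acf$lag_fs / 1000
  g <- acf$g
  wts <- rep(1, length(g))
  wts[c(1L, length(g))] <- 0.5
  J <- 2 * dt_ps * as.numeric(cos(outer(omega_rad_ps, t_ps)) %*% (wts * g))
  if (!normalized) J <- J * attr(acf, "variance")
  J
}

#' @export
print.spectral_density <- function(x, ...) {
  cat(sprintf("# spectral density: %d frequencies, %s, window = %s\n",
              nrow(x),
              ifelse(attr(x, "normalized"), "normalized (ps)", "unnormalized (au^2 ps)"),
              attr(x, "windowing")))
  cat("#", attr(x, "convention"), "\n")
  NextMethod()
}

#' @export
autoplot.spectral_density <- function(object, ...) {
  df <- as_tibble(as.data.frame(object))
  ggplot2::ggplot(df[df$omega_rad_ps > 0, ],
                  ggplot2::aes(.data$omega_rad_ps, pmax(.data$J, 0))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(omega ~ (rad / ps)), y = expression(J(omega)))
}

#' Electron-nucleus zero-quantum frequency
#'
#' The scalar (Fermi-contact) cross-relaxation that drives scalar ODNP is
#' governed by the spectral density at the electron-nucleus zero-quantum
#' (flip-flop) frequency `omega_ZQ = 2 pi (nu_e - nu_n)`. At 9.4 T
#' (263 GHz electron, 100.6 MHz carbon-13 Larmor frequency) this falls at
#' 0.263 THz, i.e. an angular frequency of about 1.65e12 rad/s.
#'
#' @param params a [zq_params()].
#' @return list with `omega_rad_ps` (rad/ps), `nu_thz` (linear frequency,
#'   THz) and `omega_thz` (angular frequency in 1e12 rad/s, the "THz"
#'   angular value).
#' @examples
#' zq_frequency(zq_params(nu_e_ghz = 263, nu_c_ghz = 0.1006))
#' @export
zq_frequency <- function(params) {
  stopifnot(inherits(params, "zq_params"))
  dnu_ghz <- params$nu_e_ghz - params$nu_c_ghz
  list(
    omega_rad_ps = 2 * pi * dnu_ghz / 1000,
    nu_thz = dnu_ghz / 1000,
    omega_thz = 2 * pi * dnu_ghz / 1000
  )
}

#' @rdname zq_frequency
#' @param nu_e_ghz electron Larmor frequency, GHz.
#' @param nu_c_ghz nuclear (carbon-13) Larmor frequency, GHz.
#' @param a_iso_mhz isotropic hyperfine coupling, MHz; quantifies the
#'   magnitude of the Fermi contact.
#' @export
zq_params <- function(nu_e_ghz, nu_c_ghz, a_iso_mhz = 0) {
  if (!(nu_e_ghz > nu_c_ghz) || nu_c_ghz < 0) {
    abort("need nu_e > nu_c >= 0")
  }
  if (a_iso_mhz < 0) abort("a_iso must be >= 0")
  structure(list(nu_e_ghz = nu_e_ghz, nu_c_ghz = nu_c_ghz,
                 a_iso_mhz = a_iso_mhz),
            class = "zq_params")
}

#' Zero-quantum cross-relaxation rate estimate
#'
#' Order-of-magnitude estimate of the scalar (Fermi-contact) zero-quantum
#' relaxation rate from the spectral-density value at the ZQ frequency:
#' `R_ZQ = (1/4) (2 pi a_iso)^2 J(omega_ZQ)`, with `a_iso` in Hz and `J`
#' in seconds. The 1/4 (2 pi a)^2 prefactor is an explicit convention of
#' this package (conventions for the scalar spectral-density prefactor
#' differ across treatments); outputs carry the convention string.
#'
#' @param J_at_zq_s spectral density at the ZQ frequency, seconds. (A `J`
#'   in ps from [acf_to_spectral_density()] is `J_ps * 1e-12` s.)
#' @param params a [zq_params()] carrying `a_iso_mhz`.
#' @return list with `rate_per_s`, `clamped` flag (negative `J` clamps the
#'   rate to 0 with a warning), and `convention`.
#' @examples
#' estimate_zq_rate(1e-13, zq_params(263, 0.1006, a_iso_mhz = 1))
#' @export
estimate_zq_rate <- function(J_at_zq_s, params) {
  stopifnot(inherits(params, "zq_params"))
  clamped <- FALSE
  J <- J_at_zq_s
  if (J < 0) {
    warn("negative spectral density: rate clamped at 0")
    J <- 0
    clamped <- TRUE
  }
  a_hz <- params$a_iso_mhz * 1e6
  list(
    rate_per_s = 0.25 * (2 * pi * a_hz)^2 * J,
    clamped = clamped,
    convention = "R_ZQ = (1/4) (2 pi a_iso)^2 J(omega_ZQ); convention-dependent"
  )
}
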