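#' Surrogate process specifications
#'
#' Light-weight parameter bundles for the synthetic-trajectory generators.
#' Each generator emulates one statistical motif of spin-density dynamics in
#' a radical-substrate complex:
#' * [ou_spec()] - memory-free Ornstein-Uhlenbeck fluctuations,
#' * [pulse_spec()] - telegraph "pulse model" hyperfine trajectories, where
#'   contact switches on during transient radical-substrate encounters,
#' * [ar_spec()] - stationary autoregressive dynamics with a finite
#'   time-point memory,
#' * [damped_osc_spec()] - an initial decay followed by sub-ps oscillations,
#'   the motif seen in spin-density autocorrelation functions.
#'
#' @param tau_c_ps correlation time (ps), > 0.
#' @param sigma stationary standard deviation (au), >= 0.
#' @param mean stationary mean (au).
#' @return A spec object for the matching `gen_*()` generator.
#' @export
ou_spec <- function(tau_c_ps, sigma = 1, mean = 0) {
  if (!(tau_c_ps > 0)) abort("tau_c_ps must be > 0")
  if (sigma < 0) abort("sigma must be >= 0")
  structure(list(tau_c_ps = tau_c_ps, sigma = sigma, mean = mean),
            class = "ou_spec")
}

#' @rdname ou_spec
#' @param encounter_rate_per_ps rate of radical-substrate encounters
#'   (events/ps); off intervals are exponential with mean `1/rate`.
#' @param mean_duration_ps mean encounter (contact) duration, ps.
#' @param amplitude contact value while an encounter lasts (au); 0 otherwise.
#' @export
pulse_spec <- function(encounter_rate_per_ps, mean_duration_ps, amplitude = 1) {
  if (!(encounter_rate_per_ps > 0)) abort("encounter_rate_per_ps must be > 0")
  if (!(mean_duration_ps > 0)) abort("mean_duration_ps must be > 0")
  structure(list(rate = encounter_rate_per_ps, duration = mean_duration_ps,
                 amplitude = amplitude),
            class = "pulse_spec")
}

#' @rdname ou_spec
#' @param phi numeric vector of autoregressive coefficients `phi_1..phi_p`.
#' @param noise_sd innovation standard deviation, > 0.
#' @export
ar_spec <- function(phi, noise_sd = 1) {
  if (!(noise_sd > 0)) abort("noise_sd must be > 0")
  phi <- as.numeric(phi)
  r <- ar_spectral_radius(phi)
  if (r >= 1) {
    abort(sprintf("non-stationary AR coefficients: companion spectral radius %.4f >= 1", r))
  }
  structure(list(phi = phi, p = length(phi), noise_sd = noise_sd),
            class = "ar_spec")
}

ar_spectral_radius <- function(phi) {
  p <- length(phi)
  if (p == 0L) return(0)
  companion <- matrix(0, p, p)
  companion[1L, ] <- phi
  if (p > 1L) companion[cbind(2:p, 1:(p - 1L))] <- 1
  max(Mod(eigen(companion, only.values = TRUE)$values))
}

#' @rdname ou_spec
#' @param components data frame with columns `decay_ps` (exponential decay
#'   time, > 0), `omega_rad_ps` (angular frequency, rad/ps) and `weight`
#'   (nonnegative, summing to 1). The process has theoretical ACF
#'   `sum_i w_i exp(-t/decay_i) cos(omega_i t)`.
#' @param noise_sd standard deviation of added white measurement noise (au).
#' @export
damped_osc_spec <- function(components, noise_sd = 0) {
  components <- as_tibble(components)
  stopifnot(all(c("decay_ps", "omega_rad_ps", "weight") %in% names(components)))
  if (any(components$decay_ps <= 0)) abort("decay times must be > 0")
  if (any(components$weight < 0)) abort("weights must be >= 0")
  if (abs(sum(components$weight) - 1) > 1e-8) abort("weights must sum to 1")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  structure(list(components = components, noise_sd = noise_sd),
            class = "damped_osc_spec")
}

wrap_traj <- function(x, n, dt_fs, model, seed) {
  trajectory(
    tibble(t_fs = (seq_len(n) - 1) * dt_fs, x = x),
    units = c(x = "au"),
    meta = list(generator = model, seed = seed, dt_fs = dt_fs)
  )
}

#' Generate surrogate trajectories
#'
#' Seed-deterministic generators emitting [trajectory()] objects accepted by
#' every downstream stage. `gen_ou()` uses the exact discrete
#' Ornstein-Uhlenbeck update `x[k+1] = x[k] e^(-dt/tau) +
#' sigma sqrt(1 - e^(-2 dt/tau)) xi[k]` from a stationary start, so sample
#' moments converge to the specified moments at the Monte-Carlo rate with no
#' integrator bias.
#'
#' @param spec generator specification (see [ou_spec()] and friends).
#' @param n number of points (>= 100 recommended for meaningful statistics).
#' @param dt_fs sampling interval, fs.
#' @param seed integer seed.
#' @return A [trajectory()] with a single channel `x`.
#' @examples
#' trj <- gen_ou(ou_spec(tau_c_ps = 0.1), n = 1000, dt_fs = 1, seed = 1)
#' @export
gen_ou <- function(spec, n, dt_fs = 1, seed = 1L) {
  stopifnot(inherits(spec, "ou_spec"))
  if (n < 4L) abort("n must be at least 4")
  set.seed(seed)
  x <- ou_path(n, dt_fs / 1000, spec$tau_c_ps, spec$sigma) + spec$mean
  wrap_traj(x, n, dt_fs, "ou", seed)
}

ou_path <- function(n, dt_ps, tau_ps, sigma) {
  if (sigma == 0) return(rep(0, n))
  rho <- exp(-dt_ps / tau_ps)
  innov_sd <- sigma * sqrt(1 - rho^2)
  x <- numeric(n)
  x[1L] <- rnorm(1L, 0, sigma)
  z <- rnorm(n - 1L, 0, innov_sd)
  # exact AR(1) recursion; filter() does the O(n) scan in C
  x[-1L] <- stats::filter(z, rho, method = "recursive", init = x[1L])
  x
}

#' @rdname gen_ou
#' @export
gen_pulse_model <- function(spec, n, dt_fs = 1, seed = 1L) {
  stopifnot(inherits(spec, "pulse_spec"))
  if (n < 4L) abort("n must be at least 4")
  set.seed(seed)
  dt_ps <- dt_fs / 1000
  total_ps <- n * dt_ps
  mean_off <- 1 / spec$rate
  mean_on <- spec$duration
  p_on <- mean_on / (mean_on + mean_off)
  # stationary start: state by equilibrium probability, residual sojourn is
  # again exponential (memoryless), so fresh draws are exact
  state_on <- runif(1L) < p_on
  # draw interval sequence until the trajectory is covered
  n_guess <- max(16L, ceiling(2.5 * total_ps / (mean_on + mean_off)) * 2L)
  times <- numeric(0)
  states <- logical(0)
  t_acc <- 0
  s <- state_on
  while (t_acc < total_ps) {
    blk_states <- rep(c(s, !s), length.out = n_guess)
    len <- rexp(n_guess) * ifelse(blk_states, mean_on, mean_off)
    times <- c(times, len)
    states <- c(states, blk_states)
    t_acc <- t_acc + sum(len)
    s <- !blk_states[n_guess]
  }
  bounds <- cumsum(times)
  tgrid <- (seq_len(n) - 1) * dt_ps
  idx <- findInterval(tgrid, bounds) + 1L
  x <- ifelse(states[idx], spec$amplitude, 0)
  wrap_traj(x, n, dt_fs, "pulse", seed)
}

#' @rdname gen_ou
#' @export
gen_ar <- function(spec, n, dt_fs = 1, seed = 1L) {
  stopifnot(inherits(spec, "ar_spec"))
  if (n < 4L) abort("n must be at least 4")
  set.seed(seed)
  p <- spec$p
  burn <- max(10L * p, 100L)
  z <- rnorm(n + burn, 0, spec$noise_sd)
  x <- if (p == 0L) z else
    as.numeric(stats::filter(z, spec$phi, method = "recursive"))
  x <- x[(burn + 1L):(burn + n)]
  wrap_traj(x, n, dt_fs, "ar", seed)
}

#' @rdname gen_ou
#' @export
gen_damped_osc <- function(spec, n, dt_fs = 1, seed = 1L) {
  stopifnot(inherits(spec, "damped_osc_spec"))
  if (n < 4L) abort("n must be at least 4")
  set.seed(seed)
  dt_ps <- dt_fs / 1000
  tgrid <- (seq_len(n) - 1) * dt_ps
  x <- numeric(n)
  comps <- spec$components
  for (i in seq_len(nrow(comps))) {
    tau <- comps$decay_ps[i]
    om <- comps$omega_rad_ps[i]
    w <- comps$weight[i]
    if (w == 0) next
    # rotated pair of exact-discretization OU processes: the process
    # A(t) cos(om t) - B(t) sin(om t) with independent unit-variance OU
    # amplitudes has ACF exactly exp(-t/tau) cos(om t)
    A <- ou_path(n, dt_ps, tau, 1)
    B <- ou_path(n, dt_ps, tau, 1)
    x <- x + sqrt(w) * (A * cos(om * tgrid) - B * sin(om * tgrid))
  }
  if (spec$noise_sd > 0) x <- x + rnorm(n, 0, spec$noise_sd)
  wrap_traj(x, n, dt_fs, "damped_osc", seed)
}

#' Theoretical ACF of a damped-oscillation spec
#'
#' @param spec a [damped_osc_spec()].
#' @param t_ps times (ps) at which to evaluate.
#' @return numeric vector `sum_i w_i exp(-t/decay_i) cos(omega_i t)`.
#' @export
damped_osc_acf <- function(spec, t_ps) {
  stopifnot(inherits(spec, "damped_osc_spec"))
  comps <- spec$components
  out <- numeric(length(t_ps))
  for (i in seq_len(nrow(comps))) {
    out <- out + comps$weight[i] *
      exp(-t_ps / comps$decay_ps[i]) * cos(comps$omega_rad_ps[i] * t_ps)
  }
  out
}

#' Autoregressive spec matched to a damped-oscillation ACF
#'
#' Solves the Yule-Walker equations on the theoretical ACF of `spec` sampled
#' at `dt_fs`, returning the order-`p` autoregressive process whose first
#' `p` correlation values match it exactly. This is the reference AR(p)
#' surrogate used to study order selection: its true generating order is
#' exactly `p`.
#'
#' @param spec a [damped_osc_spec()].
#' @param p autoregressive order.
#' @param dt_fs sampling interval, fs.
#' @param sigma stationary standard deviation of the resulting process.
#' @return An [ar_spec()].
#' @export
ar_spec_from_damped_osc <- function(spec, p = 6L, dt_fs = 1, sigma = 1) {
  t_ps <- (0:p) * dt_fs / 1000
  rho <- damped_osc_acf(spec, t_ps)
  Rm <- stats::toeplitz(rho[1:p])
  phi <- solve(Rm, rho[2:(p + 1L)])
  # innovation variance for unit process variance, scaled to sigma^2
  v <- 1 - sum(phi * rho[2:(p + 1L)])
  ar_spec(phi, noise_sd = sigma * sqrt(max(v, 1e-12)))
}

#' Synthetic paramagnetic-shift titration table
#'
#' Emulates a radical-concentration titration: observed chemical shift
#' `shift = intercept + slope * conc + noise`, the linear-in-concentration
#' paramagnetic contact-shift model whose slope is the molar-free
#' paramagnetic shift.
#'
#' @param slope_ppm_per_M molar-free paramagnetic shift (ppm/M).
#' @param intercept_ppm diamagnetic shift (ppm).
#' @param conc_M radical concentrations (M); titrations typically span
#'   0 to 0.2 M.
#' @param noise_sd_ppm measurement noise (ppm).
#' @param seed integer seed.
#' @param carbon label for the shift column.
#' @return tibble with columns `conc_M` and one shift column (ppm).
#' @export
gen_titration <- function(slope_ppm_per_M, intercept_ppm = 0,
                          conc_M = c(0, 0.05, 0.1, 0.15, 0.2),
                          noise_sd_ppm = 0.01, seed = 1L, carbon = "C1") {
  set.seed(seed)
  shift <- intercept_ppm + slope_ppm_per_M * conc_M +
    rnorm(length(conc_M), 0, noise_sd_ppm)
  out <- tibble(conc_M = conc_M, shift = shift)
  names(out)[2L] <- carbon
  out
}
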