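#' Normalized autocorrelation function of a trajectory channel
#'
#' Computes the stationary estimator
#' `g(k dt) = [ sum_i x_i x_{i+k} / (N - k) ] / [ sum_i x_i^2 / N ]`
#' of the normalized ACF `g(t) = <rho(t0) rho(t0+t)> / <rho(t0)^2>`,
#' averaging over all admissible origins. The per-lag numerator is divided
#' by its own count (unbiased per lag); the denominator is the lag-0
#' variance over all N points, so `g[0] == 1` exactly. Lags are truncated to
#' `floor(max_lag_fraction * N)` samples (default half the trajectory
#' duration) to avoid the artificial convergence to zero that full-length
#' sample ACFs of finite trajectories exhibit.
#'
#' Whether the underlying series should be mean-centered before correlating
#' is a modelling choice: the raw-product definition applied to a
#' nonzero-mean series never decays to zero and breaks the memory-kernel and
#' spectral stages, while "fluctuation" language implies mean removal.
#' Both policies are implemented (`config$centering`), and the policy used
#' is recorded in the result.
#'
#' @param traj a [trajectory()].
#' @param channel channel name.
#' @param config a [run_config()]; uses `max_lag_fraction` and `centering`.
#' @param high_precision if `TRUE`, the lag sums are accumulated in decimal
#'   arithmetic at `config$precision_digits` digits through the bundled
#'   Python helper. Double- and high-precision ACFs agree to at least 12
#'   significant digits; precision matters downstream, in the memory-kernel
#'   recursion, not here.
#' @return An `acf_result`: a tibble with columns `lag_fs` and `g`, plus
#'   attributes `variance` (the `<rho^2>` denominator after the centering
#'   policy, au^2), `n_points_used`, `centering`, `dt_fs`, `channel`.
#' @examples
#' trj <- gen_ou(ou_spec(0.1), n = 2000, dt_fs = 1, seed = 1)
#' acf1 <- compute_acf(trj, "x")
#' head(acf1)
#' @export
compute_acf <- function(traj, channel, config = run_config(),
                        high_precision = FALSE) {
  stopifnot(inherits(traj, "odnp_traj"))
  x <- traj_channel(traj, channel)
  if (any(!is.finite(x))) {
    abort(sprintf("channel '%s' contains non-finite samples", channel))
  }
  n <- length(x)
  x_raw <- x
  if (config$centering == "mean") x <- x - mean(x)
  v0 <- sum(x^2) / n
  if (v0 <= 0 || (config$centering == "mean" && sd(x) == 0)) {
    abort("zero variance: channel is constant under the centering policy")
  }
  n_lag <- floor(config$max_lag_fraction * n)
  if (n_lag < 2L) abort("trajectory too short for the requested max_lag_fraction")
  if (high_precision && !is.na(config$precision_digits)) {
    res <- hp_call(list(
      op = "acf_sums", x = x_raw, n_lag = n_lag,
      center = (config$centering == "mean"),
      digits = config$precision_digits
    ))
    sums <- res$sums
    v0 <- res$v0
  } else {
    sums <- acf_lag_sums(x, n_lag)
  }
  g <- (sums / (n - seq_len(n_lag) + 1)) / v0
  g[1L] <- 1
  dt <- traj_dt(traj)
  new_tibble(
    tibble(lag_fs = (seq_len(n_lag) - 1) * dt, g = g),
    variance = v0,
    n_points_used = n,
    centering = config$centering,
    dt_fs = dt,
    channel = channel,
    precision_digits = if (high_precision) config$precision_digits else NA_integer_,
    config = config_echo(config),
    class = "acf_result"
  )
}

# raw lag sums sum_i x_i x_{i+k}, k = 0..n_lag-1, via FFT convolution
acf_lag_sums <- function(x, n_lag) {
  n <- length(x)
  m <- stats::nextn(2L * n, 2L)
  fx <- fft(c(x, rep(0, m - n)))
  s <- Re(fft(fx * Conj(fx), inverse = TRUE)) / m
  s[1L] <- sum(x^2)  # exact lag-0, immune to FFT rounding
  s[seq_len(n_lag)]
}

#' Construct an ACF result from explicit values
#'
#' Used for analytic oracles (closed-form ACFs sampled on a grid) and by
#' [reconstruct_acf()]. Validates the normalization invariant `g[0] == 1`
#' and `|g| <= 1 + 1e-9`.
#'
#' @param g ACF values starting at lag 0.
#' @param dt_fs lag spacing, fs.
#' @param variance the unnormalized lag-0 covariance (au^2).
#' @param centering centering policy tag.
#' @param channel channel tag.
#' @param tolerance allowed excess of `|g|` over 1. The default 1e-9 is the
#'   invariant for measured/analytic ACFs; [reconstruct_acf()] relaxes it
#'   because forward-marched solutions carry O(dt^2) discretization error.
#' @return An `acf_result` tibble.
#' @export
acf_result <- function(g, dt_fs, variance = 1, centering = "mean",
                       channel = NA_character_, tolerance = 1e-9) {
  if (abs(g[1L] - 1) > 1e-12) abort("g[0] must equal 1")
  g[1L] <- 1
  if (max(abs(g)) > 1 + tolerance) {
    abort("|g| exceeds 1 + tolerance: not a valid normalized ACF")
  }
  new_tibble(
    tibble(lag_fs = (seq_along(g) - 1) * dt_fs, g = as.numeric(g)),
    variance = variance,
    n_points_used = NA_integer_,
    centering = centering,
    dt_fs = dt_fs,
    channel = channel,
    precision_digits = NA_integer_,
    config = NULL,
    class = "acf_result"
  )
}

#' @export
print.acf_result <- function(x, ...) {
  cat(sprintf(
    "# ACF: %d lags (dt = %g fs), centering = %s, variance = %.6g au^2\n",
    nrow(x), attr(x, "dt_fs"), attr(x, "centering"), attr(x, "variance")))
  NextMethod()
}

#' @export
autoplot.acf_result <- function(object, ...) {
  ggplot2::ggplot(as_tibble(as.data.frame(object)),
                  ggplot2::aes(.data$lag_fs / 1000, .data$g)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (ps)", y = "g(t)")
}

#' Inter-channel covariance matrix
#'
#' Unbiased (n-1 denominator) covariances of mean-centered channels, the
#' quantity used to map how spin-density fluctuations on different atoms
#' co-vary. The matrix is symmetric by construction and its diagonal equals
#' the per-channel variances.
#'
#' @param traj a [trajectory()].
#' @param channels channel names (>= 2).
#' @return A `spin_covariance` object wrapping the covariance matrix.
#' @export
compute_covariance <- function(traj, channels = traj_channels(traj)) {
  stopifnot(inherits(traj, "odnp_traj"))
  if (length(channels) < 2L) abort("need at least 2 channels")
  for (ch in channels) traj_channel(traj, ch)
  m <- as.matrix(as.data.frame(traj)[, channels, drop = FALSE])
  if (any(!is.finite(m))) abort("channels contain non-finite samples")
  v <- stats::cov(m)
  structure(list(matrix = v, channels = channels),
            class = "spin_covariance")
}

#' @export
print.spin_covariance <- function(x, ...) {
  cat(sprintf("# covariance of %d channels (au^2); %d positive, %d negative off-diagonal entries\n",
              length(x$channels),
              sum(x$matrix[upper.tri(x$matrix)] > 0),
              sum(x$matrix[upper.tri(x$matrix)] < 0)))
  print(x$matrix, ...)
  invisible(x)
}

#' @export
tidy.spin_covariance <- function(x, ...) {
  m <- x$matrix
  out <- tidyr::expand_grid(row = rownames(m), col = colnames(m))
  out$covariance <- as.vector(t(m))
  out$sign <- dplyr::case_when(out$covariance > 0 ~ "positive",
                               out$covariance < 0 ~ "negative",
                               TRUE ~ "zero")
  out
}

#' @exportS3Method odnptraj::result_payload
result_payload.spin_covariance <- function(obj) {
  list(channels = obj$channels,
       matrix = as.data.frame(obj$matrix),
       positive = as.data.frame(obj$matrix * (obj$matrix > 0)),
       negative = as.data.frame(obj$matrix * (obj$matrix < 0)))
}
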