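#' Fit an autoregressive model to a trajectory channel
#'
#' Conditional least-squares fit of a mean-centered AR(p) model
#' `x_t = phi_1 x_{t-1} + ... + phi_p x_{t-p} + e_t`. The memory of the
#' process in physical time is `p * dt`: an order-6 fit at 1 fs sampling
#' means the dynamics carries information over 6 fs, the hallmark of
#' non-Markovian spin-density fluctuations.
#'
#' The reported AIC uses the Gaussian conditional likelihood convention
#' `AIC = n_eff log(sigma2_hat) + 2 (p + 1)` (noise level counted as a
#' parameter); the convention is recorded in the result because absolute
#' AIC values are software-convention dependent -- only differences and the
#' argmin are comparable across implementations.
#'
#' @param traj a [trajectory()].
#' @param channel channel name.
#' @param p autoregressive order (>= 0); `p = 0` fits white noise.
#' @param n_condition number of initial points conditioned on (defaults to
#'   `p`; [select_order()] uses a common value so AICs are comparable
#'   across orders).
#' @return An `ar_fit` list: `order`, `phi`, `innovation_variance`, `aic`,
#'   `stationary` (companion spectral radius < 1), `memory_time_fs`,
#'   `n_eff`, `residuals`, `convention`.
#' @examples
#' trj <- gen_ar(ar_spec(0.9), n = 2000, seed = 1)
#' fit <- fit_ar(trj, "x", p = 1)
#' tidy(fit)
#' @export
fit_ar <- function(traj, channel, p, n_condition = p) {
  stopifnot(inherits(traj, "odnp_traj"))
  x <- traj_channel(traj, channel)
  n <- length(x)
  p <- as.integer(p)
  if (p < 0L) abort("p must be >= 0")
  if (n <= 10L * max(p, 1L)) {
    abort(sprintf("insufficient data: need n > 10 p (n = %d, p = %d)", n, p))
  }
  n_condition <- max(as.integer(n_condition), p)
  x <- x - mean(x)
  idx <- (n_condition + 1L):n
  n_eff <- length(idx)
  if (p == 0L) {
    resid <- x[idx]
    phi <- numeric(0)
    sigma2 <- sum(resid^2) / n_eff
  } else {
    lagmat <- embed(x, p + 1L)          # columns: x_t, x_{t-1}, ..., x_{t-p}
    rows <- idx - p                      # align embed rows with idx
    y <- lagmat[rows, 1L]
    X <- lagmat[rows, -1L, drop = FALSE]
    qrX <- qr(X)
    phi <- as.numeric(qr.coef(qrX, y))
    resid <- y - X %*% phi
    sigma2 <- sum(resid^2) / n_eff
  }
  structure(
    list(
      order = p,
      phi = phi,
      innovation_variance = sigma2,
      aic = n_eff * log(sigma2) + 2 * (p + 1),
      stationary = ar_spectral_radius(phi) < 1,
      spectral_radius = ar_spectral_radius(phi),
      memory_time_fs = p * traj_dt(traj),
      n_eff = n_eff,
      residuals = as.numeric(resid),
      channel = channel,
      dt_fs = traj_dt(traj),
      convention = "AIC = n_eff log(sigma2_ML) + 2 (p + 1); conditional least squares"
    ),
    class = "ar_fit"
  )
}

#' @export
print.ar_fit <- function(x, ...) {
  cat(sprintf("AR(%d) fit on '%s' (dt = %g fs): memory time %g fs\n",
              x$order, x$channel, x$dt_fs, x$memory_time_fs))
  if (x$order > 0L) {
    cat("  phi:", paste(sprintf("%.4f", x$phi), collapse = ", "), "\n")
  }
  cat(sprintf("  innovation variance %.6g, AIC %.2f, %s\n",
              x$innovation_variance, x$aic,
              ifelse(x$stationary, "stationary", "NON-STATIONARY")))
  invisible(x)
}

#' @export
tidy.ar_fit <- function(x, ...) {
  if (x$order == 0L) {
    return(tibble(term = character(0), estimate = numeric(0)))
  }
  tibble(term = paste0("phi", seq_len(x$order)), estimate = x$phi)
}

#' @export
glance.ar_fit <- function(x, ...) {
  tibble(order = x$order, innovation_variance = x$innovation_variance,
         aic = x$aic, stationary = x$stationary,
         spectral_radius = x$spectral_radius,
         memory_time_fs = x$memory_time_fs, n_eff = x$n_eff)
}

#' Autoregressive order selection by AIC
#'
#' Fits AR(p) for `p = 0..p_max` by conditional least squares on a common
#' conditioning window (so the likelihoods are comparable), selects the
#' AIC-minimal order, verifies its stationarity, and reports coefficient
#' convergence: the first order at which the shared coefficients change by
#' less than `converge_tol` (relative) when the order is increased by one.
#' A converged order bounds the time-point memory of the process from
#' below; higher orders may still carry non-zero coefficients, so the
#' selected order is a minimal description, not a unique truth.
#'
#' @param traj a [trajectory()].
#' @param channel channel name.
#' @param p_max largest order scanned (>= 1).
#' @param converge_tol relative coefficient-change threshold (default 1%).
#' @param compare_arma if `TRUE`, also reports the AIC of an ARMA(p, 1)
#'   alternative alongside (report only; moving-average terms are never
#'   selected automatically because their physical meaning for spin-density
#'   memory is unclear).
#' @return An `ar_order_scan`: tibble with one row per order (`order`,
#'   `aic`, `innovation_variance`, `stationary`, and the coefficient
#'   change `rel_change` to the next order), plus attributes `best`
#'   (the winning `ar_fit`), `converged_order`, `p_max`.
#' @export
select_order <- function(traj, channel, p_max = run_config()$ar_max_order,
                         converge_tol = 0.01, compare_arma = FALSE) {
  p_max <- as.integer(p_max)
  if (p_max < 1L) abort("p_max must be >= 1")
  fits <- purrr::map(0:p_max, function(p) {
    fit_ar(traj, channel, p, n_condition = p_max)
  })
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  best_idx <- which.min(aics)
  best <- fits[[best_idx]]
  rel_change <- rep(NA_real_, p_max + 1L)
  for (p in 1:p_max) {
    cur <- fits[[p]]$phi      # order p-1 (may be empty)
    nxt <- fits[[p + 1L]]$phi # order p
    if (length(cur) == 0L) next
    scale <- max(abs(cur), 1e-12)
    rel_change[p] <- max(abs(nxt[seq_along(cur)] - cur)) / scale
  }
  conv <- which(rel_change < converge_tol)
  converged_order <- if (length(conv)) conv[1L] - 1L else NA_integer_
  tab <- tibble(
    order = 0:p_max,
    aic = aics,
    innovation_variance = vapply(fits, `[[`, numeric(1), "innovation_variance"),
    stationary = vapply(fits, `[[`, logical(1), "stationary"),
    rel_change = rel_change
  )
  if (compare_arma) {
    tab$aic_arma1 <- vapply(0:p_max, function(p) {
      x <- traj_channel(traj, channel)
      fit <- tryCatch(
        stats::arima(x - mean(x), order = c(p, 0L, 1L), include.mean = FALSE,
                     method = "CSS"),
        error = function(e) NULL)
      if (is.null(fit)) NA_real_ else
        length(fit$residuals) * log(fit$sigma2) + 2 * (p + 2)
    }, numeric(1))
  }
  if (!best$stationary) {
    warn("AIC-minimal AR fit is non-stationary (spectral radius >= 1)")
  }
  new_tibble(tab, best = best, converged_order = converged_order,
             p_max = p_max, channel = channel, class = "ar_order_scan")
}

#' @export
print.ar_order_scan <- function(x, ...) {
  b <- attr(x, "best")
  cat(sprintf("# AR order scan 0..%d on '%s': AIC-minimal order %d (memory %g fs)\n",
              attr(x, "p_max"), attr(x, "channel"), b$order, b$memory_time_fs))
  co <- attr(x, "converged_order")
  cat(sprintf("# coefficients converged (<1%% change) from order %s\n",
              ifelse(is.na(co), "never within scan", co)))
  NextMethod()
}

#' @export
glance.ar_order_scan <- function(x, ...) {
  b <- attr(x, "best")
  tibble(best_order = b$order, best_aic = b$aic,
         converged_order = attr(x, "converged_order"),
         stationary = b$stationary, memory_time_fs = b$memory_time_fs)
}

#' @export
autoplot.ar_order_scan <- function(object, ...) {
  ggplot2::ggplot(as_tibble(as.data.frame(object)),
                  ggplot2::aes(.data$order, .data$aic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "best")$order,
                        linetype = 2) +
    ggplot2::labs(x = "AR order p", y = "AIC")
}

#' Ljung-Box whiteness check of AR residuals
#'
#' @param fit an `ar_fit`.
#' @param lag number of autocorrelation lags pooled.
#' @return htest object from [stats::Box.test()] with `fitdf = order`.
#' @export
ar_whiteness <- function(fit, lag = 20L) {
  stopifnot(inherits(fit, "ar_fit"))
  stats::Box.test(fit$residuals, lag = lag, type = "Ljung-Box",
                  fitdf = fit$order)
}
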