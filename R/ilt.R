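#' Correlation-time spectrum by regularized inverse Laplace transform
#'
#' Decomposes a decaying ACF into a nonnegative distribution of exponential
#' correlation times (CONTIN-style):
#' `min_w || sum_j w_j exp(-t/tau_j) - g(t) ||^2 + lambda ||L2 w||^2`
#' subject to `w >= 0`, with `L2` the second-difference smoothness operator,
#' solved by nonnegative least squares on the augmented system. Because the
#' exponential basis cannot represent negative ACF lobes, only lags before
#' the first zero crossing of `g` feed the inversion; the truncation is
#' recorded in the result.
#'
#' @param acf an `acf_result` whose `g` decays (`g` at the last used lag
#'   below `g[0]`).
#' @param tau_grid_ps strictly increasing correlation-time grid, ps;
#'   default log-spaced from the config's `tau_grid` spec (60 points/decade
#'   over 1e-3..1e2 ps, spanning sub-0.1 ps initial decays and slower
#'   0.5-1 ps components with margin).
#' @param lambda smoothness weight; `"auto"` (or `NA`) picks the L-curve
#'   corner by maximum curvature over a log-spaced candidate set.
#' @param config a [run_config()].
#' @return A `ctime_spectrum`: tibble with `tau_ps`, `weight`, plus
#'   attributes `lambda`, `residual_norm`, `n_lags_used`, `truncated_at_fs`.
#' @examples
#' t_fs <- 0:2999
#' g <- 0.7 * exp(-t_fs / 50) + 0.3 * exp(-t_fs / 700)
#' sp <- ilt_acf(acf_result(g, dt_fs = 1), lambda = 1e-3)
#' summarize_components(sp)
#' @export
ilt_acf <- function(acf, tau_grid_ps = NULL, lambda = "auto",
                    config = run_config()) {
  stopifnot(inherits(acf, "acf_result"))
  if (is.null(tau_grid_ps)) {
    tg <- config$tau_grid
    n_pts <- ceiling(log10(tg$to_ps / tg$from_ps) * tg$points_per_decade) + 1L
    tau_grid_ps <- 10^seq(log10(tg$from_ps), log10(tg$to_ps), length.out = n_pts)
  }
  if (any(diff(tau_grid_ps) <= 0)) abort("tau grid must be strictly increasing")
  t_ps <- acf$lag_fs / 1000
  g <- acf$g
  # exponential basis cannot carry negative lobes: stop at first crossing
  neg <- which(g < 0)
  trunc_fs <- NA_real_
  if (length(neg)) {
    keep <- seq_len(neg[1L] - 1L)
    trunc_fs <- acf$lag_fs[neg[1L]]
    t_ps <- t_ps[keep]
    g <- g[keep]
  }
  if (length(g) < 5L) abort("too few usable lags before the first zero crossing")
  if (g[length(g)] >= g[1L]) {
    abort("ACF does not decay over the usable lag range; ILT not applicable")
  }
  A <- exp(-outer(t_ps, tau_grid_ps, "/"))
  nt <- length(tau_grid_ps)
  L <- second_diff_operator(nt)
  solve_at <- function(lam) {
    Aa <- rbind(A, sqrt(lam) * L)
    ba <- c(g, rep(0, nrow(L)))
    w <- nnls_lh(Aa, ba)
    list(w = w, resid = sqrt(sum((A %*% w - g)^2)),
         smooth = sqrt(sum((L %*% w)^2)))
  }
  auto <- identical(lambda, "auto") || (is.numeric(lambda) && is.na(lambda))
  if (auto && !is.na(config$ilt_regularization)) {
    lambda <- config$ilt_regularization
    auto <- FALSE
  }
  if (auto) {
    lams <- 10^seq(-6, 1, length.out = 15)
    fits <- purrr::map(lams, solve_at)
    lambda <- lams[lcurve_corner(
      log(vapply(fits, `[[`, numeric(1), "resid") + 1e-300),
      log(vapply(fits, `[[`, numeric(1), "smooth") + 1e-300)
    )]
    fit <- fits[[which(lams == lambda)]]
  } else {
    if (!(is.numeric(lambda) && lambda >= 0)) abort("lambda must be >= 0 or 'auto'")
    fit <- solve_at(lambda)
  }
  w <- fit$w
  if (all(w == 0) && fit$resid > 0.5 * sqrt(sum(g^2))) {
    warn("all-zero ILT solution with large residual: flagged non-decaying input")
  }
  new_tibble(
    tibble(tau_ps = tau_grid_ps, weight = w),
    lambda = lambda,
    residual_norm = fit$resid,
    n_lags_used = length(g),
    truncated_at_fs = trunc_fs,
    config = config_echo(config),
    class = "ctime_spectrum"
  )
}

second_diff_operator <- function(n) {
  if (n < 3L) return(matrix(0, 0, n))
  L <- matrix(0, n - 2L, n)
  for (i in seq_len(n - 2L)) L[i, i:(i + 2L)] <- c(1, -2, 1)
  L
}

# L-curve corner: index of maximum discrete curvature of (x, y)
lcurve_corner <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(1L)
  k <- numeric(n)
  for (i in 2:(n - 1L)) {
    dx1 <- x[i] - x[i - 1L]; dy1 <- y[i] - y[i - 1L]
    dx2 <- x[i + 1L] - x[i]; dy2 <- y[i + 1L] - y[i]
    cross <- dx1 * dy2 - dy1 * dx2
    den <- (dx1^2 + dy1^2)^1.5
    k[i] <- if (den > 0) abs(cross) / den else 0
  }
  which.max(k)
}

# Lawson-Hanson nonnegative least squares (no NNLS solver ships in the
# environment); active-set iteration with QR subproblem solves
nnls_lh <- function(A, b, tol = NULL, max_iter = 10L * ncol(A)) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w_grad <- crossprod(A, b - A %*% x)
  tol <- tol %||% (10 * .Machine$double.eps * max(abs(w_grad)) * max(dim(A)))
  iter <- 0L
  while (any(!passive & w_grad > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w_grad))
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      z[passive][is.na(z[passive])] <- 0
      if (all(z[passive] > 0)) break
      bad <- passive & (z <= 0)
      alpha <- min(x[bad] / (x[bad] - z[bad]))
      x <- x + alpha * (z - x)
      passive <- passive & (x > tol * max(abs(x), 1))
      x[!passive] <- 0
    }
    x <- z
    w_grad <- crossprod(A, b - A %*% x)
  }
  pmax(x, 0)
}

#' Summarize a correlation-time spectrum into discrete components
#'
#' Finds local maxima of the weight distribution carrying at least 1% of
#' the total mass and integrates each over its watershed region (split at
#' the minima between adjacent peaks).
#'
#' @param spectrum a `ctime_spectrum` from [ilt_acf()].
#' @param min_mass smallest reported component mass (fraction of total).
#' @return tibble with `tau_ps` (peak position) and `mass` per component,
#'   ordered by `tau_ps`.
#' @export
summarize_components <- function(spectrum, min_mass = 0.01) {
  stopifnot(inherits(spectrum, "ctime_spectrum"))
  w <- spectrum$weight
  tau <- spectrum$tau_ps
  total <- sum(w)
  if (total <= 0) return(tibble(tau_ps = numeric(0), mass = numeric(0)))
  if (diff(range(w)) < 1e-10 * max(w)) {
    # flat distribution: no resolvable components
    return(tibble(tau_ps = numeric(0), mass = numeric(0)))
  }
  n <- length(w)
  is_peak <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) w[i - 1L] else -Inf
    right <- if (i < n) w[i + 1L] else -Inf
    w[i] > 0 && w[i] >= left && w[i] > right
  }, logical(1))
  peaks <- which(is_peak)
  if (!length(peaks)) return(tibble(tau_ps = numeric(0), mass = numeric(0)))
  # watershed boundaries: minima between consecutive peaks
  bounds <- c(0L, vapply(seq_len(length(peaks) - 1L), function(k) {
    seg <- peaks[k]:peaks[k + 1L]
    seg[which.min(w[seg])]
  }, integer(1)), n)
  comp <- purrr::map_dfr(seq_along(peaks), function(k) {
    region <- (bounds[k] + 1L):bounds[k + 1L]
    tibble(tau_ps = tau[peaks[k]], mass = sum(w[region]))
  })
  comp <- comp[comp$mass >= min_mass * total, , drop = FALSE]
  dplyr::arrange(comp, .data$tau_ps)
}

#' @export
print.ctime_spectrum <- function(x, ...) {
  cat(sprintf(
    "# correlation-time spectrum: %d grid points, lambda = %.3g, residual %.3g\n",
    nrow(x), attr(x, "lambda"), attr(x, "residual_norm")))
  if (!is.na(attr(x, "truncated_at_fs"))) {
    cat(sprintf("# lags truncated at first ACF zero crossing (%g fs)\n",
                attr(x, "truncated_at_fs")))
  }
  NextMethod()
}

#' @export
autoplot.ctime_spectrum <- function(object, ...) {
  ggplot2::ggplot(as_tibble(as.data.frame(object)),
                  ggplot2::aes(.data$tau_ps, .data$weight)) +
    ggplot2::geom_area(alpha = 0.4) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau[c] ~ (ps)), y = "weight")
}
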