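#' Pipeline run configuration
#'
#' Bundles the numerical choices that every stage echoes into its results,
#' so any output file can be traced back to the exact settings that made it.
#'
#' @param precision_digits decimal digits carried through the memory-kernel
#'   recursion (default 100, matching the high-precision protocol the
#'   analysis is built around). `NA` selects plain double precision.
#' @param max_lag_fraction fraction of the trajectory duration up to which
#'   autocorrelation functions are evaluated, in (0, 0.5]. The default 0.5
#'   guards against the artificial convergence to zero that full-length
#'   sample ACFs show on finite trajectories.
#' @param centering `"mean"` (default) removes the channel mean before
#'   correlating; `"none"` correlates raw values.
#' @param tau_grid correlation-time grid for the inverse Laplace transform:
#'   `list(from_ps, to_ps, points_per_decade)`.
#' @param ilt_regularization Tikhonov smoothness weight for the ILT;
#'   `NA` selects it automatically from the L-curve corner.
#' @param ar_max_order largest autoregressive order scanned by
#'   [select_order()].
#' @param deriv_order finite-difference order (2 or 4) of the time
#'   derivatives entering the Volterra memory equation; see
#'   [solve_memory_kernel()] for the trade-off.
#' @param gregory_order order of the Gregory end-correction of the
#'   convolution quadrature (1 = trapezoid, 2, or 3).
#' @param seed integer seed echoed into results (generators take their own
#'   `seed` argument; this one records the session default).
#'
#' @return A list with class `run_config`.
#' @export
run_config <- function(precision_digits = 100L,
                       max_lag_fraction = 0.5,
                       centering = c("mean", "none"),
                       tau_grid = list(from_ps = 1e-3, to_ps = 1e2,
                                       points_per_decade = 60L),
                       ilt_regularization = NA_real_,
                       ar_max_order = 12L,
                       deriv_order = 2L,
                       gregory_order = 3L,
                       seed = NA_integer_) {
  centering <- match.arg(centering)
  if (!is.na(precision_digits)) {
    precision_digits <- as.integer(precision_digits)
    if (precision_digits < 10L) abort("precision_digits must be >= 10 (or NA for double)")
  }
  if (!(max_lag_fraction > 0 && max_lag_fraction <= 0.5)) {
    abort("max_lag_fraction must lie in (0, 0.5]")
  }
  if (!deriv_order %in% c(2L, 4L)) abort("deriv_order must be 2 or 4")
  if (!gregory_order %in% 1:3) abort("gregory_order must be 1, 2 or 3")
  if (!is.na(ilt_regularization) && ilt_regularization < 0) {
    abort("ilt_regularization must be nonnegative")
  }
  if (ar_max_order < 1L) abort("ar_max_order must be positive")
  structure(
    list(
      precision_digits = precision_digits,
      max_lag_fraction = max_lag_fraction,
      centering = centering,
      tau_grid = tau_grid,
      ilt_regularization = ilt_regularization,
      ar_max_order = as.integer(ar_max_order),
      deriv_order = as.integer(deriv_order),
      gregory_order = as.integer(gregory_order),
      seed = seed
    ),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("ODNP trajectory-analysis run configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.list(v)) v <- paste(names(v), unlist(v), sep = "=", collapse = ", ")
    cat(sprintf("  %-20s %s\n", nm, paste(v, collapse = ", ")))
  }
  invisible(x)
}

config_echo <- function(config) {
  stopifnot(inherits(config, "run_config"))
  unclass(config)
}
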