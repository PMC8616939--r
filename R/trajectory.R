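#' Multi-channel femtosecond trajectory
#'
#' A trajectory is a tibble whose first column `t_fs` holds strictly
#' increasing, uniformly spaced times in femtoseconds and whose remaining
#' columns hold one observable each: atomic spin densities (atomic units,
#' `"au"`), distances (Angstrom, `"A"`) or angles (degrees, `"deg"`).
#' The sampling interval `dt` and per-channel unit tags travel as attributes,
#' so the object pipes through dplyr verbs like any tibble while the analysis
#' stages ([compute_acf()], [fit_ar()], ...) can recover the physical grid.
#'
#' @param data data frame with time in the first column (fs) and one column
#'   per channel. The time column is renamed to `t_fs`.
#' @param units named character vector of unit tags per channel; channels not
#'   named here default to `"au"` (spin density in atomic populations).
#' @param meta named list of free-form provenance strings.
#'
#' @return A `trajectory` tibble (classes `odnp_traj`, `tbl_df`).
#' @examples
#' trj <- trajectory(data.frame(t = 0:9, C2 = sin(0:9)))
#' traj_dt(trj)
#' @export
trajectory <- function(data, units = NULL, meta = list()) {
  data <- as_tibble(data)
  if (ncol(data) < 2L) {
    abort("a trajectory needs a time column plus at least one channel")
  }
  names(data)[1L] <- "t_fs"
  validate_times(data$t_fs)
  channels <- names(data)[-1L]
  for (ch in channels) {
    if (!is.numeric(data[[ch]])) {
      abort(sprintf("channel '%s' is not numeric", ch))
    }
  }
  u <- rep("au", length(channels))
  names(u) <- channels
  if (!is.null(units)) {
    bad <- setdiff(names(units), channels)
    if (length(bad)) abort(sprintf("units given for unknown channel(s): %s",
                                   paste(bad, collapse = ", ")))
    u[names(units)] <- unname(units)
  }
  new_tibble(
    data,
    dt_fs = diff(data$t_fs[1:2]),
    units = u,
    meta = meta,
    class = "odnp_traj"
  )
}

validate_times <- function(t) {
  if (length(t) < 4L) abort("trajectory needs at least 4 time points")
  if (anyNA(t) || !is.numeric(t)) abort("times must be numeric and non-missing")
  dt <- t[2L] - t[1L]
  if (!(dt > 0)) abort("times must be strictly increasing")
  d <- diff(t)
  off <- which(abs(d - dt) > 1e-9 * max(dt, abs(t[-1L])))
  if (length(off)) {
    abort(sprintf(
      "non-uniform time spacing: interval %d (t = %g fs) differs from dt = %g fs",
      off[1L] + 1L, t[off[1L] + 1L], dt
    ))
  }
  invisible(dt)
}

#' @rdname trajectory
#' @param x a trajectory.
#' @export
traj_dt <- function(x) attr(x, "dt_fs")

#' @rdname trajectory
#' @export
traj_channels <- function(x) setdiff(names(x), "t_fs")

#' @rdname trajectory
#' @export
traj_units <- function(x) attr(x, "units")

traj_channel <- function(x, channel) {
  if (!channel %in% traj_channels(x)) {
    abort(sprintf("channel '%s' not found (have: %s)",
                  channel, paste(traj_channels(x), collapse = ", ")))
  }
  x[[channel]]
}

#' @export
print.odnp_traj <- function(x, ...) {
  cat(sprintf("# trajectory: %d points, dt = %g fs, %d channel(s)\n",
              nrow(x), traj_dt(x), length(traj_channels(x))))
  u <- traj_units(x)
  cat("#  ", paste(sprintf("%s [%s]", names(u), u), collapse = ", "), "\n")
  NextMethod()
}

known_units <- c("au", "A", "deg", "ppm", "ps", "fs")

#' Read and write columnar trajectories
#'
#' Plain-text interchange format for trajectories: column 1 is time in fs,
#' each further column one named channel. Units ride on header suffixes
#' (`C2:au`, `HBond:A`, `Angle:deg`); an untagged header defaults to atomic
#' units. `write_trajectory()` and `read_trajectory()` round-trip all numeric
#' payloads to better than 1e-12 relative.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `read_trajectory()` returns a [trajectory()];
#'   `write_trajectory()` returns `path` invisibly.
#' @export
read_trajectory <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  reader <- if (format == "tsv") readr::read_tsv else readr::read_csv
  raw <- suppressWarnings(reader(
    path,
    col_types = readr::cols(.default = readr::col_double()),
    progress = FALSE, show_col_types = FALSE
  ))
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    abort(sprintf("non-numeric cell at row %d, column %d of '%s' (got %s)",
                  probs$row[1L], probs$col[1L], path,
                  probs$actual[1L]))
  }
  nms <- names(raw)
  units <- character(0)
  out_names <- nms
  for (i in seq_along(nms)[-1L]) {
    parts <- strsplit(nms[i], ":", fixed = TRUE)[[1L]]
    if (length(parts) > 1L && parts[length(parts)] %in% known_units) {
      unit <- parts[length(parts)]
      nm <- paste(parts[-length(parts)], collapse = ":")
    } else {
      unit <- "au"
      nm <- nms[i]
    }
    out_names[i] <- nm
    units[nm] <- unit
  }
  names(raw) <- out_names
  trajectory(raw, units = units, meta = list(source = path, format = format))
}

#' @rdname read_trajectory
#' @param traj a [trajectory()].
#' @export
write_trajectory <- function(traj, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "odnp_traj"))
  u <- traj_units(traj)
  out <- as_tibble(as.data.frame(traj))
  names(out) <- c("t_fs", paste0(names(u), ":", unname(u)))
  if (format == "tsv") {
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' @export
autoplot.odnp_traj <- function(object, channels = NULL, ...) {
  channels <- channels %||% traj_channels(object)
  long <- tidyr::pivot_longer(as_tibble(as.data.frame(object))[, c("t_fs", channels)],
                              -"t_fs", names_to = "channel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$t_fs / 1000, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (ps)", y = NULL)
}
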