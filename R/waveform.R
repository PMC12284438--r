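#' Periodic sampled waveform
#'
#' One cardiac cycle of a uniformly sampled periodic signal (volume flow
#' rate in mL/s or pressure in mmHg). Samples cover exactly one period:
#' `time[1] = 0` and the implied sample after the last one is `t = period`
#' (the endpoint is not duplicated), so the per-cycle integral is
#' `mean(values) * period` exactly.
#'
#' @param time Sample times (s), strictly increasing, uniform, starting
#'   at 0.
#' @param values Sampled values, same length as `time`.
#' @param period Cycle period T (s); defaults to `n * dt`.
#' @return Object of class `waveform`.
#' @export
waveform <- function(time, values, period = NULL) {
  stopifnot(length(time) == length(values), length(time) >= 4L)
  dt <- diff(time)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("waveform time samples must be uniform and strictly increasing")
  if (abs(time[1]) > 1e-12) stop("waveform time must start at 0")
  if (is.null(period)) period <- length(time) * dt[1]
  if (abs(period - length(time) * dt[1]) > 1e-9 * period)
    stop("period must equal n_samples * dt (endpoint-exclusive sampling)")
  structure(list(time = as.numeric(time), values = as.numeric(values),
                 period = period),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "waveform: %d samples over T = %.4g s; range [%.4g, %.4g], mean %.4g\n",
    length(x$time), x$period, min(x$values), max(x$values),
    mean(x$values)))
  invisible(x)
}

#' Periodic linear interpolation of a waveform
#'
#' @param wf A [waveform()].
#' @param t Query times (s), any real values; evaluated at `t mod period`.
#' @return Interpolated values.
#' @export
wf_interp <- function(wf, t) {
  n <- length(wf$time)
  dt <- wf$period / n
  s <- (t %% wf$period) / dt
  i0 <- floor(s)
  frac <- s - i0
  i0 <- as.integer(i0 %% n)
  i1 <- (i0 + 1L) %% n
  (1 - frac) * wf$values[i0 + 1L] + frac * wf$values[i1 + 1L]
}

#' Per-cycle integral (volume for a flow waveform)
#' @param wf A [waveform()].
#' @return `mean(values) * period` (exact for periodic uniform sampling).
#' @export
wf_cycle_integral <- function(wf) mean(wf$values) * wf$period

#' Read / write a waveform as two-column CSV (`time_s,value`)
#' @param path File path.
#' @param period Optional period override (defaults to `n * dt`).
#' @return A [waveform()].
#' @export
read_waveform_csv <- function(path, period = NULL) {
  d <- utils::read.csv(path)
  waveform(d[[1]], d[[2]], period = period)
}

#' @rdname read_waveform_csv
#' @param wf A [waveform()].
#' @export
write_waveform_csv <- function(wf, path) {
  utils::write.csv(data.frame(time_s = wf$time, value = wf$values),
                   path, row.names = FALSE)
  invisible(path)
}
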