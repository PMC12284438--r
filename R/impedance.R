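#' Pulse-pressure waveform
#'
#' Subtracts the diastolic (minimum) pressure so the waveform's minimum
#' is exactly zero. Using the pulse pressure in the impedance ratio
#' removes the diastolic baseline from the 0 Hz term while leaving every
#' nonzero harmonic -- and hence the characteristic impedance --
#' unchanged.
#'
#' @param P A pressure [waveform()] (mmHg).
#' @return A pressure [waveform()] with `min(values) = 0`.
#' @export
pulse_pressure_waveform <- function(P) {
  stopifnot(inherits(P, "waveform"))
  waveform(P$time, P$values - min(P$values), P$period)
}

#' Systolic-minus-diastolic pressure amplitude
#'
#' @param P A pressure [waveform()] (mmHg).
#' @return `max(P) - min(P)` (mmHg); the pulse pressure at that station.
#' @export
delta_mpa_pressure <- function(P) {
  stopifnot(inherits(P, "waveform"))
  max(P$values) - min(P$values)
}

#' Pulmonary arterial impedance spectrum
#'
#' Discrete Fourier transforms of one period of pressure and flow;
#' `Z(omega) = P(omega) / Q(omega)` at each harmonic of 1/T. Harmonics
#' where the flow magnitude falls below `floor_rel` times the first
#' harmonic's are masked (excluded from summary statistics) to avoid
#' division blow-up.
#'
#' @param P Pressure [waveform()] (mmHg). Apply
#'   [pulse_pressure_waveform()] first for the pulse-pressure convention.
#' @param Q Flow [waveform()] (mL/s); must share the period and sampling
#'   of `P`.
#' @param floor_rel Relative flow-harmonic magnitude floor.
#' @return Object of class `impedance_spectrum`: data fields `freq_hz`,
#'   `Z` (complex, mmHg s/mL), `masked` (logical), and the period.
#' @export
impedance_spectrum <- function(P, Q, floor_rel = 1e-6) {
  stopifnot(inherits(P, "waveform"), inherits(Q, "waveform"))
  if (abs(P$period - Q$period) > 1e-12 * P$period ||
      length(P$values) != length(Q$values))
    stop("pressure and flow waveforms must share period and sampling")
  n <- length(P$values)
  Ph <- stats::fft(P$values) / n
  Qh <- stats::fft(Q$values) / n
  n_h <- floor(n / 2)                    # harmonics 0 .. Nyquist-1
  keep <- seq_len(n_h + 1L)
  freq <- (keep - 1L) / P$period
  Ph <- Ph[keep]; Qh <- Qh[keep]
  if (length(Qh) < 2L || Mod(Qh[2]) == 0)
    stop("flow waveform has no first harmonic")
  masked <- Mod(Qh) < floor_rel * Mod(Qh[2])
  Z <- ifelse(masked, NA_complex_, Ph / Qh)
  structure(list(freq_hz = freq, Z = Z, masked = masked,
                 period = P$period),
            class = "impedance_spectrum")
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf(
    "impedance spectrum: %d harmonics (df = %.3g Hz), %d masked\n",
    length(x$freq_hz), 1 / x$period, sum(x$masked)))
  invisible(x)
}

#' Zero-frequency impedance Z0
#'
#' The 0 Hz component of the spectrum: the ratio of mean pressure to
#' mean flow.
#'
#' @param spec An [impedance_spectrum()].
#' @return Z0 (mmHg s/mL), real.
#' @export
z0 <- function(spec) {
  stopifnot(inherits(spec, "impedance_spectrum"))
  if (spec$masked[1])
    stop("mean flow is (near) zero: Z0 undefined")
  Re(spec$Z[1])
}

#' Characteristic impedance Zc
#'
#' Mean of `|Z|` over the harmonics in `(0, f_max]` Hz, excluding 0 Hz
#' and masked harmonics. Averaging the magnitude keeps Zc real.
#'
#' @param spec An [impedance_spectrum()].
#' @param f_max Upper frequency bound (Hz), default 250.
#' @return Zc (mmHg s/mL).
#' @export
zc <- function(spec, f_max = 250) {
  stopifnot(inherits(spec, "impedance_spectrum"))
  sel <- spec$freq_hz > 0 & spec$freq_hz <= f_max & !spec$masked
  if (sum(sel) < 3L)
    stop("fewer than 3 usable harmonics in (0, ", f_max,
         "] Hz; sample the waveforms more finely or longer")
  mean(Mod(spec$Z[sel]))
}

#' Write an impedance spectrum and its summary indices
#'
#' CSV columns `freq_hz,re_z,im_z,abs_z` plus a JSON summary `{Z0, Zc}`.
#' @param spec An [impedance_spectrum()].
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @param f_max Band bound for Zc (Hz).
#' @export
write_impedance <- function(spec, csv_path = NULL, json_path = NULL,
                            f_max = 250) {
  if (!is.null(csv_path))
    utils::write.csv(data.frame(
      freq_hz = spec$freq_hz, re_z = Re(spec$Z), im_z = Im(spec$Z),
      abs_z = Mod(spec$Z)), csv_path, row.names = FALSE, na = "")
  if (!is.null(json_path))
    jsonlite::write_json(list(Z0 = z0(spec), Zc = zc(spec, f_max)),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(spec)
}
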