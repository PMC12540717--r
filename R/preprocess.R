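#' Two-stage sEMG denoising filters
#'
#' The preprocessing chain removes power-line interference and out-of-band
#' noise in two stages applied in order: a narrow-band 50 Hz IIR notch,
#' then a 4th-order Butterworth band-pass between 10 and 500 Hz (order
#' refers to the analog prototype; the digital band-pass realization has
#' twice as many poles). Both stages are designed at the record's sampling
#' rate from center/cutoff frequencies; filtering is causal single-pass by
#' default with a zero-phase two-pass option.
#'
#' @name preprocess
NULL

stage_poles <- function(stage) polyroot(rev(stage$a))

check_stable <- function(stage, what) {
  if (any(Mod(stage_poles(stage)) >= 1 - 1e-12))
    stop(sprintf("%s: designed filter is unstable", what))
  invisible(TRUE)
}

#' Design a narrow-band IIR notch filter
#'
#' Second-order notch with unit zeros on the unit circle at the target
#' frequency, so the tone at `f0` is rejected while DC and frequencies a
#' few bandwidths away pass essentially untouched. The -3 dB width is
#' approximately `f0 / Q`.
#'
#' @param fs Sampling rate in Hz.
#' @param f0 Notch center frequency in Hz (default 50, power-line).
#' @param Q Quality factor (dimensionless); default 30, i.e. a ~1.7 Hz
#'   notch at 50 Hz.
#' @return A notch stage: list with `b`, `a` coefficient vectors (powers of
#'   z^-1), `f0`, `Q`, `fs`.
#' @export
design_notch <- function(fs, f0 = 50, Q = 30) {
  if (f0 <= 0 || f0 >= fs / 2)
    stop("design_notch: f0 must lie strictly between 0 and fs/2")
  if (Q <= 0) stop("design_notch: Q must be positive")
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  b <- b / a[1L]
  a <- a / a[1L]
  stage <- list(type = "notch", b = b, a = a, f0 = f0, Q = Q, fs = fs)
  check_stable(stage, "design_notch")
  stage
}

#' Design a Butterworth band-pass filter
#'
#' Maximally-flat band-pass from the analog Butterworth prototype of the
#' given order, bilinear-transformed at the sampling rate.
#'
#' @param fs Sampling rate in Hz.
#' @param low Lower -3 dB cutoff in Hz (default 10).
#' @param high Upper -3 dB cutoff in Hz (default 500).
#' @param order Analog prototype order (default 4).
#' @return A band-pass stage: list with `b`, `a`, `low`, `high`, `order`,
#'   `fs`.
#' @export
design_bandpass <- function(fs, low = 10, high = 500, order = 4) {
  if (low <= 0) stop("design_bandpass: low cutoff must be positive")
  if (high >= fs / 2) stop("design_bandpass: high cutoff must be below fs/2")
  if (low >= high) stop("design_bandpass: low must be below high")
  if (order < 1) stop("design_bandpass: order must be >= 1")
  ba <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  stage <- list(type = "bandpass", b = as.numeric(ba$b), a = as.numeric(ba$a),
                low = low, high = high, order = order, fs = fs)
  check_stable(stage, "design_bandpass")
  stage
}

#' Build the full preprocessing filter specification
#'
#' @param fs Sampling rate in Hz the filters are designed for.
#' @param notch_freq,notch_Q Notch center frequency and quality factor.
#' @param bp_low,bp_high,bp_order Band-pass cutoffs and prototype order.
#' @param zero_phase Apply each stage forward-backward (zero phase) instead
#'   of the causal single pass.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(fs, notch_freq = 50, notch_Q = 30,
                        bp_low = 10, bp_high = 500, bp_order = 4,
                        zero_phase = FALSE) {
  structure(
    list(fs = fs,
         notch = design_notch(fs, notch_freq, notch_Q),
         bandpass = design_bandpass(fs, bp_low, bp_high, bp_order),
         zero_phase = isTRUE(zero_phase)),
    class = "filter_spec"
  )
}

#' Complex frequency response of a filter stage
#'
#' Evaluates H(e^{i 2 pi f / fs}) from the stage's transfer-function
#' coefficients directly.
#'
#' @param stage A stage from [design_notch()] or [design_bandpass()], or a
#'   whole [filter_spec()] (stages multiply).
#' @param f Frequencies in Hz.
#' @return Complex response at each frequency.
#' @export
filter_response <- function(stage, f) {
  if (inherits(stage, "filter_spec"))
    return(filter_response(stage$notch, f) * filter_response(stage$bandpass, f))
  z <- exp(-1i * 2 * pi * f / stage$fs)
  num <- vapply(z, function(zz) sum(stage$b * zz^(seq_along(stage$b) - 1L)),
                complex(1))
  den <- vapply(z, function(zz) sum(stage$a * zz^(seq_along(stage$a) - 1L)),
                complex(1))
  num / den
}

apply_stage <- function(x, stage, zero_phase) {
  if (zero_phase)
    as.numeric(signal::filtfilt(stage$b, stage$a, x))
  else
    as.numeric(signal::filter(stage$b, stage$a, x))
}

#' Apply the two-stage preprocessing chain to a record
#'
#' Each channel is passed through the notch and then the band-pass stage.
#' Output length equals input length and all labels are preserved.
#'
#' @param record A [signal_record()].
#' @param spec A [filter_spec()] designed at the record's sampling rate.
#' @return A filtered [signal_record()].
#' @export
apply_preprocessing <- function(record, spec) {
  stopifnot(inherits(record, "signal_record"), inherits(spec, "filter_spec"))
  if (!isTRUE(all.equal(record$fs, spec$fs)))
    stop(sprintf("apply_preprocessing: record fs (%g) does not match filter design fs (%g)",
                 record$fs, spec$fs))
  out <- apply(record$samples, 2L, function(x) {
    x <- apply_stage(x, spec$notch, spec$zero_phase)
    apply_stage(x, spec$bandpass, spec$zero_phase)
  })
  signal_record(out, record$fs, record$channel_names,
                record$gesture, record$subject, record$session)
}
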