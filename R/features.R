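#' Windowing and feature-extraction configuration
#'
#' `window_spec` fixes the overlapping segmentation: window length in
#' milliseconds and the overlap as a fraction of the window. The defaults
#' (256 ms, 25 % overlap) give 512-sample windows advancing by 384 samples
#' at 2 kHz.
#'
#' @param window_ms Window length in milliseconds.
#' @param overlap_frac Overlap between consecutive windows as a fraction of
#'   the window length, in [0, 1).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(window_ms = 256, overlap_frac = 0.25) {
  if (window_ms <= 0) stop("window_spec: window_ms must be positive")
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("window_spec: overlap_frac must lie in [0, 1)")
  structure(list(window_ms = window_ms, overlap_frac = overlap_frac),
            class = "window_spec")
}

#' @describeIn window_spec Configuration for the thresholded and banded
#'   features. `wamp_threshold` / `myop_threshold` are in signal units
#'   (amplitude); the frequency-ratio bands split the 10-500 Hz passband at
#'   its midpoint by default. `wl_convention` selects the conventional
#'   waveform length (sum of absolute successive differences) or the
#'   as-printed squared-amplitude form; `pkf_convention` selects peak
#'   frequency as the frequency of maximum power or the as-printed
#'   half-total-power form.
#' @param wamp_threshold,myop_threshold Amplitude thresholds in signal units.
#' @param fr_low_band,fr_high_band Length-2 numeric (low, high) Hz bands for
#'   the frequency ratio numerator and denominator.
#' @param wl_convention `"conventional"` or `"as-printed"`.
#' @param pkf_convention `"conventional"` or `"as-printed"`.
#' @param log_epsilon Additive constant inside the log-detector logarithm.
#' @export
feature_config <- function(wamp_threshold = 0.01, myop_threshold = 0.01,
                           fr_low_band = c(10, 250),
                           fr_high_band = c(250, 500),
                           wl_convention = c("conventional", "as-printed"),
                           pkf_convention = c("conventional", "as-printed"),
                           log_epsilon = 1e-12) {
  wl_convention <- match.arg(wl_convention)
  pkf_convention <- match.arg(pkf_convention)
  if (wamp_threshold < 0 || myop_threshold < 0)
    stop("feature_config: thresholds must be >= 0")
  if (!(fr_low_band[1] < fr_low_band[2] && fr_low_band[2] <= fr_high_band[1] &&
        fr_high_band[1] < fr_high_band[2]))
    stop("feature_config: frequency-ratio bands must satisfy LLC < ULC <= LHC < UHC")
  if (log_epsilon <= 0) stop("feature_config: log_epsilon must be positive")
  structure(list(wamp_threshold = wamp_threshold,
                 myop_threshold = myop_threshold,
                 fr_low_band = fr_low_band, fr_high_band = fr_high_band,
                 wl_convention = wl_convention,
                 pkf_convention = pkf_convention,
                 log_epsilon = log_epsilon),
            class = "feature_config")
}

#' Window geometry in samples
#'
#' @param wspec A [window_spec()].
#' @param fs Sampling rate in Hz.
#' @return List with window length `W`, step and overlap, all in samples.
#' @export
window_geometry <- function(wspec, fs) {
  W <- round(wspec$window_ms * fs / 1000)
  if (W < 2) stop("window_geometry: window shorter than 2 samples")
  step <- W - round(wspec$overlap_frac * W)
  list(W = as.integer(W), step = as.integer(step),
       overlap = as.integer(W - step))
}

#' Segment a record into overlapping windows
#'
#' Windows of length `W = round(window_ms * fs / 1000)` advance by
#' `W - round(overlap_frac * W)` samples; a trailing remainder shorter than
#' one window is discarded. All channels are cut at the same sample
#' offsets, and each window inherits the record's labels.
#'
#' @param record A [signal_record()].
#' @param wspec A [window_spec()].
#' @return List of windows; each has `values` (W x n_channels matrix),
#'   `start` (1-based sample index), `fs` and the record labels.
#' @export
segment <- function(record, wspec) {
  stopifnot(inherits(record, "signal_record"), inherits(wspec, "window_spec"))
  geo <- window_geometry(wspec, record$fs)
  n <- nrow(record$samples)
  if (n < geo$W)
    stop(sprintf("segment: record has %d samples, shorter than one %d-sample window",
                 n, geo$W))
  starts <- seq.int(1L, n - geo$W + 1L, by = geo$step)
  lapply(starts, function(s) {
    list(values = record$samples[s:(s + geo$W - 1L), , drop = FALSE],
         start = s, fs = record$fs, gesture = record$gesture,
         subject = record$subject, session = record$session)
  })
}

time_feature_names <- c("MAV", "RMS", "VAR", "AAC", "DASDV", "ZC", "WL",
                        "WAMP", "iEMG", "MYOP", "LOG")
freq_feature_names <- c("TP", "PKF", "FR", "MNF", "MDF", "MNP")

#' All 17 per-window feature names, in canonical order
#' @return Character vector of length 17.
#' @export
feature_names <- function() c(time_feature_names, freq_feature_names)

#' Time-domain features of one window
#'
#' Computes the 11 time-domain descriptors of a single-channel window:
#' mean absolute value (MAV), root mean square (RMS), variance about zero
#' (VAR), average amplitude change (AAC), difference absolute standard
#' deviation value (DASDV), zero crossings (ZC, strict sign-product test),
#' waveform length (WL), Willison amplitude (WAMP), integrated EMG (iEMG),
#' myopulse percentage rate (MYOP) and the log detector (LOG).
#'
#' @param x Numeric vector of window samples, length >= 2.
#' @param cfg A [feature_config()].
#' @return Named numeric vector of length 11.
#' @export
time_features <- function(x, cfg = feature_config()) {
  if (length(x) < 2L) stop("time_features: need at least 2 samples")
  if (!all(is.finite(x))) stop("time_features: non-finite samples")
  N <- length(x)
  d <- diff(x)
  wl <- if (cfg$wl_convention == "conventional") sum(abs(d))
        else sum(x^2) / (N - 1)
  c(MAV   = mean(abs(x)),
    RMS   = sqrt(mean(x^2)),
    VAR   = sum(x^2) / (N - 1),
    AAC   = sum(abs(d)) / N,
    DASDV = sqrt(sum(d^2) / (N - 1)),
    ZC    = sum(x[-N] * x[-1L] < 0),
    WL    = wl,
    WAMP  = sum(abs(d) >= cfg$wamp_threshold),
    iEMG  = sum(abs(x)),
    MYOP  = mean(abs(x) >= cfg$myop_threshold),
    LOG   = exp(mean(log(abs(x) + cfg$log_epsilon))))
}

#' One-sided periodogram of a window
#'
#' Rectangular-taper periodogram of the mean-detrended window, normalized
#' so that the spectral powers sum to the mean square of the detrended
#' signal (Parseval consistency).
#'
#' @param x Numeric vector of window samples, length >= 2.
#' @param fs Sampling rate in Hz.
#' @return List of class `power_spectrum` with `power` (P_k >= 0) and
#'   `freqs` (Hz, from 0 to fs/2).
#' @export
power_spectrum <- function(x, fs) {
  if (length(x) < 2L) stop("power_spectrum: need at least 2 samples")
  if (!all(is.finite(x))) stop("power_spectrum: non-finite samples")
  N <- length(x)
  xd <- x - mean(x)
  X <- stats::fft(xd)
  M <- N %/% 2L + 1L
  p <- Mod(X[seq_len(M)])^2 / N^2
  # fold negative frequencies onto positive bins (DC and, for even N,
  # Nyquist are their own mirror)
  scale <- rep(2, M)
  scale[1L] <- 1
  if (N %% 2L == 0L) scale[M] <- 1
  structure(list(power = p * scale, freqs = (seq_len(M) - 1L) * fs / N),
            class = "power_spectrum")
}

#' Frequency-domain features of a power spectrum
#'
#' Total power (TP), peak frequency (PKF), frequency ratio (FR) of
#' low-band to high-band power, mean frequency (MNF), median frequency
#' (MDF, first bin whose cumulative power reaches half the total, no
#' interpolation) and mean power (MNP).
#'
#' @param s A [power_spectrum()].
#' @param cfg A [feature_config()].
#' @return Named numeric vector of length 6. On an all-zero spectrum
#'   MNF/MDF/FR are returned as `NA` with a warning.
#' @export
freq_features <- function(s, cfg = feature_config()) {
  stopifnot(inherits(s, "power_spectrum"))
  P <- s$power
  f <- s$freqs
  M <- length(P)
  TP <- sum(P)
  MNP <- TP / M
  if (TP <= 0) {
    warning("freq_features: all-zero spectrum; MNF/MDF/FR undefined")
    pkf <- if (cfg$pkf_convention == "as-printed") TP / 2 else NA_real_
    return(c(TP = TP, PKF = pkf, FR = NA_real_, MNF = NA_real_,
             MDF = NA_real_, MNP = MNP))
  }
  MNF <- sum(f * P) / TP
  MDF <- f[which(cumsum(P) >= TP / 2)[1L]]
  PKF <- if (cfg$pkf_convention == "conventional") f[which.max(P)]
         else TP / 2
  lo <- cfg$fr_low_band
  hi <- cfg$fr_high_band
  denom <- sum(P[f >= hi[1] & f <= hi[2]])
  if (denom <= 0)
    stop("freq_features: zero power in the high band; frequency ratio undefined")
  FR <- sum(P[f >= lo[1] & f <= lo[2]]) / denom
  c(TP = TP, PKF = PKF, FR = FR, MNF = MNF, MDF = MDF, MNP = MNP)
}

window_features <- function(values, fs, cfg) {
  unlist(lapply(seq_len(ncol(values)), function(ch) {
    x <- values[, ch]
    c(time_features(x, cfg), freq_features(power_spectrum(x, fs), cfg))
  }), use.names = FALSE)
}

#' Extract the full windows-by-features matrix from a set of records
#'
#' Segments every record, computes all 17 features per channel per window
#' and stacks the results. Rows are ordered by (record order, window
#' start); columns are channel-major (all features of channel 1, then
#' channel 2, ...), named `<feature>_<channel>`.
#'
#' @param records List of [signal_record()] objects sharing sampling rate
#'   and channel count.
#' @param wspec A [window_spec()].
#' @param fcfg A [feature_config()].
#' @return A [feature_matrix()] with `17 * n_channels` columns.
#' @export
extract_feature_matrix <- function(records, wspec = window_spec(),
                                   fcfg = feature_config()) {
  if (inherits(records, "signal_record")) records <- list(records)
  stopifnot(length(records) >= 1L)
  nch <- ncol(records[[1L]]$samples)
  fs <- records[[1L]]$fs
  for (r in records) {
    if (ncol(r$samples) != nch)
      stop("extract_feature_matrix: records have inconsistent channel counts")
    if (!isTRUE(all.equal(r$fs, fs)))
      stop("extract_feature_matrix: records have inconsistent sampling rates")
  }
  cols <- unlist(lapply(records[[1L]]$channel_names, function(ch)
    paste(feature_names(), ch, sep = "_")))
  per_record <- lapply(records, function(r) {
    wins <- segment(r, wspec)
    vals <- t(vapply(wins, function(w) window_features(w$values, fs, fcfg),
                     numeric(17L * nch)))
    list(vals = vals, n = length(wins), gesture = r$gesture,
         subject = r$subject, session = r$session)
  })
  vals <- do.call(rbind, lapply(per_record, `[[`, "vals"))
  colnames(vals) <- cols
  feature_matrix(vals,
                 gesture = unlist(lapply(per_record, function(p) rep(p$gesture, p$n))),
                 subject = unlist(lapply(per_record, function(p) rep(p$subject, p$n))),
                 session = unlist(lapply(per_record, function(p) rep(p$session, p$n))))
}
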