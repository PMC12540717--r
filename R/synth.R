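#' Synthetic sEMG generation specification
#'
#' Emulates a 6-gesture, 2-channel forearm acquisition at 2 kHz with 40 s
#' per task: band-limited Gaussian noise carrying an EMG-like 20-450 Hz
#' spectrum, amplitude-modulated by a gesture- and channel-specific burst
#' envelope, with additive 50 Hz power-line interference and a small white
#' noise floor. Sessions differ by a multiplicative amplitude perturbation
#' (electrode drift surrogate).
#'
#' @param n_gestures Number of gesture classes.
#' @param n_channels Number of electrode channels.
#' @param fs Sampling rate in Hz.
#' @param task_duration_s Seconds of continuous recording per task.
#' @param class_profiles Data frame, one row per gesture, with columns
#'   `amp_1..amp_C` (activation amplitude per channel, arbitrary signal
#'   units), `burst_rate` (bursts per second) and `burst_duty` (on
#'   fraction of each burst cycle). Rows must be pairwise distinct.
#' @param spectral_band Length-2 Hz band shaping the carrier noise.
#' @param interference_amp Amplitude of the 50 Hz interference component.
#' @param noise_floor Standard deviation of the additive white floor.
#' @param session_jitter Half-width of the uniform multiplicative
#'   amplitude perturbation applied per session; the first session stays
#'   at the nominal gain and acts as the reference recording.
#' @param seed Integer seed for dataset generation.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_gestures = 6, n_channels = 2, fs = 2000,
                           task_duration_s = 40,
                           class_profiles = default_class_profiles(n_gestures,
                                                                   n_channels),
                           spectral_band = c(20, 450),
                           interference_amp = 0.2, noise_floor = 0.05,
                           session_jitter = 0, seed = 0L) {
  if (spectral_band[1] <= 0 || spectral_band[2] >= fs / 2 ||
      spectral_band[1] >= spectral_band[2])
    stop("synthetic_spec: spectral_band must lie within (0, fs/2)")
  amp_cols <- paste0("amp_", seq_len(n_channels))
  if (!all(c(amp_cols, "burst_rate", "burst_duty") %in% names(class_profiles)))
    stop("synthetic_spec: class_profiles must have amp_<ch>, burst_rate, burst_duty")
  if (nrow(class_profiles) != n_gestures)
    stop("synthetic_spec: one class_profiles row per gesture required")
  if (anyDuplicated(class_profiles) > 0)
    stop("synthetic_spec: class_profiles rows must be pairwise distinct")
  if (any(class_profiles[amp_cols] < 0))
    stop("synthetic_spec: amplitudes must be >= 0")
  structure(list(n_gestures = as.integer(n_gestures),
                 n_channels = as.integer(n_channels), fs = fs,
                 task_duration_s = task_duration_s,
                 class_profiles = class_profiles,
                 spectral_band = spectral_band,
                 interference_amp = interference_amp,
                 noise_floor = noise_floor,
                 session_jitter = session_jitter, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_class_profiles <- function(n_gestures = 6, n_channels = 2) {
  base <- data.frame(
    amp_1 = c(0.50, 0.85, 0.67, 1.00, 0.58, 0.76),
    amp_2 = c(0.85, 0.50, 0.67, 1.00, 0.76, 0.58),
    burst_rate = c(1.0, 1.0, 2.0, 0.5, 1.5, 0.8),
    burst_duty = c(0.5, 0.5, 0.4, 0.6, 0.5, 0.55)
  )
  if (n_gestures > 6 || n_channels > 2)
    stop("default_class_profiles: defaults cover up to 6 gestures x 2 channels; supply class_profiles")
  out <- base[seq_len(n_gestures), c(paste0("amp_", seq_len(n_channels)),
                                     "burst_rate", "burst_duty")]
  rownames(out) <- NULL
  out
}

#' Gesture label set of a synthetic spec
#' @param spec A [synthetic_spec()].
#' @return Character vector `g1..gN`.
#' @export
synthetic_labels <- function(spec) paste0("g", seq_len(spec$n_gestures))

burst_envelope <- function(n, fs, rate, duty) {
  t <- (seq_len(n) - 1L) / fs
  phase <- (t * rate) %% 1
  # constant baseline activation plus periodic bursts
  0.35 + 0.65 * as.numeric(phase < duty)
}

#' Generate one synthetic sEMG record
#'
#' @param spec A [synthetic_spec()].
#' @param gesture Gesture index in 1..n_gestures.
#' @param subject,session Label strings for the record.
#' @param session_gain Multiplicative amplitude factor (session drift);
#'   1 by default.
#' @return A [signal_record()] of `fs * task_duration_s` samples. Uses R's
#'   global RNG stream; seed it for reproducibility.
#' @export
generate_record <- function(spec, gesture, subject = "sub1",
                            session = "S1", session_gain = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (gesture < 1 || gesture > spec$n_gestures)
    stop(sprintf("generate_record: gesture index %d outside 1..%d",
                 gesture, spec$n_gestures))
  n <- round(spec$fs * spec$task_duration_s)
  prof <- spec$class_profiles[gesture, ]
  bp <- design_bandpass(spec$fs, spec$spectral_band[1], spec$spectral_band[2],
                        order = 4)
  env <- burst_envelope(n, spec$fs, prof$burst_rate, prof$burst_duty)
  t <- (seq_len(n) - 1L) / spec$fs
  samples <- vapply(seq_len(spec$n_channels), function(ch) {
    carrier <- as.numeric(signal::filter(bp$b, bp$a, stats::rnorm(n)))
    amp <- prof[[paste0("amp_", ch)]] * session_gain
    phase <- stats::runif(1L, 0, 2 * pi)
    amp * env * carrier +
      spec$interference_amp * sin(2 * pi * 50 * t + phase) +
      spec$noise_floor * stats::rnorm(n)
  }, numeric(n))
  signal_record(samples, spec$fs,
                channel_names = paste0("ch", seq_len(spec$n_channels)),
                gesture = synthetic_labels(spec)[gesture],
                subject = subject, session = session)
}

#' Generate in-memory records for subjects x sessions x gestures
#'
#' Fully reproducible from `spec$seed`: the RNG is seeded once and records
#' are generated in a fixed (subject, session, gesture) order; per-session
#' gains are drawn first.
#'
#' @param spec A [synthetic_spec()].
#' @param subjects,sessions Character vectors of ids.
#' @return List of [signal_record()]s in (subject, session, gesture) order.
#' @export
generate_records <- function(spec, subjects = "sub1", sessions = "S1") {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  # the first session is the nominal (enrollment) recording; later sessions
  # drift within +/- session_jitter of it, so the train-vs-test amplitude
  # drift of a cross-session protocol is bounded by the stated jitter
  gains <- 1 + spec$session_jitter * stats::runif(length(sessions), -1, 1)
  gains[1L] <- 1
  names(gains) <- sessions
  out <- list()
  for (sub in subjects)
    for (ses in sessions)
      for (g in seq_len(spec$n_gestures))
        out[[length(out) + 1L]] <-
          generate_record(spec, g, subject = sub, session = ses,
                          session_gain = gains[[ses]])
  out
}

#' Generate a synthetic dataset on disk with a YAML manifest
#'
#' One delimited-text signal file per (subject, session, gesture), plus a
#' manifest referencing them all. Byte-identical across runs with the same
#' spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @param subjects,sessions Character vectors of ids.
#' @param out_dir Writable output directory (created if missing).
#' @return The [dataset_manifest()]; the manifest file is written as
#'   `manifest.yaml` inside `out_dir`.
#' @export
generate_dataset <- function(spec, subjects = "sub1", sessions = "S1",
                             out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop(sprintf("generate_dataset: cannot create directory %s", out_dir))
  records <- generate_records(spec, subjects, sessions)
  entries <- do.call(rbind, lapply(records, function(r) {
    fname <- sprintf("%s_%s_%s.csv", r$subject, r$session, r$gesture)
    write_signal(r, file.path(out_dir, fname))
    data.frame(path = fname, gesture = r$gesture, subject = r$subject,
               session = r$session, stringsAsFactors = FALSE)
  }))
  # on disk the manifest references files relative to its own directory;
  # the returned object carries resolved paths
  rel <- dataset_manifest(entries, fs = spec$fs,
                          channel_names = paste0("ch", seq_len(spec$n_channels)),
                          label_set = synthetic_labels(spec))
  write_manifest(rel, file.path(out_dir, "manifest.yaml"))
  rel$entries$path <- file.path(out_dir, rel$entries$path)
  rel
}
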