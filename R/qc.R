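#' Quality-control configuration for trial filtering
#'
#' Thresholds for the four trial filters applied over the full -420 to
#' +120 ms range: amplifier saturation (absolute cutoff), movement bursts
#' (moving-window Pearson correlation across all electrodes), 50 Hz line
#' noise (relative spectral power), and early licks (lick within the first
#' 100 ms after stimulus onset).
#'
#' @param saturation_cutoff_mv absolute voltage cutoff in mV (default 2)
#' @param qc_window_ms half-open window over which filters operate
#' @param burst_window_ms moving-window length for burst detection
#' @param burst_stride_ms stride of the moving window (50% overlap by default)
#' @param burst_correlation_threshold minimum pairwise Pearson r over a window
#'   for it to count as a burst; pairs involving a constant channel score 0.
#'   The default (0.95) sits above the correlations the stereotyped evoked
#'   response itself induces across a laminar probe on high-intensity trials,
#'   while movement bursts drive every pair essentially to 1
#' @param line_noise_freq_hz line frequency (50 Hz mains)
#' @param line_noise_bandwidth_hz half-width of the band around the line
#'   frequency whose periodogram power is compared against the total
#' @param line_noise_power_threshold flag when band power exceeds this fraction
#'   of total 1-150 Hz power on any channel
#' @param early_lick_window_ms half-open window of lick latencies to exclude
#' @return a `qc_config` list
#' @export
qc_config <- function(saturation_cutoff_mv = 2,
                      qc_window_ms = c(-420, 120),
                      burst_window_ms = 20,
                      burst_stride_ms = 10,
                      burst_correlation_threshold = 0.95,
                      line_noise_freq_hz = 50,
                      line_noise_bandwidth_hz = 1,
                      line_noise_power_threshold = 0.25,
                      early_lick_window_ms = c(0, 100)) {
  assert_scalar_number(saturation_cutoff_mv, "saturation_cutoff_mv", lower = 1e-9)
  assert_scalar_number(burst_correlation_threshold,
                       "burst_correlation_threshold", 0, 1)
  assert_scalar_number(line_noise_power_threshold,
                       "line_noise_power_threshold", 0, 1)
  structure(list(saturation_cutoff_mv = saturation_cutoff_mv,
                 qc_window_ms = qc_window_ms,
                 burst_window_ms = burst_window_ms,
                 burst_stride_ms = burst_stride_ms,
                 burst_correlation_threshold = burst_correlation_threshold,
                 line_noise_freq_hz = line_noise_freq_hz,
                 line_noise_bandwidth_hz = line_noise_bandwidth_hz,
                 line_noise_power_threshold = line_noise_power_threshold,
                 early_lick_window_ms = early_lick_window_ms),
            class = "qc_config")
}

#' Extract one trial from a cohort as a standalone object
#'
#' @param cohort an `lfp_cohort`
#' @param i trial row index
#' @return an `lfp_trial` list with `signal`, `time_ms`, `lick_latency_ms`,
#'   `intensity_pct` and identifiers
#' @export
get_trial <- function(cohort, i) {
  structure(list(signal = cohort$signal[[i]],
                 time_ms = attr(cohort, "time_ms"),
                 lick_latency_ms = cohort$lick_latency_ms[[i]],
                 intensity_pct = cohort$intensity_pct[[i]],
                 trial_id = cohort$trial_id[[i]],
                 mouse_id = cohort$mouse_id[[i]],
                 session_id = cohort$session_id[[i]]),
            class = "lfp_trial")
}

qc_window_cols <- function(time_ms, window_ms) {
  which(time_ms >= window_ms[1] & time_ms < window_ms[2])
}

#' Trial quality-control detectors
#'
#' Each detector returns `TRUE` when its artifact is present within the QC
#' window:
#' * `detect_saturation()`: any sample on any channel reaches the absolute
#'   cutoff (default +-2 mV).
#' * `detect_burst()`: some moving 20 ms window in which *all* electrode pairs
#'   correlate at or above the threshold (Pearson r; a pair involving a
#'   constant channel scores 0).
#' * `detect_line_noise()`: on some channel, periodogram power within
#'   +-1 Hz of 50 Hz exceeds the configured fraction of total 1-150 Hz power.
#' * `detect_early_lick()`: the lick latency falls in \[0, 100) ms.
#'
#' @param trial an `lfp_trial` (see [get_trial()])
#' @param qc a [qc_config()]
#' @return logical flag
#' @export
detect_saturation <- function(trial, qc = qc_config()) {
  cols <- qc_window_cols(trial$time_ms, qc$qc_window_ms)
  any(abs(trial$signal[, cols, drop = FALSE]) >= qc$saturation_cutoff_mv)
}

#' @rdname detect_saturation
#' @export
detect_burst <- function(trial, qc = qc_config()) {
  sig <- trial$signal
  if (nrow(sig) < 2) abort("burst detection requires at least 2 channels")
  cols <- qc_window_cols(trial$time_ms, qc$qc_window_ms)
  sig <- sig[, cols, drop = FALSE]
  wlen <- qc$burst_window_ms          # samples == ms at 1 kHz
  stride <- qc$burst_stride_ms
  if (wlen < 2) abort("burst window must span at least 2 samples")
  starts <- seq(1, ncol(sig) - wlen + 1, by = stride)
  for (st in starts) {
    block <- t(sig[, st:(st + wlen - 1), drop = FALSE])
    sds <- apply(block, 2, stats::sd)
    if (any(sds == 0)) next  # constant channel: pair r := 0, window cannot trip
    r <- stats::cor(block)
    if (min(r[upper.tri(r)]) >= qc$burst_correlation_threshold) return(TRUE)
  }
  FALSE
}

#' @rdname detect_saturation
#' @export
detect_line_noise <- function(trial, qc = qc_config()) {
  cols <- qc_window_cols(trial$time_ms, qc$qc_window_ms)
  sig <- trial$signal[, cols, drop = FALSE]
  n <- ncol(sig)
  fs <- 1000
  freqs <- (seq_len(n) - 1) * fs / n
  band <- freqs >= qc$line_noise_freq_hz - qc$line_noise_bandwidth_hz &
          freqs <= qc$line_noise_freq_hz + qc$line_noise_bandwidth_hz
  total <- freqs >= 1 & freqs <= 150
  for (ch in seq_len(nrow(sig))) {
    p <- Mod(stats::fft(sig[ch, ]))^2
    tot <- sum(p[total])
    if (tot > 0 && sum(p[band & total]) / tot > qc$line_noise_power_threshold) {
      return(TRUE)
    }
  }
  FALSE
}

#' @rdname detect_saturation
#' @export
detect_early_lick <- function(trial, qc = qc_config()) {
  lat <- trial$lick_latency_ms
  !is.na(lat) && lat >= qc$early_lick_window_ms[1] &&
    lat < qc$early_lick_window_ms[2]
}

#' Apply all four trial filters to a cohort
#'
#' A trial is kept iff none of the detectors fires; rejected trials are listed
#' in a rejection table with every triggered reason. Running the filter twice
#' is idempotent.
#'
#' @param cohort an `lfp_cohort` (a whole cohort or one session's trials)
#' @param qc a [qc_config()]
#' @return a list with `kept` (the filtered `lfp_cohort`) and `rejections`
#'   (tibble: trial_id, mouse_id, session_id, reasons semicolon-joined)
#' @export
filter_trials <- function(cohort, qc = qc_config()) {
  n <- nrow(cohort)
  keep <- logical(n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    trial <- get_trial(cohort, i)
    hits <- c(saturation = detect_saturation(trial, qc),
              burst = detect_burst(trial, qc),
              line_noise = detect_line_noise(trial, qc),
              early_lick = detect_early_lick(trial, qc))
    keep[i] <- !any(hits)
    reasons[i] <- paste(names(hits)[hits], collapse = ";")
  }
  rejections <- tibble::tibble(
    trial_id = cohort$trial_id[!keep],
    mouse_id = cohort$mouse_id[!keep],
    session_id = cohort$session_id[!keep],
    reasons = reasons[!keep])
  list(kept = cohort_slice(cohort, keep), rejections = rejections)
}
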