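#' Causal Butterworth filter specification
#'
#' The LFP preprocessing chain: a first-order low-pass at 150 Hz followed by a
#' band-stop removing the 47-53 Hz mains band, both applied causally (output
#' at time t depends only on inputs at or before t). `bandstop_order` is the
#' design order of the band-stop prototype; the realized band-stop transfer
#' function has twice that order.
#'
#' @param lowpass_cutoff_hz low-pass corner frequency in Hz
#' @param lowpass_order low-pass design order
#' @param bandstop_band_hz two-element stop band in Hz
#' @param bandstop_order band-stop prototype design order
#' @return a `filter_spec` list
#' @export
filter_spec <- function(lowpass_cutoff_hz = 150, lowpass_order = 1,
                        bandstop_band_hz = c(47, 53), bandstop_order = 6) {
  structure(list(lowpass_cutoff_hz = lowpass_cutoff_hz,
                 lowpass_order = lowpass_order,
                 bandstop_band_hz = bandstop_band_hz,
                 bandstop_order = bandstop_order),
            class = "filter_spec")
}

# Butterworth zero-pole design on the digital plane (bilinear transform with
# frequency prewarping), identical to signal::butter's internal design but
# kept in zero-pole-gain form.
butter_zpg <- function(n, W, type) {
  T_ <- 2
  W <- 2 / T_ * tan(pi * W / T_)
  pole <- exp(1i * pi * (2 * (1:n) + n - 1) / (2 * n))
  if (n %% 2 == 1) pole[(n + 1) / 2] <- -1
  zpg <- signal::Zpg(zero = numeric(0), pole = pole, gain = 1)
  zpg <- signal::sftrans(zpg, W = W, stop = (type %in% c("stop", "high")))
  signal::bilinear(zpg, T = T_)
}

# Convert a Zpg to second-order sections (list of biquads) plus overall gain.
# Conjugate pairs are grouped; any real root forms a first-order section.
zpg_to_sos <- function(zpg) {
  group_pairs <- function(r) {
    r <- r[order(-abs(r), Re(r), Im(r))]
    secs <- list()
    used <- rep(FALSE, length(r))
    for (i in seq_along(r)) {
      if (used[i]) next
      used[i] <- TRUE
      if (abs(Im(r[i])) < 1e-12) {
        secs[[length(secs) + 1]] <- c(1, -Re(r[i]))
      } else {
        j <- which(!used & abs(r - Conj(r[i])) < 1e-8)[1]
        used[j] <- TRUE
        secs[[length(secs) + 1]] <- c(1, -2 * Re(r[i]), abs(r[i])^2)
      }
    }
    secs
  }
  bsec <- group_pairs(zpg$zero)
  asec <- group_pairs(zpg$pole)
  n <- max(length(bsec), length(asec))
  list(b = c(bsec, rep(list(1), n - length(bsec))),
       a = c(asec, rep(list(1), n - length(asec))),
       gain = Re(zpg$gain))
}

sos_filter <- function(sos, x) {
  for (i in seq_along(sos$b)) {
    x <- as.numeric(signal::filter(sos$b[[i]], sos$a[[i]], x))
  }
  sos$gain * x
}

#' Apply causal Butterworth low-pass and band-stop filtering
#'
#' Filters each channel with zero initial conditions; the first samples of a
#' trial therefore carry the filter transient, identically in training and
#' testing data. The band-stop is realized as a cascade of second-order
#' sections from the zero-pole design, which keeps its notch zeros exactly on
#' the unit circle (a single high-order difference equation loses the notch
#' depth to coefficient rounding).
#'
#' @param signal numeric matrix channels x samples (or a vector for a single
#'   channel) in mV
#' @param spec a [filter_spec()]
#' @param fs sampling rate in Hz
#' @return filtered signal of the same shape
#' @export
apply_butterworth <- function(signal, spec = filter_spec(), fs = 1000) {
  nyq <- fs / 2
  if (spec$lowpass_cutoff_hz >= nyq) {
    abort("low-pass cutoff must be below the Nyquist frequency")
  }
  if (any(spec$bandstop_band_hz <= 0) || any(spec$bandstop_band_hz >= nyq)) {
    abort("band-stop band must lie within (0, Nyquist)")
  }
  lp <- zpg_to_sos(butter_zpg(spec$lowpass_order,
                              spec$lowpass_cutoff_hz / nyq, "low"))
  bs <- zpg_to_sos(butter_zpg(spec$bandstop_order,
                              spec$bandstop_band_hz / nyq, "stop"))
  vec <- is.null(dim(signal))
  m <- if (vec) matrix(signal, nrow = 1) else signal
  out <- t(apply(m, 1, function(x) sos_filter(bs, sos_filter(lp, x))))
  if (vec) as.numeric(out) else out
}

#' Frequency response magnitude of the filtering chain
#'
#' Evaluates the designed low-pass + band-stop cascade at the given
#' frequencies.
#'
#' @param freq_hz frequencies in Hz
#' @param spec a [filter_spec()]
#' @param fs sampling rate in Hz
#' @return magnitude response at each frequency
#' @export
butterworth_response <- function(freq_hz, spec = filter_spec(), fs = 1000) {
  nyq <- fs / 2
  lp <- zpg_to_sos(butter_zpg(spec$lowpass_order,
                              spec$lowpass_cutoff_hz / nyq, "low"))
  bs <- zpg_to_sos(butter_zpg(spec$bandstop_order,
                              spec$bandstop_band_hz / nyq, "stop"))
  vapply(freq_hz, function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    h <- 1 + 0i
    for (sos in list(lp, bs)) {
      for (i in seq_along(sos$b)) {
        num <- sum(sos$b[[i]] * z^(seq_along(sos$b[[i]]) - 1))
        den <- sum(sos$a[[i]] * z^(seq_along(sos$a[[i]]) - 1))
        h <- h * num / den
      }
      h <- h * sos$gain
    }
    abs(h)
  }, numeric(1))
}

#' Butterworth-filter every trial of a cohort
#'
#' @param cohort an `lfp_cohort`
#' @param spec a [filter_spec()]
#' @param fs sampling rate in Hz
#' @return the cohort with filtered signal matrices
#' @export
preprocess_cohort <- function(cohort, spec = filter_spec(), fs = 1000) {
  cohort$signal <- lapply(cohort$signal, apply_butterworth, spec = spec, fs = fs)
  attr(cohort, "filtered") <- TRUE
  cohort
}

#' Current source density from a laminar mean evoked LFP
#'
#' Plain second spatial difference along depth with the convention that a
#' current sink is negative: `csd_i = -(v_{i-1} - 2 v_i + v_{i+1}) / h^2`.
#' The profile loses the outermost electrode on each side.
#'
#' @param mean_lfp matrix depth x time, mean evoked LFP in mV, electrodes
#'   uniformly spaced
#' @param spacing_um electrode spacing in micrometers
#' @return matrix (depth - 2) x time in mV / um^2
#' @export
compute_csd <- function(mean_lfp, spacing_um = 25) {
  if (nrow(mean_lfp) < 3) abort("CSD requires at least 3 channels")
  n <- nrow(mean_lfp)
  i <- 2:(n - 1)
  -(mean_lfp[i - 1, , drop = FALSE] - 2 * mean_lfp[i, , drop = FALSE] +
      mean_lfp[i + 1, , drop = FALSE]) / spacing_um^2
}

#' Assign cortical layers from a CSD profile
#'
#' Layer 4 is the channel carrying the most-negative (deepest sink) CSD value
#' within the first 25 ms after stimulus onset; ties resolve to the shallowest
#' channel. The remaining layers are placed at fixed depth offsets from the
#' L4 channel (nearest electrode), mirroring depth-based estimation of the
#' L5/L6 border. One representative channel per layer is returned.
#'
#' @param csd matrix (n_channels - 2) x time from [compute_csd()]
#' @param channel_depths depths in micrometers of the *original* channels
#' @param time_ms time grid matching the CSD columns
#' @param sink_window_ms half-open post-onset window to search for the sink
#' @param smooth_ms boxcar width of the temporal smoothing applied before the
#'   sink search (pointwise minima are noise-prone on finite trial averages)
#' @param offsets_um named depth offsets of L2/3, L5 and L6 relative to L4
#' @param flat_tol minimal absolute CSD magnitude; a flatter profile errors
#' @return named integer vector: channel index per layer
#' @export
assign_layers <- function(csd, channel_depths, time_ms,
                          sink_window_ms = c(0, 25), smooth_ms = 5,
                          offsets_um = c("L2/3" = -200, "L5" = 175, "L6" = 375),
                          flat_tol = 1e-12) {
  cols <- which(time_ms >= sink_window_ms[1] & time_ms < sink_window_ms[2])
  block <- csd[, cols, drop = FALSE]
  if (smooth_ms > 1 && ncol(block) >= smooth_ms) {
    sm <- t(apply(block, 1, function(x) {
      as.numeric(stats::filter(x, rep(1 / smooth_ms, smooth_ms), sides = 2))
    }))
    keep <- colSums(is.na(sm)) == 0
    if (any(keep)) block <- sm[, keep, drop = FALSE]
  }
  if (max(abs(block)) < flat_tol) {
    abort("flat CSD profile: no identifiable current sink")
  }
  sink_val <- apply(block, 1, min)
  l4_inner <- which(sink_val == min(sink_val))[1]  # shallowest on ties
  l4 <- l4_inner + 1L  # interior row i maps to original channel i + 1
  d4 <- channel_depths[l4]
  out <- c("L4" = l4)
  for (ly in names(offsets_um)) {
    target <- d4 + offsets_um[[ly]]
    out[[ly]] <- which.min(abs(channel_depths - target))
  }
  out[c("L2/3", "L4", "L5", "L6")]
}

#' Mean evoked LFP and recovered layer map for a cohort
#'
#' Averages the high-intensity stimulus trials, computes the CSD, and assigns
#' layers from the short-latency sink.
#'
#' @param cohort an `lfp_cohort`
#' @param min_intensity trials at or above this intensity enter the average
#' @inheritParams assign_layers
#' @return named integer vector: channel index per layer
#' @export
recover_layer_map <- function(cohort, min_intensity = 100,
                              sink_window_ms = c(0, 25),
                              offsets_um = c("L2/3" = -200, "L5" = 175,
                                             "L6" = 375)) {
  idx <- which(cohort$intensity_pct >= min_intensity)
  if (length(idx) == 0) abort("no trials at or above `min_intensity`")
  mean_lfp <- Reduce(`+`, cohort$signal[idx]) / length(idx)
  csd <- compute_csd(mean_lfp, spacing_um =
                       diff(attr(cohort, "channel_depths"))[1])
  assign_layers(csd, attr(cohort, "channel_depths"),
                attr(cohort, "time_ms"), sink_window_ms = sink_window_ms,
                offsets_um = offsets_um)
}
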