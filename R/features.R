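#' Analysis window specification
#'
#' Half-open windows in ms relative to stimulus onset: PRE = \[-400, 0)
#' (spontaneous activity, 400 samples), PERI = \[0, 100) (evoked activity,
#' 100 samples), FULL = PRE then PERI concatenated. The PERI window may be
#' truncated to its first `peri_truncation_ms` milliseconds for the
#' shortened-signal sweep.
#'
#' @param name `"PRE"`, `"PERI"` or `"FULL"`
#' @param peri_truncation_ms optional truncation of the PERI part, in (0, 100]
#' @return a `window_spec` list
#' @export
window_spec <- function(name = c("PRE", "PERI", "FULL"),
                        peri_truncation_ms = NULL) {
  name <- match.arg(name)
  if (!is.null(peri_truncation_ms)) {
    if (name == "PRE") abort("truncation only applies to the PERI window")
    assert_scalar_number(peri_truncation_ms, "peri_truncation_ms",
                         lower = 1, upper = 100)
  }
  structure(list(name = name, peri_truncation_ms = peri_truncation_ms),
            class = "window_spec")
}

window_parts <- function(window) {
  peri_end <- window$peri_truncation_ms %||% 100
  switch(window$name,
         PRE = list(c(-400, 0)),
         PERI = list(c(0, peri_end)),
         FULL = list(c(-400, 0), c(0, peri_end)))
}

window_cols <- function(time_ms, part) {
  which(time_ms >= part[1] & time_ms < part[2])
}

layer_channels <- function(layer_selector, layer_map) {
  layers <- if (identical(layer_selector, "ALL")) {
    c("L2/3", "L4", "L5", "L6")
  } else {
    layer_selector
  }
  missing <- setdiff(layers, names(layer_map))
  if (length(missing) > 0) {
    abort(sprintf("layer(s) %s missing from the layer map",
                  paste(missing, collapse = ", ")))
  }
  layer_map[layers]
}

#' RAW feature vector of one trial
#'
#' Per-sample values of the selected layer's representative channel over the
#' window, at 1 kHz resolution: 400 features for PRE, 100 for PERI, 500 for
#' FULL, per layer. `layer_selector = "ALL"` concatenates the four layers in
#' the fixed order L2/3, L4, L5, L6. The trial signal is expected to be
#' Butterworth-filtered (see [preprocess_cohort()]).
#'
#' @param trial an `lfp_trial` (see [get_trial()])
#' @param window a [window_spec()]
#' @param layer_selector `"L2/3"`, `"L4"`, `"L5"`, `"L6"` or `"ALL"`
#' @param layer_map named channel index per layer
#' @return named numeric feature vector
#' @export
extract_raw <- function(trial, window, layer_selector, layer_map) {
  chans <- layer_channels(layer_selector, layer_map)
  out <- numeric(0)
  for (ly in names(chans)) {
    for (part in window_parts(window)) {
      cols <- window_cols(trial$time_ms, part)
      v <- trial$signal[chans[[ly]], cols]
      names(v) <- sprintf("%s.RAW.t%+04d", gsub("/", "", ly),
                          as.integer(trial$time_ms[cols]))
      out <- c(out, v)
    }
  }
  out
}

# Single-sided amplitude spectrum of one window: bin 0 is the signed mean
# X_0 / N, bins k >= 1 are 2|X_k| / N, kept up to freq_cap_hz.
fft_amplitudes <- function(x, fs = 1000, freq_cap_hz) {
  n <- length(x)
  X <- stats::fft(x)
  kmax <- floor(freq_cap_hz * n / fs)
  k <- 0:kmax
  amp <- c(Re(X[1]) / n, 2 * Mod(X[k[-1] + 1]) / n)
  names(amp) <- sprintf("%gHz", k * fs / n)
  amp
}

#' FFT feature vector of one trial
#'
#' Single-sided amplitude spectrum of the filtered window signal. Bins run
#' from 0 Hz up to 147.5 Hz for PRE (2.5 Hz resolution, 60 features) and up
#' to 140 Hz for PERI (10 Hz resolution, 15 features); FULL transforms the
#' two windows separately and concatenates (75 features per layer). Feature 0
#' (0 Hz) is the signed average of the window signal. Caps are applied as Hz
#' thresholds, so a truncated PERI window recomputes its bin count from the
#' same 140 Hz cap.
#'
#' @inheritParams extract_raw
#' @return named numeric feature vector
#' @export
extract_fft <- function(trial, window, layer_selector, layer_map) {
  chans <- layer_channels(layer_selector, layer_map)
  out <- numeric(0)
  for (ly in names(chans)) {
    for (part in window_parts(window)) {
      cols <- window_cols(trial$time_ms, part)
      cap <- if (part[1] < 0) 147.5 else 140
      amp <- fft_amplitudes(trial$signal[chans[[ly]], cols], freq_cap_hz = cap)
      names(amp) <- sprintf("%s.FFT.%s.%s", gsub("/", "", ly),
                            if (part[1] < 0) "PRE" else "PERI", names(amp))
      out <- c(out, amp)
    }
  }
  out
}

#' Feature matrix for a cohort
#'
#' Applies [extract_raw()] or [extract_fft()] to every trial and binds the
#' result into a tibble (one row per trial, `trial_id` first). Attributes
#' record the layout needed by sequence-aware classifiers: `n_series`
#' (channels concatenated) and `series_length` (samples per channel, RAW
#' only).
#'
#' @param cohort a filtered `lfp_cohort`
#' @param window a [window_spec()]
#' @param feature_type `"RAW"` or `"FFT"`
#' @param layer_selector `"L2/3"`, `"L4"`, `"L5"`, `"L6"` or `"ALL"`
#' @return an `lfp_features` tibble
#' @export
feature_matrix <- function(cohort, window, feature_type = c("RAW", "FFT"),
                           layer_selector = "L4") {
  feature_type <- match.arg(feature_type)
  layer_map <- attr(cohort, "layer_map")
  fn <- if (feature_type == "RAW") extract_raw else extract_fft
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    fn(get_trial(cohort, i), window, layer_selector, layer_map)
  })
  m <- do.call(rbind, rows)
  out <- tibble::as_tibble(m)
  out <- dplyr::bind_cols(tibble::tibble(trial_id = cohort$trial_id), out)
  n_series <- if (identical(layer_selector, "ALL")) 4L else 1L
  structure(out,
            feature_type = feature_type,
            n_series = n_series,
            series_length = if (feature_type == "RAW")
              (ncol(m) %/% n_series) else NA_integer_,
            class = c("lfp_features", class(out)))
}

features_as_matrix <- function(features) {
  as.matrix(features[, setdiff(names(features), "trial_id"), drop = FALSE])
}

#' Train-anchored Min-Max scaler
#'
#' `fit_minmax()` learns per-feature minima and maxima from training rows
#' only; `apply_minmax()` maps `x` to `(x - min) / (max - min)` so that
#' training values span \[0, 1\]. Test values are not clipped and may fall
#' outside that range. Constant training columns are mapped to 0 with a
#' warning.
#'
#' @param x numeric matrix or feature tibble (any `trial_id` column ignored)
#' @return `fit_minmax()`: a `minmax_scaler`; `apply_minmax()`: the scaled
#'   object of the same type as its input
#' @export
fit_minmax <- function(x) {
  m <- if (is.data.frame(x)) features_as_matrix(x) else as.matrix(x)
  mins <- apply(m, 2, min)
  maxs <- apply(m, 2, max)
  if (any(maxs == mins)) {
    warn(sprintf("%d constant feature column(s) will scale to 0",
                 sum(maxs == mins)))
  }
  structure(list(min = mins, max = maxs, names = colnames(m)),
            class = "minmax_scaler")
}

#' @rdname fit_minmax
#' @param scaler a fitted `minmax_scaler`
#' @export
apply_minmax <- function(scaler, x) {
  is_df <- is.data.frame(x)
  m <- if (is_df) features_as_matrix(x) else as.matrix(x)
  if (!is.null(scaler$names) && !is.null(colnames(m)) &&
      !identical(colnames(m), scaler$names)) {
    abort("feature columns do not match the fitted scaler")
  }
  rng <- scaler$max - scaler$min
  scaled <- sweep(m, 2, scaler$min)
  nz <- rng > 0
  scaled[, nz] <- sweep(scaled[, nz, drop = FALSE], 2, rng[nz], "/")
  scaled[, !nz] <- 0
  if (is_df) {
    out <- x
    out[, colnames(m)] <- tibble::as_tibble(scaled)
    out
  } else {
    scaled
  }
}

#' Invert a Min-Max transform
#' @param scaler a fitted `minmax_scaler`
#' @param x scaled matrix
#' @return matrix on the original scale (constant columns return their min)
#' @export
invert_minmax <- function(scaler, x) {
  m <- as.matrix(x)
  rng <- scaler$max - scaler$min
  sweep(sweep(m, 2, rng, "*"), 2, scaler$min, "+")
}
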