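#' Configuration for the synthetic laminar LFP cohort generator
#'
#' Defines the study conditions emulated by [generate_cohort()]: a go/no-go
#' single-whisker detection task in head-fixed mice, recorded with a laminar
#' multi-electrode probe spanning cortical layers 2/3 to 6. Each session mixes
#' catch trials (0% intensity) with stimulus trials at 20-100% of maximum
#' whisker deflection in randomized order; the evoked LFP response is a sharp
#' negative deflection peaking 5-10 ms after stimulus onset, largest in layer 4,
#' and the behavioral response rate grows monotonically with intensity.
#'
#' @param n_mice number of mice in the cohort
#' @param sessions_per_mouse recording sessions per mouse
#' @param n_catch catch (0% intensity) trials per session
#' @param intensity_repeats repeats of each non-zero intensity per session
#'   (with the defaults 50 + 5 x 50 = 300 trials per session, 83% of them
#'   stimulus trials)
#' @param n_channels electrodes on the probe shank
#' @param channel_spacing_um inter-electrode spacing in micrometers
#' @param depth_offset_um cortical depth of the most superficial electrode
#' @param ar_coef first-order autoregressive coefficient of the spontaneous
#'   background activity (per channel, 1 ms steps)
#' @param noise_scale_mv stationary standard deviation of the background in mV
#' @param channel_corr fraction of background innovation variance shared
#'   across channels (cross-channel correlation of the spontaneous activity)
#' @param peak_latency_ms latency of the evoked trough after stimulus onset
#' @param rise_ms,decay_ms time constants of the difference-of-exponentials
#'   evoked kernel
#' @param peak_amplitude_mv evoked trough magnitude in mV at 100% intensity in
#'   layer 4; amplitude is linear in intensity
#' @param layer_multipliers named per-layer amplitude multipliers; layer 4
#'   must carry the largest value
#' @param stim_60hz_amplitude_mv amplitude of an optional stimulus-following
#'   60 Hz component confined to the 0-100 ms stimulus window (off by default)
#' @param false_alarm_rate,asymptote,midpoint_pct,slope psychometric
#'   parameters: response probability is `false_alarm_rate` on catch trials and
#'   `fa + (asymptote - fa) * plogis(slope * (intensity - midpoint))` otherwise
#' @param latency_meanlog,latency_sdlog log-normal parameters of the lick
#'   latency beyond the 100 ms window-of-opportunity onset
#' @param artifact_rates named per-trial injection probabilities for
#'   `saturation`, `burst`, `line_noise`, `early_lick`
#' @param line_noise_amplitude_mv 50 Hz amplitude used when injecting the
#'   line-noise artifact
#' @param seed integer seed; equal configs and seeds yield identical cohorts
#' @return a `generator_config` list
#' @export
generator_config <- function(n_mice = 4,
                             sessions_per_mouse = 1,
                             n_catch = 50,
                             intensity_repeats = 50,
                             n_channels = 32,
                             channel_spacing_um = 25,
                             depth_offset_um = 100,
                             ar_coef = 0.9,
                             noise_scale_mv = 0.1,
                             channel_corr = 0.2,
                             peak_latency_ms = 7,
                             rise_ms = 2,
                             decay_ms = 15,
                             peak_amplitude_mv = 0.8,
                             layer_multipliers = c("L2/3" = 0.6, "L4" = 1.0,
                                                   "L5" = 0.7, "L6" = 0.45),
                             stim_60hz_amplitude_mv = 0,
                             false_alarm_rate = 0.1,
                             asymptote = 0.95,
                             midpoint_pct = 40,
                             slope = 0.08,
                             latency_meanlog = log(130),
                             latency_sdlog = 0.3,
                             artifact_rates = c(saturation = 0, burst = 0,
                                                line_noise = 0, early_lick = 0),
                             line_noise_amplitude_mv = 0.4,
                             seed = 1L) {
  cfg <- structure(
    list(n_mice = n_mice, sessions_per_mouse = sessions_per_mouse,
         n_catch = n_catch, intensity_repeats = intensity_repeats,
         n_channels = n_channels, channel_spacing_um = channel_spacing_um,
         depth_offset_um = depth_offset_um,
         ar_coef = ar_coef, noise_scale_mv = noise_scale_mv,
         channel_corr = channel_corr,
         peak_latency_ms = peak_latency_ms, rise_ms = rise_ms,
         decay_ms = decay_ms, peak_amplitude_mv = peak_amplitude_mv,
         layer_multipliers = layer_multipliers,
         stim_60hz_amplitude_mv = stim_60hz_amplitude_mv,
         psychometric = list(false_alarm_rate = false_alarm_rate,
                             asymptote = asymptote,
                             midpoint_pct = midpoint_pct, slope = slope,
                             latency_meanlog = latency_meanlog,
                             latency_sdlog = latency_sdlog),
         artifact_rates = artifact_rates,
         line_noise_amplitude_mv = line_noise_amplitude_mv,
         seed = as.integer(seed)),
    class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  assert_scalar_number(cfg$n_mice, "n_mice", lower = 0)
  assert_scalar_number(cfg$sessions_per_mouse, "sessions_per_mouse", lower = 0)
  assert_scalar_number(cfg$n_catch, "n_catch", lower = 0)
  assert_scalar_number(cfg$intensity_repeats, "intensity_repeats", lower = 0)
  assert_scalar_number(cfg$n_channels, "n_channels", lower = 4)
  assert_scalar_number(cfg$channel_spacing_um, "channel_spacing_um", lower = 1)
  assert_scalar_number(cfg$ar_coef, "ar_coef", lower = 0, upper = 0.999)
  assert_scalar_number(cfg$noise_scale_mv, "noise_scale_mv", lower = 0)
  assert_scalar_number(cfg$channel_corr, "channel_corr", lower = 0, upper = 1)
  assert_scalar_number(cfg$peak_amplitude_mv, "peak_amplitude_mv", lower = 0)
  assert_scalar_number(cfg$stim_60hz_amplitude_mv, "stim_60hz_amplitude_mv", lower = 0)
  p <- cfg$psychometric
  assert_scalar_number(p$false_alarm_rate, "false_alarm_rate", 0, 1)
  assert_scalar_number(p$asymptote, "asymptote", 0, 1)
  assert_scalar_number(p$slope, "slope", lower = 0)
  lm <- cfg$layer_multipliers
  if (!all(c("L2/3", "L4", "L5", "L6") %in% names(lm))) {
    abort("configuration error: `layer_multipliers` must name L2/3, L4, L5, L6")
  }
  if (any(lm < 0)) abort("configuration error: `layer_multipliers` must be >= 0")
  if (lm[["L4"]] < max(lm)) {
    abort("configuration error: `layer_multipliers` must be largest for L4")
  }
  ar <- cfg$artifact_rates
  if (!all(c("saturation", "burst", "line_noise", "early_lick") %in% names(ar)) ||
      any(ar < 0 | ar > 1)) {
    abort("configuration error: `artifact_rates` must be named rates in [0, 1]")
  }
  # evoked kernel must vanish before stimulus onset
  tstar <- kernel_peak_offset(cfg$rise_ms, cfg$decay_ms)
  if (cfg$peak_latency_ms < tstar) {
    abort("configuration error: `peak_latency_ms` smaller than the kernel rise allows")
  }
  invisible(cfg)
}

# Evoked-amplitude depth profile: one focal Gaussian generator per layer,
# centered on its representative channel, dominant in L4. The profile's
# spatial curvature is therefore deepest at the L4 channel, so the CSD sink
# localizes there, as for a focal thalamorecipient current sink.
channel_multipliers <- function(depths_um, layer_map, layer_multipliers,
                                sigma_um = 60) {
  centers <- depths_um[layer_map]
  amps <- unname(layer_multipliers[names(layer_map)])
  rowSums(vapply(seq_along(centers), function(i) {
    amps[i] * exp(-((depths_um - centers[i]) / sigma_um)^2)
  }, numeric(length(depths_um))))
}

# Latency of the difference-of-exponentials peak relative to kernel onset.
kernel_peak_offset <- function(rise_ms, decay_ms) {
  log(decay_ms / rise_ms) * rise_ms * decay_ms / (decay_ms - rise_ms)
}

# Depth boundaries (um) separating L2/3 | L4 | L5 | L6.
layer_boundaries_um <- function() c(l4_top = 350, l5_top = 500, l6_top = 700)

channel_layers_from_depths <- function(depths_um) {
  b <- layer_boundaries_um()
  layers <- ifelse(depths_um < b[["l4_top"]], "L2/3",
            ifelse(depths_um < b[["l5_top"]], "L4",
            ifelse(depths_um < b[["l6_top"]], "L5", "L6")))
  layers
}

# One representative (most central) channel per layer.
layer_map_from_depths <- function(depths_um) {
  layers <- channel_layers_from_depths(depths_um)
  out <- integer(0)
  for (ly in c("L2/3", "L4", "L5", "L6")) {
    idx <- which(layers == ly)
    if (length(idx) > 0) {
      out[[ly]] <- idx[ceiling(length(idx) / 2)]
    }
  }
  out
}

#' Evoked LFP response kernel
#'
#' Stereotyped stimulus-evoked waveform: a negative difference-of-exponentials
#' deflection whose trough falls `peak_latency_ms` after stimulus onset
#' (default 7 ms, within the characteristic 5-10 ms of the laminar evoked
#' response), zero before onset, with magnitude linear in stimulus intensity
#' and scaled per cortical layer (largest in L4). An optional 60 Hz
#' stimulus-following component is confined to the 0-100 ms stimulus window.
#'
#' @param intensity_pct stimulus intensity, one of 0, 20, 40, 60, 80, 100
#' @param layer cortical layer, one of `"L2/3"`, `"L4"`, `"L5"`, `"L6"`
#' @param time_ms time grid in ms (0 = stimulus onset)
#' @param config a [generator_config()]
#' @return numeric waveform in mV, one value per sample of `time_ms`
#' @export
evoked_kernel <- function(intensity_pct, layer, time_ms = time_grid_ms(),
                          config = generator_config()) {
  if (!intensity_pct %in% intensity_levels()) {
    abort("`intensity_pct` must be one of 0, 20, 40, 60, 80, 100")
  }
  w <- numeric(length(time_ms))
  if (intensity_pct == 0) return(w)
  mult <- config$layer_multipliers[[layer]]
  amp <- config$peak_amplitude_mv * (intensity_pct / 100) * mult
  tr <- config$rise_ms
  td <- config$decay_ms
  tstar <- kernel_peak_offset(tr, td)
  t0 <- config$peak_latency_ms - tstar
  tt <- time_ms - t0
  pos <- tt > 0
  g <- numeric(length(time_ms))
  g[pos] <- exp(-tt[pos] / td) - exp(-tt[pos] / tr)
  gpeak <- exp(-tstar / td) - exp(-tstar / tr)
  w <- -amp * g / gpeak
  if (config$stim_60hz_amplitude_mv > 0) {
    stim <- time_ms >= 0 & time_ms < 100
    w[stim] <- w[stim] + config$stim_60hz_amplitude_mv * (intensity_pct / 100) *
      sin(2 * pi * 60 * time_ms[stim] / 1000)
  }
  w
}

#' Simulated behavioral response (lick) for one trial
#'
#' Draws whether the animal licks and, if so, the lick latency. The response
#' probability equals the false-alarm rate on catch trials (intensity 0) and
#' follows a saturating logistic psychometric curve in intensity otherwise, so
#' the expected response rate is non-decreasing in intensity. Latencies fall
#' beyond the +100 ms window-of-opportunity onset, log-normally distributed.
#' Uses the current RNG stream; seed the caller for reproducibility.
#'
#' @param intensity_pct stimulus intensity in percent
#' @param psych psychometric parameter list (see [generator_config()])
#' @return lick latency in ms, or `NA` if no lick
#' @export
behavioral_response <- function(intensity_pct,
                                psych = generator_config()$psychometric) {
  p <- response_probability(intensity_pct, psych)
  if (runif(1) < p) {
    100 + rlnorm(1, psych$latency_meanlog, psych$latency_sdlog)
  } else {
    NA_real_
  }
}

response_probability <- function(intensity_pct, psych) {
  if (intensity_pct == 0) return(psych$false_alarm_rate)
  psych$false_alarm_rate + (psych$asymptote - psych$false_alarm_rate) *
    plogis(psych$slope * (intensity_pct - psych$midpoint_pct))
}

# Background activity: AR(1) per channel with shared innovations across
# channels. Returns channels x samples in mV with stationary sd noise_scale_mv.
simulate_background <- function(n_channels, n_samples, config) {
  common <- rnorm(n_samples)
  innov <- matrix(rnorm(n_samples * n_channels), n_samples, n_channels)
  e <- sqrt(1 - config$channel_corr) * innov + sqrt(config$channel_corr) * common
  x <- apply(e, 2, function(col) {
    as.numeric(stats::filter(col, config$ar_coef, method = "recursive"))
  })
  t(x) * config$noise_scale_mv * sqrt(1 - config$ar_coef^2)
}

new_cohort <- function(trials, time_ms, channel_depths, layer_map, config) {
  structure(trials,
            time_ms = time_ms,
            channel_depths = channel_depths,
            layer_map = layer_map,
            config = config,
            class = c("lfp_cohort", class(tibble::tibble())))
}

#' Generate a synthetic cohort of laminar LFP trials
#'
#' Produces the full mice -> sessions -> trials hierarchy as a tibble with one
#' row per trial: multi-channel signal matrices (channels x 540 samples,
#' -420 to +120 ms at 1 kHz), randomized stimulus intensities with the
#' configured catch/stimulus mix, simulated lick latencies, and any injected
#' artifacts flagged in `qc_flags`. Deterministic given the config seed.
#'
#' @param config a [generator_config()]
#' @return an `lfp_cohort` tibble with attributes `time_ms`, `channel_depths`,
#'   `layer_map`, and `config`
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(n_mice = 1, n_catch = 2,
#'                                            intensity_repeats = 1,
#'                                            n_channels = 8))
#' nrow(cohort)  # 2 catch + 5 stimulus trials
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  time_ms <- time_grid_ms()
  depths <- config$depth_offset_um +
    config$channel_spacing_um * (seq_len(config$n_channels) - 1)
  layer_map <- layer_map_from_depths(depths)
  ch_mult <- channel_multipliers(depths, layer_map, config$layer_multipliers)
  # unit kernel: 100% intensity, multiplier 1
  unit_cfg <- config
  unit_cfg$layer_multipliers[] <- 1
  unit_kernel <- evoked_kernel(100, "L4", time_ms, unit_cfg)
  n_samples <- length(time_ms)

  rows <- withr::with_seed(config$seed, {
    out <- list()
    for (m in seq_len(config$n_mice)) {
      for (s in seq_len(config$sessions_per_mouse)) {
        intensities <- sample(c(rep(0, config$n_catch),
                                rep(c(20, 40, 60, 80, 100),
                                    each = config$intensity_repeats)))
        for (k in seq_along(intensities)) {
          inten <- intensities[k]
          sig <- simulate_background(config$n_channels, n_samples, config)
          if (inten > 0) {
            sig <- sig + outer(ch_mult * inten / 100, unit_kernel)
          }
          lat <- behavioral_response(inten, config$psychometric)
          trial <- list(signal = sig, lick_latency_ms = lat,
                        qc_flags = character(0))
          for (kind in c("saturation", "burst", "line_noise", "early_lick")) {
            if (runif(1) < config$artifact_rates[[kind]]) {
              trial <- inject_artifact_impl(trial, kind, time_ms, config)
            }
          }
          out[[length(out) + 1L]] <- tibble::tibble(
            trial_id = sprintf("m%02d_s%02d_t%03d", m, s, k),
            mouse_id = sprintf("m%02d", m),
            session_id = sprintf("m%02d_s%02d", m, s),
            intensity_pct = inten,
            lick_latency_ms = trial$lick_latency_ms,
            qc_flags = list(trial$qc_flags),
            signal = list(trial$signal))
        }
      }
    }
    out
  })
  trials <- if (length(rows) == 0) {
    tibble::tibble(trial_id = character(), mouse_id = character(),
                   session_id = character(), intensity_pct = numeric(),
                   lick_latency_ms = numeric(), qc_flags = list(),
                   signal = list())
  } else {
    dplyr::bind_rows(rows)
  }
  new_cohort(trials, time_ms, depths, layer_map, config)
}

# Artifact injection on a bare trial list(signal, lick_latency_ms, qc_flags).
# Each artifact is constructed to trip the corresponding QC detector.
inject_artifact_impl <- function(trial, kind, time_ms, config) {
  sig <- trial$signal
  n <- ncol(sig)
  switch(kind,
    saturation = {
      # 5 ms pulse on one channel beyond the +-2 mV cutoff
      ch <- sample.int(nrow(sig), 1)
      t0 <- sample.int(n - 5, 1)
      sig[ch, t0:(t0 + 4)] <- sig[ch, t0:(t0 + 4)] +
        sample(c(-1, 1), 1) * 2.5
    },
    burst = {
      # 60 ms common high-amplitude oscillatory transient on every channel
      t0 <- sample.int(n - 60, 1)
      span <- t0:(t0 + 59)
      env <- 0.5 * (1 - cos(2 * pi * seq_along(span) / length(span)))
      wave <- 1.6 * env * sin(2 * pi * 80 * seq_along(span) / 1000)
      sig[, span] <- sig[, span] + rep(wave, each = nrow(sig))
    },
    line_noise = {
      phase <- runif(1, 0, 2 * pi)
      wave <- config$line_noise_amplitude_mv *
        sin(2 * pi * 50 * time_ms / 1000 + phase)
      sig <- sig + rep(wave, each = nrow(sig))
    },
    early_lick = {
      lat <- runif(1, 10, 90)
      trial$lick_latency_ms <- lat
      # broadband muscle transient from the lick onward
      span <- which(time_ms >= lat & time_ms < lat + 30)
      sig[, span] <- sig[, span] +
        matrix(rnorm(nrow(sig) * length(span), sd = 0.5),
               nrow(sig), length(span))
    },
    abort(sprintf("unknown artifact kind '%s'", kind))
  )
  trial$signal <- sig
  trial$qc_flags <- union(trial$qc_flags, kind)
  trial
}

#' Inject an artifact into cohort trials
#'
#' Adds one of the four artifact types the quality-control filters screen
#' for — amplifier saturation, a movement burst common to all electrodes, a
#' continuous 50 Hz line-noise contamination, or an early lick with its
#' broadband muscle transient — and records the kind in `qc_flags`. By
#' construction every injected artifact trips the corresponding detector in
#' [filter_trials()].
#'
#' @param cohort an `lfp_cohort`
#' @param kind one of `"saturation"`, `"burst"`, `"line_noise"`, `"early_lick"`
#' @param trials integer row indices to modify (default: all)
#' @param seed integer seed for the injection randomness
#' @return the modified cohort
#' @export
inject_artifact <- function(cohort, kind,
                            trials = seq_len(nrow(cohort)), seed = 1L) {
  kinds <- c("saturation", "burst", "line_noise", "early_lick")
  if (!kind %in% kinds) {
    abort(sprintf("unknown artifact kind '%s'; valid kinds: %s",
                  kind, paste(kinds, collapse = ", ")))
  }
  time_ms <- attr(cohort, "time_ms")
  config <- attr(cohort, "config")
  withr::with_seed(seed, {
    for (i in trials) {
      trial <- list(signal = cohort$signal[[i]],
                    lick_latency_ms = cohort$lick_latency_ms[[i]],
                    qc_flags = cohort$qc_flags[[i]])
      trial <- inject_artifact_impl(trial, kind, time_ms, config)
      cohort$signal[[i]] <- trial$signal
      cohort$lick_latency_ms[[i]] <- trial$lick_latency_ms
      cohort$qc_flags[[i]] <- trial$qc_flags
    }
  })
  cohort
}

#' Subset a cohort while preserving its metadata attributes
#'
#' @param cohort an `lfp_cohort`
#' @param idx integer or logical row index
#' @return the subset cohort, still an `lfp_cohort`
#' @export
cohort_slice <- function(cohort, idx) {
  trials <- tibble::as_tibble(cohort)[idx, , drop = FALSE]
  new_cohort(trials, attr(cohort, "time_ms"), attr(cohort, "channel_depths"),
             attr(cohort, "layer_map"), attr(cohort, "config"))
}

#' Cohort metadata accessors
#'
#' @param cohort an `lfp_cohort`
#' @return `cohort_time_ms()`: the trial time grid in ms;
#'   `cohort_layer_map()`: named channel index per cortical layer;
#'   `cohort_channel_depths()`: electrode depths in micrometers.
#' @export
cohort_time_ms <- function(cohort) attr(cohort, "time_ms")

#' @rdname cohort_time_ms
#' @export
cohort_layer_map <- function(cohort) attr(cohort, "layer_map")

#' @rdname cohort_time_ms
#' @export
cohort_channel_depths <- function(cohort) attr(cohort, "channel_depths")

#' Replace the cohort layer map (e.g. with one recovered by [assign_layers()])
#' @param cohort an `lfp_cohort`
#' @param layer_map named integer vector of channel indices
#' @return the cohort with the new layer map
#' @export
set_layer_map <- function(cohort, layer_map) {
  attr(cohort, "layer_map") <- layer_map
  cohort
}

#' Write / read a cohort archive
#'
#' The archive is one directory per cohort: `manifest.json` (generator config,
#' time grid, channel depths, layer map), `trials.csv` (per-trial metadata with
#' semicolon-joined QC flags) and `signals.csv` (one row per trial x channel,
#' sample values in wide columns). Round-trips are lossless for metadata and
#' within float-text tolerance for signals.
#'
#' @param cohort an `lfp_cohort`
#' @param dir archive directory (created if needed)
#' @return `write_cohort()`: `dir` invisibly; `read_cohort()`: the cohort
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- attr(cohort, "config")
  manifest <- list(
    config = unclass(cfg),
    time_ms = attr(cohort, "time_ms"),
    channel_depths = attr(cohort, "channel_depths"),
    layer_map = as.list(attr(cohort, "layer_map")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  meta <- tibble::as_tibble(cohort)[, c("trial_id", "mouse_id", "session_id",
                                        "intensity_pct", "lick_latency_ms")]
  meta$qc_flags <- vapply(cohort$qc_flags, paste, "", collapse = ";")
  readr::write_csv(meta, file.path(dir, "trials.csv"))
  sig <- purrr::map2_dfr(cohort$trial_id, cohort$signal, function(id, m) {
    df <- tibble::as_tibble(m, .name_repair = ~ sprintf("s%03d", seq_along(.x)))
    df$trial_id <- id
    df$channel <- seq_len(nrow(m))
    df[, c("trial_id", "channel", setdiff(names(df), c("trial_id", "channel")))]
  })
  readr::write_csv(sig, file.path(dir, "signals.csv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- manifest$config
  cfg$psychometric <- as.list(cfg$psychometric)
  class(cfg) <- "generator_config"
  meta <- readr::read_csv(file.path(dir, "trials.csv"),
                          show_col_types = FALSE,
                          col_types = readr::cols(
                            qc_flags = readr::col_character()))
  sig <- readr::read_csv(file.path(dir, "signals.csv"), show_col_types = FALSE)
  signals <- lapply(meta$trial_id, function(id) {
    block <- sig[sig$trial_id == id, , drop = FALSE]
    block <- block[order(block$channel), , drop = FALSE]
    as.matrix(block[, grep("^s\\d+$", names(block)), drop = FALSE]) |>
      unname()
  })
  trials <- tibble::tibble(
    trial_id = meta$trial_id, mouse_id = meta$mouse_id,
    session_id = meta$session_id, intensity_pct = meta$intensity_pct,
    lick_latency_ms = meta$lick_latency_ms,
    qc_flags = lapply(meta$qc_flags, function(f) {
      if (is.na(f) || f == "") character(0) else strsplit(f, ";")[[1]]
    }),
    signal = signals)
  new_cohort(trials, manifest$time_ms, manifest$channel_depths,
             unlist(manifest$layer_map), cfg)
}
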