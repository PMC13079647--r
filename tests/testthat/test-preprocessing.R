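make_trial <- function(signal, lick = NA_real_) {
  structure(list(signal = signal, time_ms = time_grid_ms(),
                 lick_latency_ms = lick, intensity_pct = 0,
                 trial_id = "t", mouse_id = "m", session_id = "s"),
            class = "lfp_trial")
}

test_that("saturation detector applies the +-2 mV rule inside the QC window", {
  qc <- qc_config()
  sig <- matrix(0, 2, 540)
  expect_false(detect_saturation(make_trial(sig), qc))
  sig[1, 300] <- 2.1
  expect_true(detect_saturation(make_trial(sig), qc))
  sig2 <- matrix(stats::runif(2 * 540, -1.9, 1.9), 2, 540)
  expect_false(detect_saturation(make_trial(sig2), qc))
  # a -2.5 mV excursion outside a narrowed QC window does not count
  qc_narrow <- qc_config(qc_window_ms = c(-400, 100))
  sig3 <- matrix(0, 2, 540)
  sig3[2, 5] <- -2.5   # at -416 ms
  expect_false(detect_saturation(make_trial(sig3), qc_narrow))
  expect_true(detect_saturation(make_trial(sig3), qc_config()))
})

test_that("burst detector needs a common waveform on all channels", {
  qc <- qc_config()
  tt <- seq_len(540)
  common <- sin(2 * pi * tt / 25)
  withr::with_seed(4, {
    sig <- rbind(common, common, common) + matrix(rnorm(3 * 540, sd = 1e-3), 3)
  })
  expect_true(detect_burst(make_trial(sig), qc))
  # independent white noise: false with high probability across seeds
  hits <- vapply(1:50, function(s) {
    withr::with_seed(s, detect_burst(make_trial(matrix(rnorm(4 * 540), 4)), qc))
  }, TRUE)
  expect_lt(mean(hits), 0.05)
  expect_error(detect_burst(make_trial(matrix(rnorm(540), 1)), qc),
               "at least 2 channels")
  # constant channel: its pairs score 0, so a window cannot trip
  sigc <- rbind(common, common, 0)
  expect_false(detect_burst(make_trial(sigc), qc))
})

test_that("line-noise detector isolates 50 Hz power", {
  qc <- qc_config()
  tt <- time_grid_ms() / 1000
  pure50 <- matrix(sin(2 * pi * 50 * tt), 1)
  expect_true(detect_line_noise(make_trial(pure50), qc))
  expect_true(detect_line_noise(make_trial(pure50),
                                qc_config(line_noise_power_threshold = 0.99)))
  pure10 <- matrix(sin(2 * pi * 10 * tt), 1)
  expect_false(detect_line_noise(make_trial(pure10), qc))
  # flag is monotone in the 50 Hz amplitude over white noise
  withr::with_seed(9, {
    noise <- rnorm(540, sd = 0.2)
    flags <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), function(a) {
      detect_line_noise(make_trial(matrix(noise + a * sin(2 * pi * 50 * tt), 1)), qc)
    }, TRUE)
  })
  expect_true(all(diff(as.integer(flags)) >= 0))
  expect_false(flags[1])
  expect_true(flags[5])
})

test_that("early-lick detector flags licks in [0, 100) only", {
  qc <- qc_config()
  sig <- matrix(0, 2, 540)
  expect_true(detect_early_lick(make_trial(sig, lick = 50), qc))
  expect_false(detect_early_lick(make_trial(sig, lick = 250), qc))
  expect_false(detect_early_lick(make_trial(sig, lick = NA_real_), qc))
  expect_true(detect_early_lick(make_trial(sig, lick = 0), qc))
  expect_false(detect_early_lick(make_trial(sig, lick = 100), qc))
})

test_that("filter_trials composes the detectors, records reasons, and is idempotent", {
  co <- small_cohort(seed = 51)
  co <- inject_artifact(co, "saturation", trials = 1:2, seed = 1)
  co <- inject_artifact(co, "line_noise", trials = 2:3, seed = 2)
  out <- filter_trials(co)
  expect_equal(nrow(out$kept) + nrow(out$rejections), nrow(co))
  expect_equal(sort(out$rejections$trial_id), sort(co$trial_id[1:3]))
  r2 <- out$rejections$reasons[out$rejections$trial_id == co$trial_id[2]]
  expect_true(grepl("saturation", r2) && grepl("line_noise", r2))
  again <- filter_trials(out$kept)
  expect_equal(nrow(again$rejections), 0)
  expect_identical(again$kept$trial_id, out$kept$trial_id)
  empty <- filter_trials(cohort_slice(co, integer(0)))
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$rejections), 0)
})

test_that("Butterworth chain is causal, linear, and notches 50 Hz", {
  expect_equal(apply_butterworth(rep(0, 600)), rep(0, 600))
  imp <- c(rep(0, 100), 1, rep(0, 199))
  h <- apply_butterworth(imp)
  expect_lt(max(abs(h[1:100])), 1e-10)
  # designed response: deep notch at 50 Hz, near-unit gain at 10 Hz
  expect_lt(butterworth_response(50), 0.01)
  expect_gt(butterworth_response(10), 0.8)
  expect_lt(abs(butterworth_response(10) - 1), 0.2)
  # attenuation at 50 Hz exceeds attenuation at 10 Hz, realized on signals
  t5 <- seq(0, 4.999, by = 1e-3)
  out50 <- apply_butterworth(sin(2 * pi * 50 * t5))
  out10 <- apply_butterworth(sin(2 * pi * 10 * t5))
  expect_lt(max(abs(utils::tail(out50, 1000))), 0.01)
  expect_gt(max(abs(utils::tail(out10, 1000))), 0.8)
  expect_error(apply_butterworth(rep(0, 10), filter_spec(lowpass_cutoff_hz = 600)),
               "Nyquist")
})

test_that("CSD is the negated second spatial difference with sink-negative convention", {
  depths <- seq(100, 800, by = 100)
  tt <- 5
  linear <- outer(depths, rep(1, tt))
  expect_equal(compute_csd(linear, 100), matrix(0, 6, tt))
  quad <- outer(depths^2, rep(1, tt))
  csd_q <- compute_csd(quad, 100)
  expect_equal(csd_q, matrix(-2, 6, tt))  # constant, negated curvature
  expect_error(compute_csd(linear[1:2, , drop = FALSE]), "3 channels")
  # a voltage trough at one depth yields a negative CSD (sink) there
  prof <- rep(0, 8); prof[4] <- -1
  csd_s <- compute_csd(outer(prof, 1), 100)
  expect_lt(csd_s[3, 1], 0)
})

test_that("layer assignment recovers the generator ground truth and breaks ties shallow", {
  co <- cached_cohort("layers", function() generate_cohort(generator_config(
    n_mice = 1, n_catch = 0, intensity_repeats = 5, seed = 61)))
  expect_equal(recover_layer_map(co),
               cohort_layer_map(co)[c("L2/3", "L4", "L5", "L6")])
  # two equal minimal sinks: the shallower interior channel wins
  csd <- matrix(0, 6, 30)
  csd[2, 10] <- -1; csd[5, 10] <- -1
  lm <- assign_layers(csd, seq(100, 800, by = 100), time_ms = seq(0, 29))
  expect_equal(unname(lm[["L4"]]), 3)  # interior row 2 -> channel 3
  expect_error(assign_layers(matrix(0, 6, 30), seq(100, 800, by = 100),
                             time_ms = seq(0, 29)),
               "flat CSD")
})

test_that("QC keeps artifact-free trials and catches injected ones at scale", {
  co <- cached_cohort("qc200", function() generate_cohort(generator_config(
    n_mice = 1, n_catch = 34, intensity_repeats = 34, n_channels = 8,
    channel_spacing_um = 100, seed = 71)))  # 204 clean trials
  out <- filter_trials(co)
  expect_lt(nrow(out$rejections) / nrow(co), 0.05)
  for (kind in c("saturation", "burst", "line_noise", "early_lick")) {
    coa <- inject_artifact(co, kind, trials = 1:40, seed = 3)
    res <- filter_trials(cohort_slice(coa, 1:40))
    expect_gt(nrow(res$rejections) / 40, 0.95)
  }
})
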