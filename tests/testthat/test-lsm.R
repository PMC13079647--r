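test_that("reservoir structure is frozen by the seed and respects Dale signs", {
  cfg <- reservoir_config(seed = 3)
  a <- build_reservoir(cfg)
  b <- build_reservoir(cfg)
  expect_identical(a$W, b$W)
  expect_identical(a$input_neurons, b$input_neurons)
  expect_equal(a$n, 135)
  expect_equal(mean(a$excitatory), 0.8)
  expect_true(all(diag(a$W) == 0))
  # outgoing weights: columns are presynaptic
  for (j in seq_len(a$n)) {
    w <- a$W[, j]
    if (a$excitatory[j]) expect_gte(min(w), 0) else expect_lte(max(w), 0)
  }
  # sparse connectivity under the default length scale
  expect_lt(mean(a$W != 0), 0.2)
  # lambda -> 0: no recurrent connections
  z <- build_reservoir(reservoir_config(lambda_grid = 1e-9, seed = 3))
  expect_equal(sum(z$W != 0), 0)
  # C = 1, lambda -> infinity: all-to-all minus self-connections
  full <- build_reservoir(reservoir_config(
    grid = c(2, 2, 2), C = c(EE = 1, EI = 1, IE = 1, II = 1),
    lambda_grid = 1e9, seed = 3))
  expect_equal(sum(full$W != 0), 8 * 7)
})

test_that("input encoding is linear, seeded, and zero-preserving", {
  res <- build_reservoir(reservoir_config(seed = 5))
  z <- encode_input(rep(0, 100), res, "RAW")
  expect_equal(z, matrix(0, 100, res$n))
  withr::with_seed(2, u <- runif(100))
  c1 <- encode_input(u, res, "RAW")
  expect_equal(encode_input(3 * u, res, "RAW"), 3 * c1)
  expect_identical(encode_input(u, res, "RAW"), c1)
  expect_error(encode_input(runif(101), res, "RAW", n_series = 2), "multiple")
  # FFT vectors become constant held currents
  cf <- encode_input(runif(15), res, "FFT")
  expect_equal(nrow(cf), res$config$fft_hold_steps)
  expect_equal(cf[1, ], cf[nrow(cf), ])
})

test_that("LIF dynamics: quiescence, analytic membrane charge, closed-form ISI", {
  iso <- reservoir_config(grid = c(1, 1, 2), C = c(EE = 0, EI = 0, IE = 0, II = 0),
                          input_fraction = 1, input_gain = 1, seed = 7)
  res <- build_reservoir(iso)
  # zero current -> no spikes, zero state
  st0 <- simulate_reservoir(matrix(0, 50, 2), res)
  expect_equal(sum(st0$raster), 0)
  expect_equal(st0$state, rep(0, 2))
  expect_error(simulate_reservoir(matrix(NaN, 5, 2), res), "non-finite")
  # subthreshold constant current matches the discrete analytic solution
  I <- 0.5
  n_steps <- 80
  st <- simulate_reservoir(matrix(I, n_steps, 2), res)
  a <- iso$dt_ms / iso$tau_m_ms
  analytic <- I * (1 - (1 - a)^n_steps)
  expect_equal(st$v_final, rep(analytic, 2), tolerance = 1e-6)
  # suprathreshold: inter-spike interval within one dt of
  # tau_m * log(I / (I - theta)) + refractory
  for (I in c(1.5, 2, 4)) {
    st <- simulate_reservoir(matrix(I, 400, 2), res)
    isi <- unique(diff(which(st$raster[1, ])))
    expect_length(isi, 1)
    theory <- iso$tau_m_ms * log(I / (I - iso$theta)) + iso$refractory_ms
    expect_lte(abs(isi - theory), iso$dt_ms + 1e-9)
  }
  # doubling a subthreshold current into the suprathreshold regime spikes more
  lo <- simulate_reservoir(matrix(0.9, 200, 2), res)
  hi <- simulate_reservoir(matrix(1.8, 200, 2), res)
  expect_gt(sum(hi$raster), sum(lo$raster))
})

test_that("batched state computation reproduces the single-trial simulator", {
  cfg <- reservoir_config(seed = 11)
  res <- build_reservoir(cfg)
  withr::with_seed(3, X <- matrix(runif(5 * 100), 5, 100))
  states <- lfpdecode:::lsm_state_matrix(X, res, "RAW", 1L)
  for (i in 1:5) {
    st <- simulate_reservoir(encode_input(X[i, ], res, "RAW"), res)
    expect_equal(unname(states[i, ]), st$state)
  }
})

test_that("readout separates separable states and is chance-level on permuted labels", {
  withr::with_seed(5, {
    states <- rbind(matrix(rnorm(40 * 20, 2), 40),
                    matrix(rnorm(40 * 20, -2), 40))
    y <- rep(c(1, 0), each = 40)
    ro <- fit_readout(states, y, lambda = 1e-4)
    p <- as.numeric(predict(ro, states, type = "response", s = 1e-4))
    expect_equal(mean((p >= 0.5) == (y == 1)), 1)
    expect_error(fit_readout(states, rep(1, 80)), "both classes")
    # permuted labels: held-out accuracy approximately 0.5
    yp <- sample(y)
    accs <- vapply(1:5, function(f) {
      te <- seq(f, 80, by = 5)
      ro2 <- fit_readout(states[-te, ], yp[-te], lambda = 0.1)
      p2 <- as.numeric(predict(ro2, states[te, ], type = "response", s = 0.1))
      mean((p2 >= 0.5) == (yp[te] == 1))
    }, 1)
    expect_lt(abs(mean(accs) - 0.5), 0.15)
  })
})

test_that("trained LSM is deterministic, probabilistic, and accurate on the high-SNR task", {
  co <- bench_cohort()
  cosub <- cohort_slice(co, co$intensity_pct %in% c(0, 100))
  y <- label_trials(cosub, "SD")
  fm <- feature_matrix(cosub, window_spec("PERI"), "RAW", "L4")
  tr <- cosub$mouse_id != "m04"
  sc <- fit_minmax(lfpdecode:::subset_features(fm, tr))
  xtr <- apply_minmax(sc, lfpdecode:::subset_features(fm, tr))
  xte <- apply_minmax(sc, lfpdecode:::subset_features(fm, !tr))
  m1 <- lsm_train(xtr, y[tr])
  m2 <- lsm_train(xtr, y[tr])
  p1 <- lsm_predict(m1, xte)
  expect_identical(p1, lsm_predict(m2, xte))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_gte(mean((p1 >= 0.5) == (y[!tr] == 1)), 0.9)
  expect_error(lsm_predict(structure(list(), class = "lsm_model"), xte),
               "trained")
  # tidy/glance expose the readout and reservoir summary
  td <- tidy(m1)
  expect_equal(nrow(td), 136)
  expect_equal(glance(m1)$n_neurons, 135)
})

test_that("LSM accuracy grows with the generator evoked amplitude", {
  accs <- vapply(c(0.1, 0.4, 0.8), function(amp) {
    co <- preprocess_cohort(generate_cohort(generator_config(
      n_mice = 2, n_catch = 12, intensity_repeats = 8, n_channels = 8,
      channel_spacing_um = 100, peak_amplitude_mv = amp, seed = 303)))
    cosub <- cohort_slice(co, co$intensity_pct %in% c(0, 100))
    y <- label_trials(cosub, "SD")
    fm <- feature_matrix(cosub, window_spec("PERI"), "RAW", "L4")
    tr <- cosub$mouse_id == "m01"
    sc <- fit_minmax(lfpdecode:::subset_features(fm, tr))
    m <- lsm_train(apply_minmax(sc, lfpdecode:::subset_features(fm, tr)), y[tr])
    p <- lsm_predict(m, apply_minmax(sc, lfpdecode:::subset_features(fm, !tr)))
    mean((p >= 0.5) == (y[!tr] == 1))
  }, 1)
  expect_true(all(diff(accs) >= -0.05))
  expect_gt(accs[3], accs[1])
})
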