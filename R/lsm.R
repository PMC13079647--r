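#' Liquid State Machine reservoir configuration
#'
#' The reservoir follows the classical liquid-state-machine construction: a
#' fixed, sparse, recurrent network of leaky integrate-and-fire (LIF) neurons
#' on a 3 x 3 x 15 grid (135 neurons), 80% excitatory, with
#' distance-dependent Gaussian connectivity `C * exp(-(d / lambda)^2)` whose
#' base probability `C` depends on the (pre, post) excitatory/inhibitory
#' type pair. The simulation step equals the 1 kHz LFP sampling (dt = 1 ms);
#' spikes propagate with a one-step delay and are low-pass filtered with time
#' constant `tau_s_ms` to form the analog state read out by a trained
#' logistic readout.
#'
#' @param grid three integers, the reservoir grid dimensions
#' @param excitatory_fraction fraction of excitatory neurons (in (0, 1))
#' @param lambda_grid connectivity length scale in grid units
#' @param C named base connection probabilities for EE, EI, IE, II pairs
#' @param w_scale synaptic weight scale (inhibitory weights are negative and
#'   twice this scale on average, balancing the 80/20 E/I split)
#' @param tau_m_ms membrane time constant
#' @param theta spike threshold (dimensionless membrane units)
#' @param v_reset reset value after a spike
#' @param refractory_ms absolute refractory period
#' @param tau_s_ms state-filter time constant
#' @param dt_ms simulation step
#' @param input_fraction fraction of neurons receiving external input
#' @param input_gain scale of the input currents (features are Min-Max scaled
#'   to \[0, 1\] upstream, so the gain sets the drive in threshold units)
#' @param fft_hold_steps steps an FFT feature vector is held as constant
#'   input current
#' @param rate_band_hz two-element band of acceptable mean firing rates;
#'   training warns when the reservoir leaves it
#' @param seed integer seed freezing the random reservoir structure
#' @return a `reservoir_config` list
#' @export
reservoir_config <- function(grid = c(3, 3, 15),
                             excitatory_fraction = 0.8,
                             lambda_grid = 2,
                             C = c(EE = 0.3, EI = 0.2, IE = 0.4, II = 0.1),
                             w_scale = 0.12,
                             tau_m_ms = 20,
                             theta = 1,
                             v_reset = 0,
                             refractory_ms = 2,
                             tau_s_ms = 800,
                             dt_ms = 1,
                             input_fraction = 0.3,
                             input_gain = 6,
                             fft_hold_steps = 50,
                             rate_band_hz = c(1, 100),
                             seed = 1L) {
  assert_scalar_number(excitatory_fraction, "excitatory_fraction", 1e-9, 1 - 1e-9)
  assert_scalar_number(dt_ms, "dt_ms", lower = 1e-9)
  assert_scalar_number(refractory_ms, "refractory_ms", lower = 0)
  if (theta <= v_reset) abort("configuration error: `theta` must exceed `v_reset`")
  if (!all(c("EE", "EI", "IE", "II") %in% names(C))) {
    abort("configuration error: `C` must name EE, EI, IE, II")
  }
  structure(list(grid = grid, excitatory_fraction = excitatory_fraction,
                 lambda_grid = lambda_grid, C = C, w_scale = w_scale,
                 tau_m_ms = tau_m_ms, theta = theta, v_reset = v_reset,
                 refractory_ms = refractory_ms, tau_s_ms = tau_s_ms,
                 dt_ms = dt_ms, input_fraction = input_fraction,
                 input_gain = input_gain, fft_hold_steps = fft_hold_steps,
                 rate_band_hz = rate_band_hz,
                 seed = as.integer(seed)),
            class = "reservoir_config")
}

#' Build the frozen random reservoir structure
#'
#' Samples neuron types, distance-dependent recurrent connectivity and input
#' projection weights; deterministic given `config$seed`. No
#' self-connections; outgoing weights are non-negative for excitatory and
#' non-positive for inhibitory neurons.
#'
#' @param config a [reservoir_config()]
#' @return a `reservoir` list with `W` (recurrent weight matrix, post x pre),
#'   `excitatory` (logical per neuron), `positions`, `input_neurons` and
#'   `input_sign`
#' @export
build_reservoir <- function(config = reservoir_config()) {
  n <- prod(config$grid)
  withr::with_seed(config$seed, {
    pos <- as.matrix(expand.grid(x = seq_len(config$grid[1]),
                                 y = seq_len(config$grid[2]),
                                 z = seq_len(config$grid[3])))
    exc <- rep(FALSE, n)
    exc[sample.int(n, round(config$excitatory_fraction * n))] <- TRUE
    d2 <- as.matrix(stats::dist(pos))^2
    type <- ifelse(exc, "E", "I")
    pair <- outer(type, type, function(pre, post) paste0(pre, post))
    Cmat <- matrix(config$C[pair], n, n)
    prob <- Cmat * exp(-d2 / config$lambda_grid^2)
    diag(prob) <- 0
    conn <- matrix(runif(n * n), n, n) < prob   # conn[pre, post]
    mag <- matrix(abs(rnorm(n * n, mean = config$w_scale,
                            sd = config$w_scale / 2)), n, n)
    sgn <- ifelse(exc, 1, -2)                   # inhibition stronger, 80/20 split
    W_pre_post <- conn * mag * sgn              # rows = pre (sign by pre type)
    W <- t(W_pre_post)                          # W[post, pre]
    n_in <- max(1L, round(config$input_fraction * n))
    input_neurons <- sort(sample.int(n, n_in))
    input_sign <- runif(n_in, 0.5, 1.5)   # positive per-neuron input gains
    structure(list(W = W, excitatory = exc, positions = pos,
                   input_neurons = input_neurons, input_sign = input_sign,
                   n = n, config = config),
              class = "reservoir")
  })
}

#' Encode a feature vector as per-neuron input currents
#'
#' RAW traces are injected as analog currents: each sample drives the seeded
#' random subset of input neurons through fixed signed weights (an affine map
#' with zero offset, so zero input yields zero current). FFT vectors are
#' rendered as a constant current (their signed projection) held for
#' `fft_hold_steps` steps.
#'
#' @param features numeric vector: a RAW windowed trace (possibly several
#'   concatenated channels) or an FFT feature vector
#' @param reservoir a [build_reservoir()] structure
#' @param feature_type `"RAW"` or `"FFT"`
#' @param n_series number of concatenated channels (RAW only)
#' @return matrix time steps x neurons of input currents
#' @export
encode_input <- function(features, reservoir, feature_type = "RAW",
                         n_series = 1L) {
  cfg <- reservoir$config
  n <- reservoir$n
  idx <- reservoir$input_neurons
  if (feature_type == "RAW") {
    len <- length(features) / n_series
    if (len != round(len)) {
      abort("RAW feature length is not a multiple of the channel count")
    }
    U <- matrix(features, nrow = len)          # time x series
    # each series drives an equal share of the input neurons
    share <- split(seq_along(idx),
                   rep_len(seq_len(n_series), length(idx)))
    out <- matrix(0, nrow(U), n)
    for (s in seq_len(n_series)) {
      cols <- idx[share[[s]]]
      out[, cols] <- cfg$input_gain * U[, s] %o% reservoir$input_sign[share[[s]]]
    }
    out
  } else {
    # feature components distributed cyclically over the input neurons and
    # held as constant currents
    comp <- features[((seq_along(idx) - 1) %% length(features)) + 1]
    proj <- cfg$input_gain * comp * reservoir$input_sign
    out <- matrix(0, cfg$fft_hold_steps, n)
    out[, idx] <- rep(proj, each = cfg$fft_hold_steps)
    out
  }
}

#' Simulate the LIF reservoir for one input
#'
#' Explicit-Euler leaky integrate-and-fire update per step:
#' `v <- v + (dt / tau_m) * (-v + input + recurrent)`; a neuron spikes when
#' `v >= theta`, is reset, and held for the refractory period; spikes
#' propagate with a one-step delay; the filtered state is
#' `s <- s * exp(-dt / tau_s) + spikes`.
#'
#' @param currents matrix time steps x neurons of input currents
#' @param reservoir a [build_reservoir()] structure
#' @return a `reservoir_state` list: `state` (final filtered values, one per
#'   neuron), `raster` (logical neurons x time spike raster), `rate_hz`
#'   (mean firing rate per neuron)
#' @export
simulate_reservoir <- function(currents, reservoir) {
  if (any(!is.finite(currents))) abort("non-finite input current")
  cfg <- reservoir$config
  n <- reservoir$n
  T_ <- nrow(currents)
  v <- rep(cfg$v_reset, n)
  s <- numeric(n)
  refr <- numeric(n)
  spk_prev <- numeric(n)
  raster <- matrix(FALSE, n, T_)
  decay <- exp(-cfg$dt_ms / cfg$tau_s_ms)
  a <- cfg$dt_ms / cfg$tau_m_ms
  for (t in seq_len(T_)) {
    input <- currents[t, ] + as.numeric(reservoir$W %*% spk_prev)
    v <- v + a * (-v + input)
    v[refr > 0] <- cfg$v_reset
    spike <- v >= cfg$theta & refr <= 0
    v[spike] <- cfg$v_reset
    refr <- pmax(refr - cfg$dt_ms, 0)
    refr[spike] <- cfg$refractory_ms
    s <- s * decay + spike
    spk_prev <- as.numeric(spike)
    raster[, t] <- spike
  }
  structure(list(state = s, raster = raster, v_final = v,
                 rate_hz = rowMeans(raster) * 1000 / cfg$dt_ms),
            class = "reservoir_state")
}

# Batched final-state computation: rows of `x` are trials. Returns a
# trials x neurons state matrix. Identical dynamics to simulate_reservoir(),
# vectorized across trials for speed.
lsm_state_matrix <- function(x, reservoir, feature_type = "RAW",
                             n_series = 1L) {
  cfg <- reservoir$config
  n <- reservoir$n
  B <- nrow(x)
  if (any(!is.finite(x))) abort("non-finite input current")
  if (feature_type == "RAW") {
    T_ <- ncol(x) / n_series
    if (T_ != round(T_)) abort("RAW feature length is not a multiple of the channel count")
  } else {
    T_ <- cfg$fft_hold_steps
  }
  idx <- reservoir$input_neurons
  share <- split(seq_along(idx), rep_len(seq_len(n_series), length(idx)))
  v <- matrix(cfg$v_reset, n, B)
  s <- matrix(0, n, B)
  total_spikes <- 0
  refr <- matrix(0, n, B)
  spk_prev <- matrix(0, n, B)
  decay <- exp(-cfg$dt_ms / cfg$tau_s_ms)
  a <- cfg$dt_ms / cfg$tau_m_ms
  W <- reservoir$W
  for (t in seq_len(T_)) {
    input <- W %*% spk_prev
    if (feature_type == "RAW") {
      for (sr in seq_len(n_series)) {
        rows <- idx[share[[sr]]]
        u_t <- x[, (sr - 1) * T_ + t]          # length B
        input[rows, ] <- input[rows, ] +
          cfg$input_gain * reservoir$input_sign[share[[sr]]] %o% u_t
      }
    } else {
      comp_idx <- ((seq_along(idx) - 1) %% ncol(x)) + 1
      input[idx, ] <- input[idx, ] +
        cfg$input_gain * (reservoir$input_sign * t(x[, comp_idx, drop = FALSE]))
    }
    v <- v + a * (-v + input)
    v[refr > 0] <- cfg$v_reset
    spike <- v >= cfg$theta & refr <= 0
    v[spike] <- cfg$v_reset
    refr <- pmax(refr - cfg$dt_ms, 0)
    refr[spike] <- cfg$refractory_ms
    s <- s * decay + spike
    spk_prev <- spike + 0
    total_spikes <- total_spikes + sum(spike)
  }
  out <- t(s)
  attr(out, "mean_rate_hz") <- total_spikes / (n * B * T_) * 1000 / cfg$dt_ms
  out
}

#' Fit the linear readout on reservoir states
#'
#' Ridge-regularized logistic regression on the final-time filtered states,
#' emitting class probabilities.
#'
#' @param states matrix trials x neurons
#' @param labels binary labels (0/1)
#' @param lambda ridge penalty
#' @return a fitted glmnet readout
#' @export
fit_readout <- function(states, labels, lambda = 0.1) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2) abort("readout requires both classes present")
  # glmnet warns below 8 observations per class; expected at bootstrap scale
  suppressWarnings(glmnet::glmnet(states, y, family = "binomial", alpha = 0,
                                  lambda = lambda, standardize = FALSE))
}

#' Train a Liquid State Machine classifier
#'
#' Builds the frozen reservoir from the config seed, drives it with the
#' (Min-Max scaled) feature rows, and fits the logistic readout on the
#' final-time filtered states. Inference is noise-free and fully
#' deterministic given (config, seed, data).
#'
#' @param x feature matrix (trials x features) or `lfp_features` tibble
#' @param y binary labels
#' @param config a [reservoir_config()]
#' @param readout_lambda ridge penalty of the readout
#' @param feature_type `"RAW"` or `"FFT"` (taken from `x`'s attribute when
#'   present)
#' @param n_series concatenated channel count (attribute when present)
#' @return an `lsm_model`
#' @export
lsm_train <- function(x, y, config = reservoir_config(),
                      readout_lambda = 0.1,
                      feature_type = attr(x, "feature_type") %||% "RAW",
                      n_series = attr(x, "n_series") %||% 1L) {
  m <- if (is.data.frame(x)) features_as_matrix(x) else as.matrix(x)
  reservoir <- build_reservoir(config)
  states <- lsm_state_matrix(m, reservoir, feature_type, n_series)
  rate <- attr(states, "mean_rate_hz")
  if (rate < config$rate_band_hz[1] || rate > config$rate_band_hz[2]) {
    warn(sprintf("mean reservoir firing rate %.1f Hz outside the %g-%g Hz band",
                 rate, config$rate_band_hz[1], config$rate_band_hz[2]))
  }
  readout <- fit_readout(states, y, readout_lambda)
  mean_rate <- rate
  structure(list(config = config, reservoir = reservoir, readout = readout,
                 readout_lambda = readout_lambda,
                 feature_type = feature_type, n_series = n_series,
                 train_mean_rate_hz = mean_rate),
            class = "lsm_model")
}

#' Predict positive-class probabilities from a trained LSM
#'
#' @param model an [lsm_train()] model
#' @param x feature matrix or `lfp_features` tibble
#' @return numeric vector of probabilities in \[0, 1\]
#' @export
lsm_predict <- function(model, x) {
  if (!inherits(model, "lsm_model") || is.null(model$readout)) {
    abort("`model` must be a trained lsm_model")
  }
  m <- if (is.data.frame(x)) features_as_matrix(x) else as.matrix(x)
  states <- lsm_state_matrix(m, model$reservoir, model$feature_type,
                             model$n_series)
  as.numeric(predict(model$readout, states, type = "response",
                     s = model$readout_lambda))
}

#' @method tidy lsm_model
#' @export
tidy.lsm_model <- function(x, ...) {
  b <- as.numeric(coef(x$readout, s = x$readout_lambda))
  tibble::tibble(term = c("(Intercept)", sprintf("neuron_%03d", seq_len(x$reservoir$n))),
                 estimate = b,
                 excitatory = c(NA, x$reservoir$excitatory))
}

#' @method glance lsm_model
#' @export
glance.lsm_model <- function(x, ...) {
  tibble::tibble(n_neurons = x$reservoir$n,
                 n_connections = sum(x$reservoir$W != 0),
                 excitatory_fraction = mean(x$reservoir$excitatory),
                 readout_lambda = x$readout_lambda,
                 feature_type = x$feature_type,
                 train_mean_rate_hz = x$train_mean_rate_hz)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
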