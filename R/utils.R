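#' @importFrom rlang %||% abort warn
#' @importFrom stats plogis rlnorm rnorm runif predict coef quantile median sd
#' @importFrom utils head
NULL

# Derive a reproducible child seed from a base seed and small integer tags.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed) %% 100003
  for (t in tags) s <- (s * 131 + as.double(t) + 7) %% 2147483629
  as.integer(s)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("configuration error: `%s` must be a single number in [%s, %s]",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

#' Allowed whisker stimulus intensities (percent of maximum deflection)
#' @keywords internal
intensity_levels <- function() c(0, 20, 40, 60, 80, 100)

#' Uniform trial time grid in milliseconds
#'
#' Half-open convention: the grid includes `start_ms` and excludes `end_ms`,
#' sampled at `fs` Hz. The default spans the peri-trial epoch used for
#' quality control, -420 ms to +120 ms around stimulus onset (540 samples
#' at 1 kHz).
#'
#' @param start_ms,end_ms window bounds in ms relative to stimulus onset
#' @param fs sampling rate in Hz
#' @return numeric vector of sample times in ms
#' @export
time_grid_ms <- function(start_ms = -420, end_ms = 120, fs = 1000) {
  step <- 1000 / fs
  seq(start_ms, end_ms - step, by = step)
}

sem <- function(x) stats::sd(x) / sqrt(length(x))
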