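# Small cohorts shared across tests. The 8-channel probe uses 100 um spacing
# so it still spans all four cortical layers.

small_config <- function(n_mice = 2, n_catch = 6, intensity_repeats = 3,
                         seed = 42L, ...) {
  generator_config(n_mice = n_mice, n_catch = n_catch,
                   intensity_repeats = intensity_repeats,
                   n_channels = 8, channel_spacing_um = 100,
                   seed = seed, ...)
}

small_cohort <- function(...) generate_cohort(small_config(...))

# cached, shared across test files within a run
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, maker) {
  if (is.null(.cohort_cache[[key]])) .cohort_cache[[key]] <- maker()
  .cohort_cache[[key]]
}

# a preprocessed 4-mouse cohort used by classifier/validation tests
bench_cohort <- function() {
  cached_cohort("bench", function() {
    preprocess_cohort(generate_cohort(generator_config(
      n_mice = 4, n_catch = 10, intensity_repeats = 5,
      n_channels = 8, channel_spacing_um = 100, seed = 101L)))
  })
}

# shared toy problem: two well-separated Gaussian clouds over 12 features,
# with sequence-layout attributes so every algorithm accepts it
toy_data <- function(n_per_class = 30, gap = 2, seed = 5) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * 12, gap), n_per_class),
               matrix(rnorm(n_per_class * 12, -gap), n_per_class))
  })
  colnames(x) <- sprintf("f%02d", 1:12)
  attr(x, "feature_type") <- "RAW"
  attr(x, "n_series") <- 1L
  attr(x, "series_length") <- 12L
  list(x = x, y = rep(c(1, 0), each = n_per_class))
}

# a probe classifier whose probabilities are a logistic in the first feature
# column; `beta` controls over/under-confidence. Used to exercise Platt
# calibration through the real fit/predict contract.
fit_classifier.clf_probe <- function(clf, x, y, ...) {
  structure(list(name = "probe", params = clf$params, seed = clf$seed,
                 fit = NULL, beta = clf$params$beta %||% 1),
            class = c("fitted_probe", "lfp_fitted"))
}

predict_prob.fitted_probe <- function(clf, x, ...) {
  m <- if (is.data.frame(x)) as.matrix(x[, -1]) else as.matrix(x)
  stats::plogis(clf$beta * m[, 1])
}

probe_classifier <- function(beta) {
  structure(list(name = "probe", params = list(beta = beta), seed = 1L),
            class = c("clf_probe", "lfp_classifier"))
}

registerS3method("fit_classifier", "clf_probe", fit_classifier.clf_probe,
                 envir = asNamespace("lfpdecode"))
registerS3method("predict_prob", "fitted_probe", predict_prob.fitted_probe,
                 envir = asNamespace("lfpdecode"))

`%||%` <- function(a, b) if (is.null(a)) b else a
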