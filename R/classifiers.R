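#' Classifier registry
#'
#' A uniform trainable-classifier contract over the six benchmarked
#' algorithms: Decision Tree (DT, rpart), Random Forest (RF, ranger),
#' gradient-boosted trees (XGB, xgboost), a ROCKET-style random convolutional
#' kernel transform with ridge-logistic readout (RCKT, implemented
#' in-package), ridge-penalized logistic regression (GLM, glmnet) and the
#' spiking Liquid State Machine (LSM, implemented in-package). Every
#' classifier trains on a feature matrix plus binary labels via
#' [fit_classifier()] and emits positive-class probabilities via
#' [predict_prob()]; stochastic algorithms are seeded for full
#' reproducibility.
#'
#' @param name one of `"DT"`, `"RF"`, `"XGB"`, `"RCKT"`, `"GLM"`, `"LSM"`
#' @param params named list of hyperparameters (see [default_grid()] for the
#'   tunable ones per algorithm)
#' @param seed integer seed for any algorithmic randomness
#' @return an `lfp_classifier` specification
#' @export
build_classifier <- function(name, params = list(), seed = 1L) {
  valid <- c("DT", "RF", "XGB", "RCKT", "GLM", "LSM")
  if (!name %in% valid) {
    abort(sprintf("unknown classifier '%s'; valid names: %s",
                  name, paste(valid, collapse = ", ")))
  }
  structure(list(name = name, params = params, seed = as.integer(seed)),
            class = c(paste0("clf_", tolower(name)), "lfp_classifier"))
}

#' Fit a classifier / predict probabilities
#'
#' @param clf an [build_classifier()] specification (`fit_classifier`) or a
#'   fitted model (`predict_prob`)
#' @param x numeric feature matrix, trials x features (an `lfp_features`
#'   tibble is accepted; its layout attributes are forwarded to
#'   sequence-aware algorithms)
#' @param y binary labels (0/1)
#' @param ... unused
#' @return `fit_classifier()`: a fitted `lfp_fitted` model;
#'   `predict_prob()`: numeric positive-class probabilities
#' @export
fit_classifier <- function(clf, x, y, ...) UseMethod("fit_classifier")

#' @rdname fit_classifier
#' @export
predict_prob <- function(clf, x, ...) UseMethod("predict_prob")

clf_matrix <- function(x) {
  if (is.data.frame(x)) features_as_matrix(x) else as.matrix(x)
}

new_fitted <- function(clf, fit, extra = list()) {
  structure(c(list(name = clf$name, params = clf$params, seed = clf$seed,
                   fit = fit), extra),
            class = c(paste0("fitted_", tolower(clf$name)), "lfp_fitted"))
}

check_two_classes <- function(y) {
  if (length(unique(as.integer(y))) < 2) {
    abort("training labels must contain both classes")
  }
}

# ---- DT ---------------------------------------------------------------

#' @export
fit_classifier.clf_dt <- function(clf, x, y, ...) {
  check_two_classes(y)
  m <- clf_matrix(x)
  colnames(m) <- sprintf("f%05d", seq_len(ncol(m)))
  df <- as.data.frame(m)
  df$.label <- factor(y, levels = c(0, 1))
  p <- clf$params
  fit <- rpart::rpart(.label ~ ., data = df, method = "class",
                      control = rpart::rpart.control(
                        maxdepth = p$maxdepth %||% 10,
                        cp = p$cp %||% 0.01,
                        minsplit = p$minsplit %||% 10,
                        xval = 0))
  new_fitted(clf, fit)
}

#' @export
predict_prob.fitted_dt <- function(clf, x, ...) {
  m <- clf_matrix(x)
  colnames(m) <- sprintf("f%05d", seq_len(ncol(m)))
  unname(predict(clf$fit, as.data.frame(m), type = "prob")[, "1"])
}

# ---- RF ---------------------------------------------------------------

#' @export
fit_classifier.clf_rf <- function(clf, x, y, ...) {
  check_two_classes(y)
  m <- clf_matrix(x)
  colnames(m) <- sprintf("f%05d", seq_len(ncol(m)))
  p <- clf$params
  fit <- ranger::ranger(x = m, y = factor(y, levels = c(0, 1)),
                        probability = TRUE,
                        num.trees = p$num_trees %||% 200,
                        mtry = max(1, floor((p$mtry_frac %||% 0.33) * ncol(m))),
                        seed = clf$seed, num.threads = 1)
  new_fitted(clf, fit)
}

#' @export
predict_prob.fitted_rf <- function(clf, x, ...) {
  m <- clf_matrix(x)
  colnames(m) <- sprintf("f%05d", seq_len(ncol(m)))
  unname(predict(clf$fit, data = m, num.threads = 1)$predictions[, "1"])
}

# ---- XGB --------------------------------------------------------------

#' @export
fit_classifier.clf_xgb <- function(clf, x, y, ...) {
  check_two_classes(y)
  p <- clf$params
  dtrain <- xgboost::xgb.DMatrix(clf_matrix(x), label = as.integer(y))
  fit <- withr::with_seed(clf$seed,
    xgboost::xgb.train(params = list(objective = "binary:logistic",
                                     max_depth = p$max_depth %||% 3,
                                     eta = p$eta %||% 0.3,
                                     nthread = 1),
                       data = dtrain,
                       nrounds = p$nrounds %||% 50,
                       verbose = 0))
  new_fitted(clf, fit)
}

#' @export
predict_prob.fitted_xgb <- function(clf, x, ...) {
  as.numeric(predict(clf$fit, xgboost::xgb.DMatrix(clf_matrix(x))))
}

# ---- GLM (ridge-penalized logistic regression) ------------------------

#' @export
fit_classifier.clf_glm <- function(clf, x, y, ...) {
  check_two_classes(y)
  lam <- clf$params$lambda %||% 0.01
  # glmnet warns below 8 observations per class; expected at bootstrap scale
  fit <- suppressWarnings(
    glmnet::glmnet(clf_matrix(x), as.integer(y), family = "binomial",
                   alpha = 0, lambda = lam, standardize = FALSE))
  new_fitted(clf, fit, list(lambda = lam))
}

#' @export
predict_prob.fitted_glm <- function(clf, x, ...) {
  as.numeric(predict(clf$fit, clf_matrix(x), type = "response",
                     s = clf$lambda))
}

# ---- RCKT (random convolutional kernel transform) ---------------------

# Random kernels in the ROCKET style: length in {7, 9, 11}, centered normal
# weights, random bias, exponentially sampled dilation, optional padding.
# Multivariate input mixes a random subset of channels per kernel.
rocket_kernels <- function(n_kernels, series_length, n_series, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n_kernels), function(i) {
      len <- sample(c(7L, 9L, 11L), 1)
      max_exp <- log2((series_length - 1) / (len - 1))
      dil <- 2L^as.integer(runif(1, 0, max(max_exp, 0)))
      w <- rnorm(len)
      n_ch <- sample.int(n_series, 1)
      list(length = len, dilation = dil,
           weights = w - mean(w),
           bias = runif(1, -1, 1),
           padding = sample(c(TRUE, FALSE), 1),
           channels = sort(sample.int(n_series, n_ch)),
           ch_weights = rnorm(n_ch))
    })
  })
}

# Apply kernels to all trials at once; returns trials x (2 * n_kernels)
# pooled features (max and proportion of positive values per kernel).
rocket_transform <- function(x, kernels, series_length, n_series) {
  B <- nrow(x)
  out <- matrix(0, B, 2 * length(kernels))
  for (ki in seq_along(kernels)) {
    k <- kernels[[ki]]
    span <- (k$length - 1) * k$dilation
    pad <- if (k$padding) span %/% 2 else 0
    starts <- seq(1 - pad, series_length - span + pad)
    if (length(starts) < 1) starts <- 1
    conv <- matrix(k$bias, B, length(starts))
    for (ci in seq_along(k$channels)) {
      ch <- k$channels[ci]
      off <- (ch - 1) * series_length
      for (li in seq_len(k$length)) {
        pos <- starts + (li - 1) * k$dilation
        valid <- pos >= 1 & pos <= series_length
        if (!any(valid)) next
        conv[, valid] <- conv[, valid] +
          (k$ch_weights[ci] * k$weights[li]) * x[, off + pos[valid], drop = FALSE]
      }
    }
    out[, 2 * ki - 1] <- apply(conv, 1, max)
    out[, 2 * ki] <- rowMeans(conv > 0)
  }
  colnames(out) <- paste0("k", rep(seq_along(kernels), each = 2),
                          c("_max", "_ppv"))
  out
}

#' @export
fit_classifier.clf_rckt <- function(clf, x, y, ...) {
  check_two_classes(y)
  m <- clf_matrix(x)
  p <- clf$params
  n_series <- attr(x, "n_series") %||% 1L
  series_length <- attr(x, "series_length") %||% ncol(m)
  if (is.na(series_length)) series_length <- ncol(m)  # FFT rows as a sequence
  kernels <- rocket_kernels(p$n_kernels %||% 200, series_length, n_series,
                            clf$seed)
  feat <- rocket_transform(m, kernels, series_length, n_series)
  scaler <- suppressWarnings(fit_minmax(feat))
  feat <- apply_minmax(scaler, feat)
  lam <- p$lambda %||% 0.1
  readout <- suppressWarnings(
    glmnet::glmnet(feat, as.integer(y), family = "binomial",
                   alpha = 0, lambda = lam, standardize = FALSE))
  new_fitted(clf, readout,
             list(kernels = kernels, scaler = scaler, lambda = lam,
                  n_series = n_series, series_length = series_length))
}

#' @export
predict_prob.fitted_rckt <- function(clf, x, ...) {
  m <- clf_matrix(x)
  feat <- rocket_transform(m, clf$kernels, clf$series_length, clf$n_series)
  feat <- apply_minmax(clf$scaler, feat)
  as.numeric(predict(clf$fit, feat, type = "response", s = clf$lambda))
}

# ---- LSM --------------------------------------------------------------

#' @export
fit_classifier.clf_lsm <- function(clf, x, y, ...) {
  check_two_classes(y)
  p <- clf$params
  config <- p$config %||% reservoir_config(seed = clf$seed)
  model <- lsm_train(x, y, config = config,
                     readout_lambda = p$readout_lambda %||% 0.1,
                     feature_type = attr(x, "feature_type") %||% "RAW",
                     n_series = attr(x, "n_series") %||% 1L)
  new_fitted(clf, model)
}

#' @export
predict_prob.fitted_lsm <- function(clf, x, ...) {
  lsm_predict(clf$fit, x)
}

# ---- grids ------------------------------------------------------------

#' Default hyperparameter grids
#'
#' Small, documented grids (at most 12 points) searched by
#' [grid_search_cv()]. The GLM grid spans four orders of magnitude of ridge
#' penalty.
#'
#' @param name classifier name
#' @return list of named parameter lists, in search order
#' @export
default_grid <- function(name) {
  valid <- c("DT", "RF", "XGB", "RCKT", "GLM", "LSM")
  if (!name %in% valid) {
    abort(sprintf("unknown classifier '%s'; valid names: %s",
                  name, paste(valid, collapse = ", ")))
  }
  switch(name,
    DT = lapply(c(2, 5, 10), function(d) list(maxdepth = d, cp = 0.01)),
    RF = unlist(lapply(c(100, 300), function(nt) {
      lapply(c(0.1, 0.33), function(mf) list(num_trees = nt, mtry_frac = mf))
    }), recursive = FALSE),
    XGB = unlist(lapply(c(30, 100), function(nr) {
      lapply(c(2, 4), function(md) list(nrounds = nr, max_depth = md))
    }), recursive = FALSE),
    RCKT = lapply(c(0.01, 0.1, 1), function(l) {
      list(n_kernels = 200, lambda = l)
    }),
    GLM = lapply(c(1e-3, 1e-2, 1e-1, 1), function(l) list(lambda = l)),
    LSM = lapply(c(0.01, 0.1, 1), function(l) list(readout_lambda = l)))
}
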