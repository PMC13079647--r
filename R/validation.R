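#' Leave-one-mouse-out split plan with bootstraps
#'
#' One split family per mouse: all trials of the held-out mouse form the
#' testing set and are never seen during scaling, balancing, grid search or
#' training. Each family carries `n_bootstraps` bootstrap entries whose seeds
#' depend only on (plan seed, mouse, bootstrap index), so two algorithms
#' evaluated under the same plan receive byte-identical training multisets.
#' A 4-mouse, 10-bootstrap plan yields 40 evaluations per
#' scenario-algorithm.
#'
#' @param cohort an `lfp_cohort` (at least 2 mice)
#' @param n_bootstraps bootstrap samples per training-testing split
#' @param seed integer plan seed
#' @return a `split_plan` tibble: held_out_mouse, bootstrap (0-based),
#'   bootstrap_seed
#' @export
make_split_plan <- function(cohort, n_bootstraps = 10, seed = 1L) {
  mice <- sort(unique(cohort$mouse_id))
  if (length(mice) < 2) {
    abort("cross-individual validation requires at least 2 mice")
  }
  plan <- tidyr::expand_grid(held_out_mouse = mice,
                             bootstrap = seq_len(n_bootstraps) - 1L)
  plan$bootstrap_seed <- purrr::map2_int(
    match(plan$held_out_mouse, mice), plan$bootstrap,
    function(m, b) derive_seed(seed, m, b))
  structure(plan, seed = as.integer(seed),
            class = c("split_plan", class(plan)))
}

#' Balance classes by downsampling the majority
#'
#' Uniformly downsamples the majority class without replacement so both
#' classes keep the minority count; the positive fraction of the result is
#' exactly 0.5.
#'
#' @param idx indices (or any vector) identifying the trials
#' @param labels binary labels aligned with `idx`
#' @param seed integer seed for the downsampling draw
#' @return the balanced subset of `idx`
#' @export
balance_by_downsampling <- function(idx, labels, seed = 1L) {
  labels <- as.integer(labels)
  pos <- idx[labels == 1]
  neg <- idx[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) {
    abort("both classes must be present to balance")
  }
  n <- min(length(pos), length(neg))
  withr::with_seed(seed, {
    if (length(pos) > n) pos <- sample(pos, n)
    if (length(neg) > n) neg <- sample(neg, n)
  })
  c(pos, neg)
}

#' Stratified k-fold grid search
#'
#' Evaluates every grid point by stratified k-fold cross-validated accuracy
#' (threshold 0.5) and returns the first grid point attaining the maximum
#' (ties broken by grid order).
#'
#' @param name classifier name (see [build_classifier()])
#' @param grid list of parameter lists, e.g. [default_grid()]
#' @param x training feature matrix
#' @param y training labels
#' @param k number of folds
#' @param seed integer seed for fold assignment
#' @param clf_seed seed passed to the classifier itself
#' @return list: `best_params`, `cv_accuracy` (per grid point), `best_index`
#' @export
grid_search_cv <- function(name, grid, x, y, k = 3, seed = 1L, clf_seed = 1L) {
  if (length(grid) == 0) abort("grid must be non-empty")
  y <- as.integer(y)
  n <- length(y)
  if (n < k) abort("fewer trials than folds")
  if (length(grid) == 1) {
    return(list(best_params = grid[[1]], cv_accuracy = NA_real_,
                best_index = 1L))
  }
  folds <- integer(n)
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      rows <- sample(which(y == cls))
      folds[rows] <- rep_len(seq_len(k), length(rows))
    }
  })
  acc <- vapply(grid, function(params) {
    fold_acc <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2 || !any(!tr)) return(NA_real_)
      clf <- build_classifier(name, params, seed = clf_seed)
      fit <- fit_classifier(clf, subset_features(x, tr), y[tr])
      p <- predict_prob(fit, subset_features(x, !tr))
      mean((p >= 0.5) == (y[!tr] == 1))
    }, numeric(1))
    mean(fold_acc, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(acc)  # first maximum = grid order tie-break
  list(best_params = grid[[best]], cv_accuracy = acc, best_index = best)
}

# Row-subset a feature matrix while preserving layout attributes.
subset_features <- function(x, rows) {
  if (is.data.frame(x)) {
    out <- x[rows, , drop = FALSE]
    attr(out, "feature_type") <- attr(x, "feature_type")
    attr(out, "n_series") <- attr(x, "n_series")
    attr(out, "series_length") <- attr(x, "series_length")
    out
  } else {
    m <- x[rows, , drop = FALSE]
    attr(m, "feature_type") <- attr(x, "feature_type")
    attr(m, "n_series") <- attr(x, "n_series")
    attr(m, "series_length") <- attr(x, "series_length")
    m
  }
}

# ---- metrics ----------------------------------------------------------

#' Classification metrics from probabilities
#'
#' `roc_auc()` is the trapezoidal area under the ROC curve (equivalently the
#' tie-corrected Mann-Whitney statistic); `pr_auc()` is average precision
#' (the step-wise area under the precision-recall curve); `brier_score()` is
#' the mean squared probability error.
#'
#' @param p predicted positive-class probabilities
#' @param y binary labels (0/1)
#' @return a single number
#' @export
roc_auc <- function(p, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname roc_auc
#' @export
pr_auc <- function(p, y) {
  y <- as.integer(y)
  if (sum(y == 1) == 0 || sum(y == 0) == 0) return(NA_real_)
  ord <- order(p, decreasing = TRUE)
  y <- y[ord]
  p <- p[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  # evaluate at distinct thresholds only (last index of each tied block)
  keep <- c(p[-1] != p[-length(p)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / sum(y == 1)
  sum(diff(c(0, rec)) * prec)
}

#' @rdname roc_auc
#' @export
brier_score <- function(p, y) mean((p - as.integer(y))^2)

#' Evaluate a fitted model on a testing set
#'
#' Computes accuracy at threshold 0.5, ROC AUC, PR AUC and the Brier score;
#' when a Platt calibrator is supplied, probabilities are transformed before
#' all metrics. On a single-class testing set the AUCs are reported as `NA`
#' with a warning.
#'
#' @param fitted a fitted classifier from [fit_classifier()]
#' @param x testing feature matrix
#' @param y testing labels
#' @param calibrator optional [platt_calibrate()] result
#' @return one-row tibble of metrics
#' @export
evaluate_model <- function(fitted, x, y, calibrator = NULL) {
  y <- as.integer(y)
  p <- predict_prob(fitted, x)
  if (!is.null(calibrator)) p <- predict(calibrator, p)
  if (length(unique(y)) < 2) {
    warn("single-class testing set: ROC/PR AUC undefined")
  }
  tibble::tibble(accuracy = mean((p >= 0.5) == (y == 1)),
                 roc_auc = roc_auc(p, y),
                 pr_auc = pr_auc(p, y),
                 brier = brier_score(p, y),
                 calibrated = !is.null(calibrator))
}

# ---- Platt calibration ------------------------------------------------

#' Platt calibration with a training hold-out
#'
#' Splits the training set (stratified) into a model part (67%) and a
#' calibration hold-out (33%), refits the classifier on the model part, and
#' fits a univariate logistic regression mapping its hold-out probabilities
#' to the hold-out labels. The returned calibrator contains the refitted
#' model; testing data plays no role in calibration.
#'
#' @param clf an unfitted classifier specification
#' @param x training feature matrix
#' @param y training labels
#' @param holdout_fraction fraction of the training set held out
#' @param seed integer seed for the stratified split
#' @return a `platt_calibrator`: `model` (refit on 67%), `calibration`
#'   (the logistic map), usable via `predict(calibrator, p)`
#' @export
platt_calibrate <- function(clf, x, y, holdout_fraction = 1 / 3, seed = 1L) {
  y <- as.integer(y)
  n <- length(y)
  hold <- logical(n)
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      rows <- which(y == cls)
      hold[sample(rows, max(1, round(holdout_fraction * length(rows))))] <- TRUE
    }
  })
  if (length(unique(y[hold])) < 2) {
    abort("calibration hold-out contains a single class")
  }
  if (length(unique(y[!hold])) < 2) {
    abort("model part contains a single class")
  }
  model <- fit_classifier(clf, subset_features(x, !hold), y[!hold])
  p_hold <- predict_prob(model, subset_features(x, hold))
  # separation on an easy hold-out makes the logistic map step-like but
  # still monotone; glm.fit's separation warning is expected there
  cal <- suppressWarnings(stats::glm(y[hold] ~ p_hold,
                                     family = stats::binomial()))
  structure(list(model = model, calibration = cal,
                 holdout_fraction = holdout_fraction,
                 n_model = sum(!hold), n_holdout = sum(hold)),
            class = "platt_calibrator")
}

#' @export
predict.platt_calibrator <- function(object, newdata, ...) {
  as.numeric(predict(object$calibration,
                     data.frame(p_hold = as.numeric(newdata)),
                     type = "response"))
}

#' @method tidy platt_calibrator
#' @export
tidy.platt_calibrator <- function(x, ...) {
  co <- coef(x$calibration)
  tibble::tibble(term = names(co), estimate = as.numeric(co))
}

# ---- significance tests -----------------------------------------------

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired values (e.g. accuracies of two
#' algorithms over the same mouse x bootstrap splits). Zero differences are
#' dropped (classic convention) and their count reported; the exact
#' `psignrank` null distribution is used for up to 25 non-zero pairs without
#' ties, otherwise a normal approximation with continuity and tie
#' correction. With fewer than 2 non-zero differences the p-value is `NA`.
#'
#' @param a,b paired numeric vectors of equal length
#' @return one-row tibble: statistic (W+), p_value, n_nonzero, n_zero
#' @export
paired_wilcoxon <- function(a, b) {
  if (length(a) != length(b)) abort("paired vectors must have equal length")
  d <- a - b
  zero <- d == 0
  d <- d[!zero]
  n <- length(d)
  if (n < 2) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          n_nonzero = n, n_zero = sum(zero)))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= 25) {
    p <- 2 * min(stats::psignrank(W, n),
                 1 - stats::psignrank(W - 1, n))
  } else {
    mu <- n * (n + 1) / 4
    tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
    z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(statistic = W, p_value = min(p, 1),
                 n_nonzero = n, n_zero = sum(zero))
}

#' Exact test of classification accuracy against chance
#'
#' Builds the 2x2 contingency table of observed correct/incorrect counts
#' against the counts expected under chance-level accuracy and applies
#' Fisher's exact test.
#'
#' @param correct_count number of correctly classified samples
#' @param n total samples (> 0)
#' @param chance chance-level accuracy
#' @return two-sided p-value
#' @export
fisher_exact_vs_chance <- function(correct_count, n, chance = 0.5) {
  if (n <= 0) abort("`n` must be positive")
  if (correct_count < 0 || correct_count > n) {
    abort("`correct_count` must lie in [0, n]")
  }
  expected <- round(chance * n)
  tab <- matrix(c(correct_count, n - correct_count,
                  expected, n - expected), nrow = 2)
  stats::fisher.test(tab)$p.value
}

#' Wall-clock runtime per sample
#'
#' @param fn a zero-argument callable
#' @param n_samples the set size the runtime is normalized by
#' @return list: `seconds_per_sample`, `seconds_total`, and `value` (the
#'   callable's result)
#' @export
measure_runtime <- function(fn, n_samples) {
  if (n_samples <= 0) abort("`n_samples` must be positive")
  t0 <- proc.time()[["elapsed"]]
  value <- fn()
  dt <- proc.time()[["elapsed"]] - t0
  list(seconds_per_sample = dt / n_samples, seconds_total = dt, value = value)
}
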