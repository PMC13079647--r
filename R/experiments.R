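#' Classification scenario specification
#'
#' One cell of the benchmark grid: the task (SD = stimulus detection,
#' RP = response prediction), the analysis window (PRE, PERI, FULL, with an
#' optional truncated PERI for the shortened-signal sweep), the feature type
#' (RAW or FFT), the cortical layer (or ALL for the four-layer
#' concatenation), the stimulus-intensity subset, and the class-balancing
#' toggles.
#'
#' @param task `"SD"` (positive = stimulus present) or `"RP"` (positive =
#'   lick within the +100 to +500 ms window of opportunity)
#' @param window `"PRE"`, `"PERI"` or `"FULL"`
#' @param feature_type `"RAW"` or `"FFT"`
#' @param layer `"L2/3"`, `"L4"`, `"L5"`, `"L6"` or `"ALL"`
#' @param intensity_subset `"all"` or a numeric vector of intensities to
#'   keep (e.g. `c(0, 100)` to contrast catch and full-intensity trials)
#' @param balance downsample the training set to a 50/50 class mix
#' @param balance_test downsample the testing set likewise (so chance-level
#'   accuracy is 50%)
#' @param peri_truncation_ms optional truncation of the PERI window in ms
#' @return a `scenario_spec` list
#' @export
scenario_spec <- function(task = c("SD", "RP"),
                          window = c("PERI", "PRE", "FULL"),
                          feature_type = c("RAW", "FFT"),
                          layer = "L4",
                          intensity_subset = "all",
                          balance = TRUE,
                          balance_test = TRUE,
                          peri_truncation_ms = NULL) {
  task <- match.arg(task)
  window <- match.arg(window)
  feature_type <- match.arg(feature_type)
  if (!layer %in% c("L2/3", "L4", "L5", "L6", "ALL")) {
    abort("`layer` must be one of L2/3, L4, L5, L6, ALL")
  }
  if (!is.null(peri_truncation_ms) && window == "PRE") {
    abort("PERI truncation requires the PERI or FULL window")
  }
  structure(list(task = task, window = window, feature_type = feature_type,
                 layer = layer, intensity_subset = intensity_subset,
                 balance = balance, balance_test = balance_test,
                 peri_truncation_ms = peri_truncation_ms),
            class = "scenario_spec")
}

#' Binary labels for a classification task
#'
#' SD: positive iff a stimulus was presented (intensity > 0). RP: positive
#' iff the lick latency falls in the +100 to +500 ms window of opportunity.
#' Trials with licks before +100 ms must have been excluded upstream by
#' [filter_trials()]; encountering one here is an error.
#'
#' @param cohort an `lfp_cohort` (or its trial tibble)
#' @param task `"SD"` or `"RP"`
#' @return integer vector of 0/1 labels
#' @export
label_trials <- function(cohort, task) {
  if (!task %in% c("SD", "RP")) abort(sprintf("unknown task '%s'", task))
  lat <- cohort$lick_latency_ms
  if (any(!is.na(lat) & lat >= 0 & lat < 100)) {
    abort("early-lick trials present; run filter_trials() first")
  }
  if (task == "SD") {
    as.integer(cohort$intensity_pct > 0)
  } else {
    as.integer(!is.na(lat) & lat >= 100 & lat < 500)
  }
}

scenario_id <- function(scenario) {
  subset_lbl <- if (identical(scenario$intensity_subset, "all")) "all" else
    paste(scenario$intensity_subset, collapse = "+")
  sprintf("%s.%s.%s.%s.%s%s", scenario$task, scenario$window,
          scenario$feature_type, gsub("/", "", scenario$layer), subset_lbl,
          if (is.null(scenario$peri_truncation_ms)) "" else
            sprintf(".%gms", scenario$peri_truncation_ms))
}

#' Run one classification scenario under a split plan
#'
#' For every (held-out mouse, bootstrap) entry of the plan: balance the
#' training mice's trials by downsampling, draw the bootstrap sample (seeded
#' identically across algorithms), fit the train-anchored Min-Max scaler,
#' tune hyperparameters by stratified 3-fold grid search, train the selected
#' model on the full bootstrap multiset, and evaluate on the held-out mouse.
#' Runtime is wall-clock seconds normalized by the respective set size.
#'
#' @param cohort a QC-filtered, Butterworth-filtered `lfp_cohort`
#' @param scenario a [scenario_spec()]
#' @param algorithm classifier name (see [build_classifier()])
#' @param plan a [make_split_plan()]
#' @param grid hyperparameter grid (default: [default_grid()] of the
#'   algorithm)
#' @param calibrate apply [platt_calibrate()] (refit on 67% of the training
#'   multiset, logistic map from the 33% hold-out)
#' @param cv_folds folds of the tuning cross-validation
#' @return an `lfp_eval` tibble, one row per evaluation
#' @export
run_scenario <- function(cohort, scenario, algorithm, plan,
                         grid = default_grid(algorithm),
                         calibrate = FALSE, cv_folds = 3) {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (!identical(scenario$intensity_subset, "all")) {
    keep <- cohort$intensity_pct %in% scenario$intensity_subset
    cohort <- cohort_slice(cohort, keep)
  }
  labels <- label_trials(cohort, scenario$task)
  sid <- scenario_id(scenario)
  sc_task <- scenario$task; sc_window <- scenario$window
  sc_ftype <- scenario$feature_type; sc_layer <- scenario$layer
  win <- window_spec(scenario$window, scenario$peri_truncation_ms)
  feats <- feature_matrix(cohort, win, scenario$feature_type, scenario$layer)
  mouse <- cohort$mouse_id
  rows <- purrr::pmap(plan, function(held_out_mouse, bootstrap,
                                     bootstrap_seed, ...) {
    tr_all <- which(mouse != held_out_mouse)
    te_all <- which(mouse == held_out_mouse)
    tr <- if (scenario$balance) {
      balance_by_downsampling(tr_all, labels[tr_all],
                              seed = derive_seed(bootstrap_seed, 11))
    } else tr_all
    te <- if (scenario$balance_test) {
      balance_by_downsampling(te_all, labels[te_all],
                              seed = derive_seed(bootstrap_seed, 17))
    } else te_all
    boot <- withr::with_seed(derive_seed(bootstrap_seed, 13),
                             sample(tr, length(tr), replace = TRUE))
    x_tr <- subset_features(feats, boot)
    y_tr <- labels[boot]
    scaler <- suppressWarnings(fit_minmax(x_tr))
    x_tr <- subset_features(apply_minmax(scaler, x_tr), TRUE)
    x_te <- subset_features(apply_minmax(scaler, subset_features(feats, te)),
                            TRUE)
    y_te <- labels[te]
    clf_seed <- derive_seed(bootstrap_seed, 23)
    gs <- grid_search_cv(algorithm, grid, x_tr, y_tr, k = cv_folds,
                         seed = derive_seed(bootstrap_seed, 19),
                         clf_seed = clf_seed)
    clf <- build_classifier(algorithm, gs$best_params, seed = clf_seed)
    calibrator <- NULL
    if (calibrate) {
      train_rt <- measure_runtime(function() {
        platt_calibrate(clf, x_tr, y_tr,
                        seed = derive_seed(bootstrap_seed, 29))
      }, length(boot))
      calibrator <- train_rt$value
      fitted <- calibrator$model
    } else {
      train_rt <- measure_runtime(function() fit_classifier(clf, x_tr, y_tr),
                                  length(boot))
      fitted <- train_rt$value
    }
    infer_rt <- measure_runtime(function() predict_prob(fitted, x_te),
                                length(te))
    metrics <- evaluate_model(fitted, x_te, y_te, calibrator)
    dplyr::bind_cols(
      tibble::tibble(scenario = sid,
                     task = sc_task, window = sc_window,
                     feature_type = sc_ftype, layer = sc_layer,
                     algorithm = algorithm,
                     held_out_mouse = held_out_mouse,
                     bootstrap = bootstrap,
                     n_train = length(boot), n_test = length(te),
                     train_multiset = paste(sort(boot), collapse = ","),
                     train_runtime_per_sample = train_rt$seconds_per_sample,
                     infer_runtime_per_sample = infer_rt$seconds_per_sample),
      metrics)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("lfp_eval", class(out))
  out
}

#' Run the full benchmark grid
#'
#' Cross product of scenarios and algorithms; one tidy row per evaluation.
#'
#' @param cohort a QC-filtered, Butterworth-filtered `lfp_cohort`
#' @param scenarios list of [scenario_spec()]s
#' @param algorithms character vector of classifier names
#' @param plan a [make_split_plan()]
#' @param ... forwarded to [run_scenario()]
#' @return an `lfp_benchmark` tibble
#' @export
run_benchmark <- function(cohort, scenarios, algorithms, plan, ...) {
  out <- purrr::map_dfr(scenarios, function(sc) {
    purrr::map_dfr(algorithms, function(alg) {
      run_scenario(cohort, sc, alg, plan, ...)
    })
  })
  class(out) <- c("lfp_benchmark", "lfp_eval", class(tibble::tibble()))
  out
}

#' Stimulus-detection accuracy across intensities and peri-stimulus lengths
#'
#' For every (intensity, peri length) cell, runs the SD task contrasting
#' catch trials against that intensity on the truncated PERI window and
#' aggregates mean accuracy and its standard error over the plan's
#' evaluations.
#'
#' @param cohort a QC-filtered, Butterworth-filtered `lfp_cohort`
#' @param plan a [make_split_plan()]
#' @param intensities non-zero intensities to contrast against catch trials
#' @param lengths_ms peri-stimulus signal lengths in ms
#' @param algorithm classifier name (default the Liquid State Machine)
#' @param layer cortical layer
#' @param ... forwarded to [run_scenario()]
#' @return an `lfp_sweep` tibble: intensity_pct, length_ms, mean_accuracy,
#'   sem, n; full per-evaluation reports in `attr(, "reports")`
#' @export
peri_length_sweep <- function(cohort, plan,
                              intensities = c(20, 40, 60, 80, 100),
                              lengths_ms = seq(20, 100, by = 20),
                              algorithm = "LSM", layer = "L4", ...) {
  reports <- purrr::map_dfr(intensities, function(inten) {
    purrr::map_dfr(lengths_ms, function(len) {
      sc <- scenario_spec("SD", "PERI", "RAW", layer,
                          intensity_subset = c(0, inten),
                          peri_truncation_ms = len)
      ev <- run_scenario(cohort, sc, algorithm, plan, ...)
      ev$intensity_pct <- inten
      ev$length_ms <- len
      ev
    })
  })
  out <- reports |>
    dplyr::group_by(.data$intensity_pct, .data$length_ms) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                     sem = sem(.data$accuracy),
                     n = dplyr::n(), .groups = "drop")
  attr(out, "reports") <- reports
  class(out) <- c("lfp_sweep", class(out))
  out
}

#' Calibration analysis on balanced and imbalanced data
#'
#' Re-runs the selected algorithms with and without training-set
#' downsampling and with and without Platt calibration, keeping the testing
#' set at its natural class mix, and adds a naive always-positive baseline
#' per split.
#'
#' @param cohort a QC-filtered, Butterworth-filtered `lfp_cohort`
#' @param plan a [make_split_plan()]
#' @param algorithms classifier names
#' @param intensity_subset `"all"` (83% stimulus trials with the default
#'   session mix) or a vector such as `c(0, 100)`
#' @param layer,feature_type,window scenario fixings
#' @param ... forwarded to [run_scenario()]
#' @return an `lfp_eval` tibble with `balanced` and `calibrated` columns,
#'   including `algorithm = "naive_positive"` baseline rows
#' @export
run_imbalanced_analysis <- function(cohort, plan,
                                    algorithms = c("GLM", "LSM"),
                                    intensity_subset = "all",
                                    layer = "L4", feature_type = "RAW",
                                    window = "PERI", ...) {
  grid_cells <- tidyr::expand_grid(algorithm = algorithms,
                                   balanced = c(TRUE, FALSE),
                                   calibrated = c(FALSE, TRUE))
  out <- purrr::pmap_dfr(grid_cells, function(algorithm, balanced, calibrated) {
    sc <- scenario_spec("SD", window, feature_type, layer,
                        intensity_subset = intensity_subset,
                        balance = balanced, balance_test = FALSE)
    ev <- run_scenario(cohort, sc, algorithm, plan, calibrate = calibrated, ...)
    ev$balanced <- balanced
    ev
  })
  # naive always-positive baseline on the same testing sets
  if (!identical(intensity_subset, "all")) {
    cohort <- cohort_slice(cohort, cohort$intensity_pct %in% intensity_subset)
  }
  labels <- label_trials(cohort, "SD")
  naive <- purrr::pmap_dfr(plan, function(held_out_mouse, ...) {
    y <- labels[cohort$mouse_id == held_out_mouse]
    tibble::tibble(algorithm = "naive_positive",
                   held_out_mouse = held_out_mouse,
                   accuracy = mean(y == 1),
                   roc_auc = NA_real_, pr_auc = NA_real_,
                   brier = mean((1 - y)^2),
                   calibrated = FALSE, balanced = FALSE)
  })
  out <- dplyr::bind_rows(out, dplyr::distinct(naive))
  class(out) <- c("lfp_eval", class(tibble::tibble()))
  out
}
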