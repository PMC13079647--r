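#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_point
#'   geom_errorbar geom_col scale_fill_viridis_c labs theme_minimal
#'   facet_grid position_dodge
NULL

#' Heatmap of median benchmark accuracy
#'
#' @param object an `lfp_benchmark` from [run_benchmark()]
#' @param ... unused
#' @return a ggplot
#' @method autoplot lfp_benchmark
#' @export
autoplot.lfp_benchmark <- function(object, ...) {
  med <- object |>
    dplyr::group_by(.data$scenario, .data$algorithm) |>
    dplyr::summarise(accuracy = stats::median(.data$accuracy),
                     .groups = "drop")
  ggplot(med, aes(x = .data$scenario, y = .data$algorithm,
                  fill = .data$accuracy)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0.4, 1)) +
    labs(x = "classification scenario", y = NULL,
         fill = "median\naccuracy") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Accuracy against peri-stimulus signal length per intensity
#'
#' @param object an `lfp_sweep` from [peri_length_sweep()]
#' @param ... unused
#' @return a ggplot
#' @method autoplot lfp_sweep
#' @export
autoplot.lfp_sweep <- function(object, ...) {
  ggplot(object, aes(x = .data$length_ms, y = .data$mean_accuracy,
                     colour = factor(.data$intensity_pct),
                     group = .data$intensity_pct)) +
    geom_line() +
    geom_point() +
    geom_errorbar(aes(ymin = .data$mean_accuracy - .data$sem,
                      ymax = .data$mean_accuracy + .data$sem), width = 2) +
    labs(x = "peri-stimulus signal length (ms)", y = "mean accuracy",
         colour = "intensity (%)") +
    theme_minimal()
}

#' Psychometric curve of a cohort
#'
#' Empirical response rate (lick within the window of opportunity) per
#' stimulus intensity, with standard error over sessions.
#'
#' @param cohort an `lfp_cohort`
#' @return a ggplot
#' @export
plot_psychometric <- function(cohort) {
  df <- tibble::as_tibble(cohort) |>
    dplyr::mutate(response = !is.na(.data$lick_latency_ms) &
                    .data$lick_latency_ms >= 100 &
                    .data$lick_latency_ms < 500) |>
    dplyr::group_by(.data$session_id, .data$intensity_pct) |>
    dplyr::summarise(rate = mean(.data$response), .groups = "drop") |>
    dplyr::group_by(.data$intensity_pct) |>
    dplyr::summarise(response_rate = mean(.data$rate), sem = sem(.data$rate),
                     .groups = "drop")
  ggplot(df, aes(x = .data$intensity_pct, y = .data$response_rate)) +
    geom_line() +
    geom_point() +
    geom_errorbar(aes(ymin = .data$response_rate - .data$sem,
                      ymax = .data$response_rate + .data$sem), width = 2) +
    labs(x = "stimulus intensity (%)", y = "response rate") +
    theme_minimal()
}

#' Trial-averaged evoked LFP per layer
#'
#' @param cohort an `lfp_cohort`
#' @param intensity intensity of the trials to average
#' @return a ggplot
#' @export
plot_evoked <- function(cohort, intensity = 100) {
  idx <- which(cohort$intensity_pct == intensity)
  if (length(idx) == 0) abort("no trials at the requested intensity")
  mean_lfp <- Reduce(`+`, cohort$signal[idx]) / length(idx)
  lm <- attr(cohort, "layer_map")
  df <- purrr::map_dfr(names(lm), function(ly) {
    tibble::tibble(layer = ly, time_ms = attr(cohort, "time_ms"),
                   lfp_mv = mean_lfp[lm[[ly]], ])
  })
  ggplot(df, aes(x = .data$time_ms, y = .data$lfp_mv, colour = .data$layer)) +
    geom_line() +
    labs(x = "time from stimulus onset (ms)", y = "mean LFP (mV)") +
    theme_minimal()
}

#' Summaries of evaluation tables
#'
#' `tidy()` returns per-evaluation rows (metrics only); `glance()` aggregates
#' to one row per scenario x algorithm with median accuracy and mean AUCs.
#'
#' @param x an `lfp_eval` tibble
#' @param ... unused
#' @return a tibble
#' @method tidy lfp_eval
#' @export
tidy.lfp_eval <- function(x, ...) {
  keep <- intersect(c("scenario", "algorithm", "held_out_mouse", "bootstrap",
                      "accuracy", "roc_auc", "pr_auc", "brier", "calibrated",
                      "balanced"), names(x))
  tibble::as_tibble(x)[, keep]
}

#' @rdname tidy.lfp_eval
#' @method glance lfp_eval
#' @export
glance.lfp_eval <- function(x, ...) {
  grp <- intersect(c("scenario", "algorithm", "calibrated", "balanced"),
                   names(x))
  tibble::as_tibble(x) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(n_evaluations = dplyr::n(),
                     median_accuracy = stats::median(.data$accuracy),
                     mean_roc_auc = mean(.data$roc_auc, na.rm = TRUE),
                     mean_pr_auc = mean(.data$pr_auc, na.rm = TRUE),
                     mean_brier = mean(.data$brier, na.rm = TRUE),
                     .groups = "drop")
}

#' @importFrom rlang .data
NULL
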