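# brute-force metric oracles over explicit threshold sweeps
brute_roc_auc <- function(p, y) {
  thr <- sort(unique(c(-Inf, p, Inf)))
  tpr <- vapply(thr, function(t) mean(p[y == 1] >= t), 1)
  fpr <- vapply(thr, function(t) mean(p[y == 0] >= t), 1)
  ord <- order(fpr, tpr)
  sum(diff(fpr[ord]) * (utils::head(tpr[ord], -1) + utils::tail(tpr[ord], -1)) / 2)
}

brute_pr_auc <- function(p, y) {
  thr <- sort(unique(p), decreasing = TRUE)
  rec <- prec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- p >= thr[i]
    rec[i] <- sum(pred & y == 1) / sum(y == 1)
    prec[i] <- sum(pred & y == 1) / max(sum(pred), 1)
  }
  sum(diff(c(0, rec)) * prec)
}

# hypergeometric enumeration oracle for the 2x2 exact test
brute_fisher <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  prob <- function(a) {
    b <- rs[1] - a; c <- cs[1] - a; d <- rs[2] - c
    if (any(c(b, c, d) < 0)) return(NA_real_)
    exp(lchoose(cs[1], a) + lchoose(cs[2], b) - lchoose(n, rs[1]))
  }
  p_obs <- prob(tab[1, 1])
  support <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  ps <- vapply(support, prob, 1)
  sum(ps[ps <= p_obs + 1e-12])
}

test_that("split plans pair every mouse with every bootstrap, reproducibly", {
  co <- bench_cohort()
  plan <- make_split_plan(co, n_bootstraps = 10, seed = 5)
  expect_equal(nrow(plan), 4 * 10)
  expect_equal(dplyr::n_distinct(plan$held_out_mouse), 4)
  expect_true(all(table(plan$held_out_mouse) == 10))
  expect_identical(plan, make_split_plan(co, n_bootstraps = 10, seed = 5))
  plan2 <- make_split_plan(co, n_bootstraps = 1, seed = 5)
  expect_equal(nrow(plan2), 4)
  one_mouse <- cohort_slice(co, co$mouse_id == "m01")
  expect_error(make_split_plan(one_mouse), "at least 2 mice")
  expect_true(all(plan$bootstrap_seed < 2^31))
})

test_that("downsampling balances to the minority count exactly", {
  idx <- 1:160
  y <- rep(c(1, 0), c(100, 60))
  bal <- balance_by_downsampling(idx, y, seed = 2)
  expect_equal(sum(y[bal] == 1), 60)
  expect_equal(sum(y[bal] == 0), 60)
  expect_equal(mean(y[bal]), 0.5)
  expect_false(any(duplicated(bal)))
  even <- balance_by_downsampling(1:10, rep(c(0, 1), 5), seed = 2)
  expect_setequal(even, 1:10)
  expect_error(balance_by_downsampling(1:5, rep(1, 5), seed = 2), "both classes")
})

test_that("grid search returns the best point with deterministic folds and tie-break", {
  d <- withr::with_seed(3, {
    x <- rbind(matrix(rnorm(30 * 5, 2), 30), matrix(rnorm(30 * 5, -2), 30))
    list(x = x, y = rep(c(1, 0), each = 30))
  })
  single <- grid_search_cv("GLM", list(list(lambda = 0.5)), d$x, d$y, seed = 1)
  expect_equal(single$best_params$lambda, 0.5)
  # a degenerate point (complexity penalty forbidding any split) must lose
  degen <- list(maxdepth = 1, cp = 1)        # root-only tree, chance level
  good <- list(maxdepth = 5, cp = 0.01)
  gs <- grid_search_cv("DT", list(degen, good), d$x, d$y, seed = 1)
  expect_equal(gs$best_index, 2L)
  gs2 <- grid_search_cv("DT", list(degen, good), d$x, d$y, seed = 1)
  expect_identical(gs$cv_accuracy, gs2$cv_accuracy)
  # exact ties resolve to grid order
  tie <- grid_search_cv("GLM", list(list(lambda = 1e-3), list(lambda = 1e-3)),
                        d$x, d$y, seed = 1)
  expect_equal(tie$best_index, 1L)
  expect_error(grid_search_cv("GLM", list(list(lambda = 1)), d$x[1:2, ],
                              d$y[1:2], k = 3), "fewer trials than folds")
})

test_that("ROC/PR/Brier match brute-force oracles and behave at the edges", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      n <- sample(10:50, 1)
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      p <- round(runif(n), 2)  # ties included
      expect_equal(roc_auc(p, y), brute_roc_auc(p, y), tolerance = 1e-12)
      expect_equal(pr_auc(p, y), brute_pr_auc(p, y), tolerance = 1e-12)
      expect_equal(brier_score(p, y), mean((p - y)^2), tolerance = 1e-12)
    }
  })
  # perfect probabilities
  y <- c(0, 1, 0, 1)
  expect_equal(roc_auc(y, y), 1)
  expect_equal(brier_score(y, y), 0)
  # constant 0.5 on balanced labels
  expect_equal(brier_score(rep(0.5, 4), y), 0.25)
  expect_equal(roc_auc(rep(0.5, 4), y), 0.5)
  # random scores at scale: AUC near 1/2
  withr::with_seed(8, {
    y2 <- rep(c(0, 1), 1000)
    p2 <- runif(2000)
  })
  expect_lt(abs(roc_auc(p2, y2) - 0.5), 0.03)
  expect_true(is.na(roc_auc(c(0.2, 0.8), c(1, 1))))
})

test_that("evaluate_model reports calibrated metrics and warns on one-class tests", {
  d <- toy_data(gap = 3, seed = 21)
  f <- fit_classifier(build_classifier("GLM", list(lambda = 1e-3)), d$x, d$y)
  ev <- evaluate_model(f, d$x, d$y)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$roc_auc, 1)
  expect_false(ev$calibrated)
  expect_warning(ev1 <- evaluate_model(f, d$x[d$y == 1, ], d$y[d$y == 1]),
                 "single-class")
  expect_true(is.na(ev1$roc_auc))
})

test_that("Platt calibration refits on 67%, stays monotone, and fixes overconfidence", {
  withr::with_seed(31, {
    z <- rnorm(2000)
    q <- stats::plogis(1.2 * z)          # true conditional probability
    y <- rbinom(2000, 1, q)
    x <- cbind(z, matrix(rnorm(2000 * 2, sd = 0.01), ncol = 2))
  })
  colnames(x) <- c("f1", "f2", "f3")
  # overconfident probe: reports plogis(4 z) instead of plogis(1.2 z)
  over <- probe_classifier(beta = 4)
  cal <- platt_calibrate(over, x, y, seed = 3)
  expect_equal(cal$n_model / (cal$n_model + cal$n_holdout), 2 / 3,
               tolerance = 0.01)
  p_raw <- predict_prob(fit_classifier(over, x, y), x)
  p_cal <- predict(cal, p_raw)
  expect_lt(brier_score(p_cal, y), brier_score(p_raw, y))
  # monotone map
  grid_p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(predict(cal, grid_p)) >= 0))
  # an already-calibrated probe moves Brier by less than 0.02
  good <- probe_classifier(beta = 1.2)
  cal_g <- platt_calibrate(good, x, y, seed = 3)
  p_g <- predict_prob(fit_classifier(good, x, y), x)
  expect_lt(abs(brier_score(predict(cal_g, p_g), y) - brier_score(p_g, y)),
            0.02)
  expect_error(platt_calibrate(over, x[y == 1, ], y[y == 1], seed = 3),
               "class")
  expect_equal(nrow(tidy(cal)), 2)
})

test_that("paired signed-rank test matches exact enumeration and conventions", {
  # 8 strictly positive differences: two-sided exact p = 2 / 2^8
  a <- 1:8 + 0.5
  b <- 1:8 - 0.5
  res <- paired_wilcoxon(a + c(0.01 * 1:8), b)   # distinct |d|, all positive
  expect_equal(res$p_value, 2 / 256)
  # agreement with stats::wilcox.test where its exact path applies
  withr::with_seed(41, {
    x1 <- rnorm(12); x2 <- rnorm(12) + 0.5
  })
  expect_equal(paired_wilcoxon(x1, x2)$p_value,
               stats::wilcox.test(x1, x2, paired = TRUE, exact = TRUE)$p.value)
  # symmetry under swapping the pair
  expect_equal(paired_wilcoxon(x1, x2)$p_value,
               paired_wilcoxon(x2, x1)$p_value)
  # identical vectors: no non-zero differences -> absent result
  same <- paired_wilcoxon(x1, x1)
  expect_true(is.na(same$p_value))
  expect_equal(same$n_zero, 12)
  # zero differences are dropped and counted
  mix <- paired_wilcoxon(c(x1, 1), c(x1[1], x2[-1], 1))
  expect_equal(mix$n_zero, 2)
  expect_error(paired_wilcoxon(1:3, 1:4), "equal length")
})

test_that("accuracy-vs-chance exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact_vs_chance(5, 10), 1)
  tab <- matrix(c(10, 0, 5, 5), 2)
  expect_equal(fisher_exact_vs_chance(10, 10), brute_fisher(tab),
               tolerance = 1e-12)
  for (k in 5:10) {
    tab_k <- matrix(c(k, 10 - k, 5, 5), 2)
    expect_equal(fisher_exact_vs_chance(k, 10), brute_fisher(tab_k),
                 tolerance = 1e-12)
  }
  ps <- vapply(5:10, fisher_exact_vs_chance, 1, n = 10)
  expect_true(all(diff(ps) <= 1e-12))
  expect_error(fisher_exact_vs_chance(1, 0), "positive")
  expect_error(fisher_exact_vs_chance(11, 10), "\\[0, n\\]")
})

test_that("runtime accounting normalizes wall-clock by set size per phase", {
  rt <- measure_runtime(function() { Sys.sleep(0.2); "done" }, 100)
  expect_equal(rt$seconds_per_sample, 0.002, tolerance = 0.2)
  expect_equal(rt$value, "done")
  raw <- measure_runtime(function() Sys.sleep(0.05), 1)
  expect_equal(raw$seconds_per_sample, raw$seconds_total)
  expect_error(measure_runtime(function() NULL, 0), "positive")
})
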