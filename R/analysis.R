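# underlying data-point count backing each per-worker mean, used by the
# at-least-min_points eligibility rule
metric_support <- function(metrics, metric_name) {
  switch(metric_name,
         mscl1 = metrics$n_retest,
         rmscl1 = metrics$n_warned,
         metrics$n_videos)
}

#' Correlate one worker metric with mean PCC
#'
#' Pearson correlation (two-sided p-value from the t distribution) between a
#' per-worker metric and the worker's mean probability of the correct
#' class. A worker enters the analysis only if the metric is defined for
#' them and the mean rests on at least `min_points` underlying data points
#' (re-rated videos for MSCL1, revised warnings for RMSCL1, rated videos
#' otherwise). The Bonferroni flag tests `p < alpha / n_metrics` for the
#' family of four primary metrics at `alpha = 0.05`, i.e. `p < 0.0125` by
#' default.
#'
#' @param metrics A per-worker metrics tibble from [compute_all_metrics()].
#' @param metric_name Column to correlate (e.g. `"mpil1"`).
#' @param min_points Minimum underlying data points per worker; defaults to
#'   the study's at-least-5-points rule.
#' @param alpha Family-wise significance level for the Bonferroni flag.
#' @param n_metrics Size of the metric family for Bonferroni correction.
#' @return A one-row tibble: `metric`, `n_workers`, `r`, `p_value`,
#'   `passes_bonferroni`.
#' @export
correlate_metric <- function(metrics, metric_name, min_points = 5L,
                             alpha = 0.05, n_metrics = 4L) {
  if (!metric_name %in% names(metrics)) {
    abort(sprintf("no column '%s' in the metrics table", metric_name))
  }
  x <- metrics[[metric_name]]
  ok <- !is.na(x) & !is.na(metrics$mean_pcc) &
    metric_support(metrics, metric_name) >= min_points
  x <- x[ok]
  y <- metrics$mean_pcc[ok]
  n <- length(x)
  if (n < 3) {
    abort(sprintf("metric '%s' is defined with enough support for only %d worker(s); need >= 3",
                  metric_name, n))
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warn(sprintf("metric '%s' (or mean PCC) is constant across workers; correlation undefined",
                 metric_name))
    return(tibble::tibble(metric = metric_name, n_workers = n,
                          r = NA_real_, p_value = NA_real_,
                          passes_bonferroni = FALSE))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(
    metric = metric_name,
    n_workers = n,
    r = unname(ct$estimate),
    p_value = ct$p.value,
    passes_bonferroni = ct$p.value < alpha / n_metrics
  )
}

#' Correlation screen over the primary metrics
#'
#' Runs [correlate_metric()] for each of the four primary behavioral metrics
#' (MSCL1, MPIL1, penalized time, mean time) and stacks the results.
#'
#' @inheritParams correlate_metric
#' @param metric_names Metrics to screen.
#' @return A `metric_correlations` tibble, one row per metric.
#' @export
correlate_metrics <- function(metrics,
                              metric_names = c("mscl1", "mpil1", "pt",
                                               "mean_time_s"),
                              min_points = 5L, alpha = 0.05) {
  out <- purrr::map(metric_names, function(m) {
    correlate_metric(metrics, m, min_points = min_points, alpha = alpha,
                     n_metrics = length(metric_names))
  }) |> dplyr::bind_rows()
  class(out) <- c("metric_correlations", class(out))
  out
}

#' Sweep the penalized-time weighting constant
#'
#' Recomputes penalized time at every value of the weighting constant `c` on
#' a grid (default 0.05 to 10.0 in steps of 0.05, 200 points) and correlates
#' each against mean PCC. Since PT is linear in `c` — the time term and the
#' revision distance do not change — both are computed once per worker and
#' the grid is evaluated vectorially; p-values use the exact t transform of
#' Pearson's r. Workers enter if their PT is defined and they rated at least
#' `config$min_videos_metrics` videos.
#'
#' @param responses A validated responses tibble.
#' @param scored Scored records from [score_responses()].
#' @param config A [study_config()].
#' @param grid Numeric grid of `c` values.
#' @return A `pt_sweep` tibble with columns `c`, `r`, `p_value`,
#'   `positive_significant`, and attributes `n_workers` and `any_positive`
#'   (`TRUE` iff some grid point has r > 0 with p < 0.05).
#' @export
sweep_pt_constant <- function(responses, scored, config = study_config(),
                              grid = seq(0.05, 10, by = 0.05)) {
  if (any(grid <= 0)) abort("all c values must be positive")
  pcc_by_worker <- worker_pcc(scored, attempt = 1L)
  parts <- responses |>
    dplyr::filter(.data$attempt == 1L) |>
    dplyr::group_by(.data$worker_id) |>
    dplyr::summarise(
      n_videos = dplyr::n_distinct(.data$video_id),
      never_warned = all(.data$t1_s >= config$T_s),
      time_term = mean(.data$t1_s + dplyr::coalesce(.data$t2_s, 0)),
      .groups = "drop")
  rms <- purrr::map_dbl(parts$worker_id, function(w) {
    compute_rmscl1(responses[responses$worker_id == w, ], config)
  })
  parts$rmscl1 <- rms
  parts <- parts |>
    dplyr::left_join(pcc_by_worker[c("worker_id", "mean_pcc")],
                     by = "worker_id") |>
    dplyr::filter(.data$n_videos >= config$min_videos_metrics,
                  .data$never_warned | !is.na(.data$rmscl1),
                  !is.na(.data$mean_pcc))
  n <- nrow(parts)
  if (n < 3) {
    abort(sprintf("penalized time is defined for only %d eligible worker(s); need >= 3", n))
  }
  # workers x grid matrix of PT values; never-warned workers sit at the
  # baseline M for every c
  base <- ifelse(parts$never_warned, config$M, parts$time_term)
  slope <- ifelse(parts$never_warned, 0, parts$rmscl1)
  ptmat <- outer(base, rep(1, length(grid))) + outer(slope, grid)
  y <- parts$mean_pcc
  sds <- apply(ptmat, 2, sd)
  r <- rep(NA_real_, length(grid))
  ok <- sds > 0 & sd(y) > 0
  if (any(ok)) r[ok] <- drop(cor(ptmat[, ok, drop = FALSE], y))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out <- tibble::tibble(c = grid, r = r, p_value = p,
                        positive_significant = !is.na(r) & r > 0 & p < 0.05)
  class(out) <- c("pt_sweep", class(out))
  attr(out, "n_workers") <- n
  attr(out, "any_positive") <- any(out$positive_significant)
  out
}

# worker-level k-fold assignment: shuffle rows once under the seed, then
# deal fold labels 1..k in order, so fold sizes differ by at most one
make_folds <- function(n, k, seed) {
  if (n < k) abort(sprintf("cannot make %d folds from %d workers", k, n))
  ord <- withr::with_seed(seed, sample.int(n))
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(k), n)
  folds
}

# k-fold cross-validated MAE (percentage points) of an OLS regression of
# mean_pcc on `features`; features = character(0) gives the intercept-only
# baseline
cv_mae <- function(d, features, k, seed) {
  folds <- make_folds(nrow(d), k, seed)
  errs <- numeric(nrow(d))
  for (f in seq_len(k)) {
    test <- folds == f
    if (length(features) == 0) {
      pred <- mean(d$mean_pcc[!test])
    } else {
      fit <- lm(stats::reformulate(features, "mean_pcc"), data = d[!test, ])
      pred <- predict(fit, newdata = d[test, ])
    }
    errs[test] <- abs(pred - d$mean_pcc[test])
  }
  mean(errs) * 100
}

subset_label <- function(features) {
  if (length(features) == 0) "(intercept only)" else paste(features, collapse = " + ")
}

#' Metric-subset regressions of mean PCC
#'
#' Evaluates every non-empty subset of the correlative metrics (by default
#' MSCL1, MPIL1 and mean time: 7 subsets) as predictors of per-worker mean
#' PCC in an ordinary-least-squares linear regression, reporting the
#' worker-level k-fold cross-validated mean absolute error in percentage
#' points. Folds partition workers — one worker is never split across
#' folds — by a single shuffle under `seed` with fold sizes differing by at
#' most one.
#'
#' Each subset is evaluated on two cohorts, mirroring how missing metrics
#' shape the analysis: `cv_same_set` uses every worker with all of that
#' subset's metrics defined (so cohort size varies by subset), and
#' `fixed_55_subset` restricts each subset to the fixed intersection cohort
#' of workers with *all* candidate metrics defined. An intercept-only
#' baseline row per cohort gives the MAE of predicting every worker at the
#' cohort mean.
#'
#' @param metrics Per-worker metrics tibble from [compute_all_metrics()].
#' @param predictors Candidate metric columns.
#' @param k Number of folds. Default 5.
#' @param seed Shuffle seed recorded in every report.
#' @param include_baseline Add intercept-only baseline rows. Default `TRUE`.
#' @return A `pcc_regression` object: a list with `reports` (tibble with one
#'   row per subset and cohort mode: `feature_subset`, `features`
#'   (list-column), `mae_pct`, `n_workers`, `cohort_mode`, `coefficients`
#'   (list-column of full-cohort OLS coefficients), `seed`), plus `fits`
#'   (full-cohort `lm` objects), `k`, `seed`, `predictors`.
#' @export
fit_subset_regressions <- function(metrics, predictors = c("mscl1", "mpil1",
                                                           "mean_time_s"),
                                   k = 5L, seed = 1L,
                                   include_baseline = TRUE) {
  missing <- setdiff(c(predictors, "mean_pcc"), names(metrics))
  if (length(missing) > 0) {
    abort(sprintf("metrics table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  subsets <- unlist(lapply(seq_along(predictors), function(m) {
    combn(predictors, m, simplify = FALSE)
  }), recursive = FALSE)
  if (include_baseline) subsets <- c(subsets, list(character(0)))
  intersection <- tidyr::drop_na(metrics, dplyr::all_of(c(predictors, "mean_pcc")))

  one <- function(features, cohort, mode) {
    d <- tidyr::drop_na(cohort, dplyr::all_of(c(features, "mean_pcc")))
    if (nrow(d) < k) {
      abort(sprintf("subset {%s}: %d workers with all metrics defined, fewer than %d folds",
                    subset_label(features), nrow(d), k))
    }
    fit <- if (length(features) == 0) {
      lm(mean_pcc ~ 1, data = d)
    } else {
      lm(stats::reformulate(features, "mean_pcc"), data = d)
    }
    mae <- cv_mae(d, features, k, seed)
    list(
      report = tibble::tibble(
        feature_subset = subset_label(features),
        features = list(features),
        mae_pct = mae,
        n_workers = nrow(d),
        cohort_mode = mode,
        coefficients = list(stats::coef(fit)),
        seed = as.integer(seed)),
      fit = fit)
  }

  results <- c(
    purrr::map(subsets, one, cohort = metrics, mode = "cv_same_set"),
    purrr::map(subsets, one, cohort = intersection, mode = "fixed_55_subset")
  )
  reports <- dplyr::bind_rows(purrr::map(results, "report"))
  fits <- purrr::map(results, "fit")
  names(fits) <- paste(reports$feature_subset, reports$cohort_mode, sep = " | ")
  structure(list(reports = reports, fits = fits, k = as.integer(k),
                 seed = as.integer(seed), predictors = predictors),
            class = "pcc_regression")
}

#' @export
print.pcc_regression <- function(x, ...) {
  cat(sprintf("<pcc_regression> %d-fold CV, seed %d\n", x$k, x$seed))
  print(dplyr::select(x$reports, "feature_subset", "cohort_mode",
                      "n_workers", "mae_pct"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a metric-subset regression
#'
#' `tidy()` returns one row per (subset, cohort mode, coefficient) with the
#' full-cohort OLS estimate; `glance()` returns the per-subset summary (MAE
#' in percentage points, cohort size, seed).
#'
#' @param x A `pcc_regression` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pcc_regression <- function(x, ...) {
  x$reports |>
    dplyr::mutate(term_tbl = purrr::map(.data$coefficients, function(b) {
      tibble::tibble(term = names(b), estimate = unname(b))
    })) |>
    dplyr::select("feature_subset", "cohort_mode", "n_workers", "term_tbl") |>
    tidyr::unnest("term_tbl")
}

#' @rdname tidy.pcc_regression
#' @export
glance.pcc_regression <- function(x, ...) {
  dplyr::select(x$reports, "feature_subset", "cohort_mode", "n_workers",
                "mae_pct", "seed")
}

#' Cross-cohort generalization error
#'
#' Fits the metric-to-PCC regression for each metric subset on one worker
#' cohort (no cross-validation) and measures the mean absolute error, in
#' percentage points, on a disjoint cohort of different workers rating
#' different videos. Any shared `worker_id` between the cohorts is treated
#' as contamination and raises an error. The in-sample (training cohort)
#' MAE of each fit is reported alongside for comparison.
#'
#' @param train_metrics,test_metrics Per-worker metrics tibbles for the two
#'   disjoint cohorts.
#' @param predictors Candidate metric columns.
#' @return A tibble with one row per subset: `feature_subset`, `features`,
#'   `mae_pct` (test cohort), `mae_train_pct` (in-sample), `n_workers`
#'   (test), `n_train`, `cohort_mode = "cross_cohort"`, `coefficients`.
#' @export
cross_cohort_mae <- function(train_metrics, test_metrics,
                             predictors = c("mscl1", "mpil1", "mean_time_s")) {
  shared <- intersect(train_metrics$worker_id, test_metrics$worker_id)
  if (length(shared) > 0) {
    abort(sprintf("cohort contamination: %d worker id(s) appear in both cohorts (e.g. %s)",
                  length(shared), shared[1]))
  }
  subsets <- unlist(lapply(seq_along(predictors), function(m) {
    combn(predictors, m, simplify = FALSE)
  }), recursive = FALSE)
  purrr::map(subsets, function(features) {
    tr <- tidyr::drop_na(train_metrics, dplyr::all_of(c(features, "mean_pcc")))
    te <- tidyr::drop_na(test_metrics, dplyr::all_of(c(features, "mean_pcc")))
    if (nrow(tr) < length(features) + 1 || nrow(te) == 0) {
      abort(sprintf("subset {%s}: not enough workers with defined metrics (train %d, test %d)",
                    subset_label(features), nrow(tr), nrow(te)))
    }
    fit <- lm(stats::reformulate(features, "mean_pcc"), data = tr)
    tibble::tibble(
      feature_subset = subset_label(features),
      features = list(features),
      mae_pct = mean(abs(predict(fit, newdata = te) - te$mean_pcc)) * 100,
      mae_train_pct = mean(abs(stats::fitted(fit) - tr$mean_pcc)) * 100,
      n_workers = nrow(te),
      n_train = nrow(tr),
      cohort_mode = "cross_cohort",
      coefficients = list(stats::coef(fit)))
  }) |> dplyr::bind_rows()
}

#' Correlations of the penalized-time components with mean PCC
#'
#' Diagnoses the two ingredients of penalized time separately: (1) the mean
#' total time (initial plus revision) spent on warned videos and (2) the
#' revision distance RMSCL1, each correlated against the worker's mean PCC
#' over workers with at least `min_points` revised warnings.
#'
#' @param responses A validated responses tibble.
#' @param scored Scored records from [score_responses()].
#' @param config A [study_config()].
#' @param min_points Minimum revised warnings per worker; defaults to the
#'   study config's analysis rule.
#' @return A two-row tibble like [correlate_metric()]'s output, metrics
#'   `post_warning_time` and `rmscl1`.
#' @export
postwarning_correlations <- function(responses, scored,
                                     config = study_config(),
                                     min_points = config$min_points_analysis) {
  pcc_by_worker <- worker_pcc(scored, attempt = 1L)
  a1 <- dplyr::filter(responses, .data$attempt == 1L, .data$warned)
  if (nrow(a1) == 0) abort("no warned ratings in the data")
  rmat <- answers_matrix(a1, config$M, revised = TRUE)
  a1 <- a1[rowSums(!is.na(rmat)) > 0, , drop = FALSE]
  per_worker <- a1 |>
    dplyr::group_by(.data$worker_id) |>
    dplyr::summarise(
      n_warned = dplyr::n(),
      post_warning_time = mean(.data$t1_s + dplyr::coalesce(.data$t2_s, 0)),
      .groups = "drop")
  per_worker$rmscl1 <- purrr::map_dbl(per_worker$worker_id, function(w) {
    compute_rmscl1(responses[responses$worker_id == w, ], config)
  })
  d <- per_worker |>
    dplyr::left_join(pcc_by_worker[c("worker_id", "mean_pcc")],
                     by = "worker_id") |>
    dplyr::filter(.data$n_warned >= min_points, !is.na(.data$mean_pcc))
  d$n_videos <- d$n_warned  # support column expected by correlate_metric
  d$n_retest <- d$n_warned
  dplyr::bind_rows(
    correlate_metric(d, "post_warning_time", min_points = min_points,
                     n_metrics = 2L),
    correlate_metric(d, "rmscl1", min_points = min_points, n_metrics = 2L))
}
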