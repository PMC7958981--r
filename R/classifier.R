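#' Logistic-regression classifier specification
#'
#' The performance gold standard is a binary logistic-regression classifier
#' that maps a worker's ordinal answer vector to a probability of autism.
#' Its coefficients are treated as configuration — supplied by the user or
#' generated by [simulate_classifier()] — never trained by this package.
#' Ordinal answer codes enter the linear predictor as plain integers.
#'
#' @param weights Numeric vector of length M, one coefficient per question.
#' @param intercept Scalar intercept of the linear predictor.
#' @param positive_class Label whose probability the classifier emits.
#'   Default `"autism"`.
#' @return A `classifier_spec` object.
#' @export
#' @examples
#' spec <- classifier_spec(weights = c(1, 0, 0), intercept = -2)
#' predict_probability(c(2, 3, 1), spec)  # logit -2 + 2 = 0 -> 0.5
classifier_spec <- function(weights, intercept = 0,
                            positive_class = "autism") {
  weights <- as.numeric(weights)
  if (length(weights) < 1 || any(!is.finite(weights))) {
    abort("weights must be a non-empty vector of finite numbers")
  }
  if (!is.finite(intercept)) abort("intercept must be finite")
  structure(list(weights = weights, intercept = as.numeric(intercept),
                 positive_class = positive_class),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("<classifier_spec> %d features, intercept %.4g, positive class '%s'\n",
              length(x$weights), x$intercept, x$positive_class))
  invisible(x)
}

#' Read or write a classifier specification as YAML
#'
#' @param path File path.
#' @return `read_classifier_spec()` returns a `classifier_spec`;
#'   `write_classifier_spec()` returns `path` invisibly.
#' @export
read_classifier_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  classifier_spec(weights = raw$weights, intercept = raw$intercept %||% 0,
                  positive_class = raw$positive_class %||% "autism")
}

#' @rdname read_classifier_spec
#' @param spec A `classifier_spec`.
#' @export
write_classifier_spec <- function(spec, path) {
  stopifnot(inherits(spec, "classifier_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' Probability of autism for an answer vector
#'
#' Evaluates the logistic model `1 / (1 + exp(-(intercept + sum_j w_j a_j)))`
#' on one answer vector or on a matrix of answer vectors (one per row).
#'
#' @param answers Numeric vector of length M, or a numeric matrix with M
#'   columns.
#' @param spec A [classifier_spec()].
#' @return Probability (or vector of probabilities) in (0, 1).
#' @export
predict_probability <- function(answers, spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (is.matrix(answers)) {
    if (ncol(answers) != length(spec$weights)) {
      abort(sprintf("answer matrix has %d columns but classifier has %d weights",
                    ncol(answers), length(spec$weights)))
    }
    logit <- drop(answers %*% spec$weights) + spec$intercept
  } else {
    if (length(answers) != length(spec$weights)) {
      abort(sprintf("answer vector has length %d but classifier has %d weights",
                    length(answers), length(spec$weights)))
    }
    logit <- sum(answers * spec$weights) + spec$intercept
  }
  plogis(logit)
}

#' Probability of the correct class (PCC)
#'
#' The PCC of a rating is the classifier's probability of autism `p` when
#' the video's true class is autism, and `1 - p` when it is neurotypical.
#' Averaged per worker, it is the performance criterion every behavioral
#' metric is screened against.
#'
#' @param p_autism Probability (or vector of probabilities) of autism.
#' @param true_class Character vector of true class labels.
#' @param positive_class Label treated as the positive class.
#' @return PCC value(s) in [0, 1].
#' @export
#' @examples
#' pcc(0.8, "autism")        # 0.8
#' pcc(0.8, "neurotypical")  # 0.2
pcc <- function(p_autism, true_class, positive_class = "autism") {
  if (any(p_autism < 0 | p_autism > 1, na.rm = TRUE)) {
    abort("p_autism must lie in [0, 1]")
  }
  ifelse(true_class == positive_class, p_autism, 1 - p_autism)
}

#' Hard classification at a probability threshold
#'
#' A probability exactly at the threshold classifies as the positive class
#' (the `>=` convention).
#'
#' @inheritParams pcc
#' @param threshold Probability cut-off, default 0.5.
#' @param negative_class Label returned below threshold.
#' @return Character vector of predicted labels.
#' @export
classify <- function(p_autism, threshold = 0.5, positive_class = "autism",
                     negative_class = "neurotypical") {
  if (any(p_autism < 0 | p_autism > 1, na.rm = TRUE)) {
    abort("p_autism must lie in [0, 1]")
  }
  ifelse(p_autism >= threshold, positive_class, negative_class)
}

#' Score every rating with the classifier
#'
#' Joins the responses to the video table, evaluates the classifier on each
#' answer vector and returns one scored record per rating event: the
#' probability of autism, the probability of the correct class, and the
#' hard prediction at the configured threshold.
#'
#' @param responses A validated responses tibble ([read_responses()]).
#' @param videos A videos tibble ([read_videos()]).
#' @param spec A [classifier_spec()].
#' @param config A [study_config()].
#' @param use_revised If `TRUE`, score the revised answer vectors instead of
#'   the originals; rows without revisions are dropped. Default `FALSE`.
#' @return A tibble with columns `worker_id`, `video_id`, `attempt`,
#'   `p_autism`, `pcc`, `predicted_class`.
#' @export
score_responses <- function(responses, videos, spec, config = study_config(),
                            use_revised = FALSE) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (length(spec$weights) != config$M) {
    abort(sprintf("classifier has %d weights but config declares M = %d questions",
                  length(spec$weights), config$M))
  }
  unknown <- setdiff(unique(responses$video_id), videos$video_id)
  if (length(unknown) > 0) {
    abort(sprintf("responses reference video(s) missing from the video table: %s",
                  paste(utils::head(unknown, 3), collapse = ", ")))
  }
  df <- responses
  if (use_revised) {
    rmat <- answers_matrix(df, config$M, revised = TRUE)
    keep <- rowSums(!is.na(rmat)) > 0
    df <- df[keep, , drop = FALSE]
    amat <- rmat[keep, , drop = FALSE]
  } else {
    amat <- answers_matrix(df, config$M)
  }
  p <- if (nrow(df) == 0) numeric(0) else predict_probability(amat, spec)
  cls <- videos$true_class[match(df$video_id, videos$video_id)]
  tibble::tibble(
    worker_id = df$worker_id,
    video_id = df$video_id,
    attempt = df$attempt,
    p_autism = p,
    pcc = pcc(p, cls, spec$positive_class),
    predicted_class = classify(p, config$pcc_threshold, spec$positive_class)
  )
}

#' Per-worker mean PCC
#'
#' `worker_pcc()` summarises scored records into one row per worker:
#' the arithmetic mean PCC and the number of scored videos it rests on.
#' `mean_worker_pcc()` returns the scalar mean for a single worker.
#'
#' By default only original (attempt 1) ratings enter the mean, so each
#' worker contributes a single performance figure; set `attempt = 2` (or
#' `NULL` for all attempts) to score the re-ratings instead.
#'
#' @param scored A scored tibble from [score_responses()].
#' @param attempt Which attempt's records to average, or `NULL` for all.
#' @return A tibble with `worker_id`, `mean_pcc`, `n_scored`.
#' @export
worker_pcc <- function(scored, attempt = 1L) {
  df <- scored
  if (!is.null(attempt)) df <- dplyr::filter(df, .data$attempt %in% !!attempt)
  df |>
    dplyr::group_by(.data$worker_id) |>
    dplyr::summarise(mean_pcc = mean(.data$pcc),
                     n_scored = dplyr::n(), .groups = "drop")
}

#' @rdname worker_pcc
#' @param worker_id The worker to average.
#' @export
mean_worker_pcc <- function(scored, worker_id, attempt = 1L) {
  df <- worker_pcc(scored, attempt = attempt)
  row <- df[df$worker_id == worker_id, ]
  if (nrow(row) == 0) {
    abort(sprintf("no scored records for worker %s at the requested attempt",
                  worker_id))
  }
  row$mean_pcc
}
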