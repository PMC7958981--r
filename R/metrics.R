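#' L1 distance between two answer vectors
#'
#' The primitive underlying all three L1 reliability metrics: the sum of
#' absolute differences between ordinal answer codes, question by question.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
#' @examples
#' l1_distance(c(0, 3, 1), c(2, 0, 1))  # 5
l1_distance <- function(a, b) {
  if (length(a) != length(b)) {
    abort(sprintf("answer vectors differ in length (%d vs %d)",
                  length(a), length(b)))
  }
  sum(abs(a - b))
}

#' Mean same-child L1 distance (MSCL1)
#'
#' Test–retest reliability of a worker: the same videos are re-rated after a
#' delay (30 days in the reference design), and MSCL1 is the mean, over
#' videos rated at both attempts, of the L1 distance between the two answer
#' vectors. 0 means perfectly reproduced answers; a value of M (e.g. 13)
#' means the worker's answer moved by one ordinal level per question on
#' average. Pairing is strictly by `video_id`; videos rated only once do not
#' enter the mean. Returns `NA` when the worker has no re-rated video.
#'
#' @param responses Responses of a single worker.
#' @param config A [study_config()].
#' @return Non-negative scalar, or `NA_real_` if undefined.
#' @export
compute_mscl1 <- function(responses, config = study_config()) {
  assert_single_worker(responses, "MSCL1")
  a1 <- responses[responses$attempt == 1L, ]
  a2 <- responses[responses$attempt == 2L, ]
  paired <- intersect(a1$video_id, a2$video_id)
  if (length(paired) == 0) return(NA_real_)
  m1 <- answers_matrix(a1[match(paired, a1$video_id), ], config$M)
  m2 <- answers_matrix(a2[match(paired, a2$video_id), ], config$M)
  sum(abs(m2 - m1)) / length(paired)
}

#' Mean pairwise internal L1 distance (MPIL1)
#'
#' Internal variability of a worker's answers across distinct videos: the
#' mean L1 distance over all N(N-1)/2 unordered pairs of the worker's
#' attempt-1 answer vectors. Exactly 0 when the worker submits one identical
#' answer vector for every video (copy-paste answering). Returns `NA` when
#' fewer than two videos were rated.
#'
#' @inheritParams compute_mscl1
#' @return Non-negative scalar, or `NA_real_` if undefined.
#' @export
compute_mpil1 <- function(responses, config = study_config()) {
  assert_single_worker(responses, "MPIL1")
  a1 <- responses[responses$attempt == 1L, ]
  if (nrow(a1) < 2) return(NA_real_)
  m <- answers_matrix(a1, config$M)
  mean(stats::dist(m, method = "manhattan"))
}

#' Revision mean same-child L1 distance (RMSCL1)
#'
#' For videos on which the worker was warned for rating too quickly and
#' reopened the task, the mean L1 distance between the initial and revised
#' answer vectors. Returns `NA` when no warned rating carries revisions.
#' Only original (attempt 1) ratings are considered.
#'
#' @inheritParams compute_mscl1
#' @return Non-negative scalar, or `NA_real_` if undefined.
#' @export
compute_rmscl1 <- function(responses, config = study_config()) {
  assert_single_worker(responses, "RMSCL1")
  a1 <- responses[responses$attempt == 1L & responses$warned, ]
  if (nrow(a1) == 0) return(NA_real_)
  rmat <- answers_matrix(a1, config$M, revised = TRUE)
  has_rev <- rowSums(!is.na(rmat)) > 0
  if (!any(has_rev)) return(NA_real_)
  amat <- answers_matrix(a1, config$M)
  mean(rowSums(abs(rmat[has_rev, , drop = FALSE] - amat[has_rev, , drop = FALSE])))
}

#' Penalized time (PT)
#'
#' Trustworthiness metric. A worker who never triggered the minimum-time
#' warning (every attempt-1 rating took at least `T_s` seconds) receives the
#' baseline score M, the question count. Otherwise PT is the mean total
#' rating time — initial time plus revision time, summed over all rated
#' videos and divided by the number of videos N — plus `c` times RMSCL1,
#' the revision distance. Missing revision times contribute 0 seconds.
#' A warned worker who never reopened any task has no revision record, so
#' RMSCL1 and hence PT are undefined (`NA`).
#'
#' @inheritParams compute_mscl1
#' @return Non-negative scalar, or `NA_real_` if undefined.
#' @export
compute_pt <- function(responses, config = study_config()) {
  assert_single_worker(responses, "PT")
  a1 <- responses[responses$attempt == 1L, ]
  if (nrow(a1) == 0) return(NA_real_)
  if (all(a1$t1_s >= config$T_s)) return(as.numeric(config$M))
  rmscl1 <- compute_rmscl1(responses, config)
  if (is.na(rmscl1)) return(NA_real_)
  time_term <- mean(a1$t1_s + dplyr::coalesce(a1$t2_s, 0))
  time_term + config$c * rmscl1
}

#' Mean rating time
#'
#' Mean initial time in seconds spent per video across a worker's attempt-1
#' ratings.
#'
#' @inheritParams compute_mscl1
#' @return Non-negative scalar.
#' @export
compute_mean_time <- function(responses) {
  assert_single_worker(responses, "mean time")
  a1 <- responses[responses$attempt == 1L, ]
  if (nrow(a1) == 0) return(NA_real_)
  mean(a1$t1_s)
}

#' Rescale a mean rating time to a different question count
#'
#' Rating tasks of different lengths are compared by scaling the mean time
#' proportionally to the number of questions: a pilot task of 31 questions
#' averaging 557.7 s corresponds to 233.9 s for a 13-question task.
#'
#' @param mean_time_s Mean time in seconds observed on the source task.
#' @param from_questions Question count of the source task.
#' @param to_questions Question count of the target task.
#' @return Scaled mean time in seconds.
#' @export
#' @examples
#' proportional_mean_time(557.7, 31, 13)  # 233.9 to one decimal
proportional_mean_time <- function(mean_time_s, from_questions, to_questions) {
  stopifnot(from_questions > 0, to_questions > 0, mean_time_s >= 0)
  mean_time_s * to_questions / from_questions
}

#' Compute all per-worker metrics
#'
#' Runs the four behavioral metrics (plus RMSCL1 and the eligibility counts)
#' for every worker who rated at least `config$min_videos_metrics` distinct
#' videos on the original task, and attaches the worker's mean PCC. Workers
#' under the video threshold are excluded — not errored — and reported in
#' the `excluded` attribute of the result. Within an eligible worker's row,
#' a metric whose own precondition fails (no re-rated video for MSCL1, no
#' revised warning for RMSCL1 and PT) is `NA`: undefined metrics propagate
#' as explicit absences, never as zeros, because which workers have a
#' defined metric is itself informative.
#'
#' @param responses A validated responses tibble (all workers).
#' @param scored Scored records from [score_responses()]; mean PCC is taken
#'   over attempt-1 records.
#' @param config A [study_config()].
#' @return A tibble with one row per eligible worker and columns
#'   `worker_id`, `n_videos`, `n_retest`, `n_warned`, `mscl1`, `mpil1`,
#'   `pt`, `rmscl1`, `mean_time_s`, `mean_pcc`. The tibble carries an
#'   `excluded` attribute listing the workers dropped by the video
#'   threshold.
#' @export
compute_all_metrics <- function(responses, scored, config = study_config()) {
  pcc_by_worker <- worker_pcc(scored, attempt = 1L)
  per_worker <- responses |>
    dplyr::group_by(.data$worker_id) |>
    dplyr::summarise(
      n_videos = dplyr::n_distinct(.data$video_id[.data$attempt == 1L]),
      .groups = "drop")
  excluded <- dplyr::filter(per_worker, .data$n_videos < config$min_videos_metrics)
  eligible <- dplyr::filter(per_worker, .data$n_videos >= config$min_videos_metrics)

  rows <- purrr::map(eligible$worker_id, function(w) {
    rw <- responses[responses$worker_id == w, ]
    a1 <- rw[rw$attempt == 1L, ]
    rmat <- answers_matrix(a1, config$M, revised = TRUE)
    tibble::tibble(
      worker_id = w,
      n_videos = length(unique(a1$video_id)),
      n_retest = length(intersect(a1$video_id,
                                  rw$video_id[rw$attempt == 2L])),
      n_warned = sum(a1$warned & rowSums(!is.na(rmat)) > 0),
      mscl1 = compute_mscl1(rw, config),
      mpil1 = compute_mpil1(rw, config),
      pt = compute_pt(rw, config),
      rmscl1 = compute_rmscl1(rw, config),
      mean_time_s = compute_mean_time(rw)
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::left_join(pcc_by_worker[c("worker_id", "mean_pcc")], by = "worker_id")
  if (nrow(out) == 0) {
    out <- tibble::tibble(worker_id = character(), n_videos = integer(),
                          n_retest = integer(), n_warned = integer(),
                          mscl1 = numeric(), mpil1 = numeric(), pt = numeric(),
                          rmscl1 = numeric(), mean_time_s = numeric(),
                          mean_pcc = numeric())
  }
  attr(out, "excluded") <- excluded
  out
}
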