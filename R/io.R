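#' Read worker responses from CSV
#'
#' The canonical interchange format is a UTF-8 comma-separated table with a
#' header row and one row per (worker, video, attempt) rating event:
#' `worker_id, video_id, attempt, t1_s, warned, t2_s, a1..aM, r1..rM`.
#' `a1..aM` are the 0-based ordinal answer codes for the M questions;
#' `r1..rM` hold the revised answers and are empty unless the rating was
#' warned and the worker reopened the task. `attempt` is 1 for the original
#' task and 2 for the delayed re-rating of the same video.
#'
#' Ingestion is strict: rows are never silently dropped. Any malformed row
#' aborts with an error naming the offending worker, video and question, so
#' a successful read returns exactly as many records as the file has rows.
#'
#' @param path Path to a responses CSV.
#' @param config A [study_config()]; supplies `M`, the per-question level
#'   counts used for range validation, and the warning threshold used to
#'   cross-check the `warned` flag.
#' @return A tibble of validated responses, one row per rating event.
#' @export
read_responses <- function(path, config = study_config()) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  M <- config$M
  spec <- readr::cols(
    worker_id = readr::col_character(),
    video_id = readr::col_character(),
    attempt = readr::col_integer(),
    t1_s = readr::col_double(),
    warned = readr::col_logical(),
    t2_s = readr::col_double(),
    .default = readr::col_integer()
  )
  df <- readr::read_csv(path, col_types = spec, na = c("", "NA"),
                        progress = FALSE)
  required <- c("worker_id", "video_id", "attempt", "t1_s", "warned", "t2_s",
                answer_cols(M), revision_cols(M))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("responses file %s is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  df <- tibble::as_tibble(df[required])
  validate_responses(df, config)
}

#' Validate a responses table
#'
#' Enforces the data contract for rating events: answer codes within the
#' configured per-question ranges, unique (worker, video, attempt) keys,
#' revision fields present only on warned rows, and non-negative times. The
#' recorded `warned` flag is additionally cross-checked against
#' `t1_s < T_s`; a mismatch (the flag claims a warning the timing does not
#' support) raises a warning naming the rows, since the warning was a
#' platform event the data should describe consistently.
#'
#' @param responses A responses tibble (see [read_responses()] for columns).
#' @param config A [study_config()].
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_responses <- function(responses, config = study_config()) {
  M <- config$M
  acol <- answer_cols(M)
  rcol <- revision_cols(M)

  dup <- duplicated(responses[c("worker_id", "video_id", "attempt")])
  if (any(dup)) {
    d <- responses[dup, ][1, ]
    abort(sprintf("duplicate record: worker %s, video %s, attempt %d",
                  d$worker_id, d$video_id, d$attempt))
  }
  if (any(is.na(responses$t1_s)) || any(responses$t1_s < 0)) {
    abort("t1_s must be present and non-negative on every row")
  }
  if (!all(responses$attempt %in% c(1L, 2L))) {
    abort("attempt must be 1 (original task) or 2 (delayed re-rating)")
  }

  amat <- answers_matrix(responses, M)
  if (any(is.na(amat))) {
    bad <- which(is.na(amat), arr.ind = TRUE)[1, ]
    abort(sprintf("missing answer: worker %s, video %s, question %d",
                  responses$worker_id[bad[1]], responses$video_id[bad[1]], bad[2]))
  }
  for (j in seq_len(M)) {
    out <- which(amat[, j] < 0 | amat[, j] > config$levels[j] - 1 |
                   amat[, j] != round(amat[, j]))
    if (length(out) > 0) {
      i <- out[1]
      abort(sprintf(
        "answer code %g out of range [0, %d] for worker %s, video %s, question %d",
        amat[i, j], config$levels[j] - 1,
        responses$worker_id[i], responses$video_id[i], j))
    }
  }

  rmat <- answers_matrix(responses, M, revised = TRUE)
  has_rev <- rowSums(!is.na(rmat)) > 0
  partial <- has_rev & rowSums(is.na(rmat)) > 0
  if (any(partial)) {
    i <- which(partial)[1]
    abort(sprintf("partially filled revision answers for worker %s, video %s",
                  responses$worker_id[i], responses$video_id[i]))
  }
  bad_unwarned <- !responses$warned & (has_rev | !is.na(responses$t2_s))
  if (any(bad_unwarned)) {
    i <- which(bad_unwarned)[1]
    abort(sprintf(
      "unwarned rating carries revision data: worker %s, video %s, attempt %d",
      responses$worker_id[i], responses$video_id[i], responses$attempt[i]))
  }
  for (j in seq_len(M)) {
    v <- rmat[has_rev, j]
    out <- which(v < 0 | v > config$levels[j] - 1 | v != round(v))
    if (length(out) > 0) {
      i <- which(has_rev)[out[1]]
      abort(sprintf(
        "revised answer code %g out of range [0, %d] for worker %s, video %s, question %d",
        rmat[i, j], config$levels[j] - 1,
        responses$worker_id[i], responses$video_id[i], j))
    }
  }
  if (any(!is.na(responses$t2_s) & responses$t2_s < 0)) {
    abort("t2_s must be non-negative where present")
  }

  inconsistent <- responses$warned & responses$t1_s >= config$T_s
  if (any(inconsistent)) {
    warn(sprintf(
      "%d row(s) flagged warned despite t1_s >= %g s (first: worker %s, video %s)",
      sum(inconsistent), config$T_s,
      responses$worker_id[which(inconsistent)[1]],
      responses$video_id[which(inconsistent)[1]]))
  }
  # canonical column types so a write/read round trip is exact
  responses$worker_id <- as.character(responses$worker_id)
  responses$video_id <- as.character(responses$video_id)
  responses$attempt <- as.integer(responses$attempt)
  responses$t1_s <- as.numeric(responses$t1_s)
  responses$t2_s <- as.numeric(responses$t2_s)
  responses$warned <- as.logical(responses$warned)
  responses[c(acol, rcol)] <- lapply(responses[c(acol, rcol)], as.integer)
  responses
}

#' Write worker responses to CSV
#'
#' Inverse of [read_responses()]: absent revision answers and times are
#' serialized as empty cells, times keep full precision, so a write/read
#' round trip reproduces the record set exactly.
#'
#' @param responses A validated responses tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  readr::write_csv(responses, path, na = "")
  invisible(path)
}

#' Read or write the video table
#'
#' The video table has columns `video_id`, `true_class` (exactly `"autism"`
#' or `"neurotypical"`) and an optional non-negative `duration_s`. The true
#' class orients the probability-of-correct-class calculation.
#'
#' @param path Path to a videos CSV.
#' @return `read_videos()` returns a tibble with one row per video;
#'   `write_videos()` returns `path` invisibly.
#' @export
read_videos <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(
    video_id = readr::col_character(),
    true_class = readr::col_character(),
    .default = readr::col_double()
  ), na = c("", "NA"), progress = FALSE)
  if (!all(c("video_id", "true_class") %in% names(df))) {
    abort("videos file must have columns video_id and true_class")
  }
  if (!"duration_s" %in% names(df)) df$duration_s <- NA_real_
  bad <- !df$true_class %in% c("autism", "neurotypical")
  if (any(bad)) {
    abort(sprintf("unknown class label %s for video %s (allowed: autism, neurotypical)",
                  df$true_class[which(bad)[1]], df$video_id[which(bad)[1]]))
  }
  if (anyDuplicated(df$video_id)) abort("duplicate video_id in videos file")
  if (any(!is.na(df$duration_s) & df$duration_s < 0)) {
    abort("duration_s must be non-negative")
  }
  tibble::as_tibble(df[c("video_id", "true_class", "duration_s")])
}

#' @rdname read_videos
#' @param videos A videos tibble.
#' @export
write_videos <- function(videos, path) {
  readr::write_csv(videos, path, na = "")
  invisible(path)
}
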