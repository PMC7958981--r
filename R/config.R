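#' Study configuration
#'
#' Bundles the design constants of a crowd-rating study: the minimum-time
#' warning threshold, the number of questions per rating task, the ordinal
#' scale of each question, and the eligibility rules that gate which workers
#' enter the metric and correlation analyses.
#'
#' @param T_s Warning threshold in seconds. Ratings submitted faster than
#'   this trigger a revision request. Default 120 s (the two-minute rule).
#' @param M Number of multiple-choice questions per video rating task.
#'   Default 13.
#' @param levels Integer vector of length `M`: number of ordinal answer
#'   levels per question. Answer codes for question `j` are the integers
#'   `0:(levels[j] - 1)`. Default 4 levels for every question.
#' @param c Weighting constant balancing the revision-distance term of the
#'   penalized-time metric against its time term. Default 1.
#' @param min_videos_metrics Minimum number of distinct videos a worker must
#'   have rated for any per-worker metric to be computed. Default 10.
#' @param min_points_analysis Minimum number of underlying data points a
#'   worker's mean value must rest on to enter a correlation analysis.
#'   Default 5.
#' @param pcc_threshold Probability cut-off for hard classification.
#'   Default 0.5.
#' @param seed Default seed recorded in reports. Default 1.
#'
#' @return A `study_config` object (a named list).
#' @export
#' @examples
#' cfg <- study_config()
#' cfg$T_s
study_config <- function(T_s = 120, M = 13L, levels = rep(4L, M), c = 1,
                         min_videos_metrics = 10L, min_points_analysis = 5L,
                         pcc_threshold = 0.5, seed = 1L) {
  M <- as.integer(M)
  levels <- as.integer(levels)
  if (M < 1) abort("M must be >= 1")
  if (length(levels) != M) abort("levels must have one entry per question (length M)")
  if (any(levels < 2)) abort("every question needs at least 2 answer levels")
  if (T_s <= 0) abort("T_s must be positive")
  if (c <= 0) abort("c must be positive")
  if (pcc_threshold <= 0 || pcc_threshold >= 1) abort("pcc_threshold must be in (0, 1)")
  if (min_videos_metrics < 2) abort("min_videos_metrics must be >= 2")
  structure(
    list(T_s = T_s, M = M, levels = levels, c = c,
         min_videos_metrics = as.integer(min_videos_metrics),
         min_points_analysis = as.integer(min_points_analysis),
         pcc_threshold = pcc_threshold, seed = as.integer(seed)),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat(sprintf("  questions (M): %d, levels: %s\n", x$M,
              paste(unique(x$levels), collapse = "/")))
  cat(sprintf("  warning threshold: %g s, penalized-time c: %g\n", x$T_s, x$c))
  cat(sprintf("  eligibility: >= %d videos for metrics, >= %d points for analysis\n",
              x$min_videos_metrics, x$min_points_analysis))
  cat(sprintf("  classification threshold: %g\n", x$pcc_threshold))
  invisible(x)
}

#' Read or write a study configuration as YAML
#'
#' The on-disk format is a flat key–value document mirroring the fields of
#' [study_config()] exactly.
#'
#' @param path File path.
#' @return `read_study_config()` returns a `study_config`;
#'   `write_study_config()` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(study_config, raw)
}

#' @rdname read_study_config
#' @param config A `study_config` object.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
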