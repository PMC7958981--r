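#' @importFrom rlang %||% .data abort warn
#' @importFrom stats cor lm plogis predict pt rbeta rnorm runif sd setNames
#' @importFrom utils combn
NULL

# column names holding the M first-pass answers / revised answers
answer_cols <- function(M) paste0("a", seq_len(M))
revision_cols <- function(M) paste0("r", seq_len(M))

# clip a numeric matrix column-wise to the valid ordinal range [0, levels - 1]
clip_to_levels <- function(x, levels) {
  stopifnot(ncol(x) == length(levels))
  for (j in seq_along(levels)) {
    x[, j] <- pmin(pmax(x[, j], 0L), levels[j] - 1L)
  }
  x
}

# extract the answer (or revision) block of a responses tibble as an
# integer matrix, one row per response row
answers_matrix <- function(responses, M, revised = FALSE) {
  cols <- if (revised) revision_cols(M) else answer_cols(M)
  missing <- setdiff(cols, names(responses))
  if (length(missing) > 0) {
    abort(sprintf("responses table is missing answer column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  m <- as.matrix(responses[cols])
  storage.mode(m) <- "double"
  m
}

assert_single_worker <- function(responses, what) {
  ids <- unique(responses$worker_id)
  if (length(ids) != 1) {
    abort(sprintf(
      "%s is a per-worker statistic: expected responses from exactly one worker, got %d",
      what, length(ids)))
  }
  invisible(ids)
}

# run `code` under a fixed RNG seed when `seed` is supplied, otherwise
# continue the caller's RNG stream (used so cohort-level wrappers can seed
# once and call the piecewise generators without re-seeding)
with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, force(code))
}
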