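# hand-construct a wide responses tibble for one worker; answers (and
# optional revised) are matrices with one row per video
build_responses <- function(worker = "w1", videos, answers, attempt = 1L,
                            t1 = 150, warned = NULL, revised = NULL,
                            t2 = NULL, M = ncol(answers)) {
  n <- length(videos)
  answers <- matrix(as.integer(answers), n, M)
  if (is.null(warned)) warned <- rep(FALSE, n)
  if (is.null(t2)) t2 <- rep(NA_real_, n)
  if (is.null(revised)) {
    rev <- matrix(NA_integer_, n, M)
  } else {
    rev <- matrix(as.integer(revised), n, M)
  }
  t1 <- rep_len(t1, n)
  ans <- tibble::as_tibble(answers, .name_repair = ~paste0("a", seq_len(M)))
  rv <- tibble::as_tibble(rev, .name_repair = ~paste0("r", seq_len(M)))
  dplyr::bind_cols(
    tibble::tibble(worker_id = worker, video_id = videos,
                   attempt = as.integer(attempt), t1_s = t1,
                   warned = warned, t2_s = t2),
    ans, rv)
}

# a small balanced video table matching video ids v1..vn
build_videos <- function(n, balance = 0.5) {
  n_pos <- round(n * balance)
  tibble::tibble(video_id = paste0("v", seq_len(n)),
                 true_class = c(rep("autism", n_pos),
                                rep("neurotypical", n - n_pos)),
                 duration_s = 40)
}
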