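# Naive, loop-based recomputations of every per-worker metric, written
# directly from the definitions and kept independent of the package's
# vectorized implementations.

oracle_answers <- function(row, M, revised = FALSE) {
  cols <- paste0(if (revised) "r" else "a", seq_len(M))
  as.numeric(row[1, cols])
}

oracle_mscl1 <- function(responses, M) {
  a1 <- responses[responses$attempt == 1, ]
  a2 <- responses[responses$attempt == 2, ]
  paired <- intersect(a1$video_id, a2$video_id)
  if (length(paired) == 0) return(NA_real_)
  total <- 0
  for (v in paired) {
    x <- oracle_answers(a1[a1$video_id == v, ], M)
    y <- oracle_answers(a2[a2$video_id == v, ], M)
    for (j in seq_len(M)) total <- total + abs(y[j] - x[j])
  }
  total / length(paired)
}

oracle_mpil1 <- function(responses, M) {
  a1 <- responses[responses$attempt == 1, ]
  N <- nrow(a1)
  if (N < 2) return(NA_real_)
  total <- 0
  for (i1 in seq_len(N - 1)) {
    for (i2 in (i1 + 1):N) {
      x <- oracle_answers(a1[i1, ], M)
      y <- oracle_answers(a1[i2, ], M)
      for (j in seq_len(M)) total <- total + abs(y[j] - x[j])
    }
  }
  total / (0.5 * N * (N - 1))
}

oracle_rmscl1 <- function(responses, M) {
  a1 <- responses[responses$attempt == 1 & responses$warned, ]
  dists <- c()
  for (i in seq_len(nrow(a1))) {
    r <- oracle_answers(a1[i, ], M, revised = TRUE)
    if (all(is.na(r))) next
    x <- oracle_answers(a1[i, ], M)
    dists <- c(dists, sum(abs(r - x)))
  }
  if (length(dists) == 0) return(NA_real_)
  mean(dists)
}

oracle_pt <- function(responses, M, T_s, c) {
  a1 <- responses[responses$attempt == 1, ]
  if (all(a1$t1_s >= T_s)) return(as.numeric(M))
  r <- oracle_rmscl1(responses, M)
  if (is.na(r)) return(NA_real_)
  total <- 0
  for (i in seq_len(nrow(a1))) {
    t2 <- a1$t2_s[i]
    total <- total + a1$t1_s[i] + (if (is.na(t2)) 0 else t2)
  }
  total / nrow(a1) + c * r
}

oracle_mean_time <- function(responses) {
  a1 <- responses[responses$attempt == 1, ]
  mean(a1$t1_s)
}

# Independent 5-fold CV MAE: explicit normal equations and an explicit fold
# loop. The fold rule (single shuffle under the seed, labels dealt 1..k) is
# part of the documented contract and is re-implemented here from that
# description.
oracle_cv_mae <- function(d, features, k, seed) {
  n <- nrow(d)
  ord <- withr::with_seed(seed, sample.int(n))
  folds <- integer(n)
  folds[ord] <- rep(seq_len(k), length.out = n)
  y <- d$mean_pcc
  errs <- numeric(n)
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    if (length(features) == 0) {
      pred <- rep(mean(y[train]), length(test))
    } else {
      Xtr <- cbind(1, as.matrix(d[train, features, drop = FALSE]))
      Xte <- cbind(1, as.matrix(d[test, features, drop = FALSE]))
      beta <- solve(t(Xtr) %*% Xtr, t(Xtr) %*% y[train])
      pred <- drop(Xte %*% beta)
    }
    errs[test] <- abs(pred - y[test])
  }
  mean(errs) * 100
}
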