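cfg13 <- study_config()  # 13 questions, 4 levels, T = 120 s

test_that("l1_distance sums absolute ordinal differences", {
  expect_equal(l1_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(l1_distance(c(0, 3, 1), c(2, 0, 1)), 5)
  expect_equal(l1_distance(rep(1, 13), rep(2, 13)), 13)
  expect_error(l1_distance(c(1, 2), c(1, 2, 3)), "length")
})

test_that("MSCL1 averages same-video L1 distance across attempts", {
  a1 <- withr::with_seed(5, matrix(sample(0:2, 13 * 4, replace = TRUE), 4))
  vids <- paste0("v", 1:4)
  # identical re-rating
  resp <- dplyr::bind_rows(build_responses("w1", vids, a1),
                           build_responses("w1", vids, a1, attempt = 2L))
  expect_equal(compute_mscl1(resp, cfg13), 0)
  # one ordinal level up on every question of every paired video -> 13
  resp2 <- dplyr::bind_rows(build_responses("w1", vids, a1),
                            build_responses("w1", vids, a1 + 1L, attempt = 2L))
  expect_equal(compute_mscl1(resp2, cfg13), 13)
  # hand computation: per-video distances 3 and 5 -> mean 4
  x <- matrix(0L, 2, 13)
  y <- x
  y[1, 1:3] <- 1L
  y[2, 1:5] <- 1L
  resp3 <- dplyr::bind_rows(build_responses("w1", c("v1", "v2"), x),
                            build_responses("w1", c("v1", "v2"), y,
                                            attempt = 2L))
  expect_equal(compute_mscl1(resp3, cfg13), 4)
  # pairing is by video id: unpaired videos are ignored, no retest -> NA
  expect_equal(compute_mscl1(build_responses("w1", vids, a1), cfg13),
               NA_real_)
})

test_that("MSCL1 is symmetric under swapping the attempt labels", {
  a1 <- withr::with_seed(6, matrix(sample(0:3, 13 * 5, replace = TRUE), 5))
  a2 <- withr::with_seed(7, matrix(sample(0:3, 13 * 5, replace = TRUE), 5))
  vids <- paste0("v", 1:5)
  fwd <- dplyr::bind_rows(build_responses("w1", vids, a1),
                          build_responses("w1", vids, a2, attempt = 2L))
  swp <- dplyr::bind_rows(build_responses("w1", vids, a2),
                          build_responses("w1", vids, a1, attempt = 2L))
  expect_equal(compute_mscl1(fwd, cfg13), compute_mscl1(swp, cfg13))
})

test_that("MPIL1 averages over all unordered video pairs", {
  # copy-paste answering -> exactly 0
  fixed <- matrix(rep(c(1L, 2L, 0L, 3L), length.out = 13), 10, 13,
                  byrow = TRUE)
  expect_equal(compute_mpil1(
    build_responses("w1", paste0("v", 1:10), fixed), cfg13), 0)
  # N = 2: single pair, denominator 1
  two <- rbind(rep(0L, 13), c(rep(1L, 4), rep(0L, 9)))
  expect_equal(compute_mpil1(
    build_responses("w1", c("v1", "v2"), two), cfg13), 4)
  # N = 3 with pairwise distances 2, 4, 6 -> mean 4
  three <- rbind(rep(0L, 13),
                 c(2L, rep(0L, 12)),
                 c(2L, 2L, 2L, rep(0L, 10)))
  expect_equal(compute_mpil1(
    build_responses("w1", paste0("v", 1:3), three), cfg13), 4)
  # a single rated video leaves the metric undefined
  expect_equal(compute_mpil1(
    build_responses("w1", "v1", matrix(0L, 1, 13)), cfg13), NA_real_)
})

test_that("RMSCL1 averages revision distance over revised warnings", {
  base <- matrix(0L, 3, 13)
  rev <- base
  rev[1, 1] <- 1L          # distance 1
  rev[2, 1:2] <- 1L        # distance 2
  rev[3, 1:3] <- 2L        # distance 6
  resp <- build_responses("w1", paste0("v", 1:3), base, t1 = 60,
                          warned = rep(TRUE, 3), revised = rev,
                          t2 = c(10, 20, 30))
  expect_equal(compute_rmscl1(resp, cfg13), 3)
  # identical revisions -> 0; no warnings -> NA
  same <- build_responses("w1", "v1", matrix(1L, 1, 13), t1 = 60,
                          warned = TRUE, revised = matrix(1L, 1, 13), t2 = 5)
  expect_equal(compute_rmscl1(same, cfg13), 0)
  expect_equal(compute_rmscl1(
    build_responses("w1", "v1", matrix(1L, 1, 13)), cfg13), NA_real_)
})

test_that("penalized time follows the per-worker branch rule", {
  # never warned -> baseline M = 13 regardless of times
  slow <- build_responses("w1", paste0("v", 1:3), matrix(0L, 3, 13),
                          t1 = c(120, 300, 500))
  expect_equal(compute_pt(slow, cfg13), 13)
  # one video, t1 = 60, t2 = 30, revision distance 2, c = 1 -> 92
  rev <- matrix(0L, 1, 13)
  rev[1, 1:2] <- 1L
  fast <- build_responses("w1", "v1", matrix(0L, 1, 13), t1 = 60,
                          warned = TRUE, revised = rev, t2 = 30)
  expect_equal(compute_pt(fast, cfg13), 92)
  # with c = 0 the revision term vanishes
  cfg_c0 <- study_config(c = 1e-12)
  expect_equal(compute_pt(fast, cfg_c0), 90, tolerance = 1e-9)
  # warned worker who never revised has undefined PT
  ignored <- build_responses("w1", "v1", matrix(0L, 1, 13), t1 = 60,
                             warned = TRUE)
  expect_equal(compute_pt(ignored, cfg13), NA_real_)
  # unwarned videos contribute t2 = 0 to the time sum
  mixed <- dplyr::bind_rows(
    build_responses("w1", "v1", matrix(0L, 1, 13), t1 = 60, warned = TRUE,
                    revised = rev, t2 = 30),
    build_responses("w1", "v2", matrix(0L, 1, 13), t1 = 200))
  expect_equal(compute_pt(mixed, cfg13), (60 + 30 + 200) / 2 + 2)
})

test_that("PT time term scales with time while the revision term does not", {
  rev <- matrix(0L, 1, 13)
  rev[1, 1:4] <- 1L
  make <- function(k) build_responses("w1", "v1", matrix(0L, 1, 13),
                                      t1 = 60 * k, warned = TRUE,
                                      revised = rev, t2 = 30 * k)
  cfg_small_T <- study_config(T_s = 1e6)  # keep the worker in the warned branch
  pt1 <- compute_pt(make(1), cfg_small_T)
  pt3 <- compute_pt(make(3), cfg_small_T)
  expect_equal(pt3 - cfg_small_T$c * 4, 3 * (pt1 - cfg_small_T$c * 4))
})

test_that("mean rating time averages initial times and rescales by question count", {
  resp <- build_responses("w1", c("v1", "v2"), matrix(0L, 2, 13),
                          t1 = c(100, 140))
  expect_equal(compute_mean_time(resp), 120)
  expect_equal(compute_mean_time(
    build_responses("w1", "v1", matrix(0L, 1, 13), t1 = 557.7)), 557.7)
  expect_equal(round(proportional_mean_time(557.7, 31, 13), 1), 233.9)
})

test_that("metrics are invariant to video order and question order", {
  cfg <- study_config(M = 6, levels = rep(4L, 6), min_videos_metrics = 2)
  a1 <- withr::with_seed(9, matrix(sample(0:3, 6 * 5, replace = TRUE), 5))
  a2 <- withr::with_seed(10, matrix(sample(0:3, 6 * 5, replace = TRUE), 5))
  vids <- paste0("v", 1:5)
  resp <- dplyr::bind_rows(build_responses("w1", vids, a1),
                           build_responses("w1", vids, a2, attempt = 2L))
  vperm <- withr::with_seed(1, sample(5))
  qperm <- withr::with_seed(2, sample(6))
  shuffled <- dplyr::bind_rows(
    build_responses("w1", vids[vperm], a1[vperm, qperm]),
    build_responses("w1", vids[vperm], a2[vperm, qperm], attempt = 2L))
  expect_equal(compute_mscl1(shuffled, cfg), compute_mscl1(resp, cfg))
  expect_equal(compute_mpil1(shuffled, cfg), compute_mpil1(resp, cfg))
})

test_that("L1 metrics respect the maximal-range bound", {
  cfg <- study_config(M = 4, levels = rep(4L, 4), min_videos_metrics = 2)
  lo <- matrix(0L, 2, 4)
  hi <- matrix(3L, 2, 4)
  opposed <- rbind(lo[1, ], hi[1, ])
  expect_equal(compute_mpil1(
    build_responses("w1", c("v1", "v2"), opposed), cfg), sum(cfg$levels - 1))
  resp <- dplyr::bind_rows(build_responses("w1", c("v1", "v2"), lo),
                           build_responses("w1", c("v1", "v2"), hi,
                                           attempt = 2L))
  expect_equal(compute_mscl1(resp, cfg), sum(cfg$levels - 1))
})

test_that("compute_all_metrics applies the 10-video rule and missingness", {
  cfg <- study_config(M = 3, levels = rep(4L, 3))
  videos <- build_videos(12)
  spec <- classifier_spec(c(1, -1, 0.5), 0)
  nine <- withr::with_seed(3, matrix(sample(0:3, 9 * 3, replace = TRUE), 9))
  ten <- withr::with_seed(4, matrix(sample(0:3, 10 * 3, replace = TRUE), 10))
  resp <- validate_responses(dplyr::bind_rows(
    build_responses("wfew", videos$video_id[1:9], nine),
    build_responses("wten", videos$video_id[1:10], ten)), cfg)
  scored <- score_responses(resp, videos, spec, cfg)
  m <- compute_all_metrics(resp, scored, cfg)

  expect_equal(m$worker_id, "wten")               # 9-video worker excluded
  expect_equal(attr(m, "excluded")$worker_id, "wfew")
  expect_true(is.na(m$mscl1))                     # no retest
  expect_true(is.na(m$rmscl1))                    # never warned
  expect_equal(m$pt, 3)                           # baseline M
  expect_false(is.na(m$mpil1))
  expect_equal(m$n_videos, 10L)
  expect_equal(m$mean_pcc, mean_worker_pcc(scored, "wten"))
})

test_that("pipeline metrics equal naive double-loop recomputation on random workers", {
  cfg <- as_study_config(sim_config(), min_videos_metrics = 2)
  co <- simulate_cohort(sim_config(n_workers = 12, n_videos = 10), seed = 101)
  for (w in unique(co$responses$worker_id)) {
    rw <- co$responses[co$responses$worker_id == w, ]
    expect_equal(compute_mscl1(rw, cfg), oracle_mscl1(rw, cfg$M),
                 tolerance = 1e-10)
    expect_equal(compute_mpil1(rw, cfg), oracle_mpil1(rw, cfg$M),
                 tolerance = 1e-10)
    expect_equal(compute_rmscl1(rw, cfg), oracle_rmscl1(rw, cfg$M),
                 tolerance = 1e-10)
    expect_equal(compute_pt(rw, cfg), oracle_pt(rw, cfg$M, cfg$T_s, cfg$c),
                 tolerance = 1e-10)
    expect_equal(compute_mean_time(rw), oracle_mean_time(rw),
                 tolerance = 1e-10)
  }
})
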