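#' Simulation configuration
#'
#' Parameters of the synthetic crowd-rating study. Defaults emulate the
#' reference design: a balanced set of 24 short videos (12 autism, 12
#' neurotypical), 60 workers, 13 four-level ordinal questions, a 120 s
#' minimum-time warning, and a delayed re-rating of the same videos.
#'
#' Workers differ along a latent *diligence* axis. Each video carries a
#' latent "ideal" answer vector that the ground-truth classifier scores
#' confidently toward the correct class; each worker also carries a personal
#' *habitual* answer vector (their careless default). A worker answers each
#' question from the ideal vector with probability equal to their diligence
#' and from their habitual vector otherwise, plus a small rounded Gaussian
#' perturbation on the ordinal scale. Fully lazy (copy-paste) workers reuse
#' their habitual vector verbatim on every video.
#'
#' With `coupling = TRUE` the behavioral axes are tied to diligence the way
#' a real careless workforce ties them: diligent workers spend more time per
#' rating (so rarely trigger warnings), revise toward the ideal vector when
#' warned, and are more likely to return for the re-rating. With
#' `coupling = FALSE` (the null mode) answer quality still varies across
#' workers, but rating times, revision behavior and revision content are
#' drawn independently of diligence — revisions are pure ordinal noise — so
#' time-based trust metrics carry no signal about performance.
#'
#' @param n_videos Number of videos. Default 24.
#' @param n_workers Number of workers. Default 60.
#' @param class_balance Fraction of videos with true class autism (exact up
#'   to deterministic rounding). Default 0.5.
#' @param M Questions per task. Default 13.
#' @param levels Per-question ordinal level counts. Default 4 each.
#' @param T_s Warning threshold in seconds. Default 120.
#' @param retest Generate the delayed second attempt. Default `TRUE`.
#' @param coupling Tie times/revisions/retest attrition to diligence (see
#'   Details). Default `TRUE`.
#' @param lazy_fraction Probability a worker is a copy-paste answerer.
#'   Default 0.15.
#' @param answer_noise_sd SD of the rounded Gaussian ordinal perturbation
#'   added to non-lazy answers. Default 0.3.
#' @param retest_drift_sd Extra perturbation SD at the second attempt.
#'   Default 0.4.
#' @param retest_skip Baseline probability of skipping the second attempt;
#'   under coupling it is scaled by (1 - diligence) so low performers drop
#'   out more, reproducing the informative missingness of real cohorts.
#'   Default 0.5.
#' @param rating_prob Probability a worker rates any given video at attempt
#'   1. Default 0.9.
#' @param separation Minimum classifier PCC required of each video's ideal
#'   answer vector. Default 0.8.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_videos = 24L, n_workers = 60L, class_balance = 0.5,
                       M = 13L, levels = rep(4L, M), T_s = 120,
                       retest = TRUE, coupling = TRUE, lazy_fraction = 0.15,
                       answer_noise_sd = 0.3, retest_drift_sd = 0.4,
                       retest_skip = 0.5, rating_prob = 0.9,
                       separation = 0.8) {
  if (class_balance <= 0 || class_balance >= 1) {
    abort("class_balance must lie strictly between 0 and 1")
  }
  if (n_videos < 2) abort("n_videos must be >= 2")
  if (n_workers < 1) abort("n_workers must be >= 1")
  M <- as.integer(M)
  levels <- as.integer(levels)
  if (length(levels) != M) abort("levels must have length M")
  structure(list(n_videos = as.integer(n_videos),
                 n_workers = as.integer(n_workers),
                 class_balance = class_balance, M = M, levels = levels,
                 T_s = T_s, retest = retest, coupling = coupling,
                 lazy_fraction = lazy_fraction,
                 answer_noise_sd = answer_noise_sd,
                 retest_drift_sd = retest_drift_sd,
                 retest_skip = retest_skip, rating_prob = rating_prob,
                 separation = separation),
            class = "sim_config")
}

#' Study configuration matching a simulation configuration
#'
#' @param config A [sim_config()].
#' @param ... Overrides passed on to [study_config()].
#' @return A [study_config()] with the simulation's `T_s`, `M` and `levels`.
#' @export
as_study_config <- function(config, ...) {
  stopifnot(inherits(config, "sim_config"))
  study_config(T_s = config$T_s, M = config$M, levels = config$levels, ...)
}

#' Generate a ground-truth classifier
#'
#' Draws one weight per question from a standard normal (symmetric around
#' zero, almost surely all nonzero) and sets the intercept so that the
#' neutral mid-scale answer vector scores probability exactly 0.5.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return A [classifier_spec()].
#' @export
simulate_classifier <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_maybe(seed, {
    w <- rnorm(config$M)
    mid <- (config$levels - 1) / 2
    classifier_spec(weights = w, intercept = -sum(w * mid),
                    positive_class = "autism")
  })
}

# directed draw of one ideal answer vector: per question, sample the code
# with probability proportional to exp(sign * sharpness * w_j * code), so
# autism videos load on the positive-weight direction and neurotypical
# videos on the negative
draw_ideal <- function(spec, levels, positive, sharpness = 1.8) {
  sgn <- if (positive) 1 else -1
  vapply(seq_along(levels), function(j) {
    codes <- 0:(levels[j] - 1)
    pr <- exp(sgn * sharpness * spec$weights[j] * codes)
    sample(codes, 1, prob = pr / sum(pr))
  }, numeric(1))
}

#' Generate synthetic videos with latent ideal answer vectors
#'
#' Assigns true classes with exact balance (deterministic rounding, order
#' shuffled) and draws, for each video, a latent "ideal" answer vector that
#' the ground-truth classifier scores toward the correct class with PCC at
#' least `config$separation` (rejection sampling with bounded retries).
#' Video durations emulate short clips (mean ~48 s).
#'
#' @param config A [sim_config()].
#' @param spec The ground-truth [classifier_spec()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @param id_prefix Prefix for video ids (used to keep cohorts disjoint).
#' @return A list with `videos` (tibble `video_id`, `true_class`,
#'   `duration_s`) and `ideal` (numeric matrix of ideal answer vectors,
#'   rownames = video ids).
#' @export
simulate_videos <- function(config, spec, seed = NULL, id_prefix = "") {
  stopifnot(inherits(config, "sim_config"), inherits(spec, "classifier_spec"))
  with_seed_maybe(seed, {
    n <- config$n_videos
    n_pos <- round(n * config$class_balance)
    cls <- sample(c(rep("autism", n_pos), rep("neurotypical", n - n_pos)))
    ideal <- matrix(0, n, config$M)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(200)) {
        v <- draw_ideal(spec, config$levels, cls[i] == "autism")
        p <- predict_probability(v, spec)
        if (pcc(p, cls[i]) >= config$separation) { ok <- TRUE; break }
      }
      if (!ok) {
        abort(sprintf("could not generate a separable ideal vector for video %d (class %s)",
                      i, cls[i]))
      }
      ideal[i, ] <- v
    }
    ids <- sprintf("%sv%03d", id_prefix, seq_len(n))
    rownames(ideal) <- ids
    list(
      videos = tibble::tibble(
        video_id = ids, true_class = cls,
        duration_s = round(pmax(10, rnorm(n, 47.75, 30.71)), 1)),
      ideal = ideal)
  })
}

#' Generate worker profiles
#'
#' Draws per-worker latent behavior parameters. Diligence follows a
#' Beta(5, 2) (most workers fairly diligent, a long careless tail). Under
#' coupling, mean rating time rises with diligence and revision effort
#' equals diligence; in the null mode both are independent uniform draws.
#' Lazy workers are fast regardless.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @param id_prefix Prefix for worker ids.
#' @return A tibble with one row per worker: `worker_id`, `diligence`,
#'   `lazy`, `answer_noise_sd`, `retest_drift_sd`, `time_rate_s`,
#'   `revise_effort`.
#' @export
simulate_worker_profiles <- function(config, seed = NULL, id_prefix = "") {
  stopifnot(inherits(config, "sim_config"))
  with_seed_maybe(seed, {
    n <- config$n_workers
    diligence <- rbeta(n, 5, 2)
    lazy <- runif(n) < config$lazy_fraction
    if (config$coupling) {
      time_rate <- pmax(15, 30 + 330 * diligence + rnorm(n, 0, 20))
      revise_effort <- diligence
    } else {
      time_rate <- runif(n, 30, 360)
      revise_effort <- runif(n)
    }
    time_rate[lazy] <- runif(sum(lazy), 20, 80)
    tibble::tibble(
      worker_id = sprintf("%sw%03d", id_prefix, seq_len(n)),
      diligence = diligence, lazy = lazy,
      answer_noise_sd = config$answer_noise_sd,
      retest_drift_sd = config$retest_drift_sd,
      time_rate_s = time_rate, revise_effort = revise_effort)
  })
}

# one attempt's answers for one worker across their rated videos:
# ideal-vs-habitual mixture at rate `diligence`, plus rounded Gaussian
# ordinal noise, clipped to the valid code range; lazy workers emit the
# habitual vector verbatim
draw_answers <- function(ideal, habitual, profile, levels, extra_sd = 0) {
  nv <- nrow(ideal)
  M <- ncol(ideal)
  if (profile$lazy) {
    return(matrix(habitual, nv, M, byrow = TRUE))
  }
  take <- matrix(runif(nv * M) < profile$diligence, nv, M)
  hab <- matrix(habitual, nv, M, byrow = TRUE)
  ans <- ifelse(take, ideal, hab)
  noise_sd <- profile$answer_noise_sd + extra_sd
  if (noise_sd > 0) {
    ans <- ans + round(matrix(rnorm(nv * M, 0, noise_sd), nv, M))
  }
  clip_to_levels(ans, levels)
}

#' Simulate worker responses
#'
#' Generates attempt-1 ratings for each worker on a random subset of videos
#' (each video rated with probability `config$rating_prob`), applies the
#' minimum-time warning mechanic — ratings faster than `T_s` seconds are
#' flagged, and the worker may reopen the task to revise answers and log
#' extra time — and, when `config$retest` is on, re-runs the whole
#' generation for a delayed second attempt with added answer drift. Under
#' coupling, warned diligent workers revise toward the video's ideal vector
#' and low-diligence workers tend to skip the retest; in the null mode
#' revisions perturb answers at random and retest attrition is uniform.
#'
#' @param profiles Worker profiles from [simulate_worker_profiles()].
#' @param videos Video list from [simulate_videos()].
#' @param config A [sim_config()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return A validated responses tibble (see [read_responses()]).
#' @export
simulate_responses <- function(profiles, videos, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_maybe(seed, {
    M <- config$M
    levels <- config$levels
    ideal_all <- videos$ideal
    n_videos <- nrow(ideal_all)

    gen_attempt <- function(prof, habitual, vids, extra_sd) {
      nv <- length(vids)
      ideal <- ideal_all[vids, , drop = FALSE]
      ans <- draw_answers(ideal, habitual, prof, levels, extra_sd)
      t1 <- pmax(5, rnorm(nv, prof$time_rate_s, 0.25 * prof$time_rate_s))
      warned <- t1 < config$T_s
      rev <- matrix(NA_real_, nv, M)
      t2 <- rep(NA_real_, nv)
      for (i in which(warned)) {
        p_rev <- if (config$coupling) 0.3 + 0.7 * prof$revise_effort else 0.7
        if (runif(1) >= p_rev) next  # warning ignored: no revision record
        if (config$coupling) {
          move <- runif(M) < prof$revise_effort
          r <- ifelse(move, ideal[i, ], ans[i, ])
          t2[i] <- (20 + 200 * prof$revise_effort) * runif(1, 0.7, 1.3)
        } else {
          r <- ans[i, ] + round(rnorm(M, 0, 1.2))
          t2[i] <- runif(1, 10, 240)
        }
        rev[i, ] <- clip_to_levels(matrix(r, 1), levels)
      }
      list(ans = ans, t1 = t1, warned = warned, rev = rev, t2 = t2)
    }

    rows <- purrr::map(seq_len(nrow(profiles)), function(wi) {
      prof <- profiles[wi, ]
      habitual <- vapply(levels, function(L) sample.int(L, 1) - 1, numeric(1))
      rated <- which(runif(n_videos) < config$rating_prob)
      if (length(rated) == 0) rated <- sample.int(n_videos, 1)
      out <- list()

      a1 <- gen_attempt(prof, habitual, rated, extra_sd = 0)
      out[[1]] <- build_response_rows(prof$worker_id,
                                      rownames(ideal_all)[rated], 1L, a1, M)
      if (config$retest) {
        p_skip <- if (config$coupling) {
          min(0.9, config$retest_skip * 2 * (1 - prof$diligence))
        } else config$retest_skip
        if (runif(1) >= p_skip) {
          a2 <- gen_attempt(prof, habitual, rated,
                            extra_sd = prof$retest_drift_sd)
          out[[2]] <- build_response_rows(prof$worker_id,
                                          rownames(ideal_all)[rated], 2L, a2, M)
        }
      }
      dplyr::bind_rows(out)
    })
    validate_responses(dplyr::bind_rows(rows), as_study_config(config))
  })
}

# assemble one attempt's matrices into wide response rows
build_response_rows <- function(worker_id, video_ids, attempt, a, M) {
  ans <- tibble::as_tibble(a$ans, .name_repair = ~answer_cols(M))
  rev <- tibble::as_tibble(a$rev, .name_repair = ~revision_cols(M))
  dplyr::bind_cols(
    tibble::tibble(worker_id = worker_id, video_id = video_ids,
                   attempt = attempt, t1_s = a$t1, warned = a$warned,
                   t2_s = a$t2),
    ans, rev)
}

#' Simulate a complete cohort
#'
#' Convenience wrapper: draws a ground-truth classifier, a balanced video
#' set and a worker population, generates all responses, and scores them.
#'
#' @param config A [sim_config()].
#' @param seed Seed for the whole cohort.
#' @param id_prefix Prefix applied to worker and video ids.
#' @return A list with `responses`, `videos`, `ideal`, `classifier`,
#'   `profiles`, `scored` (from [score_responses()]), and `study` (the
#'   matching [study_config()]).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L,
                            id_prefix = "") {
  withr::with_seed(seed, {
    spec <- simulate_classifier(config)
    vids <- simulate_videos(config, spec, id_prefix = id_prefix)
    profiles <- simulate_worker_profiles(config, id_prefix = id_prefix)
    responses <- simulate_responses(profiles, vids, config)
    study <- as_study_config(config)
    scored <- score_responses(responses, vids$videos, spec, study)
    list(responses = responses, videos = vids$videos, ideal = vids$ideal,
         classifier = spec, profiles = profiles, scored = scored,
         study = study)
  })
}

#' Simulate a disjoint cohort pair
#'
#' Generates two cohorts — disjoint worker ids, disjoint video ids — from
#' the same generative parameters and the same ground-truth classifier, the
#' design used to measure cross-cohort generalization of the metric-to-PCC
#' regression.
#'
#' @param config A [sim_config()].
#' @param seed Master seed.
#' @return A list with `train` and `test` (each as [simulate_cohort()]'s
#'   value) sharing one `classifier`.
#' @export
make_cohort_pair <- function(config = sim_config(), seed = 1L) {
  withr::with_seed(seed, {
    spec <- simulate_classifier(config)
    one <- function(prefix) {
      vids <- simulate_videos(config, spec, id_prefix = prefix)
      profiles <- simulate_worker_profiles(config, id_prefix = prefix)
      responses <- simulate_responses(profiles, vids, config)
      study <- as_study_config(config)
      scored <- score_responses(responses, vids$videos, spec, study)
      list(responses = responses, videos = vids$videos, ideal = vids$ideal,
           classifier = spec, profiles = profiles, scored = scored,
           study = study)
    }
    train <- one("A_")
    test <- one("B_")
    list(train = train, test = test, classifier = spec)
  })
}
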