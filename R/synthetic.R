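#' Default body-brain coupling matrix
#'
#' A stable VAR(1) coupling over the seven canonical channels: moderate
#' self-coupling on the diagonal, weak global coupling everywhere, and
#' stronger coupling inside the body block (RES, ECG, EDA) and inside the
#' brain block (Fz, Cz, Pz, Oz).  Chosen to place the whole-system
#' Phi_MIP in a regime where MIP cuts are informative.
#'
#' @param diag_coupling self-coupling (default 0.5).
#' @param global off-diagonal coupling between any two channels
#'   (default 0.03).
#' @param intra extra off-diagonal coupling within the body and brain
#'   blocks (default 0.09).
#' @param oz_scale factor applied to all off-diagonal couplings of Oz
#'   (default 0.5): the occipital channel is the most loosely coupled
#'   node already at rest, making the \{Oz\} cut the system's habitual
#'   weakest link.
#' @return 7 x 7 matrix with dimnames [phistar_channels].
#' @export
default_coupling <- function(diag_coupling = 0.5, global = 0.03,
                             intra = 0.09, oz_scale = 0.5) {
  n <- 7
  A <- matrix(global, n, n, dimnames = list(phistar_channels, phistar_channels))
  A[.body_idx, .body_idx] <- global + intra
  A[.brain_idx, .brain_idx] <- global + intra
  oz <- which(phistar_channels == "Oz")
  A[oz, ] <- A[oz, ] * oz_scale
  A[, oz] <- A[, oz] * oz_scale
  diag(A) <- diag_coupling
  A
}

spectral_radius <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))

#' Configuration of the synthetic cohort simulator
#'
#' The simulator draws stationary VAR(1) recordings over the seven
#' canonical channels.  During the stimulus phase the coupling matrix is
#' modified, per subject and condition, by a factor
#' `kappa = kappa_condition * eta_subject` (eta log-normal with mean 1):
#' the occipital channel Oz is decoupled from the rest, the EDA-RES
#' coupling is strengthened, and all body-brain cross couplings are
#' weakened.  Questionnaire differences between conditions follow the
#' subject's imposed effect size linearly plus noise.
#'
#' @param n_subjects number of subjects (default 22).
#' @param frames frames per recording (default 225,000 = 900 s at
#'   250 Hz).
#' @param rate sampling rate in Hz.
#' @param A base coupling matrix (default [default_coupling()]).
#' @param noise innovation covariance (default identity).
#' @param oz_decoupling delta_oz in \[0, 1\]: Oz off-diagonal couplings are
#'   scaled by `1 - kappa * delta_oz` during the stimulus.
#' @param eda_res_boost delta_br >= 0 added (times kappa) to the EDA-RES
#'   couplings during the stimulus.
#' @param global_decoupling delta_g in \[0, 1\]: body-brain cross-block
#'   couplings are scaled by `1 - kappa * delta_g` during the stimulus.
#' @param kappa_sync,kappa_async condition scaling of the stimulus effect
#'   (`kappa_sync > kappa_async >= 0`).
#' @param sigma_subj log-sd of the log-normal per-subject effect
#'   heterogeneity eta.
#' @param rating_intercept,rating_slope,rating_noise linear model of the
#'   Q1-Q3 SYNC-ASYNC differences on the subject's effect size
#'   `(kappa_sync - kappa_async) * eta`.
#' @param q78_effect mean SYNC-ASYNC shift of the control items Q7/Q8.
#' @param burn_in frames discarded before the recording starts.
#' @param seed master seed; every draw of the cohort derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 22, frames = 225000, rate = 250,
                       A = default_coupling(), noise = diag(7),
                       oz_decoupling = 0.8, eda_res_boost = 0.15,
                       global_decoupling = 0.15,
                       kappa_sync = 1, kappa_async = 0.5,
                       sigma_subj = 0.2,
                       rating_intercept = 5, rating_slope = 60,
                       rating_noise = 5, q78_effect = 8,
                       burn_in = 1000, seed = 1L) {
  stopifnot(
    n_subjects >= 1, frames >= 10,
    oz_decoupling >= 0, oz_decoupling <= 1,
    eda_res_boost >= 0,
    global_decoupling >= 0, global_decoupling <= 1,
    kappa_sync > kappa_async, kappa_async >= 0,
    sigma_subj >= 0, rating_noise >= 0, burn_in >= 0
  )
  cfg <- structure(
    list(n_subjects = as.integer(n_subjects), frames = as.integer(frames),
         rate = rate, A = as.matrix(A), noise = as.matrix(noise),
         oz_decoupling = oz_decoupling, eda_res_boost = eda_res_boost,
         global_decoupling = global_decoupling,
         kappa_sync = kappa_sync, kappa_async = kappa_async,
         sigma_subj = sigma_subj,
         rating_intercept = rating_intercept, rating_slope = rating_slope,
         rating_noise = rating_noise, q78_effect = q78_effect,
         burn_in = as.integer(burn_in), seed = as.integer(seed)),
    class = "sim_config"
  )
  if (spectral_radius(cfg$A) >= 1)
    stop("base coupling matrix is unstable (spectral radius >= 1)")
  # stability of the stimulus coupling at an extreme subject effect
  kmax <- cfg$kappa_sync * exp(3 * sigma_subj)
  if (spectral_radius(stim_coupling(cfg, kmax)) >= 1)
    stop("stimulus-modified coupling is unstable at extreme subject effects; weaken the modifiers")
  cfg
}

#' Stimulus-phase coupling matrix
#'
#' Applies the three stimulus modifiers to the base coupling at strength
#' `kappa`: Oz off-diagonal couplings scaled by `1 - kappa * delta_oz`,
#' body-brain cross couplings scaled by `1 - kappa * delta_g` (both
#' floored at 0), and `kappa * delta_br` added to the EDA-RES couplings.
#'
#' @param config a [sim_config()].
#' @param kappa effect strength (condition scaling times subject effect).
#' @return Modified 7 x 7 coupling matrix.
#' @export
stim_coupling <- function(config, kappa) {
  A <- config$A
  oz <- which(phistar_channels == "Oz")
  f_oz <- max(0, 1 - kappa * config$oz_decoupling)
  A[oz, -oz] <- A[oz, -oz] * f_oz
  A[-oz, oz] <- A[-oz, oz] * f_oz
  f_g <- max(0, 1 - kappa * config$global_decoupling)
  A[.body_idx, .brain_idx] <- A[.body_idx, .brain_idx] * f_g
  A[.brain_idx, .body_idx] <- A[.brain_idx, .body_idx] * f_g
  eda <- which(phistar_channels == "EDA")
  res <- which(phistar_channels == "RES")
  A[eda, res] <- A[eda, res] + kappa * config$eda_res_boost
  A[res, eda] <- A[res, eda] + kappa * config$eda_res_boost
  A
}

#' Per-subject effect heterogeneity
#'
#' Deterministic given the config seed: `eta_i` ~ log-normal with
#' `meanlog = -sigma_subj^2 / 2` (so `E[eta] = 1`), keeping every
#' subject's kappa positive.
#'
#' @param config a [sim_config()].
#' @return Numeric vector of length `n_subjects`.
#' @export
subject_effects <- function(config) {
  withr::with_seed(config$seed, {
    rlnorm(config$n_subjects, meanlog = -config$sigma_subj^2 / 2,
           sdlog = config$sigma_subj)
  })
}

subject_ids <- function(config) sprintf("S%02d", seq_len(config$n_subjects))

#' Simulate one recording
#'
#' VAR(1) dynamics `x(t) = A_phase x(t-1) + eps(t)` with the base
#' coupling in the pre and post phases and the stimulus-modified coupling
#' (see [stim_coupling()]) in the middle third.  The state is continuous
#' across phase switches; `burn_in` initial frames are discarded.  The
#' draw is reproducible from the config seed, the subject index and the
#' condition alone.
#'
#' @param config a [sim_config()].
#' @param subject subject index in `1..n_subjects`.
#' @param condition `"SYNC"` or `"ASYNC"`.
#' @return A [recording()].
#' @export
simulate_recording <- function(config, subject, condition = c("SYNC", "ASYNC")) {
  condition <- match.arg(condition)
  stopifnot(subject >= 1, subject <= config$n_subjects)
  eta <- subject_effects(config)[subject]
  kappa <- eta * switch(condition, SYNC = config$kappa_sync,
                        ASYNC = config$kappa_async)
  A_stim <- stim_coupling(config, kappa)
  if (spectral_radius(A_stim) >= 1)
    stop("stimulus-modified coupling matrix is unstable for this subject")

  f3 <- config$frames %/% 3
  lens <- c(config$burn_in + f3, f3, config$frames - 2 * f3)
  As <- list(config$A, A_stim, config$A)
  L <- chol(config$noise)
  seed <- config$seed + 1000L * as.integer(subject) +
    if (condition == "SYNC") 1L else 2L
  X <- withr::with_seed(seed, {
    x <- rep(0, 7)
    parts <- vector("list", 3)
    for (ph in 1:3) {
      eps <- matrix(rnorm(lens[ph] * 7), ncol = 7) %*% L
      parts[[ph]] <- cpp_var_simulate(As[[ph]], eps, x)
      x <- parts[[ph]][lens[ph], ]
    }
    do.call(rbind, parts)
  })
  X <- X[-seq_len(config$burn_in), , drop = FALSE]
  colnames(X) <- phistar_channels
  recording(X, subject_id = subject_ids(config)[subject],
            condition = condition, rate = config$rate, warn = FALSE)
}

#' Simulate the questionnaire ratings of the cohort
#'
#' For Q1-Q3 the SYNC-ASYNC difference of each subject is
#' `rating_intercept + rating_slope * effect + noise`, where `effect =
#' (kappa_sync - kappa_async) * eta`; the ASYNC rating is drawn around
#' the scale midpoint and both are clipped to \[0, 100\].  Q4-Q9 are drawn
#' near 50; the control items Q7 and Q8 receive a small positive SYNC
#' shift (`q78_effect`).
#'
#' @param config a [sim_config()].
#' @param effects per-subject effect sizes; default derives them from the
#'   config.
#' @return Data frame with `subject_id`, `condition`, `Q1`..`Q9` (two
#'   rows per subject).
#' @export
simulate_ratings <- function(config, effects = NULL) {
  if (is.null(effects))
    effects <- (config$kappa_sync - config$kappa_async) * subject_effects(config)
  n <- config$n_subjects
  clip <- function(x) pmin(100, pmax(0, x))
  withr::with_seed(config$seed + 900001L, {
    ratings <- expand.grid(subject_id = subject_ids(config),
                           condition = c("SYNC", "ASYNC"),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    for (q in paste0("Q", 1:9)) ratings[[q]] <- NA_real_
    for (i in seq_len(n)) {
      rs <- which(ratings$subject_id == subject_ids(config)[i] &
                    ratings$condition == "SYNC")
      ra <- which(ratings$subject_id == subject_ids(config)[i] &
                    ratings$condition == "ASYNC")
      for (q in paste0("Q", 1:3)) {
        d <- config$rating_intercept + config$rating_slope * effects[i] +
          rnorm(1, 0, config$rating_noise)
        base <- rnorm(1, 40, 10)
        ratings[[q]][ra] <- clip(base)
        ratings[[q]][rs] <- clip(base + d)
      }
      for (q in paste0("Q", 4:9)) {
        shift <- if (q %in% c("Q7", "Q8")) config$q78_effect else 0
        ratings[[q]][ra] <- clip(rnorm(1, 45, 10))
        ratings[[q]][rs] <- clip(rnorm(1, 45, 10) + shift)
      }
    }
    ratings
  })
}

#' Simulate a full cohort
#'
#' Materialises every recording of the subject x condition grid together
#' with the ratings table and the ground-truth effect sizes.  A full-size
#' cohort holds 44 recordings of 225,000 x 7 doubles (about 550 MB);
#' for full-size analyses prefer [analyze_cohort()], which simulates and
#' analyses one recording at a time.
#'
#' @param config a [sim_config()].
#' @return List of class `sim_cohort` with `recordings` (nested list,
#'   `recordings[[subject_id]][[condition]]`), `ratings`, `truth` (data
#'   frame with `subject_id`, `eta`, `kappa_sync`, `kappa_async`,
#'   `effect`) and `config`.
#' @export
simulate_cohort <- function(config) {
  eta <- subject_effects(config)
  truth <- data.frame(
    subject_id = subject_ids(config), eta = eta,
    kappa_sync = config$kappa_sync * eta,
    kappa_async = config$kappa_async * eta,
    effect = (config$kappa_sync - config$kappa_async) * eta,
    stringsAsFactors = FALSE
  )
  recordings <- lapply(seq_len(config$n_subjects), function(i) {
    list(SYNC = simulate_recording(config, i, "SYNC"),
         ASYNC = simulate_recording(config, i, "ASYNC"))
  })
  names(recordings) <- subject_ids(config)
  structure(
    list(recordings = recordings, ratings = simulate_ratings(config),
         truth = truth, config = config),
    class = "sim_cohort"
  )
}

#' Simulate and analyse a cohort, one recording at a time
#'
#' Streams over the subject x condition grid: each recording is
#' simulated, pushed through [run_subject()], and discarded, so memory
#' stays flat for full-size cohorts.
#'
#' @param config a [sim_config()].
#' @param wconfig a [window_config()].
#' @param complexes,verbose passed to [run_subject()].
#' @return A `cohort_series` (see [bind_series()]).
#' @export
analyze_cohort <- function(config, wconfig = window_config(),
                           complexes = TRUE, verbose = FALSE) {
  series <- list()
  for (i in seq_len(config$n_subjects)) {
    for (cond in c("SYNC", "ASYNC")) {
      if (verbose)
        message(sprintf("subject %d / %d, %s", i, config$n_subjects, cond))
      rec <- simulate_recording(config, i, cond)
      series[[length(series) + 1]] <-
        run_subject(rec, wconfig, complexes = complexes)
    }
  }
  bind_series(series)
}
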