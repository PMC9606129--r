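#' A multichannel physiological recording
#'
#' Frames x channels matrix with metadata.  A full study recording is
#' 225,000 frames at 250 Hz (900 s): 300 s pre-stimulus rest, 300 s
#' stimulation, 300 s post-stimulus rest.
#'
#' @param data numeric matrix, frames x channels.
#' @param subject_id subject identifier.
#' @param condition `"SYNC"` or `"ASYNC"` (synchronous or asynchronous
#'   stroking).
#' @param rate sampling rate in Hz (default 250).
#' @param labels channel names; defaults to `colnames(data)`, else the
#'   canonical seven ([phistar_channels]) when the matrix has 7 columns.
#' @param warn warn when the recording is not the expected full length or
#'   does not carry the canonical channel labels (default TRUE; set FALSE
#'   for toy inputs).
#' @return An object of class `recording`.
#' @export
recording <- function(data, subject_id = "S1",
                      condition = c("SYNC", "ASYNC"), rate = 250,
                      labels = NULL, warn = TRUE) {
  condition <- match.arg(condition)
  data <- as.matrix(data)
  if (is.null(labels)) {
    labels <- colnames(data)
    if (is.null(labels)) {
      labels <- if (ncol(data) == 7) phistar_channels
                else paste0("ch", seq_len(ncol(data)))
    }
  }
  if (length(labels) != ncol(data)) stop("labels must match the number of columns")
  if (warn) {
    if (nrow(data) != 225000)
      warning(sprintf("expected 225,000 frames, got %d", nrow(data)))
    if (!identical(as.character(labels), phistar_channels))
      warning("channel labels differ from the canonical seven (RES, ECG, EDA, Fz, Cz, Pz, Oz)")
  }
  colnames(data) <- labels
  structure(
    list(subject_id = subject_id, condition = condition, data = data,
         rate = rate, labels = as.character(labels)),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject %s, %s, %d frames x %d channels @ %g Hz\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data), x$rate))
  invisible(x)
}

#' Sliding-window configuration
#'
#' Defaults follow the study settings: windows of 250 frames (1 s at
#' 250 Hz) shifted by 250 frames, lag tau = 50 frames (0.2 s).  Window
#' lengths of 500 and 750 frames are supported alternatives.
#'
#' @param window_len window length in frames (>= `tau + 2`).
#' @param shift shift between consecutive windows in frames.
#' @param tau lag in frames.
#' @param ridge covariance ridge (NULL = automatic, see
#'   [estimate_lagged_model()]).
#' @param stride compute every `stride`-th step only (default 1 = every
#'   step); larger strides subsample the timeline to cut cost.
#' @return An object of class `window_config`.
#' @export
window_config <- function(window_len = 250, shift = 250, tau = 50,
                          ridge = NULL, stride = 1) {
  cfg <- list(window_len = as.integer(window_len), shift = as.integer(shift),
              tau = as.integer(tau), ridge = ridge, stride = as.integer(stride))
  if (cfg$window_len < cfg$tau + 2)
    stop(sprintf("window_len (%d) must be at least tau + 2 (%d)",
                 cfg$window_len, cfg$tau + 2))
  if (cfg$shift < 1 || cfg$stride < 1) stop("shift and stride must be >= 1")
  structure(cfg, class = "window_config")
}

#' Number of steps a recording yields
#' @param rec a [recording()].
#' @param config a [window_config()].
#' @export
n_steps <- function(rec, config) nrow(rec$data) %/% config$shift

#' Extract the window of one step (with zero-padding)
#'
#' Step `t` is right-aligned to the frame `t * shift`: it covers frames
#' `(t*shift - window_len, t*shift]`.  Frames before the start of the
#' recording are filled with zeros, so for window lengths above the shift
#' only the first few steps carry padding.
#'
#' @param rec a [recording()].
#' @param config a [window_config()].
#' @param step step index in `1..n_steps(rec, config)`.
#' @return window_len x channels matrix.
#' @export
get_window <- function(rec, config, step) {
  end <- step * config$shift
  start <- end - config$window_len + 1L
  if (end > nrow(rec$data)) stop("step beyond the end of the recording")
  if (start >= 1) return(rec$data[start:end, , drop = FALSE])
  pad <- matrix(0, nrow = 1L - start, ncol = ncol(rec$data),
                dimnames = list(NULL, colnames(rec$data)))
  rbind(pad, rec$data[seq_len(end), , drop = FALSE])
}

#' All sliding windows of a recording
#'
#' @inheritParams get_window
#' @return List of window matrices, one per step (a full recording gives
#'   900).
#' @export
sliding_windows <- function(rec, config = window_config()) {
  lapply(seq_len(n_steps(rec, config)), function(s) get_window(rec, config, s))
}

#' Phase label of each step
#'
#' For a full 900-step timeline: steps 1-300 are the pre-stimulus rest,
#' 301-600 the stimulus phase, 601-900 the post-stimulus rest.  Shorter
#' timelines are split by the same thirds.
#'
#' @param steps integer vector of step indices.
#' @param total total number of steps of the timeline (default 900).
#' @return Factor with levels pre, stim, post.
#' @export
phase_of_step <- function(steps, total = 900) {
  b1 <- total / 3
  b2 <- 2 * total / 3
  factor(ifelse(steps <= b1, "pre", ifelse(steps <= b2, "stim", "post")),
         levels = c("pre", "stim", "post"))
}

#' Run the full per-window analysis of one recording
#'
#' For every computed step the whole-system MIP search and (optionally)
#' the complex analysis are run on the lagged Gaussian model of the
#' window.  Windows in which a channel is constant are flagged missing
#' (NA), reported via a warning, and excluded from downstream phase
#' statistics.
#'
#' @param rec a [recording()].
#' @param config a [window_config()].
#' @param complexes also compute the complex/main-complex summary per
#'   window (default TRUE; FALSE restricts to the whole-system MIP and is
#'   much faster, e.g. for the tau scan).
#' @param verbose print progress every 100 steps.
#' @return A data frame of class `subject_series` with one row per
#'   computed step: `subject_id`, `condition`, `step`, `phase`,
#'   `phi_mip`, `mip_cut`, `mutual_info`, `beta_opt` and, when
#'   `complexes = TRUE`, `sum_main_phi`, `n_complexes`,
#'   `n_main_complexes`, `max_main_subset`, `max_main_phi`.
#' @export
run_subject <- function(rec, config = window_config(), complexes = TRUE,
                        verbose = FALSE) {
  stopifnot(inherits(rec, "recording"), inherits(config, "window_config"))
  total <- n_steps(rec, config)
  steps <- seq(1L, total, by = config$stride)
  rows <- vector("list", length(steps))
  n_failed <- 0L
  for (i in seq_along(steps)) {
    s <- steps[i]
    row <- list(step = s, phi_mip = NA_real_, mip_cut = NA_character_,
                mutual_info = NA_real_, beta_opt = NA_real_)
    if (complexes)
      row <- c(row, list(sum_main_phi = NA_real_, n_complexes = NA_integer_,
                         n_main_complexes = NA_integer_,
                         max_main_subset = NA_character_,
                         max_main_phi = NA_real_))
    res <- tryCatch({
      w <- get_window(rec, config, s)
      model <- estimate_lagged_model(w, tau = config$tau, ridge = config$ridge)
      if (complexes) {
        rep <- summarize_complexes(model)
        full <- rep$subset_phis[rep$subset_phis$size == ncol(w), ]
        list(phi_mip = full$phi_mip, mip_cut = full$mip_cut,
             mutual_info = full$mutual_info, beta_opt = full$beta_opt,
             sum_main_phi = rep$sum_main_phi,
             n_complexes = rep$n_complexes,
             n_main_complexes = rep$n_main_complexes,
             max_main_subset = if (is.null(rep$max_main)) NA_character_
                               else rep$max_main$label,
             max_main_phi = if (is.null(rep$max_main)) NA_real_
                            else rep$max_main$phi_mip)
      } else {
        pr <- mip_search(model, per_partition = FALSE)
        list(phi_mip = pr$phi_mip, mip_cut = pr$mip_cut,
             mutual_info = pr$mutual_info, beta_opt = pr$beta_opt)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
    } else {
      row[names(res)] <- res
    }
    rows[[i]] <- row
    if (verbose && i %% 100 == 0)
      message(sprintf("  step %d / %d", s, total))
  }
  if (n_failed > 0)
    warning(sprintf("%d window(s) failed (e.g. constant channel) and were flagged missing",
                    n_failed))
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  out <- cbind(
    data.frame(subject_id = rec$subject_id, condition = rec$condition,
               stringsAsFactors = FALSE),
    out
  )
  out$phase <- phase_of_step(out$step, total)
  out <- out[, c("subject_id", "condition", "step", "phase",
                 setdiff(names(out), c("subject_id", "condition", "step", "phase")))]
  attr(out, "config") <- config
  attr(out, "total_steps") <- total
  class(out) <- c("subject_series", "data.frame")
  out
}

#' Remove the linear trend of a series
#'
#' Subtracts the least-squares line fitted over the whole series (missing
#' values excluded from the fit, preserved in the output).  Applied to the
#' per-window Phi series before phase statistics; detrended Phi values can
#' be negative.
#'
#' @param x numeric vector (>= 2 non-missing points).
#' @param index abscissa of the fit (default `seq_along(x)`; pass the step
#'   numbers when the series is strided).
#' @return Numeric vector of residuals, same length as `x`.
#' @export
detrend_series <- function(x, index = seq_along(x)) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("need at least 2 non-missing points to detrend")
  fit <- lm.fit(cbind(1, index[ok]), x[ok])
  out <- rep(NA_real_, length(x))
  out[ok] <- fit$residuals
  out
}

#' Trailing moving average (display only)
#'
#' `ma[t]` is the mean of the last `len` available values up to `t`
#' (fewer at the start of the series).  Used to smooth time-series plots;
#' never used in statistics.
#'
#' @param x numeric vector.
#' @param len window length in steps (default 150).
#' @return Numeric vector, same length as `x`.
#' @export
moving_average <- function(x, len = 150) {
  len <- as.integer(len)
  if (len < 1) stop("len must be >= 1")
  vapply(seq_along(x), function(t) {
    mean(x[max(1L, t - len + 1L):t], na.rm = TRUE)
  }, 0)
}

#' Scan the time lag tau
#'
#' Computes the mean whole-system Phi_MIP across recordings (and across a
#' strided subsample of windows) for each candidate lag and returns the
#' lag with the maximum mean.  Ties are broken towards the smallest lag.
#'
#' @param recordings list of [recording()] objects.
#' @param taus candidate lags in frames (default `1:250`; `tau = 0` is
#'   rejected because past and present states coincide and the
#'   information quantities degenerate).
#' @param config base [window_config()]; its `tau` is overridden by each
#'   candidate and its `stride` controls the window subsample (default
#'   every 10th window).
#' @param verbose print progress.
#' @return List with `tau` (selected lag) and `profile` (data frame with
#'   `tau`, `mean_phi_mip`).
#' @export
tau_scan <- function(recordings, taus = 1:250,
                     config = window_config(stride = 10), verbose = FALSE) {
  if (length(recordings) == 0) stop("need at least one recording")
  if (inherits(recordings, "recording")) recordings <- list(recordings)
  taus <- as.integer(taus)
  if (length(taus) == 0) stop("empty tau range")
  if (any(taus < 1))
    stop("tau = 0 is not admissible: past and present states coincide")
  prof <- vapply(taus, function(tv) {
    cfg <- config
    cfg$tau <- tv
    if (cfg$window_len < tv + 2)
      stop(sprintf("window_len (%d) too short for tau = %d", cfg$window_len, tv))
    vals <- unlist(lapply(recordings, function(r) {
      run_subject(r, cfg, complexes = FALSE)$phi_mip
    }))
    if (verbose) message(sprintf("tau = %d: mean Phi_MIP = %.5g", tv,
                                 mean(vals, na.rm = TRUE)))
    mean(vals, na.rm = TRUE)
  }, 0)
  list(tau = taus[which.max(prof)],
       profile = data.frame(tau = taus, mean_phi_mip = prof))
}

#' Plot a subject series
#'
#' Draws the detrended per-step series of a measure with its trailing
#' moving average and the stimulus-phase boundaries.
#'
#' @param x a `subject_series`.
#' @param measure column to plot (default `"phi_mip"`).
#' @param ma_len moving-average length in steps (default 150).
#' @param detrend detrend before plotting (default TRUE).
#' @param ... passed to [graphics::plot()].
#' @export
plot.subject_series <- function(x, measure = "phi_mip", ma_len = 150,
                                detrend = TRUE, ...) {
  y <- x[[measure]]
  if (detrend) y <- detrend_series(y, x$step)
  total <- attr(x, "total_steps")
  if (is.null(total)) total <- max(x$step)
  graphics::plot(x$step, y, type = "l", col = "grey70",
                 xlab = "step", ylab = measure, ...)
  graphics::lines(x$step, moving_average(y, ma_len), col = "blue", lwd = 2)
  graphics::abline(v = c(total / 3, 2 * total / 3), lty = 2)
  invisible(x)
}
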