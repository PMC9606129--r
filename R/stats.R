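#' Bind per-subject series into a cohort table
#'
#' @param series_list list of `subject_series` data frames from
#'   [run_subject()].
#' @return One data frame of class `cohort_series` with all rows.
#' @export
bind_series <- function(series_list) {
  if (inherits(series_list, "subject_series")) series_list <- list(series_list)
  out <- do.call(rbind, lapply(series_list, as.data.frame))
  attr(out, "config") <- attr(series_list[[1]], "config")
  attr(out, "total_steps") <- attr(series_list[[1]], "total_steps")
  class(out) <- c("cohort_series", "data.frame")
  out
}

# detrend one measure within each subject x condition block
detrend_by_recording <- function(cohort, measure) {
  key <- interaction(cohort$subject_id, cohort$condition, drop = TRUE)
  out <- rep(NA_real_, nrow(cohort))
  for (k in levels(key)) {
    i <- which(key == k)
    out[i] <- detrend_series(cohort[[measure]][i], cohort$step[i])
  }
  out
}

#' Phase contrasts by Welch's t-test
#'
#' Pools the (optionally detrended) per-window values of a measure across
#' subjects within each phase and compares the three phase pairs
#' (pre vs stim, stim vs post, pre vs post) with Welch's two-sample
#' t-test.  Raw p-values are reported without multiplicity correction.
#'
#' @param cohort a `cohort_series` (see [bind_series()]) or a single
#'   `subject_series`.
#' @param measure column to contrast (default `"phi_mip"`).
#' @param condition restrict to one condition (`"SYNC"`/`"ASYNC"`);
#'   default uses all rows.
#' @param detrend detrend per subject x condition before pooling
#'   (default TRUE).
#' @param pooled pool windows across subjects (default TRUE, giving the
#'   large degrees of freedom of window-level tests); FALSE contrasts
#'   per-subject phase means instead.
#' @return Data frame with one row per phase pair: `phase_a`, `phase_b`,
#'   `mean_a`, `mean_b`, `t`, `df`, `p`.
#' @export
phase_contrast <- function(cohort, measure = "phi_mip", condition = NULL,
                           detrend = TRUE, pooled = TRUE) {
  df <- as.data.frame(cohort)
  if (!is.null(condition)) df <- df[df$condition == condition, , drop = FALSE]
  vals <- if (detrend) detrend_by_recording(df, measure) else df[[measure]]
  phase <- df$phase
  if (!pooled) {
    key <- interaction(df$subject_id, df$condition, phase, drop = TRUE)
    agg <- tapply(vals, key, mean, na.rm = TRUE)
    parts <- strsplit(names(agg), ".", fixed = TRUE)
    phase <- factor(vapply(parts, function(p) p[[3]], ""),
                    levels = c("pre", "stim", "post"))
    vals <- as.numeric(agg)
  }
  pairs <- list(c("pre", "stim"), c("stim", "post"), c("pre", "post"))
  rows <- lapply(pairs, function(p) {
    a <- vals[phase == p[1] & !is.na(vals)]
    b <- vals[phase == p[2] & !is.na(vals)]
    if (length(a) < 2 || length(b) < 2)
      stop(sprintf("phase '%s' or '%s' has fewer than 2 values", p[1], p[2]))
    tt <- t.test(a, b, var.equal = FALSE)
    data.frame(phase_a = p[1], phase_b = p[2],
               mean_a = mean(a), mean_b = mean(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "measure") <- measure
  out
}

# per-subject frequency table of a key column in two phases, then the
# stim-minus-pre difference averaged across subjects
frequency_diff <- function(cohort, key_col, condition) {
  df <- as.data.frame(cohort)
  df <- df[df$condition == condition & !is.na(df[[key_col]]), , drop = FALSE]
  if (nrow(df) == 0) stop("no rows for condition ", condition)
  keys <- sort(unique(df[[key_col]]))
  subjects <- unique(df$subject_id)
  diffs <- matrix(0, nrow = length(subjects), ncol = length(keys),
                  dimnames = list(subjects, keys))
  for (s in seq_along(subjects)) {
    for (ph in c("pre", "stim")) {
      rows <- df[[key_col]][df$subject_id == subjects[s] & df$phase == ph]
      if (length(rows) == 0) next
      fr <- table(factor(rows, levels = keys)) / length(rows)
      diffs[s, ] <- diffs[s, ] + if (ph == "stim") as.numeric(fr) else -as.numeric(fr)
    }
  }
  out <- data.frame(key = keys, diff = colMeans(diffs),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$diff), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_subjects") <- length(subjects)
  out
}

#' MIP-cut frequency differences between stimulus and rest
#'
#' For each subject, the frequency of each whole-system MIP cut among the
#' stimulus-phase windows minus its frequency among the pre-stimulus
#' windows; averaged across subjects and sorted by descending difference.
#' Within a condition the differences sum to zero.
#'
#' @param cohort a `cohort_series`.
#' @param condition `"SYNC"` or `"ASYNC"`.
#' @return Data frame with columns `key` (cut label) and `diff`.
#' @export
mip_cut_frequency_diff <- function(cohort, condition) {
  frequency_diff(cohort, "mip_cut", condition)
}

#' Strongest-main-complex frequency differences between stimulus and rest
#'
#' As [mip_cut_frequency_diff()], keyed by the subset that is the
#' strongest main complex of each window.
#'
#' @inheritParams mip_cut_frequency_diff
#' @export
main_complex_frequency_diff <- function(cohort, condition) {
  frequency_diff(cohort, "max_main_subset", condition)
}

#' Per-subject condition-difference score of subsystem integrity
#'
#' For each subject with both conditions, the per-window sum of Phi_MIP
#' over main complexes is (optionally detrended and) baseline-subtracted
#' by the subject's mean pre-stimulus value within each condition; the
#' score is the sum over stimulus-phase steps of the SYNC minus ASYNC
#' difference.  It is invariant to per-condition additive constants and
#' antisymmetric under swapping the conditions.
#'
#' @param cohort a `cohort_series` containing both conditions.
#' @param measure column to score (default `"sum_main_phi"`).
#' @param detrend detrend per subject x condition first (default TRUE).
#' @return Data frame with `subject_id` and `s_phi`.
#' @export
s_statistic <- function(cohort, measure = "sum_main_phi", detrend = TRUE) {
  df <- as.data.frame(cohort)
  vals <- if (detrend) detrend_by_recording(df, measure) else df[[measure]]
  df$.val <- vals
  subjects <- unique(df$subject_id)
  rows <- lapply(subjects, function(sj) {
    d <- df[df$subject_id == sj, , drop = FALSE]
    if (!all(c("SYNC", "ASYNC") %in% d$condition))
      stop(sprintf("subject %s is missing a condition", sj))
    bs <- function(cond) {
      dc <- d[d$condition == cond, , drop = FALSE]
      base <- mean(dc$.val[dc$phase == "pre"], na.rm = TRUE)
      stim <- dc[dc$phase == "stim", c("step", ".val")]
      stim$.val <- stim$.val - base
      stim
    }
    sy <- bs("SYNC"); as <- bs("ASYNC")
    m <- merge(sy, as, by = "step", suffixes = c("_sync", "_async"))
    data.frame(subject_id = sj,
               s_phi = sum(m$.val_sync - m$.val_async, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Peak-end condition-difference score
#'
#' An alternative to the stimulus-phase sum: per condition the
#' baseline-subtracted stimulus-phase series is summarised by the mean of
#' its maximum and its final value (the peak-end rule), and the summaries
#' are differenced across conditions.
#'
#' @inheritParams s_statistic
#' @return Data frame with `subject_id` and `s_peak_end`.
#' @export
peak_end_summary <- function(cohort, measure = "sum_main_phi", detrend = TRUE) {
  df <- as.data.frame(cohort)
  vals <- if (detrend) detrend_by_recording(df, measure) else df[[measure]]
  df$.val <- vals
  subjects <- unique(df$subject_id)
  rows <- lapply(subjects, function(sj) {
    d <- df[df$subject_id == sj, , drop = FALSE]
    if (!all(c("SYNC", "ASYNC") %in% d$condition))
      stop(sprintf("subject %s is missing a condition", sj))
    pe <- function(cond) {
      dc <- d[d$condition == cond, , drop = FALSE]
      base <- mean(dc$.val[dc$phase == "pre"], na.rm = TRUE)
      stim <- dc$.val[dc$phase == "stim"] - base
      stim <- stim[!is.na(stim)]
      if (length(stim) == 0) stop("no stimulus-phase values for subject ", sj)
      mean(c(max(stim), stim[length(stim)]))
    }
    data.frame(subject_id = sj, s_peak_end = pe("SYNC") - pe("ASYNC"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' RHI index and related questionnaire summaries
#'
#' The RHI index of a subject in a condition is the mean of questionnaire
#' items Q1-Q3 (referral of touch and ownership) on the 0-100
#' visual-analogue scale.
#'
#' @param ratings data frame with columns `subject_id`, `condition`,
#'   `Q1`..`Q9`.
#' @return Data frame with `subject_id`, `condition`, `rhi_index`.
#' @export
rhi_index <- function(ratings) {
  need <- c("subject_id", "condition", paste0("Q", 1:3))
  miss <- setdiff(need, names(ratings))
  if (length(miss) > 0)
    stop("ratings table is missing column(s): ", paste(miss, collapse = ", "))
  qs <- as.matrix(ratings[, paste0("Q", 1:3)])
  if (anyNA(qs)) stop("missing questionnaire item(s) in Q1-Q3")
  if (any(qs < 0 | qs > 100)) stop("ratings must lie in [0, 100]")
  data.frame(subject_id = ratings$subject_id, condition = ratings$condition,
             rhi_index = rowMeans(qs), stringsAsFactors = FALSE)
}

#' Per-subject condition differences of the questionnaire
#'
#' Computes, for each subject present in both conditions, `dQx = Qx_SYNC -
#' Qx_ASYNC` for every item, the RHI-index difference `d_rhi`
#' (mean of dQ1-dQ3), and the extended mean `d_ext` over
#' dQ1, dQ2, dQ3, dQ7, dQ8 (adding the two control items whose denial is
#' weakened during the illusion).
#'
#' @inheritParams rhi_index
#' @return Data frame with `subject_id`, `dQ1`..`dQ9`, `d_rhi`, `d_ext`.
#' @export
rating_differences <- function(ratings) {
  items <- paste0("Q", 1:9)
  have <- intersect(items, names(ratings))
  if (!all(paste0("Q", 1:3) %in% have))
    stop("ratings table must contain at least Q1-Q3")
  sync <- ratings[ratings$condition == "SYNC", , drop = FALSE]
  async <- ratings[ratings$condition == "ASYNC", , drop = FALSE]
  common <- intersect(sync$subject_id, async$subject_id)
  sync <- sync[match(common, sync$subject_id), , drop = FALSE]
  async <- async[match(common, async$subject_id), , drop = FALSE]
  out <- data.frame(subject_id = common, stringsAsFactors = FALSE)
  for (q in have) out[[paste0("d", q)]] <- sync[[q]] - async[[q]]
  out$d_rhi <- rowMeans(out[, paste0("dQ", 1:3)])
  if (all(c("dQ7", "dQ8") %in% names(out)))
    out$d_ext <- rowMeans(out[, paste0("dQ", c(1:3, 7, 8))])
  out
}

#' Merge the condition-difference score with questionnaire differences
#'
#' @param cohort a `cohort_series` with both conditions.
#' @param ratings ratings table (see [rhi_index()]).
#' @param ... passed to [s_statistic()].
#' @return Data frame with one row per subject present in both inputs.
#' @export
subject_scores <- function(cohort, ratings, ...) {
  s <- s_statistic(cohort, ...)
  d <- rating_differences(ratings)
  merge(s, d, by = "subject_id")
}

#' Pearson correlation between the score and a rating difference
#'
#' @param scores output of [subject_scores()] (or any data frame holding
#'   the two columns).
#' @param x,y column names to correlate (defaults `"s_phi"` and
#'   `"d_rhi"`).
#' @return List with `r`, `n` and two-sided `p`.
#' @export
correlate_scores <- function(scores, x = "s_phi", y = "d_rhi") {
  ct <- cor.test(scores[[x]], scores[[y]], method = "pearson")
  list(r = unname(ct$estimate), n = nrow(scores), p = ct$p.value)
}
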