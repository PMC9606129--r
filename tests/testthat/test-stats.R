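test_that("the phase contrast reproduces a hand-computed Welch test", {
  # toy samples {0,0,1,1} (pre) vs {1,1,2,2} (stim):
  # t = -1 / sqrt(1/6) = -sqrt(6), Welch df = 6
  cohort <- toy_cohort("S1", "SYNC", total = 12, value_fun = function(sj, cond, steps) {
    v <- rep(0, 12)
    v[1:4] <- c(0, 0, 1, 1)    # pre
    v[5:8] <- c(1, 1, 2, 2)    # stim
    v[9:12] <- c(0, 1, 0, 1)   # post
    v
  })
  pc <- phase_contrast(cohort, "phi_mip", detrend = FALSE)
  i <- which(pc$phase_a == "pre" & pc$phase_b == "stim")
  expect_equal(pc$t[i], -sqrt(6), tolerance = 1e-9)
  expect_equal(pc$df[i], 6, tolerance = 1e-9)
  expect_equal(pc$p[i], 2 * pt(-sqrt(6), 6), tolerance = 1e-9)
  expect_error(phase_contrast(cohort[cohort$step > 4, ], detrend = FALSE),
               "fewer than 2")
})

test_that("the phase contrast holds its type-I error on null data", {
  set.seed(61)
  hits <- 0
  for (r in 1:400) {
    cohort <- toy_cohort("S1", "SYNC", total = 30,
                         value_fun = function(sj, cond, steps) rnorm(30))
    pc <- phase_contrast(cohort, "phi_mip", detrend = FALSE)
    hits <- hits + (pc$p[pc$phase_a == "pre" & pc$phase_b == "stim"] < 0.05)
  }
  # binomial band around 0.05 at 400 replicates
  expect_gt(hits / 400, 0.05 - 3.5 * sqrt(0.05 * 0.95 / 400))
  expect_lt(hits / 400, 0.05 + 3.5 * sqrt(0.05 * 0.95 / 400))
})

test_that("an imposed stimulus shift is detected in the right direction", {
  set.seed(67)
  cohort <- toy_cohort(sprintf("S%d", 1:5), "SYNC", total = 90,
                       value_fun = function(sj, cond, steps) {
                         rnorm(90) - 0.5 * (phase_of_step(steps, 90) == "stim")
                       })
  pc <- phase_contrast(cohort, "phi_mip", detrend = FALSE)
  i <- which(pc$phase_a == "pre" & pc$phase_b == "stim")
  expect_gt(pc$t[i], 0)     # pre above stim: a drop
  expect_lt(pc$p[i], 0.01)
  # per-subject-mean variant agrees in direction
  pc2 <- phase_contrast(cohort, "phi_mip", detrend = FALSE, pooled = FALSE)
  expect_gt(pc2$t[pc2$phase_a == "pre" & pc2$phase_b == "stim"], 0)
})

test_that("cut-frequency differences are zero-sum and rank imposed shifts first", {
  # identical cut distribution in both phases: all differences zero
  c0 <- toy_cohort(c("S1", "S2"), "SYNC", total = 12,
                   value_fun = function(sj, cond, steps) rnorm(12),
                   cut_fun = function(sj, cond, steps) rep(c("a|b", "c|d"), 6))
  d0 <- mip_cut_frequency_diff(c0, "SYNC")
  expect_true(all(abs(d0$diff) < 1e-12))

  # stimulus phase switches to the oz cut
  set.seed(71)
  c1 <- toy_cohort(c("S1", "S2", "S3"), "SYNC", total = 30,
                   value_fun = function(sj, cond, steps) rnorm(30),
                   cut_fun = function(sj, cond, steps) {
                     ifelse(phase_of_step(steps, 30) == "stim" &
                              runif(30) < 0.8, "rest|Oz",
                            sample(c("a|b", "c|d"), 30, replace = TRUE))
                   })
  d1 <- mip_cut_frequency_diff(c1, "SYNC")
  expect_equal(d1$key[1], "rest|Oz")
  expect_equal(sum(d1$diff), 0, tolerance = 1e-12)
  d2 <- main_complex_frequency_diff(c1, "SYNC")
  expect_equal(sum(d2$diff), 0, tolerance = 1e-12)
})

test_that("the subject score matches direct arithmetic and its invariances", {
  # 6 steps: pre {1,2}, stim {3,4}, post {5,6}
  base <- function(sync_stim, async_stim) {
    toy_cohort("S1", total = 6, value_fun = function(sj, cond, steps) {
      stim <- if (cond == "SYNC") sync_stim else async_stim
      c(0, 0, stim, 0, 0)
    })
  }
  co <- base(c(0.2, 0.3), c(0.1, 0.1))
  s <- s_statistic(co, detrend = FALSE)
  expect_equal(s$s_phi, 0.3, tolerance = 1e-12)

  # identical series in both conditions: zero
  co0 <- toy_cohort("S1", total = 6,
                    value_fun = function(sj, cond, steps) sin(steps))
  expect_equal(s_statistic(co0, detrend = FALSE)$s_phi, 0, tolerance = 1e-12)

  # adding a constant to every window of one condition is absorbed by its
  # baseline
  co_shift <- base(c(0.2, 0.3), c(0.1, 0.1))
  co_shift$phi_mip[co_shift$condition == "SYNC"] <-
    co_shift$phi_mip[co_shift$condition == "SYNC"] + 5
  co_shift$sum_main_phi <- co_shift$phi_mip
  expect_equal(s_statistic(co_shift, detrend = FALSE)$s_phi, 0.3,
               tolerance = 1e-12)

  # swapping conditions flips the sign
  co_sw <- base(c(0.1, 0.1), c(0.2, 0.3))
  expect_equal(s_statistic(co_sw, detrend = FALSE)$s_phi, -0.3,
               tolerance = 1e-12)

  expect_error(s_statistic(co[co$condition == "SYNC", ], detrend = FALSE),
               "missing a condition")
})

test_that("the peak-end summary follows the peak-end rule", {
  # steps 1-2 pre = 0, 3-4 stim, 5-6 post = 0
  co <- toy_cohort("S1", total = 6, value_fun = function(sj, cond, steps) {
    stim <- if (cond == "SYNC") c(0.1, 0.4) else c(0, 0)
    c(0, 0, stim, 0, 0)
  })
  pe <- peak_end_summary(co, detrend = FALSE)
  expect_equal(pe$s_peak_end, mean(c(0.4, 0.4)) - 0, tolerance = 1e-12)

  # monotone stimulus series: mean(max, last) = last value
  co2 <- toy_cohort("S1", total = 9, value_fun = function(sj, cond, steps) {
    stim <- if (cond == "SYNC") c(0.1, 0.2, 0.3) else c(0, 0, 0)
    c(0, 0, 0, stim, 0, 0, 0)
  })
  pe2 <- peak_end_summary(co2, detrend = FALSE)
  expect_equal(pe2$s_peak_end, 0.3, tolerance = 1e-12)
})

test_that("the RHI index and rating differences follow the questionnaire rules", {
  r <- data.frame(subject_id = c("S1", "S1"), condition = c("SYNC", "ASYNC"),
                  Q1 = c(90, 50), Q2 = c(60, 50), Q3 = c(90, 50),
                  Q4 = 50, Q5 = 50, Q6 = 50, Q7 = c(60, 40), Q8 = c(55, 45),
                  Q9 = 50)
  idx <- rhi_index(r)
  expect_equal(idx$rhi_index[idx$condition == "SYNC"], 80)
  expect_equal(idx$rhi_index[idx$condition == "ASYNC"], 50)

  d <- rating_differences(r)
  expect_equal(d$d_rhi, 30)
  expect_equal(d$d_ext, mean(c(40, 10, 40, 20, 10)))

  r_bad <- r; r_bad$Q2 <- NULL
  expect_error(rhi_index(r_bad), "Q2")
  r_na <- r; r_na$Q1[1] <- NA
  expect_error(rhi_index(r_na), "missing")
})

test_that("score-rating correlation behaves at both extremes", {
  # perfectly linear: r = 1
  sc <- data.frame(s_phi = 1:10, d_rhi = 3 + 2 * (1:10))
  ct <- correlate_scores(sc)
  expect_equal(ct$r, 1, tolerance = 1e-12)
  expect_equal(ct$n, 10)

  # independent scores: rejection rate ~ alpha
  set.seed(73)
  hits <- 0
  for (r in 1:500) {
    sc <- data.frame(s_phi = rnorm(21), d_rhi = rnorm(21))
    hits <- hits + (correlate_scores(sc)$p < 0.05)
  }
  expect_gt(hits / 500, 0.05 - 3.5 * sqrt(0.05 * 0.95 / 500))
  expect_lt(hits / 500, 0.05 + 3.5 * sqrt(0.05 * 0.95 / 500))
})
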