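# Spike detection, burst segmentation, burst exclusion, phase and
# classification.

test_that("spike detection counts upward threshold crossings and is shift-equivariant", {
  t <- seq(0, 100, by = 0.1)
  expect_length(detect_spikes(rep(-60, length(t)), t), 0)
  # sinusoid crossing -30 upward a known number of times (crossings fall
  # mid-sample at t = 2.5, 12.5, ..., 92.5)
  V <- -30 + 20 * sin(2 * pi * t / 10 - pi / 2)
  sp <- detect_spikes(V, t)
  expect_length(sp, 10)
  sp_shift <- detect_spikes(V, t + 500)
  expect_equal(sp_shift, sp + 500)
  # crossing from exactly the threshold value is not an upward crossing
  expect_length(detect_spikes(c(-30, -29, -31), c(1, 2, 3)), 0)
})

test_that("ISI threshold follows the percentile rule with a nearest-rank oracle", {
  # two bursts of five spikes separated by 500 ms pauses
  sp <- cumsum(c(0, rep(10, 4), 500, rep(10, 4), 500))
  isi <- diff(sp)
  p90 <- sort(isi)[ceiling(0.9 * length(isi))]  # brute-force nearest rank
  res <- isi_burst_threshold(sp)
  expect_equal(p90, 500)
  expect_equal(res$threshold, 0.5 * (p90 + 10))
  expect_false(res$tonic)
  # equal ISIs: threshold equals the common ISI and is within 10 ms of both
  # extremes, hence tonic
  res2 <- isi_burst_threshold(seq(0, 900, by = 100))
  expect_equal(res2$threshold, 100)
  expect_true(res2$tonic)
  expect_error(isi_burst_threshold(5), "two spikes")
})

test_that("burst segmentation groups by ISI threshold", {
  one <- segment_bursts(42, 100)
  expect_equal(nrow(one), 1)
  expect_equal(one$n_spikes, 1L)
  b <- segment_bursts(c(0, 10, 20, 600, 610), 100)
  expect_equal(b$onset, c(0, 600))
  expect_equal(b$offset, c(20, 610))
  expect_equal(b$n_spikes, c(3L, 2L))
  # all ISIs above threshold: every spike its own burst
  solo <- segment_bursts(c(0, 200, 400), 100)
  expect_equal(nrow(solo), 3)
  expect_true(all(solo$n_spikes == 1L))
})

test_that("opponent-gap merging joins bursts without intervening activity, transitively", {
  b <- data.frame(onset = c(0, 100, 200), offset = c(50, 150, 250),
                  n_spikes = c(3L, 2L, 4L))
  # one opponent spike between the first two bursts blocks that merge
  m1 <- merge_opponent_gaps(b, events_other = 75)
  expect_equal(nrow(m1), 2)
  expect_equal(m1$onset, c(0, 100))
  expect_equal(m1$n_spikes, c(3L, 6L))
  # no opponent events: a chain of three merges into one burst
  m2 <- merge_opponent_gaps(b, events_other = numeric(0))
  expect_equal(nrow(m2), 1)
  expect_equal(m2$offset, 250)
  expect_equal(m2$n_spikes, 9L)
})

test_that("burst exclusion matches a sweep-line oracle on random interval sets", {
  # independent oracle: event sweep with activity counters
  sweep_overlap <- function(a, b) {
    ev <- rbind(cbind(a[, 1], 1, 1), cbind(a[, 2], -1, 1),
                cbind(b[, 1], 1, 2), cbind(b[, 2], -1, 2))
    ev <- ev[order(ev[, 1], ev[, 2]), , drop = FALSE]
    on <- c(0, 0); last <- -Inf; ov <- 0
    for (i in seq_len(nrow(ev))) {
      if (on[1] > 0 && on[2] > 0) ov <- ov + ev[i, 1] - last
      on[ev[i, 3]] <- on[ev[i, 3]] + ev[i, 2]
      last <- ev[i, 1]
    }
    ov
  }
  rand_intervals <- function(T_trial) {
    k <- sample(1:6, 1)
    pts <- sort(stats::runif(2 * k, 0, T_trial))
    matrix(pts, ncol = 2, byrow = TRUE)
  }
  set.seed(7)
  worst <- 0
  for (i in 1:1000) {
    T_trial <- 1000
    a <- rand_intervals(T_trial); b <- rand_intervals(T_trial)
    res <- suppressWarnings(burst_exclusion(a, b, T_trial))
    oracle_ov <- sweep_overlap(a, b)
    worst <- max(worst, abs(res$O_network - oracle_ov))
    t1 <- sum(a[, 2] - a[, 1]); t2 <- sum(b[, 2] - b[, 1])
    x_oracle <- (t1 * t2 / T_trial - oracle_ov) /
      (t1 * t2 / T_trial - max(0, t1 + t2 - T_trial))
    expect_equal(res$x_network, min(1, max(0, x_oracle)), tolerance = 1e-9)
    expect_true(res$x_network >= 0 && res$x_network <= 1)
  }
  expect_lt(worst, 1e-9)
})

test_that("burst exclusion endpoints: perfect alternation 1, chance overlap 0, zero activity undefined", {
  a <- rbind(c(0, 100), c(400, 500))
  b <- rbind(c(200, 300), c(600, 700))
  expect_equal(burst_exclusion(a, b, 800)$x_network, 1)
  # O_network equal to chance overlap: t1 = t2 = T/2 overlapping by T/4
  a2 <- rbind(c(0, 500)); b2 <- rbind(c(250, 750))
  expect_equal(burst_exclusion(a2, b2, 1000)$x_network, 0)
  expect_true(is.na(burst_exclusion(rbind(c(0, 0)), b2, 1000)$x_network))
})

test_that("phase and period agree with a per-cycle oracle and swap to 1 - phi", {
  mk <- function(on) data.frame(onset = on, offset = on + 50,
                                n_spikes = 5L)
  # cell 2 midway between cell 1 onsets
  b1 <- mk(seq(0, 2000, by = 400)); b2 <- mk(seq(200, 2200, by = 400))
  pp <- phase_and_period(b1, b2)
  expect_equal(pp$phi, 0.5)
  expect_equal(pp$period, 400)
  # coincident onsets give phase 0
  expect_equal(phase_and_period(b1, b1)$phi, 0)
  # jittered trains against an explicit per-cycle computation
  set.seed(21)
  on1 <- cumsum(c(100, stats::runif(8, 350, 450)))
  on2 <- on1[-1] - stats::runif(8, 150, 250)
  pp2 <- phase_and_period(mk(on1), mk(on2))
  period_o <- mean(diff(on1))
  phis_o <- vapply(seq_along(on1[-length(on1)]), function(k) {
    nxt <- on2[on2 >= on1[k]][1]
    ((nxt - on1[k]) / period_o) %% 1
  }, numeric(1))
  expect_equal(pp2$period, period_o, tolerance = 1e-12)
  expect_equal(pp2$phi, mean(phis_o) %% 1, tolerance = 1e-12)
  # swapping the cells reflects the phase: phi -> (1 - phi) mod 1
  pp_sw <- phase_and_period(mk(on2), mk(on1))
  wrap <- (pp2$phi + pp_sw$phi) %% 1
  expect_lt(min(wrap, 1 - wrap), 0.05)
  expect_true(is.na(phase_and_period(mk(100), mk(on2))$phi))
})

test_that("classification applies the functionality criteria and is total", {
  # ideal antiphase bursters: functional
  s1 <- burster_spec(period = 400, phase_offset = 0.1, duty = 0.35)
  s2 <- burster_spec(period = 400, phase_offset = 0.6, duty = 0.35)
  bt <- make_burster_traces(s1, s2, duration = 4000)
  cl <- classify_output(bt$trace)
  expect_s3_class(cl, "circuit_output")
  expect_equal(cl$classification, "functional")
  expect_equal(cl$phi, 0.5, tolerance = 0.01)
  expect_equal(cl$period, 400, tolerance = 1)
  expect_gt(cl$x_network, 0.95)
  # same geometry, period 1200 ms: outside the period bound
  l1 <- burster_spec(period = 1200, phase_offset = 0.1, duty = 0.35)
  l2 <- burster_spec(period = 1200, phase_offset = 0.7, duty = 0.35)
  bl <- make_burster_traces(l1, l2, duration = 12000)
  expect_equal(classify_output(bl$trace, transient = 1000)$classification,
               "active_nonfunctional")
  # silence is silence
  silent <- bt$trace
  silent$V2 <- rep(-65, length(silent$V2))
  cl_s <- classify_output(silent)
  expect_equal(cl_s$classification, "one_silent")
  expect_equal(cl_s$silenced_cell, "cell2")
  both <- bt$trace
  both$V1 <- both$V2 <- rep(-65, length(both$V1))
  expect_equal(classify_output(both)$silenced_cell, "both")
  # deterministic
  expect_identical(classify_output(bt$trace)$classification,
                   classify_output(bt$trace)$classification)
})
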