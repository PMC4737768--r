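test_that("mirrored spike trains never cross the decision threshold", {
  tt <- seq(10, 900, by = 10)
  rec <- synthetic_spike_record(list(tt, tt), T = 1000)
  out <- accumulate_and_decide(rec, list(A = 1, B = 2), threshold = 3)
  expect_false(out$crossed)
  expect_true(is.na(out$choice))
})

test_that("a silent competitor yields the gamma waiting time of the active population", {
  # population A Poisson at 100 Hz, B silent, threshold 7: the crossing is
  # the 7th event, i.e. gamma(7, 100 Hz) with mean 70 ms
  set.seed(41)
  n_rep <- 300
  times <- vapply(seq_len(n_rep), function(r) {
    spk <- cumsum(stats::rexp(40, rate = 100 / 1000))  # ms
    rec <- synthetic_spike_record(list(spk, numeric(0)), T = 2000)
    accumulate_and_decide(rec, list(A = 1, B = 2), 7)$decision_time
  }, numeric(1))
  se <- stats::sd(times) / sqrt(n_rep)     # theoretical sd ~ sqrt(7)/0.1
  expect_lt(abs(mean(times) - 70), 3 * se)
  expect_equal(stats::sd(times), sqrt(7) / 0.1, tolerance = 0.15)
})

test_that("sensory delay shifts accumulation onset and reported times", {
  spk <- c(5, 10, 15, 80, 90, 100)
  rec <- synthetic_spike_record(list(spk, numeric(0)), T = 200)
  out <- accumulate_and_decide(rec, list(A = 1, B = 2), 3, t_delta = 60)
  # the three early spikes are ignored; crossing at the third late spike
  expect_equal(out$decision_time, 100 - 60)
  expect_equal(out$choice, "A")
})

test_that("equal offers are chosen at chance within binomial error", {
  tr <- run_choice_experiment(cbind(1.5, 1.5), n_trials = 60, T = 1200,
                              seed = 17)
  p <- mean(tr$choice[tr$crossed] == "A")
  n <- sum(tr$crossed)
  expect_gt(n, 30)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / n))
})

test_that("psychometric choice sharpens and speeds up as offers separate", {
  offers <- rbind(c(2.5, 2.25), c(2.5, 0.25))
  tr <- run_choice_experiment(offers, n_trials = 40, T = 1200, seed = 19)
  hard <- tr[tr$pair == 1, ]; easy <- tr[tr$pair == 2, ]
  expect_gt(mean(easy$chose_better[easy$crossed]), 0.95)  # ratio -> 0 limit
  expect_gt(mean(easy$chose_better[easy$crossed]),
            mean(hard$chose_better[hard$crossed]) - 0.02)
  expect_lt(mean(easy$decision_time, na.rm = TRUE),
            mean(hard$decision_time, na.rm = TRUE))
})

test_that("raising the threshold increases both accuracy and decision time", {
  offers <- cbind(2.5, 1.75)
  lo <- run_choice_experiment(offers, n_trials = 80, threshold = 2,
                              T = 1200, seed = 23)
  hi <- run_choice_experiment(offers, n_trials = 80, threshold = 12,
                              T = 1200, seed = 23)
  expect_gt(mean(hi$chose_better[hi$crossed]),
            mean(lo$chose_better[lo$crossed]))
  expect_gt(mean(hi$decision_time, na.rm = TRUE),
            mean(lo$decision_time, na.rm = TRUE))
})

test_that("quantile normalization recovers logarithms for log-normal samples", {
  set.seed(3)
  times <- exp(stats::rnorm(4000, mean = 5, sd = 0.4))
  nrm <- normalize_decision_times(times)
  # transform applied to its own pool: standard normal moments
  expect_equal(mean(nrm$normalized), 0, tolerance = 1e-6)
  expect_equal(stats::sd(nrm$normalized), 1, tolerance = 0.01)
  # the recovered transform is logarithmic up to affine terms
  expect_gt(nrm$log_r2, 0.999)
  pred <- stats::predict(nrm$log_fit)
  expect_equal(cor(pred, nrm$normalized[is.finite(times)]), 1,
               tolerance = 1e-3)
})

test_that("chronometric regression slopes behave for degenerate and planted data", {
  # constant times give slope 0
  z <- rep(0, 100)
  ratios <- rep(seq(0.1, 1, by = 0.1), each = 10)
  reg0 <- chronometric_regression(z, ratios, n_boot = 20)
  expect_equal(reg0$slope, 0)
  # planted linear dependence is recovered
  set.seed(8)
  z2 <- 1.5 * ratios - 0.75 + stats::rnorm(100, sd = 0.05)
  reg <- chronometric_regression(z2, ratios, n_boot = 50)
  expect_equal(reg$slope, 1.5, tolerance = 0.1)
  expect_gt(reg$r2, 0.95)
})

test_that("chain reaction times scale the threshold as theta_0 * gamma^NRM", {
  m <- make_nrm_chain(4)
  rt <- sequential_reaction_times(m, c(0, 2), theta_0 = 70, n_trials = 20,
                                  T = 900, seed = 5)
  expect_equal(rt$threshold, 70 * 0.7^c(0, 2))
  expect_true(all(rt$n_crossed > 0))
  expect_true(all(rt$p_correct > 0.9))
  # harder (more distal) decisions are slower
  expect_gt(rt$mean_rt[rt$nrm == 2], rt$mean_rt[rt$nrm == 0])
})
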