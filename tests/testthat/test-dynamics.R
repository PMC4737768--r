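test_that("reward-input profiles have the stated shapes and stay non-negative", {
  const <- reward_input_constant(400)
  expect_equal(input_rate(const, c(0, 50)), c(400, 400))
  de <- reward_input_double_exp(70, t_r = 110, t_d = 300, t_delta = 60)
  tt <- seq(0, 1500, by = 0.5)
  r <- input_rate(de, tt)
  expect_true(all(r >= 0))
  expect_equal(r[tt < 60], rep(0, sum(tt < 60)))   # silent before the delay
  expect_equal(max(r), 70, tolerance = 1e-6)       # normalized peak
  rg <- reward_input_raised_gaussian(10, 75, t_p = 250, tau = 60)
  expect_equal(input_rate(rg, 250), 75)
  expect_equal(input_rate(rg, -1e6), 10, tolerance = 1e-9)
  expect_equal(input_rate(scale_input(rg, 10), 250), 750)
})

test_that("rate dynamics: zero weights and input stay silent; leak relaxes exponentially", {
  m <- make_binary_choice(1, 1)
  net <- build_discrete_network(m, eta = 0, tau_m = 25)
  net$W <- net$W * 0; net$w_r <- net$w_r * 0
  tr <- simulate_rate(net, reward_input_constant(0), T = 20, h = 0.05)
  expect_true(all(tr$rates == 0))
  # no recurrence, constant drive I: rate approaches k*(I - theta) with tau_m
  net2 <- build_discrete_network(m, eta = 0, tau_m = 25)
  net2$W <- net2$W * 0
  I <- net2$w_r[1] * 40  # drive of neuron 1 at 40 Hz input
  tr2 <- simulate_rate(net2, reward_input_constant(40), T = 200, h = 0.02,
                       record_dt = 1)
  lam_inf <- net2$k * max(I - net2$theta[1], 0)
  expect_equal(tr2$rates[nrow(tr2$rates), 1], lam_inf, tolerance = 1e-3)
  # time constant: at t = tau_m the gap to the asymptote is 1/e of the start
  at_tau <- tr2$rates[which.min(abs(tr2$times - 25)), 1]
  expect_equal((lam_inf - at_tau) / lam_inf, exp(-1), tolerance = 0.02)
})

test_that("rectification identity holds pointwise on recorded traces", {
  net <- build_discrete_network(make_two_step())
  tr <- simulate_rate(net, reward_input_constant(400), T = 30, h = 0.05)
  expect_true(all(tr$rates >= 0))
  expect_equal(tr$rates,
               net$k * pmax(tr$u - matrix(net$theta, nrow(tr$u),
                                          ncol(tr$u), byrow = TRUE), 0))
})

test_that("two-step rate dynamics settle to the optimal values within 10 ms", {
  m <- make_two_step()
  net <- build_discrete_network(m)
  tr <- simulate_rate(net, reward_input_constant(400), T = 60, h = 0.05,
                      record_dt = 0.1)
  V <- decode_value_trace(tr)
  vstar <- value_iteration(m)$values[colnames(V)]
  nz <- vstar > 0
  dev <- abs(sweep(V[, nz], 2, vstar[nz])) / matrix(vstar[nz], nrow(V),
                                                    sum(nz), byrow = TRUE)
  settle <- if (any(dev > 0.02)) max(tr$times[apply(dev > 0.02, 1, any)]) else 0
  expect_lte(settle, 10)
  expect_equal(as.numeric(V[nrow(V), ]), unname(vstar), tolerance = 1e-3)
})

test_that("halving the Euler step changes the rate solution at O(h)", {
  net <- build_discrete_network(make_two_step())
  at <- function(h) {
    tr <- simulate_rate(net, reward_input_constant(400), T = 5, h = h,
                        record_dt = 5)
    tr$rates[nrow(tr$rates), ]
  }
  d1 <- max(abs(at(0.2) - at(0.1)))
  d2 <- max(abs(at(0.1) - at(0.05)))
  expect_lt(d2, 0.7 * d1)  # consistent first-order convergence
})

test_that("spiking is silent below threshold and Poisson-like above it", {
  m <- make_binary_choice(1, 1)
  net <- build_discrete_network(m, eta = 0, tau_m = 25)
  # drive below threshold -> no spikes
  rec0 <- simulate_spiking(net, reward_input_constant(0), T = 100, seed = 1)
  expect_equal(nrow(rec0$spikes), 0)
  # single neuron under constant suprathreshold drive: empirical rate within
  # 3 standard errors of the closed-form k*(I - theta)
  net1 <- net
  net1$W <- net1$W * 0                      # no recurrence
  rate_in <- 60
  lam_true <- net1$k * net1$w_r[1] * rate_in
  rec <- simulate_spiking(net1, reward_input_constant(rate_in), T = 8000,
                          h = 0.1, seed = 5, n_runs = 8)
  counts <- spike_counts(rec)[1, ]
  est <- mean(counts) / 8                   # Hz over 8 s
  se <- stats::sd(counts / 8) / sqrt(length(counts))
  expect_lt(abs(est - lam_true), 3 * se + 1)
})

test_that("trial-averaged spiking agrees with the mean-field rate trace", {
  m <- make_two_step()
  net <- build_discrete_network(m)
  inp <- reward_input_constant(400)
  rate <- simulate_rate(net, inp, T = 150, h = 0.05, record_dt = 1)
  rec <- simulate_spiking(net, inp, T = 150, h = 0.1, seed = 11, n_runs = 30)
  counts <- spike_counts(rec, t_end = 150, t_start = 50)  # steady-state window
  emp <- rowMeans(counts) / 0.1                            # Hz
  mf <- colMeans(rate$rates[rate$times > 50, ])
  active <- mf > 50
  expect_lt(max(abs(emp[active] - mf[active]) / mf[active]), 0.15)
})

test_that("initial conditions with equal decoded values converge to the same values", {
  # two different rate patterns whose per-state sums (hence decoded values)
  # coincide: all neurons at 200 Hz vs action-split 0/150/450 Hz
  m <- make_random_mdp(6, 3, discount = 0.9, seed = 15)
  net <- build_discrete_network(m)
  init1 <- rep(200, net$n_neurons)
  split3 <- c(0, 150, 450)
  init2 <- split3[match(net$coding$action, unique(net$coding$action))]
  v0_1 <- decode_values(init1, net$coding, net$lambda_r, net$V0,
                        states = net$states)
  v0_2 <- decode_values(init2, net$coding, net$lambda_r, net$V0,
                        states = net$states)
  expect_equal(v0_1, v0_2)   # identical represented values at t = 0
  tr1 <- simulate_rate(net, reward_input_constant(400), T = 400, h = 0.05,
                       init_rates = init1, record_dt = 2)
  tr2 <- simulate_rate(net, reward_input_constant(400), T = 400, h = 0.05,
                       init_rates = init2, record_dt = 2)
  V1 <- decode_values(tr1$rates, net$coding, net$lambda_r, net$V0,
                      states = net$states)
  V2 <- decode_values(tr2$rates, net$coding, net$lambda_r, net$V0,
                      states = net$states)
  # same asymptotic decoded values ...
  expect_equal(V1[nrow(V1), ], V2[nrow(V2), ], tolerance = 1e-4)
  # ... though the interim value trajectories differ
  mid <- which.min(abs(tr1$times - 6))
  expect_gt(max(abs(V1[mid, ] - V2[mid, ])), 0.01)
})

test_that("smoothed rates conserve spike counts and recover regular-train plateaus", {
  # empty record -> identically zero trace
  rec0 <- synthetic_spike_record(list(numeric(0), numeric(0)), T = 500)
  sm0 <- smooth_rates(rec0)
  expect_true(all(sm0$rates == 0))
  # kernel normalization: integral of the smoothed rate ~ spike count
  rec1 <- synthetic_spike_record(list(seq(200, 300, by = 2)), T = 1000)
  sm1 <- smooth_rates(rec1, kernel_sigma = 40, dt = 1)
  integral <- sum(sm1$rates) * 1e-3  # Hz * s
  expect_equal(integral, 51, tolerance = 0.5)
  # regular 100 Hz train -> plateau estimate 100 +/- 1 Hz away from the edges
  rec2 <- synthetic_spike_record(list(seq(10, 990, by = 10)), T = 1000)
  sm2 <- smooth_rates(rec2, kernel_sigma = 40, dt = 1)
  mid <- sm2$times > 300 & sm2$times < 700
  expect_true(all(abs(sm2$rates[mid, 1] - 100) < 1))
  # exponential-moving-average mode stays close to the plateau too
  sm3 <- smooth_rates(rec2, kernel_sigma = 40, dt = 1, mode = "ema")
  expect_equal(mean(sm3$rates[mid, 1]), 100, tolerance = 5)
})

test_that("spike records and rate traces export as plain text", {
  rec <- synthetic_spike_record(list(c(1.5, 20), c(7)), T = 100)
  p1 <- withr::local_tempfile(fileext = ".txt")
  write_spikes(rec, p1)
  df <- utils::read.table(p1, header = TRUE)
  expect_equal(nrow(df), 3)
  expect_equal(sort(names(df)), c("neuron", "time"))
  net <- build_discrete_network(make_binary_choice(1, 2), eta = 0, tau_m = 25)
  tr <- simulate_rate(net, reward_input_constant(10), T = 10, record_dt = 1)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_rates(tr, p2)
  df2 <- utils::read.table(p2, header = TRUE)
  expect_equal(ncol(df2), 1 + net$n_neurons)
})
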