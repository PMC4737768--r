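test_that("repeated deterministic transitions follow the closed-form delta trajectory", {
  m <- tiny_mdp()
  net <- init_learning_network(m, eta = 20)
  alpha <- 0.2
  j_target <- which(net$coding$state == "b")  # successors of (a, x) ... partly
  sample1 <- list(state = "a", action = "y", reward = 0, next_state = "a")
  for (n in 1:8) {
    net <- delta_update_discrete(net, sample1, alpha)
    i <- which(net$coding$state == "a" & net$coding$action == "y")
    expected <- net$c * m$discount * (1 - (1 - alpha)^n)
    expect_equal(net$W_exc[i, which(net$coding$state == "a")],
                 rep(expected, 2), tolerance = 1e-12)
  }
})

test_that("stochastic transitions converge to c*gamma*P in expectation", {
  m <- make_two_step()
  net <- init_learning_network(m, eta = 20)
  i <- which(net$coding$state == "0" & net$coding$action == "R")
  j <- which(net$coding$state == "2")[1]
  alpha <- 0.05
  set.seed(31)
  n_upd <- 2000
  w_trace <- numeric(n_upd)
  for (t in seq_len(n_upd)) {
    s2 <- sample(c("2", "3"), 1)  # the coin-flip door
    net <- delta_update_discrete(net, list(state = "0", action = "R",
                                           reward = 0, next_state = s2),
                                 alpha)
    w_trace[t] <- net$W_exc[i, j]
  }
  expected <- net$c * 0.5  # c * gamma * P(door) with gamma = 1, P = 1/2
  # stationary AR(1): sd = target * sqrt(alpha / (2 - alpha)), autocorrelation
  # time 1/alpha; the burn-in is discarded
  w_ss <- w_trace[-(1:200)]
  sd_ss <- expected * sqrt(alpha / (2 - alpha))
  se <- sd_ss * sqrt(2 / alpha / length(w_ss))
  expect_lt(abs(mean(w_ss) - expected), 4 * se)
})

test_that("stochastic rewards drive the reward synapse to c*E[r]", {
  m <- make_binary_choice(1, 1)
  net <- init_learning_network(m, eta = 0)
  alpha <- 0.02
  set.seed(12)
  for (t in 1:10000) {
    r <- stats::rbinom(1, 1, 0.75)
    net <- delta_update_discrete(net, list(state = "offer", action = "A",
                                           reward = r, next_state = "T"),
                                 alpha)
  }
  i <- which(net$coding$state == "offer" & net$coding$action == "A")
  # asymptotic mean c * 0.75, sd ~ c * sqrt(alpha/2) * sd(r)
  expect_lt(abs(net$w_r[i] - net$c * 0.75), 3 * net$c * sqrt(alpha / 2) * 0.43 + 0.02)
})

test_that("postsynaptic gating leaves all other synapses bitwise unchanged", {
  m <- make_two_step()
  net <- build_discrete_network(m)
  before <- as.matrix(net$W_exc)
  wr_before <- net$w_r
  i <- which(net$coding$state == "2" & net$coding$action == "L")
  # a surprising transition/reward so the gated row genuinely moves
  net2 <- delta_update_discrete(net, list(state = "2", action = "L",
                                          reward = 0.25, next_state = "3"), 0.3)
  after <- as.matrix(net2$W_exc)
  expect_identical(after[-i, ], before[-i, ])
  expect_identical(net2$w_r[-i], wr_before[-i])
  expect_false(identical(after[i, ], before[i, ]))
  # inhibitory weights are never updated
  expect_identical(as.matrix(net2$W_inh), as.matrix(net$W_inh))
})

test_that("the FA rule with indicator bases equals the discrete rule exactly", {
  m <- tiny_mdp()
  b <- indicator_basis(m)
  net_a <- init_learning_network(m, eta = 20)
  net_b <- net_a
  smp <- list(state = "a", action = "x", reward = 0.6, next_state = "b")
  for (rep in 1:5) {
    net_a <- delta_update_discrete(net_a, smp, 0.13)
    net_b <- delta_update_fa(net_b, b, smp, 0.13)
  }
  expect_identical(as.matrix(net_a$W_exc), as.matrix(net_b$W_exc))
  expect_identical(net_a$w_r, net_b$w_r)
})

test_that("FA updates vanish in expectation at the batch target weights", {
  task <- pendulum_task()
  b <- make_basis_grid(list(c(-pi, pi), c(-2 * pi, 2 * pi)), pi,
                       actions = as.character(task$torques),
                       periodic = c(TRUE, FALSE))
  net <- build_fa_network(task, b, n_mc = 2^14, method = "lattice")
  set.seed(6)
  n_s <- 3000
  S <- cbind(stats::runif(n_s, -pi, pi), stats::runif(n_s, -2 * pi, 2 * pi))
  upd <- matrix(0, net$n_neurons, net$n_neurons)
  alpha <- 1
  for (kk in seq_len(n_s)) {
    for (a in seq_along(task$torques)) {
      s2 <- pendulum_step(task, S[kk, ], task$torques[a])
      g_s <- as.numeric(basis_cells_eval(b, matrix(S[kk, ], 1)))
      g_s2 <- as.numeric(basis_cells_eval(b, matrix(s2, 1)))
      psi <- g_s[b$cell] * (b$action == as.character(task$torques[a]))
      gbar <- g_s2[b$cell]
      upd <- upd + alpha * psi *
        (outer(rep(1, net$n_neurons),
               net$c * net$gamma * b$mass * gbar) - net$W_exc)
    }
  }
  mean_upd <- upd / (n_s * 3)
  # expected update ~ 0 at the targets, relative to the weight scale
  expect_lt(max(abs(mean_upd)) / max(abs(net$W_exc)), 0.1)
})

test_that("FA learning decreases the distance to the target weights", {
  task <- pendulum_task()
  b <- make_basis_grid(list(c(-pi, pi), c(-2 * pi, 2 * pi)), pi,
                       actions = as.character(task$torques),
                       periodic = c(TRUE, FALSE))
  targets <- build_fa_network(task, b, n_mc = 2^14, method = "lattice")
  net <- targets
  net$W_exc <- net$W_exc * 0
  net$w_r <- net$w_r * 0
  net$W <- net$W_fixed
  err0 <- sqrt(mean((net$W_exc - targets$W_exc)^2))
  set.seed(9)
  errs <- numeric(4)
  for (ep in 1:4) {
    for (kk in 1:150) {
      s <- c(stats::runif(1, -pi, pi), stats::runif(1, -2 * pi, 2 * pi))
      a <- sample(task$torques, 1)
      s2 <- pendulum_step(task, s, a)
      net <- delta_update_fa(net, b, list(state = s,
                                          action = as.character(a),
                                          reward = pendulum_reward(s2),
                                          next_state = s2), 0.05)
    }
    errs[ep] <- sqrt(mean((net$W_exc - targets$W_exc)^2))
  }
  expect_lt(errs[1], err0)
  expect_lt(errs[4], errs[1])
  expect_lt(errs[4], 0.5 * err0)
})

test_that("parallel sampling recovers the true weights and lifts performance", {
  m <- make_random_mdp(8, 2, discount = 0.9, seed = 44)
  alpha <- 0.05
  res <- parallel_sampling_train(m, alpha, n_trials = 150, seed = 2,
                                 eval_every = 50)
  tg <- res$targets
  rms <- sqrt(mean((as.matrix(res$network$W_exc) - as.matrix(tg$W_exc))^2))
  scale <- sqrt(mean(as.matrix(tg$W_exc)^2))
  # O(sqrt(alpha)) noise floor around the targets
  expect_lt(rms, 3 * sqrt(alpha) * scale)
  expect_gt(utils::tail(res$curve$performance, 1), 0.9)
  # zero learning rate: flat curve at the initial performance
  res0 <- parallel_sampling_train(m, alpha = 0, n_trials = 3, seed = 2)
  expect_equal(diff(range(res0$curve$performance)), 0)
})
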