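test_that("compiled weights encode transitions in reverse, inhibition within states", {
  m <- make_two_step()
  net <- build_discrete_network(m)  # k = 1, eta = 20
  cc <- 1 / 1 + 20
  expect_equal(net$c, cc)
  # gamma = 1: thresholds vanish
  expect_true(all(net$theta == 0))
  # neuron (root, R) receives c * gamma * 0.5 from each neuron of states 2, 3
  i <- which(net$coding$state == "0" & net$coding$action == "R")
  from23 <- which(net$coding$state %in% c("2", "3"))
  expect_equal(as.numeric(net$W_exc[i, from23]), rep(cc * 0.5, 4))
  # and nothing from state 1
  from1 <- which(net$coding$state == "1")
  expect_equal(as.numeric(net$W_exc[i, from1]), c(0, 0))
  # deterministic transition: (root, L) gets c * gamma to both state-1 neurons
  iL <- which(net$coding$state == "0" & net$coding$action == "L")
  expect_equal(as.numeric(net$W_exc[iL, from1]), rep(cc, 2))
  # lateral inhibition -c between distinct same-state neurons, none to self
  expect_equal(as.numeric(net$W_inh[i, iL]), -cc)
  expect_equal(as.numeric(net$W_inh[i, i]), 0)
  expect_true(all(as.matrix(net$W_inh) <= 0))
  expect_true(all(as.matrix(net$W_exc) >= 0))
  # reward-input weights c * rbar (terminal states carry no neurons)
  expect_equal(net$w_r, cc * m$r[m$sa$state != "T"])
  expect_false("T" %in% net$coding$state)
  expect_error(build_discrete_network(m, k = 0), "positive")
})

test_that("thresholds carry the scaled baseline value for discounted tasks", {
  m <- make_nrm_chain(4, discount = 0.7)
  net <- build_discrete_network(m, lambda_r = 400, V0 = 0.5)
  expect_equal(net$theta,
               rep(-400 * net$c * 0.5 * (1 - 0.7), net$n_neurons))
})

test_that("rate-model steady state decodes to value-iteration values (fixed-point oracle)", {
  # the binding contract on a batch of random discrete MDPs
  set.seed(1)
  for (i in 1:6) {
    g <- c(0.7, 0.9, 0.98)[(i - 1) %% 3 + 1]
    m <- make_random_mdp(sample(3:20, 1), sample(2:4, 1), discount = g,
                         seed = 100 + i)
    vv <- value_iteration(m)$values
    net <- build_discrete_network(m)
    ss <- steady_state_rates(net, h = 0.2, max_T = 20000, tol = 1e-4, polish = TRUE)
    expect_true(ss$converged)
    d <- decode_values(ss$rates, net$coding, net$lambda_r, net$V0,
                       states = net$states)
    expect_lt(max(abs(d - vv)), 1e-6)
  }
})

test_that("steady state satisfies the inactive-neuron inequality and the sum rule", {
  m <- make_random_mdp(10, 3, discount = 0.9, seed = 77)
  vi <- value_iteration(m)
  net <- build_discrete_network(m)
  ss <- steady_state_rates(net, h = 0.2, max_T = 60000)
  lam <- ss$rates
  vt <- decode_values(lam, net$coding, net$lambda_r, net$V0,
                      states = net$states)
  q <- m$r + m$discount * as.numeric(m$P %*% vt)
  v_of_neuron <- vt[net$coding$state]
  active <- lam > 1e-6
  # Vtilde(s_i) >= Qtilde(s_i, a_i), equality for active neurons
  expect_true(all(v_of_neuron - q >= -1e-6))
  expect_lt(max(abs((v_of_neuron - q)[active])), 1e-6)
  # sum rule: per-state rates sum to lambda_r * (V* + V0)
  sums <- tapply(lam, factor(net$coding$state, levels = net$states), sum)
  expect_equal(as.numeric(sums),
               as.numeric(net$lambda_r * (vi$values + net$V0)),
               tolerance = 1e-6)
})

test_that("indicator bases reduce the FA compiler to the discrete one", {
  m <- tiny_mdp(discount = 0.9)
  net_d <- build_discrete_network(m, k = 1, eta = 20, V0 = 0.3)
  net_fa <- build_fa_network(m, indicator_basis(m), k = 1, eta = 20,
                             V0 = 0.3)
  expect_lt(max(abs(as.matrix(net_fa$W) - as.matrix(net_d$W))), 1e-10)
  expect_lt(max(abs(net_fa$w_r - net_d$w_r)), 1e-10)
  expect_lt(max(abs(net_fa$theta - net_d$theta)), 1e-10)
})

test_that("FA weight integrals concentrate with more Monte-Carlo samples", {
  task <- pendulum_task()
  b <- make_basis_grid(list(c(-pi, pi), c(-2 * pi, 2 * pi)), pi / 2,
                       actions = as.character(task$torques),
                       periodic = c(TRUE, FALSE))
  w_at <- function(n_mc, seed) {
    net <- build_fa_network(task, b, n_mc = n_mc, seed = seed)
    net$W_exc[1, 2]
  }
  sd_small <- stats::sd(vapply(1:8, function(s) w_at(500, s), numeric(1)))
  sd_large <- stats::sd(vapply(1:8, function(s) w_at(2000, s), numeric(1)))
  # quadrupling the samples should halve the standard error
  expect_lt(sd_large, sd_small / 1.4)
})

test_that("feedforward ablation removes exactly the lateral inhibition", {
  m <- make_binary_choice(2, 1)
  net <- build_discrete_network(m, eta = 0, tau_m = 25)
  ff <- remove_lateral_inhibition(net)
  expect_equal(as.matrix(ff$W), as.matrix(net$W_exc))
  expect_true(all(as.matrix(ff$W_inh) == 0))
  expect_equal(ff$w_r, net$w_r)
})

test_that("network serialization writes a readable structured-text file", {
  net <- build_discrete_network(make_two_step())
  path <- withr::local_tempfile(fileext = ".json")
  write_network(net, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$n_neurons, net$n_neurons)
  expect_equal(obj$constants$eta, 20)
  W2 <- Matrix::sparseMatrix(i = obj$weights$i, j = obj$weights$j,
                             x = obj$weights$x,
                             dims = c(net$n_neurons, net$n_neurons))
  expect_lt(max(abs(as.matrix(W2) - as.matrix(net$W))), 1e-12)
})
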