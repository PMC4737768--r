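test_that("two-step door task reproduces its printed returns", {
  m <- make_two_step()
  vi <- value_iteration(m)
  expect_equal(unname(vi$values["0"]), 1)                 # closed loop
  expect_equal(best_open_loop(m, 2)$value, 0.75)          # best open loop
  expect_equal(best_open_loop(m, 2, first_action = "R")$value, 0.5)
  expect_equal(transition_of(m, "0", "R"), c(`2` = 0.5, `3` = 0.5))
  # both actions in state 1 have the same optimal value
  q <- vi$q[m$sa$state == "1"]
  expect_equal(q[1], q[2])
  # both second actions after first-L yield 3/4
  expect_equal(unname(vi$values["1"]), 0.75)
})

test_that("every task generator yields a valid MDP that terminates where required", {
  tasks <- list(make_two_step(), make_blackjack(), make_flag_maze(),
                make_binary_choice(2.2, 1), make_nrm_chain(5),
                make_multireward_chain(6, 3), make_devaluation_maze())
  for (m in tasks) {
    expect_s3_class(m, "mdp")
    expect_true(all(abs(Matrix::rowSums(m$P) - 1) < 1e-12))
    expect_true(all(lengths(sapply(m$states, actions_of, m = m)) >= 1))
  }
  # episodic (gamma = 1) tasks reach the absorbing state with probability 1:
  # under the uniform policy the expected occupancy of non-terminal states is
  # finite, which the policy-evaluation solve of an all-ones reward detects.
  for (m in list(make_two_step(), make_blackjack())) {
    m1 <- m; m1$r <- rep(1, length(m1$r))
    m1$r[m1$sa$state %in% m1$terminal] <- 0
    occ <- policy_evaluation(m1, uniform_policy(m1))
    expect_true(all(is.finite(occ)))
  }
})

test_that("blackjack rewards, deck model, and hand bookkeeping are correct", {
  m <- make_blackjack()
  # rewards 0 loss / 0.5 draw / 1 win: standing on 21 vs dealer 10 pays
  # P(win) + 0.5 P(draw) computed from the dealer model; bounded by (0, 1]
  r21 <- reward_of(m, "p21_d10_h", "stop")
  expect_gt(r21, 0.8)
  expect_lte(r21, 1)
  # drawing never pays immediately
  expect_true(all(m$r[m$sa$action == "draw"] == 0))
  # the deck model: enumerate the 13 ranks directly
  p_card <- c(rep(1/13, 9), 4/13)  # values 1..9, 10
  p <- transition_of(m, "p12_d5_h", "draw")
  expect_equal(unname(p["end"]), 4/13)            # only a ten busts hard 12
  expect_equal(unname(p["p13_d5_h"]), 1/13)
  # usable-ace hand: drawing an ace on soft 12 gives soft 13
  p2 <- transition_of(m, "p12_d5_u", "draw")
  expect_equal(unname(p2["p13_d5_u"]), 1/13)
  # hitting on 21 is allowed (mistakenly), and a soft 21 can survive a draw
  expect_true("draw" %in% actions_of(m, "p21_d5_u"))
  p3 <- transition_of(m, "p21_d5_u", "draw")
  expect_false("end" %in% names(p3))   # soft 21 never busts on one card
  # all non-terminal states have hand values <= 21
  sums <- as.integer(sub("^p(\\d+)_.*", "\\1", setdiff(m$states, "end")))
  expect_true(all(sums >= 12 & sums <= 21))
})

test_that("flag maze slips perpendicular, counts flag states, and pays collected flags", {
  lay <- default_maze()
  m <- make_flag_maze(lay)
  # state count: open non-goal cells x 2^3 masks + terminal
  n_open <- sum(!lay$walls) - 1
  expect_equal(length(m$states), n_open * 8 + 1)
  # slip probability splits evenly between the two perpendicular directions
  s0 <- names(m$start)
  p <- transition_of(m, s0, "D")
  expect_true(all(abs(Matrix::rowSums(m$P) - 1) < 1e-12))
  # moving down from the corner: perpendicular slips are L (wall, stay) and R
  expect_equal(sum(p), 1)
  expect_true(any(abs(p - 0.9) < 1e-12))   # intended direction
  expect_true(any(abs(p - 0.05) < 1e-12))  # one perpendicular slip each
  # goal reward equals the number of flags collected: with all flags set,
  # stepping into the goal pays 3
  vi <- value_iteration(m)
  goal_rows <- which(m$sa$state != "done" &
                       sapply(seq_len(nrow(m$sa)), function(k)
                         m$P[k, "done"] > 0))
  full_mask <- grepl("_m7$", m$sa$state[goal_rows])
  r_goal <- m$r[goal_rows][full_mask]
  expect_true(all(abs(r_goal / m$P[goal_rows, "done"][full_mask] - 3) < 1e-9))
  # the optimal policy collects all three flags
  expect_gt(unname(vi$values[s0]), 0.9 * 3 * m$discount^30)
})

test_that("binary-choice task has max-offer optimum and offered rewards", {
  m <- make_binary_choice(2.2, 1)
  expect_equal(unname(value_iteration(m)$values["offer"]), 2.2)
  expect_equal(reward_of(m, "offer", "A"), 2.2)  # 1A = 2.2B in B units
  expect_equal(reward_of(m, "offer", "B"), 1)
  m_eq <- make_binary_choice(1.5, 1.5)
  q <- value_iteration(m_eq)$q
  expect_equal(q[1], q[2])  # both actions optimal under equal offers
})

test_that("movement chain values follow the gamma^NRM closed form", {
  m <- make_nrm_chain(6, n_actions = 3, discount = 0.7)
  v <- value_iteration(m)$values
  for (k in 0:5)
    expect_equal(unname(v[sprintf("n%d", k)]), 0.7^k, tolerance = 1e-9)
  # incorrect actions are worthless everywhere
  q <- value_iteration(m)$q
  expect_true(all(q[m$sa$action != "go" & !(m$sa$state %in% m$terminal)] == 0))
})

test_that("multireward chain blocks double harvesting and is value-nonmonotone", {
  # with r_mid = 0 the chain reduces to the single-reward one
  m0 <- make_multireward_chain(6, 3, r_mid = 0)
  expect_equal(value_iteration(m0)$values[sprintf("n%d", 5:0)],
               value_iteration(make_nrm_chain(6))$values[sprintf("n%d", 5:0)],
               tolerance = 1e-9)
  # brute force over deterministic policies: no policy beats
  # r_mid * gamma^(n - 1 - at) + gamma^(n - 1) from the start state
  m <- make_multireward_chain(5, 2, r_mid = 1)
  bf <- brute_force_optimal(m)
  g <- m$discount
  bound <- 1 * g^(5 - 1 - 2) + g^(5 - 1)
  expect_lt(bf[["n4"]], bound + 1e-9)
  # value just before the intermediate reward exceeds the value just after
  v <- value_iteration(make_multireward_chain(8, 4, r_mid = 1))$values
  expect_gt(v[["n4"]], v[["n3"]])
  expect_gt(v[["n4"]], v[["n0"]])  # non-monotone in NRM
})

test_that("devaluation maze flips the root choice when cheese is devalued", {
  m_base <- make_devaluation_maze()
  vi_base <- value_iteration(m_base)
  expect_equal(names(which.max(vi_base$policy[["0"]])), "L")
  expect_equal(unname(vi_base$values["0"]), 4)
  m_dev <- make_devaluation_maze(devalued = TRUE)
  expect_equal(reward_of(m_dev, "1", "L"), 2)   # cheese 4 -> 2
  vi_dev <- value_iteration(m_dev)
  expect_equal(names(which.max(vi_dev$policy[["0"]])), "R")
  expect_equal(unname(vi_dev$values["0"]), 3)
})

test_that("maze layouts parse from ASCII and reject malformed maps", {
  lay <- maze_layout(c("S.G", "F.."))
  expect_equal(lay$n_rows, 2)
  expect_equal(nrow(lay$flags), 1)
  expect_error(maze_layout(c("S.G", "..")), "equal width")
  expect_error(maze_layout(c("..G", "F..")), "start")
  expect_error(maze_layout(c("SQG", "F..")), "invalid")
})
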