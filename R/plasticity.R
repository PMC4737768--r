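#' Postsynaptically gated delta-rule update from one sampled transition
#'
#' If action `a` performed in state `s` yields reward `r` and leads to `s'`,
#' only the synapses onto the postsynaptic neuron coding `(s, a)` change:
#' every excitatory weight from presynaptic neuron `j` moves toward
#' `c * gamma * 1[s_j = s']` (so in expectation it converges to
#' `c * gamma * P(s_j | s, a)`), and the reward synapse moves toward `c * r`
#' (the external input fires at `rho = r + r_0`; the offset `r_0` keeps the
#' rate non-negative and cancels from the target). Inhibitory weights do not
#' depend on the environment and are never updated.
#'
#' @param network a discrete `spiking_network`.
#' @param sample list with `state`, `action`, `reward`, `next_state`.
#' @param alpha learning rate in `(0, 1]`.
#' @return the updated network.
#' @export
delta_update_discrete <- function(network, sample, alpha) {
  stopifnot(alpha > 0, alpha <= 1)
  i <- which(network$coding$state == sample$state &
             network$coding$action == sample$action)
  if (length(i) != 1)
    stop("unknown state-action pair (", sample$state, ", ", sample$action, ")")
  target <- network$c * network$gamma *
    as.numeric(network$coding$state == sample$next_state)
  W_exc <- network$W_exc
  W_exc[i, ] <- W_exc[i, ] + alpha * (target - W_exc[i, ])
  network$W_exc <- W_exc
  network$W <- W_exc + network$W_inh
  network$w_r[i] <- network$w_r[i] +
    alpha * (network$c * sample$reward - network$w_r[i])
  network
}

#' Stochastic-gradient weight update for basis-function networks
#'
#' Per-sample step toward the batch targets of [build_fa_network()], gated by
#' the postsynaptic basis activation:
#' `dw_ij = alpha * psi_i(s, a) * (c * gamma * m_i * gbar_j(s') - w_ij)` for
#' the excitatory part and
#' `dw_r_i = alpha * psi_i(s, a) * (c * m_i * r - w_r_i)` for the reward
#' synapse, with basis mass `m_i`. Under uniform parallel sampling the
#' expected update vanishes exactly at the batch target weights, and with
#' indicator bases the rule reduces to [delta_update_discrete()].
#'
#' @param network an `"fa"` `spiking_network` (or the indicator-basis
#'   reduction of a discrete one).
#' @param basis the network's `basis_set`.
#' @param sample list with `state` (numeric state vector, or state id for
#'   indicator bases), `action` (label in `basis$actions`), `reward`,
#'   `next_state`.
#' @param alpha learning rate.
#' @return the updated network (the excitatory part is tracked in `W_exc`;
#'   the effective `W` keeps the fixed inhibitory/diagonal part).
#' @export
delta_update_fa <- function(network, basis, sample, alpha) {
  stopifnot(alpha > 0, alpha <= 1)
  a_idx <- match(sample$action, basis$actions)
  if (is.na(a_idx)) stop("unknown action ", sample$action)
  g_s <- as.numeric(basis_cells_eval(basis, rbind_state(sample$state)))
  g_s2 <- as.numeric(basis_cells_eval(basis, rbind_state(sample$next_state)))
  # psi_i(s, a) = g_{cell(i)}(s) 1[a_i = a]; gbar_j(s') = g_{cell(j)}(s').
  psi <- g_s[basis$cell] * (basis$action == sample$action)
  gbar <- g_s2[basis$cell]

  fixed <- network$W_fixed
  if (is.null(fixed)) fixed <- network$W_inh
  gate <- alpha * psi
  target <- network$c * network$gamma * basis$mass * gbar
  W_exc <- as.matrix(network$W_exc)
  W_exc <- W_exc + gate * (matrix(target, network$n_neurons,
                                  network$n_neurons, byrow = TRUE) - W_exc)
  network$W_exc <- W_exc
  network$w_r <- network$w_r + gate * (network$c * basis$mass * sample$reward -
                                       network$w_r)
  network$W <- W_exc + fixed
  network
}

rbind_state <- function(s) {
  if (is.character(s)) s else matrix(s, nrow = 1)
}

#' Initialize a network for learning (weights unknown)
#'
#' Builds the network scaffold for a task with the environment-independent
#' parts in place (lateral inhibition, thresholds, constants) but zero
#' excitatory and reward weights, ready for the delta-rule updates.
#'
#' @param m an `mdp` (discrete case) -- used only for its state-action coding
#'   and discount, not its transition/reward content.
#' @inheritParams build_discrete_network
#' @return a `spiking_network` with `W_exc = 0`, `w_r = 0`.
#' @export
init_learning_network <- function(m, k = 1, eta = 20, lambda_r = 400,
                                  V0 = 0, tau_m = 20, tau_s = 2) {
  net <- build_discrete_network(m, k, eta, lambda_r, V0 = V0,
                                tau_m = tau_m, tau_s = tau_s)
  net$W_exc <- net$W_exc * 0
  net$w_r <- net$w_r * 0
  net$W <- net$W_exc + net$W_inh
  net
}

#' Model learning by parallel sampling
#'
#' Simplified exploration: in every trial, each state-action pair of the task
#' is experienced once with one sampled successor (discrete case), and the
#' delta rule is applied to all of them. After each trial the network
#' dynamics are run to steady state (1 s is ample) and the decoded policy is
#' scored with [normalized_performance()].
#'
#' @param m the true environment (`mdp`).
#' @param alpha learning rate (0.01 for blackjack, 0.05 for maze in the
#'   reference settings).
#' @param n_trials number of parallel-sampling trials.
#' @param k,eta,lambda_r,V0,tau_m,tau_s network constants.
#' @param seed RNG seed.
#' @param eval_every record performance every this many trials (default 1).
#' @return list with `network` (learned), `curve` (data.frame
#'   `trial`, `performance`), and `targets` (the true-weight network for
#'   comparison).
#' @export
parallel_sampling_train <- function(m, alpha, n_trials, k = 1, eta = 20,
                                    lambda_r = 400, V0 = 0, tau_m = 20,
                                    tau_s = 2, seed = 1, eval_every = 1) {
  set.seed(seed)
  net <- init_learning_network(m, k, eta, lambda_r, V0, tau_m, tau_s)
  targets <- build_discrete_network(m, k, eta, lambda_r, V0 = V0,
                                    tau_m = tau_m, tau_s = tau_s)
  n <- net$n_neurons
  # Indicator of neuron state, used to vectorize the whole-trial update.
  state_of <- net$coding$state
  keep <- !(m$sa$state %in% m$terminal)   # rows the network represents
  P <- m$P[keep, , drop = FALSE]
  r_keep <- m$r[keep]
  cg <- net$c * net$gamma
  curve <- list()
  for (trial in seq_len(n_trials)) {
    # One sampled successor per state-action pair.
    succ <- apply(P, 1, function(p) sample.int(length(p), 1, prob = p))
    succ_state <- m$states[succ]
    if (alpha > 0) {
      Tgt <- cg * outer(succ_state, state_of, "==")
      net$W_exc <- (1 - alpha) * net$W_exc + alpha * Tgt
      net$w_r <- (1 - alpha) * net$w_r + alpha * net$c * r_keep
      net$W <- net$W_exc + net$W_inh
    }
    if (trial %% eval_every == 0 || trial == n_trials) {
      ss <- steady_state_rates(net, max_T = 1000, tol = 1e-6)
      pol <- extract_policy(ss$rates, net$coding)
      perf <- normalized_performance(m, pol)
      curve[[length(curve) + 1]] <- data.frame(trial = trial,
                                               performance = perf)
    }
  }
  list(network = net, curve = do.call(rbind, curve), targets = targets)
}
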