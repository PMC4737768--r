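#' Compile a finite MDP into a recurrent spiking network
#'
#' One neuron codes for each state-action pair (`cell i` codes `(s_i, a_i)`).
#' With the gain constant `c = 1/k + eta`, the weights are
#' * excitatory, reverse-directed: the weight from any presynaptic neuron `j`
#'   (coding state `s_j`, any action) onto neuron `i` is
#'   `w_exc_ij = c * gamma * P(s_j | s_i, a_i)`;
#' * inhibitory, within a state: `w_inh_ij = -c` between distinct neurons
#'   with `s_i = s_j`;
#' * reward-input: `w_r_i = c * rbar(s_i, a_i)`, driven by a Poisson unit of
#'   rate `lambda_r`;
#' * threshold: `theta = -lambda_r * c * V0 * (1 - gamma)`, identical across
#'   neurons.
#'
#' At the steady state of the mean-field rate dynamics the per-state summed
#' rates satisfy `sum_i lambda_i = lambda_r * (V*(s) + V0)`, i.e. the network
#' activity encodes the Bellman-optimal values.
#'
#' @param m an `mdp` object.
#' @param k gain of the rectified-linear rate function (Hz/mV, > 0).
#' @param eta afterhyperpolarization magnitude (mV, >= 0).
#' @param lambda_r nominal reward-input rate (Hz).
#' @param V0 value baseline; rates represent `V + V0`, so `V0` must exceed
#'   `-min V*`. `NULL` (default) picks 0 when `min V* > 0` holds, otherwise
#'   `-min V* + 0.1 * range(V*)`.
#' @param tau_m,tau_s membrane and synaptic time constants (ms, `tau_s <
#'   tau_m`).
#' Terminal (absorbing, zero-reward) states are not represented by neurons:
#' their value is identically 0 and giving them units would add a neutral
#' self-excitation mode at `gamma = 1` that never relaxes. When `V0 > 0`
#' (discounted tasks with negative values) the baseline contribution a
#' terminal successor would have carried is folded into the reward weight,
#' `w_r_i = c * (rbar + gamma * P(terminal | s_i, a_i) * V0)`, keeping the
#' fixed point exact.
#'
#' @return an object of class `spiking_network` with the effective weight
#'   matrix `W` (= `W_exc + W_inh`), its parts, reward weights `w_r`,
#'   thresholds `theta`, neuron coding table `coding` (non-terminal
#'   state-action pairs), and all constants.
#' @export
build_discrete_network <- function(m, k = 1, eta = 20, lambda_r = 400,
                                   V0 = NULL, tau_m = 20, tau_s = 2) {
  if (k <= 0) stop("gain k must be positive")
  if (eta < 0) stop("eta must be non-negative")
  if (tau_s >= tau_m) stop("tau_s must be smaller than tau_m")
  cc <- 1 / k + eta
  n <- nrow(m$sa)
  gamma <- m$discount

  if (is.null(V0)) {
    v <- value_iteration(m)$values
    # With gamma = 1 the threshold -lambda_r*c*V0*(1-gamma) vanishes, so no
    # nonzero baseline can be realized; episodic tasks here have V* >= 0.
    V0 <- if (gamma == 1 || min(v) > 0 || max(v) == min(v)) 0
          else -min(v) + 0.1 * (max(v) - min(v))
    if (gamma == 1 && min(v) < 0)
      warning("gamma = 1 with negative optimal values: V0 = 0 cannot ",
              "represent them as non-negative rates")
  }

  keep <- !(m$sa$state %in% m$terminal)
  coding <- m$sa[keep, , drop = FALSE]
  rownames(coding) <- NULL
  states <- setdiff(m$states, m$terminal)
  n <- nrow(coding)
  P <- m$P[keep, , drop = FALSE]

  # State membership indicator: E[s, j] = 1 iff neuron j codes state s.
  E <- Matrix::sparseMatrix(i = match(coding$state, states),
                            j = seq_len(n), x = 1,
                            dims = c(length(states), n))
  W_exc <- cc * gamma * (P[, states, drop = FALSE] %*% E)
  W_inh <- -cc * (Matrix::t(E) %*% E - Matrix::Diagonal(n))
  theta <- rep(-lambda_r * cc * V0 * (1 - gamma), n)
  p_term <- if (length(m$terminal) > 0)
    Matrix::rowSums(P[, m$terminal, drop = FALSE]) else rep(0, n)
  w_r <- cc * (m$r[keep] + gamma * p_term * V0)

  structure(list(
    W = W_exc + W_inh, W_exc = W_exc, W_inh = W_inh, W_fixed = W_inh,
    w_r = w_r, theta = theta,
    k = k, eta = eta, c = cc, lambda_r = lambda_r, V0 = V0,
    tau_m = tau_m, tau_s = tau_s, gamma = gamma,
    coding = coding, states = states, n_neurons = n,
    kind = "discrete"
  ), class = "spiking_network")
}

#' @export
print.spiking_network <- function(x, ...) {
  cat("<spiking_network:", x$kind, ">", x$n_neurons,
      "neurons; k =", x$k, "Hz/mV, eta =", x$eta, "mV, gamma =", x$gamma, "\n")
  invisible(x)
}

#' Remove lateral inhibition (feedforward ablation)
#'
#' Sets all inhibitory recurrent weights to zero, leaving only the excitatory
#' recurrence and the feedforward reward input. Used as a control: without
#' within-state competition the losing population is never actively
#' suppressed.
#'
#' @param network a `spiking_network`.
#' @return the ablated network.
#' @export
remove_lateral_inhibition <- function(network) {
  if (is.null(network$W_inh))
    stop("feedforward ablation is defined for discrete networks")
  network$W_inh <- network$W_inh * 0
  network$W_fixed <- network$W_inh
  network$W <- network$W_exc
  network
}

#' Compile a continuous task into a network with basis-function coding
#'
#' Function-approximation generalization of [build_discrete_network()]. With
#' `T_ij = <psi_i(s, a), P(s' | s, a) psibar_j(s')>` (the transition-weighted
#' overlap between basis `i` and the action-marginalized basis of `j`,
#' reverse-directed as in the discrete case) and
#' `G_ij = <psibar_i, psibar_j>` the plain overlap, the effective weights are
#' `w_ij = c * (gamma * T_ij - G_ij + delta_ij)`, the reward weights
#' `w_r_i = c * <psi_i, rbar>`, and the per-neuron thresholds
#' `theta_i = -lambda_r * c * V0 * (1 - gamma) * m_i` with basis mass
#' `m_i = integral of psi_i`. Active neurons at the mean-field steady state
#' then satisfy the basis-projected Bellman condition
#' `<psi_i, Vtilde> = <psi_i, rbar + gamma P Vtilde>`, so the represented
#' value function matches the optimal one at the resolution of the code.
#' For indicator bases all integrals collapse to sums and the discrete
#' weights are recovered exactly.
#'
#' Transition and reward integrals are evaluated over the covered region
#' either by seeded Monte-Carlo (`method = "mc"`, `n_mc` uniform samples) or
#' by a deterministic midpoint lattice with about `n_mc` nodes
#' (`method = "lattice"`, far more accurate for smooth integrands and the
#' recommended choice for large basis grids, where Monte-Carlo sampling noise
#' in the weights can destabilize the dynamics); overlaps use the closed
#' form.
#'
#' @param task a `pendulum_task` (or any object with `torques` and for which
#'   [pendulum_step()]/[pendulum_reward()] apply) -- or an `mdp` when `basis`
#'   is an indicator basis, in which case all integrals are exact.
#' @param basis a `basis_set` whose actions match the task's.
#' @param k,eta,lambda_r,V0,tau_m,tau_s as in [build_discrete_network()].
#' @param gamma discount factor (default 0.98).
#' @param control_dt control interval for the continuous dynamics (s).
#' @param n_mc number of integration nodes.
#' @param seed RNG seed for the Monte-Carlo integrals.
#' @param method `"mc"` (seeded uniform sampling) or `"lattice"`
#'   (deterministic midpoint quadrature).
#' @return a `spiking_network` (kind `"fa"`) carrying the basis in `$basis`.
#' @export
build_fa_network <- function(task, basis, k = 1, eta = 20, lambda_r = 400,
                             V0 = 0, tau_m = 20, tau_s = 2, gamma = 0.98,
                             control_dt = 0.1, n_mc = 1e4, seed = 1,
                             method = c("mc", "lattice")) {
  method <- match.arg(method)
  if (k <= 0) stop("gain k must be positive")
  cc <- 1 / k + eta

  if (basis$type == "indicator") {
    m <- basis$mdp
    net <- build_discrete_network(m, k, eta, lambda_r, V0 = V0,
                                  tau_m = tau_m, tau_s = tau_s)
    net$kind <- "fa"
    net$basis <- basis
    return(net)
  }

  G <- basis_overlap(basis)
  # Gaussian overlaps are strictly positive; distant pairs may underflow to
  # exactly 0 in double precision, which is harmless. Reject genuinely
  # non-positive (negative or non-finite) overlaps.
  if (any(!is.finite(G)) || any(G < 0) || any(diag(G) <= 0))
    stop("basis overlaps must be positive")
  n_cells <- basis$n_cells
  n_act <- length(basis$actions)
  n <- basis$n_neurons

  set.seed(seed)
  d <- length(basis$lower)
  if (method == "mc") {
    S <- matrix(stats::runif(n_mc * d), n_mc, d)
    S <- sweep(sweep(S, 2, basis$upper - basis$lower, "*"), 2, basis$lower, "+")
  } else {
    # Midpoint lattice with about n_mc nodes, proportioned to side lengths.
    sides <- basis$upper - basis$lower
    n1 <- max(2L, round(sqrt(n_mc * sides[1] / sides[2])))
    ns <- if (d == 2) c(n1, max(2L, ceiling(n_mc / n1)))
          else rep(max(2L, ceiling(n_mc^(1 / d))), d)
    axes <- lapply(seq_len(d), function(kk)
      basis$lower[kk] + (seq_len(ns[kk]) - 0.5) * sides[kk] / ns[kk])
    S <- as.matrix(expand.grid(axes))
    colnames(S) <- NULL
  }
  n_nodes <- nrow(S)
  vol <- basis$volume

  # Transition-weighted overlaps per action, at the cell level:
  # T_cells[[a]][ci, cj] = integral g_ci(s) g_cj(f(s, a)) ds.
  # Accumulated over node chunks to bound memory.
  T_cells <- replicate(n_act, matrix(0, n_cells, n_cells), simplify = FALSE)
  r_cells <- matrix(0, n_cells, n_act)
  chunks <- split(seq_len(n_nodes), ceiling(seq_len(n_nodes) / 2e4))
  for (ch in chunks) {
    A <- basis_cells_eval(basis, S[ch, , drop = FALSE])
    for (a in seq_len(n_act)) {
      S2 <- pendulum_step(task, S[ch, , drop = FALSE], task$torques[a],
                          control_dt)
      B <- basis_cells_eval(basis, S2)
      T_cells[[a]] <- T_cells[[a]] + crossprod(A, B) * (vol / n_nodes)
      r_cells[, a] <- r_cells[, a] +
        as.numeric(crossprod(A, pendulum_reward(S2))) * (vol / n_nodes)
    }
  }

  # Expand cell-level integrals to the neuron level. Neuron order: action
  # blocks of cells (neuron = (a - 1) * n_cells + cell). T depends on the
  # postsynaptic action and the cells only; G depends on the cells only.
  W_exc <- matrix(0, n, n)
  G_exp <- matrix(0, n, n)
  for (a in seq_len(n_act)) {
    rows <- (a - 1) * n_cells + seq_len(n_cells)
    for (b in seq_len(n_act)) {
      cols <- (b - 1) * n_cells + seq_len(n_cells)
      W_exc[rows, cols] <- cc * gamma * T_cells[[a]]
      G_exp[rows, cols] <- G
    }
  }
  W_fixed <- cc * (diag(n) - G_exp)
  W <- W_exc + W_fixed
  w_r <- cc * as.numeric(r_cells)
  theta <- rep(-lambda_r * cc * V0 * (1 - gamma) * basis$mass, n)

  coding <- data.frame(cell = basis$cell, action = basis$action,
                       stringsAsFactors = FALSE)

  structure(list(
    W = W, W_exc = W_exc, W_fixed = W_fixed, W_inh = NULL,
    w_r = w_r, theta = theta,
    k = k, eta = eta, c = cc, lambda_r = lambda_r, V0 = V0,
    tau_m = tau_m, tau_s = tau_s, gamma = gamma,
    coding = coding, states = NULL, n_neurons = n,
    basis = basis, task = task, control_dt = control_dt,
    kind = "fa"
  ), class = "spiking_network")
}

#' Serialize a network to a structured-text file
#'
#' Writes the weights as sparse triplets together with a metadata block
#' (constants and the neuron coding table) as JSON.
#'
#' @param network a `spiking_network`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  Wt <- Matrix::summary(methods::as(methods::as(Matrix::Matrix(network$W,
    sparse = TRUE), "generalMatrix"), "TsparseMatrix"))
  obj <- list(
    kind = network$kind,
    n_neurons = network$n_neurons,
    constants = list(k = network$k, eta = network$eta,
                     lambda_r = network$lambda_r, V0 = network$V0,
                     tau_m = network$tau_m, tau_s = network$tau_s,
                     gamma = network$gamma),
    coding = network$coding,
    weights = data.frame(i = Wt$i, j = Wt$j, x = Wt$x),
    w_r = network$w_r,
    theta = network$theta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
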