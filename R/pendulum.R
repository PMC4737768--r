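#' Pendulum swing-up task description
#'
#' A rigid pendulum on a one-degree-of-freedom joint, to be swung up from the
#' hanging rest position `(phi, phidot) = (pi, 0)` and balanced at the upright
#' goal `(0, 0)` using only three torques, which are too weak for a direct
#' swing-up. The dynamics are
#' `phidd = (-mu * phid + m * g * l * sin(phi) + a) / (m * l^2)`
#' with angle `phi` wrapped to `(-pi, pi]` and angular velocity clipped to
#' `[-2*pi, 2*pi]` rad/s. The immediate reward is a Gaussian centered on the
#' goal, `r(s) = exp(-(phi^2 + 0.2 * phid^2))`.
#'
#' @param friction,mass,length,gravity physical constants (defaults 0.05
#'   kg m^2/s, 1 kg, 1 m, 9.81 m/s^2).
#' @param torques available torques in N m (default `c(-5, 0, 5)`).
#' @param velocity_limit clip for `|phidot|` (default `2*pi` rad/s).
#' @return an object of class `pendulum_task`.
#' @export
pendulum_task <- function(friction = 0.05, mass = 1, length = 1,
                          gravity = 9.81, torques = c(-5, 0, 5),
                          velocity_limit = 2 * pi) {
  structure(list(mu = friction, m = mass, l = length, g = gravity,
                 torques = torques, vmax = velocity_limit,
                 start = c(pi, 0)),
            class = "pendulum_task")
}

wrap_angle <- function(phi) {
  phi <- (phi + pi) %% (2 * pi) - pi
  # Map the branch point -pi to +pi so the interval is (-pi, pi].
  ifelse(phi <= -pi, phi + 2 * pi, phi)
}

#' Pendulum reward function
#' @param state numeric vector `c(phi, phidot)` or a 2-column matrix.
#' @return Gaussian reward `exp(-(phi^2 + 0.2 * phid^2))`.
#' @export
pendulum_reward <- function(state) {
  if (is.matrix(state)) exp(-(state[, 1]^2 + 0.2 * state[, 2]^2))
  else exp(-(state[1]^2 + 0.2 * state[2]^2))
}

#' Integrate the pendulum dynamics over one control interval
#'
#' Forward-Euler integration with an inner step much finer than the control
#' interval; vectorized over states (rows).
#'
#' @param task a `pendulum_task`.
#' @param state `c(phi, phidot)` or matrix with one state per row.
#' @param torque applied torque (N m), recycled over rows.
#' @param control_dt control interval in seconds (default 0.1).
#' @param euler_dt inner Euler step (default 1e-3 s).
#' @return next state(s), same shape as the input.
#' @export
pendulum_step <- function(task, state, torque, control_dt = 0.1,
                          euler_dt = 1e-3) {
  single <- !is.matrix(state)
  if (single) state <- matrix(state, nrow = 1)
  phi <- state[, 1]; phid <- state[, 2]
  n_sub <- max(1L, round(control_dt / euler_dt))
  h <- control_dt / n_sub
  for (i in seq_len(n_sub)) {
    acc <- (-task$mu * phid + task$m * task$g * task$l * sin(phi) + torque) /
      (task$m * task$l^2)
    phi <- phi + h * phid
    phid <- phid + h * acc
    phid <- pmin(pmax(phid, -task$vmax), task$vmax)
  }
  out <- unname(cbind(wrap_angle(phi), phid))
  if (single) out[1, ] else out
}

pendulum_grid <- function(phi_spacing = pi / 8, vel_spacing = pi / 8,
                          vmax = 2 * pi) {
  list(phi = seq(-pi + phi_spacing, pi, by = phi_spacing),
       vel = seq(-vmax, vmax, by = vel_spacing))
}

pend_state_id <- function(i, j) sprintf("g%d_%d", i, j)

#' Tabular discretization of the pendulum task (dynamic-programming oracle)
#'
#' Snaps the deterministic continuous dynamics to the nearest point of a
#' regular grid over `(phi, phidot)`, producing a finite MDP whose value
#' iteration solution serves as the ground-truth oracle for the
#' function-approximation network. Rewards are evaluated at the landing
#' state, `rbar(s, a) = r(f(s, a))`.
#'
#' @param task a `pendulum_task`.
#' @param control_dt control interval (s).
#' @param phi_spacing,vel_spacing grid spacings (default `pi/16` for a grid
#'   finer than the network's basis grid).
#' @param discount discount factor (default 0.98).
#' @return an `mdp`; the attribute `"grid"` holds the grid coordinates and
#'   `"coords"` the per-state `(phi, phidot)` matrix.
#' @export
discretize_pendulum <- function(task, control_dt = 0.1,
                                phi_spacing = pi / 16, vel_spacing = pi / 16,
                                discount = 0.98) {
  stopifnot(control_dt > 0)
  grid <- pendulum_grid(phi_spacing, vel_spacing, task$vmax)
  np <- length(grid$phi); nv <- length(grid$vel)
  coords <- cbind(rep(grid$phi, times = nv), rep(grid$vel, each = np))
  ids <- pend_state_id(rep(seq_len(np), times = nv), rep(seq_len(nv), each = np))

  snap <- function(states) {
    # Nearest grid point with circular angle distance.
    ip <- round((wrap_angle(states[, 1]) + pi) / phi_spacing)
    ip[ip == 0] <- np  # -pi wraps to +pi end of the circle
    ip[ip > np] <- np
    iv <- round((states[, 2] + task$vmax) / vel_spacing) + 1
    iv <- pmin(pmax(iv, 1), nv)
    (iv - 1) * np + ip
  }

  actions <- stats::setNames(rep(list(as.character(task$torques)), length(ids)), ids)
  transitions <- stats::setNames(vector("list", length(ids)), ids)
  rewards <- stats::setNames(vector("list", length(ids)), ids)
  for (a in seq_along(task$torques)) {
    nxt <- pendulum_step(task, coords, task$torques[a], control_dt)
    k <- snap(nxt)
    rew <- pendulum_reward(nxt)
    lab <- as.character(task$torques[a])
    for (s in seq_along(ids)) {
      transitions[[s]][[lab]] <- stats::setNames(1, ids[k[s]])
      rewards[[s]][[lab]] <- rew[s]
    }
  }
  start_id <- ids[snap(matrix(task$start, nrow = 1))]
  m <- mdp(states = ids, actions = actions, transitions = transitions,
           rewards = rewards, discount = discount,
           start = stats::setNames(1, start_id))
  attr(m, "grid") <- grid
  attr(m, "coords") <- coords
  m
}

#' Discounted return of a pendulum policy by continuous rollout
#'
#' @param task a `pendulum_task`.
#' @param policy_fn function mapping a state matrix (rows `(phi, phidot)`) to
#'   a vector of torque indices (1-based into `task$torques`), or `NULL` for
#'   uniformly random torques.
#' @param discount discount factor.
#' @param n_steps rollout length (control steps).
#' @param control_dt control interval (s).
#' @param n_rollouts number of rollouts (only > 1 is useful for random
#'   policies).
#' @param seed RNG seed for random torques.
#' @return mean discounted return over rollouts.
#' @export
pendulum_return <- function(task, policy_fn, discount = 0.98, n_steps = 300,
                            control_dt = 0.1, n_rollouts = 1, seed = 1) {
  set.seed(seed)
  total <- numeric(n_rollouts)
  for (rr in seq_len(n_rollouts)) {
    s <- matrix(task$start, nrow = 1)
    disc <- 1
    for (t in seq_len(n_steps)) {
      ai <- if (is.null(policy_fn)) sample.int(length(task$torques), 1)
            else policy_fn(s)[1]
      s <- matrix(pendulum_step(task, s[1, ], task$torques[ai], control_dt),
                  nrow = 1)
      total[rr] <- total[rr] + disc * pendulum_reward(s[1, ])
      disc <- disc * discount
    }
  }
  mean(total)
}

#' Grid-policy lookup function for the pendulum
#'
#' Turns a tabular policy on a discretized pendulum MDP into a continuous
#' policy by nearest-grid-point lookup.
#'
#' @param m_disc MDP from [discretize_pendulum()].
#' @param policy policy over `m_disc` (e.g. from [value_iteration()]).
#' @param task a `pendulum_task`.
#' @return function usable as `policy_fn` in [pendulum_return()].
#' @export
pendulum_grid_policy <- function(m_disc, policy, task) {
  grid <- attr(m_disc, "grid")
  np <- length(grid$phi); nv <- length(grid$vel)
  phi_spacing <- grid$phi[2] - grid$phi[1]
  vel_spacing <- grid$vel[2] - grid$vel[1]
  act <- vapply(m_disc$states, function(s) {
    p <- policy[[s]]
    match(names(p)[which.max(p)], as.character(task$torques))
  }, integer(1))
  function(states) {
    if (!is.matrix(states)) states <- matrix(states, nrow = 1)
    ip <- round((wrap_angle(states[, 1]) + pi) / phi_spacing)
    ip[ip == 0] <- np; ip[ip > np] <- np
    iv <- round((states[, 2] + task$vmax) / vel_spacing) + 1
    iv <- pmin(pmax(iv, 1), nv)
    unname(act[(iv - 1) * np + ip])
  }
}

#' Normalized performance of a pendulum policy
#'
#' Same normalization as [normalized_performance()]: 0 for uniformly random
#' torques, 1 for the optimal policy of the fine-grid oracle, both evaluated
#' by continuous rollouts from the hanging start state.
#'
#' @param task a `pendulum_task`.
#' @param policy_fn continuous policy function (see [pendulum_return()]).
#' @param oracle optional precomputed list with `j_opt` and `j_rand` (as
#'   returned in the `"oracle"` attribute) to avoid re-solving the grid MDP.
#' @param discount,n_steps,control_dt rollout settings.
#' @param n_random_rollouts rollouts used for the random-policy reference.
#' @param seed RNG seed.
#' @return normalized performance (attribute `"oracle"` carries the reusable
#'   reference returns).
#' @export
pendulum_performance <- function(task, policy_fn, oracle = NULL,
                                 discount = 0.98, n_steps = 300,
                                 control_dt = 0.1, n_random_rollouts = 30,
                                 seed = 1) {
  if (is.null(oracle)) {
    m_disc <- discretize_pendulum(task, control_dt, discount = discount)
    vi <- value_iteration(m_disc, tol = 1e-8)
    opt_fn <- pendulum_grid_policy(m_disc, vi$policy, task)
    j_opt <- pendulum_return(task, opt_fn, discount, n_steps, control_dt)
    j_rand <- pendulum_return(task, NULL, discount, n_steps, control_dt,
                              n_rollouts = n_random_rollouts, seed = seed)
    oracle <- list(j_opt = j_opt, j_rand = j_rand)
  }
  j <- pendulum_return(task, policy_fn, discount, n_steps, control_dt)
  out <- (j - oracle$j_rand) / (oracle$j_opt - oracle$j_rand)
  attr(out, "oracle") <- oracle
  out
}
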