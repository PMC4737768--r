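#' Dynamic-programming oracles
#'
#' Exact value computations against which the neural planner is validated.
#' `value_iteration` solves the Bellman optimality equation
#' `V*(s) = max_a [ rbar(s,a) + gamma * sum_s' P(s'|s,a) V*(s') ]`
#' by synchronous sweeps; `policy_evaluation` solves the linear Bellman
#' expectation equation for a fixed policy by a direct sparse solve.
#'
#' @name dynamic-programming
NULL

# A policy is a named list: policy[[state]] = named prob vector over actions.
new_policy <- function(probs) {
  structure(probs, class = "sp_policy")
}

#' @export
print.sp_policy <- function(x, ...) {
  cat("<policy> over", length(x), "states\n")
  invisible(x)
}

#' Uniform random policy of an MDP
#' @param m an `mdp` object.
#' @return policy assigning equal probability to every available action.
#' @export
uniform_policy <- function(m) {
  grp <- sa_groups(m)
  new_policy(lapply(grp, function(k) {
    a <- m$sa$action[k]
    stats::setNames(rep(1 / length(a), length(a)), a)
  }))
}

#' Greedy policy with respect to a state-action value vector
#'
#' Ties are broken deterministically in favor of the lowest action index
#' (the order in which actions were declared).
#'
#' @param m an `mdp` object.
#' @param q numeric vector of action values, one per row of `m$sa`.
#' @return deterministic policy.
#' @export
greedy_policy <- function(m, q) {
  grp <- sa_groups(m)
  new_policy(lapply(grp, function(k) {
    a <- m$sa$action[k]
    p <- stats::setNames(rep(0, length(a)), a)
    p[which.max(q[k])] <- 1
    p
  }))
}

#' Epsilon-greedy mixture of a deterministic policy with the uniform policy
#' @param m an `mdp` object.
#' @param policy base policy.
#' @param epsilon probability mass given to uniform action selection.
#' @return mixed policy.
#' @export
epsilon_greedy <- function(m, policy, epsilon) {
  unif <- uniform_policy(m)
  new_policy(stats::setNames(lapply(m$states, function(s) {
    (1 - epsilon) * policy[[s]] + epsilon * unif[[s]]
  }), m$states))
}

# Flatten a policy to a probability per state-action row. States missing
# from the policy (typically absorbing terminals, which networks do not
# represent) default to uniform action choice; their value is pinned anyway.
policy_sa_probs <- function(m, policy) {
  vapply(seq_len(nrow(m$sa)), function(k) {
    p <- policy[[m$sa$state[k]]]
    if (is.null(p)) return(1 / length(actions_of(m, m$sa$state[k])))
    unname(p[m$sa$action[k]])
  }, numeric(1))
}

#' Value iteration
#'
#' @param m an `mdp` object.
#' @param tol convergence tolerance on the sup-norm Bellman residual.
#' @param max_iter iteration cap; exceeding it (which signals a
#'   non-terminating task with `gamma = 1`) is an error.
#' @return list with `values` (named numeric), `policy` (greedy, deterministic,
#'   lowest-index tie break), `q` (state-action values), `n_iter`, `residual`.
#' @export
value_iteration <- function(m, tol = 1e-10, max_iter = 1e5) {
  stopifnot(tol > 0)
  n_s <- length(m$states)
  grp <- sa_groups(m)
  grp_idx <- rep(seq_len(n_s), times = lengths(grp))
  ord <- unlist(grp, use.names = FALSE)
  v <- numeric(n_s)
  term <- m$states %in% m$terminal
  for (it in seq_len(max_iter)) {
    q <- m$r + m$discount * as.numeric(m$P %*% v)
    v_new <- as.numeric(tapply(q[ord], grp_idx, max))
    v_new[term] <- 0
    res <- max(abs(v_new - v))
    v <- v_new
    if (res < tol) {
      pol <- greedy_policy(m, q)
      return(list(values = stats::setNames(v, m$states), policy = pol, q = q,
                  n_iter = it, residual = res))
    }
  }
  stop("value iteration did not converge within ", max_iter,
       " sweeps (gamma = 1 on a non-terminating task?)")
}

#' Policy evaluation by direct linear solve
#'
#' Solves `(I - gamma * P_pi) V = r_pi` restricted to non-terminal states;
#' terminal states are pinned at value 0. With `gamma = 1` the system is
#' singular if the policy can cycle forever among non-terminal states, which
#' surfaces as a solve error.
#'
#' @param m an `mdp` object.
#' @param policy a policy over `m`'s actions.
#' @return named numeric vector of state values.
#' @export
policy_evaluation <- function(m, policy) {
  n_s <- length(m$states)
  probs <- policy_sa_probs(m, policy)
  if (any(is.na(probs))) stop("policy does not cover all state-action pairs")
  # Aggregate state-action rows into per-state rows under the policy.
  S <- Matrix::sparseMatrix(i = match(m$sa$state, m$states),
                            j = seq_len(nrow(m$sa)), x = probs,
                            dims = c(n_s, nrow(m$sa)))
  P_pi <- S %*% m$P
  r_pi <- as.numeric(S %*% m$r)
  free <- !(m$states %in% m$terminal)
  v <- numeric(n_s)
  if (any(free)) {
    A <- Matrix::Diagonal(sum(free)) - m$discount * P_pi[free, free, drop = FALSE]
    v[free] <- as.numeric(Matrix::solve(A, r_pi[free]))
  }
  stats::setNames(v, m$states)
}

#' Best open-loop action sequence
#'
#' Open-loop control precommits to a fixed action sequence at the start and
#' plays it out regardless of the states visited. All sequences up to the
#' given horizon are enumerated exhaustively; this requires the task to use a
#' common action alphabet across non-terminal states.
#'
#' @param m an `mdp` object whose non-terminal states share one action set.
#' @param horizon sequence length (>= 1).
#' @param first_action optional action the sequence is constrained to start
#'   with.
#' @param max_sequences enumeration cap.
#' @return list with `sequence` (character vector) and `value` (expected
#'   discounted return from the start distribution).
#' @export
best_open_loop <- function(m, horizon, first_action = NULL,
                           max_sequences = 1e6) {
  stopifnot(horizon >= 1)
  nonterm <- setdiff(m$states, m$terminal)
  alph <- unique(m$sa$action[m$sa$state %in% nonterm])
  per_state <- lapply(nonterm, function(s) actions_of(m, s))
  if (!all(vapply(per_state, function(a) setequal(a, alph), logical(1))))
    stop("open-loop enumeration requires a common action set across states")
  if (length(alph)^horizon > max_sequences)
    stop("enumeration cap exceeded: ", length(alph), "^", horizon, " sequences")

  seqs <- expand.grid(rep(list(alph), horizon), stringsAsFactors = FALSE)
  if (!is.null(first_action)) seqs <- seqs[seqs[[1]] == first_action, , drop = FALSE]

  n_s <- length(m$states)
  start <- numeric(n_s); start[match(names(m$start), m$states)] <- m$start
  term <- m$states %in% m$terminal
  # Per-action transition matrix / reward vector over states (terminal rows absorb).
  Pa <- list(); ra <- list()
  for (a in alph) {
    rows <- vapply(m$states, function(s)
      if (term[match(s, m$states)]) which(m$sa$state == s)[1]
      else which(m$sa$state == s & m$sa$action == a), integer(1))
    Pa[[a]] <- m$P[rows, , drop = FALSE]
    ra[[a]] <- ifelse(term, 0, m$r[rows])
  }
  best <- -Inf; best_seq <- NULL
  for (i in seq_len(nrow(seqs))) {
    p <- start; total <- 0; disc <- 1
    for (t in seq_len(horizon)) {
      a <- seqs[i, t]
      total <- total + disc * sum(p * ra[[a]])
      p <- as.numeric(Matrix::crossprod(Pa[[a]], p))
      disc <- disc * m$discount
    }
    if (total > best + 1e-12) { best <- total; best_seq <- unlist(seqs[i, ]) }
  }
  list(sequence = unname(best_seq), value = best)
}

#' Expected discounted return of a policy from the start distribution
#' @param m an `mdp` object.
#' @param policy a policy.
#' @return scalar expected return.
#' @export
policy_return <- function(m, policy) {
  v <- policy_evaluation(m, policy)
  sum(m$start * v[names(m$start)])
}

#' Normalized performance of a policy
#'
#' Scores a policy on the scale where uniform random action selection maps to
#' 0 and the optimal policy maps to 1:
#' `(J(policy) - J(random)) / (J(optimal) - J(random))`.
#' Returns are computed exactly by policy evaluation (the default) or, when
#' `n_rollouts > 0`, estimated from seeded Monte-Carlo rollouts.
#'
#' @param m an `mdp` object.
#' @param policy policy to score.
#' @param n_rollouts 0 for exact evaluation, otherwise the number of rollouts
#'   used to estimate `J(policy)` (the reference returns stay exact).
#' @param seed RNG seed for rollouts.
#' @param max_steps rollout truncation horizon.
#' @return scalar normalized performance.
#' @export
normalized_performance <- function(m, policy, n_rollouts = 0, seed = 1,
                                   max_steps = 1000) {
  opt <- value_iteration(m)
  j_opt <- sum(m$start * opt$values[names(m$start)])
  j_rand <- policy_return(m, uniform_policy(m))
  if (abs(j_opt - j_rand) < 1e-12)
    stop("degenerate task: optimal and random policies have equal return")
  j_pol <- if (n_rollouts >= 1) {
    mean(rollout_returns(m, policy, n_rollouts, seed, max_steps))
  } else {
    policy_return(m, policy)
  }
  (j_pol - j_rand) / (j_opt - j_rand)
}

#' Monte-Carlo rollout returns of a policy
#'
#' @param m an `mdp` object.
#' @param policy policy to roll out.
#' @param n number of episodes.
#' @param seed RNG seed.
#' @param max_steps truncation horizon per episode.
#' @return numeric vector of discounted returns.
#' @export
rollout_returns <- function(m, policy, n, seed = 1, max_steps = 1000) {
  set.seed(seed)
  sa_key <- paste(m$sa$state, m$sa$action, sep = "\r")
  sa_row <- stats::setNames(seq_len(nrow(m$sa)), sa_key)
  succ <- lapply(seq_len(nrow(m$sa)), function(k) {
    p <- m$P[k, ]
    nz <- which(p > 0)
    list(states = m$states[nz], probs = unname(p[nz]))
  })
  vapply(seq_len(n), function(e) {
    s <- sample(names(m$start), 1, prob = m$start)
    total <- 0; disc <- 1
    for (t in seq_len(max_steps)) {
      if (s %in% m$terminal) break
      pr <- policy[[s]]
      a <- if (length(pr) == 1) names(pr) else sample(names(pr), 1, prob = pr)
      k <- sa_row[[paste(s, a, sep = "\r")]]
      total <- total + disc * m$r[k]
      disc <- disc * m$discount
      sc <- succ[[k]]
      s <- if (length(sc$states) == 1) sc$states else sample(sc$states, 1, prob = sc$probs)
    }
    total
  }, numeric(1))
}

#' Random MDP generator (for property-style validation)
#'
#' Draws a dense random transition kernel (normalized uniform variates, with a
#' configurable number of nonzero successors), uniform rewards in `[0, 1]`,
#' and a uniform start distribution.
#'
#' @param n_states number of states.
#' @param n_actions actions per state.
#' @param discount discount factor (< 1; no terminal states are generated).
#' @param seed RNG seed.
#' @param n_succ number of successor states per state-action pair.
#' @return an `mdp` object.
#' @export
make_random_mdp <- function(n_states, n_actions, discount = 0.9, seed = 1,
                            n_succ = min(3, n_states)) {
  set.seed(seed)
  states <- sprintf("s%02d", seq_len(n_states))
  acts <- sprintf("a%d", seq_len(n_actions))
  actions <- stats::setNames(rep(list(acts), n_states), states)
  transitions <- list(); rewards <- list()
  for (s in states) {
    transitions[[s]] <- list(); rewards[[s]] <- list()
    for (a in acts) {
      to <- sample(states, n_succ)
      p <- stats::runif(n_succ) + 0.05
      transitions[[s]][[a]] <- stats::setNames(p / sum(p), to)
      rewards[[s]][[a]] <- stats::runif(1)
    }
  }
  start <- stats::setNames(rep(1 / n_states, n_states), states)
  mdp(states, actions, transitions, rewards, discount, start = start)
}
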