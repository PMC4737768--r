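#' Decode state values from population activity
#'
#' The approximate value of state `s` is the scaled sum of the rates of all
#' neurons coding for `s` (any action), relative to the baseline:
#' `Vtilde(s) = (1/lambda_r) * sum_{i | s_i = s} lambda_i - V0`.
#' Decoding is linear in the activity.
#'
#' @param activity numeric vector of firing rates (Hz, one per neuron), or a
#'   matrix with neurons in columns (e.g. `rate_trace$rates`) or in rows with
#'   runs in columns (e.g. from [spike_counts()] divided by the window).
#' @param coding data.frame with a `state` column (one row per neuron), e.g.
#'   `network$coding`.
#' @param lambda_r reward-input rate used as the value scale (Hz).
#' @param V0 value baseline.
#' @param states optional state ordering for the result (defaults to order of
#'   first appearance in `coding`).
#' @return named vector of decoded values (or a matrix with one decoded value
#'   vector per input row/column, matching the input orientation).
#' @export
decode_values <- function(activity, coding, lambda_r, V0 = 0, states = NULL) {
  if (is.null(states)) states <- unique(coding$state)
  M <- outer(states, coding$state, "==") * 1  # n_states x n_neurons
  if (is.matrix(activity)) {
    if (ncol(activity) == length(coding$state)) {
      out <- activity %*% t(M) / lambda_r - V0   # rows = time points
      colnames(out) <- states
    } else if (nrow(activity) == length(coding$state)) {
      out <- M %*% activity / lambda_r - V0      # cols = runs
      rownames(out) <- states
    } else stop("activity dimensions do not match the coding table")
    return(out)
  }
  stats::setNames(as.numeric(M %*% activity) / lambda_r - V0, states)
}

#' Decode values from a rate trace
#' @param trace a `rate_trace` produced from a discrete network.
#' @return matrix `n_times x n_states` of decoded values.
#' @export
decode_value_trace <- function(trace) {
  net <- trace$network
  decode_values(trace$rates, net$coding, net$lambda_r, net$V0,
                states = net$states)
}

#' Extract a policy from population activity
#'
#' Per state, selects the action encoded by the most active neuron among the
#' neurons coding for that state (deterministic tie break by action order).
#' States whose neurons are all silent fall back to the uniform policy and
#' are flagged in the `"fallback_states"` attribute.
#'
#' @param activity numeric vector of rates or spike counts, one per neuron.
#' @param coding data.frame with `state` and `action` columns.
#' @return an `sp_policy`; attribute `"fallback_states"` lists degenerate
#'   states.
#' @export
extract_policy <- function(activity, coding) {
  states <- unique(coding$state)
  fallback <- character(0)
  probs <- lapply(states, function(s) {
    idx <- which(coding$state == s)
    a <- coding$action[idx]
    p <- stats::setNames(rep(0, length(a)), a)
    if (max(activity[idx]) <= 0) {
      fallback <<- c(fallback, s)
      p[] <- 1 / length(a)
    } else {
      p[which.max(activity[idx])] <- 1
    }
    p
  })
  pol <- new_policy(stats::setNames(probs, states))
  attr(pol, "fallback_states") <- fallback
  pol
}

#' Performance of the decoded policy as a function of planning time
#'
#' For each time `t` in `time_grid`, decodes a policy from the cumulative
#' spike counts in `[0, t]` (no burn-in: time serves both to let the dynamics
#' converge and to estimate rates from counts) and scores it with
#' [normalized_performance()] (exact policy evaluation by default).
#'
#' @param record a `spike_record` from a discrete-task network.
#' @param m the `mdp` the network was compiled from.
#' @param time_grid vector of planning times (ms).
#' @param n_rollouts passed to [normalized_performance()] (0 = exact).
#' @param seed rollout seed.
#' @return data.frame with columns `t`, `run`, `performance`; the attribute
#'   `"summary"` holds per-`t` mean/median/sem across runs.
#' @export
performance_vs_time <- function(record, m, time_grid, n_rollouts = 0,
                                seed = 1) {
  coding <- record$network$coding
  # reference returns are computed once
  j_opt <- sum(m$start * value_iteration(m)$values[names(m$start)])
  j_rand <- policy_return(m, uniform_policy(m))
  score <- function(pol) {
    j <- if (n_rollouts >= 1)
      mean(rollout_returns(m, pol, n_rollouts, seed))
    else policy_return(m, pol)
    (j - j_rand) / (j_opt - j_rand)
  }
  rows <- list()
  for (t in time_grid) {
    counts <- spike_counts(record, t_end = t)
    for (run in seq_len(record$n_runs)) {
      pol <- extract_policy(counts[, run], coding)
      rows[[length(rows) + 1]] <- data.frame(t = t, run = run,
                                             performance = score(pol))
    }
  }
  out <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(out, out$t), function(d)
    data.frame(t = d$t[1], mean = mean(d$performance),
               median = stats::median(d$performance),
               sem = stats::sd(d$performance) / sqrt(nrow(d)),
               n_runs = nrow(d))))
  attr(out, "summary") <- agg[order(agg$t), ]
  out
}

# --- function-approximation (distributed code) decoding --------------------

#' Decode a continuous value function from basis-coded activity
#'
#' `Vtilde(s) = (1/lambda_r) * sum_i lambda_i * g_i(s) - V0` with the
#' action-marginalized basis `g_i`.
#'
#' @param activity per-neuron rates (Hz).
#' @param basis the `basis_set` of the network.
#' @param states matrix of query states (rows).
#' @param lambda_r,V0 value scale and baseline.
#' @return numeric vector of decoded values at the query states.
#' @export
fa_decode_values <- function(activity, basis, states, lambda_r, V0 = 0) {
  Gs <- basis_cells_eval(basis, states)    # n_points x n_cells
  n_act <- length(basis$actions)
  lam_cells <- matrix(activity, basis$n_cells, n_act)
  as.numeric(Gs %*% rowSums(lam_cells)) / lambda_r - V0
}

#' Continuous greedy policy from basis-coded activity
#'
#' Selects `a*(s) = argmax_a sum_i lambda_i psi_i(s, a)`; with one preferred
#' action per neuron this is the action whose cell population has the highest
#' basis-weighted activity at `s`.
#'
#' @param activity per-neuron rates or spike counts.
#' @param basis the `basis_set`.
#' @return function mapping a state matrix to action indices (usable as
#'   `policy_fn` in [pendulum_return()]).
#' @export
fa_extract_policy <- function(activity, basis) {
  n_act <- length(basis$actions)
  lam_cells <- matrix(activity, basis$n_cells, n_act)
  function(states) {
    if (!is.matrix(states)) states <- matrix(states, nrow = 1)
    Gs <- basis_cells_eval(basis, states)        # n_points x n_cells
    scores <- Gs %*% lam_cells                   # n_points x n_act
    max.col(scores, ties.method = "first")
  }
}
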