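#' Construct a finite Markov decision process
#'
#' A Markov decision process (MDP) consists of a finite set of states, a set
#' of available actions per state, a transition kernel `P(s' | s, a)`, expected
#' immediate rewards `rbar(s, a)`, and a temporal discount factor `gamma`.
#' Terminal states are modeled explicitly as absorbing states with a single
#' zero-reward action, which keeps episodic (`gamma = 1`) tasks well posed.
#'
#' Internally the constructor flattens the task to a state-action table with a
#' sparse transition matrix, which is the representation all dynamic
#' programming routines and the network compiler operate on.
#'
#' @param states character vector of state identifiers.
#' @param actions named list mapping each state to a character vector of its
#'   available actions (every state needs at least one).
#' @param transitions nested named list: `transitions[[s]][[a]]` is a named
#'   numeric vector of successor probabilities (must sum to 1 within 1e-12).
#' @param rewards nested named list: `rewards[[s]][[a]]` is the expected
#'   immediate reward of taking `a` in `s`.
#' @param discount discount factor in `[0, 1]`. `gamma = 1` is only admissible
#'   for tasks that terminate with probability 1.
#' @param terminal character vector of absorbing terminal states. Terminal
#'   states may be omitted from `actions`/`transitions`; they are then given a
#'   single zero-reward self-loop automatically.
#' @param start optional named numeric vector with the initial-state
#'   distribution (defaults to a point mass on the first non-terminal state).
#'
#' @return An object of class `mdp` with elements `states`, `terminal`,
#'   `sa` (data.frame of state-action pairs), `P` (sparse `n_sa x n_states`
#'   transition matrix), `r` (expected rewards per state-action row),
#'   `discount`, and `start`.
#' @export
mdp <- function(states, actions, transitions, rewards, discount,
                terminal = character(), start = NULL) {
  stopifnot(is.character(states), length(states) >= 1, !anyDuplicated(states))
  if (discount < 0 || discount > 1) stop("discount must lie in [0, 1]")
  if (!all(terminal %in% states)) stop("terminal states must be listed in `states`")

  for (s in setdiff(terminal, names(actions))) {
    actions[[s]] <- "stay"
    transitions[[s]] <- list(stay = stats::setNames(1, s))
    rewards[[s]] <- list(stay = 0)
  }

  missing_act <- setdiff(states, names(actions))
  if (length(missing_act) > 0)
    stop("states without actions: ", paste(missing_act, collapse = ", "))

  sa_state <- character(0); sa_action <- character(0)
  for (s in states) {
    acts <- actions[[s]]
    if (length(acts) < 1) stop("state ", s, " has no actions")
    sa_state <- c(sa_state, rep(s, length(acts)))
    sa_action <- c(sa_action, acts)
  }
  n_sa <- length(sa_state)
  n_s <- length(states)
  state_index <- stats::setNames(seq_len(n_s), states)

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  r <- numeric(n_sa)
  for (k in seq_len(n_sa)) {
    s <- sa_state[k]; a <- sa_action[k]
    p <- transitions[[s]][[a]]
    if (is.null(p)) stop("missing transition vector for (", s, ", ", a, ")")
    if (any(p < 0)) stop("negative transition probability at (", s, ", ", a, ")")
    if (abs(sum(p) - 1) > 1e-12)
      stop("transition probabilities for (", s, ", ", a, ") sum to ", sum(p))
    if (!all(names(p) %in% states))
      stop("unknown successor state in transition of (", s, ", ", a, ")")
    ii <- c(ii, rep(k, length(p)))
    jj <- c(jj, state_index[names(p)])
    xx <- c(xx, unname(p))
    rk <- rewards[[s]][[a]]
    if (is.null(rk) || !is.finite(rk)) stop("missing reward for (", s, ", ", a, ")")
    r[k] <- rk
  }
  P <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n_sa, n_s),
                            dimnames = list(NULL, states))

  if (is.null(start)) {
    s0 <- setdiff(states, terminal)[1]
    if (is.na(s0)) s0 <- states[1]
    start <- stats::setNames(1, s0)
  }
  if (abs(sum(start) - 1) > 1e-9 || any(start < 0) ||
      !all(names(start) %in% states))
    stop("`start` must be a probability distribution over states")

  obj <- list(
    states = states,
    terminal = terminal,
    sa = data.frame(state = sa_state, action = sa_action,
                    stringsAsFactors = FALSE),
    P = P,
    r = r,
    discount = discount,
    start = start
  )
  class(obj) <- "mdp"
  obj
}

#' @export
print.mdp <- function(x, ...) {
  cat("<mdp> ", length(x$states), " states (", length(x$terminal),
      " terminal), ", nrow(x$sa), " state-action pairs, gamma = ",
      x$discount, "\n", sep = "")
  invisible(x)
}

#' Number of state-action pairs of an MDP
#' @param m an `mdp` object.
#' @return integer count of state-action rows.
#' @export
n_state_actions <- function(m) nrow(m$sa)

#' Actions available in a state
#' @param m an `mdp` object.
#' @param state state identifier.
#' @return character vector of action names.
#' @export
actions_of <- function(m, state) m$sa$action[m$sa$state == state]

#' Transition probability vector of a state-action pair
#' @param m an `mdp` object.
#' @param state,action identifiers of the pair.
#' @return named numeric vector of successor probabilities (nonzero entries).
#' @export
transition_of <- function(m, state, action) {
  k <- which(m$sa$state == state & m$sa$action == action)
  if (length(k) != 1) stop("unknown state-action pair (", state, ", ", action, ")")
  p <- m$P[k, ]
  p[p > 0]
}

#' Expected immediate reward of a state-action pair
#' @param m an `mdp` object.
#' @param state,action identifiers of the pair.
#' @return scalar expected reward.
#' @export
reward_of <- function(m, state, action) {
  k <- which(m$sa$state == state & m$sa$action == action)
  if (length(k) != 1) stop("unknown state-action pair (", state, ", ", action, ")")
  m$r[k]
}

# Row indices of the state-action table grouped by state, in state order.
sa_groups <- function(m) split(seq_len(nrow(m$sa)), factor(m$sa$state, levels = m$states))

#' Write an MDP to a structured-text (JSON) file
#'
#' The format mirrors the nested-list constructor arguments:
#' `{"states": [...], "actions": {state: [...]},
#'   "transitions": {state: {action: {next_state: prob}}},
#'   "rewards": {state: {action: r}}, "discount": g, "terminal": [...],
#'   "start": {state: prob}}`.
#'
#' @param m an `mdp` object.
#' @param path file to write (UTF-8 JSON).
#' @return `path`, invisibly.
#' @export
write_mdp <- function(m, path) {
  grp <- sa_groups(m)
  acts <- lapply(grp, function(k) m$sa$action[k])
  trans <- lapply(grp, function(k) {
    out <- lapply(k, function(kk) {
      p <- m$P[kk, ]
      as.list(p[p > 0])
    })
    names(out) <- m$sa$action[k]
    out
  })
  rew <- lapply(grp, function(k) {
    out <- as.list(m$r[k])
    names(out) <- m$sa$action[k]
    out
  })
  obj <- list(states = m$states, actions = acts, transitions = trans,
              rewards = rew, discount = m$discount, terminal = m$terminal,
              start = as.list(m$start))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an MDP from a structured-text (JSON) file
#' @param path file written by [write_mdp()] (or hand-authored in the same
#'   format).
#' @return an `mdp` object.
#' @export
read_mdp <- function(path) {
  obj <- jsonlite::read_json(path)
  trans <- lapply(obj$transitions, function(per_state)
    lapply(per_state, function(p) unlist(p)))
  rew <- lapply(obj$rewards, function(per_state) lapply(per_state, as.numeric))
  start <- if (!is.null(obj$start)) unlist(obj$start) else NULL
  mdp(states = unlist(obj$states),
      actions = lapply(obj$actions, unlist),
      transitions = trans,
      rewards = rew,
      discount = obj$discount,
      terminal = as.character(unlist(obj$terminal)),
      start = start)
}
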