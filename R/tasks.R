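#' Two-step door task
#'
#' A depth-two decision tree with four decision states and two actions (L, R)
#' each. Turning right at the root leads through a stochastically operating
#' door to one of two states with probability 1/2 each; turning left leads
#' deterministically to a state in which both second actions pay 3/4. Behind
#' the door, exactly one action pays 1 (L in the first door state, R in the
#' second). The task separates open-loop from closed-loop control: the best
#' precommitted sequence earns 3/4 (starting L) or 1/2 (starting R), while
#' state-dependent closed-loop control earns 1.
#'
#' @return an `mdp` with `discount = 1` and start state `"0"`.
#' @export
make_two_step <- function() {
  mdp(
    states = c("0", "1", "2", "3", "T"),
    actions = list(`0` = c("L", "R"), `1` = c("L", "R"),
                   `2` = c("L", "R"), `3` = c("L", "R")),
    transitions = list(
      `0` = list(L = c(`1` = 1), R = c(`2` = 0.5, `3` = 0.5)),
      `1` = list(L = c(T = 1), R = c(T = 1)),
      `2` = list(L = c(T = 1), R = c(T = 1)),
      `3` = list(L = c(T = 1), R = c(T = 1))
    ),
    rewards = list(
      `0` = list(L = 0, R = 0),
      `1` = list(L = 0.75, R = 0.75),
      `2` = list(L = 1, R = 0),
      `3` = list(L = 0, R = 1)
    ),
    discount = 1,
    terminal = "T",
    start = c(`0` = 1)
  )
}

# ---------------------------------------------------------------------------
# Blackjack

# Infinite deck: ranks A,2..9,10/J/Q/K; value 10 has probability 4/13.
card_probs <- function() {
  p <- c(rep(1 / 13, 9), 4 / 13)
  stats::setNames(p, as.character(1:10))
}

# Add a card to a hand (total counts one ace as 11 iff `usable`).
# Returns list(total, usable); total > 21 means bust.
add_card <- function(total, usable, card) {
  total <- total + card
  if (card == 1 && total + 10 <= 21) { total <- total + 10; usable <- TRUE }
  if (total > 21 && usable) { total <- total - 10; usable <- FALSE }
  list(total = total, usable = usable)
}

# Distribution over the dealer's final total (18 = "bust" bucket is coded 0),
# given the open card, hitting until 17 with an infinite deck.
dealer_final_dist <- function(open_card) {
  pc <- card_probs()
  memo <- new.env()
  rec <- function(total, usable) {
    if (total >= 17) {
      out <- stats::setNames(numeric(6), c(as.character(17:21), "bust"))
      out[if (total > 21) "bust" else as.character(total)] <- 1
      return(out)
    }
    key <- paste(total, usable)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- stats::setNames(numeric(6), c(as.character(17:21), "bust"))
    for (c in 1:10) {
      h <- add_card(total, usable, c)
      out <- out + pc[[as.character(c)]] * rec(h$total, h$usable)
    }
    memo[[key]] <- out
    out
  }
  init <- if (open_card == 1) list(total = 11, usable = TRUE)
          else list(total = open_card, usable = FALSE)
  rec(init$total, init$usable)
}

bj_state <- function(total, dealer, usable)
  sprintf("p%d_d%d_%s", total, dealer, if (usable) "u" else "h")

# Player-hand distribution at the first decision point: cards are drawn until
# the total reaches 12 (no decision exists below 12 because drawing cannot
# bust), mirroring the standard textbook formulation of the game.
bj_start_hand_dist <- function() {
  pc <- card_probs()
  dist <- new.env(); dist$x <- list()
  rec <- function(total, usable, prob) {
    if (total >= 12) {
      key <- paste(total, usable)
      cur <- dist$x[[key]]
      dist$x[[key]] <- if (is.null(cur)) prob else cur + prob
      return(invisible())
    }
    for (c in 1:10) {
      h <- add_card(total, usable, c)
      rec(h$total, h$usable, prob * pc[[as.character(c)]])
    }
  }
  rec(0, FALSE, 1)
  dist$x
}

#' Blackjack task
#'
#' The agent plays blackjack against a dealer with an infinite deck (cards
#' drawn with replacement; face cards count 10, an ace counts 1 or 11).
#' States jointly encode the player's hand total (12-21), the dealer's open
#' card (ace-10), and whether the player holds a usable ace. Actions are
#' `draw` and `stop`; drawing is (mistakenly) allowed even on 21. Stopping
#' makes the dealer play out (hitting until 17) and pays the expected value of
#' 1 for a win, 1/2 for a draw, and 0 for a loss. Busting pays 0. The start
#' distribution follows from dealing cards until the hand total reaches 12.
#'
#' @return an `mdp` with `discount = 1` (finite-horizon task).
#' @export
make_blackjack <- function() {
  pc <- card_probs()
  states <- character(0)
  for (tt in 12:21) for (d in 1:10) for (u in c(FALSE, TRUE))
    states <- c(states, bj_state(tt, d, u))
  actions <- stats::setNames(rep(list(c("draw", "stop")), length(states)), states)
  dealer_dists <- lapply(1:10, dealer_final_dist)

  transitions <- list(); rewards <- list()
  for (tt in 12:21) for (d in 1:10) for (u in c(FALSE, TRUE)) {
    s <- bj_state(tt, d, u)
    draw_p <- numeric(0)
    bust_p <- 0
    for (c in 1:10) {
      h <- add_card(tt, u, c)
      pcc <- pc[[as.character(c)]]
      if (h$total > 21) bust_p <- bust_p + pcc
      else {
        ns <- bj_state(h$total, d, h$usable)
        draw_p[ns] <- (if (is.na(draw_p[ns])) 0 else draw_p[ns]) + pcc
      }
    }
    if (bust_p > 0) draw_p["end"] <- bust_p
    dd <- dealer_dists[[d]]
    p_win <- dd[["bust"]] + sum(dd[as.character(17:21)][17:21 < tt])
    p_draw <- if (tt >= 17) dd[[as.character(tt)]] else 0
    transitions[[s]] <- list(draw = draw_p, stop = c(end = 1))
    rewards[[s]] <- list(draw = 0, stop = p_win + 0.5 * p_draw)
  }

  hand <- bj_start_hand_dist()
  start <- stats::setNames(numeric(0), character(0))
  for (key in names(hand)) {
    parts <- strsplit(key, " ")[[1]]
    tt <- as.integer(parts[1]); u <- as.logical(parts[2])
    for (d in 1:10)
      start[bj_state(tt, d, u)] <- hand[[key]] * pc[[as.character(d)]]
  }
  mdp(states = c(states, "end"), actions = actions, transitions = transitions,
      rewards = rewards, discount = 1, terminal = "end", start = start)
}

# ---------------------------------------------------------------------------
# Flag maze

#' Parse an ASCII maze layout
#'
#' Characters: `#` wall, `.` corridor, `S` start, `G` goal, `F` flag (all of
#' `S`, `G`, `F` are also corridor cells).
#'
#' @param text either a single string with newline-separated rows or a
#'   character vector of rows (all the same width).
#' @param slip probability that a move slips perpendicular to the intended
#'   direction (split evenly between the two perpendicular directions).
#' @return an object of class `maze_layout` with the wall grid, start, goal,
#'   flag coordinates, and slip probability.
#' @export
maze_layout <- function(text, slip = 0.1) {
  rows <- if (length(text) == 1) strsplit(text, "\n")[[1]] else text
  rows <- rows[nzchar(rows)]
  if (length(unique(nchar(rows))) != 1) stop("maze rows must have equal width")
  grid <- do.call(rbind, strsplit(rows, ""))
  if (!all(grid %in% c("#", ".", "S", "G", "F"))) stop("invalid maze character")
  find <- function(ch) which(grid == ch, arr.ind = TRUE)
  start <- find("S"); goal <- find("G"); flags <- find("F")
  if (nrow(start) != 1) stop("maze needs exactly one start cell S")
  if (nrow(goal) != 1) stop("maze needs exactly one goal cell G")
  structure(list(walls = grid == "#", start = start[1, ], goal = goal[1, ],
                 flags = flags, slip = slip, n_rows = nrow(grid),
                 n_cols = ncol(grid)),
            class = "maze_layout")
}

#' Default 9 x 6 flag-maze layout with three flags
#' @param slip slip probability (default 0.1).
#' @return a `maze_layout`.
#' @export
default_maze <- function(slip = 0.1) {
  maze_layout(c(
    "S...#...G",
    ".##.#.#..",
    ".F..#.#..",
    ".#.....#.",
    ".#.##.##.",
    "...F...F."
  ), slip = slip)
}

maze_cell_id <- function(r, c) sprintf("c%d_%d", r, c)
maze_state_id <- function(r, c, mask) sprintf("c%d_%d_m%d", r, c, mask)

# Directions: intended move and its two perpendicular slips.
maze_dirs <- list(U = c(-1, 0), D = c(1, 0), L = c(0, -1), R = c(0, 1))
maze_perp <- list(U = c("L", "R"), D = c("L", "R"), L = c("U", "D"), R = c("U", "D"))

#' Grid-world maze with collectible flags
#'
#' The agent moves left, right, up, or down one cell at a time; moving into a
#' wall leaves the position unchanged. With probability `slip` (default 0.1)
#' the executed move is perpendicular to the intended one (0.05 per side).
#' Visiting a flag cell collects its flag; entering the goal ends the episode
#' with a reward equal to the number of flags collected. The state encodes
#' the cell together with the flag-collection bitmask.
#'
#' @param layout a `maze_layout` (default [default_maze()]).
#' @param discount discount factor (default 0.98).
#' @return an `mdp` with terminal state `"done"`.
#' @export
make_flag_maze <- function(layout = default_maze(), discount = 0.98) {
  stopifnot(inherits(layout, "maze_layout"))
  walls <- layout$walls
  n_flags <- nrow(layout$flags)
  open_cells <- which(!walls, arr.ind = TRUE)
  flag_key <- if (n_flags > 0)
    stats::setNames(seq_len(n_flags),
                    maze_cell_id(layout$flags[, 1], layout$flags[, 2]))
  else stats::setNames(integer(0), character(0))
  goal_id <- maze_cell_id(layout$goal[1], layout$goal[2])

  in_bounds <- function(r, c)
    r >= 1 && r <= layout$n_rows && c >= 1 && c <= layout$n_cols && !walls[r, c]

  # Resulting (cell, mask) of physically moving in direction d from (r, c).
  land <- function(r, c, mask, d) {
    dd <- maze_dirs[[d]]
    r2 <- r + dd[1]; c2 <- c + dd[2]
    if (!in_bounds(r2, c2)) { r2 <- r; c2 <- c }
    cid <- maze_cell_id(r2, c2)
    fk <- flag_key[cid]
    if (!is.na(fk)) mask <- bitwOr(mask, bitwShiftL(1L, fk - 1L))
    list(r = r2, c = c2, mask = mask, cid = cid)
  }

  states <- character(0); actions <- list(); transitions <- list(); rewards <- list()
  for (i in seq_len(nrow(open_cells))) {
    r <- open_cells[i, 1]; c <- open_cells[i, 2]
    if (maze_cell_id(r, c) == goal_id) next  # goal is entered, never occupied
    for (mask in 0:(2^n_flags - 1)) {
      s <- maze_state_id(r, c, mask)
      states <- c(states, s)
      actions[[s]] <- names(maze_dirs)
      transitions[[s]] <- list(); rewards[[s]] <- list()
      for (a in names(maze_dirs)) {
        outcomes <- list(list(p = 1 - layout$slip, d = a),
                         list(p = layout$slip / 2, d = maze_perp[[a]][1]),
                         list(p = layout$slip / 2, d = maze_perp[[a]][2]))
        p <- numeric(0); rew <- 0
        for (o in outcomes) {
          l <- land(r, c, mask, o$d)
          if (l$cid == goal_id) {
            p["done"] <- (if (is.na(p["done"])) 0 else p["done"]) + o$p
            rew <- rew + o$p * sum(bitwAnd(l$mask, bitwShiftL(1L, seq_len(n_flags) - 1L)) > 0)
          } else {
            ns <- maze_state_id(l$r, l$c, l$mask)
            p[ns] <- (if (is.na(p[ns])) 0 else p[ns]) + o$p
          }
        }
        transitions[[s]][[a]] <- p
        rewards[[s]][[a]] <- rew
      }
    }
  }
  start_mask <- 0L
  sf <- flag_key[maze_cell_id(layout$start[1], layout$start[2])]
  if (!is.na(sf)) start_mask <- bitwShiftL(1L, sf - 1L)
  start_id <- maze_state_id(layout$start[1], layout$start[2], start_mask)
  m <- mdp(states = c(states, "done"), actions = actions,
           transitions = transitions, rewards = rewards, discount = discount,
           terminal = "done", start = stats::setNames(1, start_id))
  # Reachability check: the goal must be reachable from the start.
  v <- value_iteration(m)$values
  if (v[start_id] <= 0) stop("goal unreachable from start in this layout")
  m
}

# ---------------------------------------------------------------------------
# Binary economic choice, movement chains, devaluation maze

#' One-state binary choice task
#'
#' A single offer state with two actions, A and B, whose rewards equal the
#' offered values measured in units of option B. Both actions terminate the
#' trial.
#'
#' @param value_A,value_B offered values (B units).
#' @return an `mdp` with `discount = 1`.
#' @export
make_binary_choice <- function(value_A, value_B) {
  mdp(states = c("offer", "T"),
      actions = list(offer = c("A", "B")),
      transitions = list(offer = list(A = c(T = 1), B = c(T = 1))),
      rewards = list(offer = list(A = value_A, B = value_B)),
      discount = 1, terminal = "T", start = c(offer = 1))
}

#' Sequential movement chain indexed by number of remaining movements
#'
#' A linear chain of states labeled by the number of remaining movements
#' (NRM). In every state one action (`go`) advances the chain; the remaining
#' `n_actions - 1` actions abort the trial to a no-reward terminal. The final
#' correct movement (from NRM 0) yields reward 1, so the optimal value of the
#' state with NRM `n` is `gamma^n`.
#'
#' @param n_steps chain length (states NRM `n_steps - 1` down to 0).
#' @param n_actions actions per state (>= 2; 1 correct, rest incorrect).
#' @param discount discount factor (default 0.7).
#' @return an `mdp`; states are named `"n<k>"`, terminals `"goal"`/`"abort"`.
#' @export
make_nrm_chain <- function(n_steps, n_actions = 2, discount = 0.7) {
  stopifnot(n_steps >= 1, n_actions >= 2)
  ks <- (n_steps - 1):0
  states <- sprintf("n%d", ks)
  wrong <- sprintf("x%d", seq_len(n_actions - 1))
  actions <- list(); transitions <- list(); rewards <- list()
  for (k in ks) {
    s <- sprintf("n%d", k)
    succ <- if (k == 0) "goal" else sprintf("n%d", k - 1)
    actions[[s]] <- c("go", wrong)
    transitions[[s]] <- c(list(go = stats::setNames(1, succ)),
                          stats::setNames(rep(list(c(abort = 1)), n_actions - 1), wrong))
    rewards[[s]] <- c(list(go = if (k == 0) 1 else 0),
                      stats::setNames(rep(list(0), n_actions - 1), wrong))
  }
  mdp(states = c(states, "goal", "abort"), actions = actions,
      transitions = transitions, rewards = rewards, discount = discount,
      terminal = c("goal", "abort"),
      start = stats::setNames(1, sprintf("n%d", n_steps - 1)))
}

#' Movement chain with an intermediate reward
#'
#' Same chain as [make_nrm_chain()] but the correct movement out of the state
#' with NRM `intermediate_at` additionally yields reward `r_mid`. To rule out
#' harvesting the intermediate reward repeatedly, incorrect actions in states
#' past the intermediate reward lead to the state immediately after it
#' (NRM `intermediate_at - 1`) instead of aborting.
#'
#' @param n_steps chain length.
#' @param intermediate_at NRM index whose correct action pays `r_mid`
#'   (0 < `intermediate_at` < `n_steps`).
#' @param r_mid intermediate reward magnitude (default 1).
#' @param n_actions actions per state.
#' @param discount discount factor (default 0.7).
#' @return an `mdp`.
#' @export
make_multireward_chain <- function(n_steps, intermediate_at, r_mid = 1,
                                   n_actions = 2, discount = 0.7) {
  stopifnot(intermediate_at > 0, intermediate_at < n_steps)
  m0 <- make_nrm_chain(n_steps, n_actions, discount)
  # Rebuild with modified rewards/transitions.
  ks <- (n_steps - 1):0
  wrong <- sprintf("x%d", seq_len(n_actions - 1))
  after <- sprintf("n%d", intermediate_at - 1)
  actions <- list(); transitions <- list(); rewards <- list()
  for (k in ks) {
    s <- sprintf("n%d", k)
    succ <- if (k == 0) "goal" else sprintf("n%d", k - 1)
    wrong_to <- if (k <= intermediate_at - 1) after else "abort"
    actions[[s]] <- c("go", wrong)
    transitions[[s]] <- c(list(go = stats::setNames(1, succ)),
                          stats::setNames(rep(list(stats::setNames(1, wrong_to)),
                                              n_actions - 1), wrong))
    r_go <- if (k == 0) 1 else if (k == intermediate_at) r_mid else 0
    rewards[[s]] <- c(list(go = r_go),
                      stats::setNames(rep(list(0), n_actions - 1), wrong))
  }
  mdp(states = m0$states, actions = actions, transitions = transitions,
      rewards = rewards, discount = discount, terminal = c("goal", "abort"),
      start = stats::setNames(1, sprintf("n%d", n_steps - 1)))
}

#' Devaluation maze
#'
#' A depth-two decision tree with three decision states. From the root
#' (state 0), turning left reaches state 1 whose best outcome is the cheese
#' (reward 4 at baseline, 2 after devaluation; the alternative pays 1);
#' turning right reaches state 2 whose two outcomes pay 3 and 2. At baseline
#' the optimal plan is L then L (total 4); after devaluation it flips to R
#' then L (total 3). The two right-hand rewards sum to 5 > 4, which is what
#' defeats linear spreading-activation planners on this task.
#'
#' @param devalued if `TRUE`, the cheese reward is 2 instead of 4.
#' @param r_cheese_base,r_cheese_deval baseline and devalued cheese rewards.
#' @param r_other reward of the alternative action in state 1.
#' @param r_right rewards of the two actions in state 2 (L, R).
#' @return an `mdp` with `discount = 1`.
#' @export
make_devaluation_maze <- function(devalued = FALSE, r_cheese_base = 4,
                                  r_cheese_deval = 2, r_other = 1,
                                  r_right = c(3, 2)) {
  cheese <- if (devalued) r_cheese_deval else r_cheese_base
  mdp(
    states = c("0", "1", "2", "T"),
    actions = list(`0` = c("L", "R"), `1` = c("L", "R"), `2` = c("L", "R")),
    transitions = list(
      `0` = list(L = c(`1` = 1), R = c(`2` = 1)),
      `1` = list(L = c(T = 1), R = c(T = 1)),
      `2` = list(L = c(T = 1), R = c(T = 1))
    ),
    rewards = list(
      `0` = list(L = 0, R = 0),
      `1` = list(L = cheese, R = r_other),
      `2` = list(L = r_right[1], R = r_right[2])
    ),
    discount = 1, terminal = "T", start = c(`0` = 1)
  )
}
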