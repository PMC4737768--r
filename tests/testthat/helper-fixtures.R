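# Shared fixtures for the test suite. Everything is generated in code.

# A tiny 2-state, 2-action MDP with known structure.
tiny_mdp <- function(discount = 0.9) {
  mdp(
    states = c("a", "b"),
    actions = list(a = c("x", "y"), b = c("x", "y")),
    transitions = list(
      a = list(x = c(a = 0.2, b = 0.8), y = c(a = 1)),
      b = list(x = c(b = 1), y = c(a = 0.5, b = 0.5))
    ),
    rewards = list(a = list(x = 1, y = 0), b = list(x = 0.5, y = 0)),
    discount = discount,
    start = c(a = 1)
  )
}

# Exhaustive evaluation of every deterministic policy (brute-force oracle for
# value iteration on small MDPs).
brute_force_optimal <- function(m) {
  grp <- split(seq_len(nrow(m$sa)), factor(m$sa$state, levels = m$states))
  choices <- lapply(m$states, function(s) actions_of(m, s))
  combos <- expand.grid(choices, stringsAsFactors = FALSE)
  best <- rep(-Inf, length(m$states))
  for (i in seq_len(nrow(combos))) {
    probs <- lapply(seq_along(m$states), function(si) {
      a <- actions_of(m, m$states[si])
      p <- stats::setNames(rep(0, length(a)), a)
      p[combos[i, si]] <- 1
      p
    })
    names(probs) <- m$states
    v <- policy_evaluation(m, structure(probs, class = "sp_policy"))
    best <- pmax(best, v)
  }
  stats::setNames(best, m$states)
}

# Construct a spike_record by hand (for readout tests).
synthetic_spike_record <- function(times_per_neuron, T, n_runs = 1, run = NULL) {
  spikes <- do.call(rbind, lapply(seq_along(times_per_neuron), function(i) {
    tt <- times_per_neuron[[i]]
    if (length(tt) == 0) return(NULL)
    data.frame(run = if (is.null(run)) 1L else run, neuron = i, time = tt)
  }))
  if (is.null(spikes))
    spikes <- data.frame(run = integer(0), neuron = integer(0),
                         time = numeric(0))
  structure(list(spikes = spikes, n_neurons = length(times_per_neuron),
                 n_runs = n_runs, T = T, h = 0.1, seed = 0, network = NULL),
            class = "spike_record")
}
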