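#' Spike-count-difference decision rule
#'
#' Accumulates spike counts per population from the onset of the reward
#' input; a decision is made deterministically in favor of the population
#' with the higher count as soon as the count difference between any two
#' populations reaches the threshold. Trials where no pair ever crosses are
#' flagged rather than dropped.
#'
#' @param record a `spike_record`.
#' @param populations named list of neuron index vectors (>= 2 populations).
#' @param threshold decision threshold `theta_dec` in spikes (> 0).
#' @param t_delta sensory delay: accumulation starts at this time (ms) and
#'   decision times are reported relative to it.
#' @return data.frame with one row per run: `run`, `choice` (population
#'   name, `NA` if never crossed), `decision_time` (ms after accumulation
#'   start), `crossed`.
#' @export
accumulate_and_decide <- function(record, populations, threshold,
                                  t_delta = 0) {
  stopifnot(length(populations) >= 2, threshold > 0, t_delta >= 0)
  pop_names <- names(populations)
  if (is.null(pop_names)) pop_names <- sprintf("pop%d", seq_along(populations))
  pop_of <- integer(record$n_neurons)
  for (p in seq_along(populations)) pop_of[populations[[p]]] <- p
  sp <- record$spikes
  sel <- sp$time >= t_delta & pop_of[sp$neuron] > 0
  sp <- sp[sel, ]
  out <- data.frame(run = seq_len(record$n_runs),
                    choice = NA_character_,
                    decision_time = NA_real_, crossed = FALSE)
  for (rr in seq_len(record$n_runs)) {
    srr <- sp[sp$run == rr, ]
    if (nrow(srr) == 0) next
    ord <- order(srr$time)
    pops <- pop_of[srr$neuron[ord]]
    times <- srr$time[ord]
    counts <- integer(length(populations))
    for (e in seq_along(pops)) {
      counts[pops[e]] <- counts[pops[e]] + 1L
      if (max(counts) - min(counts) >= threshold) {
        win <- which.max(counts)
        out$choice[rr] <- pop_names[win]
        out$decision_time[rr] <- times[e] - t_delta
        out$crossed[rr] <- TRUE
        break
      }
    }
  }
  out
}

#' Populations encoding the actions of one state
#' @param network a discrete `spiking_network`.
#' @param state state identifier.
#' @return named list of neuron indices, one population per action.
#' @export
action_populations <- function(network, state) {
  idx <- which(network$coding$state == state)
  stats::setNames(as.list(idx), network$coding$action[idx])
}

#' Simulated binary-choice experiment
#'
#' For every offer pair, compiles the one-state binary-choice network
#' (reward-input synapses equal to the offered values in units of option B),
#' runs seeded spiking trials with a double-exponential reward input, and
#' applies the spike-count-difference decision rule.
#'
#' @param offers 2-column matrix (or data.frame) of offer values (A, B).
#' @param n_trials trials per offer pair.
#' @param input reward-input profile (default the offer-value double
#'   exponential with `lambda_max = 70` Hz, `t_r = 110`, `t_d = 300`,
#'   `t_delta = 60` ms).
#' @param threshold decision threshold (spikes, default 7).
#' @param k,eta,tau_m,tau_s neuron constants (binary-choice defaults `k = 1`
#'   Hz/mV, `eta = 0`, `tau_m = 25` ms, `tau_s = 2` ms).
#' @param feedforward if `TRUE`, lateral inhibition is removed (control
#'   variant).
#' @param T,h simulation horizon and step (ms).
#' @param seed base RNG seed (each offer pair uses `seed + pair index`).
#' @return data.frame of trials: offers, `value_ratio` (smaller/larger),
#'   `choice` (`"A"`/`"B"`), `chose_better`, `decision_time` (ms after input
#'   onset), `time_from_offer` (ms), `crossed`, `run`, `pair`.
#' @export
run_choice_experiment <- function(offers, n_trials = 100,
                                  input = reward_input_double_exp(70),
                                  threshold = 7, k = 1, eta = 0, tau_m = 25,
                                  tau_s = 2, feedforward = FALSE, T = 1500,
                                  h = 0.1, seed = 1) {
  offers <- as.matrix(offers)
  rows <- list()
  for (i in seq_len(nrow(offers))) {
    vA <- unname(offers[i, 1]); vB <- unname(offers[i, 2])
    m <- make_binary_choice(vA, vB)
    net <- build_discrete_network(m, k = k, eta = eta,
                                  lambda_r = input$lambda_max, V0 = 0,
                                  tau_m = tau_m, tau_s = tau_s)
    if (feedforward) net <- remove_lateral_inhibition(net)
    rec <- simulate_spiking(net, input, T = T, h = h, seed = seed + i,
                            n_runs = n_trials)
    pops <- action_populations(net, "offer")
    dec <- accumulate_and_decide(rec, pops, threshold, t_delta = input$onset)
    better <- if (vA >= vB) "A" else "B"
    rows[[i]] <- data.frame(
      row.names = NULL,
      pair = i, run = dec$run, offer_A = vA, offer_B = vB,
      value_ratio = min(vA, vB) / max(vA, vB),
      choice = dec$choice,
      chose_better = dec$choice == better,
      decision_time = dec$decision_time,
      time_from_offer = dec$decision_time + input$onset,
      crossed = dec$crossed
    )
  }
  do.call(rbind, rows)
}

#' Default offer grid for chronometric/psychometric simulations
#'
#' Offer pairs with the larger value fixed at `v_max` (B units) and value
#' ratios spanning `(0, 1]` on a uniform grid.
#'
#' @param ratios vector of value ratios in `(0, 1]`.
#' @param v_max larger offer value (B units).
#' @return 2-column matrix of (A, B) offers.
#' @export
default_offer_grid <- function(ratios = seq(0.1, 1, by = 0.1), v_max = 2.5) {
  stopifnot(all(ratios > 0), all(ratios <= 1))
  cbind(A = rep(v_max, length(ratios)), B = v_max * ratios)
}

#' Quantile normalization of decision times to a standard normal
#'
#' Estimates the monotone transform that maps the pooled decision-time
#' distribution onto a standard normal (normal scores), together with the
#' best-fitting logarithmic transform `a + b * log(t)` for comparison.
#'
#' @param times vector of decision times (ms; `NA`s allowed and ignored).
#' @return list with `normalized` (per input element), `transform`
#'   (interpolating function time -> z), `log_fit` (lm of z on `log(t)`),
#'   and `log_r2`.
#' @export
normalize_decision_times <- function(times) {
  ok <- is.finite(times)
  t_ok <- times[ok]
  n <- length(t_ok)
  if (n < 3) stop("need at least 3 finite decision times")
  z <- stats::qnorm((rank(t_ok, ties.method = "average") - 0.5) / n)
  normalized <- rep(NA_real_, length(times))
  normalized[ok] <- z
  ord <- order(t_ok)
  transform <- stats::approxfun(t_ok[ord], z[ord], rule = 2, ties = "ordered")
  log_fit <- stats::lm(z ~ log(t_ok))
  list(normalized = normalized, transform = transform, log_fit = log_fit,
       log_r2 = summary(log_fit)$r.squared)
}

#' Chronometric regression of normalized decision times on value ratio
#'
#' Least-squares fit of the per-ratio mean normalized decision time on the
#' value ratio. The slope's standard error is obtained by resampling trials
#' at the seed (run) level.
#'
#' @param normalized normalized decision times (one per trial).
#' @param ratios value ratio per trial.
#' @param runs run/seed identifier per trial (for the resampled SE);
#'   `NULL` for plain trial bootstrap.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return list with `slope`, `intercept`, `r2` (on per-ratio means),
#'   `slope_se`, `means` (per-ratio data.frame), `residuals`.
#' @export
chronometric_regression <- function(normalized, ratios, runs = NULL,
                                    n_boot = 200, seed = 1) {
  ok <- is.finite(normalized)
  d <- data.frame(z = normalized[ok], ratio = ratios[ok],
                  run = if (is.null(runs)) seq_len(sum(ok)) else runs[ok])
  means <- do.call(rbind, lapply(split(d, d$ratio), function(g)
    data.frame(ratio = g$ratio[1], z = mean(g$z), n = nrow(g))))
  fit <- stats::lm(z ~ ratio, data = means)
  slope <- unname(stats::coef(fit)[2])
  set.seed(seed)
  ids <- unique(d$run)
  boots <- vapply(seq_len(n_boot), function(b) {
    take <- sample(ids, length(ids), replace = TRUE)
    db <- do.call(rbind, lapply(take, function(id) d[d$run == id, ]))
    mb <- vapply(split(db$z, db$ratio), mean, numeric(1))
    rb <- as.numeric(names(mb))
    if (length(mb) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(mb ~ rb))[2])
  }, numeric(1))
  list(slope = slope, intercept = unname(stats::coef(fit)[1]),
       r2 = summary(fit)$r.squared,
       slope_se = stats::sd(boots, na.rm = TRUE),
       means = means, residuals = stats::residuals(fit))
}

#' Reaction times in sequential movement chains
#'
#' For each requested NRM (number of remaining movements), simulates the
#' chain network with the raised-Gaussian reward input (scaled up for
#' behavioral/population readout) and applies the decision rule between the
#' action populations of the state with that NRM, with the temporally
#' discounted threshold `theta_dec = theta_0 * gamma^NRM`.
#'
#' @param m a chain task from [make_nrm_chain()] or
#'   [make_multireward_chain()].
#' @param nrm_values NRM conditions to simulate (states `"n<k>"` must exist).
#' @param theta_0 base decision threshold (default 70).
#' @param n_trials trials per NRM.
#' @param input single-neuron-scale input profile (default raised Gaussian
#'   `lambda_base = 10`, `lambda_max = 75` Hz, `t_p = 250`, `tau = 60` ms).
#' @param behavior_scale factor applied to the input rates for the
#'   behavioral readout (default 10).
#' @param k,eta,tau_m,tau_s neuron constants (sequential-task defaults
#'   `eta = 3` mV, `tau_m = 50` ms).
#' @param T,h horizon and step (ms).
#' @param seed base RNG seed.
#' @return data.frame per NRM: `nrm`, `threshold`, `mean_rt`, `sem_rt`,
#'   `p_correct`, `n_crossed`; attribute `"trials"` holds the trial table.
#' @export
sequential_reaction_times <- function(m, nrm_values, theta_0 = 70,
                                      n_trials = 100,
                                      input = reward_input_raised_gaussian(10, 75),
                                      behavior_scale = 10, k = 1, eta = 3,
                                      tau_m = 50, tau_s = 2, T = 1500,
                                      h = 0.1, seed = 1) {
  net <- build_discrete_network(m, k = k, eta = eta, lambda_r = 400, V0 = 0,
                                tau_m = tau_m, tau_s = tau_s)
  inp <- scale_input(input, behavior_scale)
  rows <- list(); trials <- list()
  for (j in seq_along(nrm_values)) {
    nrm <- nrm_values[j]
    state <- sprintf("n%d", nrm)
    if (!state %in% m$states) stop("no state with NRM ", nrm)
    thr <- theta_0 * m$discount^nrm
    rec <- simulate_spiking(net, inp, T = T, h = h, seed = seed + j,
                            n_runs = n_trials)
    pops <- action_populations(net, state)
    dec <- accumulate_and_decide(rec, pops, thr, t_delta = inp$onset)
    dec$nrm <- nrm
    trials[[j]] <- dec
    rt <- dec$decision_time[dec$crossed]
    rows[[j]] <- data.frame(
      nrm = nrm, threshold = thr,
      mean_rt = mean(rt), sem_rt = stats::sd(rt) / sqrt(length(rt)),
      p_correct = mean(dec$choice[dec$crossed] == "go"),
      n_crossed = sum(dec$crossed)
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "trials") <- do.call(rbind, trials)
  out
}
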