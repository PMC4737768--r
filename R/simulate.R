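#' Mean-field rate dynamics
#'
#' Forward-Euler integration of the rate reduction of the spiking network,
#' `tau_m * du/dt = -u + W %*% lambda - eta * lambda + I_ext(t)`,
#' with `lambda = k * [u - theta]_+` and
#' `I_ext_i(t) = w_r_i * input_rate(t)`. Deterministic given its inputs; the
#' fixed point of the Euler map coincides with the fixed point of the ODE for
#' any stable step size.
#'
#' @param network a `spiking_network`.
#' @param input a `reward_input` profile (rate of the reward Poisson unit; in
#'   the rate model its expectation enters directly).
#' @param T simulation horizon (ms).
#' @param h integration step (ms, default 0.05; must resolve `tau_s` although
#'   the rate model itself only involves `tau_m`).
#' @param init_rates initial firing rates (Hz), scalar or per neuron.
#' @param record_dt sampling interval of the returned trace (ms).
#' @return an object of class `rate_trace`: `times` (ms), `rates`
#'   (`n_times x n_neurons`, Hz), `u` (membrane potentials, mV), plus network
#'   metadata for decoding.
#' @export
simulate_rate <- function(network, input, T, h = 0.05, init_rates = 0,
                          record_dt = 1) {
  stopifnot(T > 0, h > 0)
  n <- network$n_neurons
  lam0 <- rep(init_rates, length.out = n)
  u <- network$theta + lam0 / network$k
  W <- network$W
  w_r <- network$w_r
  theta <- network$theta
  k <- network$k; eta <- network$eta; tau_m <- network$tau_m

  n_steps <- ceiling(T / h)
  every <- max(1L, round(record_dt / h))
  n_rec <- floor(n_steps / every) + 1L
  times <- numeric(n_rec); rates <- matrix(0, n_rec, n); us <- matrix(0, n_rec, n)
  lam <- k * pmax(u - theta, 0)
  times[1] <- 0; rates[1, ] <- lam; us[1, ] <- u
  rec <- 1L
  for (step in seq_len(n_steps)) {
    t <- (step - 1) * h
    drive <- as.numeric(W %*% lam) - eta * lam + w_r * input_rate(input, t)
    u <- u + (h / tau_m) * (-u + drive)
    if (any(abs(u) > 1e6)) stop("rate dynamics diverged (|u| > 1e6 mV)")
    lam <- k * pmax(u - theta, 0)
    if (step %% every == 0L) {
      rec <- rec + 1L
      times[rec] <- step * h; rates[rec, ] <- lam; us[rec, ] <- u
    }
  }
  structure(list(times = times[seq_len(rec)],
                 rates = rates[seq_len(rec), , drop = FALSE],
                 u = us[seq_len(rec), , drop = FALSE],
                 network = network),
            class = "rate_trace")
}

#' @export
print.rate_trace <- function(x, ...) {
  cat("<rate_trace>", length(x$times), "samples x", ncol(x$rates),
      "neurons, T =", max(x$times), "ms\n")
  invisible(x)
}

#' Steady-state firing rates of the rate model
#'
#' Integrates the rate dynamics under a constant reward input until the
#' rates stop changing (sup-norm change below `tol` over a 10 ms window), up
#' to `max_T`.
#'
#' @param network a `spiking_network`.
#' @param rate constant reward-input rate (Hz; default the network's nominal
#'   `lambda_r`).
#' @param h integration step (ms). The Euler fixed point is independent of
#'   `h`, so a coarse (but stable) step is fine for steady-state finding.
#' @param tol target accuracy of the returned rates (Hz). Convergence is
#'   declared from the geometric tail of the per-chunk rate changes.
#' @param max_T time cap (ms).
#' @param init_rates initial rates (Hz).
#' @param polish if `TRUE`, refine the integrator's end state by an
#'   active-set solve of the piecewise-linear fixed-point equations
#'   (`c * lambda_A = W_AA lambda_A + I_A - theta_A` on the active set,
#'   adding/dropping neurons until all rates are positive and all inactive
#'   drives subthreshold). This resolves winner-take-all competitions whose
#'   action-value gaps are too small for the dynamics to settle in
#'   reasonable time; it is skipped (with the integrator state returned)
#'   when the active-set system is singular, which happens exactly for tied
#'   actions, whose rate split is genuinely history-dependent.
#' @return named list `rates` (steady-state rates, Hz), `converged`, `T_used`.
#' @export
steady_state_rates <- function(network, rate = network$lambda_r, h = 0.05,
                               tol = 1e-6, max_T = 5000, init_rates = 0,
                               polish = FALSE) {
  n <- network$n_neurons
  lam <- rep(init_rates, length.out = n)
  u <- network$theta + lam / network$k
  W <- network$W; w_r <- network$w_r; theta <- network$theta
  k <- network$k; eta <- network$eta; tau_m <- network$tau_m
  I <- w_r * rate
  chunk <- round(10 / h)
  t_used <- 0
  delta_old <- Inf
  repeat {
    lam_old <- lam
    for (step in seq_len(chunk)) {
      drive <- as.numeric(W %*% lam) - eta * lam + I
      u <- u + (h / tau_m) * (-u + drive)
      lam <- k * pmax(u - theta, 0)
    }
    if (any(abs(u) > 1e6)) stop("rate dynamics diverged (|u| > 1e6 mV)")
    t_used <- t_used + chunk * h
    delta <- max(abs(lam - lam_old))
    # Estimate the remaining distance to the fixed point from the geometric
    # decay of successive chunk-to-chunk changes.
    rho <- delta / delta_old
    tail <- if (is.finite(rho) && rho < 1) delta * rho / (1 - rho) else Inf
    done <- delta == 0 || max(delta, tail) < tol
    if (done || t_used >= max_T) {
      if (polish) {
        pol <- active_set_polish(network, rate, lam)
        if (!is.null(pol)) return(list(rates = pol, converged = TRUE,
                                       T_used = t_used))
      }
      return(list(rates = lam, converged = done, T_used = t_used))
    }
    delta_old <- delta
  }
}

# Exact fixed point of the rectified-linear rate equations by active-set
# iteration, seeded with the integrator's active set. Within one state the
# difference of two active neurons is an exactly neutral direction of the
# active linear dynamics (winner-take-all acts only through the
# rectification boundary), so the active set is first reduced to one neuron
# per state -- the current-rate leader -- and wrong leaders are corrected by
# swap moves when their dropped competitor's drive turns out suprathreshold.
# Returns NULL if the iteration fails to settle (the integrator state is
# then used as is).
active_set_polish <- function(network, rate, lam, max_iter = 200) {
  W <- as.matrix(network$W)
  b_full <- network$w_r * rate - network$theta
  cc <- 1 / network$k + network$eta
  state_of <- network$coding$state
  act <- lam > max(lam) * 1e-9
  if (!any(act)) return(lam * 0)
  # one active neuron per state: keep the leader
  for (s in unique(state_of[act])) {
    grp <- which(state_of == s & act)
    if (length(grp) > 1) act[setdiff(grp, grp[which.max(lam[grp])])] <- FALSE
  }
  for (it in seq_len(max_iter)) {
    M <- diag(cc, sum(act)) - W[act, act, drop = FALSE]
    sol <- tryCatch(solve(M, b_full[act]), error = function(e) NULL)
    if (is.null(sol) || any(!is.finite(sol))) return(NULL)
    if (any(sol < 0)) {
      act[which(act)[which.min(sol)]] <- FALSE
      if (!any(act)) return(NULL)
      next
    }
    lam_new <- numeric(length(lam))
    lam_new[act] <- sol
    # inactive neurons must be at or below threshold
    drive <- as.numeric(W[, act, drop = FALSE] %*% sol) + b_full
    viol <- !act & drive > 1e-9 * max(abs(drive))
    if (!any(viol)) return(lam_new)
    add <- which(!act)[which.max(drive[!act])]
    swap_out <- which(act & state_of == state_of[add])
    act[swap_out] <- FALSE  # the state's current leader loses its slot
    act[add] <- TRUE
  }
  NULL
}

#' Stochastic spiking dynamics
#'
#' Simulates the full spike-response network: membrane potentials integrate
#' synaptically filtered presynaptic spike trains (exponential kernel
#' `epsilon(t) = (1/tau_s) exp(-t/tau_s)`, unit time-integral), each neuron's
#' own spike triggers an instantaneous afterhyperpolarizing current pulse of
#' magnitude `eta`, and spikes are emitted as an inhomogeneous Poisson
#' process with instantaneous rate `k * [u - theta]_+` (at most one spike per
#' neuron per step; `h` must keep `lambda * h` small). The reward input is an
#' independent Poisson train with rate `input_rate(t)` through synapses
#' `w_r`, shared by all neurons within a run. Multiple trials (`n_runs`) are
#' simulated in one vectorized pass with independent noise.
#'
#' @param network a `spiking_network`.
#' @param input a `reward_input` profile.
#' @param T horizon (ms).
#' @param h step (ms, default 0.1).
#' @param init_rates initial rates (Hz), scalar or per neuron.
#' @param seed RNG seed.
#' @param n_runs number of independent trials.
#' @return an object of class `spike_record`: `spikes` data.frame
#'   (`run`, `neuron`, `time`), `n_neurons`, `n_runs`, `T`, `h`, `seed`, and
#'   network metadata.
#' @export
simulate_spiking <- function(network, input, T, h = 0.1, init_rates = 0,
                             seed = 1, n_runs = 1) {
  stopifnot(T > 0, h > 0, h <= 0.5)
  set.seed(seed)
  n <- network$n_neurons
  lam0 <- rep(init_rates, length.out = n)
  u <- matrix(network$theta + lam0 / network$k, n, n_runs)
  s_tr <- matrix(0, n, n_runs)        # recurrent synaptic traces (Hz)
  s_r <- numeric(n_runs)              # reward-input trace (Hz)
  W <- network$W; w_r <- network$w_r; theta <- network$theta
  k <- network$k; tau_m <- network$tau_m; tau_s <- network$tau_s
  ahp <- 1000 * network$eta / tau_m   # mV decrement per own spike
  dec <- exp(-h / tau_s)
  kick <- 1000 / tau_s                # trace increment per spike (Hz)

  n_steps <- ceiling(T / h)
  spk_step <- vector("list", n_steps)
  for (step in seq_len(n_steps)) {
    t <- (step - 1) * h
    drive <- as.matrix(W %*% s_tr) + outer(w_r, s_r)
    u <- u + (h / tau_m) * (-u + drive)
    if (any(abs(u) > 1e6)) stop("spiking dynamics diverged (|u| > 1e6 mV)")
    lam <- k * pmax(u - theta, 0)
    p <- pmin(lam * (h / 1000), 1)
    spk <- matrix(stats::runif(n * n_runs) < p, n, n_runs)
    u <- u - ahp * spk
    s_tr <- s_tr * dec + kick * spk
    r_rate <- input_rate(input, t)
    r_spk <- stats::runif(n_runs) < pmin(r_rate * (h / 1000), 1)
    s_r <- s_r * dec + kick * r_spk
    if (any(spk)) {
      idx <- which(spk)
      spk_step[[step]] <- cbind(run = ((idx - 1L) %/% n) + 1L,
                                neuron = ((idx - 1L) %% n) + 1L,
                                step = step)
    }
  }
  allspk <- do.call(rbind, spk_step)
  spikes <- if (is.null(allspk)) {
    data.frame(run = integer(0), neuron = integer(0), time = numeric(0))
  } else {
    data.frame(run = allspk[, "run"], neuron = allspk[, "neuron"],
               time = allspk[, "step"] * h)
  }
  structure(list(spikes = spikes, n_neurons = n, n_runs = n_runs, T = T,
                 h = h, seed = seed, network = network),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat("<spike_record>", nrow(x$spikes), "spikes,", x$n_neurons, "neurons x",
      x$n_runs, "runs, T =", x$T, "ms\n")
  invisible(x)
}

#' Spike counts per neuron in a time window
#'
#' @param record a `spike_record`.
#' @param t_end end of the counting window (ms).
#' @param t_start start of the window (ms, default 0; spikes with
#'   `t_start < time <= t_end` are counted).
#' @return matrix `n_neurons x n_runs` of counts.
#' @export
spike_counts <- function(record, t_end = record$T, t_start = 0) {
  sp <- record$spikes
  sel <- sp$time > t_start & sp$time <= t_end
  counts <- matrix(0, record$n_neurons, record$n_runs)
  if (any(sel)) {
    tab <- table(factor(sp$neuron[sel], levels = seq_len(record$n_neurons)),
                 factor(sp$run[sel], levels = seq_len(record$n_runs)))
    counts <- matrix(as.numeric(tab), record$n_neurons, record$n_runs)
  }
  counts
}

#' Smoothed firing-rate estimate from spike trains
#'
#' Bins the spikes and convolves with either a Gaussian kernel (default
#' `sigma = 40` ms) or an exponential moving average (`tau = 40` ms),
#' averaging across runs.
#'
#' @param record a `spike_record`.
#' @param kernel_sigma Gaussian kernel width / EMA time constant (ms).
#' @param dt sampling step of the estimate (ms).
#' @param mode `"gaussian"` or `"ema"`.
#' @return a `rate_trace` (trial-averaged; `u` is `NULL`).
#' @export
smooth_rates <- function(record, kernel_sigma = 40, dt = 1,
                         mode = c("gaussian", "ema")) {
  mode <- match.arg(mode)
  edges <- seq(0, record$T + dt, by = dt)
  mids <- edges[-1] - dt / 2
  n_bins <- length(mids)
  counts <- matrix(0, n_bins, record$n_neurons)
  sp <- record$spikes
  if (nrow(sp) > 0) {
    b <- pmin(pmax(ceiling(sp$time / dt), 1L), n_bins)
    tab <- table(factor(b, levels = seq_len(n_bins)),
                 factor(sp$neuron, levels = seq_len(record$n_neurons)))
    counts <- matrix(as.numeric(tab), n_bins, record$n_neurons)
  }
  # counts -> trial-averaged rate in Hz
  rate_raw <- counts / record$n_runs / (dt / 1000)
  if (mode == "gaussian") {
    half <- ceiling(4 * kernel_sigma / dt)
    kt <- (-half:half) * dt
    kern <- exp(-kt^2 / (2 * kernel_sigma^2))
    kern <- kern / sum(kern)
    sm <- apply(rate_raw, 2, function(x)
      stats::filter(c(rep(0, half), x, rep(0, half)), kern,
                    sides = 2)[half + seq_len(n_bins)])
  } else {
    a <- dt / kernel_sigma
    sm <- apply(rate_raw, 2, function(x) {
      y <- numeric(length(x)); acc <- 0
      for (i in seq_along(x)) { acc <- acc + a * (x[i] - acc); y[i] <- acc }
      y
    })
  }
  structure(list(times = mids, rates = sm, u = NULL, network = record$network),
            class = "rate_trace")
}

#' Write a spike record as two-column text
#' @param record a `spike_record`.
#' @param path output file (`neuron_id time_ms` per line; a third column with
#'   the run index is added when `n_runs > 1`).
#' @return `path`, invisibly.
#' @export
write_spikes <- function(record, path) {
  df <- record$spikes[order(record$spikes$run, record$spikes$time), ]
  out <- if (record$n_runs > 1) df[, c("neuron", "time", "run")]
         else df[, c("neuron", "time")]
  utils::write.table(out, path, row.names = FALSE, col.names = TRUE,
                     quote = FALSE, sep = "\t")
  invisible(path)
}

#' Write a rate trace as a delimited table
#' @param trace a `rate_trace`.
#' @param path output file (column `time_ms` + one column per neuron).
#' @return `path`, invisibly.
#' @export
write_rates <- function(trace, path) {
  df <- data.frame(time_ms = trace$times, trace$rates)
  names(df)[-1] <- sprintf("n%d", seq_len(ncol(trace$rates)))
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
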