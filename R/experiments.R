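#' Benchmark-task planning performance versus planning time
#'
#' Compiles the task into a network with preset (true-environment) weights,
#' runs seeded spiking trials under the constant reward input, and scores the
#' policy decoded from cumulative spike counts in `[0, t]` for each `t`.
#'
#' @param task `"blackjack"`, `"maze"`, or `"pendulum"`.
#' @param time_grid planning times (ms).
#' @param n_seeds number of independent spiking runs.
#' @param seed base RNG seed.
#' @param h integration step (ms; the pendulum uses a finer default because
#'   of its high population rates).
#' @param fa_n_nodes quadrature nodes for the pendulum weight integrals.
#' @return data.frame (`t`, `run`, `performance`) with a per-`t` summary in
#'   the `"summary"` attribute (as in [performance_vs_time()]).
#' @export
benchmark_performance <- function(task = c("blackjack", "maze", "pendulum"),
                                  time_grid = seq(25, 300, by = 25),
                                  n_seeds = 5, seed = 1, h = NULL,
                                  fa_n_nodes = 2^16) {
  task <- match.arg(task)
  input <- reward_input_constant(400)
  if (task %in% c("blackjack", "maze")) {
    m <- if (task == "blackjack") make_blackjack() else make_flag_maze()
    net <- build_discrete_network(m, k = 1, eta = 20, lambda_r = 400,
                                  tau_m = 20, tau_s = 2)
    if (is.null(h)) h <- 0.1
    rec <- simulate_spiking(net, input, T = max(time_grid), h = h,
                            seed = seed, n_runs = n_seeds)
    return(performance_vs_time(rec, m, time_grid))
  }
  # Pendulum: distributed basis-function code.
  ptask <- pendulum_task()
  basis <- make_basis_grid(list(c(-pi, pi), c(-2 * pi, 2 * pi)), pi / 8,
                           actions = as.character(ptask$torques),
                           periodic = c(TRUE, FALSE))
  net <- build_fa_network(ptask, basis, k = 1, eta = 20, lambda_r = 400,
                          tau_m = 20, tau_s = 2, gamma = 0.98,
                          n_mc = fa_n_nodes, method = "lattice")
  if (is.null(h)) h <- 0.02
  rec <- simulate_spiking(net, input, T = max(time_grid), h = h,
                          seed = seed, n_runs = n_seeds)
  oracle <- NULL
  rows <- list()
  for (t in time_grid) {
    counts <- spike_counts(rec, t_end = t)
    for (run in seq_len(n_seeds)) {
      polfn <- fa_extract_policy(counts[, run], basis)
      perf <- pendulum_performance(ptask, polfn, oracle = oracle)
      oracle <- attr(perf, "oracle")
      rows[[length(rows) + 1]] <- data.frame(t = t, run = run,
                                             performance = as.numeric(perf))
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

#' First planning time reaching a performance level
#' @param perf_df output of [benchmark_performance()] /
#'   [performance_vs_time()].
#' @param level performance level (default 0.95).
#' @param stat `"median"` or `"mean"` across runs.
#' @return first `t` (ms) whose summary statistic reaches `level` (`Inf` if
#'   never).
#' @export
time_to_performance <- function(perf_df, level = 0.95,
                                stat = c("median", "mean")) {
  stat <- match.arg(stat)
  s <- attr(perf_df, "summary")
  hit <- s$t[s[[stat]] >= level]
  if (length(hit) == 0) Inf else min(hit)
}

# --- experiment configs ----------------------------------------------------

experiment_ids <- c("fig1c", "fig1d", "fig2", "fig3b", "fig3c", "fig4",
                    "fig5", "fig6", "fig7", "fig8", "benchmarks")

#' Default configuration of a reproduction experiment
#'
#' Returns the full parameter block for one of the built-in experiments:
#' neuron constants, reward-input time course, decision parameters, run
#' counts, and seeds, following the reference simulation settings (benchmark
#' planning: `k = 1` Hz/mV, `eta = 20` mV, `tau_m = 20` ms, `lambda_r = 400`
#' Hz; binary choice: `eta = 0`, `tau_m = 25` ms with the double-exponential
#' offer input; sequential tasks: `eta = 3` mV, `tau_m = 50` ms, `gamma =
#' 0.7` with the raised-Gaussian input).
#'
#' @param experiment experiment identifier (see `Details`).
#' @return named list of defaults.
#' @export
default_experiment_config <- function(experiment) {
  experiment <- match.arg(experiment, experiment_ids)
  base <- list(experiment = experiment, seed = 1, out_dir = NULL,
               tau_s = 2, k = 1, h = 0.1)
  extra <- switch(experiment,
    fig1c = ,
    benchmarks = list(eta = 20, tau_m = 20, lambda_r = 400,
                      n_runs = 5, time_grid = seq(25, 300, by = 25),
                      tasks = c("blackjack", "maze", "pendulum")),
    fig1d = list(eta = 20, tau_m = 20, lambda_r = 400, n_runs = 3,
                 n_trials = 40, alphas = c(blackjack = 0.01, maze = 0.05),
                 tasks = c("blackjack", "maze")),
    fig2 = list(eta = 20, tau_m = 20, lambda_r = 400, T = 100,
                n_runs = 1),
    fig3b = list(eta = 0, tau_m = 25,
                 input = list(kind = "double_exponential", lambda_max = 2.6,
                              t_r = 110, t_d = 300, t_delta = 60),
                 baseline_rate = 5.2, n_runs = 30, T = 1000,
                 offers = list(low = c(1.2, 2.4), medium = c(2.2, 2.2),
                               high = c(3.4, 1.4))),
    fig3c = list(eta = 0, tau_m = 25,
                 input = list(kind = "raised_gaussian", lambda_base = 4.5,
                              lambda_max = 27.9, t_p = 95, tau = 30),
                 baseline_rate = 16.5, n_runs = 30, T = 1500,
                 offers = list(large = c(2, 0), small = c(1, 0))),
    fig4 = list(eta = 0, tau_m = 25,
                input = list(kind = "double_exponential", lambda_max = 1.6,
                             t_r = 110, t_d = 300, t_delta = 60),
                lambda_max_B = 5.4, relative_value = 2.2, n_runs = 30,
                T = 1000, offer_range = 0:10),
    fig5 = list(eta = 0, tau_m = 25,
                input = list(kind = "double_exponential", lambda_max = 70,
                             t_r = 110, t_d = 300, t_delta = 60),
                theta_dec = 7, n_runs = 100, T = 1500,
                ratios = seq(0.1, 1, by = 0.1), v_max = 2.5),
    fig6 = list(eta = 3, tau_m = 50, gamma = 0.7,
                input = list(kind = "raised_gaussian", lambda_base = 10,
                             lambda_max = 75, t_p = 250, tau = 60),
                theta_0 = 70, behavior_scale = 10, n_runs = 30,
                n_trials = 100, n_steps = 5, T = 1500),
    fig7 = list(eta = 3, tau_m = 50, gamma = 0.7,
                input = list(kind = "raised_gaussian", lambda_base = 10,
                             lambda_max = 75, t_p = 250, tau = 60),
                theta_0 = 70, behavior_scale = 10, n_runs = 30,
                n_trials = 100, n_steps = 8, intermediate_at = 4,
                r_mid = 1, T = 1500),
    fig8 = list(eta = 3, tau_m = 50,
                input = list(kind = "raised_gaussian", lambda_base = 10,
                             lambda_max = 75, t_p = 250, tau = 60),
                theta_0 = 7, behavior_scale = 10, n_trials = 100,
                T = 1500, gamma_spread = 1.2)
  )
  utils::modifyList(base, extra)
}

config_input <- function(spec) {
  if (inherits(spec, "reward_input")) return(spec)
  switch(spec$kind,
    constant = reward_input_constant(spec$rate),
    double_exponential = reward_input_double_exp(spec$lambda_max, spec$t_r,
                                                 spec$t_d, spec$t_delta),
    raised_gaussian = reward_input_raised_gaussian(spec$lambda_base,
                                                   spec$lambda_max,
                                                   spec$t_p, spec$tau),
    stop("unknown input kind: ", spec$kind)
  )
}

#' Validate (and complete) an experiment configuration
#'
#' Reads a YAML or JSON configuration file, fills in the experiment's
#' defaults for missing fields, and checks the invariants (rates
#' non-negative, time constants positive, known experiment id). Unknown
#' fields are reported as errors naming the field.
#'
#' @param path configuration file (YAML if the `yaml` package is installed
#'   and the extension is `.yml`/`.yaml`, otherwise JSON). An empty file
#'   yields the full default configuration for the `experiment` field, which
#'   then must be supplied via `experiment`.
#' @param experiment fallback experiment id when the file does not set one.
#' @return the completed configuration list (invisibly echoes it).
#' @export
validate_config <- function(path = NULL, experiment = NULL) {
  user <- list()
  if (!is.null(path) && file.exists(path) &&
      nzchar(trimws(paste(readLines(path, warn = FALSE), collapse = "")))) {
    user <- if (grepl("\\.ya?ml$", path) &&
                requireNamespace("yaml", quietly = TRUE)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
    if (is.null(user)) user <- list()
  }
  exp_id <- user$experiment %||% experiment
  if (is.null(exp_id)) stop("config field `experiment` is missing")
  cfg <- default_experiment_config(exp_id)
  unknown <- setdiff(names(user), c(names(cfg), "experiment"))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, user)
  check_pos <- function(field) {
    if (!is.null(cfg[[field]]) && (!is.numeric(cfg[[field]]) || any(cfg[[field]] <= 0)))
      stop("config field `", field, "` must be positive")
  }
  for (f in intersect(names(cfg), c("tau_s", "tau_m", "k", "h", "T",
                                    "n_runs", "n_trials", "theta_dec",
                                    "theta_0", "gamma_spread")))
    check_pos(f)
  if (!is.null(cfg$eta) && cfg$eta < 0) stop("config field `eta` must be >= 0")
  if (!is.null(cfg$input)) {
    rates <- unlist(cfg$input[intersect(names(cfg$input),
                                        c("rate", "lambda_max", "lambda_base"))])
    if (any(rates < 0)) stop("config input rates must be >= 0")
    config_input(cfg$input)  # errors on malformed blocks
  }
  invisible(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, dir, name) {
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run a reproduction experiment
#'
#' Executes one of the built-in experiments deterministically for the given
#' seed and writes its result tables plus a manifest (configuration, seed,
#' package version) to the output directory.
#'
#' @param config configuration list from [validate_config()] /
#'   [default_experiment_config()] (possibly modified), or an experiment id
#'   string.
#' @param out_dir output directory (created if needed; overrides
#'   `config$out_dir`).
#' @return named list of the result tables (invisibly); files are written
#'   when an output directory is set.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- default_experiment_config(config)
  cfg <- config
  out_dir <- out_dir %||% cfg$out_dir
  results <- switch(cfg$experiment,
    fig1c = ,
    benchmarks = exp_benchmarks(cfg),
    fig1d = exp_learning(cfg),
    fig2 = exp_two_step(cfg),
    fig3b = exp_offer_timecourse(cfg),
    fig3c = exp_offer_timecourse(cfg),
    fig4 = exp_value_tuning(cfg),
    fig5 = exp_choice_behavior(cfg),
    fig6 = exp_sequential(cfg),
    fig7 = exp_sequential(cfg),
    fig8 = exp_devaluation(cfg),
    stop("unknown experiment id: ", cfg$experiment)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(results)) write_tsv(results[[nm]], out_dir,
                                         paste0(nm, ".tsv"))
    manifest <- list(experiment = cfg$experiment, seed = cfg$seed,
                     config = cfg,
                     package_version = as.character(utils::packageVersion("spikeplan")),
                     written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(results)
}

exp_benchmarks <- function(cfg) {
  out <- list()
  t95 <- numeric(length(cfg$tasks))
  for (i in seq_along(cfg$tasks)) {
    task <- cfg$tasks[i]
    perf <- benchmark_performance(task, time_grid = cfg$time_grid,
                                  n_seeds = cfg$n_runs, seed = cfg$seed)
    s <- attr(perf, "summary")
    s$task <- task
    out[[paste0("performance_", task)]] <- s
    t95[i] <- time_to_performance(perf)
  }
  out$time_to_95 <- data.frame(task = cfg$tasks, t_ms = t95)
  out
}

exp_learning <- function(cfg) {
  out <- list()
  for (task in cfg$tasks) {
    m <- if (task == "blackjack") make_blackjack() else make_flag_maze()
    alpha <- cfg$alphas[[task]]
    curves <- lapply(seq_len(cfg$n_runs), function(r)
      cbind(parallel_sampling_train(m, alpha, cfg$n_trials,
                                    seed = cfg$seed + r)$curve, run = r))
    cv <- do.call(rbind, curves)
    agg <- do.call(rbind, lapply(split(cv, cv$trial), function(d)
      data.frame(trial = d$trial[1], performance_mean = mean(d$performance),
                 ci_low = min(d$performance), ci_high = max(d$performance))))
    agg$task <- task
    out[[paste0("learning_", task)]] <- agg
  }
  out
}

exp_two_step <- function(cfg) {
  m <- make_two_step()
  net <- build_discrete_network(m, k = cfg$k, eta = cfg$eta,
                                lambda_r = cfg$lambda_r, tau_m = cfg$tau_m,
                                tau_s = cfg$tau_s)
  tr <- simulate_rate(net, reward_input_constant(cfg$lambda_r), T = cfg$T,
                      h = 0.05, record_dt = 0.5)
  V <- decode_value_trace(tr)
  rates <- data.frame(time_ms = tr$times, tr$rates)
  names(rates)[-1] <- paste(net$coding$state, net$coding$action, sep = "_")
  values <- data.frame(time_ms = tr$times, V, check.names = FALSE)
  rec <- simulate_spiking(net, reward_input_constant(cfg$lambda_r),
                          T = cfg$T, h = cfg$h, seed = cfg$seed)
  list(rates = rates, values = values, spikes = rec$spikes,
       optimal = data.frame(state = names(value_iteration(m)$values),
                            value = as.numeric(value_iteration(m)$values)))
}

exp_offer_timecourse <- function(cfg) {
  input <- config_input(cfg$input)
  out <- list()
  for (nm in names(cfg$offers)) {
    vv <- cfg$offers[[nm]]
    m <- make_binary_choice(vv[1], vv[2])
    lam_scale <- max(input_rate(input, seq(0, cfg$T, by = 1)))
    net <- build_discrete_network(m, k = cfg$k, eta = cfg$eta,
                                  lambda_r = lam_scale, V0 = 0,
                                  tau_m = cfg$tau_m, tau_s = cfg$tau_s)
    rec <- simulate_spiking(net, input, T = cfg$T, h = cfg$h,
                            seed = cfg$seed, n_runs = cfg$n_runs)
    sm <- smooth_rates(rec, kernel_sigma = 40)
    df <- data.frame(time_ms = sm$times,
                     rate_A = sm$rates[, 1] + cfg$baseline_rate,
                     rate_B = sm$rates[, 2] + cfg$baseline_rate,
                     input_hz = input_rate(input, sm$times),
                     offer = nm)
    out[[paste0("rates_", nm)]] <- df
  }
  out
}

exp_value_tuning <- function(cfg) {
  input <- config_input(cfg$input)
  rows_offer <- list(); rows_chosen <- list()
  for (vB in cfg$offer_range) {
    vA <- cfg$relative_value  # one unit of A, in B units
    m <- make_binary_choice(vA, vB)
    net <- build_discrete_network(m, k = cfg$k, eta = cfg$eta,
                                  lambda_r = input$lambda_max, V0 = 0,
                                  tau_m = cfg$tau_m, tau_s = cfg$tau_s)
    rec <- simulate_spiking(net, input, T = cfg$T, h = cfg$h,
                            seed = cfg$seed + vB, n_runs = cfg$n_runs)
    counts <- spike_counts(rec, t_end = cfg$T)
    mean_rates <- rowMeans(counts) / (cfg$T / 1000)
    rows_offer[[length(rows_offer) + 1]] <-
      data.frame(offer_B = vB, rate_B_cell = mean_rates[2])
    rows_chosen[[length(rows_chosen) + 1]] <-
      data.frame(offer_B = vB, rate_chosen_value = sum(mean_rates[1:2]) *
                   cfg$lambda_max_B / input$lambda_max)
  }
  list(offer_value_cell = do.call(rbind, rows_offer),
       chosen_value_cell = do.call(rbind, rows_chosen))
}

exp_choice_behavior <- function(cfg) {
  input <- config_input(cfg$input)
  offers <- default_offer_grid(cfg$ratios, cfg$v_max)
  trials <- run_choice_experiment(offers, n_trials = cfg$n_runs,
                                  input = input, threshold = cfg$theta_dec,
                                  k = cfg$k, eta = cfg$eta,
                                  tau_m = cfg$tau_m, tau_s = cfg$tau_s,
                                  T = cfg$T, h = cfg$h, seed = cfg$seed)
  nrm <- normalize_decision_times(trials$decision_time)
  trials$normalized_time <- nrm$normalized
  reg <- chronometric_regression(trials$normalized_time, trials$value_ratio,
                                 runs = interaction(trials$pair, trials$run))
  psycho <- do.call(rbind, lapply(split(trials, trials$value_ratio), function(d)
    data.frame(value_ratio = d$value_ratio[1],
               p_choose_better = mean(d$chose_better[d$crossed]),
               mean_decision_time = mean(d$decision_time, na.rm = TRUE),
               n = nrow(d))))
  list(trials = trials, psychometric = psycho,
       chronometric = data.frame(slope = reg$slope, slope_se = reg$slope_se,
                                 intercept = reg$intercept, r2 = reg$r2,
                                 log_r2 = nrm$log_r2))
}

exp_sequential <- function(cfg) {
  m <- if (cfg$experiment == "fig7")
    make_multireward_chain(cfg$n_steps, cfg$intermediate_at, cfg$r_mid,
                           discount = cfg$gamma)
  else make_nrm_chain(cfg$n_steps, discount = cfg$gamma)
  input <- config_input(cfg$input)
  net <- build_discrete_network(m, k = cfg$k, eta = cfg$eta, lambda_r = 400,
                                V0 = 0, tau_m = cfg$tau_m, tau_s = cfg$tau_s)
  rec <- simulate_spiking(net, input, T = cfg$T, h = cfg$h, seed = cfg$seed,
                          n_runs = cfg$n_runs)
  sm <- smooth_rates(rec, kernel_sigma = 40)
  nrm_states <- grep("^n", m$states, value = TRUE)
  go_idx <- vapply(nrm_states, function(s)
    which(net$coding$state == s & net$coding$action == "go"), integer(1))
  rates <- data.frame(time_ms = sm$times, sm$rates[, go_idx])
  names(rates)[-1] <- paste0("nrm", sub("n", "", nrm_states))
  peaks <- data.frame(
    nrm = as.integer(sub("n", "", nrm_states)),
    peak_rate = apply(sm$rates[, go_idx, drop = FALSE], 2, max),
    peak_time = sm$times[apply(sm$rates[, go_idx, drop = FALSE], 2, which.max)])
  nrm_vals <- sort(peaks$nrm)
  rts <- sequential_reaction_times(m, nrm_vals, theta_0 = cfg$theta_0,
                                   n_trials = cfg$n_trials, input = input,
                                   behavior_scale = cfg$behavior_scale,
                                   k = cfg$k, eta = cfg$eta,
                                   tau_m = cfg$tau_m, tau_s = cfg$tau_s,
                                   T = cfg$T, h = cfg$h, seed = cfg$seed)
  list(rates = rates, peaks = peaks[order(peaks$nrm), ], reaction_times = rts)
}

exp_devaluation <- function(cfg) {
  input <- config_input(cfg$input)
  out <- list()
  for (cond in c("baseline", "devalued")) {
    m <- make_devaluation_maze(devalued = cond == "devalued")
    net <- build_discrete_network(m, k = cfg$k, eta = cfg$eta,
                                  lambda_r = 400, V0 = 0, tau_m = cfg$tau_m,
                                  tau_s = cfg$tau_s)
    rec <- simulate_spiking(net, input, T = cfg$T, h = cfg$h,
                            seed = cfg$seed, n_runs = cfg$n_trials)
    # Root choice per trial.
    dec <- accumulate_and_decide(rec, action_populations(net, "0"),
                                 cfg$theta_0 * m$discount)
    sm <- smooth_rates(rec, kernel_sigma = 40)
    rates <- data.frame(time_ms = sm$times, sm$rates)
    names(rates)[-1] <- paste(net$coding$state, net$coding$action, sep = "_")
    out[[paste0("rates_", cond)]] <- rates
    out[[paste0("choices_", cond)]] <-
      data.frame(condition = cond,
                 p_left = mean(dec$choice[dec$crossed] == "L"),
                 n_crossed = sum(dec$crossed))
    # Spreading-activation baseline.
    map <- devaluation_corridor_map(devalued = cond == "devalued")
    act <- spreading_activation_map(map, cfg$gamma_spread)
    gp <- gradient_path(act, "root")
    out[[paste0("spreading_", cond)]] <-
      data.frame(condition = cond, goal = gp$goal, reward = gp$reward)
  }
  out
}
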