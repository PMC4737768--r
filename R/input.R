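#' Reward-input time courses
#'
#' The external (reward) input to the network is a Poisson spike train whose
#' rate follows one of three profiles:
#' * `constant`: a fixed rate (used for planning with `lambda_r = 400` Hz),
#' * `double_exponential`:
#'   `lambda(t) = lambda_max * alpha * (exp(-(t - t_delta)/t_d) -
#'    exp(-(t - t_delta)/t_r)) * H(t - t_delta)` with the normalizer `alpha`
#'   chosen so the peak equals `lambda_max` (used for offer-value inputs),
#' * `raised_gaussian`:
#'   `lambda(t) = lambda_base + (lambda_max - lambda_base) *
#'    exp(-(t - t_p)^2 / tau^2)` (used for sequential tasks).
#'
#' All times are in milliseconds and rates in Hz; profiles are non-negative.
#'
#' @param rate constant rate (Hz).
#' @return an object of class `reward_input`; evaluate it with
#'   [input_rate()].
#' @export
reward_input_constant <- function(rate) {
  stopifnot(rate >= 0)
  structure(list(kind = "constant", rate = rate, onset = 0),
            class = "reward_input")
}

#' @rdname reward_input_constant
#' @param lambda_max peak rate (Hz).
#' @param t_r,t_d rise and decay time constants (ms).
#' @param t_delta onset delay (ms); the profile is 0 before it.
#' @export
reward_input_double_exp <- function(lambda_max, t_r = 110, t_d = 300,
                                    t_delta = 60) {
  stopifnot(lambda_max >= 0, t_r > 0, t_d > t_r)
  # Normalizer so that max_t lambda(t) = lambda_max.
  q <- t_r / t_d
  alpha <- 1 / (q^(q / (1 - q)) - q^(1 / (1 - q)))
  structure(list(kind = "double_exponential", lambda_max = lambda_max,
                 t_r = t_r, t_d = t_d, t_delta = t_delta, alpha = alpha,
                 onset = t_delta),
            class = "reward_input")
}

#' @rdname reward_input_constant
#' @param lambda_base baseline rate (Hz).
#' @param t_p peak time (ms).
#' @param tau Gaussian width (ms).
#' @export
reward_input_raised_gaussian <- function(lambda_base, lambda_max, t_p = 250,
                                         tau = 60) {
  stopifnot(lambda_base >= 0, lambda_max >= lambda_base)
  structure(list(kind = "raised_gaussian", lambda_base = lambda_base,
                 lambda_max = lambda_max, t_p = t_p, tau = tau, onset = 0),
            class = "reward_input")
}

#' Evaluate a reward-input profile
#' @param input a `reward_input` object.
#' @param t time(s) in ms.
#' @return rate(s) in Hz.
#' @export
input_rate <- function(input, t) {
  switch(input$kind,
    constant = rep(input$rate, length(t)),
    double_exponential = {
      tt <- t - input$t_delta
      r <- input$lambda_max * input$alpha *
        (exp(-tt / input$t_d) - exp(-tt / input$t_r))
      ifelse(tt >= 0, pmax(r, 0), 0)
    },
    raised_gaussian = input$lambda_base +
      (input$lambda_max - input$lambda_base) *
        exp(-(t - input$t_p)^2 / input$tau^2),
    stop("unknown input kind")
  )
}

#' @export
print.reward_input <- function(x, ...) {
  cat("<reward_input:", x$kind, ">\n")
  invisible(x)
}

#' Scale a reward-input profile
#'
#' Multiplies the rate parameters by a factor (used, e.g., to switch from
#' single-neuron to population rates for behavioral simulations).
#'
#' @param input a `reward_input`.
#' @param factor multiplicative factor (> 0).
#' @return scaled `reward_input`.
#' @export
scale_input <- function(input, factor) {
  stopifnot(factor > 0)
  for (f in intersect(names(input), c("rate", "lambda_max", "lambda_base")))
    input[[f]] <- input[[f]] * factor
  input
}
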