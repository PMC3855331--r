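#' Behavioural trait parameters of the learning agent
#'
#' Five parameters describe one individual: `alpha0`, the initial learning
#' rate; `tau0`, the time constant (seconds) of the exponential learning-rate
#' decay that models cognitive inflexibility (`Inf` = constant rate);
#' `omega`, the multiplicative reward-seeking weight (`omega > 1` =
#' over-valuation of rewards); `rho`, the risk coefficient multiplying the
#' running spread of experienced penalties (positive = risk seeking,
#' negative = risk averse); and `epsilon`, the softmax temperature.
#'
#' Penalty sensitivity is deliberately not a parameter: only delivered
#' rewards are re-weighted, penalties enter the learning signal unscaled.
#'
#' @param alpha0 initial learning rate, in (0, 1].
#' @param tau0 decay time constant in seconds, > 0; `Inf` for no decay.
#' @param omega reward-seeking weight, >= 0.
#' @param rho risk coefficient, any real.
#' @param epsilon softmax temperature, > 0.
#' @return An object of class `trait_params`.
#' @export
#' @examples
#' trait_params(alpha0 = 0.3, tau0 = Inf, omega = 1, rho = 0, epsilon = 0.5)
trait_params <- function(alpha0, tau0 = Inf, omega = 1, rho = 0,
                         epsilon = 0.5) {
  stopifnot(
    is.numeric(alpha0), length(alpha0) == 1, alpha0 > 0, alpha0 <= 1,
    is.numeric(tau0), length(tau0) == 1, tau0 > 0,
    is.numeric(omega), length(omega) == 1, omega >= 0,
    is.numeric(rho), length(rho) == 1, is.finite(rho),
    is.numeric(epsilon), length(epsilon) == 1, epsilon > 0
  )
  structure(list(alpha0 = alpha0, tau0 = tau0, omega = omega, rho = rho,
                 epsilon = epsilon),
            class = "trait_params")
}

#' @export
print.trait_params <- function(x, ...) {
  cat(sprintf(
    "trait_params: alpha0=%.4g tau0=%s omega=%.4g rho=%.4g epsilon=%.4g\n",
    x$alpha0, if (is.infinite(x$tau0)) "Inf" else sprintf("%.4g", x$tau0),
    x$omega, x$rho, x$epsilon))
  invisible(x)
}

#' Read / write trait parameters as JSON
#'
#' `tau0 = Inf` is serialized as the string `"inf"`.
#'
#' @param params a [trait_params()].
#' @param path file path.
#' @export
write_trait_params <- function(params, path) {
  x <- unclass(params)
  if (is.infinite(x$tau0)) x$tau0 <- "inf"
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trait_params
#' @export
read_trait_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tau0 <- x$tau0
  if (is.character(tau0)) tau0 <- if (tolower(tau0) == "inf") Inf else
    as.numeric(tau0)
  trait_params(alpha0 = x$alpha0, tau0 = tau0, omega = x$omega,
               rho = x$rho, epsilon = x$epsilon)
}

#' Fresh agent state
#'
#' All action values start at zero; penalty statistics (count, running mean
#' and sum of squared deviations, per hole) are empty. Values and statistics
#' are indexed by physical hole, so that a spatial reversal confronts
#' learned values with new contingencies.
#'
#' @param n_holes number of holes (default 4).
#' @return An object of class `agent_state`.
#' @export
agent_state <- function(n_holes = 4) {
  structure(list(
    q_values = numeric(n_holes),
    pen_n = numeric(n_holes),
    pen_mean = numeric(n_holes),
    pen_m2 = numeric(n_holes),
    elapsed_seconds = 0,
    pellets_earned = 0L
  ), class = "agent_state")
}

#' Learning rate at a given session time
#'
#' `alpha0 * exp(-t / tau0)`: exponential decay of the learning rate across
#' the session models cognitive inflexibility — individuals with small
#' `tau0` stop updating early and freeze their preferences.
#'
#' @param params a [trait_params()].
#' @param t_seconds elapsed session time(s), >= 0.
#' @return Learning rate(s) in (0, alpha0].
#' @export
learning_rate_at <- function(params, t_seconds) {
  if (any(t_seconds < 0)) stop("t_seconds must be non-negative")
  if (is.infinite(params$tau0)) {
    rep(params$alpha0, length(t_seconds))
  } else {
    params$alpha0 * exp(-t_seconds / params$tau0)
  }
}

#' Integrated learning rate (global flexibility index)
#'
#' The time integral of the decaying learning rate over the session,
#' `alpha0 * tau0 * (1 - exp(-T/tau0))` (or `alpha0 * T` without decay);
#' increasing in both `alpha0` and `tau0`, it summarises overall capacity
#' to keep learning and is the model-side analogue of behavioural
#' flexibility.
#'
#' @param params a [trait_params()].
#' @param session_seconds integration horizon (default 3600).
#' @return The area under the learning-rate curve, in units of seconds.
#' @export
area_under_alpha <- function(params, session_seconds = 3600) {
  if (is.infinite(params$tau0)) {
    params$alpha0 * session_seconds
  } else {
    params$alpha0 * params$tau0 * (1 - exp(-session_seconds / params$tau0))
  }
}

#' Risk level of an option: running spread of experienced penalties
#'
#' Population standard deviation of all penalty values recorded for the
#' hole — zero-penalty trials included — maintained as running statistics;
#' zero when the hole was sampled at most once.
#'
#' @param state an [agent_state()] (or any list with `pen_n`, `pen_m2`).
#' @param hole hole index.
#' @return Non-negative spread in pellet units.
#' @export
risk_level <- function(state, hole) {
  n <- state$pen_n[hole]
  if (n <= 1) 0 else sqrt(state$pen_m2[hole] / n)
}

#' Trait-weighted learning signal
#'
#' `omega * pellets + penalty + rho * risk`: delivered reward re-weighted by
#' reward seeking, penalty passed through unscaled, plus the risk bonus.
#'
#' @param params a [trait_params()].
#' @param pellets pellets delivered this trial.
#' @param penalty_pellets realized penalty (0 or the option's value).
#' @param risk current risk level of the chosen hole.
#' @return The scalar learning signal in pellet units.
#' @export
effective_signal <- function(params, pellets, penalty_pellets, risk) {
  params$omega * pellets + penalty_pellets + params$rho * risk
}

#' One temporal-difference update
#'
#' Records the trial's penalty value (0 if none) in the hole's running
#' penalty statistics first, then moves the hole's Q-value toward the
#' trait-weighted learning signal by the decayed learning rate at the
#' trial's start time. Other holes are untouched.
#'
#' @param state an [agent_state()].
#' @param params a [trait_params()].
#' @param hole hole index chosen this trial.
#' @param outcome a `trial_outcome` from [sample_outcome()].
#' @param t_seconds session time at trial start (default: the state clock).
#' @return The updated `agent_state` (clock not advanced).
#' @export
update_value <- function(state, params, hole, outcome,
                         t_seconds = state$elapsed_seconds) {
  penval <- outcome$penalty_pellets
  state$pen_n[hole] <- state$pen_n[hole] + 1
  d <- penval - state$pen_mean[hole]
  state$pen_mean[hole] <- state$pen_mean[hole] + d / state$pen_n[hole]
  state$pen_m2[hole] <- state$pen_m2[hole] +
    d * (penval - state$pen_mean[hole])
  risk <- risk_level(state, hole)
  sig <- effective_signal(params, outcome$pellets, penval, risk)
  alpha <- learning_rate_at(params, t_seconds)
  state$q_values[hole] <- state$q_values[hole] +
    alpha * (sig - state$q_values[hole])
  state
}

#' Softmax choice probabilities
#'
#' `p(a)` proportional to `exp(Q[a] / epsilon)`, computed with a max shift
#' so it is stable for `|Q|/epsilon` of at least 1e3 and invariant under
#' adding a constant to all Q-values.
#'
#' @param q numeric vector of action values.
#' @param epsilon softmax temperature, > 0.
#' @return Probability vector summing to 1.
#' @export
action_probabilities <- function(q, epsilon) {
  stopifnot(epsilon > 0, length(q) >= 1)
  z <- (q - max(q)) / epsilon
  e <- exp(z)
  e / sum(e)
}

#' Sample one action
#'
#' During forced exploration the choice is uniform over holes (the
#' infinite-temperature limit); afterwards it follows the softmax over the
#' current Q-values. One uniform draw is consumed either way; exact ties in
#' value are resolved by the draw, never by option order.
#'
#' @param state an [agent_state()].
#' @param params a [trait_params()].
#' @param in_forced_exploration logical.
#' @return The chosen hole index.
#' @export
select_action <- function(state, params, in_forced_exploration = FALSE) {
  k <- length(state$q_values)
  u <- runif(1)
  if (in_forced_exploration) {
    min(floor(u * k) + 1, k)
  } else {
    p <- action_probabilities(state$q_values, params$epsilon)
    which(u <= cumsum(p))[1]
  }
}
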