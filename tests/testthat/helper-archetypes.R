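# Shared fixtures: canonical configs and the two trait archetypes used
# throughout the suite.

cfg_episode <- rgt_config()                       # model analysis clock
cfg_behav <- rgt_config(clock = "behavioural")    # operant-procedure clock

params_good <- trait_params(alpha0 = 0.3, tau0 = Inf, omega = 1, rho = 0,
                            epsilon = 0.5)
params_poor <- trait_params(alpha0 = 0.2, tau0 = 600, omega = 2, rho = 1,
                            epsilon = 1)

# brute-force population SD, the oracle for the running risk statistic
sd_pop <- function(x) if (length(x) <= 1) 0 else
  sqrt(mean((x - mean(x))^2))

# mean last-20-minute advantageous percentage over seeded sessions
mean_last20 <- function(params, seeds, config = cfg_episode) {
  mean(vapply(seeds, function(s) {
    bin_profile(run_session(config, params, seed = s,
                            keep_log = FALSE))$last20_percent
  }, 0), na.rm = TRUE)
}

# build a session_record from a hand-written trial table (for binning and
# classification edge cases without simulation)
fake_record <- function(t_start, option, config = cfg_episode) {
  n_bins <- ceiling(config$session_seconds / config$bin_seconds)
  b <- pmin(floor(t_start / config$bin_seconds) + 1, n_bins)
  adv <- option %in% config$advantageous_set
  if (length(t_start) == 0) {
    return(rgtraits:::new_session_record(
      data.frame(), params_good, config, agent_state(), NA_integer_,
      bin_adv = integer(n_bins), bin_tot = integer(n_bins)))
  }
  trials <- data.frame(
    t_start_s = t_start, hole = unname(config$location_map[option]),
    option = option, pellets = unname(config$reward_pellets[option]),
    penalty_applied = FALSE, penalty_pellets = 0,
    elapsed_s = config$episode_seconds * config$reward_pellets[option])
  rgtraits:::new_session_record(
    trials, params_good, config, agent_state(), NA_integer_,
    bin_adv = as.integer(tabulate(b[adv], n_bins)),
    bin_tot = as.integer(tabulate(b, n_bins)))
}
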