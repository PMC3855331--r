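new_session_record <- function(trials, params, config, final_state, seed,
                               bin_adv, bin_tot) {
  structure(list(
    trials = trials,
    params_used = params,
    config_used = config,
    final_state = final_state,
    rng_seed = seed,
    bin_adv = bin_adv,
    bin_tot = bin_tot
  ), class = "session_record")
}

#' Simulate one RGT session
#'
#' Runs the trait-modulated temporal-difference learner through one session:
#' uniform forced exploration during the initial phase, softmax choice
#' afterwards, probabilistic time-out penalties with per-pellet time
#' accounting, and value updates at the decayed learning rate. The session
#' ends when the clock reaches the session cap or the pellet cap is hit.
#'
#' @param config an [rgt_config()].
#' @param params a [trait_params()].
#' @param seed integer seed for reproducibility, or `NULL` to use the
#'   current RNG stream.
#' @param carried_state an [agent_state()] to start from (values and penalty
#'   statistics retained; session clock and pellet count reset), or `NULL`
#'   for a fresh agent.
#' @param keep_log keep the trial-by-trial log (set `FALSE` for speed in
#'   likelihood evaluations; bin counts are always kept).
#' @param engine `"cpp"` (default) or `"r"` for the pure-R reference loop;
#'   both consume the RNG identically and give bit-identical sessions.
#' @param max_trials hard guard on the number of trials.
#' @param t_offset origin of the learning-rate decay clock (and of the
#'   forced-exploration window), in seconds. Zero for a first session; a
#'   reversal session carrying the agent's inflexibility over passes the
#'   end-of-RGT time. Bins always use the within-session clock.
#' @return An object of class `session_record` with the trial log
#'   (`t_start_s`, `hole`, `option`, `pellets`, `penalty_applied`,
#'   `penalty_pellets`, `elapsed_s`), the final [agent_state()], per-bin
#'   advantageous/total counts, and the inputs used.
#' @export
#' @examples
#' rec <- run_session(rgt_config(), trait_params(alpha0 = 0.3), seed = 1)
#' bin_profile(rec)
run_session <- function(config, params, seed = NULL, carried_state = NULL,
                        keep_log = TRUE, engine = c("cpp", "r"),
                        max_trials = 2000L, t_offset = 0) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "rgt_config"), inherits(params, "trait_params"))
  st <- carried_state %||% agent_state(length(config$option_labels))
  with_seed(seed, {
    if (engine == "cpp") {
      raw <- cpp_run_session(
        unname(config$reward_pellets), unname(config$penalty_pellets),
        unname(config$penalty_prob), unname(config$timeout_seconds),
        as.integer(config$location_map[config$option_labels]),
        config$option_labels %in% config$advantageous_set,
        config$episode_seconds, config$session_seconds,
        config$pellet_cap, config$forced_exploration_seconds,
        config$bin_seconds,
        config$clock == "behavioural", t_offset,
        params$alpha0, params$tau0, params$omega, params$rho, params$epsilon,
        st$q_values, st$pen_n, st$pen_mean, st$pen_m2,
        keep_log, as.integer(max_trials))
    } else {
      raw <- run_session_r(config, params, st, keep_log, max_trials,
                           t_offset)
    }
    final <- structure(list(
      q_values = raw$q, pen_n = raw$pen_n, pen_mean = raw$pen_mean,
      pen_m2 = raw$pen_m2, elapsed_seconds = raw$elapsed_seconds,
      pellets_earned = as.integer(raw$pellets_earned)
    ), class = "agent_state")
    trials <- NULL
    if (keep_log) {
      trials <- data.frame(
        t_start_s = as.numeric(raw$log_t_start),
        hole = as.integer(raw$log_hole),
        option = config$option_labels[as.integer(raw$log_option)],
        pellets = as.integer(raw$log_pellets),
        penalty_applied = as.integer(raw$log_penalty_applied) == 1L,
        penalty_pellets = as.numeric(raw$log_penalty_pellets),
        elapsed_s = as.numeric(raw$log_elapsed)
      )
    }
    new_session_record(trials, params, config, final, seed,
                       raw$bin_adv, raw$bin_tot)
  })
}

# Pure-R reference session loop built from the exported operations; consumes
# the RNG in the same order as the C++ engine (one uniform for the choice,
# one for the penalty) so seeded sessions are bit-identical across engines.
run_session_r <- function(config, params, st, keep_log, max_trials,
                          t_offset = 0) {
  n_bins <- ceiling(config$session_seconds / config$bin_seconds)
  bin_adv <- integer(n_bins)
  bin_tot <- integer(n_bins)
  option_of_hole <- character(length(config$location_map))
  option_of_hole[config$location_map[config$option_labels]] <-
    config$option_labels
  log_rows <- list()
  trial <- 0L
  while (st$elapsed_seconds < config$session_seconds &&
         st$pellets_earned < config$pellet_cap && trial < max_trials) {
    t0 <- st$elapsed_seconds
    hole <- select_action(st, params,
                          in_forced_exploration =
                            t0 + t_offset <
                            config$forced_exploration_seconds)
    opt <- option_of_hole[hole]
    out <- sample_outcome(config, opt)
    st <- update_value(st, params, hole, out, t_seconds = t0 + t_offset)
    b <- min(floor(t0 / config$bin_seconds) + 1, n_bins)
    bin_tot[b] <- bin_tot[b] + 1L
    if (opt %in% config$advantageous_set) bin_adv[b] <- bin_adv[b] + 1L
    trial <- trial + 1L
    if (keep_log) {
      log_rows[[trial]] <- data.frame(
        t_start_s = t0, hole = hole, option = opt, pellets = out$pellets,
        penalty_applied = out$penalty_applied,
        penalty_pellets = out$penalty_pellets,
        elapsed_s = out$elapsed_seconds)
    }
    st$elapsed_seconds <- t0 + out$elapsed_seconds
    st$pellets_earned <- st$pellets_earned + out$pellets
  }
  list(
    q = st$q_values, pen_n = st$pen_n, pen_mean = st$pen_mean,
    pen_m2 = st$pen_m2, elapsed_seconds = st$elapsed_seconds,
    pellets_earned = st$pellets_earned, n_trials = trial,
    bin_adv = bin_adv, bin_tot = bin_tot,
    log_t_start = if (keep_log) vapply(log_rows, `[[`, 0, "t_start_s"),
    log_hole = if (keep_log) vapply(log_rows, function(r) as.numeric(r$hole), 0),
    log_option = if (keep_log)
      match(vapply(log_rows, `[[`, "", "option"), config$option_labels),
    log_pellets = if (keep_log) vapply(log_rows, `[[`, 0, "pellets"),
    log_penalty_applied = if (keep_log)
      as.integer(vapply(log_rows, `[[`, NA, "penalty_applied")),
    log_penalty_pellets = if (keep_log)
      vapply(log_rows, `[[`, 0, "penalty_pellets"),
    log_elapsed = if (keep_log) vapply(log_rows, `[[`, 0, "elapsed_s")
  )
}

#' Simulate a reversal session continuing from a finished RGT session
#'
#' Runs a session on the spatially reversed task, starting from the agent's
#' end-of-RGT hole-indexed values and penalty statistics. The session clock
#' and the pellet count are reset, as in a fresh behavioural session. By
#' default the learning-rate decay clock — the agent's inflexibility — is
#' carried over (so an agent whose learning rate has decayed to zero cannot
#' relearn the swapped contingencies, and no forced exploration is
#' re-imposed); set `reset_decay_clock = TRUE` to restart the decay and the
#' forced-exploration phase instead.
#'
#' @param config the original (identity-mapped) [rgt_config()].
#' @param params a [trait_params()].
#' @param carried_state the final [agent_state()] of the RGT session.
#' @param seed integer seed or `NULL`.
#' @param reset_decay_clock logical (default `FALSE`).
#' @inheritParams run_session
#' @return A `session_record` on the reversed configuration.
#' @export
run_reversal_session <- function(config, params, carried_state, seed = NULL,
                                 keep_log = TRUE, engine = c("cpp", "r"),
                                 max_trials = 2000L,
                                 reset_decay_clock = FALSE) {
  stopifnot(inherits(carried_state, "agent_state"))
  offset <- if (reset_decay_clock) 0 else carried_state$elapsed_seconds
  st <- carried_state
  st$elapsed_seconds <- 0
  st$pellets_earned <- 0L
  run_session(make_reversed(config), params, seed = seed,
              carried_state = st, keep_log = keep_log, engine = engine,
              max_trials = max_trials, t_offset = offset)
}

#' @export
print.session_record <- function(x, ...) {
  n <- if (!is.null(x$trials)) nrow(x$trials) else sum(x$bin_tot)
  cat(sprintf(
    "session_record: %d trials, %d pellets, %.0f s elapsed (seed %s)\n",
    n, x$final_state$pellets_earned, x$final_state$elapsed_seconds,
    x$rng_seed %||% "<stream>"))
  invisible(x)
}

#' Binned performance profile of a session
#'
#' Percentage of advantageous choices per 10-minute bin (trials assigned by
#' start time, half-open bins), per-bin trial counts, and the pooled
#' percentage over trials starting in the final 20 minutes — the quantity
#' the good/poor classification and the likelihood fit operate on. Empty
#' bins are `NA`.
#'
#' @param record a `session_record`.
#' @return An object of class `performance_profile` with fields
#'   `percent` (x10..x60), `counts`, `adv_counts`, `last20_percent`,
#'   `last20_n`.
#' @export
bin_profile <- function(record) {
  stopifnot(inherits(record, "session_record"))
  tot <- record$bin_tot
  adv <- record$bin_adv
  if (sum(tot) == 0) stop("degenerate session: no trials recorded")
  cfg <- record$config_used
  n_bins <- length(tot)
  pct <- ifelse(tot > 0, 100 * adv / tot, NA_real_)
  # final two bins pooled at the trial level
  idx <- c(n_bins - 1, n_bins)
  l20n <- sum(tot[idx])
  l20 <- if (l20n > 0) 100 * sum(adv[idx]) / l20n else NA_real_
  structure(list(
    percent = setNames(pct, paste0("x", seq_len(n_bins) *
                                     cfg$bin_seconds / 60)),
    counts = setNames(tot, paste0("n", seq_len(n_bins) *
                                    cfg$bin_seconds / 60)),
    adv_counts = adv,
    last20_percent = l20,
    last20_n = l20n
  ), class = "performance_profile")
}

# Construct a performance_profile directly from percentages/counts
# (e.g. read from a CSV of observed profiles).
#' Assemble a performance profile from bin percentages and counts
#'
#' For profiles that come from data files rather than simulated records.
#' If the final-20-minute percentage is not supplied it is recomputed by
#' pooling the final two bins.
#'
#' @param percent numeric vector of per-bin advantageous percentages
#'   (`NA` for empty bins).
#' @param counts integer vector of per-bin trial counts (may be `NULL`
#'   when only percentages are known).
#' @param last20_percent optional pooled final-20-minute percentage.
#' @return A `performance_profile`.
#' @export
performance_profile <- function(percent, counts = NULL,
                                last20_percent = NULL) {
  n_bins <- length(percent)
  stopifnot(all(is.na(percent) | (percent >= 0 & percent <= 100)))
  if (is.null(counts)) counts <- rep(NA_integer_, n_bins)
  stopifnot(length(counts) == n_bins)
  adv <- ifelse(is.na(percent) | is.na(counts), NA_real_,
                round(percent * counts / 100))
  idx <- c(n_bins - 1, n_bins)
  if (is.null(last20_percent)) {
    l20n <- sum(counts[idx], na.rm = TRUE)
    last20_percent <- if (isTRUE(l20n > 0))
      100 * sum(adv[idx], na.rm = TRUE) / l20n else NA_real_
  }
  l20n <- sum(counts[idx], na.rm = TRUE)
  structure(list(
    percent = setNames(percent, paste0("x", seq_len(n_bins) * 10)),
    counts = setNames(counts, paste0("n", seq_len(n_bins) * 10)),
    adv_counts = adv,
    last20_percent = last20_percent,
    last20_n = l20n
  ), class = "performance_profile")
}

#' @export
print.performance_profile <- function(x, ...) {
  cat("performance_profile (% advantageous per bin):\n")
  print(round(x$percent, 1))
  cat(sprintf("last 20 min: %.1f%% over %d trials\n",
              x$last20_percent, x$last20_n))
  invisible(x)
}

#' Classify a session as good / poor / undecided decision making
#'
#' Good decision makers exceed 70% advantageous choices over the final 20
#' minutes, poor decision makers fall below 30%; anything else (boundaries
#' included) is undecided.
#'
#' @param profile a `performance_profile`.
#' @return `"good"`, `"poor"` or `"undecided"`.
#' @export
classify_rgt <- function(profile) {
  stopifnot(inherits(profile, "performance_profile"))
  l20 <- profile$last20_percent
  if (is.na(l20) || (!is.na(profile$last20_n) && profile$last20_n == 0)) {
    stop("unclassifiable: no trials in the final 20 minutes")
  }
  if (l20 > 70) "good" else if (l20 < 30) "poor" else "undecided"
}

#' Preferred contingency pair at the end of an RGT session
#'
#' Whichever contingency pair (advantageous C/D or disadvantageous A/B)
#' received the majority of the final-20-minute choices; exact 50/50 ties
#' resolve to advantageous.
#'
#' @param record the RGT `session_record`.
#' @return `"advantageous"` or `"disadvantageous"`.
#' @export
preferred_contingency <- function(record) {
  prof <- bin_profile(record)
  if (prof$last20_n == 0) stop("no trials in the final 20 minutes")
  if (prof$last20_percent >= 50) "advantageous" else "disadvantageous"
}

#' Flexibility score of a reversal session
#'
#' Percentage of final-20-minute reversal trials directed at the new
#' location of the contingency pair the individual preferred before the
#' reversal, i.e. trials that still obtained the preferred contingency.
#' Categories: flexible (> 60), undecided (40--60), inflexible (< 40).
#'
#' @param reversal_record the reversal `session_record`.
#' @param preferred `"advantageous"` or `"disadvantageous"`, from
#'   [preferred_contingency()] on the pre-reversal session.
#' @return A list with `percent`, `n` and `category`.
#' @export
flexibility_score <- function(reversal_record,
                              preferred = c("advantageous",
                                            "disadvantageous")) {
  preferred <- match.arg(preferred)
  prof <- bin_profile(reversal_record)
  if (prof$last20_n == 0) {
    stop("unclassifiable: no reversal trials in the final 20 minutes")
  }
  pct <- if (preferred == "advantageous") prof$last20_percent else
    100 - prof$last20_percent
  list(percent = pct, n = prof$last20_n,
       category = classify_flexibility(pct))
}

#' @rdname flexibility_score
#' @param percent a flexibility percentage.
#' @export
classify_flexibility <- function(percent) {
  if (is.na(percent)) stop("flexibility percentage undefined")
  if (percent > 60) "flexible" else if (percent < 40) "inflexible" else
    "undecided"
}

#' Write a session record / performance profiles to tidy CSV
#'
#' @param record a `session_record` with a trial log.
#' @param path output file.
#' @export
write_session_csv <- function(record, path) {
  stopifnot(!is.null(record$trials))
  df <- cbind(seed = record$rng_seed %||% NA_integer_, record$trials)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @param profiles named list of `performance_profile` objects (names used
#'   as rat ids).
#' @export
write_profile_csv <- function(profiles, path) {
  rows <- lapply(names(profiles), function(id) {
    p <- profiles[[id]]
    data.frame(rat_id = id, t(p$percent), t(p$counts),
               last20 = p$last20_percent)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_profile_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  ncols <- grep("^n[0-9]+$", names(df), value = TRUE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    performance_profile(
      percent = as.numeric(df[i, xcols]),
      counts = if (length(ncols)) as.integer(df[i, ncols]) else NULL,
      last20_percent = if ("last20" %in% names(df)) df$last20[i] else NULL)
  })
  names(out) <- df$rat_id
  out
}
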