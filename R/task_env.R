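#' Rat Gambling Task contingency configuration
#'
#' Builds the canonical RGT contingency table: four options (A--D) deliver
#' one or two food pellets and are followed, with option-specific
#' probability, by a time-out penalty during which no food can be obtained.
#' Time-outs are expressed as equivalent immediate pellet losses via the
#' mean time to obtain and consume one pellet (9 s), giving the canonical
#' penalty table A:-50, B:-25, C:-4/3, D:-2/3. Options C and D (small
#' reward, short and/or rare time-outs) are advantageous in the long run.
#'
#' @param penalty_values `"canonical"` uses the printed canonical penalty table
#'   (-50, -25, -4/3, -2/3); `"computed"` derives penalties exactly as
#'   `-timeout_seconds / episode_seconds` (A becomes -148/3, B -74/3).
#' @param clock `"episode"` (default): session time advances only by pellet
#'   consumption (9 s per pellet) and a time-out is charged entirely as its
#'   converted pellet penalty — the model's analysis clock, under which one
#'   session is a fixed hour of consumption-equivalent time. `"behavioural"`:
#'   realized time-outs also consume session time, as in the operant
#'   procedure.
#' @param episode_seconds mean seconds to obtain and consume one pellet.
#' @param session_seconds session duration cap, seconds.
#' @param pellet_cap session ends once this many pellets are earned; default
#'   250 under the behavioural clock (the procedure's satiety cap) and `Inf`
#'   under the episode clock, where the cap would otherwise truncate every
#'   session before the final bins.
#' @param forced_exploration_seconds initial phase with uniform choice.
#' @param bin_seconds width of the performance bins.
#' @param location_map named integer vector mapping each option's
#'   contingency to a physical hole (default identity). Must be a bijection.
#'
#' @return An object of class `rgt_config`.
#' @seealso [make_reversed()], [sample_outcome()], [expected_outcome_value()]
#' @export
#' @examples
#' cfg <- rgt_config()
#' expected_outcome_value(cfg)
rgt_config <- function(penalty_values = c("canonical", "computed"),
                       clock = c("episode", "behavioural"),
                       episode_seconds = 9,
                       session_seconds = 3600,
                       pellet_cap = NULL,
                       forced_exploration_seconds = 600,
                       bin_seconds = 600,
                       location_map = NULL) {
  penalty_values <- match.arg(penalty_values)
  clock <- match.arg(clock)
  if (is.null(pellet_cap)) {
    pellet_cap <- if (clock == "episode") Inf else 250
  }
  labels <- c("A", "B", "C", "D")
  reward_pellets <- c(A = 2, B = 2, C = 1, D = 1)
  timeout_seconds <- c(A = 444, B = 222, C = 12, D = 6)
  penalty_prob <- c(A = 1 / 2, B = 1 / 4, C = 1 / 4, D = 1 / 2)
  penalty_pellets <- if (penalty_values == "canonical") {
    c(A = -50, B = -25, C = -4 / 3, D = -2 / 3)
  } else {
    convert_timeout_to_penalty(timeout_seconds, episode_seconds)
  }
  if (is.null(location_map)) location_map <- setNames(1:4, labels)

  cfg <- structure(list(
    option_labels = labels,
    reward_pellets = reward_pellets,
    timeout_seconds = timeout_seconds,
    penalty_prob = penalty_prob,
    penalty_pellets = penalty_pellets,
    episode_seconds = episode_seconds,
    session_seconds = session_seconds,
    pellet_cap = pellet_cap,
    forced_exploration_seconds = forced_exploration_seconds,
    bin_seconds = bin_seconds,
    advantageous_set = c("C", "D"),
    penalty_values = penalty_values,
    clock = clock,
    location_map = location_map
  ), class = "rgt_config")
  validate_rgt_config(cfg)
  cfg
}

validate_rgt_config <- function(cfg) {
  stopifnot(
    all(cfg$penalty_prob >= 0 & cfg$penalty_prob <= 1),
    all(cfg$timeout_seconds > 0),
    all(cfg$penalty_pellets <= 0),
    all(cfg$reward_pellets >= 1),
    cfg$episode_seconds > 0,
    setequal(
      c(cfg$advantageous_set, setdiff(cfg$option_labels, cfg$advantageous_set)),
      cfg$option_labels
    )
  )
  lm <- cfg$location_map
  if (!setequal(names(lm), cfg$option_labels) ||
      !setequal(lm, seq_along(cfg$option_labels))) {
    stop("location_map must be a bijection from options onto holes")
  }
  invisible(cfg)
}

#' @export
print.rgt_config <- function(x, ...) {
  cat("RGT configuration (penalty values: ", x$penalty_values,
      "; clock: ", x$clock, ")\n", sep = "")
  tab <- data.frame(
    option = x$option_labels,
    pellets = unname(x$reward_pellets),
    timeout_s = unname(x$timeout_seconds),
    p_penalty = unname(x$penalty_prob),
    penalty_pellets = round(unname(x$penalty_pellets), 3),
    hole = unname(x$location_map)
  )
  print(tab, row.names = FALSE)
  cat("session ", x$session_seconds, " s, cap ", x$pellet_cap,
      " pellets, forced exploration ", x$forced_exploration_seconds,
      " s\n", sep = "")
  invisible(x)
}

#' Express a time-out as an equivalent immediate pellet loss
#'
#' A time-out of `timeout_seconds` forgoes `timeout_seconds /
#' episode_seconds` pellets, since one pellet is obtained and consumed every
#' `episode_seconds` seconds in the absence of penalties.
#'
#' @param timeout_seconds non-negative time-out duration(s), seconds.
#' @param episode_seconds mean seconds per pellet (> 0).
#' @return Non-positive penalty in pellet units, same length as
#'   `timeout_seconds`.
#' @export
#' @examples
#' convert_timeout_to_penalty(c(12, 6), 9)  # -4/3, -2/3
convert_timeout_to_penalty <- function(timeout_seconds, episode_seconds) {
  if (!is.numeric(episode_seconds) || length(episode_seconds) != 1 ||
      episode_seconds <= 0) {
    stop("episode_seconds must be a single positive number")
  }
  if (any(timeout_seconds < 0)) stop("timeout_seconds must be non-negative")
  -timeout_seconds / episode_seconds
}

#' Sample one trial outcome for an option
#'
#' Delivers the option's reward and, with the configured probability, its
#' time-out penalty. Trial duration is the per-pellet consumption time,
#' plus any realized time-out under the behavioural clock (under the
#' episode clock the time-out is charged only as its converted pellet
#' penalty).
#'
#' @param config an [rgt_config()].
#' @param option one of the option labels.
#' @return A list of class `trial_outcome` with fields `option`, `pellets`,
#'   `penalty_applied`, `penalty_pellets` (0 if no penalty) and
#'   `elapsed_seconds`.
#' @export
sample_outcome <- function(config, option) {
  if (!option %in% config$option_labels) {
    stop("unknown option: ", option)
  }
  pen <- runif(1) < config$penalty_prob[[option]]
  pellets <- config$reward_pellets[[option]]
  structure(list(
    option = option,
    pellets = pellets,
    penalty_applied = pen,
    penalty_pellets = if (pen) config$penalty_pellets[[option]] else 0,
    elapsed_seconds = config$episode_seconds * pellets +
      if (pen && config$clock == "behavioural")
        config$timeout_seconds[[option]] else 0
  ), class = "trial_outcome")
}

#' Expected pellet value of one trial of each option
#'
#' Closed form `reward + penalty_prob * penalty`; the fixed point of
#' trait-neutral temporal-difference learning and the oracle for
#' convergence tests. Under the canonical table C and D both yield 2/3,
#' while A yields -23 and B -4.25.
#'
#' @param config an [rgt_config()].
#' @param options options to evaluate (default all, in canonical order).
#' @return Named numeric vector of expected pellet values per trial.
#' @export
expected_outcome_value <- function(config, options = config$option_labels) {
  if (!all(options %in% config$option_labels)) {
    stop("unknown option(s): ",
         paste(setdiff(options, config$option_labels), collapse = ", "))
  }
  config$reward_pellets[options] +
    config$penalty_prob[options] * config$penalty_pellets[options]
}

#' Spatially reversed task configuration
#'
#' Swaps the holes carrying the disadvantageous contingencies (A, B) with
#' those carrying the advantageous ones (C, D), leaving the contingencies
#' themselves untouched. Applying it twice restores the original map.
#'
#' @param config an [rgt_config()].
#' @return An `rgt_config` with the pair-swapped location map.
#' @export
make_reversed <- function(config) {
  lm <- config$location_map
  new <- lm
  new["A"] <- lm[["C"]]
  new["C"] <- lm[["A"]]
  new["B"] <- lm[["D"]]
  new["D"] <- lm[["B"]]
  config$location_map <- new
  validate_rgt_config(config)
  config
}

#' Read / write a task configuration as JSON
#'
#' @param config an [rgt_config()].
#' @param path file path.
#' @return `read_task_config` returns an `rgt_config`;
#'   `write_task_config` returns `path` invisibly.
#' @export
write_task_config <- function(config, path) {
  x <- unclass(config)
  x$location_map <- as.list(x$location_map)
  if (is.infinite(x$pellet_cap)) x$pellet_cap <- "inf"
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lab <- x$option_labels
  cap <- x$pellet_cap
  if (is.character(cap)) cap <- if (tolower(cap) == "inf") Inf else
    as.numeric(cap)
  cfg <- structure(list(
    option_labels = lab,
    reward_pellets = setNames(as.numeric(x$reward_pellets), lab),
    timeout_seconds = setNames(as.numeric(x$timeout_seconds), lab),
    penalty_prob = setNames(as.numeric(x$penalty_prob), lab),
    penalty_pellets = setNames(as.numeric(x$penalty_pellets), lab),
    episode_seconds = x$episode_seconds,
    session_seconds = x$session_seconds,
    pellet_cap = cap,
    forced_exploration_seconds = x$forced_exploration_seconds,
    bin_seconds = x$bin_seconds,
    advantageous_set = x$advantageous_set,
    penalty_values = x$penalty_values %||% "canonical",
    clock = x$clock %||% "episode",
    location_map = unlist(x$location_map)
  ), class = "rgt_config")
  validate_rgt_config(cfg)
  cfg
}
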