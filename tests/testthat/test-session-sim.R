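test_that("seeded sessions are deterministic and engine-independent", {
  for (p in list(params_good, params_poor)) {
    a <- run_session(cfg_episode, p, seed = 7)
    b <- run_session(cfg_episode, p, seed = 7)
    expect_identical(a$trials, b$trials)
    # the pure-R reference loop reproduces the C++ engine bit for bit
    r <- run_session(cfg_episode, p, seed = 7, engine = "r")
    expect_identical(a$trials, r$trials)
    expect_equal(unclass(a$final_state), unclass(r$final_state),
                 tolerance = 1e-13)
  }
  # behavioural clock too
  a <- run_session(cfg_behav, params_poor, seed = 3)
  r <- run_session(cfg_behav, params_poor, seed = 3, engine = "r")
  expect_identical(a$trials, r$trials)
})

test_that("session caps hold for random parameter draws (both clocks)", {
  with_seed(13, for (i in 1:100) {
    p <- trait_params(alpha0 = runif(1, 0.05, 1),
                      tau0 = sample(c(runif(1, 60, 2000), Inf), 1),
                      omega = runif(1, 0.5, 3), rho = runif(1, -1, 2),
                      epsilon = runif(1, 0.1, 3))
    cfg <- if (i %% 2) cfg_behav else cfg_episode
    rec <- run_session(cfg, p, keep_log = TRUE)
    tr <- rec$trials
    expect_true(all(diff(tr$t_start_s) > 0))
    expect_true(all(tr$t_start_s < cfg$session_seconds))
    expect_lte(rec$final_state$pellets_earned, cfg$pellet_cap)
    expect_identical(sum(rec$bin_tot), nrow(tr))
    expect_identical(sum(rec$bin_adv),
                     sum(tr$option %in% cfg$advantageous_set))
  })
})

test_that("under the behavioural clock an advantageous-only agent hits the
           pellet cap before the hour", {
  # near-deterministic preference for C via a converged-like state
  st <- agent_state()
  st$q_values <- c(-50, -50, 50, -50)
  p <- trait_params(alpha0 = 0.01, tau0 = Inf, epsilon = 0.1)
  cfg <- rgt_config(clock = "behavioural", forced_exploration_seconds = 0)
  rec <- run_session(cfg, p, seed = 5, carried_state = st)
  expect_identical(rec$final_state$pellets_earned, 250L)
  expect_lt(rec$final_state$elapsed_seconds, 3600)
})

test_that("binning follows half-open 10-minute windows", {
  # trial exactly at 600 s falls in bin 2, not bin 1 (half-open windows)
  rec <- fake_record(c(0, 599.9, 600, 1200), rep("C", 4))
  prof <- bin_profile(rec)
  expect_identical(unname(prof$counts), c(2L, 1L, 1L, 0L, 0L, 0L))
  expect_true(all(prof$percent[1:3] == 100))
  expect_true(all(is.na(prof$percent[4:6])))
  # alternating C/A trials -> 50% in every occupied bin
  tt <- seq(0, 3599, by = 60)
  rec2 <- fake_record(tt, rep(c("C", "A"), length.out = length(tt)))
  expect_true(all(bin_profile(rec2)$percent == 50))
  # last-20-min percentage pools the final two bins at the trial level
  rec3 <- fake_record(c(2400, 2500, 3000, 3100), c("C", "C", "C", "A"))
  expect_equal(bin_profile(rec3)$last20_percent, 75)
  # zero-trial record is degenerate
  rec0 <- fake_record(numeric(0), character(0))
  expect_error(bin_profile(rec0), "degenerate")
})

test_that("good/poor classification uses strict 70/30 bounds", {
  prof <- function(l20) performance_profile(rep(l20, 6), rep(10L, 6))
  expect_identical(classify_rgt(prof(85)), "good")
  expect_identical(classify_rgt(prof(20)), "poor")
  expect_identical(classify_rgt(prof(70)), "undecided")
  expect_identical(classify_rgt(prof(30)), "undecided")
  expect_identical(classify_rgt(prof(50)), "undecided")
  empty <- performance_profile(c(50, 50, 50, 50, NA, NA),
                               c(10L, 10L, 10L, 10L, 0L, 0L))
  expect_error(classify_rgt(empty), "unclassifiable")
})

test_that("archetype agents classify good and poor by the last-20 rule", {
  g <- mean_last20(params_good, 1:5)
  p <- mean_last20(params_poor, 1:5)
  expect_gt(g, 70)
  expect_lt(p, 30)
})

test_that("flexibility scoring tracks the preferred contingency", {
  # reversal record whose trials all obtain the advantageous contingency
  rev_cfg <- make_reversed(cfg_episode)
  tt <- seq(0, 3599, by = 12)
  all_adv <- fake_record(tt, rep(c("C", "D"), length.out = length(tt)),
                         config = rev_cfg)
  fs <- flexibility_score(all_adv, "advantageous")
  expect_equal(fs$percent, 100)
  expect_identical(fs$category, "flexible")
  # an agent that keeps obtaining A/B scores 0 for an advantageous-preferrer
  all_dis <- fake_record(tt, rep(c("A", "B"), length.out = length(tt)),
                         config = rev_cfg)
  fs2 <- flexibility_score(all_dis, "advantageous")
  expect_equal(fs2$percent, 0)
  expect_identical(fs2$category, "inflexible")
  # band edges: 40-60 undecided, boundaries included
  expect_identical(classify_flexibility(50), "undecided")
  expect_identical(classify_flexibility(40), "undecided")
  expect_identical(classify_flexibility(60), "undecided")
  expect_identical(classify_flexibility(60.5), "flexible")
  expect_identical(classify_flexibility(39.5), "inflexible")
})

test_that("reversal carries values; frozen agents cannot relearn", {
  # alpha0 ~ 0: Q-values unchanged through the whole reversal session
  p0 <- trait_params(alpha0 = 1e-9, tau0 = Inf, epsilon = 0.5)
  st <- agent_state()
  st$q_values <- c(1, 2, 3, 4)
  rev <- run_reversal_session(cfg_episode, p0, st, seed = 1)
  expect_equal(rev$final_state$q_values, c(1, 2, 3, 4), tolerance = 1e-5)
  # flexible archetype re-tracks the advantageous pair; an inflexible one
  # (decayed learning rate carried over) keeps visiting the old holes
  flex_mean <- function(p, seeds) {
    mean(vapply(seeds, function(s) {
      rgt <- run_session(cfg_episode, p, seed = s, keep_log = FALSE)
      rev <- run_reversal_session(cfg_episode, p, rgt$final_state,
                                  seed = 1000 + s, keep_log = FALSE)
      flexibility_score(rev, "advantageous")$percent
    }, 0), na.rm = TRUE)
  }
  expect_gt(flex_mean(trait_params(0.5, Inf, epsilon = 0.5), 1:20), 60)
  expect_lt(flex_mean(trait_params(0.5, 120, epsilon = 0.5), 1:20), 40)
})

test_that("session and profile CSV round trips preserve the data", {
  rec <- run_session(cfg_episode, params_good, seed = 2)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(f1, f2)))
  write_session_csv(rec, f1)
  back <- read.csv(f1)
  expect_identical(nrow(back), nrow(rec$trials))
  expect_equal(back$t_start_s, rec$trials$t_start_s)
  prof <- bin_profile(rec)
  write_profile_csv(list(rat1 = prof), f2)
  back2 <- read_profile_csv(f2)
  expect_equal(unname(back2$rat1$percent), unname(prof$percent))
  expect_equal(back2$rat1$last20_percent, prof$last20_percent)
})
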