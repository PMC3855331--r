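fake_fit <- function(logL, k = 5L, n_obs = 6L, n_individuals = NULL) {
  v <- switch(as.character(k),
              "5" = model_variant(),
              "4" = model_variant(TRUE, TRUE, FALSE),
              "3" = model_variant(TRUE, FALSE, FALSE),
              "2" = model_variant(FALSE, FALSE, FALSE))
  structure(list(variant = v, log_likelihood = logL, n_obs = n_obs,
                 n_individuals = n_individuals),
            class = "fit_result")
}

test_that("BIC penalises parameters and adds over individuals", {
  expect_equal(bic(fake_fit(-10, k = 5L, n_obs = 6L)), 5 * log(6) + 20)
  # fewer parameters at equal likelihood -> smaller BIC
  expect_lt(bic(fake_fit(-10, k = 4L)), bic(fake_fit(-10, k = 5L)))
  # cohort BIC is the sum of per-rat BICs
  fits <- list(fake_fit(-10), fake_fit(-12), fake_fit(-8))
  agg <- cohort_fit(fits)
  expect_equal(agg$bic_total, sum(vapply(fits, bic, 0)))
  expect_equal(agg$log_likelihood, -30)
  expect_identical(agg$n_individuals, 3L)
})

test_that("likelihood-ratio test follows the chi-squared reference", {
  same <- lrt(fake_fit(-10, 5L), fake_fit(-10, 4L))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_identical(same$df, 1L)
  # canonical value: statistic 10.83 on 1 df -> p ~ 0.001
  out <- lrt(fake_fit(-10, 5L), fake_fit(-10 - 10.83 / 2, 4L))
  expect_equal(out$p_value, 0.001, tolerance = 0.01)
  expect_true(out$simulation_based)
  # degrees of freedom scale with the number of individuals
  out2 <- lrt(fake_fit(-10, 5L, n_individuals = 10L),
              fake_fit(-20, 3L, n_individuals = 10L))
  expect_identical(out2$df, 20L)
  # non-nested pair (risk-only vs reward-only) is rejected
  risk_only <- structure(list(variant = model_variant(FALSE, TRUE, FALSE),
                              log_likelihood = -5, n_obs = 6L),
                         class = "fit_result")
  expect_error(lrt(fake_fit(-4, 3L), risk_only), "nested")
})

test_that("permutation correlation p-values behave at the extremes", {
  x <- 1:10
  r1 <- with_seed(1, mc_permutation_corr(x, x, n_perm = 999))
  expect_equal(r1$r, 1)
  expect_lte(r1$p_value, 0.01)
  expect_gte(r1$p_value, 1 / 1000)
  # two-sided symmetry: y = -x gives the same p as y = x under one seed
  r2 <- with_seed(1, mc_permutation_corr(x, -x, n_perm = 999))
  expect_equal(r2$r, -1)
  expect_identical(r2$p_value, r1$p_value)
  expect_error(mc_permutation_corr(x, rep(1, 10)), "zero variance")
  expect_error(mc_permutation_corr(1:2, 2:1), "length")
})

test_that("permutation p-values are calibrated under the null", {
  # independent normal pairs: p approximately uniform (KS at 0.01)
  pvals <- with_seed(42, vapply(1:200, function(i) {
    mc_permutation_corr(rnorm(12), rnorm(12), n_perm = 199)$p_value
  }, 0))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(pvals >= 1 / 200 & pvals <= 1))
})

test_that("group correlation reduces scores to median splits", {
  x <- c(1:10)          # split: low half vs high half
  y <- x * 3 + 100      # identical split
  g <- with_seed(2, group_correlation(x, y, n_perm = 499))
  expect_equal(g$r, 1)
  g2 <- with_seed(2, group_correlation(x, -y, n_perm = 499))
  expect_equal(g2$r, -1)
  # balanced 10/10 splits force an even number of disagreements; with
  # 16/20 agreement the phi correlation is (16 - 4) / 20 = 0.6
  sx <- rep(c(1, -1), each = 10)
  sy <- sx
  sy[c(1, 2, 11, 12)] <- -sy[c(1, 2, 11, 12)]   # 4 flips, still 10/10
  expect_equal(sum(sy), 0)
  g3 <- with_seed(3, group_correlation(sx, sy, n_perm = 499))
  expect_equal(g3$r, 0.6)
  expect_error(group_correlation(rep(1, 5), 1:5), "degenerate")
  # internal consistency with the permutation test on sign vectors
  mc <- with_seed(7, mc_permutation_corr(g3$sign_x, g3$sign_y,
                                         n_perm = 499))
  expect_equal(mc$r, g3$r)
})

test_that("global index sums oriented within-trait ranks", {
  tab <- data.frame(
    lat = c(1.0, 2.0, 3.0),     # short latency = poor-like -> orientation -1
    flex = c(80, 50, 20),       # low flexibility = poor-like -> -1
    fi = c(50, 100, 200),       # high activity = poor-like -> +1
    risk = c(12, 6, 1))         # few assessments = poor-like -> -1
  ori <- c(lat = -1, flex = -1, fi = 1, risk = -1)
  gi <- global_index(tab, ori)
  # hand enumeration: rat1 ranks (3,1,1,1)=6; rat2 (2,2,2,2)=8;
  # rat3 (1,3,3,3)=10
  expect_equal(gi$index, c(6, 8, 10))
  # identical rows share the index through average ranks
  tab2 <- tab[c(1, 1, 3), ]
  gi2 <- global_index(tab2, ori)
  expect_equal(gi2$index[1], gi2$index[2])
  # invariant under a strictly monotone transform of one column
  tab3 <- tab
  tab3$fi <- log(tab3$fi)
  expect_equal(global_index(tab3, ori)$index, gi$index)
  # missing cells are ranked on the available values and flagged
  tab4 <- tab
  tab4$lat[2] <- NA
  gi4 <- global_index(tab4, ori)
  expect_identical(gi4$n_missing, c(0, 1, 0))
})

test_that("median-split profiles mark the poor-like side, ties high", {
  tab <- data.frame(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1))
  ori <- c(a = 1, b = -1)
  prof <- median_split_profile(tab, ori)
  # oriented medians: a >= 2.5 marks rows 3,4; -b >= -2.5 marks rows 3,4
  expect_identical(prof$a, c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(prof$b, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(prof$n_high, c(0, 0, 2, 2))
  # a score exactly at the median is marked high
  tab2 <- data.frame(a = c(1, 2, 3))
  expect_identical(median_split_profile(tab2, c(a = 1))$a,
                   c(FALSE, TRUE, TRUE))
  # degenerate cohort of identical scores: everyone marked
  tab3 <- data.frame(a = rep(5, 4))
  expect_true(all(median_split_profile(tab3, c(a = 1))$a))
})

test_that("final valuations separate archetypes as in the learned
           Q-value summary", {
  recs <- list(
    good = lapply(1:6, function(s)
      run_session(cfg_episode, params_good, seed = s, keep_log = FALSE)),
    poor = lapply(1:6, function(s)
      run_session(cfg_episode, params_poor, seed = 100 + s,
                  keep_log = FALSE)))
  qs <- qvalue_summary(recs)
  get <- function(g, p) qs$mean_q[qs$group == g & qs$pair == p]
  # neutral agents value the advantageous pair near its expected 2/3 and
  # the disadvantageous pair below zero
  expect_equal(get("good", "advantageous"), 2 / 3, tolerance = 0.3)
  expect_lt(get("good", "disadvantageous"), 0)
  # poor agents over-value the disadvantageous pair
  expect_gt(get("poor", "disadvantageous"), get("poor", "advantageous"))
  expect_gt(get("poor", "advantageous"), 0)
  # an agent that cannot learn keeps all values at zero
  frozen <- list(zero = list(run_session(
    cfg_episode, trait_params(1e-9, Inf), seed = 1, keep_log = FALSE)))
  qs0 <- qvalue_summary(frozen)
  expect_true(all(abs(qs0$mean_q) < 1e-6))
  expect_error(qvalue_summary(list(empty = list())), "empty group")
})
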