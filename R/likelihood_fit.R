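#' Model variant: which behavioural traits are free
#'
#' The estimation always includes the initial learning rate `alpha0` and the
#' softmax temperature `epsilon`. Each trait flag frees one further
#' parameter: reward seeking frees `omega` (otherwise pinned at 1), risk
#' seeking frees `rho` (otherwise 0), and cognitive inflexibility frees the
#' decay constant `tau0` (otherwise fixed at infinity, i.e. a constant
#' learning rate). The full model therefore has five free parameters.
#'
#' @param reward_seeking,risk_seeking,inflexibility logical flags.
#' @return An object of class `model_variant`.
#' @export
model_variant <- function(reward_seeking = TRUE, risk_seeking = TRUE,
                          inflexibility = TRUE) {
  structure(list(
    reward_seeking = isTRUE(reward_seeking),
    risk_seeking = isTRUE(risk_seeking),
    inflexibility = isTRUE(inflexibility),
    n_free_parameters = 2L + isTRUE(reward_seeking) + isTRUE(risk_seeking) +
      isTRUE(inflexibility)
  ), class = "model_variant")
}

#' The seven nested trait variants
#'
#' Full model, the three two-trait models and the three one-trait models,
#' named by their active traits.
#'
#' @return Named list of [model_variant()] objects.
#' @export
variant_set <- function() {
  list(
    full = model_variant(TRUE, TRUE, TRUE),
    `reward+risk` = model_variant(TRUE, TRUE, FALSE),
    `reward+inflex` = model_variant(TRUE, FALSE, TRUE),
    `risk+inflex` = model_variant(FALSE, TRUE, TRUE),
    reward = model_variant(TRUE, FALSE, FALSE),
    risk = model_variant(FALSE, TRUE, FALSE),
    inflex = model_variant(FALSE, FALSE, TRUE)
  )
}

variant_nested_in <- function(nested, full) {
  (!nested$reward_seeking || full$reward_seeking) &&
    (!nested$risk_seeking || full$risk_seeking) &&
    (!nested$inflexibility || full$inflexibility) &&
    nested$n_free_parameters < full$n_free_parameters
}

#' Search specification for the simulation-based fit
#'
#' Two-stage search: a coarse grid over the free parameters followed by
#' Nelder-Mead refinement from the best point, every likelihood evaluation
#' reusing the same per-run seeds (common random numbers) so the objective
#' is deterministic given the master seed.
#'
#' @param n_runs simulated sessions per likelihood evaluation (default 50).
#' @param grid named list of grid values per parameter.
#' @param bounds named list of `c(lo, hi)` search bounds (`tau0` upper bound
#'   may be `Inf`; internally the decay rate `1/tau0` is searched).
#' @param refine_maxit Nelder-Mead iteration budget.
#' @param default_bin_n assumed per-bin trial count when a profile carries
#'   only percentages.
#' @param posterior_temper temperature for the grid-posterior trait
#'   summary: grid weights are `exp(logL / posterior_temper)`. The
#'   simulated log-likelihood carries seed-to-seed evaluation noise of
#'   several units at the default run budget (measured SD roughly 3-15
#'   across independent seed sets), so differences on that scale are not
#'   evidence; the default temperature of 5 treats them accordingly. Set
#'   to 1 for untempered weights.
#' @param map_shrinkage if `TRUE`, candidate selection maximises the
#'   log-likelihood minus a weak quadratic penalty toward neutral trait
#'   values (log-normal around omega = 1 with sd 0.5, normal around rho = 0
#'   with sd 1, log-normal around alpha0 = 0.1 and epsilon = 0.5 with sd 1,
#'   half-normal on the decay rate 1/tau0 with sd 1/300 per second). This
#'   maximum-a-posteriori variant regularises the flat directions of the
#'   simulated likelihood (e.g. the softmax scale degeneracy between omega
#'   and epsilon on saturated profiles) and is the recommended estimator for
#'   per-individual trait profiling; model comparison uses the pure
#'   maximum-likelihood default. The reported `log_likelihood` is always
#'   the unpenalised value at the selected parameters.
#' @return An object of class `search_spec`.
#' @export
search_spec <- function(n_runs = 50,
                        grid = list(
                          alpha0 = c(0.02, 0.06, 0.15, 0.35, 0.8),
                          tau0 = c(120, 300, 900, Inf),
                          omega = c(0.6, 1, 1.6, 2.5, 4),
                          rho = c(-0.75, -0.25, 0.25, 0.75, 1.5),
                          epsilon = c(0.1, 0.3, 0.8, 2)
                        ),
                        bounds = list(
                          alpha0 = c(0.01, 1),
                          tau0 = c(60, Inf),
                          omega = c(0.5, 4),
                          rho = c(-1, 2),
                          epsilon = c(0.05, 5)
                        ),
                        refine_maxit = 150,
                        default_bin_n = 30,
                        posterior_temper = 5,
                        map_shrinkage = FALSE) {
  stopifnot(n_runs >= 2, posterior_temper > 0)
  structure(list(n_runs = n_runs, grid = grid, bounds = bounds,
                 refine_maxit = refine_maxit,
                 default_bin_n = default_bin_n,
                 posterior_temper = posterior_temper,
                 map_shrinkage = isTRUE(map_shrinkage)),
            class = "search_spec")
}

# weak quadratic penalty toward neutral traits (see search_spec docs);
# subtracted from the log-likelihood when map_shrinkage is on
.shrink_penalty <- function(params) {
  k <- if (is.infinite(params$tau0)) 0 else 1 / params$tau0
  (log(params$omega) / 0.5)^2 / 2 +
    (params$rho / 1)^2 / 2 +
    (log(params$alpha0 / 0.1) / 1)^2 / 2 +
    (log(params$epsilon / 0.5) / 1)^2 / 2 +
    (k * 300)^2 / 2
}

# ---- parameter transforms -------------------------------------------------

free_param_names <- function(variant) {
  c("alpha0",
    if (variant$reward_seeking) "omega",
    if (variant$risk_seeking) "rho",
    if (variant$inflexibility) "tau0",
    "epsilon")
}

# unconstrained z <-> bounded parameter value; log-logistic scale for the
# positive parameters, linear-logistic for rho, decay-rate scale for tau0
.encode_one <- function(name, value, bounds) {
  b <- bounds[[name]]
  clamp <- function(f) pmin(pmax(f, 1e-7), 1 - 1e-7)
  if (name == "tau0") {
    kmax <- 1 / b[1]
    k <- if (is.infinite(value)) 0 else 1 / value
    qlogis(clamp(k / kmax))
  } else if (name == "rho") {
    qlogis(clamp((value - b[1]) / (b[2] - b[1])))
  } else {
    qlogis(clamp((log(value) - log(b[1])) / (log(b[2]) - log(b[1]))))
  }
}

.decode_one <- function(name, z, bounds) {
  b <- bounds[[name]]
  f <- plogis(z)
  if (name == "tau0") {
    k <- f / b[1]                       # rate in [0, 1/lower-bound)
    if (k < 1e-12) Inf else 1 / k
  } else if (name == "rho") {
    b[1] + f * (b[2] - b[1])
  } else {
    exp(log(b[1]) + f * (log(b[2]) - log(b[1])))
  }
}

encode_params <- function(params, variant, bounds) {
  nm <- free_param_names(variant)
  vapply(nm, function(n) .encode_one(n, params[[n]], bounds), 0)
}

decode_params <- function(z, variant, bounds) {
  nm <- free_param_names(variant)
  v <- setNames(
    vapply(seq_along(nm), function(i) .decode_one(nm[i], z[i], bounds), 0),
    nm)
  trait_params(
    alpha0 = v[["alpha0"]],
    tau0 = if (variant$inflexibility) v[["tau0"]] else Inf,
    omega = if (variant$reward_seeking) v[["omega"]] else 1,
    rho = if (variant$risk_seeking) v[["rho"]] else 0,
    epsilon = v[["epsilon"]])
}

# ---- fast pooled simulation ----------------------------------------------

# flatten the config once per fit for lean C++ calls
.cfg_vectors <- function(config) {
  list(
    reward = unname(config$reward_pellets),
    penalty = unname(config$penalty_pellets),
    prob = unname(config$penalty_prob),
    timeout = unname(config$timeout_seconds),
    holes = as.integer(config$location_map[config$option_labels]),
    adv = config$option_labels %in% config$advantageous_set,
    episode = config$episode_seconds,
    session = config$session_seconds,
    cap = config$pellet_cap,
    forced = config$forced_exploration_seconds,
    bin = config$bin_seconds,
    behavioural = config$clock == "behavioural",
    n_bins = as.integer(ceiling(config$session_seconds / config$bin_seconds)),
    n_holes = length(config$option_labels)
  )
}

.cpp_session_lean <- function(v, params, q, pn, pmean, pm2, t_offset = 0) {
  cpp_run_session(v$reward, v$penalty, v$prob, v$timeout, v$holes, v$adv,
                  v$episode, v$session, v$cap, v$forced, v$bin,
                  v$behavioural, t_offset,
                  params$alpha0, params$tau0, params$omega, params$rho,
                  params$epsilon, q, pn, pmean, pm2, FALSE, 2000L)
}

# pooled per-bin advantageous/total counts over run_seeds; optionally also a
# carried-over reversal session per run (same seeded stream)
sim_pooled_bins <- function(params, config, run_seeds, joint = FALSE,
                            v = .cfg_vectors(config)) {
  vr <- if (joint) .cfg_vectors(make_reversed(config)) else NULL
  z <- numeric(v$n_holes)
  adv <- tot <- numeric(v$n_bins)
  radv <- rtot <- numeric(v$n_bins)
  for (s in run_seeds) {
    res <- with_seed(s, {
      a <- .cpp_session_lean(v, params, z, z, z, z)
      b <- if (joint)
        .cpp_session_lean(vr, params, a$q, a$pen_n, a$pen_mean, a$pen_m2,
                          t_offset = a$elapsed_seconds)
      list(a = a, b = b)
    })
    adv <- adv + res$a$bin_adv
    tot <- tot + res$a$bin_tot
    if (joint) {
      radv <- radv + res$b$bin_adv
      rtot <- rtot + res$b$bin_tot
    }
  }
  list(rgt = list(adv = adv, tot = tot),
       rev = if (joint) list(adv = radv, tot = rtot))
}

#' Simulated per-bin advantageous-choice probabilities
#'
#' Runs `n_runs` seeded sessions at the given parameters, pools the
#' advantageous and total trial counts per 10-minute bin across runs, and
#' returns the Laplace-smoothed probability `(adv + 1) / (tot + 2)` per bin
#' (strictly inside (0, 1)); bins empty in every run are `NA`. Identical
#' seeds give identical output — the common-random-number contract of the
#' fit.
#'
#' @param params a [trait_params()].
#' @param config an [rgt_config()].
#' @param n_runs number of simulated sessions (>= 2; default 50).
#' @param seed master seed from which the per-run seeds are derived.
#' @return A list with `p`, `adv`, `tot`, `n_runs`.
#' @export
simulate_bin_distributions <- function(params, config = rgt_config(),
                                       n_runs = 50, seed = 1) {
  stopifnot(n_runs >= 2)
  counts <- sim_pooled_bins(params, config, seed_runs(seed, n_runs))$rgt
  p <- ifelse(counts$tot > 0, (counts$adv + 1) / (counts$tot + 2), NA_real_)
  list(p = p, adv = counts$adv, tot = counts$tot, n_runs = n_runs)
}

# binomial log-likelihood plus the number of bins used
.pll <- function(profile, p, default_bin_n = 30, warn = TRUE) {
  x <- unname(profile$percent)
  n <- unname(profile$counts)
  if (all(is.na(x))) stop("degenerate profile: no observed bins")
  if (any(is.na(n) & !is.na(x))) {
    if (warn) warning("profile has percentages without trial counts; ",
                      "assuming ", default_bin_n, " trials per bin")
    n[is.na(n) & !is.na(x)] <- default_bin_n
  }
  use <- !is.na(x) & !is.na(p) & n > 0
  k <- round(x[use] * n[use] / 100)
  list(ll = sum(dbinom(k, n[use], p[use], log = TRUE)), n_bins = sum(use))
}

#' Binomial log-likelihood of an observed profile under simulated bin
#' probabilities
#'
#' Each available bin contributes an independent binomial term: the observed
#' advantageous count (`round(x_k * n_k / 100)` of `n_k` trials) at the
#' simulation-derived probability `p_k`. Bins missing on either side are
#' dropped. Profiles carrying only percentages fall back to an assumed
#' per-bin trial count, with a warning.
#'
#' @param profile a `performance_profile`.
#' @param bin_probs output of [simulate_bin_distributions()] or a plain
#'   probability vector.
#' @param default_bin_n assumed count for percent-only profiles.
#' @return The summed log-likelihood (scalar).
#' @export
profile_log_likelihood <- function(profile, bin_probs, default_bin_n = 30) {
  p <- if (is.list(bin_probs)) bin_probs$p else bin_probs
  .pll(profile, p, default_bin_n)$ll
}

# ---- maximum-likelihood fitting ------------------------------------------

# objective factory: maximises summed logL over (rgt, optional reversal)
# profiles with fixed per-run seeds; tracks the best evaluation seen
.make_objective <- function(rgt_profile, reversal_profile, config, spec,
                            run_seeds, variant) {
  v <- .cfg_vectors(config)
  joint <- !is.null(reversal_profile)
  best <- list(ll = -Inf, obj = -Inf, params = NULL, n_bins = 0L)
  n_eval <- 0L
  eval_params <- function(params) {
    counts <- sim_pooled_bins(params, config, run_seeds, joint = joint,
                              v = v)
    p_rgt <- ifelse(counts$rgt$tot > 0,
                    (counts$rgt$adv + 1) / (counts$rgt$tot + 2), NA_real_)
    a <- .pll(rgt_profile, p_rgt, spec$default_bin_n, warn = FALSE)
    ll <- a$ll
    nb <- a$n_bins
    if (joint) {
      p_rev <- ifelse(counts$rev$tot > 0,
                      (counts$rev$adv + 1) / (counts$rev$tot + 2), NA_real_)
      b <- .pll(reversal_profile, p_rev, spec$default_bin_n, warn = FALSE)
      ll <- ll + b$ll
      nb <- nb + b$n_bins
    }
    n_eval <<- n_eval + 1L
    val <- if (spec$map_shrinkage) ll - .shrink_penalty(params) else ll
    if (is.finite(val) && val > best$obj) {
      best <<- list(ll = ll, obj = val, params = params, n_bins = nb)
    }
    val
  }
  list(
    eval_params = eval_params,
    eval_z = function(z) {
      params <- decode_params(z, variant, spec$bounds)
      -eval_params(params)  # minimised
    },
    best = function() best,
    n_eval = function() n_eval
  )
}

# Posterior-mean trait summary over the coarse grid (uniform prior on the
# search box): likelihood-weighted average of each free parameter, on the
# log scale for alpha0 and epsilon and on the decay-rate scale for tau0.
# The simulated likelihood of a single session profile is flat along some
# directions (e.g. the reward weight on saturated profiles), where the ML
# point is arbitrary; averaging over the plateau yields a stabler
# per-individual trait summary for profiling and recovery analyses.
.grid_posterior_mean <- function(grid_candidates, vals, variant,
                                 temper = 5) {
  ok <- is.finite(vals)
  if (!any(ok)) return(NULL)
  w <- exp((vals[ok] - max(vals[ok])) / temper)
  w <- w / sum(w)
  gp <- grid_candidates[ok]
  wmean <- function(f) sum(w * vapply(gp, f, 0))
  trait_params(
    alpha0 = exp(wmean(function(p) log(p$alpha0))),
    tau0 = {
      k <- wmean(function(p) if (is.infinite(p$tau0)) 0 else 1 / p$tau0)
      if (k < 1e-12) Inf else 1 / k
    },
    omega = wmean(function(p) p$omega),
    rho = wmean(function(p) p$rho),
    epsilon = exp(wmean(function(p) log(p$epsilon))))
}

.grid_params <- function(variant, spec) {
  nm <- free_param_names(variant)
  g <- expand.grid(spec$grid[nm], KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i) {
    v <- as.list(g[i, , drop = FALSE])
    trait_params(
      alpha0 = v$alpha0,
      tau0 = if (variant$inflexibility) v$tau0 else Inf,
      omega = if (variant$reward_seeking) v$omega else 1,
      rho = if (variant$risk_seeking) v$rho else 0,
      epsilon = v$epsilon)
  })
}

#' Simulation-based maximum-likelihood fit of the trait parameters
#'
#' Estimates an individual's trait parameters from its binned performance
#' profile by maximising the simulated binomial likelihood: a coarse grid
#' over the variant's free parameters followed by Nelder-Mead refinement
#' from the best candidate. Every evaluation simulates `spec$n_runs`
#' sessions with the same per-run seeds (common random numbers), so the fit
#' is fully reproducible from the master seed. Inactive traits are pinned
#' at their neutral values.
#'
#' @param profile the RGT `performance_profile` to fit.
#' @param variant a [model_variant()].
#' @param config an [rgt_config()].
#' @param spec a [search_spec()].
#' @param seed master seed governing all per-evaluation seeds.
#' @param extra_starts list of [trait_params()] used as additional
#'   refinement starts (e.g. optima of nested variants, guaranteeing the
#'   fitted likelihood dominates theirs under the shared seeds).
#' @param reversal_profile optional reversal `performance_profile`; when
#'   supplied the likelihood is the sum of RGT and reversal bin terms, the
#'   reversal simulated with carried-over values on the reversed task.
#' @return An object of class `fit_result`: fitted [trait_params()]
#'   (`params`, the maximum-likelihood point), `params_posterior_mean` (the
#'   likelihood-weighted average over the coarse grid under a uniform prior
#'   on the search box — the recommended per-individual trait summary,
#'   since the simulated likelihood can be flat along some directions),
#'   `log_likelihood`, `n_obs` (bins used), `n_runs`, `seed`,
#'   `n_evaluations`, the variant, and whether the fit was joint.
#' @export
fit_ml <- function(profile, variant = model_variant(),
                   config = rgt_config(), spec = search_spec(), seed = 1,
                   extra_starts = list(), reversal_profile = NULL) {
  stopifnot(inherits(profile, "performance_profile"),
            inherits(variant, "model_variant"),
            inherits(spec, "search_spec"))
  run_seeds <- seed_runs(seed, spec$n_runs)
  obj <- .make_objective(profile, reversal_profile, config, spec,
                         run_seeds, variant)

  grid_candidates <- .grid_params(variant, spec)
  candidates <- c(grid_candidates, extra_starts)
  vals <- vapply(candidates, obj$eval_params, 0)
  if (!any(is.finite(vals))) {
    stop("no finite likelihood found on the search grid")
  }
  post_mean <- .grid_posterior_mean(
    grid_candidates, vals[seq_along(grid_candidates)], variant,
    temper = spec$posterior_temper %||% 5)
  start <- candidates[[which.max(vals)]]
  z0 <- encode_params(start, variant, spec$bounds)
  optim(z0, obj$eval_z, method = "Nelder-Mead",
        control = list(maxit = spec$refine_maxit))
  best <- obj$best()
  structure(list(
    variant = variant,
    params = best$params,
    params_posterior_mean = post_mean,
    log_likelihood = best$ll,
    n_obs = best$n_bins,
    n_runs = spec$n_runs,
    seed = seed,
    run_seeds = run_seeds,
    n_evaluations = obj$n_eval(),
    joint = !is.null(reversal_profile)
  ), class = "fit_result")
}

#' Joint fit to RGT and reversal profiles of one individual
#'
#' Convenience wrapper for [fit_ml()] with a reversal profile: the
#' likelihood sums the RGT-session and reversal-session bin terms, the
#' reversal being simulated from each run's end-of-RGT state on the
#' spatially reversed task. With a `NULL` reversal profile it reduces
#' exactly to [fit_ml()].
#'
#' @inheritParams fit_ml
#' @param rgt_profile,reversal_profile the two `performance_profile`s.
#' @return A `fit_result`.
#' @export
fit_joint <- function(rgt_profile, reversal_profile,
                      variant = model_variant(), config = rgt_config(),
                      spec = search_spec(), seed = 1,
                      extra_starts = list()) {
  fit_ml(rgt_profile, variant = variant, config = config, spec = spec,
         seed = seed, extra_starts = extra_starts,
         reversal_profile = reversal_profile)
}

#' @export
print.fit_result <- function(x, ...) {
  tr <- c(if (x$variant$reward_seeking) "reward",
          if (x$variant$risk_seeking) "risk",
          if (x$variant$inflexibility) "inflex")
  cat(sprintf("fit_result (%s; k=%d%s): logL=%.3f over %d bins\n",
              if (length(tr)) paste(tr, collapse = "+") else "baseline",
              x$variant$n_free_parameters,
              if (x$joint) ", joint RGT+reversal" else "",
              x$log_likelihood, x$n_obs))
  print(x$params)
  invisible(x)
}

#' Fit every model variant to every individual of a cohort
#'
#' Fits the nested variants first, then the full model with the nested
#' optima as additional refinement starts, so that under the shared
#' per-rat seeds the full model's likelihood dominates every nested
#' variant's — the premise of the likelihood-ratio test. Per-rat master
#' seeds are derived from `seed`, identical across variants (common random
#' numbers).
#'
#' @param rgt_profiles named list of RGT `performance_profile`s.
#' @param variants named list of [model_variant()]s, one of which must be
#'   named `"full"`.
#' @param reversal_profiles optional named list of reversal profiles (same
#'   names) for joint fits.
#' @inheritParams fit_ml
#' @return Named list (by variant) of named lists (by rat) of
#'   `fit_result`s.
#' @export
fit_cohort_variants <- function(rgt_profiles, variants = variant_set(),
                                config = rgt_config(), spec = search_spec(),
                                seed = 1, reversal_profiles = NULL) {
  stopifnot("full" %in% names(variants))
  ids <- names(rgt_profiles) %||% as.character(seq_along(rgt_profiles))
  names(rgt_profiles) <- ids
  nested_names <- setdiff(names(variants), "full")
  out <- setNames(vector("list", length(variants)), names(variants))
  for (vn in names(variants)) out[[vn]] <- setNames(
    vector("list", length(ids)), ids)
  for (i in seq_along(ids)) {
    id <- ids[i]
    rat_seed <- seed + i
    rev_prof <- if (!is.null(reversal_profiles)) reversal_profiles[[id]]
    nested_params <- list()
    for (vn in nested_names) {
      f <- fit_ml(rgt_profiles[[id]], variant = variants[[vn]],
                  config = config, spec = spec, seed = rat_seed,
                  reversal_profile = rev_prof)
      out[[vn]][[id]] <- f
      nested_params[[vn]] <- f$params
    }
    out$full[[id]] <- fit_ml(rgt_profiles[[id]], variant = variants$full,
                             config = config, spec = spec, seed = rat_seed,
                             extra_starts = unname(nested_params),
                             reversal_profile = rev_prof)
  }
  out
}

#' Read / write a fit result as JSON
#'
#' @param fit a `fit_result`.
#' @param path file path.
#' @export
write_fit_json <- function(fit, path) {
  x <- list(
    variant = unclass(fit$variant),
    params = unclass(fit$params),
    log_likelihood = fit$log_likelihood,
    n_obs = fit$n_obs, n_runs = fit$n_runs, seed = fit$seed,
    run_seeds = fit$run_seeds, n_evaluations = fit$n_evaluations,
    joint = fit$joint)
  if (is.infinite(x$params$tau0)) x$params$tau0 <- "inf"
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tau0 <- x$params$tau0
  if (is.character(tau0)) tau0 <- if (tolower(tau0) == "inf") Inf else
    as.numeric(tau0)
  structure(list(
    variant = structure(as.list(x$variant), class = "model_variant"),
    params = trait_params(x$params$alpha0, tau0, x$params$omega,
                          x$params$rho, x$params$epsilon),
    log_likelihood = x$log_likelihood,
    n_obs = x$n_obs, n_runs = x$n_runs, seed = x$seed,
    run_seeds = x$run_seeds, n_evaluations = x$n_evaluations,
    joint = isTRUE(x$joint)
  ), class = "fit_result")
}
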