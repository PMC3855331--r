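#' Bayesian Information Criterion of a fit
#'
#' `k * ln(n_obs) - 2 * logL`, with `k` the variant's free-parameter count
#' and `n_obs` the number of observation bins that entered the likelihood
#' (6 per session by default; 12 for a joint RGT + reversal fit). Lower is
#' better.
#'
#' @param fit a `fit_result`.
#' @param n_obs observation count; defaults to the fit's own bin count.
#' @return The BIC (scalar).
#' @export
bic <- function(fit, n_obs = NULL) {
  n <- n_obs %||% fit$n_obs
  stopifnot(n >= 1)
  fit$variant$n_free_parameters * log(n) - 2 * fit$log_likelihood
}

#' Likelihood-ratio test between nested trait variants
#'
#' `2 * (logL_full - logL_nested)` referred to the chi-squared distribution
#' with degrees of freedom equal to the free-parameter difference (times
#' the number of individuals when the fits are cohort sums). The likelihood
#' is simulation-based, so the chi-squared reference is approximate; the
#' result carries a `simulation_based` caveat flag.
#'
#' @param full_fit,nested_fit `fit_result`s (or cohort aggregates from
#'   [cohort_fit()]); the nested variant's active traits must be a strict
#'   subset of the full variant's.
#' @return A list with `statistic`, `df`, `p_value`, `simulation_based`.
#' @export
lrt <- function(full_fit, nested_fit) {
  if (!variant_nested_in(nested_fit$variant, full_fit$variant)) {
    stop("variants are not properly nested")
  }
  n_ind_f <- full_fit$n_individuals %||% 1L
  n_ind_n <- nested_fit$n_individuals %||% 1L
  stopifnot(n_ind_f == n_ind_n)
  stat <- 2 * (full_fit$log_likelihood - nested_fit$log_likelihood)
  stat <- max(stat, 0)
  df <- (full_fit$variant$n_free_parameters -
           nested_fit$variant$n_free_parameters) * n_ind_f
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE),
       simulation_based = TRUE)
}

#' Aggregate per-individual fits of one variant into a cohort fit
#'
#' Sums log-likelihoods and observation counts across individuals; the BIC
#' of the aggregate is the sum of the per-individual BICs (each individual
#' has its own parameters, so the cohort free-parameter count scales with
#' the number of individuals — recorded in `n_individuals` and used by
#' [lrt()] for the degrees of freedom).
#'
#' @param fits list of `fit_result`s for the same variant.
#' @return A list of class `cohort_fit`.
#' @export
cohort_fit <- function(fits) {
  stopifnot(length(fits) >= 1)
  v <- fits[[1]]$variant
  ok <- vapply(fits, function(f)
    identical(unclass(f$variant), unclass(v)), NA)
  stopifnot(all(ok))
  structure(list(
    variant = v,
    log_likelihood = sum(vapply(fits, `[[`, 0, "log_likelihood")),
    n_obs = sum(vapply(fits, `[[`, 0, "n_obs")),
    bic_total = sum(vapply(fits, bic, 0)),
    n_individuals = length(fits)
  ), class = "cohort_fit")
}

#' Model-comparison table across trait variants
#'
#' One row per variant: free parameters per individual, cohort
#' log-likelihood, cohort BIC (sum of per-individual BICs), and the
#' likelihood-ratio test against the full model.
#'
#' @param fits_by_variant named list (variant name -> list of per-rat
#'   `fit_result`s), as returned by [fit_cohort_variants()]; must contain
#'   `"full"`.
#' @return A `data.frame` of class `comparison_table`.
#' @export
comparison_table <- function(fits_by_variant) {
  stopifnot("full" %in% names(fits_by_variant))
  agg <- lapply(fits_by_variant, cohort_fit)
  full <- agg$full
  rows <- lapply(names(agg), function(vn) {
    a <- agg[[vn]]
    lr <- if (vn == "full") list(statistic = NA_real_, df = NA_integer_,
                                 p_value = NA_real_) else lrt(full, a)
    data.frame(
      variant = vn,
      k = a$variant$n_free_parameters,
      log_likelihood = a$log_likelihood,
      bic = a$bic_total,
      lrt_statistic = lr$statistic,
      lrt_df = lr$df,
      lrt_p = lr$p_value
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_table", class(out))
  out
}

#' Monte-Carlo permutation test of a correlation
#'
#' Correlation of the paired values with a two-sided permutation p-value:
#' one vector is randomly permuted `n_perm` times and
#' `p = (1 + #{|r*| >= |r|}) / (n_perm + 1)`, which is a valid p-value at
#' any finite `n_perm` and never smaller than `1/(n_perm + 1)`.
#'
#' @param x,y equal-length numeric vectors (length >= 3, non-zero
#'   variance).
#' @param n_perm number of permutations (>= 100; the reference analysis
#'   used 1e5).
#' @param method `"pearson"` or `"spearman"`.
#' @return A list with `r`, `p_value`, `n_perm`.
#' @export
mc_permutation_corr <- function(x, y, n_perm = 10000,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3, n_perm >= 100)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined correlation: an input vector has zero variance")
  }
  r <- cor(x, y, method = method)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    rs <- cor(x, sample(y), method = method)
    if (abs(rs) >= abs(r) - 1e-12) hits <- hits + 1L
  }
  list(r = r, p_value = (1 + hits) / (n_perm + 1), n_perm = n_perm)
}

#' Group correlation of median-split scores
#'
#' Each vector is reduced to +1 (at or above its own median) / -1 (below),
#' and the correlation of the two sign vectors is tested with the
#' Monte-Carlo permutation test. Measures whether two scores agree on the
#' classification of individuals as high or low, regardless of scale.
#'
#' @inheritParams mc_permutation_corr
#' @return A list with `r`, `p_value`, `n_perm`, `sign_x`, `sign_y`.
#' @export
group_correlation <- function(x, y, n_perm = 10000) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  sx <- ifelse(x >= median(x), 1, -1)
  sy <- ifelse(y >= median(y), 1, -1)
  if (sd(sx) == 0 || sd(sy) == 0) {
    stop("degenerate median split: all individuals on one side")
  }
  mc <- mc_permutation_corr(sx, sy, n_perm = n_perm)
  list(r = mc$r, p_value = mc$p_value, n_perm = n_perm,
       sign_x = sx, sign_y = sy)
}

#' Sum-of-ranks composite index across trait scores
#'
#' Each score column is oriented so that larger means more poor-like,
#' ranked within the cohort (average ranks for ties, missing values ranked
#' on the available individuals and flagged), and the ranks are summed per
#' individual. Invariant under any strictly monotone transform of any
#' single column.
#'
#' @param score_table data.frame or matrix, one column per trait score.
#' @param orientations named vector of +1 / -1 per column: +1 if a higher
#'   raw score is more poor-like, -1 if a lower raw score is.
#' @return A data.frame with `index` (rank sum) and `n_missing` per row.
#' @export
global_index <- function(score_table, orientations) {
  score_table <- as.data.frame(score_table)
  stopifnot(all(names(score_table) %in% names(orientations)))
  ranks <- vapply(names(score_table), function(cn) {
    v <- score_table[[cn]] * orientations[[cn]]
    r <- rep(NA_real_, length(v))
    ok <- !is.na(v)
    r[ok] <- rank(v[ok], ties.method = "average")
    r
  }, numeric(nrow(score_table)))
  data.frame(
    index = rowSums(ranks, na.rm = TRUE),
    n_missing = rowSums(is.na(ranks)),
    row.names = rownames(score_table)
  )
}

#' Median-split trait profile table
#'
#' Marks, per individual and per trait, whether the oriented score lies on
#' the poor-like side of (or exactly at) the cohort median, and counts the
#' marks per individual. Ties at the median count as high.
#'
#' @inheritParams global_index
#' @param cohort_scores data.frame of raw trait scores.
#' @return A data.frame of class `trait_profile_table`: one logical column
#'   per trait plus `n_high`.
#' @export
median_split_profile <- function(cohort_scores, orientations) {
  cohort_scores <- as.data.frame(cohort_scores)
  stopifnot(all(names(cohort_scores) %in% names(orientations)))
  marks <- vapply(names(cohort_scores), function(cn) {
    v <- cohort_scores[[cn]] * orientations[[cn]]
    v >= median(v, na.rm = TRUE)
  }, logical(nrow(cohort_scores)))
  marks <- as.data.frame(marks)
  marks$n_high <- rowSums(marks, na.rm = TRUE)
  rownames(marks) <- rownames(cohort_scores)
  class(marks) <- c("trait_profile_table", class(marks))
  marks
}

#' End-of-session valuation of advantageous vs disadvantageous options
#'
#' Pools the final Q-values over the holes carrying the disadvantageous
#' (A, B) and advantageous (C, D) contingencies across the sessions of each
#' group, returning the group mean and a 95% t-interval per pair.
#'
#' @param records_by_group named list of lists of `session_record`s.
#' @return A data.frame with columns `group`, `pair`, `mean_q`, `ci_lo`,
#'   `ci_hi`, `n`.
#' @export
qvalue_summary <- function(records_by_group) {
  stopifnot(length(records_by_group) >= 1)
  rows <- list()
  for (g in names(records_by_group)) {
    recs <- records_by_group[[g]]
    if (length(recs) == 0) stop("empty group: ", g)
    pool <- list(disadvantageous = numeric(0), advantageous = numeric(0))
    for (r in recs) {
      cfg <- r$config_used
      q <- r$final_state$q_values
      for (opt in cfg$option_labels) {
        pair <- if (opt %in% cfg$advantageous_set) "advantageous" else
          "disadvantageous"
        pool[[pair]] <- c(pool[[pair]], q[cfg$location_map[[opt]]])
      }
    }
    for (pair in names(pool)) {
      v <- pool[[pair]]
      m <- mean(v)
      half <- if (length(v) > 1)
        qt(0.975, length(v) - 1) * sd(v) / sqrt(length(v)) else 0
      rows[[length(rows) + 1]] <- data.frame(
        group = g, pair = pair, mean_q = m,
        ci_lo = m - half, ci_hi = m + half, n = length(v))
    }
  }
  do.call(rbind, rows)
}
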