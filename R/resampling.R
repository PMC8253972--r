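# Resampling inference: subsampling bootstrap, permutation nulls, paired
# network-level comparisons, cross-modality similarity-profile correlation,
# and the best-modality count test.

#' Bootstrap confidence interval by 90% subsampling
#'
#' Each iteration draws `floor(subsample_frac * N)` dyads without replacement
#' and recomputes the statistic on the corresponding sub-similarity-matrix
#' (similarities and winning rates restricted to the retained dyads). The
#' 95% interval is the 2.5th/97.5th percentile of the draws.
#'
#' @param x a [similarity_matrix()], plain square matrix, or [dyad_cohort()].
#' @param statistic function of a square similarity matrix returning one
#'   number; defaults to [winning_rate()].
#' @param n_boot number of iterations.
#' @param subsample_frac fraction of dyads retained per iteration.
#' @param seed optional integer seed.
#' @param feature_mask used when `x` is a cohort.
#' @return List with `ci` (length 2), `draws`, `n_boot`, `subsample_frac`,
#'   `seed`.
#' @export
bootstrap_ci <- function(x, statistic = winning_rate, n_boot = 1000L,
                         subsample_frac = 0.9, seed = NULL, feature_mask = NULL) {
  s <- sim_values(x, feature_mask)
  n <- nrow(s)
  m <- floor(subsample_frac * n)
  if (m < 2L) stopf("subsample of %d dyads is too small (need >= 2)", m)
  if (n_boot < 1L) stopf("`n_boot` must be at least 1")
  draws <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, m)
      tryCatch(as.numeric(statistic(s[idx, idx, drop = FALSE])),
               error = function(e) stopf(
                 "statistic failed in bootstrap iteration %d (seed %s): %s",
                 b, format(seed %||% "<ambient>"), conditionMessage(e)))
    }, numeric(1L))
  })
  list(ci = unname(stats::quantile(draws, c(0.025, 0.975))), draws = draws,
       n_boot = n_boot, subsample_frac = subsample_frac, seed = seed)
}

#' Permutation test by reshuffling the parent-child mapping
#'
#' Each iteration applies an independent uniform random permutation to the
#' parent assignment (fixed points allowed) and recomputes the statistic.
#' The p-value uses the add-one convention
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, so the attainable floor is
#' `1 / (n_perm + 1)`.
#'
#' @inheritParams bootstrap_ci
#' @param n_perm number of permutations.
#' @return List with `p_value`, `observed`, `null` draws, `n_perm`, `seed`.
#' @export
permutation_test <- function(x, statistic = winning_rate, n_perm = 1000L,
                             seed = NULL, feature_mask = NULL) {
  s <- sim_values(x, feature_mask)
  n <- nrow(s)
  if (n < 3L) stopf("need at least 3 dyads to permute")
  if (n_perm < 1L) stopf("`n_perm` must be at least 1")
  observed <- as.numeric(statistic(s))
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      as.numeric(statistic(s[, sample.int(n), drop = FALSE]))
    }, numeric(1L))
  })
  list(p_value = (1 + sum(null >= observed)) / (1 + n_perm),
       observed = observed, null = null, n_perm = n_perm, seed = seed)
}

#' Paired comparison of network-level statistics
#'
#' Two-sided paired t-test with a paired-difference Hedges' g
#' (`g = J * mean(d) / sd(d)` with small-sample correction
#' `J = 1 - 3 / (4 df - 1)`, `d = a - b`, sample SD). With the 10 networks
#' plus the whole-brain entry this yields the df = 10 comparisons reported
#' for network-level accuracy contrasts.
#'
#' @param values_a,values_b numeric vectors of matched statistics (same
#'   networks, same order), length >= 3.
#' @param labels optional case labels (e.g. network names).
#' @return Object of class `comparison_result` with `t_stat`, `df`,
#'   `p_value`, `hedges_g`, `n_pairs`.
#' @export
paired_comparison <- function(values_a, values_b, labels = NULL) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) != length(b)) stopf("inputs differ in length (%d vs %d)",
                                    length(a), length(b))
  if (length(a) < 3L) stopf("need at least 3 matched pairs")
  if (any(!is.finite(a)) || any(!is.finite(b))) stopf("non-finite values")
  d <- a - b
  sdd <- stats::sd(d)
  if (sdd == 0) stopf("zero-variance paired differences")
  n <- length(d)
  df <- n - 1L
  t_stat <- mean(d) / (sdd / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df)
  j <- 1 - 3 / (4 * df - 1)
  structure(list(t_stat = t_stat, df = df, p_value = p,
                 hedges_g = j * mean(d) / sdd, n_pairs = n,
                 labels = labels, mean_diff = mean(d)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("paired t-test: t(%d) = %.2f, p = %.3g, Hedges' g = %.2f (n = %d)\n",
              x$df, x$t_stat, x$p_value, x$hedges_g, x$n_pairs))
  invisible(x)
}

#' Correlation between two modalities' similarity profiles
#'
#' Correlates, across dyads, the own-dyad similarities (matrix diagonals)
#' obtained from two modalities (e.g. FC vs GMV), answering whether dyads
#' that are functionally similar are also structurally similar. The p-value
#' permutes one diagonal's dyad order (two-sided on `|r|`, add-one
#' convention).
#'
#' @param sim_a,sim_b [similarity_matrix()] objects (or square matrices) over
#'   the same dyads in the same order, N >= 4.
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @return List with `r`, `p_value`, `null`, `n_dyads`.
#' @export
similarity_profile_correlation <- function(sim_a, sim_b, n_perm = 1000L,
                                           seed = NULL) {
  if (inherits(sim_a, "similarity_matrix") && inherits(sim_b, "similarity_matrix") &&
      !identical(sim_a$children, sim_b$children))
    stopf("the two similarity matrices cover different dyads")
  da <- diag(sim_values(sim_a))
  db <- diag(sim_values(sim_b))
  if (length(da) != length(db)) stopf("dyad counts differ")
  if (length(da) < 4L) stopf("need at least 4 dyads")
  if (stats::sd(da) == 0 || stats::sd(db) == 0)
    stopf("constant diagonal similarities; correlation undefined")
  r <- stats::cor(da, db)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) stats::cor(da, db[sample.int(length(db))]),
           numeric(1L))
  })
  list(r = r, p_value = (1 + sum(abs(null) >= abs(r))) / (1 + n_perm),
       null = null, n_dyads = length(da), n_perm = n_perm, seed = seed)
}

#' Is the best-performing modality best more often than chance?
#'
#' Given the number of cases (network-by-age cells) won by each candidate
#' modality, tests the count of the most frequent winner against a null in
#' which every case independently awards its win uniformly among the
#' candidates (Monte-Carlo, add-one convention).
#'
#' @param best_counts integer vector of wins per candidate (sums to the
#'   number of cases).
#' @param n_candidates number of candidate modalities.
#' @param n_perm Monte-Carlo iterations.
#' @param seed optional integer seed.
#' @return List with `p_value`, `observed`, `n_cases`.
#' @export
best_count_test <- function(best_counts, n_candidates = 3L, n_perm = 1000L,
                            seed = NULL) {
  best_counts <- as.numeric(best_counts)
  if (any(best_counts < 0)) stopf("negative win counts")
  n_cases <- sum(best_counts)
  if (n_cases < 1L) stopf("need at least one case")
  observed <- max(best_counts)
  if (n_candidates < 2L)
    return(list(p_value = 1, observed = observed, n_cases = n_cases,
                n_perm = n_perm, seed = seed))
  null_max <- with_seed(seed, {
    draws <- stats::rmultinom(n_perm, n_cases, rep(1 / n_candidates, n_candidates))
    apply(draws, 2L, max)
  })
  list(p_value = (1 + sum(null_max >= observed)) / (1 + n_perm),
       observed = observed, n_cases = n_cases, n_perm = n_perm, seed = seed)
}
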