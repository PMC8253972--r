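# The central estimator: point accuracy plus resampling inference, packaged
# as a classed object in the style of a model fit.

new_accuracy_estimate <- function(accuracy, per_child, n_dyads,
                                  ci95 = NULL, boot_draws = NULL,
                                  null_draws = NULL, permutation_p = NULL,
                                  n_boot = 0L, n_perm = 0L,
                                  subsample_frac = NA_real_, seed = NULL,
                                  modality = NULL, n_features = NULL) {
  structure(list(accuracy = accuracy, per_child = per_child, n_dyads = n_dyads,
                 ci95 = ci95, boot_draws = boot_draws, null_draws = null_draws,
                 permutation_p = permutation_p, n_boot = n_boot, n_perm = n_perm,
                 subsample_frac = subsample_frac, seed = seed,
                 modality = modality, n_features = n_features),
            class = "accuracy_estimate")
}

#' Identify parent-child dyads from brain similarity
#'
#' Fits the full identification analysis on one cohort: computes the
#' child-by-parent Pearson similarity matrix, the winning-rate accuracy and
#' per-child winning rates, a 95% confidence interval from a 1,000-iteration
#' bootstrap that subsamples 90% of the dyads without replacement, and a
#' permutation p-value from 1,000 random reshufflings of the parent-child
#' mapping.
#'
#' @param x a [dyad_cohort()] or a precomputed [similarity_matrix()].
#' @param feature_mask optional feature ids to restrict to (ignored when `x`
#'   is already a similarity matrix).
#' @param n_boot bootstrap iterations (0 skips the CI).
#' @param n_perm permutation iterations (0 skips the test).
#' @param subsample_frac fraction of dyads retained per bootstrap iteration.
#' @param seed optional integer seed governing all resampling.
#' @param direction passed to [similarity_matrix()].
#' @return An object of class `accuracy_estimate` with components `accuracy`,
#'   `per_child`, `ci95`, `permutation_p`, `boot_draws`, `null_draws` and run
#'   metadata.
#' @examples
#' co <- simulate_dyad_features(n_dyads = 12, n_features = 60, alpha = 0.8,
#'                              seed = 1)
#' fit <- dyad_identification(co, n_boot = 100, n_perm = 100, seed = 1)
#' print(fit)
#' @export
dyad_identification <- function(x, feature_mask = NULL, n_boot = 1000L,
                                n_perm = 1000L, subsample_frac = 0.9,
                                seed = NULL, direction = "child") {
  sim <- if (inherits(x, "similarity_matrix")) x
         else similarity_matrix(x, feature_mask = feature_mask, direction = direction)
  with_seed(seed, {
    est <- winning_rate_accuracy(sim)
    est$subsample_frac <- subsample_frac
    est$seed <- seed
    if (n_boot > 0L) {
      bt <- bootstrap_ci(sim, n_boot = n_boot, subsample_frac = subsample_frac)
      est$ci95 <- bt$ci
      est$boot_draws <- bt$draws
      est$n_boot <- n_boot
    }
    if (n_perm > 0L) {
      pt <- permutation_test(sim, n_perm = n_perm)
      est$permutation_p <- pt$p_value
      est$null_draws <- pt$null
      est$n_perm <- n_perm
    }
    est
  })
}

#' @export
print.accuracy_estimate <- function(x, ...) {
  cat(sprintf("Dyad identification accuracy (winning rate, chance = 50%%)\n"))
  cat(sprintf("  accuracy: %.1f%%  (N = %d dyads%s)\n", 100 * x$accuracy, x$n_dyads,
              if (!is.null(x$modality)) paste0(", ", x$modality) else ""))
  if (!is.null(x$ci95))
    cat(sprintf("  95%% CI:   [%.1f, %.1f]  (%d-times bootstrap, %.0f%% subsampling)\n",
                100 * x$ci95[1L], 100 * x$ci95[2L], x$n_boot, 100 * x$subsample_frac))
  if (!is.null(x$permutation_p))
    cat(sprintf("  perm. p:  %s  (%d permutations)\n",
                format.pval(x$permutation_p, digits = 3), x$n_perm))
  invisible(x)
}

#' @export
summary.accuracy_estimate <- function(object, ...) {
  print(object)
  q <- stats::quantile(object$per_child, c(0, 0.25, 0.5, 0.75, 1))
  cat("  per-child winning rates:\n")
  print(round(q, 3))
  invisible(object)
}

#' @export
plot.accuracy_estimate <- function(x, ...) {
  if (!is.null(x$null_draws)) {
    graphics::hist(100 * x$null_draws, breaks = 30, col = "grey85",
                   border = "white", main = "Permutation null vs observed",
                   xlab = "accuracy (%)",
                   xlim = range(100 * c(x$null_draws, x$accuracy)))
    graphics::abline(v = 100 * x$accuracy, col = "firebrick", lwd = 2)
  } else {
    graphics::hist(100 * x$per_child, breaks = 20, col = "grey85",
                   border = "white", main = "Per-child winning rates",
                   xlab = "winning rate (%)")
    graphics::abline(v = 100 * x$accuracy, col = "firebrick", lwd = 2)
  }
  invisible(x)
}

#' @export
coef.accuracy_estimate <- function(object, ...) c(accuracy = object$accuracy)
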