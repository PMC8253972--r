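# The core statistic: the child x parent similarity matrix and the
# winning-rate identification accuracy, its Monte-Carlo sampling equivalent,
# and the conventional rank-1 fingerprinting baseline.

#' Child-by-parent similarity matrix
#'
#' Entry `(i, j)` is the Pearson correlation between child `i`'s and parent
#' `j`'s feature vectors over the (optionally masked) features; the diagonal
#' corresponds to the true dyads. Per-vector means and SDs are computed from
#' the masked entries only. With `direction = "parent"` the roles are
#' reversed: each parent is compared against all children, and rows index
#' parents.
#'
#' @param cohort a [dyad_cohort()].
#' @param feature_mask optional character vector of feature ids to restrict
#'   to (at least 3 after masking).
#' @param direction identification direction; the child-centric default
#'   matches correlating a child's vector to all parents' vectors.
#' @return An object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(cohort, feature_mask = NULL,
                              direction = c("child", "parent")) {
  direction <- match.arg(direction)
  if (!inherits(cohort, "dyad_cohort")) stopf("`cohort` must be a dyad_cohort")
  if (!is.null(feature_mask)) {
    if (!length(feature_mask)) stopf("empty feature mask")
    cohort <- mask_cohort(cohort, feature_mask)
  }
  xc <- cohort$children$values
  xp <- cohort$parents$values
  if (ncol(xc) < 3L)
    stopf("need at least 3 features to correlate, got %d", ncol(xc))
  sd_c <- apply(xc, 1L, stats::sd)
  sd_p <- apply(xp, 1L, stats::sd)
  if (any(sd_c == 0))
    stopf("zero-variance feature vector for child: %s",
          id_preview(rownames(xc)[sd_c == 0]))
  if (any(sd_p == 0))
    stopf("zero-variance feature vector for parent: %s",
          id_preview(rownames(xp)[sd_p == 0]))
  values <- stats::cor(t(xc), t(xp))  # children x parents
  if (direction == "parent") values <- t(values)
  structure(list(values = values,
                 children = cohort$dyad_map$child_id,
                 parents = cohort$dyad_map$parent_id,
                 direction = direction,
                 modality = cohort$children$modality,
                 n_features = ncol(xc)),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %s, %d dyads over %d features (%s-centric)\n",
              x$modality %||% "?", nrow(x$values), x$n_features %||% NA,
              x$direction %||% "child"))
  invisible(x)
}

# Accept a similarity_matrix, a plain square matrix, or a dyad_cohort.
sim_values <- function(x, feature_mask = NULL) {
  if (inherits(x, "similarity_matrix")) {
    v <- x$values
  } else if (inherits(x, "dyad_cohort")) {
    v <- similarity_matrix(x, feature_mask = feature_mask)$values
  } else if (is.matrix(x)) {
    if (nrow(x) != ncol(x)) stopf("similarity matrix must be square")
    if (any(!is.finite(x))) stopf("similarity matrix has non-finite entries")
    v <- x
  } else stopf("expected a similarity_matrix, dyad_cohort, or square matrix")
  v
}

#' Winning-rate identification accuracy
#'
#' For child `i` with own-parent similarity `S(i, i)`, the winning rate is the
#' fraction of the `N - 1` stranger parents `j` whose similarity `S(i, j)` is
#' exceeded by `S(i, i)`; exact ties score 1/2 (which keeps the chance level
#' at exactly 50% even on degenerate inputs). [winning_rate()] returns the
#' average winning rate over children as a bare number;
#' [winning_rate_accuracy()] additionally returns the per-child rates wrapped
#' in an `accuracy_estimate`. The chance level is 50% irrespective of `N`.
#'
#' @param sim a `similarity_matrix`, a plain square matrix with true dyads on
#'   the diagonal, or a [dyad_cohort()].
#' @return [winning_rate()]: a number in `[0, 1]`;
#'   [winning_rate_accuracy()]: an `accuracy_estimate`.
#' @examples
#' s <- matrix(c(0.9, 0.1, 0.4, 0.2, 0.8, 0.3, 0.5, 0.9, 0.6), 3, 3)
#' winning_rate(s)  # 0.8333
#' @export
winning_rate <- function(sim) {
  s <- sim_values(sim)
  n <- nrow(s)
  if (n < 2L) stopf("need at least 2 dyads")
  d <- matrix(diag(s), n, n)           # (i, j) -> S(i, i)
  wins <- rowSums(s < d)
  ties <- rowSums(s == d) - 1          # remove the self comparison
  mean((wins + 0.5 * ties) / (n - 1))
}

#' @rdname winning_rate
#' @export
winning_rate_accuracy <- function(sim) {
  s <- sim_values(sim)
  n <- nrow(s)
  if (n < 2L) stopf("need at least 2 dyads")
  d <- matrix(diag(s), n, n)
  wins <- rowSums(s < d)
  ties <- rowSums(s == d) - 1
  rates <- (wins + 0.5 * ties) / (n - 1)
  names(rates) <- if (inherits(sim, "similarity_matrix")) sim$children else rownames(s)
  new_accuracy_estimate(accuracy = mean(rates), per_child = rates, n_dyads = n,
                        modality = if (inherits(sim, "similarity_matrix")) sim$modality,
                        n_features = if (inherits(sim, "similarity_matrix")) sim$n_features)
}

#' Monte-Carlo sampling version of the winning-rate accuracy
#'
#' Repeatedly draws a random child and a random stranger parent and scores 1
#' when the own-parent similarity strictly exceeds the stranger similarity
#' (1/2 on an exact tie). As the number of draws grows this converges to
#' [winning_rate()].
#'
#' @inheritParams winning_rate
#' @param n_draws number of random (child, stranger) draws.
#' @param seed optional integer seed for reproducibility.
#' @return Proportion of successful identifications.
#' @export
sampling_procedure_accuracy <- function(sim, n_draws = 100000L, seed = NULL) {
  s <- sim_values(sim)
  n <- nrow(s)
  if (n < 2L) stopf("need at least 2 dyads")
  if (n_draws < 1L) stopf("`n_draws` must be at least 1")
  with_seed(seed, {
    i <- sample.int(n, n_draws, replace = TRUE)
    j <- ((i + sample.int(n - 1L, n_draws, replace = TRUE) - 1L) %% n) + 1L
    own <- s[cbind(i, i)]
    str <- s[cbind(i, j)]
    mean((own > str) + 0.5 * (own == str))
  })
}

#' Conventional rank-1 identification accuracy
#'
#' A child is counted as identified only when their own parent attains the
#' strict row-maximum similarity; ties at the maximum score `1 / #tied`.
#' Unlike the winning-rate statistic, the chance level is `1 / N`.
#'
#' @inheritParams winning_rate
#' @return Proportion of correctly identified children.
#' @export
conventional_identification <- function(sim) {
  s <- sim_values(sim)
  n <- nrow(s)
  if (n < 2L) stopf("need at least 2 dyads")
  mx <- apply(s, 1L, max)
  hit <- diag(s) == mx
  ntied <- rowSums(s == mx)
  mean(ifelse(hit, 1 / ntied, 0))
}
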