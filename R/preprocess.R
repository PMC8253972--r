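# Vector-level preprocessing: motion scrubbing, motion distribution vectors,
# confound residualization, and subject-exclusion rules.

#' Motion scrubbing mask from a framewise-displacement series
#'
#' Frames with FD above `threshold` (default 0.5 mm) are removed together with
#' the previous frame and the two subsequent frames; windows are clipped at
#' the series boundaries (not wrapped) and overlapping windows from
#' consecutive offenders are unioned.
#'
#' @param fd_series numeric vector of per-frame FD values (mm), non-negative.
#' @param threshold FD threshold in mm.
#' @return Logical keep-mask, `TRUE` for retained frames.
#' @examples
#' scrub_mask(c(0.1, 0.6, 0.1, 0.1, 0.1, 0.1))
#' @export
scrub_mask <- function(fd_series, threshold = 0.5) {
  fd_series <- as.numeric(fd_series)
  if (!length(fd_series)) stopf("empty FD series")
  if (any(!is.finite(fd_series))) stopf("non-finite FD values")
  if (any(fd_series < 0)) stopf("negative FD values at frames: %s",
                                id_preview(which(fd_series < 0)))
  n <- length(fd_series)
  keep <- rep(TRUE, n)
  for (o in which(fd_series > threshold)) {
    w <- (o - 1L):(o + 2L)
    keep[w[w >= 1L & w <= n]] <- FALSE
  }
  keep
}

#' Motion distribution vector (20-bin FD histogram)
#'
#' Bins span `[0, 1]` mm in steps of 0.05 (20 bins, last bin right-closed;
#' values above 1 are clipped into the last bin) and the histogram is
#' normalized to sum to 1, so that it can be compared across scans by Pearson
#' correlation like any other feature vector.
#'
#' @param fd_series numeric vector of per-frame FD values (mm).
#' @return Named numeric vector of length 20 summing to 1.
#' @export
motion_histogram <- function(fd_series) {
  fd_series <- as.numeric(fd_series)
  if (!length(fd_series)) stopf("empty FD series")
  if (any(!is.finite(fd_series)) || any(fd_series < 0))
    stopf("FD values must be finite and non-negative")
  edges <- seq(0.05, 0.95, by = 0.05)
  bin <- findInterval(fd_series, edges) + 1L  # clips > 1 into bin 20
  counts <- tabulate(bin, nbins = 20L)
  out <- counts / length(fd_series)
  names(out) <- sprintf("fdbin%02d", 1:20)
  out
}

#' Residualize feature columns on confounds
#'
#' For every feature column, returns the ordinary-least-squares residuals of
#' that column regressed on an intercept plus the confound columns across
#' subjects (e.g. regressing head motion, total gray matter volume and mean
#' FD out of the data matrices).
#'
#' @param features a [feature_matrix()].
#' @param confounds numeric matrix or data frame, one row per subject in the
#'   same order as `features` (or with matching rownames).
#' @return A `feature_matrix` of residuals (columns have mean ~0).
#' @export
residualize_features <- function(features, confounds) {
  conf <- as.matrix(as.data.frame(confounds))
  if (is.null(colnames(conf))) colnames(conf) <- sprintf("c%d", seq_len(ncol(conf)))
  if (!is.null(rownames(conf)) && all(subject_ids(features) %in% rownames(conf)))
    conf <- conf[subject_ids(features), , drop = FALSE]
  if (nrow(conf) != n_subjects(features))
    stopf("confounds have %d rows for %d subjects", nrow(conf), n_subjects(features))
  storage.mode(conf) <- "double"
  if (any(!is.finite(conf))) stopf("non-finite confound values")
  x <- cbind(`(intercept)` = 1, conf)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    stopf("confounds are rank deficient; collinear columns: %s", id_preview(dropped))
  }
  res <- stats::lm.fit(x, features$values)$residuals
  dimnames(res) <- dimnames(features$values)
  feature_matrix(res, features$modality)
}

# Keep-mask for the top-`fraction` high movers; all subjects tied at the cut
# are excluded (conservative tie rule).
high_motion_keep <- function(mean_fd, fraction = 0.25) {
  if (any(!is.finite(mean_fd))) stopf("non-finite mean FD values")
  n <- length(mean_fd)
  k <- floor(fraction * n)
  if (k < 1L) return(rep(TRUE, n))
  cut <- sort(mean_fd, decreasing = TRUE)[k]
  mean_fd < cut
}

#' Exclude high-motion dyads
#'
#' Removes dyads whose child's mean FD falls in the top `fraction` at any of
#' the provided timepoints (union of per-timepoint exclusions). Ties at the
#' cut are all excluded.
#'
#' @param cohort a [dyad_cohort()] or a list of cohorts (one per timepoint)
#'   sharing the same dyads; `mean_fd` must be present in `covariates`.
#' @param fraction fraction of highest movers to remove (default 0.25).
#' @return Object of the same shape as `cohort`, restricted to retained dyads.
#' @export
exclude_high_motion <- function(cohort, fraction = 0.25) {
  cohorts <- if (inherits(cohort, "dyad_cohort")) list(cohort) else cohort
  if (!length(cohorts) || !all(vapply(cohorts, inherits, TRUE, "dyad_cohort")))
    stopf("`cohort` must be a dyad_cohort or a list of dyad_cohorts")
  keep <- rep(TRUE, cohorts[[1L]]$n_dyads)
  for (co in cohorts) {
    fd <- co$covariates$mean_fd
    if (anyNA(fd))
      stopf("mean_fd missing for children: %s",
            id_preview(co$dyad_map$child_id[is.na(fd)]))
    keep <- keep & high_motion_keep(fd, fraction)
  }
  message(sprintf("motion exclusion: retained %d of %d dyads (%.1f%%)",
                  sum(keep), length(keep), 100 * mean(keep)))
  out <- lapply(cohorts, subset_dyads, idx = which(keep))
  if (inherits(cohort, "dyad_cohort")) out[[1L]] else out
}

#' Phenotype outlier exclusion (mean + k SD rule)
#'
#' Keeps scores at or below `mean + k * SD` (sample SD, denominator `n - 1`),
#' with mean and SD computed over all present scores. The rule mirrors the
#' exclusion of extremely high testosterone measurements.
#'
#' @param scores numeric vector; `NA` means the score is absent.
#' @param k SD multiplier (default 1.5).
#' @return Logical keep-mask; `NA` where the score is absent.
#' @export
exclude_phenotype_outliers <- function(scores, k = 1.5) {
  scores <- as.numeric(scores)
  present <- !is.na(scores)
  if (!any(present)) stopf("all scores are absent")
  if (sum(present) < 2L) stopf("need at least 2 present scores")
  thr <- mean(scores[present]) + k * stats::sd(scores[present])
  ifelse(present, scores <= thr, NA)
}

#' Median split into upper and lower halves
#'
#' Children strictly above the median are labelled `"upper"`, all others with
#' a present score (including ties at the median) `"lower"`. Because the split
#' depends only on ranks, any strictly monotone transform of the scores (such
#' as the square-root transform applied to testosterone) yields the same
#' split.
#'
#' @param scores numeric vector; `NA` means absent.
#' @return Factor with levels `c("lower", "upper")`, `NA` where absent.
#' @export
median_split <- function(scores) {
  scores <- as.numeric(scores)
  present <- !is.na(scores)
  if (sum(present) < 4L) stopf("need at least 4 present scores to split")
  vals <- scores[present]
  if (max(vals) == min(vals)) stopf("all scores identical; no split possible")
  med <- stats::median(vals)
  lab <- ifelse(scores > med, "upper", "lower")
  sizes <- table(factor(lab[present], levels = c("lower", "upper")))
  message(sprintf("median split: %d lower, %d upper", sizes["lower"], sizes["upper"]))
  factor(lab, levels = c("lower", "upper"))
}
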