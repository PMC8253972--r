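# Motion scrubbing, motion histograms, confound residualization, and
# subject-exclusion rules.

test_that("scrub_mask removes the offender, its predecessor and two successors", {
  expect_equal(scrub_mask(c(0.1, 0.6, 0.1, 0.1, 0.1, 0.1)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  # no offender keeps everything
  expect_true(all(scrub_mask(rep(0.5, 10))))  # threshold is strict (> 0.5)
  # offender at the last frame: window clipped to {n-1, n}
  expect_equal(scrub_mask(c(0.1, 0.1, 0.1, 0.9)), c(TRUE, TRUE, FALSE, FALSE))
  # offender at the first frame: window clipped to {1, 2, 3}
  expect_equal(scrub_mask(c(0.9, 0.1, 0.1, 0.1)), c(FALSE, FALSE, FALSE, TRUE))
  # consecutive offenders take the union of their windows
  expect_equal(scrub_mask(c(0.6, 0.6, rep(0.1, 4))), c(rep(FALSE, 4), TRUE, TRUE))
  expect_error(scrub_mask(c(0.1, -0.2)), "negative FD")
})

test_that("scrubbing the retained subsequence again removes nothing", {
  set.seed(3)
  for (r in 1:20) {
    fd <- simulate_motion_series(80, offender_rate = 0.1)
    keep <- scrub_mask(fd)
    if (!any(keep)) next
    expect_true(all(scrub_mask(fd[keep])))
  }
})

test_that("motion histograms are 20-bin probability vectors on {0:0.05:1}", {
  h <- motion_histogram(c(0.01, 0.07))
  expect_equal(unname(h[1:2]), c(0.5, 0.5))
  expect_equal(sum(h), 1)

  expect_equal(unname(motion_histogram(rep(0.01, 5))[1]), 1)

  set.seed(4)
  fd <- simulate_motion_series(250, offender_rate = 0.2)
  h2 <- motion_histogram(fd)
  expect_length(h2, 20L)
  expect_true(all(h2 >= 0))
  expect_equal(sum(h2), 1)
  # values above 1 mm are clipped into the last bin
  expect_equal(unname(motion_histogram(c(0.02, 1.7))[20]), 0.5)
  expect_error(motion_histogram(numeric(0)), "empty")
})

test_that("residualization matches a normal-equations oracle and its edge cases", {
  set.seed(5)
  n <- 10
  vals <- matrix(rnorm(n * 6), n, 6,
                 dimnames = list(sprintf("s%02d", 1:n), sprintf("f%d", 1:6)))
  fm <- feature_matrix(vals, "GMV")
  conf <- cbind(age = rnorm(n), motion = rnorm(n))

  res <- residualize_features(fm, conf)
  # independent oracle: solve the normal equations by hand per column
  x <- cbind(1, conf)
  beta <- solve(t(x) %*% x, t(x) %*% vals)
  expect_equal(res$values, vals - x %*% beta, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(abs(colMeans(res$values)) < 1e-10))

  # a confound identical to a feature column zeroes that column
  conf2 <- cbind(c1 = vals[, 3])
  res2 <- residualize_features(fm, conf2)
  expect_true(all(abs(res2$values[, 3]) < 1e-10))

  # a confound orthogonal to a centered column leaves it centered
  y <- vals[, 1] - mean(vals[, 1])
  orth <- rnorm(n)
  orth <- orth - mean(orth)
  orth <- orth - sum(orth * y) / sum(y * y) * y
  fm3 <- feature_matrix(cbind(f1 = y, vals[, -1]), "GMV",
                        subject_ids = rownames(vals))
  res3 <- residualize_features(fm3, cbind(o = orth))
  expect_equal(unname(res3$values[, 1]), unname(y), tolerance = 1e-10)

  # rank-deficient confounds name the collinear column
  expect_error(residualize_features(fm, cbind(a = conf[, 1], b = 2 * conf[, 1])),
               "rank deficient.*b")
})

test_that("top-fraction motion exclusion removes high movers, ties conservatively", {
  co <- make_cohort(n_dyads = 8, seed = 10)
  co$covariates$mean_fd <- c(0.10, 0.12, 0.30, 0.08, 0.25, 0.15, 0.11, 0.09)
  kept <- suppressMessages(exclude_high_motion(co, fraction = 0.25))
  expect_equal(kept$n_dyads, 6L)
  expect_false(any(kept$covariates$mean_fd >= 0.25))

  # union of exclusions across two timepoints
  co2 <- co
  co2$covariates$mean_fd <- c(0.40, 0.35, 0.10, 0.09, 0.08, 0.11, 0.12, 0.13)
  both <- suppressMessages(exclude_high_motion(list(t1 = co, t2 = co2),
                                               fraction = 0.25))
  expect_equal(both$t1$n_dyads, 4L)  # {3,5} and {1,2} excluded
  expect_identical(both$t1$dyad_map$child_id, both$t2$dyad_map$child_id)

  # all-equal FDs: every subject ties at the cut and is excluded
  expect_equal(sum(dyadprint:::high_motion_keep(rep(0.2, 8), 0.25)), 0L)

  co$covariates$mean_fd[2] <- NA
  expect_error(exclude_high_motion(co), "mean_fd missing")
})

test_that("phenotype outlier rule excludes scores above mean + 1.5 SD", {
  scores <- c(1, 1, 1, 1, 1, 10)
  # mean 2.5, sd 3.674 -> threshold 8.01; only the 10 is excluded
  thr <- mean(scores) + 1.5 * sd(scores)
  keep <- exclude_phenotype_outliers(scores)
  expect_equal(keep, scores <= thr)
  expect_equal(unname(keep), c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))

  expect_true(all(exclude_phenotype_outliers(rep(4, 5))))  # SD = 0, none excluded
  keep_na <- exclude_phenotype_outliers(c(1, NA, 1, 10))
  expect_true(is.na(keep_na[2]))
  expect_error(exclude_phenotype_outliers(c(NA_real_, NA)), "absent")
})

test_that("median split puts ties in the lower half and is rank-invariant", {
  s1 <- suppressMessages(median_split(c(1, 2, 3, 4)))
  expect_equal(as.character(s1), c("lower", "lower", "upper", "upper"))

  s2 <- suppressMessages(median_split(c(1, 2, 2, 5)))
  expect_equal(as.character(s2), c("lower", "lower", "lower", "upper"))

  # strictly monotone transform (sqrt of testosterone) preserves the split
  set.seed(6)
  t_raw <- runif(20, 0.5, 16)
  expect_identical(suppressMessages(median_split(t_raw)),
                   suppressMessages(median_split(sqrt(t_raw))))

  expect_error(suppressMessages(median_split(rep(3, 6))), "identical")
})
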