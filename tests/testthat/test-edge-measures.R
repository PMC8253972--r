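# Dyad products, empirical probabilities, differential power, group
# consistency, percentile selection and lobe normalization.

test_that("per-subject z-scoring is exact, idempotent, and decomposes Pearson", {
  fm <- feature_matrix(rbind(s1 = c(1, 2, 3), s2 = c(4, 0, 2)), "GMV",
                       feature_ids = c("g1", "g2", "g3"))
  z <- zscore_subject_vectors(fm)
  expect_equal(unname(z$values[1, ]), c(-1, 0, 1))
  z2 <- zscore_subject_vectors(z)
  expect_equal(z2$values, z$values, tolerance = 1e-12)

  # sum of products of standardized vectors / (M - 1) = Pearson correlation
  co <- make_cohort(n_dyads = 5, n_features = 40, alpha = 0.6, seed = 50)
  pr <- dyad_products(co)
  sim <- similarity_matrix(co)
  expect_equal(unname(rowSums(pr) / (ncol(pr) - 1)), unname(diag(sim$values)),
               tolerance = 1e-10)

  fm$values[2, ] <- 3
  expect_error(zscore_subject_vectors(fm), "zero-variance.*s2")
})

test_that("products, P_i, DP and phi match exhaustive enumeration on 3 dyads", {
  co <- make_cohort(n_dyads = 3, n_features = 5, alpha = 0.5, seed = 51)
  xs <- dyadprint:::edge_measure_inputs(co, NULL, TRUE)
  em <- edge_measures(co)
  n <- 3; m <- 5
  floor_p <- 1 / (2 * (n - 1))

  # brute-force oracle over all 9 child x parent products per feature
  phi <- array(NA_real_, c(n, n, m))
  for (i in 1:n) for (j in 1:n) for (f in 1:m)
    phi[i, j, f] <- xs$child[i, f] * xs$parent[j, f]
  p_oracle <- matrix(NA_real_, n, m)
  for (i in 1:n) for (f in 1:m) {
    cnt <- 0
    for (j in setdiff(1:n, i)) {
      if (phi[j, i, f] > phi[i, i, f]) cnt <- cnt + 1  # stranger child, own parent
      if (phi[i, j, f] > phi[i, i, f]) cnt <- cnt + 1  # own child, stranger parent
    }
    p_oracle[i, f] <- max(cnt / (2 * (n - 1)), floor_p)
  }
  expect_equal(unname(em$p_i), p_oracle, tolerance = 1e-12)
  expect_equal(unname(em$dp), colSums(-log(p_oracle)), tolerance = 1e-12)
  phi_ii <- t(sapply(1:n, function(i) phi[i, i, ]))
  expect_equal(unname(em$phi_bar), colMeans(phi_ii), tolerance = 1e-12)
  expect_equal(unname(dyad_products(co)), phi_ii, tolerance = 1e-12)
})

test_that("P_i and DP hit their closed-form boundary values", {
  # dyad product strictly above all stranger products -> floored P_i
  child <- rbind(c(10, 1), c(-10, 1), c(0.5, 1))
  parent <- rbind(c(10, 1), c(-10, 1), c(0.5, 1))
  colnames(child) <- colnames(parent) <- c("fA", "fB")
  p <- empirical_probability(child, parent)
  expect_equal(unname(p[1, "fA"]), 1 / 4)  # clean sweep floored at 1/(2(N-1))

  # P_i = 1 for all dyads -> DP = 0
  expect_equal(unname(differential_power(matrix(1, 3, 2))), c(0, 0))
  # N = 3, P_i = 1/4 everywhere -> DP = 3 ln 4
  expect_equal(unname(differential_power(matrix(0.25, 3, 1))), 3 * log(4),
               tolerance = 1e-12)
  expect_error(differential_power(matrix(c(0.5, 0), 1, 2)), "\\(0, 1\\]")

  # worst case: dyad product strictly smallest -> P_i = 1
  childw <- rbind(c(-5, 1, 0), c(2, 1, 0.1), c(3, 1, -0.1))
  parentw <- rbind(c(5, 1, 0), c(2, 1, 0.2), c(3, 1, -0.2))
  colnames(childw) <- colnames(parentw) <- c("f1", "f2", "f3")
  pw <- empirical_probability(childw, parentw)
  expect_equal(unname(pw[1, "f1"]), 1)  # phi_11 = -25 below every cross product
})

test_that("group consistency is the mean dyad product", {
  pr <- rbind(c(0.5, 0), c(1.5, 0))
  colnames(pr) <- c("f1", "f2")
  expect_equal(group_consistency(pr), c(f1 = 1, f2 = 0))
})

test_that("planted discriminative features rank high on DP, consistent on phi", {
  study <- simulate_cohort(synthetic_spec(
    n_dyads = 30, n_nodes = 30, alpha = 0, n_discriminative = 40,
    alpha_discriminative = 0.9, consistent_frac = 0.15, consistent_mean = 4,
    seed = 52))
  co <- study$fc
  cls <- study$ground_truth$FC$feature_class
  em <- edge_measures(co)

  expect_gt(mean(em$dp[cls == "discriminative"]), mean(em$dp[cls == "background"]))
  expect_gt(mean(em$phi_bar[cls == "consistent"]), mean(em$phi_bar[cls == "background"]))
  # consistent features are similar in everyone, hence not discriminative:
  # their DP stays near the background level, far below the planted features'
  expect_lt(mean(em$dp[cls == "consistent"]), mean(em$dp[cls == "discriminative"]))

  # permuting the parent assignment destroys the planted DP advantage
  set.seed(53)
  perm <- sample(co$n_dyads)
  co_perm <- dyad_cohort(co$children,
                         subset_subjects(co$parents, subject_ids(co$parents)[perm]),
                         data.frame(child_id = co$dyad_map$child_id,
                                    parent_id = co$dyad_map$parent_id[perm]))
  em_null <- edge_measures(co_perm)
  gap_obs <- mean(em$dp[cls == "discriminative"]) - mean(em$dp[cls == "background"])
  gap_null <- mean(em_null$dp[cls == "discriminative"]) -
              mean(em_null$dp[cls == "background"])
  expect_lt(abs(gap_null), 0.25 * gap_obs)
})

test_that("percentile selection keeps ties and matches count arithmetic", {
  x <- setNames(1:400, sprintf("e%03d", 1:400))
  expect_identical(top_percentile(x, 99.75), "e400")
  expect_length(top_percentile(x, 0.001), 400L)
  xt <- setNames(c(rep(1, 398), 5, 5), sprintf("e%03d", 1:400))
  expect_setequal(top_percentile(xt, 99.75), c("e399", "e400"))
  # 35,778 edges at the 99.75th percentile -> about 90 edges
  set.seed(54)
  big <- setNames(rnorm(35778), paste0("e", 1:35778))
  expect_equal(length(top_percentile(big, 99.75)), ceiling(0.0025 * 35778),
               tolerance = 0.05)
})

test_that("lobe-normalized counts divide by the atlas lobe sizes", {
  atlas <- network_atlas(data.frame(
    node_id = c("n1", "n2", "n3", "n4", "n5", "n6"),
    network = c("MF", "MF", "DMN", "DMN", "Sub", "Sub"),
    lobe = c("PFC", "PFC", "PFC", "PFC", "Cer", "Cer"),
    hemisphere = c("L", "R", "L", "R", "L", "R")))
  got <- lobe_normalized_counts(c("n1", "n3"), atlas)
  expect_equal(got, c(Cer = 0, PFC = 0.5))
  expect_equal(lobe_normalized_counts(c("n5", "n6"), atlas), c(Cer = 1, PFC = 0))
  expect_equal(lobe_normalized_counts(character(0), atlas), c(Cer = 0, PFC = 0))
  expect_error(lobe_normalized_counts("nope", atlas), "unknown nodes")
})
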