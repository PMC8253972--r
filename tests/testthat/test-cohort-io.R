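# Domain types, FC vectorization, COMB concatenation, and TSV round trips.

test_that("lower-triangle vectorization has the right size, order and labels", {
  # 3x3 with lower triangle (0.1, 0.2, 0.3) at (2,1), (3,1), (3,2)
  m <- matrix(0, 3, 3)
  m[2, 1] <- m[1, 2] <- 0.1
  m[3, 1] <- m[1, 3] <- 0.2
  m[3, 2] <- m[2, 3] <- 0.3
  v <- vectorize_lower_triangle(m, node_ids = c("a", "b", "c"))
  expect_equal(unname(v), c(0.1, 0.2, 0.3))
  expect_equal(names(v), c("a-b", "a-c", "b-c"))

  # 2x2 -> single feature
  m2 <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  expect_length(vectorize_lower_triangle(m2, c("x", "y")), 1L)

  # 268-node atlas -> 35,778 unique edges
  n <- 268
  big <- matrix(0, n, n)
  expect_length(vectorize_lower_triangle(big, sprintf("r%03d", 1:n)), 35778L)
})

test_that("vectorize/re-embed is a round trip and asymmetry names the worst entry", {
  set.seed(1)
  m <- matrix(rnorm(36), 6, 6)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  ids <- letters[1:6]
  v <- vectorize_lower_triangle(m, ids)
  back <- edges_to_matrix(v, ids, diag = 1)
  expect_equal(back, `dimnames<-`(m, list(ids, ids)))

  bad <- m
  bad[5, 2] <- bad[5, 2] + 0.3
  expect_error(vectorize_lower_triangle(bad, ids), "not symmetric.*(e, b|b, e)")
  expect_error(vectorize_lower_triangle(matrix(0, 2, 3)), "not square")
})

test_that("COMB concatenation is length-additive and standardizes within modality", {
  fc <- make_cohort(n_dyads = 5, n_features = 8, seed = 1)$children
  set.seed(2)
  gvals <- matrix(rnorm(5 * 3, mean = 100, sd = 10), 5, 3,
                  dimnames = list(subject_ids(fc), c("g1", "g2", "g3")))
  gmv <- feature_matrix(gvals, "GMV")

  comb <- assemble_comb(fc, gmv)
  expect_identical(comb$modality, "COMB")
  expect_equal(n_features(comb), n_features(fc) + n_features(gmv))
  expect_true(all(abs(colMeans(comb$values)) < 1e-12))
  expect_true(all(abs(apply(comb$values, 2, sd) - 1) < 1e-12))

  raw <- assemble_comb(fc, gmv, standardize = FALSE)
  expect_equal(raw$values[, feature_ids(fc)], fc$values)
  expect_equal(raw$values[, c("g1", "g2", "g3")], gvals)

  gmv_bad <- feature_matrix(gvals[1:4, ], "GMV")
  expect_error(assemble_comb(fc, gmv_bad), "subject sets differ")
})

test_that("feature_matrix and dyad_cohort enforce their invariants", {
  vals <- matrix(1:6, 2, 3, dimnames = list(c("s1", "s2"), c("f1", "f2", "f3")))
  expect_error(feature_matrix(rbind(vals, s1 = 1:3), "FC"), "duplicated subject_id")
  vals_na <- vals; vals_na[2, 2] <- NA
  expect_error(feature_matrix(vals_na, "GMV"), "non-finite.*s2.*f2")

  co <- make_cohort(n_dyads = 4)
  expect_equal(co$n_dyads, 4L)
  # a child in two dyads is rejected
  dm <- co$dyad_map
  dm$child_id[2] <- dm$child_id[1]
  expect_error(dyad_cohort(co$children, co$parents, dm), "more than one dyad")
  # fewer than 3 dyads is rejected
  expect_error(dyad_cohort(co$children, co$parents, co$dyad_map[1:2, ]),
               "at least 3 dyads")
})

test_that("the shipped 3-dyad fixture loads into a validated cohort + atlas", {
  got <- read_cohort(extdata("demo_children.tsv"), extdata("demo_parents.tsv"),
                     extdata("demo_dyad_map.tsv"),
                     node_metadata_path = extdata("demo_nodes.tsv"),
                     covariates_path = extdata("demo_covariates.tsv"))
  expect_s3_class(got$cohort, "dyad_cohort")
  expect_equal(got$cohort$n_dyads, 3L)
  expect_equal(nrow(got$atlas), 4L)
  expect_equal(feature_ids(got$cohort$children), fc_edge_ids(got$atlas$node_id))
  expect_true(is.na(got$cohort$covariates$testosterone[3]))
  expect_equal(as.character(got$cohort$covariates$sex), c("M", "F", "F"))
})

test_that("a dyad map naming a missing parent fails with that id", {
  dm <- tempfile(fileext = ".tsv")
  writeLines(c("child_id\tparent_id", "c1\tp1", "c2\tpMISSING", "c3\tp3"), dm)
  expect_error(
    read_cohort(extdata("demo_children.tsv"), extdata("demo_parents.tsv"), dm),
    "missing parent_id: pMISSING")
})

test_that("non-numeric feature cells are located by row and column", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tf1\tf2", "s1\t0.5\toops", "s2\t0.1\t0.2"), bad)
  expect_error(read_feature_matrix(bad, "GMV"), "'oops' at row 1.*column 'f2'")
})

test_that("write then read is the identity on values, ids and covariates", {
  study <- simulate_cohort(synthetic_spec(n_dyads = 5, n_nodes = 8,
                                          alpha = 0.4, seed = 9))
  co <- study$gmv
  dir <- tempfile()
  write_cohort(co, dir)
  back <- read_cohort_dir(dir, modality = "GMV")
  expect_equal(back$children$values, co$children$values, tolerance = 1e-12)
  expect_equal(back$parents$values, co$parents$values, tolerance = 1e-12)
  expect_identical(back$dyad_map, co$dyad_map)
  expect_equal(back$covariates$mean_fd, co$covariates$mean_fd, tolerance = 1e-12)
  expect_identical(as.character(back$covariates$sex),
                   as.character(co$covariates$sex))
})
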