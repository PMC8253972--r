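# Atlas-derived feature masks and the per-network / covariate-split drivers.

test_that("within/between edge masks have combinatorial sizes and partition edges", {
  atlas <- make_atlas(n_nodes = 20, n_networks = 5)  # 4 nodes per network
  nets <- atlas_networks(atlas)

  w <- within_network_edge_mask(atlas, nets[1])
  expect_length(w, choose(4, 2))
  expect_length(within_network_edge_mask(atlas, "ALL"), choose(20, 2))

  b <- between_network_edge_mask(atlas, nets[1], nets[2])
  expect_length(b, 4 * 4)
  expect_identical(sort(b), sort(between_network_edge_mask(atlas, nets[2], nets[1])))
  expect_error(between_network_edge_mask(atlas, nets[1], nets[1]), "identical")

  # all within + all unordered between masks = every edge, with no overlap
  pieces <- c(lapply(nets, within_network_edge_mask, atlas = atlas),
              unlist(lapply(seq_along(nets)[-1], function(i)
                lapply(seq_len(i - 1), function(j)
                  between_network_edge_mask(atlas, nets[i], nets[j]))),
                recursive = FALSE))
  all_edges <- unlist(pieces)
  expect_identical(sort(all_edges), sort(fc_edge_ids(atlas$node_id)))
  expect_equal(anyDuplicated(all_edges), 0L)

  # node masks partition the node set
  node_masks <- lapply(nets, network_node_mask, atlas = atlas)
  expect_setequal(unlist(node_masks), atlas$node_id)
  expect_length(network_node_mask(atlas, "ALL"), 20L)
  expect_error(within_network_edge_mask(atlas, "Nope"), "valid labels")
})

test_that("268-node whole-brain masks have the expected feature counts", {
  atlas <- make_atlas(n_nodes = 268, n_networks = 10)
  expect_length(within_network_edge_mask(atlas, "ALL"), 35778L)
  expect_length(network_node_mask(atlas, "ALL"), 268L)
})

test_that("a perfect-transmission cohort saturates every network cell", {
  study <- simulate_cohort(synthetic_spec(n_dyads = 8, n_nodes = 20, alpha = 1,
                                          noise_sd = 0, n_networks = 5, seed = 60))
  tab <- per_network_analysis(fc = study$fc, gmv = study$gmv, atlas = study$atlas,
                              n_boot = 0, n_perm = 0)
  ok <- !is.na(tab$accuracy)
  expect_true(any(ok))
  expect_true(all(tab$accuracy[ok] == 1))
})

test_that("transmission planted in one network is localized by the analysis", {
  study <- simulate_cohort(synthetic_spec(
    n_dyads = 40, n_nodes = 40, alpha = 0, n_networks = 5,
    alpha_by_network = c(MF = 0.8), seed = 61))
  tab <- per_network_analysis(fc = study$fc, gmv = NULL, atlas = study$atlas,
                              networks = atlas_networks(study$atlas),
                              n_boot = 0, n_perm = 0)
  acc <- setNames(tab$accuracy, tab$network)
  expect_gt(acc["MF"], max(acc[setdiff(names(acc), "MF")]))
  expect_gt(acc["MF"], 0.9)
})

test_that("per-network permutation p-values are computed per feature mask", {
  study <- simulate_cohort(synthetic_spec(n_dyads = 12, n_nodes = 15,
                                          alpha = 0.9, n_networks = 3, seed = 62))
  tab <- per_network_analysis(fc = study$fc, gmv = study$gmv, atlas = study$atlas,
                              n_boot = 20, n_perm = 39, seed = 63)
  ok <- !is.na(tab$accuracy)
  expect_true(all(tab$p_value[ok] >= 1 / 40 & tab$p_value[ok] <= 1))
  expect_true(all(tab$ci_lo[ok] <= tab$accuracy[ok] + 1e-12))
  # whole-brain accuracy is not a weighted mean of per-network accuracies
  # (documented non-property; only required to be a valid accuracy)
  all_fc <- tab$accuracy[tab$network == "ALL" & tab$modality == "FC"]
  expect_true(all_fc >= 0 && all_fc <= 1)
  # the best flag marks the top modality within each network
  for (net in unique(tab$network)) {
    sub <- tab[tab$network == net & !is.na(tab$accuracy), ]
    if (nrow(sub)) expect_true(all(sub$accuracy[sub$best] == max(sub$accuracy)))
  }
})

test_that("a subgroup's table equals per_network_analysis on the subgroup cohort", {
  study <- simulate_cohort(synthetic_spec(n_dyads = 16, n_nodes = 15,
                                          alpha = 0.5, n_networks = 3, seed = 64))
  sexes <- as.character(study$fc$covariates$sex)
  sa <- suppressMessages(covariate_split_analysis(
    fc = study$fc, gmv = study$gmv, atlas = study$atlas, split = "sex",
    modalities = "COMB", n_boot = 0, n_perm = 0))
  for (g in c("M", "F")) {
    idx <- which(sexes == g)
    manual <- per_network_analysis(fc = subset_dyads(study$fc, idx),
                                   gmv = subset_dyads(study$gmv, idx),
                                   atlas = study$atlas, modalities = "COMB",
                                   n_boot = 0, n_perm = 0)
    expect_equal(sa$tables[[g]]$accuracy, manual$accuracy, tolerance = 1e-12)
  }
  expect_s3_class(sa$comparison, "comparison_result")
  expect_equal(sa$comparison$df, sa$comparison$n_pairs - 1L)
})

test_that("split analysis recovers a planted subgroup transmission difference", {
  study <- simulate_cohort(synthetic_spec(
    n_dyads = 60, n_nodes = 30, alpha = 0.25, n_networks = 5,
    subgroup_effects = list(sex = c(F = 0.55)), seed = 65))
  sa <- suppressMessages(covariate_split_analysis(
    fc = study$fc, gmv = study$gmv, atlas = study$atlas, split = "sex",
    modalities = "FC", n_boot = 0, n_perm = 0))
  diff <- sa$tables[["F"]]$accuracy - sa$tables[["M"]]$accuracy
  expect_gte(sum(diff > 0, na.rm = TRUE), length(diff) - 1)
  expect_lt(sa$comparison$p_value, 0.05)  # M - F strongly negative
  expect_lt(sa$comparison$t_stat, 0)
})

test_that("the full-cohort stranger flag aggregates full-matrix winning rates", {
  study <- simulate_cohort(synthetic_spec(n_dyads = 20, n_nodes = 12,
                                          alpha = 0.6, n_networks = 3, seed = 66))
  sa <- suppressMessages(covariate_split_analysis(
    fc = study$fc, gmv = study$gmv, atlas = study$atlas, split = "sex",
    modalities = "FC", strangers = "all", n_boot = 0, n_perm = 0))
  # oracle for the ALL row: mean of per-child full-cohort rates by sex
  rates <- winning_rate_accuracy(similarity_matrix(study$fc))$per_child
  sexes <- as.character(study$fc$covariates$sex)
  row_all <- function(g) {
    t <- sa$tables[[g]]
    t$accuracy[t$network == "ALL"]
  }
  expect_equal(row_all("M"), mean(rates[sexes == "M"]), tolerance = 1e-12)
  expect_equal(row_all("F"), mean(rates[sexes == "F"]), tolerance = 1e-12)
})

test_that("timepoint splits compare two cohorts paired over networks", {
  study <- simulate_cohort(synthetic_spec(
    n_dyads = 20, n_nodes = 15, alpha = 0.2, n_networks = 3,
    timepoints = c("age11", "age13"),
    alpha_by_timepoint = list(age13 = 0.9), seed = 67))
  sa <- covariate_split_analysis(fc = study$fc, gmv = study$gmv,
                                 atlas = study$atlas, split = "timepoint",
                                 modalities = "FC", n_boot = 0, n_perm = 0)
  expect_identical(sa$groups, c("age11", "age13"))
  expect_lt(sa$comparison$t_stat, 0)  # age11 - age13 < 0 by construction
  expect_gt(mean(sa$tables[["age13"]]$accuracy - sa$tables[["age11"]]$accuracy, na.rm = TRUE), 0)
})
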