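# Feature-mask construction from the atlas and the per-network /
# between-network / covariate-split analysis drivers.

atlas_network_nodes <- function(atlas, network_label) {
  if (identical(network_label, "ALL")) return(atlas$node_id)
  if (!network_label %in% atlas$network)
    stopf("unknown network '%s'; valid labels: %s", network_label,
          paste(c("ALL", atlas_networks(atlas)), collapse = ", "))
  atlas$node_id[atlas$network == network_label]
}

#' Edge and node masks from the network atlas
#'
#' [within_network_edge_mask()] returns the FC edges whose two endpoints both
#' carry `network_label` (`"ALL"` returns every edge);
#' [between_network_edge_mask()] the edges with one endpoint in each of two
#' different networks; [network_node_mask()] the GMV node features of one
#' network. Within- plus unordered between-network masks partition the full
#' edge set.
#'
#' @param atlas a [network_atlas()].
#' @param network_label,label_a,label_b network labels (see
#'   [atlas_networks()]); `"ALL"` is accepted by the within-network and node
#'   masks.
#' @return Character vector of feature ids (edge labels or node ids).
#' @export
within_network_edge_mask <- function(atlas, network_label) {
  nodes <- atlas_network_nodes(atlas, network_label)
  if (length(nodes) < 2L) return(character(0))
  all_edges <- fc_edge_ids(atlas$node_id)
  ends <- fc_edge_ends(all_edges)
  all_edges[ends[, "a"] %in% nodes & ends[, "b"] %in% nodes]
}

#' @rdname within_network_edge_mask
#' @export
between_network_edge_mask <- function(atlas, label_a, label_b) {
  if (identical(label_a, label_b))
    stopf("labels are identical ('%s'); use within_network_edge_mask()", label_a)
  na <- atlas_network_nodes(atlas, label_a)
  nb <- atlas_network_nodes(atlas, label_b)
  all_edges <- fc_edge_ids(atlas$node_id)
  ends <- fc_edge_ends(all_edges)
  all_edges[(ends[, "a"] %in% na & ends[, "b"] %in% nb) |
            (ends[, "a"] %in% nb & ends[, "b"] %in% na)]
}

#' @rdname within_network_edge_mask
#' @export
network_node_mask <- function(atlas, network_label) {
  atlas_network_nodes(atlas, network_label)
}

network_mask_for <- function(atlas, network, modality) {
  switch(modality,
         FC = within_network_edge_mask(atlas, network),
         GMV = network_node_mask(atlas, network),
         COMB = c(within_network_edge_mask(atlas, network),
                  network_node_mask(atlas, network)),
         MOTION = NULL)
}

#' Per-network identification accuracy table
#'
#' Runs the winning-rate analysis for every network (plus the whole-brain
#' `"ALL"` entry) and every available modality (FC, GMV, and their COMB
#' concatenation), with bootstrap CIs and a permutation null generated
#' separately per network so that differences in the number of edges/regions
#' between networks are taken into account. The best modality per network is
#' flagged for use with [best_count_test()]. Networks with fewer than 2 nodes
#' have no FC edges; those cells are reported as `NA` and the run continues.
#'
#' @param fc,gmv [dyad_cohort()] objects over the same dyads (either may be
#'   `NULL`).
#' @param atlas a [network_atlas()].
#' @param networks networks to analyse; default all atlas networks plus
#'   `"ALL"`.
#' @param modalities subset of `c("FC", "GMV", "COMB")`; default all
#'   available.
#' @param n_boot,n_perm,subsample_frac,seed resampling controls (0 skips).
#' @return A data frame of class `network_accuracy_table` with columns
#'   `network`, `modality`, `n_features`, `accuracy`, `ci_lo`, `ci_hi`,
#'   `p_value`, `best`.
#' @export
per_network_analysis <- function(fc = NULL, gmv = NULL, atlas,
                                 networks = NULL, modalities = NULL,
                                 n_boot = 1000L, n_perm = 1000L,
                                 subsample_frac = 0.9, seed = NULL) {
  if (is.null(fc) && is.null(gmv)) stopf("provide at least one of `fc`, `gmv`")
  available <- c(if (!is.null(fc)) "FC", if (!is.null(gmv)) "GMV",
                 if (!is.null(fc) && !is.null(gmv)) "COMB")
  modalities <- if (is.null(modalities)) available
                else match.arg(modalities, available, several.ok = TRUE)
  networks <- networks %||% c("ALL", atlas_networks(atlas))
  cohorts <- list(FC = fc, GMV = gmv,
                  COMB = if ("COMB" %in% modalities) comb_cohort(fc, gmv))
  with_seed(seed, {
    rows <- list()
    for (net in networks) {
      for (mod in modalities) {
        mask <- network_mask_for(atlas, net, mod)
        row <- data.frame(network = net, modality = mod,
                          n_features = length(mask), accuracy = NA_real_,
                          ci_lo = NA_real_, ci_hi = NA_real_,
                          p_value = NA_real_, best = FALSE,
                          stringsAsFactors = FALSE)
        if (length(mask) >= 3L) {
          sim <- similarity_matrix(cohorts[[mod]], feature_mask = mask)
          row$accuracy <- winning_rate(sim)
          if (n_boot > 0L) {
            bt <- bootstrap_ci(sim, n_boot = n_boot, subsample_frac = subsample_frac)
            row$ci_lo <- bt$ci[1L]; row$ci_hi <- bt$ci[2L]
          }
          if (n_perm > 0L)
            row$p_value <- permutation_test(sim, n_perm = n_perm)$p_value
        } else {
          message(sprintf("network %s: %d %s features; cell not computable",
                          net, length(mask), mod))
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
    out <- do.call(rbind, rows)
    for (net in unique(out$network)) {
      sel <- out$network == net & !is.na(out$accuracy)
      if (any(sel)) {
        top <- max(out$accuracy[sel])
        out$best[sel] <- out$accuracy[sel] == top
      }
    }
    class(out) <- c("network_accuracy_table", "data.frame")
    out
  })
}

#' @export
print.network_accuracy_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$accuracy <- round(100 * df$accuracy, 2)
  df$ci_lo <- round(100 * df$ci_lo, 2)
  df$ci_hi <- round(100 * df$ci_hi, 2)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Tally which modality wins each network case
#'
#' Counts, over the rows of one or more [per_network_analysis()] tables (one
#' case per network-by-table cell), how often each modality attains the best
#' accuracy. Feed the result to [best_count_test()].
#'
#' @param ... `network_accuracy_table` objects.
#' @return Named integer vector of wins per modality.
#' @export
best_modality_counts <- function(...) {
  tabs <- list(...)
  mods <- unique(unlist(lapply(tabs, function(t) t$modality)))
  counts <- stats::setNames(integer(length(mods)), mods)
  for (t in tabs) {
    b <- t[t$best & !is.na(t$accuracy), , drop = FALSE]
    for (m in b$modality) counts[m] <- counts[m] + 1L
  }
  counts
}

resolve_split_labels <- function(cohort, split, outlier_k, sqrt_transform) {
  cov <- cohort$covariates
  if (is.character(split) && length(split) == 1L) {
    if (split == "sex") {
      lab <- factor(as.character(cov$sex), levels = c("M", "F"))
      return(list(labels = lab, groups = c("M", "F"), name = "sex"))
    }
    if (split %in% c("testosterone", "cbcl")) {
      scores <- cov[[split]]
      if (all(is.na(scores))) stopf("covariate '%s' is entirely absent", split)
      if (is.null(sqrt_transform)) sqrt_transform <- split == "testosterone"
      keep <- exclude_phenotype_outliers(scores, k = outlier_k)
      scores[!is.na(keep) & !keep] <- NA
      if (sqrt_transform) scores <- sqrt(scores)
      lab <- median_split(scores)
      return(list(labels = lab, groups = c("lower", "upper"), name = split))
    }
    stopf("unknown split '%s' (use 'sex', 'timepoint', a covariate name, or a numeric score vector)",
          split)
  }
  scores <- as.numeric(split)
  if (length(scores) != cohort$n_dyads)
    stopf("numeric split scores must have one value per dyad")
  lab <- median_split(scores)
  list(labels = lab, groups = c("lower", "upper"), name = "score")
}

#' Covariate-split identification analysis
#'
#' Splits the children into two subgroups (by sex, by timepoint, or by a
#' median split of a phenotype score such as testosterone or CBCL), runs the
#' per-network analysis independently within each subgroup — by default the
#' stranger parents are restricted to the subgroup, so similarities are
#' computed only among subgroup members — and compares the two subgroups'
#' network-level accuracies with a paired t-test and Hedges' g over the
#' networks (10 networks + ALL gives df = 10). For phenotype splits,
#' extremely high scores (mean + `outlier_k` SD) are excluded first and
#' testosterone is square-root transformed before splitting.
#'
#' For `split = "timepoint"`, pass `fc` and `gmv` as named lists of two
#' cohorts (one per timepoint) over the same dyads; each timepoint then forms
#' one "subgroup" and the comparison is paired over networks.
#'
#' @inheritParams per_network_analysis
#' @param split `"sex"`, `"timepoint"`, a covariate name
#'   (`"testosterone"`/`"cbcl"`), or a numeric score vector (one per dyad).
#' @param strangers `"subgroup"` restricts candidate parents to the subgroup
#'   (default); `"all"` scores each child against every parent in the cohort.
#' @param outlier_k SD multiplier for the phenotype outlier rule.
#' @param sqrt_transform force the square-root transform on or off (`NULL` =
#'   only for testosterone).
#' @return Object of class `split_analysis`: per-group
#'   `network_accuracy_table`s and the paired `comparison` (group 1 minus
#'   group 2, groups ordered M/lower/first-timepoint first).
#' @export
covariate_split_analysis <- function(fc = NULL, gmv = NULL, atlas, split,
                                     networks = NULL, modalities = "COMB",
                                     n_boot = 0L, n_perm = 0L,
                                     subsample_frac = 0.9, seed = NULL,
                                     strangers = c("subgroup", "all"),
                                     outlier_k = 1.5, sqrt_transform = NULL) {
  strangers <- match.arg(strangers)
  if (identical(split, "timepoint")) {
    if (!is.list(fc) && !is.list(gmv))
      stopf("split = 'timepoint' needs `fc`/`gmv` as lists of per-timepoint cohorts")
    groups <- names(fc %||% gmv)
    if (length(groups) != 2L) stopf("timepoint split needs exactly 2 timepoints")
    group_cohorts <- lapply(groups, function(g)
      list(fc = if (is.list(fc)) fc[[g]] else fc,
           gmv = if (is.list(gmv)) gmv[[g]] else gmv))
    names(group_cohorts) <- groups
    split_name <- "timepoint"
  } else {
    ref <- fc %||% gmv
    spl <- resolve_split_labels(ref, split, outlier_k, sqrt_transform)
    groups <- spl$groups
    split_name <- spl$name
    dropped <- sum(is.na(spl$labels))
    if (dropped) message(sprintf("split '%s': %d dyads without a label excluded",
                                 split_name, dropped))
    group_cohorts <- lapply(groups, function(g) {
      idx <- which(!is.na(spl$labels) & spl$labels == g)
      if (length(idx) < 3L)
        stopf("subgroup '%s' has only %d dyads (need >= 3)", g, length(idx))
      list(fc = if (!is.null(fc)) subset_dyads(fc, idx),
           gmv = if (!is.null(gmv)) subset_dyads(gmv, idx),
           idx = idx)
    })
    names(group_cohorts) <- groups
  }

  with_seed(seed, {
    tables <- if (strangers == "subgroup" || identical(split, "timepoint")) {
      lapply(group_cohorts, function(gc)
        per_network_analysis(fc = gc$fc, gmv = gc$gmv, atlas = atlas,
                             networks = networks, modalities = modalities,
                             n_boot = n_boot, n_perm = n_perm,
                             subsample_frac = subsample_frac))
    } else {
      # strangers = "all": full-cohort similarity, rates aggregated by group
      if (n_boot > 0L || n_perm > 0L)
        message("strangers = 'all': bootstrap/permutation not computed")
      full <- per_network_analysis(fc = fc, gmv = gmv, atlas = atlas,
                                   networks = networks, modalities = modalities,
                                   n_boot = 0L, n_perm = 0L)
      cohorts <- list(FC = fc, GMV = gmv,
                      COMB = if ("COMB" %in% full$modality) comb_cohort(fc, gmv))
      lapply(group_cohorts, function(gc) {
        out <- full
        for (r in seq_len(nrow(out))) {
          mask <- network_mask_for(atlas, out$network[r], out$modality[r])
          if (length(mask) < 3L) next
          rates <- winning_rate_accuracy(
            similarity_matrix(cohorts[[out$modality[r]]], mask))$per_child
          out$accuracy[r] <- mean(rates[gc$idx])
        }
        out$best <- FALSE
        out
      })
    }
    acc <- lapply(tables, function(t) t$accuracy)
    ok <- stats::complete.cases(do.call(cbind, acc))
    comparison <- paired_comparison(acc[[1L]][ok], acc[[2L]][ok],
                                    labels = tables[[1L]]$network[ok])
    structure(list(split = split_name, groups = groups, tables = tables,
                   comparison = comparison, strangers = strangers),
              class = "split_analysis")
  })
}

#' @export
print.split_analysis <- function(x, ...) {
  cat(sprintf("<split_analysis> split by %s (%s vs %s; strangers: %s)\n",
              x$split, x$groups[1L], x$groups[2L], x$strangers))
  print(x$comparison)
  invisible(x)
}
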