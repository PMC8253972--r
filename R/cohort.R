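#' Paired parent-child cohort
#'
#' A `dyad_cohort` bundles a children's [feature_matrix()], a parents'
#' `feature_matrix` of the same modality and feature set, a dyad map pairing
#' each child with exactly one parent, and an optional covariate table.
#' Rows of both matrices are re-ordered so that row `i` of the children and
#' row `i` of the parents form dyad `i`; the number of dyads `N` must be at
#' least 3. Subjects present in a feature matrix but absent from the dyad map
#' are dropped (with a message); dyad-map rows naming unknown subjects are an
#' error.
#'
#' @param children,parents [feature_matrix()] objects sharing modality and
#'   feature identifiers.
#' @param dyad_map data frame with columns `child_id`, `parent_id`; `NULL`
#'   pairs subjects positionally (row `i` with row `i`).
#' @param covariates optional data frame keyed by `child_id`; recognised
#'   columns are `sex` (`"M"`/`"F"`), `timepoint` (`"age11"`/`"age13"`),
#'   `mean_fd` (mm), `testosterone` (pg/mL) and `cbcl` (score). Any may be
#'   `NA` per child.
#' @return An object of class `dyad_cohort`.
#' @export
dyad_cohort <- function(children, parents, dyad_map = NULL, covariates = NULL) {
  if (!inherits(children, "feature_matrix") || !inherits(parents, "feature_matrix"))
    stopf("`children` and `parents` must be feature_matrix objects")
  if (children$modality != parents$modality)
    stopf("modality mismatch: children %s vs parents %s",
          children$modality, parents$modality)
  if (!setequal(feature_ids(children), feature_ids(parents)))
    stopf("children and parents do not share feature ids")
  parents <- subset_features(parents, feature_ids(children))

  if (is.null(dyad_map)) {
    if (n_subjects(children) != n_subjects(parents))
      stopf("positional pairing needs equal subject counts (%d vs %d)",
            n_subjects(children), n_subjects(parents))
    dyad_map <- data.frame(child_id = subject_ids(children),
                           parent_id = subject_ids(parents),
                           stringsAsFactors = FALSE)
  }
  dyad_map <- as.data.frame(dyad_map, stringsAsFactors = FALSE)
  if (!all(c("child_id", "parent_id") %in% names(dyad_map)))
    stopf("`dyad_map` needs columns child_id and parent_id")
  dyad_map$child_id <- as.character(dyad_map$child_id)
  dyad_map$parent_id <- as.character(dyad_map$parent_id)
  if (anyDuplicated(dyad_map$child_id))
    stopf("child appears in more than one dyad: %s",
          id_preview(unique(dyad_map$child_id[duplicated(dyad_map$child_id)])))
  if (anyDuplicated(dyad_map$parent_id))
    stopf("parent appears in more than one dyad: %s",
          id_preview(unique(dyad_map$parent_id[duplicated(dyad_map$parent_id)])))
  miss_c <- setdiff(dyad_map$child_id, subject_ids(children))
  if (length(miss_c)) stopf("dyad map references missing child_id: %s", id_preview(miss_c))
  miss_p <- setdiff(dyad_map$parent_id, subject_ids(parents))
  if (length(miss_p)) stopf("dyad map references missing parent_id: %s", id_preview(miss_p))
  if (nrow(dyad_map) < 3L) stopf("need at least 3 dyads, got %d", nrow(dyad_map))

  drop_c <- setdiff(subject_ids(children), dyad_map$child_id)
  drop_p <- setdiff(subject_ids(parents), dyad_map$parent_id)
  if (length(drop_c) || length(drop_p))
    message(sprintf("dropping %d child and %d parent subjects absent from the dyad map",
                    length(drop_c), length(drop_p)))
  children <- subset_subjects(children, dyad_map$child_id)
  parents <- subset_subjects(parents, dyad_map$parent_id)

  covariates <- normalize_covariates(covariates, dyad_map$child_id)

  structure(list(children = children, parents = parents,
                 dyad_map = dyad_map, covariates = covariates,
                 n_dyads = nrow(dyad_map)),
            class = "dyad_cohort")
}

normalize_covariates <- function(covariates, child_ids) {
  base <- data.frame(child_id = child_ids,
                     sex = factor(NA_character_, levels = c("M", "F")),
                     timepoint = factor(NA_character_, levels = c("age11", "age13")),
                     mean_fd = NA_real_, testosterone = NA_real_, cbcl = NA_real_,
                     stringsAsFactors = FALSE)
  if (is.null(covariates)) return(base)
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  if (!"child_id" %in% names(covariates))
    stopf("`covariates` needs a child_id column")
  covariates$child_id <- as.character(covariates$child_id)
  if (anyDuplicated(covariates$child_id))
    stopf("duplicated child_id in covariates: %s",
          id_preview(unique(covariates$child_id[duplicated(covariates$child_id)])))
  idx <- match(child_ids, covariates$child_id)
  for (col in setdiff(names(covariates), "child_id")) {
    v <- covariates[[col]][idx]
    if (col == "sex") {
      v <- as.character(v)
      bad <- !is.na(v) & !v %in% c("M", "F")
      if (any(bad)) stopf("sex must be M or F, got: %s", id_preview(unique(v[bad])))
      v <- factor(v, levels = c("M", "F"))
    } else if (col == "timepoint") {
      v <- as.character(v)
      bad <- !is.na(v) & !v %in% c("age11", "age13")
      if (any(bad)) stopf("timepoint must be age11 or age13, got: %s",
                          id_preview(unique(v[bad])))
      v <- factor(v, levels = c("age11", "age13"))
    } else if (col %in% c("mean_fd", "testosterone", "cbcl")) {
      v <- as.numeric(v)
      if (any(!is.na(v) & !is.finite(v))) stopf("non-finite values in covariate '%s'", col)
    }
    base[[col]] <- v
  }
  base
}

#' @export
print.dyad_cohort <- function(x, ...) {
  cat(sprintf("<dyad_cohort> %s: N = %d dyads, M = %d features\n",
              x$children$modality, x$n_dyads, n_features(x$children)))
  invisible(x)
}

#' @rdname dyad_cohort
#' @param cohort a `dyad_cohort`.
#' @param feature_ids features to keep.
#' @export
mask_cohort <- function(cohort, feature_ids) {
  dyad_cohort(subset_features(cohort$children, feature_ids),
              subset_features(cohort$parents, feature_ids),
              cohort$dyad_map, cohort$covariates)
}

#' @rdname dyad_cohort
#' @param idx dyad indices (or child ids) to keep.
#' @export
subset_dyads <- function(cohort, idx) {
  if (is.character(idx)) idx <- match(idx, cohort$dyad_map$child_id)
  if (anyNA(idx) || any(idx < 1L | idx > cohort$n_dyads))
    stopf("invalid dyad selection")
  dm <- cohort$dyad_map[idx, , drop = FALSE]
  dyad_cohort(subset_subjects(cohort$children, dm$child_id),
              subset_subjects(cohort$parents, dm$parent_id),
              dm, cohort$covariates)
}

#' Build the COMB (FC + GMV) cohort from two modality cohorts
#'
#' Concatenates each subject's FC and GMV vectors. Standardization statistics
#' are pooled over children and parents so that both sides of every dyad share
#' the same per-column transform.
#'
#' @param fc,gmv `dyad_cohort` objects over the same dyads.
#' @param standardize passed to [assemble_comb()].
#' @return A `dyad_cohort` with modality `"COMB"`.
#' @export
comb_cohort <- function(fc, gmv, standardize = TRUE) {
  if (!identical(fc$dyad_map$child_id, gmv$dyad_map$child_id) ||
      !identical(fc$dyad_map$parent_id, gmv$dyad_map$parent_id))
    stopf("FC and GMV cohorts must cover the same dyads in the same order")
  stack <- function(x) feature_matrix(rbind(x$children$values, x$parents$values),
                                      modality = x$children$modality)
  comb <- assemble_comb(stack(fc), stack(gmv), standardize = standardize)
  n <- fc$n_dyads
  children <- feature_matrix(comb$values[seq_len(n), , drop = FALSE], "COMB")
  parents <- feature_matrix(comb$values[n + seq_len(n), , drop = FALSE], "COMB")
  dyad_cohort(children, parents, fc$dyad_map, fc$covariates)
}

#' Node metadata for the parcellation
#'
#' A `network_atlas` records, for every node of the parcellation, its
#' functional network (at most 10 labels), its anatomical lobe, and its
#' hemisphere (`L`/`R`).
#'
#' @param nodes data frame with columns `node_id`, `network`, `lobe`,
#'   `hemisphere`.
#' @return An object of class `network_atlas` (a data frame).
#' @export
network_atlas <- function(nodes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  need <- c("node_id", "network", "lobe", "hemisphere")
  miss <- setdiff(need, names(nodes))
  if (length(miss)) stopf("atlas is missing columns: %s", id_preview(miss))
  nodes <- nodes[need]
  for (col in need) nodes[[col]] <- as.character(nodes[[col]])
  if (anyDuplicated(nodes$node_id))
    stopf("duplicated node_id: %s",
          id_preview(unique(nodes$node_id[duplicated(nodes$node_id)])))
  if (anyNA(nodes) || any(nodes == ""))
    stopf("atlas has missing entries; every node needs a network, lobe and hemisphere")
  if (any(grepl("-", nodes$node_id, fixed = TRUE)))
    stopf("node ids must not contain '-'")
  bad_h <- !nodes$hemisphere %in% c("L", "R")
  if (any(bad_h)) stopf("hemisphere must be L or R, got: %s",
                        id_preview(unique(nodes$hemisphere[bad_h])))
  if (length(unique(nodes$network)) > 10L)
    stopf("at most 10 network labels are supported, got %d",
          length(unique(nodes$network)))
  structure(nodes, class = c("network_atlas", "data.frame"))
}

#' @export
print.network_atlas <- function(x, ...) {
  cat(sprintf("<network_atlas> %d nodes, %d networks, %d lobes\n",
              nrow(x), length(unique(x$network)), length(unique(x$lobe))))
  invisible(x)
}

#' @rdname network_atlas
#' @param atlas a `network_atlas`.
#' @export
atlas_networks <- function(atlas) sort(unique(atlas$network))
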