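# FC vectorization: strictly lower triangle of a symmetric node x node matrix,
# row-major over (i, j) with i > j. The ordering is an internal convention;
# every downstream mask keys on the node-pair labels, never on position.

lower_tri_index <- function(n) {
  if (n < 2L) return(cbind(i = integer(0), j = integer(0)))
  cbind(i = rep.int(2:n, 1:(n - 1L)), j = sequence(1:(n - 1L)))
}

#' Canonical FC edge labels for a set of nodes
#'
#' Edge features are labelled `"<a>-<b>"` where `a` precedes `b` in the node
#' ordering; node identifiers must therefore not contain `"-"`.
#'
#' @param node_ids character vector of node identifiers.
#' @return Character vector of `n(n-1)/2` edge labels in the canonical
#'   lower-triangle order.
#' @export
fc_edge_ids <- function(node_ids) {
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) stopf("duplicated node ids")
  if (any(grepl("-", node_ids, fixed = TRUE)))
    stopf("node ids must not contain '-': %s",
          id_preview(node_ids[grepl("-", node_ids, fixed = TRUE)]))
  idx <- lower_tri_index(length(node_ids))
  paste0(node_ids[idx[, "j"]], "-", node_ids[idx[, "i"]])
}

#' Split FC edge labels back into their two endpoint nodes
#'
#' @param edge_ids edge labels produced by [fc_edge_ids()].
#' @return A 2-column character matrix (`a`, `b`) of endpoints.
#' @export
fc_edge_ends <- function(edge_ids) {
  parts <- strsplit(as.character(edge_ids), "-", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stopf("malformed edge ids: %s", id_preview(edge_ids[bad]))
  out <- matrix(unlist(parts), ncol = 2L, byrow = TRUE,
                dimnames = list(NULL, c("a", "b")))
  out
}

#' Vectorize the strictly lower triangle of a symmetric matrix
#'
#' Turns a node x node symmetric matrix (e.g. an FC correlation matrix) into a
#' single subject's edge feature vector: the `n(n-1)/2` strictly-lower-triangle
#' entries in row-major order over `(i, j)` with `i > j`, each labelled with
#' its node pair. The diagonal is excluded.
#'
#' @param mat square numeric matrix, symmetric within `tol`.
#' @param node_ids node identifiers (default: rownames of `mat`).
#' @param tol symmetry tolerance on `|mat - t(mat)|`.
#' @return Named numeric vector of edge values.
#' @examples
#' m <- matrix(0, 3, 3); m[2, 1] <- m[1, 2] <- 0.1
#' m[3, 1] <- m[1, 3] <- 0.2; m[3, 2] <- m[2, 3] <- 0.3
#' vectorize_lower_triangle(m, node_ids = c("a", "b", "c"))
#' @export
vectorize_lower_triangle <- function(mat, node_ids = rownames(mat), tol = 1e-8) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat))
    stopf("matrix is not square: %d x %d", nrow(mat), ncol(mat))
  n <- nrow(mat)
  if (n < 2L) stopf("need at least 2 nodes, got %d", n)
  if (is.null(node_ids)) node_ids <- sprintf("n%03d", seq_len(n))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n) stopf("need %d node ids, got %d", n, length(node_ids))
  off <- row(mat) != col(mat)
  if (any(!is.finite(mat[off]))) {
    bad <- which(!is.finite(mat) & off, arr.ind = TRUE)[1L, ]
    stopf("non-finite off-diagonal entry at (%s, %s)",
          node_ids[bad[1L]], node_ids[bad[2L]])
  }
  asym <- abs(mat - t(mat))
  asym[!off] <- 0
  if (max(asym) > tol) {
    w <- which.max(asym)
    i <- ((w - 1L) %% n) + 1L
    j <- ((w - 1L) %/% n) + 1L
    stopf("matrix is not symmetric: worst mismatch |%.6g - %.6g| = %.3g at (%s, %s)",
          mat[i, j], mat[j, i], asym[w], node_ids[i], node_ids[j])
  }
  idx <- lower_tri_index(n)
  out <- mat[idx]
  names(out) <- fc_edge_ids(node_ids)
  out
}

#' Re-embed an edge vector into a symmetric matrix
#'
#' Inverse of [vectorize_lower_triangle()] on the off-diagonal entries.
#'
#' @param values named edge vector in canonical order for `node_ids`.
#' @param node_ids node identifiers.
#' @param diag value placed on the diagonal (default `NA`).
#' @return Symmetric `n x n` matrix.
#' @export
edges_to_matrix <- function(values, node_ids, diag = NA_real_) {
  node_ids <- as.character(node_ids)
  n <- length(node_ids)
  expected <- fc_edge_ids(node_ids)
  if (length(values) != length(expected))
    stopf("expected %d edge values for %d nodes, got %d",
          length(expected), n, length(values))
  if (!is.null(names(values)) && !identical(names(values), expected))
    values <- values[expected]
  out <- matrix(diag, n, n, dimnames = list(node_ids, node_ids))
  idx <- lower_tri_index(n)
  out[idx] <- values
  out[idx[, c(2L, 1L), drop = FALSE]] <- values
  out
}

#' Concatenate FC and GMV feature matrices into a COMB matrix
#'
#' Per-subject concatenation of the FC edge vector and the GMV region vector.
#' Because raw FC values (correlations) and GMV values (volumes) live on
#' incomparable scales, each feature column is by default z-scored across
#' subjects within its modality before concatenation; `standardize = FALSE`
#' concatenates the raw columns (a sensitivity knob).
#'
#' @param fc,gmv [feature_matrix()] objects over the same subjects.
#' @param standardize z-score columns within modality before concatenation?
#' @return A `feature_matrix` with modality `"COMB"`.
#' @export
assemble_comb <- function(fc, gmv, standardize = TRUE) {
  if (!inherits(fc, "feature_matrix") || !inherits(gmv, "feature_matrix"))
    stopf("`fc` and `gmv` must be feature_matrix objects")
  miss_fc <- setdiff(subject_ids(gmv), subject_ids(fc))
  miss_gmv <- setdiff(subject_ids(fc), subject_ids(gmv))
  if (length(miss_fc) || length(miss_gmv))
    stopf("subject sets differ: only in gmv: {%s}; only in fc: {%s}",
          id_preview(miss_fc), id_preview(miss_gmv))
  gmv <- subset_subjects(gmv, subject_ids(fc))
  overlap <- intersect(feature_ids(fc), feature_ids(gmv))
  if (length(overlap))
    stopf("FC and GMV feature ids overlap: %s", id_preview(overlap))
  a <- fc$values
  b <- gmv$values
  if (standardize) {
    a <- zscore_columns(a)
    b <- zscore_columns(b)
  }
  feature_matrix(cbind(a, b), modality = "COMB")
}

# Column z-score with sample SD; constant columns are centered only.
zscore_columns <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2L, stats::sd)
  s[s == 0] <- 1
  t((t(m) - mu) / s)
}
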