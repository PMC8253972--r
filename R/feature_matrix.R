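#' @title Subject-by-feature matrices
#'
#' @description A `feature_matrix` holds one brain modality for a set of
#' subjects: each row is one subject's feature vector \eqn{X_i(f)}, each
#' column one feature \eqn{f} (an FC edge, a GMV region, a motion-histogram
#' bin, or a concatenated COMB feature). Values must be finite; subject and
#' feature identifiers must be unique.
#'
#' @param values numeric matrix, subjects in rows, features in columns.
#' @param modality one of `"FC"`, `"GMV"`, `"COMB"`, `"MOTION"`.
#' @param subject_ids,feature_ids character identifiers; default taken from
#'   the dimnames of `values`.
#' @return An object of class `feature_matrix`.
#' @examples
#' fm <- feature_matrix(matrix(rnorm(6), 2, 3,
#'                      dimnames = list(c("s1", "s2"), c("f1", "f2", "f3"))),
#'                      modality = "GMV")
#' n_features(fm)
#' @export
feature_matrix <- function(values, modality,
                           subject_ids = rownames(values),
                           feature_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  modality <- match.arg(modality, dyad_modalities())
  if (is.null(subject_ids)) stopf("`subject_ids` missing (no rownames on `values`)")
  if (is.null(feature_ids)) stopf("`feature_ids` missing (no colnames on `values`)")
  subject_ids <- as.character(subject_ids)
  feature_ids <- as.character(feature_ids)
  if (nrow(values) != length(subject_ids))
    stopf("row count (%d) != number of subject ids (%d)", nrow(values), length(subject_ids))
  if (ncol(values) != length(feature_ids))
    stopf("column count (%d) != number of feature ids (%d)", ncol(values), length(feature_ids))
  if (anyDuplicated(subject_ids))
    stopf("duplicated subject_id: %s", id_preview(unique(subject_ids[duplicated(subject_ids)])))
  if (anyDuplicated(feature_ids))
    stopf("duplicated feature_id: %s", id_preview(unique(feature_ids[duplicated(feature_ids)])))
  bad <- which(!is.finite(values))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(values)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(values)) + 1L
    stopf("non-finite value at subject '%s', feature '%s' (%d offending cells)",
          subject_ids[i], feature_ids[j], length(bad))
  }
  dimnames(values) <- list(subject_ids, feature_ids)
  structure(list(values = values, modality = modality), class = "feature_matrix")
}

#' @rdname feature_matrix
#' @export
dyad_modalities <- function() c("FC", "GMV", "COMB", "MOTION")

#' @rdname feature_matrix
#' @param x a `feature_matrix`.
#' @export
subject_ids <- function(x) rownames(x$values)

#' @rdname feature_matrix
#' @export
feature_ids <- function(x) colnames(x$values)

#' @rdname feature_matrix
#' @export
n_subjects <- function(x) nrow(x$values)

#' @rdname feature_matrix
#' @export
n_features <- function(x) ncol(x$values)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d subjects x %d features\n",
              x$modality, n_subjects(x), n_features(x)))
  invisible(x)
}

#' Restrict or reorder a feature matrix
#'
#' @param fm a [feature_matrix()].
#' @param ids subject or feature identifiers to keep, in the requested order.
#' @return A `feature_matrix` restricted to `ids`.
#' @export
subset_features <- function(fm, ids) {
  ids <- as.character(ids)
  unknown <- setdiff(ids, feature_ids(fm))
  if (length(unknown)) stopf("unknown feature ids: %s", id_preview(unknown))
  if (!length(ids)) stopf("empty feature selection")
  feature_matrix(fm$values[, ids, drop = FALSE], fm$modality)
}

#' @rdname subset_features
#' @export
subset_subjects <- function(fm, ids) {
  ids <- as.character(ids)
  unknown <- setdiff(ids, subject_ids(fm))
  if (length(unknown)) stopf("unknown subject ids: %s", id_preview(unknown))
  if (!length(ids)) stopf("empty subject selection")
  feature_matrix(fm$values[ids, , drop = FALSE], fm$modality)
}
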