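# Tab-separated readers and writers. Dialect: UTF-8, '.' decimal, header row
# required; feature tables carry subject_id as the first column; empty
# covariate cells mean "absent".

#' Read and write feature matrix TSV files
#'
#' Format: `subject_id<TAB>f1<TAB>f2 ...` with one row per subject.
#'
#' @param path file path.
#' @param modality modality of the stored matrix (see [dyad_modalities()]).
#' @return [read_feature_matrix()] returns a [feature_matrix()];
#'   [write_feature_matrix()] returns `path` invisibly.
#' @export
read_feature_matrix <- function(path, modality) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", na.strings = character(0))
  if (ncol(df) < 2L) stopf("'%s': need a subject_id column plus at least one feature", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stopf("'%s': duplicated subject_id: %s", path,
          id_preview(unique(ids[duplicated(ids)])))
  vals <- as.matrix(df[-1L])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) | !is.finite(num))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(num)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(num)) + 1L
    stopf("'%s': non-numeric feature cell '%s' at row %d (subject '%s'), column '%s'",
          path, vals[bad[1L]], i, ids[i], colnames(vals)[j])
  }
  dimnames(num) <- list(ids, colnames(df)[-1L])
  feature_matrix(num, modality = modality)
}

#' @rdname read_feature_matrix
#' @param fm a [feature_matrix()].
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(subject_id = subject_ids(fm), fm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_dyad_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!all(c("child_id", "parent_id") %in% names(df)))
    stopf("'%s': dyad map needs columns child_id and parent_id", path)
  df[c("child_id", "parent_id")]
}

#' Read node metadata into a [network_atlas()]
#'
#' Format: `node_id<TAB>network<TAB>lobe<TAB>hemisphere`.
#'
#' @param path file path.
#' @export
read_atlas <- function(path) {
  network_atlas(utils::read.delim(path, header = TRUE, sep = "\t",
                                  colClasses = "character", check.names = FALSE))
}

read_covariates <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    na.strings = c("", "NA"), stringsAsFactors = FALSE)
}

#' Read a full dyad cohort from TSV files
#'
#' Loads child and parent feature tables, the dyad map, and optionally node
#' metadata and covariates, then assembles a fully validated [dyad_cohort()].
#' Subjects present in the feature tables but absent from the dyad map are
#' dropped (reported via a message); dyad-map rows naming unknown subjects
#' are an error.
#'
#' @param features_child_path,features_parent_path feature matrix TSVs.
#' @param dyad_map_path TSV with columns `child_id`, `parent_id`.
#' @param node_metadata_path optional atlas TSV (see [read_atlas()]).
#' @param covariates_path optional covariate TSV keyed by `child_id`.
#' @param modality modality of the feature tables.
#' @return A list with elements `cohort` ([dyad_cohort()]) and `atlas`
#'   ([network_atlas()] or `NULL`).
#' @export
read_cohort <- function(features_child_path, features_parent_path, dyad_map_path,
                        node_metadata_path = NULL, covariates_path = NULL,
                        modality = "FC") {
  children <- read_feature_matrix(features_child_path, modality)
  parents <- read_feature_matrix(features_parent_path, modality)
  dyad_map <- read_dyad_map(dyad_map_path)
  covariates <- if (!is.null(covariates_path)) read_covariates(covariates_path)
  atlas <- if (!is.null(node_metadata_path)) read_atlas(node_metadata_path)
  cohort <- dyad_cohort(children, parents, dyad_map, covariates)
  list(cohort = cohort, atlas = atlas)
}

#' Write a dyad cohort to a directory of TSV files
#'
#' Emits `children.tsv`, `parents.tsv`, `dyad_map.tsv` and `covariates.tsv`
#' in the formats read by [read_cohort()].
#'
#' @param cohort a [dyad_cohort()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_matrix(cohort$children, file.path(dir, "children.tsv"))
  write_feature_matrix(cohort$parents, file.path(dir, "parents.tsv"))
  utils::write.table(cohort$dyad_map, file.path(dir, "dyad_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cov <- cohort$covariates
  cov$sex <- as.character(cov$sex)
  cov$timepoint <- as.character(cov$timepoint)
  utils::write.table(cov, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(dir)
}

#' @rdname write_cohort
#' @param modality modality of the stored feature tables.
#' @export
read_cohort_dir <- function(dir, modality = "FC") {
  read_cohort(file.path(dir, "children.tsv"), file.path(dir, "parents.tsv"),
              file.path(dir, "dyad_map.tsv"),
              covariates_path = file.path(dir, "covariates.tsv"),
              modality = modality)$cohort
}
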