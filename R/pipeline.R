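# End-to-end orchestration: config parsing, seeded runs, stage logging, and
# report artifacts (TSV tables + JSON manifest).

pipeline_defaults <- function() {
  list(resampling = list(n_boot = 1000L, n_perm = 1000L, subsample_frac = 0.9,
                         seed = 1L),
       analysis = list(modalities = NULL, networks = NULL,
                       fc_percentile = 99.75, gmv_percentile = 90,
                       splits = list()))
}

merge_config <- function(defaults, config) {
  for (nm in names(config)) {
    defaults[[nm]] <- if (is.list(config[[nm]]) && is.list(defaults[[nm]]) &&
                          !is.null(names(config[[nm]])))
      merge_config(defaults[[nm]], config[[nm]]) else config[[nm]]
  }
  defaults
}

# Hash of the analysis-relevant configuration (the output location does not
# affect the numbers, so it is excluded).
config_hash <- function(config) {
  config$output <- NULL
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

load_pipeline_data <- function(data_cfg) {
  if (!is.null(data_cfg$simulate)) {
    spec <- do.call(synthetic_spec, data_cfg$simulate)
    message(sprintf("stage simulate: N = %d dyads, %d nodes", spec$n_dyads, spec$n_nodes))
    study <- simulate_cohort(spec)
    list(fc = study$fc, gmv = study$gmv, atlas = study$atlas, study = study)
  } else if (!is.null(data_cfg$paths)) {
    p <- data_cfg$paths
    message("stage load: reading cohort TSV files")
    atlas <- if (!is.null(p$node_metadata)) read_atlas(p$node_metadata)
    read_mod <- function(child, parent, modality) {
      if (is.null(child)) return(NULL)
      read_cohort(child, parent, p$dyad_map, covariates_path = p$covariates,
                  modality = modality)$cohort
    }
    list(fc = read_mod(p$fc_children, p$fc_parents, "FC"),
         gmv = read_mod(p$gmv_children, p$gmv_parents, "GMV"),
         atlas = atlas, study = NULL)
  } else stopf("config$data must provide either `simulate` or `paths`")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  path
}

#' Run the full identification analysis from a configuration
#'
#' Drives the whole pipeline: load or simulate the cohort, compute
#' whole-brain and per-network accuracies for FC, GMV and COMB with bootstrap
#' CIs and permutation p-values, emit edge-measure tables at the configured
#' percentiles, run the configured covariate splits, and write a manifest
#' recording the seed and a hash of the configuration. Setting `n_perm = 0`
#' (or `n_boot = 0`) skips that stage and reports the corresponding columns
#' as not computed (`NA`). Reruns with the same configuration produce
#' byte-identical numeric outputs.
#'
#' @param config a nested list or the path to a YAML file with sections
#'   `data` (either `simulate:` with [synthetic_spec()] fields or `paths:`
#'   with TSV locations), `analysis` (`modalities`, `networks`,
#'   `fc_percentile`, `gmv_percentile`, `splits`), `resampling` (`n_boot`,
#'   `n_perm`, `subsample_frac`, `seed`) and `output` (`dir`).
#' @param out_dir output directory; overrides `config$output$dir`.
#' @return Invisibly, a list with the accuracy table(s), edge measures, split
#'   results, the manifest, and the paths written.
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("`config` must be a list or a YAML file path")
  cfg <- merge_config(pipeline_defaults(), config)
  res <- cfg$resampling
  out_dir <- out_dir %||% cfg$output$dir %||% stopf("no output directory configured")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  dat <- load_pipeline_data(cfg$data)
  if (is.null(dat$atlas)) stopf("pipeline needs node metadata (an atlas)")
  first_tp <- function(x) if (inherits(x, "dyad_cohort") || is.null(x)) x else x[[1L]]
  timepoints <- if (inherits(dat$fc %||% dat$gmv, "dyad_cohort")) NULL
                else names(dat$fc %||% dat$gmv)

  paths <- character(0)
  results <- list()

  message(sprintf("stage accuracy: n_boot = %d, n_perm = %d, seed = %d",
                  res$n_boot, res$n_perm, res$seed))
  run_tp <- function(fc, gmv, tag) {
    tab <- per_network_analysis(fc = fc, gmv = gmv, atlas = dat$atlas,
                                networks = cfg$analysis$networks,
                                modalities = cfg$analysis$modalities,
                                n_boot = res$n_boot, n_perm = res$n_perm,
                                subsample_frac = res$subsample_frac,
                                seed = res$seed)
    out <- as.data.frame(tab)
    if (res$n_perm == 0L) out$p_value <- NA_real_
    f <- file.path(out_dir, paste0("accuracy", tag, ".tsv"))
    write_tsv(out, f)
    message(sprintf("  wrote %s (%d dyads)", f, (fc %||% gmv)$n_dyads))
    list(table = tab, path = f)
  }
  if (is.null(timepoints)) {
    acc <- run_tp(dat$fc, dat$gmv, "")
    results$accuracy <- acc$table
    paths <- c(paths, acc$path)
  } else {
    results$accuracy <- list()
    for (tp in timepoints) {
      acc <- run_tp(if (is.list(dat$fc)) dat$fc[[tp]] else dat$fc,
                    if (is.list(dat$gmv)) dat$gmv[[tp]] else dat$gmv,
                    paste0("_", tp))
      results$accuracy[[tp]] <- acc$table
      paths <- c(paths, acc$path)
    }
  }

  message("stage edges: differential power and group consistency")
  results$edges <- list()
  for (mod in c("FC", "GMV")) {
    co <- first_tp(dat[[tolower(mod)]])
    if (is.null(co)) next
    em <- edge_measures(co)
    pct <- if (mod == "FC") cfg$analysis$fc_percentile else cfg$analysis$gmv_percentile
    sel <- top_percentile(em$dp, pct)
    df <- as.data.frame(em)
    df$selected <- df$feature_id %in% sel
    f <- file.path(out_dir, paste0("edges_", tolower(mod), ".tsv"))
    write_tsv(df, f)
    results$edges[[mod]] <- em
    paths <- c(paths, f)
  }

  splits <- cfg$analysis$splits
  if (length(splits)) {
    results$splits <- list()
    for (sp in splits) {
      message(sprintf("stage split: %s", sp))
      sa <- covariate_split_analysis(fc = first_tp(dat$fc), gmv = first_tp(dat$gmv),
                                     atlas = dat$atlas, split = sp,
                                     networks = cfg$analysis$networks,
                                     n_boot = 0L, n_perm = 0L, seed = res$seed)
      df <- data.frame(network = sa$tables[[1L]]$network,
                       modality = sa$tables[[1L]]$modality,
                       stringsAsFactors = FALSE)
      df[[paste0("accuracy_", sa$groups[1L])]] <- sa$tables[[1L]]$accuracy
      df[[paste0("accuracy_", sa$groups[2L])]] <- sa$tables[[2L]]$accuracy
      f <- file.path(out_dir, paste0("split_", sp, ".tsv"))
      write_tsv(df, f)
      results$splits[[sp]] <- sa
      paths <- c(paths, f)
    }
  }

  manifest <- list(
    package = "dyadprint",
    version = as.character(utils::packageVersion("dyadprint")),
    seed = res$seed, n_boot = res$n_boot, n_perm = res$n_perm,
    subsample_frac = res$subsample_frac,
    permutation = if (res$n_perm > 0L) "computed" else "not computed",
    config_hash = config_hash(cfg),
    n_dyads = (first_tp(dat$fc) %||% first_tp(dat$gmv))$n_dyads,
    outputs = basename(paths))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, mf)
  results$manifest <- manifest
  results$paths <- paths
  message(sprintf("pipeline complete: %d artifacts in %s", length(paths), out_dir))
  invisible(results)
}
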