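log_msg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or a YAML file path")
  config
}

load_input_matrices <- function(data_cfg, verbose = FALSE) {
  if (!is.null(data_cfg$simulate)) {
    spec <- do.call(synthetic_spec, data_cfg$simulate)
    log_msg(verbose, "simulating %d x %d dataset (seed %d)",
            spec$nr, spec$ns, spec$seed)
    return(generate_synthetic(spec))
  }
  paths <- data_cfg$paths
  need <- c("a", "d_che", "d_dis", "s")
  missing <- setdiff(need, names(paths))
  if (length(missing) > 0)
    stopf("data paths missing: %s", paste(missing, collapse = ", "))
  for (p in unlist(paths[need]))
    if (!file.exists(p)) stopf("input matrix file not found: %s", p)
  A <- association_matrix(read_matrix_tsv(paths$a))
  list(A = A,
       D_che = similarity_matrix(read_matrix_tsv(paths$d_che),
                                 modality = "che"),
       D_dis = similarity_matrix(read_matrix_tsv(paths$d_dis),
                                 modality = "dis"),
       S = similarity_matrix(read_matrix_tsv(paths$s)))
}

write_manifest <- function(out_dir, config, seed, files) {
  cfg_file <- tempfile(fileext = ".rds")
  ## the hash covers the run-defining parameters, not the output location
  saveRDS(config[setdiff(names(config), "output")], cfg_file)
  manifest <- list(
    package = "adverank",
    version = as.character(utils::packageVersion("adverank")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    config_hash = unname(tools::md5sum(cfg_file)),
    files = as.list(tools::md5sum(files[file.exists(files)])))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run the full pipeline: data, cross-validation, ranking, artifacts
#'
#' Single entry point tying the modules together. The run configuration is
#' a list (or YAML file) with elements `data` (either
#' `data$simulate = list(...)` arguments for [synthetic_spec()], or
#' `data$paths = list(a=, d_che=, d_dis=, s=)` TSV matrix files), `model`
#' (overrides for [adverank_config()]), `seed`, `evaluate` (run
#' cross-validation, default `TRUE`), `rank` (rank candidates per drug with
#' a model trained on all data, default `TRUE`), and `top` (ranking depth,
#' default 15).
#'
#' Artifacts written to `output_dir`: simulated input matrices (when
#' simulating), `metrics.json`, `loss_trace.csv`, `rankings.tsv`,
#' `model.rds` (checkpoint), and `manifest.json` with the config echo, its
#' hash, and file checksums. Deterministic given the seed.
#'
#' @param config Run configuration (list or YAML path).
#' @param output_dir Output directory (created if absent; defaults to
#'   `config$output`).
#' @param verbose Log progress to stderr.
#' @return Invisible list with the computed objects and artifact paths.
#' @export
run_pipeline <- function(config, output_dir = NULL, verbose = FALSE) {
  config <- read_run_config(config)
  out_dir <- output_dir %||% config$output %||% stopf("no output directory given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  model_cfg <- config_with_overrides(c(config$model,
                                       if (is.null(config$model$seed))
                                         list(seed = seed)))
  if (!is.null(config$data$simulate) && is.null(config$data$simulate$seed))
    config$data$simulate$seed <- seed
  dat <- load_input_matrices(config$data, verbose)
  files <- character(0)
  if (!is.null(config$data$simulate)) {
    for (nm in c("A", "D_che", "D_dis", "S")) {
      p <- file.path(out_dir, paste0(tolower(nm), ".tsv"))
      write_matrix_tsv(dat[[nm]], p)
      files <- c(files, p)
    }
  }
  result <- list(data = dat)
  if (isTRUE(config$evaluate %||% TRUE)) {
    log_msg(verbose, "running %d-fold cross-validation", model_cfg$folds)
    cv <- cross_validate(dat$A, dat$D_che, dat$D_dis, dat$S, model_cfg,
                         seed = seed, verbose = verbose)
    metrics <- list(auc = cv$auc, aupr = cv$aupr,
                    recall = as.list(cv$recall),
                    null_auc = cv$null_auc,
                    fold_auc = cv$fold_auc, fold_aupr = cv$fold_aupr)
    mpath <- file.path(out_dir, "metrics.json")
    jsonlite::write_json(metrics, mpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    traces <- do.call(rbind, lapply(cv$folds, function(fr)
      data.frame(fold = fr$fold,
                 module = rep(c("encoder", "capsule"),
                              c(length(fr$traces$encoder),
                                length(fr$traces$capsule))),
                 epoch = c(seq_along(fr$traces$encoder),
                           seq_along(fr$traces$capsule)),
                 loss = c(fr$traces$encoder, fr$traces$capsule))))
    tpath <- file.path(out_dir, "loss_trace.csv")
    utils::write.csv(traces, tpath, row.names = FALSE)
    files <- c(files, mpath, tpath)
    result$cv <- cv
  }
  if (isTRUE(config$rank %||% TRUE)) {
    log_msg(verbose, "training the full model for candidate ranking")
    model <- adverank_fit(dat$A, dat$D_che, dat$D_dis, dat$S, model_cfg,
                          seed = seed)
    top <- config$top %||% 15L
    ranks <- do.call(rbind, lapply(seq_len(nrow(dat$A)), function(i)
      rank_candidates(model, i, top = top)))
    rpath <- file.path(out_dir, "rankings.tsv")
    utils::write.table(ranks, rpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cpath <- file.path(out_dir, "model.rds")
    save_cache(model, cpath)
    files <- c(files, rpath, cpath)
    result$model <- model
    result$rankings <- ranks
  }
  result$manifest <- write_manifest(out_dir, config, seed, files)
  result$files <- files
  invisible(result)
}
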