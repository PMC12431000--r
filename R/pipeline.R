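## End-to-end orchestration: a single YAML configuration drives the
## simulate -> preprocess -> features -> train -> evaluate chain, with a
## manifest tying every artifact to the configuration, seeds and
## per-stage wall clock.

.fileHashes <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

.simConfigFromList <- function(lst, seed) {
  lst <- lst %||% list()
  if (!is.null(lst$block_rho)) {
    lst$class_templates <- blockTemplates(lst$Cp %||% 10,
                                          lst$n_classes %||% 2,
                                          lst$block_rho)
    lst$block_rho <- NULL
  }
  lst$seed <- lst$seed %||% seed
  do.call(simConfig, lst)
}

#' Run the full pipeline from a configuration
#'
#' Executes the requested stages in order (\code{simulate},
#' \code{preprocess}, \code{features}, \code{evaluate}, optional
#' \code{ablate} and \code{stats}), writing artifacts and a manifest to
#' \code{out_dir}. Identical configuration and seed reproduce identical
#' artifact hashes.
#'
#' @param config path to a YAML file or an equivalent named list with
#'   per-stage sections; unknown stages fail fast.
#' @param out_dir output directory.
#' @param seed global seed (overridden by per-stage seeds in the
#'   config).
#' @param verbose print stage progress.
#' @return the manifest (invisibly also written as
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config, out_dir = "topofnirs_run", seed = 1L,
                        verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  known <- c("simulate", "preprocess", "features", "evaluate", "ablate",
             "stats")
  bad <- setdiff(names(config), known)
  if (length(bad)) .stopf("unknown pipeline stage(s): %s", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config, seed = seed,
                   package_version = as.character(utils::packageVersion("topofnirs")),
                   stages = list(), artifacts = list())
  say <- function(...) if (verbose) message(sprintf(...))
  tic <- function() proc.time()[["elapsed"]]

  ds <- NULL; ep <- NULL; features <- NULL
  if (!is.null(config$simulate)) {
    t0 <- tic()
    scfg <- .simConfigFromList(config$simulate, seed)
    ds <- simulateDataset(scfg)
    paths <- character(0)
    for (s in names(ds$recordings))
      paths <- c(paths, writeRecording(ds$recordings[[s]],
                                       file.path(out_dir, paste0("recording_", s))))
    manifest$stages$simulate <- list(seconds = tic() - t0,
                                     n_subjects = scfg$n_subjects,
                                     config_hash = configHash(scfg))
    manifest$artifacts <- c(manifest$artifacts, .fileHashes(paths))
    say("simulate: %d subject(s)", scfg$n_subjects)
  }
  if (!is.null(config$preprocess)) {
    if (is.null(ds)) .stopf("preprocess stage needs the simulate stage (or an input recording)")
    t0 <- tic()
    pargs <- config$preprocess
    pargs$filter <- NULL
    pcfg <- do.call(preprocessConfig, pargs %||% list())
    ep <- simulatedEpochs(ds, pcfg,
                          filter = !isFALSE(config$preprocess$filter))
    paths <- writeEpochSet(ep, file.path(out_dir, "dataset"), pcfg)
    manifest$stages$preprocess <- list(seconds = tic() - t0,
                                       n_epochs = nEpochs(ep),
                                       config_hash = configHash(pcfg))
    manifest$artifacts <- c(manifest$artifacts, .fileHashes(paths))
    say("preprocess: %d epochs", nEpochs(ep))
  }
  if (!is.null(config$features)) {
    if (is.null(ep)) .stopf("features stage needs epochs from the preprocess stage")
    t0 <- tic()
    fcfg <- do.call(featureConfig, config$features %||% list())
    features <- epochFeatures(ep, fcfg)
    paths <- writeFeatureTables(ep, features, out_dir)
    manifest$stages$features <- list(seconds = tic() - t0,
                                     config_hash = configHash(fcfg))
    manifest$artifacts <- c(manifest$artifacts, .fileHashes(paths))
    say("features: %d pairs x %d epochs", nPairs(ep), nEpochs(ep))
  }
  if (!is.null(config$evaluate)) {
    if (is.null(features)) .stopf("evaluate stage needs the features stage")
    t0 <- tic()
    ecfg <- config$evaluate
    mArgs <- ecfg$model %||% list()
    mArgs$n_classes <- mArgs$n_classes %||% length(unique(epochLabels(ep)))
    mcfg <- do.call(modelConfig, mArgs)
    tArgs <- ecfg$train %||% list()
    tArgs$seed <- tArgs$seed %||% seed
    tcfg <- do.call(trainConfig, tArgs)
    folds <- if (identical(ecfg$protocol, "loso")) makeLosoFolds(ep)
             else makeSubjectFolds(ep, tcfg$n_folds, tcfg$seed)
    report <- crossValidate(ep, features, folds, mcfg, tcfg,
                            fusion_strategy = ecfg$fusion %||% "concat",
                            verbose = verbose)
    perPath <- file.path(out_dir, "per_fold_metrics.csv")
    utils::write.csv(report$per_fold, perPath, row.names = FALSE)
    repPath <- file.path(out_dir, "eval_report.json")
    jsonlite::write_json(list(accuracy = report$accuracy,
                              accuracy_sd = report$accuracy_sd,
                              kappa = as.numeric(report$kappa),
                              macro_auc = report$macro_auc,
                              confusion = report$confusion,
                              protocol = ecfg$protocol %||% "subject_kfold",
                              seed = tcfg$seed),
                        repPath, auto_unbox = TRUE, digits = NA)
    manifest$stages$evaluate <- list(seconds = tic() - t0,
                                     accuracy = report$accuracy,
                                     kappa = as.numeric(report$kappa))
    manifest$artifacts <- c(manifest$artifacts, .fileHashes(c(perPath, repPath)))
    say("evaluate: accuracy %.2f%%, kappa %.3f", report$accuracy,
        as.numeric(report$kappa))
  }
  if (!is.null(config$stats)) {
    if (is.null(features)) .stopf("stats stage needs the features stage")
    t0 <- tic()
    st <- featureGroupStats(ep, features,
                            alpha = config$stats$alpha %||% 0.05,
                            adjust = config$stats$adjust %||% "none")
    p1 <- file.path(out_dir, "feature_tests.csv")
    utils::write.csv(st$tests, p1, row.names = FALSE)
    p2 <- file.path(out_dir, "feature_groups.csv")
    utils::write.csv(st$groups, p2, row.names = FALSE)
    manifest$stages$stats <- list(seconds = tic() - t0,
                                  n_significant = length(st$significant_pairs))
    manifest$artifacts <- c(manifest$artifacts, .fileHashes(c(p1, p2)))
    say("stats: %d significant pair(s)", length(st$significant_pairs))
  }
  if (!is.null(config$ablate)) {
    if (is.null(features)) .stopf("ablate stage needs the features stage")
    t0 <- tic()
    acfg <- config$ablate
    if (identical(acfg$kind, "threshold")) {
      tbl <- thresholdSweep(ep, thresholds = unlist(acfg$thresholds %||%
                                                      seq(0.1, 0.5, by = 0.1)))
    } else .stopf("pipeline ablate stage supports kind: threshold; use the harness functions directly for the others")
    pa <- file.path(out_dir, "ablation.csv")
    utils::write.csv(tbl, pa, row.names = FALSE)
    manifest$stages$ablate <- list(seconds = tic() - t0)
    manifest$artifacts <- c(manifest$artifacts, .fileHashes(pa))
  }
  manPath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manPath, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
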