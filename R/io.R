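## Plain-text containers: a CSV matrix plus a JSON sidecar carrying
## rate, channel roles and annotations. Checkpoints are single-file RDS
## archives of the parameter tensors plus configuration and seed.

#' Write a hemodynamic recording
#'
#' Writes \code{<prefix>_signal.csv} (samples x channels) and
#' \code{<prefix>_meta.json} (sampling rate, channel roles, trial
#' annotations).
#'
#' @param rec a \linkS4class{HemodynamicRecording}.
#' @param prefix output path prefix.
#' @return invisibly, the two paths.
#' @export
writeRecording <- function(rec, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  sigPath <- paste0(prefix, "_signal.csv")
  metaPath <- paste0(prefix, "_meta.json")
  utils::write.csv(t(signalMatrix(rec)), sigPath, row.names = FALSE)
  meta <- list(sampling_rate = samplingRate(rec),
               channel_roles = channelRoles(rec),
               annotations = annotations(rec))
  jsonlite::write_json(meta, metaPath, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(sigPath, metaPath))
}

#' Read a hemodynamic recording written by [writeRecording()]
#'
#' @param prefix path prefix used when writing.
#' @return a \linkS4class{HemodynamicRecording}.
#' @export
readRecording <- function(prefix) {
  sig <- t(as.matrix(utils::read.csv(paste0(prefix, "_signal.csv"))))
  rownames(sig) <- NULL
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  ann <- meta$annotations
  if (!is.null(ann)) ann <- as.data.frame(ann)
  HemodynamicRecording(sig, meta$sampling_rate,
                       as.data.frame(meta$channel_roles), ann)
}

#' Write an epoch set
#'
#' Writes \code{<prefix>_epochs.csv} (one row per epoch, flattened
#' channel-by-time values) and \code{<prefix>_meta.json} (labels,
#' subjects, dimensions, provenance hash of the preprocessing
#' configuration if supplied).
#'
#' @param ep an \linkS4class{EpochSet}.
#' @param prefix output path prefix.
#' @param config optional configuration to hash into the sidecar.
#' @return invisibly, the two paths.
#' @export
writeEpochSet <- function(ep, prefix, config = NULL) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  d <- dim(ep@epochs)
  flat <- matrix(ep@epochs, nrow = d[1L])   # epoch x (C*T), column-major
  epPath <- paste0(prefix, "_epochs.csv")
  metaPath <- paste0(prefix, "_meta.json")
  utils::write.csv(flat, epPath, row.names = FALSE)
  meta <- list(dims = d, labels = epochLabels(ep), subjects = subjectIds(ep),
               trial_index = ep@trialIndex, sampling_rate = samplingRate(ep),
               epoch_length_s = ep@epochLengthS,
               channel_roles = channelRoles(ep),
               config_hash = if (!is.null(config)) configHash(config))
  jsonlite::write_json(meta, metaPath, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(epPath, metaPath))
}

#' Read an epoch set written by [writeEpochSet()]
#'
#' @param prefix path prefix used when writing.
#' @return an \linkS4class{EpochSet}.
#' @export
readEpochSet <- function(prefix) {
  flat <- as.matrix(utils::read.csv(paste0(prefix, "_epochs.csv")))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  d <- as.integer(meta$dims)
  EpochSet(array(flat, dim = d), meta$labels, meta$subjects,
           meta$trial_index, meta$sampling_rate, meta$epoch_length_s,
           as.data.frame(meta$channel_roles))
}

#' Save a trained model checkpoint
#'
#' Single-file archive of the named parameter tensors, model
#' configuration, data dimensions and seed.
#'
#' @param model a \code{topotemp_model}.
#' @param path output file.
#' @param fusion optional fitted fusion transform stored alongside.
#' @export
saveCheckpoint <- function(model, path, fusion = NULL) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(params = model$params, config = model$config,
               dims = model$dims, fusion = fusion), path)
  invisible(path)
}

#' Load a checkpoint saved by [saveCheckpoint()]
#'
#' @param path checkpoint file.
#' @return list with \code{model} and \code{fusion}.
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  list(model = structure(list(config = x$config, params = x$params,
                              dims = x$dims), class = "topotemp_model"),
       fusion = x$fusion)
}

#' Stable hash of a configuration object
#'
#' MD5 of the deparsed object, used for artifact provenance.
#'
#' @param x any R object.
#' @return hex string.
#' @export
configHash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(x), tmp)
  unname(tools::md5sum(tmp))
}
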