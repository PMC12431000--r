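## Generics and accessors for the data containers.

#' @name topofnirs-accessors
#' @title Accessors for recording and epoch containers
#' @description Small accessor generics: slot access stays behind these.
#' @param object a container object.
NULL

#' @rdname topofnirs-accessors
#' @export
setGeneric("signalMatrix", function(object) standardGeneric("signalMatrix"))
#' @rdname topofnirs-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname topofnirs-accessors
#' @export
setGeneric("channelRoles", function(object) standardGeneric("channelRoles"))
#' @rdname topofnirs-accessors
#' @export
setGeneric("annotations", function(object) standardGeneric("annotations"))
#' @rdname topofnirs-accessors
#' @export
setGeneric("epochArray", function(object) standardGeneric("epochArray"))
#' @rdname topofnirs-accessors
#' @export
setGeneric("epochLabels", function(object) standardGeneric("epochLabels"))
#' @rdname topofnirs-accessors
#' @export
setGeneric("subjectIds", function(object) standardGeneric("subjectIds"))
#' @rdname topofnirs-accessors
#' @export
setGeneric("nPairs", function(object) standardGeneric("nPairs"))

#' @rdname topofnirs-accessors
#' @export
setMethod("signalMatrix", "HemodynamicRecording", function(object) object@signal)
#' @rdname topofnirs-accessors
#' @export
setMethod("samplingRate", "HemodynamicRecording", function(object) object@samplingRate)
#' @rdname topofnirs-accessors
#' @export
setMethod("samplingRate", "EpochSet", function(object) object@samplingRate)
#' @rdname topofnirs-accessors
#' @export
setMethod("samplingRate", "OpticalRecording", function(object) object@samplingRate)
#' @rdname topofnirs-accessors
#' @export
setMethod("channelRoles", "HemodynamicRecording", function(object) object@channelRoles)
#' @rdname topofnirs-accessors
#' @export
setMethod("channelRoles", "EpochSet", function(object) object@channelRoles)
#' @rdname topofnirs-accessors
#' @export
setMethod("annotations", "HemodynamicRecording", function(object) object@annotations)
#' @rdname topofnirs-accessors
#' @export
setMethod("annotations", "OpticalRecording", function(object) object@annotations)
#' @rdname topofnirs-accessors
#' @export
setMethod("epochArray", "EpochSet", function(object) object@epochs)
#' @rdname topofnirs-accessors
#' @export
setMethod("epochLabels", "EpochSet", function(object) object@labels)
#' @rdname topofnirs-accessors
#' @export
setMethod("subjectIds", "EpochSet", function(object) object@subjects)
#' @rdname topofnirs-accessors
#' @export
setMethod("nPairs", "HemodynamicRecording", function(object) nrow(object@signal) / 2L)
#' @rdname topofnirs-accessors
#' @export
setMethod("nPairs", "EpochSet", function(object) dim(object@epochs)[2L] / 2L)

#' Number of epochs
#' @param object an \linkS4class{EpochSet}.
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))
#' @rdname nEpochs
#' @export
setMethod("nEpochs", "EpochSet", function(object) dim(object@epochs)[1L])

setMethod("show", "OpticalRecording", function(object) {
  cat(sprintf("OpticalRecording: %d optodes x %d samples @ %.3g Hz, wavelengths %s nm\n",
              nrow(object@deltaOD) / 2L, ncol(object@deltaOD),
              object@samplingRate,
              paste(object@wavelengths, collapse = "/")))
  if (!is.null(object@annotations))
    cat(sprintf("  %d annotated trials\n", nrow(object@annotations)))
})

setMethod("show", "HemodynamicRecording", function(object) {
  cat(sprintf("HemodynamicRecording: %d channels (%d pairs) x %d samples @ %.3g Hz\n",
              nrow(object@signal), nPairs(object), ncol(object@signal),
              object@samplingRate))
  if (!is.null(object@annotations) && nrow(object@annotations) > 0) {
    ann <- object@annotations
    cat(sprintf("  %d trials, %d classes, %d subject(s)\n", nrow(ann),
                length(unique(ann$label)), length(unique(ann$subject))))
  }
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EpochSet: %d epochs x %d channels (%d pairs) x %d samples @ %.3g Hz\n",
              d[1L], d[2L], nPairs(object), d[3L], object@samplingRate))
  cat(sprintf("  classes: %s; subjects: %s\n",
              paste(sort(unique(object@labels)), collapse = ","),
              paste(unique(object@subjects), collapse = ",")))
})

#' Subset an epoch set by epoch index
#'
#' @param x an \linkS4class{EpochSet}.
#' @param i epoch indices (integer or logical).
#' @param j,...,drop ignored.
#' @return an \linkS4class{EpochSet} with the selected epochs.
#' @export
setMethod("[", "EpochSet", function(x, i, j, ..., drop = FALSE) {
  idx <- seq_len(nEpochs(x))[i]
  new("EpochSet", epochs = x@epochs[idx, , , drop = FALSE],
      labels = x@labels[idx], subjects = x@subjects[idx],
      trialIndex = x@trialIndex[idx], samplingRate = x@samplingRate,
      epochLengthS = x@epochLengthS, channelRoles = x@channelRoles)
})
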