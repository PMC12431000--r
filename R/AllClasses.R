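#' @import methods
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Raw optical-density recording
#'
#' Container for continuous optical-density changes measured at two
#' near-infrared wavelengths, together with the constants needed by the
#' modified Beer-Lambert inversion. Rows of \code{deltaOD} are ordered
#' per optode channel: row \code{2i - 1} holds the first-wavelength series
#' and row \code{2i} the second-wavelength series of optode \code{i}.
#'
#' @slot deltaOD numeric matrix, \code{2 * nOptodes} rows by time samples,
#'   optical-density changes (dimensionless).
#' @slot wavelengths numeric length 2, the two wavelengths in nm.
#' @slot samplingRate sampling rate in Hz.
#' @slot extinction 2 x 2 numeric matrix of extinction coefficients;
#'   rows index the two wavelengths, columns the species \code{(HbO, HbR)}.
#' @slot pathlengthFactor differential pathlength factor (dimensionless).
#' @slot separation source-detector separation in cm.
#' @slot annotations trial annotations: \code{data.frame} with columns
#'   \code{onset} (1-based sample), \code{duration_s}, \code{label}
#'   (integer class, 0-based) and \code{subject}.
#'
#' @seealso [mbllConvert()]
#' @export
setClass("OpticalRecording",
  representation(
    deltaOD = "matrix",
    wavelengths = "numeric",
    samplingRate = "numeric",
    extinction = "matrix",
    pathlengthFactor = "numeric",
    separation = "numeric",
    annotations = "data.frameOrNULL"
  )
)

setValidity("OpticalRecording", function(object) {
  msg <- character()
  if (nrow(object@deltaOD) %% 2L != 0L)
    msg <- c(msg, "deltaOD needs two wavelength rows per optode channel")
  if (length(object@wavelengths) != 2L)
    msg <- c(msg, "exactly two wavelengths are required")
  if (!.isPositiveScalar(object@samplingRate))
    msg <- c(msg, "samplingRate must be a positive scalar")
  if (!identical(dim(object@extinction), c(2L, 2L)))
    msg <- c(msg, "extinction must be a 2 x 2 matrix")
  else if (abs(det(object@extinction)) < 1e-12 * prod(pmax(abs(object@extinction[1, ]), 1)))
    msg <- c(msg, "extinction matrix is singular (species are not separable)")
  if (!.isPositiveScalar(object@pathlengthFactor))
    msg <- c(msg, "pathlengthFactor must be a positive scalar")
  if (!.isPositiveScalar(object@separation))
    msg <- c(msg, "separation must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Hemoglobin-concentration recording
#'
#' Continuous chromophore concentration changes, one row per channel.
#' Channels come in pairs: the oxygenated (HbO) and deoxygenated (HbR)
#' series of one optode form one channel pair, the unit of functional
#' coupling used throughout the package.
#'
#' @slot signal numeric matrix \code{C} x time, concentration changes
#'   (umol/L).
#' @slot samplingRate sampling rate in Hz.
#' @slot channelRoles \code{data.frame} with one row per signal row:
#'   \code{pair} (1-based pair index) and \code{species}
#'   (\code{"HbO"} or \code{"HbR"}).
#' @slot annotations trial annotations as in
#'   \linkS4class{OpticalRecording}.
#'
#' @seealso [segmentEpochs()], [filterSignal()]
#' @export
setClass("HemodynamicRecording",
  representation(
    signal = "matrix",
    samplingRate = "numeric",
    channelRoles = "data.frame",
    annotations = "data.frameOrNULL"
  )
)

setValidity("HemodynamicRecording", function(object) {
  msg <- character()
  C <- nrow(object@signal)
  if (C %% 2L != 0L) msg <- c(msg, "channel count must be even (2 per pair)")
  if (!.isPositiveScalar(object@samplingRate))
    msg <- c(msg, "samplingRate must be a positive scalar")
  roles <- object@channelRoles
  if (nrow(roles) != C) {
    msg <- c(msg, "channelRoles must have one row per channel")
  } else if (C > 0) {
    if (!all(c("pair", "species") %in% names(roles)))
      msg <- c(msg, "channelRoles needs 'pair' and 'species' columns")
    else {
      tab <- table(roles$pair, roles$species)
      if (!all(sort(unique(roles$pair)) == seq_len(C / 2L)) ||
          !all(tab == 1L) || !setequal(colnames(tab), c("HbO", "HbR")))
        msg <- c(msg, "each pair index must appear exactly once as HbO and once as HbR")
    }
  }
  ann <- object@annotations
  if (!is.null(ann) && nrow(ann) > 0) {
    if (!all(c("onset", "duration_s", "label", "subject") %in% names(ann)))
      msg <- c(msg, "annotations need onset, duration_s, label, subject columns")
    else if (any(ann$onset < 1) || any(ann$onset > ncol(object@signal)))
      msg <- c(msg, "annotation onsets must lie within the recording")
  }
  if (length(msg)) msg else TRUE
})

#' Labeled epoch set
#'
#' The model's unit of classification: \code{N} epochs, each a
#' \code{C x T} matrix of channel-by-time concentration changes, with an
#' integer class label and a subject identifier per epoch.
#'
#' @slot epochs numeric array \code{N x C x T}.
#' @slot labels integer class per epoch, in \code{0..K-1}.
#' @slot subjects subject identifier per epoch.
#' @slot trialIndex index of the parent trial each epoch was cut from
#'   (row of the source recording's annotations), used for baseline
#'   correction.
#' @slot samplingRate sampling rate in Hz.
#' @slot epochLengthS epoch length in seconds.
#' @slot channelRoles channel pairing metadata (see
#'   \linkS4class{HemodynamicRecording}).
#'
#' @seealso [segmentEpochs()], [epochFeatures()]
#' @export
setClass("EpochSet",
  representation(
    epochs = "array",
    labels = "integer",
    subjects = "character",
    trialIndex = "integer",
    samplingRate = "numeric",
    epochLengthS = "numeric",
    channelRoles = "data.frame"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@epochs)
  if (length(d) != 3L) msg <- c(msg, "epochs must be an N x C x T array")
  else {
    if (length(object@labels) != d[1L]) msg <- c(msg, "one label per epoch required")
    if (length(object@subjects) != d[1L]) msg <- c(msg, "one subject per epoch required")
    if (length(object@trialIndex) != d[1L]) msg <- c(msg, "one trialIndex per epoch required")
    if (d[2L] %% 2L != 0L) msg <- c(msg, "channel count must be even (2 per pair)")
    if (nrow(object@channelRoles) != d[2L])
      msg <- c(msg, "channelRoles must have one row per channel")
  }
  if (anyNA(object@epochs)) msg <- c(msg, "epochs must not contain missing values")
  if (length(object@labels) && any(object@labels < 0L))
    msg <- c(msg, "labels must be non-negative integers (0-based classes)")
  if (!.isPositiveScalar(object@samplingRate))
    msg <- c(msg, "samplingRate must be a positive scalar")
  if (!.isPositiveScalar(object@epochLengthS))
    msg <- c(msg, "epochLengthS must be a positive scalar")
  if (length(msg)) msg else TRUE
})

## ------------------------------------------------------------------ ##
## constructors

#' @rdname OpticalRecording-class
#' @param deltaOD,wavelengths,samplingRate,extinction,pathlengthFactor,separation,annotations
#'   see the corresponding slots.
#' @export
OpticalRecording <- function(deltaOD, wavelengths, samplingRate,
                             extinction = defaultExtinction(wavelengths),
                             pathlengthFactor = 6, separation = 3,
                             annotations = NULL) {
  new("OpticalRecording", deltaOD = as.matrix(deltaOD),
      wavelengths = as.numeric(wavelengths),
      samplingRate = as.numeric(samplingRate),
      extinction = extinction,
      pathlengthFactor = as.numeric(pathlengthFactor),
      separation = as.numeric(separation),
      annotations = annotations)
}

#' @rdname HemodynamicRecording-class
#' @param signal,samplingRate,channelRoles,annotations see the
#'   corresponding slots.
#' @export
HemodynamicRecording <- function(signal, samplingRate, channelRoles = NULL,
                                 annotations = NULL) {
  signal <- as.matrix(signal)
  if (is.null(channelRoles)) channelRoles <- interleavedRoles(nrow(signal) / 2L)
  new("HemodynamicRecording", signal = signal,
      samplingRate = as.numeric(samplingRate),
      channelRoles = channelRoles, annotations = annotations)
}

#' @rdname EpochSet-class
#' @param epochs,labels,subjects,trialIndex,samplingRate,epochLengthS,channelRoles
#'   see the corresponding slots.
#' @export
EpochSet <- function(epochs, labels, subjects = NULL, trialIndex = NULL,
                     samplingRate, epochLengthS, channelRoles = NULL) {
  epochs <- as.array(epochs)
  n <- dim(epochs)[1L]
  if (is.null(subjects)) subjects <- rep("s1", n)
  if (is.null(trialIndex)) trialIndex <- seq_len(n)
  if (is.null(channelRoles)) channelRoles <- interleavedRoles(dim(epochs)[2L] / 2L)
  new("EpochSet", epochs = epochs, labels = as.integer(labels),
      subjects = as.character(subjects), trialIndex = as.integer(trialIndex),
      samplingRate = as.numeric(samplingRate),
      epochLengthS = as.numeric(epochLengthS), channelRoles = channelRoles)
}

#' Channel roles for interleaved (HbO, HbR) channel ordering
#'
#' @param nPairs number of optode channel pairs.
#' @return \code{data.frame} with columns \code{pair} and \code{species}
#'   describing rows ordered \code{HbO_1, HbR_1, HbO_2, ...}.
#' @export
interleavedRoles <- function(nPairs) {
  data.frame(pair = rep(seq_len(nPairs), each = 2L),
             species = rep(c("HbO", "HbR"), nPairs),
             stringsAsFactors = FALSE)
}

#' Literature extinction coefficients
#'
#' Molar extinction coefficients of HbO and HbR at the requested
#' wavelengths, tabulated for the wavelengths in common fNIRS use
#' (values in 1/(mM cm), compiled from standard absorption spectra).
#'
#' @param wavelengths numeric length 2, in nm; supported: 690, 760, 780,
#'   805, 830, 850.
#' @return 2 x 2 matrix, rows = wavelengths, columns = \code{(HbO, HbR)}.
#' @export
defaultExtinction <- function(wavelengths = c(760, 850)) {
  tab <- c("690" = 0.35,  "760" = 0.1486, "780" = 0.1657,
           "805" = 0.2076, "830" = 0.2321, "850" = 0.2526)
  tabR <- c("690" = 2.051, "760" = 0.3843, "780" = 0.2436,
            "805" = 0.1964, "830" = 0.1792, "850" = 0.1798)
  key <- as.character(round(wavelengths))
  if (!all(key %in% names(tab)))
    .stopf("no tabulated extinction coefficients for wavelengths %s",
           paste(wavelengths, collapse = ", "))
  matrix(c(tab[key], tabR[key]), nrow = 2,
         dimnames = list(key, c("HbO", "HbR")))
}
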