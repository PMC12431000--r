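## Signal preprocessing: Beer-Lambert inversion, filtering, resampling,
## epoch segmentation and baseline correction.

#' Preprocessing configuration
#'
#' @param filter_kind \code{"bandpass"} (task band, removes DC) or
#'   \code{"lowpass"} (preserves DC).
#' @param band filter edges in Hz; two values for bandpass, one cutoff
#'   for lowpass.
#' @param filter_order Butterworth order (applied forward-backward, so
#'   the effective order doubles).
#' @param target_rate resample target in Hz, or \code{NULL} to keep the
#'   native rate.
#' @param epoch_length_s epoch length in seconds.
#' @param baseline_window_s length of the pre-stimulus reference
#'   interval whose mean is subtracted from every epoch of a trial.
#' @param trailing_partial what to do with a trailing partial segment of
#'   a task window: \code{"drop"} (default) or \code{"pad"}
#'   (edge-replicate to full length).
#' @param context_pad_s optional symmetric context added around each
#'   epoch (seconds); 0 keeps epochs strictly non-overlapping.
#' @return a validated \code{preprocess_config} list.
#' @export
preprocessConfig <- function(filter_kind = c("bandpass", "lowpass"),
                             band = c(0.01, 0.1), filter_order = 3,
                             target_rate = NULL, epoch_length_s = 1,
                             baseline_window_s = 1,
                             trailing_partial = c("drop", "pad"),
                             context_pad_s = 0) {
  filter_kind <- match.arg(filter_kind)
  trailing_partial <- match.arg(trailing_partial)
  if (filter_kind == "bandpass" && length(band) != 2L)
    .stopf("bandpass needs two band edges")
  if (filter_kind == "lowpass" && length(band) != 1L)
    .stopf("lowpass needs a single cutoff")
  if (any(band <= 0)) .stopf("band edges must be positive")
  if (!.isPositiveScalar(epoch_length_s)) .stopf("epoch_length_s must be > 0")
  if (!is.null(target_rate) && !.isPositiveScalar(target_rate))
    .stopf("target_rate must be > 0")
  structure(list(filter_kind = filter_kind, band = as.numeric(band),
                 filter_order = as.integer(filter_order),
                 target_rate = target_rate,
                 epoch_length_s = epoch_length_s,
                 baseline_window_s = baseline_window_s,
                 trailing_partial = trailing_partial,
                 context_pad_s = context_pad_s),
            class = "preprocess_config")
}

#' Modified Beer-Lambert conversion
#'
#' Inverts optical-density changes at two wavelengths into oxygenated and
#' deoxygenated hemoglobin concentration changes. Per optode,
#' \deqn{[\Delta HbO; \Delta HbR] = E^{-1} [\Delta OD(\lambda_1);
#' \Delta OD(\lambda_2)] / (d \, l),} where \eqn{E} is the extinction
#' matrix, \eqn{d} the differential pathlength factor and \eqn{l} the
#' source-detector separation.
#'
#' @param rec an \linkS4class{OpticalRecording}.
#' @return a \linkS4class{HemodynamicRecording} with interleaved
#'   \code{(HbO, HbR)} rows per optode and pairing metadata populated.
#' @export
mbllConvert <- function(rec) {
  stopifnot(is(rec, "OpticalRecording"))
  validObject(rec)
  E <- rec@extinction
  if (abs(det(E)) < .Machine$double.eps * 100)
    .stopf("extinction matrix is singular; HbO/HbR cannot be separated")
  Einv <- solve(E)
  scale <- rec@pathlengthFactor * rec@separation
  nOpt <- nrow(rec@deltaOD) / 2L
  out <- matrix(0, nrow = 2L * nOpt, ncol = ncol(rec@deltaOD))
  for (i in seq_len(nOpt)) {
    od <- rec@deltaOD[c(2L * i - 1L, 2L * i), , drop = FALSE]
    out[c(2L * i - 1L, 2L * i), ] <- (Einv %*% od) / scale
  }
  HemodynamicRecording(out, rec@samplingRate,
                       channelRoles = interleavedRoles(nOpt),
                       annotations = rec@annotations)
}

.designFilter <- function(cfg, rate) {
  nyq <- rate / 2
  if (any(cfg$band >= nyq))
    .stopf("filter edge %.4g Hz is at or above the Nyquist frequency %.4g Hz",
           max(cfg$band), nyq)
  if (cfg$filter_kind == "bandpass")
    signal::butter(cfg$filter_order, cfg$band / nyq, type = "pass")
  else
    signal::butter(cfg$filter_order, cfg$band / nyq, type = "low")
}

#' Zero-phase filtering
#'
#' Applies a Butterworth filter forward and backward
#' (\code{signal::filtfilt}) to every channel, preserving hemodynamic
#' phase. A bandpass removes constant offsets; a lowpass keeps them.
#'
#' @param rec a \linkS4class{HemodynamicRecording}.
#' @param cfg a [preprocessConfig()].
#' @return the filtered recording (same shape, same annotations).
#' @export
filterSignal <- function(rec, cfg) {
  stopifnot(is(rec, "HemodynamicRecording"), inherits(cfg, "preprocess_config"))
  filt <- .designFilter(cfg, rec@samplingRate)
  sig <- t(apply(rec@signal, 1L, function(x) signal::filtfilt(filt, x)))
  HemodynamicRecording(sig, rec@samplingRate, rec@channelRoles, rec@annotations)
}

#' Resample a recording
#'
#' Downsampling by zero-phase anti-alias lowpass filtering (Butterworth
#' at 80% of the new Nyquist frequency, forward-backward) followed by
#' interpolation onto the new uniform grid; trial onsets are rescaled
#' proportionally. Output length is
#' \code{round(n * targetRate / samplingRate)}.
#'
#' @param rec a \linkS4class{HemodynamicRecording}.
#' @param targetRate new sampling rate in Hz (must not exceed the
#'   current rate).
#' @return the resampled recording.
#' @export
resampleRecording <- function(rec, targetRate) {
  stopifnot(is(rec, "HemodynamicRecording"))
  if (!.isPositiveScalar(targetRate)) .stopf("targetRate must be > 0")
  if (targetRate > rec@samplingRate)
    .stopf("upsampling (%.3g -> %.3g Hz) is not supported", rec@samplingRate, targetRate)
  if (abs(targetRate - rec@samplingRate) < 1e-12) return(rec)
  ratio <- targetRate / rec@samplingRate
  nIn <- ncol(rec@signal)
  nOut <- round(nIn * ratio)
  aa <- signal::butter(4, 0.8 * ratio, type = "low")
  tOld <- (seq_len(nIn) - 1L) / rec@samplingRate
  tNew <- (seq_len(nOut) - 1L) / targetRate
  sig <- t(apply(rec@signal, 1L, function(x) {
    mu <- mean(x)                          # keep DC exact through the filter
    xf <- mu + signal::filtfilt(aa, x - mu)
    stats::approx(tOld, xf, xout = tNew, rule = 2)$y
  }))
  ann <- rec@annotations
  if (!is.null(ann) && nrow(ann) > 0)
    ann$onset <- pmax(1L, as.integer(round(ann$onset * ratio)))
  HemodynamicRecording(sig, targetRate, rec@channelRoles, ann)
}

#' Segment task windows into fixed-length epochs
#'
#' Each annotated task window is cut into
#' \code{floor(duration / epoch_length)} non-overlapping epochs, every
#' epoch inheriting the trial label and subject. Trailing partial
#' segments follow \code{cfg$trailing_partial}; optional symmetric
#' context (\code{cfg$context_pad_s}) is added around each epoch.
#'
#' @param rec an annotated \linkS4class{HemodynamicRecording}.
#' @param cfg a [preprocessConfig()].
#' @return an \linkS4class{EpochSet}.
#' @export
segmentEpochs <- function(rec, cfg) {
  stopifnot(is(rec, "HemodynamicRecording"), inherits(cfg, "preprocess_config"))
  ann <- rec@annotations
  if (is.null(ann) || nrow(ann) == 0) .stopf("recording has no trial annotations")
  rate <- rec@samplingRate
  Tlen <- as.integer(round(cfg$epoch_length_s * rate))
  pad <- as.integer(round(cfg$context_pad_s * rate))
  nTime <- ncol(rec@signal)
  C <- nrow(rec@signal)

  pieces <- list(); labs <- integer(); subs <- character(); trials <- integer()
  for (tr in seq_len(nrow(ann))) {
    durSamp <- as.integer(round(ann$duration_s[tr] * rate))
    nEp <- durSamp %/% Tlen
    rem <- durSamp %% Tlen
    if (nEp == 0L) {
      .warnf("trial %d: task window (%.3gs) shorter than epoch length; no epochs",
             tr, ann$duration_s[tr])
      next
    }
    nCut <- nEp + as.integer(cfg$trailing_partial == "pad" && rem > 0L)
    for (j in seq_len(nCut)) {
      from <- ann$onset[tr] + (j - 1L) * Tlen
      idx <- seq(from - pad, from + Tlen - 1L + pad)
      idx <- pmin(pmax(idx, 1L), nTime)      # edge-replicate out-of-range context
      seg <- rec@signal[, idx, drop = FALSE]
      if (j > nEp) {                          # padded trailing partial
        avail <- rem + 2L * pad
        seg[, seq(avail + 1L, ncol(seg))] <- seg[, avail]
      }
      pieces[[length(pieces) + 1L]] <- seg
      labs <- c(labs, as.integer(ann$label[tr]))
      subs <- c(subs, as.character(ann$subject[tr]))
      trials <- c(trials, tr)
    }
  }
  if (!length(pieces)) {
    .warnf("no epochs produced")
    ep <- array(0, dim = c(0L, C, Tlen + 2L * pad))
    return(EpochSet(ep, integer(), character(), integer(), rate,
                    cfg$epoch_length_s + 2 * cfg$context_pad_s, rec@channelRoles))
  }
  arr <- array(0, dim = c(length(pieces), C, ncol(pieces[[1L]])))
  for (k in seq_along(pieces)) arr[k, , ] <- pieces[[k]]
  EpochSet(arr, labs, subs, trials, rate,
           cfg$epoch_length_s + 2 * cfg$context_pad_s, rec@channelRoles)
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per channel, the mean of the pre-stimulus reference
#' interval of each epoch's parent trial (the
#' \code{cfg$baseline_window_s} seconds immediately before trial onset in
#' \code{rec}).
#'
#' @param ep an \linkS4class{EpochSet} produced by [segmentEpochs()].
#' @param rec the source \linkS4class{HemodynamicRecording}.
#' @param cfg a [preprocessConfig()].
#' @return the corrected \linkS4class{EpochSet}.
#' @export
baselineCorrect <- function(ep, rec, cfg) {
  stopifnot(is(ep, "EpochSet"), is(rec, "HemodynamicRecording"),
            inherits(cfg, "preprocess_config"))
  ann <- rec@annotations
  rate <- rec@samplingRate
  w <- as.integer(round(cfg$baseline_window_s * rate))
  if (w < 1L) .stopf("baseline_window_s too short for the sampling rate")
  bad <- which(ann$onset[unique(ep@trialIndex)] <= w)
  if (length(bad))
    .stopf("insufficient pre-stimulus samples for trial(s): %s",
           paste(unique(ep@trialIndex)[bad], collapse = ", "))
  arr <- ep@epochs
  for (tr in unique(ep@trialIndex)) {
    win <- seq(ann$onset[tr] - w, ann$onset[tr] - 1L)
    mu <- rowMeans(rec@signal[, win, drop = FALSE])
    rows <- which(ep@trialIndex == tr)
    for (k in rows) arr[k, , ] <- arr[k, , ] - mu
  }
  new("EpochSet", epochs = arr, labels = ep@labels, subjects = ep@subjects,
      trialIndex = ep@trialIndex, samplingRate = ep@samplingRate,
      epochLengthS = ep@epochLengthS, channelRoles = ep@channelRoles)
}

#' Standard preprocessing chain
#'
#' Convenience wrapper running resample (optional), filter, segmentation
#' and baseline correction in the conventional order.
#'
#' @param rec a \linkS4class{HemodynamicRecording}.
#' @param cfg a [preprocessConfig()].
#' @param filter apply the filtering stage (default \code{TRUE}).
#' @param baseline apply baseline correction (default \code{TRUE}).
#' @return an \linkS4class{EpochSet}.
#' @export
preprocessRecording <- function(rec, cfg, filter = TRUE, baseline = TRUE) {
  if (!is.null(cfg$target_rate)) rec <- resampleRecording(rec, cfg$target_rate)
  if (filter) rec <- filterSignal(rec, cfg)
  ep <- segmentEpochs(rec, cfg)
  if (baseline) ep <- baselineCorrect(ep, rec, cfg)
  ep
}
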