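## Synthetic hemodynamic data with controllable class-conditional
## inter-channel coupling. Emulates epoched HbO/HbR decoding data:
## boxcar task drives convolved with a double-gamma HRF, latent per-pair
## activations with a class-specific correlation template, physiological
## oscillations, drift and white noise.

#' Simulation configuration
#'
#' @param n_subjects number of simulated subjects.
#' @param n_trials_per_class trials per class per subject.
#' @param n_classes number of task classes K.
#' @param Cp number of optode channel pairs.
#' @param sampling_rate Hz (default 10, the common fNIRS working rate).
#' @param trial_task_s task-execution duration per trial (default 10 s).
#' @param rest_s inter-trial rest (default 15 s).
#' @param epoch_length_s epoch length the data are meant to be cut into.
#' @param hrf_peak_s,hrf_undershoot_s,hrf_ratio double-gamma HRF shape:
#'   response peak, undershoot peak (seconds) and undershoot ratio.
#' @param class_templates list of K \code{Cp x Cp} latent-correlation
#'   templates (symmetric PSD, unit diagonal); \code{NULL} gives
#'   identity templates.
#' @param hbr_coupling per class, length-\code{Cp} HbO-HbR coupling in
#'   \code{[-1, 1]} (magnitude of the within-pair correlation before the
#'   \code{hbr_scale} sign/amplitude is applied); scalar recycled.
#' @param task_amplitude mean neural drive during task (umol/L after
#'   HRF convolution, before noise).
#' @param act_sd standard deviation of the slow (HRF-convolved) latent
#'   activation fluctuations carrying the coupling structure.
#' @param act_fast standard deviation of the fast vasomotor fluctuation
#'   component, drawn from the same class template but not smoothed by
#'   the HRF; this is what keeps the coupling visible inside short
#'   epochs.
#' @param noise_white,noise_drift,noise_mayer,noise_resp,noise_cardiac
#'   amplitudes of measurement white noise, slow linear drift, and
#'   sinusoidal physiological components at ~0.1 Hz (Mayer waves),
#'   ~0.3 Hz (respiration) and ~1 Hz (cardiac; near Nyquist at 10 Hz and
#'   effectively undersampled, as in real recordings).
#' @param hbr_scale amplitude of HbR relative to the HbO signal
#'   (default -0.3: smaller and anti-correlated, the physiological
#'   norm).
#' @param seed integer seed; the dataset is reproducible bit-exactly
#'   from the configuration.
#' @return a validated \code{sim_config} list.
#' @export
simConfig <- function(n_subjects = 2, n_trials_per_class = 10, n_classes = 2,
                      Cp = 10, sampling_rate = 10, trial_task_s = 10,
                      rest_s = 15, epoch_length_s = 1,
                      hrf_peak_s = 6, hrf_undershoot_s = 16, hrf_ratio = 1/6,
                      class_templates = NULL, hbr_coupling = 0.3,
                      task_amplitude = 1, act_sd = 1, act_fast = 1,
                      noise_white = 0.3, noise_drift = 0.1,
                      noise_mayer = 0.2, noise_resp = 0.1,
                      noise_cardiac = 0.05, hbr_scale = -0.3, seed = 1L) {
  if (is.null(class_templates))
    class_templates <- replicate(n_classes, diag(Cp), simplify = FALSE)
  if (length(class_templates) != n_classes)
    .stopf("need one latent-correlation template per class")
  for (k in seq_along(class_templates)) {
    tpl <- class_templates[[k]]
    if (!isTRUE(all.equal(tpl, t(tpl))) || !all(abs(diag(tpl) - 1) < 1e-8))
      .stopf("class template %d must be symmetric with unit diagonal", k)
    if (min(eigen(tpl, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      .stopf("class template %d is not positive semi-definite", k)
  }
  if (is.list(hbr_coupling)) {
    stopifnot(length(hbr_coupling) == n_classes)
    hbr_coupling <- lapply(hbr_coupling, function(x) rep_len(x, Cp))
  } else {
    hbr_coupling <- replicate(n_classes, rep_len(hbr_coupling, Cp),
                              simplify = FALSE)
  }
  if (any(unlist(hbr_coupling) < -1 | unlist(hbr_coupling) > 1))
    .stopf("hbr_coupling must lie in [-1, 1]")
  amps <- c(noise_white, noise_drift, noise_mayer, noise_resp, noise_cardiac)
  if (any(amps < 0)) .stopf("noise amplitudes must be >= 0")
  structure(list(n_subjects = n_subjects,
                 n_trials_per_class = n_trials_per_class,
                 n_classes = n_classes, Cp = Cp,
                 sampling_rate = sampling_rate, trial_task_s = trial_task_s,
                 rest_s = rest_s, epoch_length_s = epoch_length_s,
                 hrf_peak_s = hrf_peak_s, hrf_undershoot_s = hrf_undershoot_s,
                 hrf_ratio = hrf_ratio, class_templates = class_templates,
                 hbr_coupling = hbr_coupling,
                 task_amplitude = task_amplitude, act_sd = act_sd,
                 act_fast = act_fast,
                 noise_white = noise_white, noise_drift = noise_drift,
                 noise_mayer = noise_mayer, noise_resp = noise_resp,
                 noise_cardiac = noise_cardiac, hbr_scale = hbr_scale,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response minus scaled
#' undershoot), peak-normalized to 1, evaluated on a >= 30 s support.
#'
#' @param cfg a [simConfig()] (only the HRF and rate fields are used).
#' @param duration_s kernel support in seconds (default 32).
#' @return numeric kernel sampled at \code{cfg$sampling_rate}.
#' @export
canonicalHrf <- function(cfg = simConfig(), duration_s = 32) {
  t <- seq(0, duration_s, by = 1 / cfg$sampling_rate)
  h <- stats::dgamma(t, shape = cfg$hrf_peak_s + 1, rate = 1) -
    cfg$hrf_ratio * stats::dgamma(t, shape = cfg$hrf_undershoot_s + 1, rate = 1)
  h / max(h)
}

## convolve each column of a matrix with a kernel, keeping length
.convolveCols <- function(x, kernel) {
  apply(x, 2L, function(col)
    stats::convolve(col, rev(kernel), type = "open")[seq_along(col)])
}

## correlated zero-mean draw from a class template (iid across time)
.templateDraw <- function(nSamp, template) {
  eps <- MASS::mvrnorm(nSamp, mu = rep(0, nrow(template)), Sigma = template)
  matrix(eps, nrow = nSamp)
}

## one fluctuation stream for a set of task windows: slow HRF-convolved
## latents plus an unsmoothed fast component, both sharing the class
## template; zero outside task windows
.fluctuationStream <- function(nTime, windows, templates, hrf, act_sd,
                               act_fast, Cp) {
  drive <- matrix(0, nTime, Cp)
  fast <- matrix(0, nTime, Cp)
  for (w in windows) {
    drive[w$idx, ] <- .templateDraw(length(w$idx), templates[[w$class]])
    fast[w$idx, ] <- .templateDraw(length(w$idx), templates[[w$class]])
  }
  ## kernel-energy normalization keeps the convolved stream at sd ~ act_sd
  act_sd * .convolveCols(drive, hrf) / sqrt(sum(hrf^2)) + act_fast * fast
}

#' Simulate one task trial
#'
#' Generates the task-window signals of all channel pairs for one trial
#' of class \code{class_k}: correlated latent activations convolved with
#' the canonical HRF under a boxcar task drive, an HbO series per pair,
#' and an HbR series coupled to it with the configured per-pair
#' correlation and \code{hbr_scale} amplitude. Only white measurement
#' noise is added here; drift and oscillations live at the recording
#' level.
#'
#' @param class_k class index (1-based).
#' @param cfg a [simConfig()].
#' @param T_trial number of samples (default: the configured task
#'   duration).
#' @return array \code{Cp x 2 x T_trial} (second axis: HbO, HbR).
#' @export
simulateTrial <- function(class_k, cfg = simConfig(),
                          T_trial = round(cfg$trial_task_s * cfg$sampling_rate)) {
  hrf <- canonicalHrf(cfg)
  windows <- list(list(idx = seq_len(T_trial), class = class_k))
  gain <- (cfg$amplitude_scale %||% rep(1, cfg$n_classes))[class_k]
  ## kernel-sum normalization: the sustained-task plateau equals amplitude
  trend <- cfg$task_amplitude * gain *
    .convolveCols(matrix(1, T_trial, 1L), hrf)[, 1L] / sum(hrf)
  fl1 <- .fluctuationStream(T_trial, windows, cfg$class_templates, hrf,
                            cfg$act_sd, cfg$act_fast, cfg$Cp)
  fl2 <- .fluctuationStream(T_trial, windows, cfg$class_templates, hrf,
                            cfg$act_sd, cfg$act_fast, cfg$Cp)
  kap <- cfg$hbr_coupling[[class_k]]
  out <- array(0, dim = c(cfg$Cp, 2L, T_trial))
  for (i in seq_len(cfg$Cp)) {
    hbo <- trend + fl1[, i] + cfg$noise_white * stats::rnorm(T_trial)
    mix <- kap[i] * fl1[, i] + sqrt(1 - kap[i]^2) * fl2[, i]
    hbr <- cfg$hbr_scale * (trend + mix) +
      cfg$noise_white * stats::rnorm(T_trial)
    out[i, 1L, ] <- hbo
    out[i, 2L, ] <- hbr
  }
  out
}

## one subject's continuous recording
.simulateSubject <- function(cfg, subject) {
  rate <- cfg$sampling_rate
  taskSamp <- round(cfg$trial_task_s * rate)
  restSamp <- round(cfg$rest_s * rate)
  nTrials <- cfg$n_classes * cfg$n_trials_per_class
  labels <- sample(rep(seq_len(cfg$n_classes) - 1L, cfg$n_trials_per_class))
  nTime <- restSamp + nTrials * (taskSamp + restSamp)
  hrf <- canonicalHrf(cfg)
  Cp <- cfg$Cp

  ## task windows, boxcar drive and fluctuation streams
  windows <- vector("list", nTrials)
  boxcar <- matrix(0, nTime, 1L)
  ampScale <- cfg$amplitude_scale %||% rep(1, cfg$n_classes)
  onsets <- integer(nTrials)
  pos <- restSamp + 1L
  for (tr in seq_len(nTrials)) {
    idx <- pos:(pos + taskSamp - 1L)
    windows[[tr]] <- list(idx = idx, class = labels[tr] + 1L)
    boxcar[idx, 1L] <- ampScale[labels[tr] + 1L]
    onsets[tr] <- pos
    pos <- pos + taskSamp + restSamp
  }
  trend <- cfg$task_amplitude * .convolveCols(boxcar, hrf)[, 1L] / sum(hrf)
  fl1 <- .fluctuationStream(nTime, windows, cfg$class_templates, hrf,
                            cfg$act_sd, cfg$act_fast, Cp)
  fl2 <- .fluctuationStream(nTime, windows, cfg$class_templates, hrf,
                            cfg$act_sd, cfg$act_fast, Cp)

  ## per-sample HbO-HbR coupling follows the active trial's class
  kapProfile <- matrix(cfg$hbr_coupling[[1L]], nTime, Cp, byrow = TRUE)
  for (tr in seq_len(nTrials)) {
    k <- labels[tr] + 1L
    idx <- onsets[tr]:min(nTime, onsets[tr] + taskSamp + restSamp - 1L)
    kapProfile[idx, ] <- matrix(cfg$hbr_coupling[[k]], length(idx), Cp,
                                byrow = TRUE)
  }

  tgrid <- seq_len(nTime) / rate
  sig <- matrix(0, 2L * Cp, nTime)
  for (i in seq_len(Cp)) {
    phys <- cfg$noise_mayer * sin(2 * pi * 0.1 * tgrid + stats::runif(1, 0, 2 * pi)) +
      cfg$noise_resp * sin(2 * pi * 0.3 * tgrid + stats::runif(1, 0, 2 * pi)) +
      cfg$noise_cardiac * sin(2 * pi * 1.0 * tgrid + stats::runif(1, 0, 2 * pi))
    drift <- cfg$noise_drift * stats::rnorm(1) * tgrid / max(tgrid)
    hbo <- trend + fl1[, i] + phys + drift + cfg$noise_white * stats::rnorm(nTime)
    mix <- kapProfile[, i] * fl1[, i] +
      sqrt(1 - kapProfile[, i]^2) * fl2[, i]
    physR <- cfg$noise_mayer * sin(2 * pi * 0.1 * tgrid + stats::runif(1, 0, 2 * pi)) +
      cfg$noise_resp * sin(2 * pi * 0.3 * tgrid + stats::runif(1, 0, 2 * pi))
    driftR <- cfg$noise_drift * stats::rnorm(1) * tgrid / max(tgrid)
    hbr <- cfg$hbr_scale * (trend + mix) + 0.5 * physR + driftR +
      cfg$noise_white * stats::rnorm(nTime)
    sig[2L * i - 1L, ] <- hbo
    sig[2L * i, ] <- hbr
  }
  ann <- data.frame(onset = onsets, duration_s = cfg$trial_task_s,
                    label = labels, subject = subject,
                    stringsAsFactors = FALSE)
  HemodynamicRecording(sig, rate, interleavedRoles(Cp), ann)
}

#' Simulate a multi-subject dataset
#'
#' @param cfg a [simConfig()]. The configured seed makes the result
#'   bit-reproducible.
#' @return list of class \code{simulated_dataset}: \code{recordings}
#'   (one annotated \linkS4class{HemodynamicRecording} per subject) and
#'   the generating \code{config}.
#' @export
simulateDataset <- function(cfg = simConfig()) {
  set.seed(cfg$seed)
  recs <- lapply(seq_len(cfg$n_subjects), function(s)
    .simulateSubject(cfg, sprintf("s%02d", s)))
  names(recs) <- vapply(recs, function(r) r@annotations$subject[1L], character(1))
  structure(list(recordings = recs, config = cfg), class = "simulated_dataset")
}

#' Epoch a simulated dataset
#'
#' Runs the standard preprocessing chain on every subject's recording
#' and concatenates the per-subject epoch sets.
#'
#' @param ds a [simulateDataset()] result.
#' @param pcfg a [preprocessConfig()]; the default keeps the native
#'   rate, applies a light 3 Hz lowpass (denoising near the Nyquist
#'   frequency while keeping the fast vasomotor band that carries the
#'   coupling structure) and baseline-corrects on the 1 s pre-stimulus
#'   interval.
#' @param filter apply the filtering stage.
#' @return an \linkS4class{EpochSet} pooling all subjects.
#' @export
simulatedEpochs <- function(ds,
                            pcfg = preprocessConfig(filter_kind = "lowpass",
                                                    band = 3),
                            filter = TRUE) {
  sets <- lapply(ds$recordings, preprocessRecording, cfg = pcfg, filter = filter)
  bindEpochSets(sets)
}

#' Concatenate epoch sets
#'
#' @param sets list of \linkS4class{EpochSet}s with identical channel
#'   layout, rate and epoch length.
#' @return the pooled \linkS4class{EpochSet}.
#' @export
bindEpochSets <- function(sets) {
  stopifnot(length(sets) >= 1L)
  d <- dim(sets[[1L]]@epochs)
  n <- sum(vapply(sets, nEpochs, integer(1)))
  arr <- array(0, dim = c(n, d[2L], d[3L]))
  labs <- integer(n); subs <- character(n); tri <- integer(n)
  at <- 0L; trOff <- 0L
  for (s in sets) {
    k <- nEpochs(s)
    if (k == 0L) next
    arr[(at + 1L):(at + k), , ] <- s@epochs
    labs[(at + 1L):(at + k)] <- s@labels
    subs[(at + 1L):(at + k)] <- s@subjects
    tri[(at + 1L):(at + k)] <- s@trialIndex + trOff
    at <- at + k
    trOff <- trOff + max(s@trialIndex)
  }
  EpochSet(arr, labs, subs, tri, sets[[1L]]@samplingRate,
           sets[[1L]]@epochLengthS, sets[[1L]]@channelRoles)
}

#' Shuffle labels for a null-control experiment
#'
#' @param ep an \linkS4class{EpochSet}.
#' @param seed permutation seed.
#' @return the epoch set with labels permuted.
#' @export
shuffleLabels <- function(ep, seed = 1L) {
  set.seed(seed)
  new("EpochSet", epochs = ep@epochs, labels = sample(ep@labels),
      subjects = ep@subjects, trialIndex = ep@trialIndex,
      samplingRate = ep@samplingRate, epochLengthS = ep@epochLengthS,
      channelRoles = ep@channelRoles)
}

#' Block-structured latent-correlation templates
#'
#' Convenience builder for class-separable coupling: each class gets a
#' template with correlation \code{rho} inside its own block of pairs
#' and identity elsewhere (disjoint blocks across classes).
#'
#' @param Cp number of pairs.
#' @param n_classes number of classes (blocks partition the pairs).
#' @param rho within-block latent correlation (default 0.8).
#' @return list of \code{Cp x Cp} templates.
#' @export
blockTemplates <- function(Cp, n_classes = 2, rho = 0.8) {
  cut <- split(seq_len(Cp), sort(rep_len(seq_len(n_classes), Cp)))
  lapply(seq_len(n_classes), function(k) {
    tpl <- diag(Cp)
    idx <- cut[[k]]
    tpl[idx, idx] <- rho
    diag(tpl) <- 1
    tpl
  })
}
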