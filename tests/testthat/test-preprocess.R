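test_that("Beer-Lambert inversion recovers known concentrations", {
  E <- defaultExtinction(c(760, 850))
  Tn <- 50
  ## zero optical density -> zero concentration
  rec0 <- OpticalRecording(matrix(0, 2, Tn), c(760, 850), 10, E)
  out0 <- mbllConvert(rec0)
  expect_equal(signalMatrix(out0), matrix(0, 2, Tn))
  expect_equal(channelRoles(out0)$species, c("HbO", "HbR"))

  ## forward-synthesized OD inverts back to the generating pair
  set.seed(7)
  for (r in 1:20) {
    hO <- rnorm(Tn); hR <- rnorm(Tn)
    d <- runif(1, 4, 8); l <- runif(1, 2, 4)
    E2 <- E * runif(1, 0.5, 2)
    od <- (E2 %*% rbind(hO, hR)) * d * l
    rec <- OpticalRecording(od, c(760, 850), 10, E2,
                            pathlengthFactor = d, separation = l)
    got <- signalMatrix(mbllConvert(rec))
    expect_lt(max(abs(got - rbind(hO, hR))) / max(abs(rbind(hO, hR))), 1e-9)
  }
})

test_that("singular extinction coefficients are rejected", {
  Esing <- matrix(c(1, 2, 1, 2), 2, 2)   # equal columns
  expect_error(OpticalRecording(matrix(0, 2, 10), c(760, 850), 10, Esing),
               "singular")
})

test_that("zero-phase filtering has the specified band behaviour", {
  rate <- 10
  t <- seq(0, 1500 - 1 / rate, by = 1 / rate)
  roles <- interleavedRoles(1)
  bp <- preprocessConfig("bandpass", c(0.01, 0.1))
  lp <- preprocessConfig("lowpass", 0.2)

  ## constant through the task bandpass -> zero (DC rejection); the
  ## 0.01 Hz corner makes edge transients decay over minutes, so the
  ## check sits in the middle of a long record
  recC <- HemodynamicRecording(matrix(3, 2, length(t)), rate, roles)
  yC <- signalMatrix(filterSignal(recC, bp))
  mid <- seq(round(0.45 * length(t)), round(0.55 * length(t)))
  expect_lt(max(abs(yC[, mid])), 1e-6)

  ## mid-band tone passes nearly unchanged
  midT <- seq(round(0.2 * length(t)), round(0.8 * length(t)))
  tone <- sin(2 * pi * 0.05 * t)
  recT <- HemodynamicRecording(rbind(tone, tone), rate, roles)
  yT <- signalMatrix(filterSignal(recT, bp))[1, midT]
  expect_lt(abs(1 - sqrt(mean(yT^2)) / sqrt(mean(tone[midT]^2))), 0.10)

  ## constant through the lowpass is preserved
  yL <- signalMatrix(filterSignal(recC, lp))
  expect_lt(max(abs(yL[, midT] - 3)), 1e-6)

  ## 1 Hz tone through the 0.2 Hz lowpass is crushed
  fast <- sin(2 * pi * 1.0 * t)
  recF <- HemodynamicRecording(rbind(fast, fast), rate, roles)
  yF <- signalMatrix(filterSignal(recF, lp))[1, midT]
  expect_lt(sqrt(mean(yF^2)) / sqrt(mean(fast[midT]^2)), 0.05)

  ## filtering is near-idempotent in the passband
  rec2 <- filterSignal(filterSignal(recT, bp), bp)
  y2 <- signalMatrix(rec2)[1, midT]
  y1 <- signalMatrix(filterSignal(recT, bp))[1, midT]
  expect_lt(sqrt(mean((y2 - y1)^2)) / sqrt(mean(y1^2)), 0.02)

  ## edge at/above Nyquist rejected
  expect_error(filterSignal(recC, preprocessConfig("lowpass", 5)), "Nyquist")
})

test_that("resampling scales lengths and onsets proportionally", {
  roles <- interleavedRoles(1)
  ann <- data.frame(onset = 200, duration_s = 2, label = 0, subject = "s1")
  rec <- HemodynamicRecording(matrix(rnorm(2000), 2, 1000), 100, roles, ann)
  out <- resampleRecording(rec, 10)
  expect_equal(ncol(signalMatrix(out)), 100)
  expect_equal(samplingRate(out), 10)
  expect_equal(annotations(out)$onset, 20)

  recC <- HemodynamicRecording(matrix(2.5, 2, 1000), 100, roles, ann)
  outC <- resampleRecording(recC, 10)
  expect_lt(max(abs(signalMatrix(outC)[, 5:95] - 2.5)), 1e-6)

  expect_error(resampleRecording(rec, -1), "targetRate")
  expect_error(resampleRecording(out, 100), "upsampling")
})

test_that("segmentation cuts task windows into labeled epochs", {
  rec <- tinyRecording(nPairs = 2, n_trials = 2, task_s = 10,
                       labels = c(0, 1))
  cfg <- preprocessConfig(epoch_length_s = 1)
  ep <- segmentEpochs(rec, cfg)
  expect_equal(nEpochs(ep), 20)
  expect_equal(dim(epochArray(ep))[3], 10)
  expect_equal(epochLabels(ep), rep(c(0L, 1L), each = 10))
  expect_equal(unique(subjectIds(ep)), "s1")

  ## 3 s epochs under drop: floor(10/3) per trial, 1 s discarded
  ep3 <- segmentEpochs(rec, preprocessConfig(epoch_length_s = 3))
  expect_equal(nEpochs(ep3), 6)
  ## pad policy keeps the trailing partial
  ep3p <- segmentEpochs(rec, preprocessConfig(epoch_length_s = 3,
                                              trailing_partial = "pad"))
  expect_equal(nEpochs(ep3p), 8)

  ## epoch too long for the window warns and yields nothing
  w <- capture_warnings(ep0 <- segmentEpochs(rec,
                                             preprocessConfig(epoch_length_s = 11)))
  expect_true(any(grepl("shorter than epoch", w)))
  expect_equal(nEpochs(ep0), 0)

  ## epoch count identity over random durations under drop
  set.seed(3)
  for (r in 1:5) {
    durs <- sample(3:12, 3, replace = TRUE)
    rate <- 10
    onsets <- cumsum(c(51, (durs[-3] + 5) * rate))
    nTime <- max(onsets) + durs[3] * rate + 50
    ann <- data.frame(onset = onsets, duration_s = durs,
                      label = 0, subject = "s1")
    rec2 <- HemodynamicRecording(matrix(rnorm(2 * nTime), 2, nTime),
                                 rate, interleavedRoles(1), ann)
    lenS <- 2
    ep2 <- segmentEpochs(rec2, preprocessConfig(epoch_length_s = lenS))
    expect_equal(nEpochs(ep2), sum(durs %/% lenS))
  }
})

test_that("baseline correction subtracts the pre-stimulus mean", {
  rate <- 10
  nTime <- 400
  roles <- interleavedRoles(1)
  sig <- matrix(5, 2, nTime)              # constant 5 everywhere
  ann <- data.frame(onset = c(101, 301), duration_s = 5, label = c(0, 1),
                    subject = "s1")
  rec <- HemodynamicRecording(sig, rate, roles, ann)
  cfg <- preprocessConfig(epoch_length_s = 1, baseline_window_s = 1)
  ep <- baselineCorrect(segmentEpochs(rec, cfg), rec, cfg)
  expect_equal(max(abs(epochArray(ep))), 0)   # 5 - 5 everywhere

  ## zero-mean baseline leaves epochs unchanged
  set.seed(9)
  sig2 <- matrix(rnorm(2 * nTime), 2, nTime)
  for (tr in 1:2) {
    win <- (ann$onset[tr] - 10):(ann$onset[tr] - 1)
    sig2[, win] <- sig2[, win] - rowMeans(sig2[, win])
  }
  rec2 <- HemodynamicRecording(sig2, rate, roles, ann)
  epRaw <- segmentEpochs(rec2, cfg)
  epBC <- baselineCorrect(epRaw, rec2, cfg)
  expect_equal(epochArray(epBC), epochArray(epRaw), tolerance = 1e-12)

  ## the mapped reference mean becomes exactly zero per channel
  set.seed(10)
  sig3 <- matrix(rnorm(2 * nTime, mean = 3), 2, nTime)
  rec3 <- HemodynamicRecording(sig3, rate, roles, ann)
  ep3 <- baselineCorrect(segmentEpochs(rec3, cfg), rec3, cfg)
  for (tr in 1:2) {
    win <- (ann$onset[tr] - 10):(ann$onset[tr] - 1)
    mu <- rowMeans(sig3[, win])
    corrected <- sig3[, win] - mu
    expect_lt(max(abs(rowMeans(corrected))), 1e-12)
    ## epochs of that trial were shifted by exactly mu
    k <- which(ep3@trialIndex == tr)[1]
    raw <- segmentEpochs(rec3, cfg)
    expect_equal(epochArray(ep3)[k, , ],
                 epochArray(raw)[k, , ] - mu, tolerance = 1e-12)
  }

  ## insufficient pre-stimulus history is a per-trial error
  annBad <- data.frame(onset = c(5, 301), duration_s = 5, label = c(0, 1),
                       subject = "s1")
  recBad <- HemodynamicRecording(sig3, rate, roles, annBad)
  expect_error(baselineCorrect(segmentEpochs(recBad, cfg), recBad, cfg),
               "insufficient pre-stimulus")
})
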