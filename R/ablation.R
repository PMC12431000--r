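## Ablation harnesses: module knockouts, connectivity-threshold sweep,
## epoch/window-length sweep, and fusion-strategy comparison.

.variantConfig <- function(base, variant) {
  cfg <- base
  switch(variant,
    full = cfg,
    no_graph_features = { cfg$use_graph <- FALSE; cfg$use_gam <- FALSE; cfg },
    no_GAM = { cfg$use_gam <- FALSE; cfg },
    no_BiLSTM = { cfg$use_bilstm <- FALSE; cfg },
    no_GAM_no_BiLSTM = { cfg$use_gam <- FALSE; cfg$use_bilstm <- FALSE; cfg },
    .stopf("unknown ablation variant '%s'", variant))
}

#' Module ablation
#'
#' Trains and scores the network with individual modules knocked out:
#' \code{no_graph_features} zeroes the graph block of the fused vector
#' and removes the connectivity features from the attention (which
#' falls back to uniform); \code{no_GAM} fixes \eqn{\alpha_i = 1/C_p};
#' \code{no_BiLSTM} feeds the mean-pooled pair sequence straight to the
#' classifier.
#'
#' @param ep,features data and graph features.
#' @param train_idx,test_idx split to score on.
#' @param variants subset of \code{c("full", "no_graph_features",
#'   "no_GAM", "no_BiLSTM", "no_GAM_no_BiLSTM")}.
#' @param model_cfg,train_cfg base configurations.
#' @param seeds one or more seeds; metrics are averaged over them.
#' @return data.frame: variant, seed, accuracy, kappa.
#' @export
moduleAblation <- function(ep, features, train_idx, test_idx,
                           variants = c("full", "no_graph_features", "no_GAM",
                                        "no_BiLSTM", "no_GAM_no_BiLSTM"),
                           model_cfg = modelConfig(n_classes = length(unique(epochLabels(ep)))),
                           train_cfg = trainConfig(), seeds = train_cfg$seed) {
  out <- data.frame()
  for (v in variants) {
    cfg <- .variantConfig(model_cfg, v)
    for (s in seeds) {
      tc <- train_cfg; tc$seed <- as.integer(s)
      res <- fitAndScore(ep, features, train_idx, test_idx, cfg, tc)
      out <- rbind(out, data.frame(variant = v, seed = s,
                                   accuracy = res$accuracy,
                                   kappa = as.numeric(res$kappa)))
    }
  }
  out
}

#' Connectivity-threshold sweep
#'
#' Recomputes the whole-head adjacency at each global connection
#' threshold and reports the average functional-connectivity efficiency
#' (AE, percent), optionally with a train/test accuracy at each
#' threshold. Fewer edges can never shorten a path, so AE is
#' non-increasing in the threshold.
#'
#' @param ep an \linkS4class{EpochSet}.
#' @param thresholds thresholds to sweep (default 0.1-0.5).
#' @param with_accuracy also train/score at each threshold (slow).
#' @param train_idx,test_idx,model_cfg,train_cfg used when
#'   \code{with_accuracy} is \code{TRUE}.
#' @param base_cfg feature configuration the sweep modifies.
#' @return data.frame: threshold, AE (and accuracy when requested).
#' @export
thresholdSweep <- function(ep, thresholds = seq(0.1, 0.5, by = 0.1),
                           with_accuracy = FALSE, train_idx = NULL,
                           test_idx = NULL,
                           model_cfg = modelConfig(n_classes = length(unique(epochLabels(ep)))),
                           train_cfg = trainConfig(),
                           base_cfg = featureConfig()) {
  out <- data.frame()
  for (th in thresholds) {
    cfg <- base_cfg
    cfg$adjacency_threshold <- th
    ae <- averageEfficiency(ep, cfg)
    row <- data.frame(threshold = th, AE = ae)
    if (with_accuracy) {
      features <- epochFeatures(ep, cfg)
      res <- fitAndScore(ep, features, train_idx, test_idx, model_cfg, train_cfg)
      row$accuracy <- res$accuracy
    }
    out <- rbind(out, row)
  }
  out
}

#' Epoch/window-length sweep
#'
#' Re-segments a simulated dataset at each epoch length and recomputes
#' the features at each sliding-window length, scoring a train/test
#' split for every combination.
#'
#' @param ds a [simulateDataset()] result.
#' @param grid data.frame with columns \code{T_epoch_s} and \code{L_s}.
#' @param model_cfg,train_cfg model and training setup.
#' @param pcfg base [preprocessConfig()] whose epoch length the sweep
#'   overrides.
#' @param test_fraction held-out fraction per combination.
#' @return data.frame: T_epoch_s, L_s, n_epochs, accuracy.
#' @export
windowSweep <- function(ds, grid = expand.grid(T_epoch_s = c(0.5, 1, 2),
                                               L_s = c(0.5, 1)),
                        model_cfg = NULL, train_cfg = trainConfig(),
                        pcfg = preprocessConfig(filter_kind = "lowpass",
                                                band = 3),
                        test_fraction = 0.25) {
  out <- data.frame()
  for (r in seq_len(nrow(grid))) {
    pc <- pcfg
    pc$epoch_length_s <- grid$T_epoch_s[r]
    ep <- simulatedEpochs(ds, pc)
    fc <- featureConfig(window_length_s = min(grid$L_s[r], grid$T_epoch_s[r]))
    features <- epochFeatures(ep, fc)
    labs <- epochLabels(ep)
    set.seed(train_cfg$seed)
    test_idx <- .stratifiedSplit(labs, test_fraction)
    train_idx <- setdiff(seq_len(nEpochs(ep)), test_idx)
    cfg <- model_cfg %||% modelConfig(n_classes = length(unique(labs)))
    res <- fitAndScore(ep, features, train_idx, test_idx, cfg, train_cfg)
    out <- rbind(out, data.frame(T_epoch_s = grid$T_epoch_s[r],
                                 L_s = grid$L_s[r], n_epochs = nEpochs(ep),
                                 accuracy = res$accuracy))
  }
  out
}

#' Fusion-strategy comparison
#'
#' Scores one split under each feature-fusion strategy (see
#' [fitFusion()]).
#'
#' @param ep,features data and features.
#' @param train_idx,test_idx split to score on.
#' @param strategies strategies to compare.
#' @param model_cfg,train_cfg model and training setup.
#' @param weights block weights for the fixed-weighted strategy.
#' @return data.frame: strategy, accuracy, kappa.
#' @export
fusionSweep <- function(ep, features, train_idx, test_idx,
                        strategies = c("concat", "zscore_concat",
                                       "minmax_concat", "fixed_weighted"),
                        model_cfg = modelConfig(n_classes = length(unique(epochLabels(ep)))),
                        train_cfg = trainConfig(), weights = c(1, 1, 1)) {
  out <- data.frame()
  for (s in strategies) {
    res <- fitAndScore(ep, features, train_idx, test_idx, model_cfg,
                       train_cfg, fusion_strategy = s, fusion_weights = weights)
    out <- rbind(out, data.frame(strategy = s, accuracy = res$accuracy,
                                 kappa = as.numeric(res$kappa)))
  }
  out
}

#' Ablation dispatcher
#'
#' Routes to the four ablation harnesses by kind.
#'
#' @param kind \code{"modules"}, \code{"threshold"}, \code{"window"} or
#'   \code{"fusion"}.
#' @param ... passed to [moduleAblation()], [thresholdSweep()],
#'   [windowSweep()] or [fusionSweep()].
#' @return the harness's results table.
#' @export
runAblation <- function(kind = c("modules", "threshold", "window", "fusion"),
                        ...) {
  kind <- match.arg(kind)
  switch(kind,
         modules = moduleAblation(...),
         threshold = thresholdSweep(...),
         window = windowSweep(...),
         fusion = fusionSweep(...))
}
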