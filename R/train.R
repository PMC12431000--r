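## Training loop (Adam + plateau scheduler), cross-validation fold
## construction, and the fit/score helper shared by the evaluation and
## ablation harnesses.

#' Training configuration
#'
#' @param lr Adam learning rate (default 1e-3).
#' @param weight_decay L2 penalty added to the gradient (default 1e-4).
#' @param batch_size minibatch size (default 5).
#' @param max_epochs training epoch cap (default 200).
#' @param scheduler_factor learning-rate multiplier applied when
#'   validation accuracy plateaus (default 0.5).
#' @param scheduler_patience plateau length in epochs before the
#'   learning rate is reduced (default 10).
#' @param val_fraction inner validation split carved from the training
#'   indices for the scheduler and checkpoint selection (default 0.2).
#' @param seed RNG seed covering initialization, shuffling and dropout.
#' @param n_folds folds for subject-specific cross-validation.
#' @param checkpoint which parameters the fit returns:
#'   \code{"final"} (default; the last epoch's parameters, after the
#'   learning-rate schedule has annealed) or \code{"best_val"} (the
#'   best-validation-accuracy epoch, ties broken by validation loss).
#' @param stop_at_train_acc optional early exit once training accuracy
#'   (percent) reaches this value; \code{NULL} (default) trains to
#'   \code{max_epochs}. Intended for memorization checks, not tuning.
#' @return a validated \code{train_config} list.
#' @export
trainConfig <- function(lr = 1e-3, weight_decay = 1e-4, batch_size = 5,
                        max_epochs = 200, scheduler_factor = 0.5,
                        scheduler_patience = 10, val_fraction = 0.2,
                        seed = 1L, n_folds = 5,
                        checkpoint = c("final", "best_val"),
                        stop_at_train_acc = NULL) {
  if (batch_size < 1 || max_epochs < 1) .stopf("batch_size and max_epochs must be >= 1")
  checkpoint <- match.arg(checkpoint)
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 scheduler_factor = scheduler_factor,
                 scheduler_patience = as.integer(scheduler_patience),
                 val_fraction = val_fraction, seed = as.integer(seed),
                 n_folds = as.integer(n_folds), checkpoint = checkpoint,
                 stop_at_train_acc = stop_at_train_acc),
            class = "train_config")
}

## map a function over matching leaves of nested parameter trees
.treeMap <- function(f, a, b = NULL, c = NULL) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (k in seq_along(a))
      out[[k]] <- .treeMap(f, a[[k]], if (!is.null(b)) b[[k]],
                           if (!is.null(c)) c[[k]])
    out
  } else {
    f(a, b, c)
  }
}

#' Adam optimizer state
#' @param params model parameter tree.
#' @return list with first/second moment trees and step counter.
#' @export
adamInit <- function(params) {
  list(m = .treeMap(function(p, ...) p * 0, params),
       v = .treeMap(function(p, ...) p * 0, params), t = 0L)
}

#' One Adam update
#'
#' Decoupled-from-nothing classic Adam: the weight-decay term is added
#' to the gradient before the moment updates.
#'
#' @param params,grads,state parameter/gradient trees and [adamInit()]
#'   state.
#' @param lr,beta1,beta2,eps,weight_decay optimizer hyperparameters.
#' @return list(params, state).
#' @export
adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  tt <- state$t
  state$m <- .treeMap(function(m, g, p) beta1 * m + (1 - beta1) * (g + weight_decay * p),
                      state$m, grads, params)
  state$v <- .treeMap(function(v, g, p) beta2 * v + (1 - beta2) * (g + weight_decay * p)^2,
                      state$v, grads, params)
  bc1 <- 1 - beta1^tt; bc2 <- 1 - beta2^tt
  params <- .treeMap(function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
                     params, state$m, state$v)
  list(params = params, state = state)
}

## stratified index split, deterministic under the current RNG stream
.stratifiedSplit <- function(labels, fraction) {
  hold <- integer(0)
  for (k in unique(labels)) {
    idx <- which(labels == k)
    nh <- max(1L, round(length(idx) * fraction))
    hold <- c(hold, sample(idx, nh))
  }
  sort(hold)
}

#' Subject-specific stratified k-fold partitions
#'
#' Within each subject, epochs of every class are dealt round-robin
#' into k folds after a seeded shuffle: folds are stratified, disjoint
#' and exhaustive per subject.
#'
#' @param ep an \linkS4class{EpochSet}.
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @return list of folds, each \code{list(subject, train, test)} with
#'   global epoch indices (train and test both within the subject).
#' @export
makeSubjectFolds <- function(ep, k = 5, seed = 1L) {
  set.seed(seed)
  labs <- epochLabels(ep); subs <- subjectIds(ep)
  folds <- list()
  for (s in unique(subs)) {
    assign <- integer(sum(subs == s))
    names(assign) <- which(subs == s)
    for (cl in unique(labs)) {
      idx <- which(subs == s & labs == cl)
      if (length(idx) < k)
        .stopf("subject %s has only %d epochs of class %d (< %d folds)",
               s, length(idx), cl, k)
      idx <- sample(idx)
      assign[as.character(idx)] <- rep_len(seq_len(k), length(idx))
    }
    for (f in seq_len(k)) {
      test <- as.integer(names(assign)[assign == f])
      train <- as.integer(names(assign)[assign != f])
      folds[[length(folds) + 1L]] <- list(subject = s, train = sort(train),
                                          test = sort(test))
    }
  }
  folds
}

#' Leave-one-subject-out partitions
#'
#' @param ep an \linkS4class{EpochSet}.
#' @return list of folds, each \code{list(subject, train, test)}; the
#'   test subject never appears in the training indices.
#' @export
makeLosoFolds <- function(ep) {
  subs <- subjectIds(ep)
  u <- unique(subs)
  if (length(u) < 2L) .stopf("leave-one-subject-out needs at least 2 subjects")
  lapply(u, function(s)
    list(subject = s, train = which(subs != s), test = which(subs == s)))
}

#' Train the network on a set of epochs
#'
#' Adam with weight decay, minibatch shuffling, and an inner
#' stratified validation split driving a reduce-on-plateau
#' learning-rate schedule. The returned parameters are the final
#' epoch's by default, or the best-validation-accuracy checkpoint when
#' \code{train_cfg$checkpoint = "best_val"}. Fully deterministic under
#' \code{train_cfg$seed}.
#'
#' @param ep an \linkS4class{EpochSet}.
#' @param features [epochFeatures()] for \code{ep}.
#' @param train_idx epoch indices to train on.
#' @param model_cfg a [modelConfig()].
#' @param train_cfg a [trainConfig()].
#' @param fusion_strategy fusion strategy for the raw/graph feature
#'   blocks (see [fitFusion()]).
#' @param fusion_weights block weights for the fixed-weighted strategy.
#' @return list: \code{model} (per the checkpoint policy),
#'   \code{fusion}, \code{history} (per-epoch train loss, validation
#'   accuracy and loss, learning rate), \code{best_epoch}, and
#'   \code{stopped_epoch} when \code{stop_at_train_acc} fired.
#' @export
trainModel <- function(ep, features, train_idx = seq_len(nEpochs(ep)),
                       model_cfg = modelConfig(n_classes = length(unique(epochLabels(ep)))),
                       train_cfg = trainConfig(),
                       fusion_strategy = "concat", fusion_weights = c(1, 1, 1)) {
  set.seed(train_cfg$seed)
  labs <- epochLabels(ep)
  d <- dim(ep@epochs)
  Cp <- nPairs(ep)
  D <- d[2L] * d[3L] + 3L * Cp + 1L

  ## inner validation split for scheduler + checkpoint selection
  val_local <- .stratifiedSplit(labs[train_idx], train_cfg$val_fraction)
  val_idx <- train_idx[val_local]
  fit_idx <- setdiff(train_idx, val_idx)

  fusion <- fitFusion(features$f3[fit_idx, , drop = FALSE], fusion_strategy,
                      C = d[2L], T_len = d[3L], Cp = Cp,
                      weights = fusion_weights)
  f3 <- applyFusion(features$f3, fusion)

  model <- initModel(model_cfg, Cp, d[3L], D, seed = train_cfg$seed)
  state <- adamInit(model$params)
  lr <- train_cfg$lr
  bestAcc <- -Inf; bestLoss <- Inf
  bestParams <- model$params; bestEpoch <- 0L
  sinceImprove <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_acc = numeric(), val_loss = numeric(),
                     lr = numeric())

  nb <- length(fit_idx)
  for (epoch in seq_len(train_cfg$max_epochs)) {
    ord <- sample(fit_idx)
    losses <- numeric(0)
    for (at in seq(1L, nb, by = train_cfg$batch_size)) {
      idx <- ord[at:min(nb, at + train_cfg$batch_size - 1L)]
      batch <- list(X = ep@epochs[idx, , , drop = FALSE],
                    f3 = f3[idx, , drop = FALSE],
                    pf = features$pairFeatures[idx, , , drop = FALSE])
      fwd <- modelForward(model, batch, ep@channelRoles, train = TRUE)
      loss <- crossEntropy(fwd$probs, labs[idx])
      if (!is.finite(loss))
        .stopf("non-finite loss at epoch %d (lr %.3g); aborting", epoch, lr)
      losses <- c(losses, loss)
      grads <- modelBackward(model, fwd$cache, labs[idx])
      upd <- adamStep(model$params, grads, state, lr,
                      weight_decay = train_cfg$weight_decay)
      model$params <- upd$params
      state <- upd$state
    }
    ## validation metrics in eval mode; checkpoint = best accuracy,
    ## accuracy ties broken by lower validation cross-entropy
    valProbs <- .forwardIndices(model, ep, f3, features, val_idx)
    valAcc <- 100 * mean(max.col(valProbs) - 1L == labs[val_idx])
    valLoss <- crossEntropy(valProbs, labs[val_idx])
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = mean(losses),
                                   val_acc = valAcc, val_loss = valLoss,
                                   lr = lr))
    better <- valAcc > bestAcc + 1e-9 ||
      (valAcc > bestAcc - 1e-9 && valLoss < bestLoss - 1e-12)
    if (better) {
      bestParams <- model$params; bestEpoch <- epoch; bestLoss <- valLoss
    }
    if (valAcc > bestAcc + 1e-9) {
      bestAcc <- valAcc
      sinceImprove <- 0L
    } else {
      sinceImprove <- sinceImprove + 1L
      if (sinceImprove >= train_cfg$scheduler_patience) {
        lr <- lr * train_cfg$scheduler_factor
        sinceImprove <- 0L
      }
    }
    if (!is.null(train_cfg$stop_at_train_acc)) {
      trProbs <- .forwardIndices(model, ep, f3, features, train_idx)
      trAcc <- 100 * mean(max.col(trProbs) - 1L == labs[train_idx])
      hist$train_acc[nrow(hist)] <- trAcc
      if (trAcc >= train_cfg$stop_at_train_acc) {
        ## memorization mode: the current (memorizing) parameters are
        ## the result of interest
        bestParams <- model$params
        stoppedEpoch <- epoch
        break
      }
    }
  }
  stopped <- exists("stoppedEpoch", inherits = FALSE)
  if (identical(train_cfg$checkpoint, "best_val") || stopped)
    model$params <- bestParams
  list(model = model, fusion = fusion, history = hist,
       best_epoch = bestEpoch,
       stopped_epoch = if (stopped) stoppedEpoch)
}

.forwardIndices <- function(model, ep, f3, features, idx, batch_size = 64L) {
  out <- matrix(0, length(idx), model$config$n_classes)
  for (at in seq(1L, length(idx), by = batch_size)) {
    sel <- idx[at:min(length(idx), at + batch_size - 1L)]
    batch <- list(X = ep@epochs[sel, , , drop = FALSE],
                  f3 = f3[sel, , drop = FALSE],
                  pf = features$pairFeatures[sel, , , drop = FALSE])
    out[at:(at + length(sel) - 1L), ] <-
      modelForward(model, batch, ep@channelRoles)$probs
  }
  out
}

#' Fit, score and report on one train/test split
#'
#' @param ep,features data and its graph features.
#' @param train_idx,test_idx disjoint epoch indices.
#' @param model_cfg,train_cfg,fusion_strategy,fusion_weights passed to
#'   [trainModel()].
#' @return list: \code{fit} (the [trainModel()] result), \code{probs},
#'   \code{pred}, \code{confusion}, \code{accuracy}, \code{kappa},
#'   \code{auc} (macro one-vs-rest), \code{n_test}.
#' @export
fitAndScore <- function(ep, features, train_idx, test_idx,
                        model_cfg = modelConfig(n_classes = length(unique(epochLabels(ep)))),
                        train_cfg = trainConfig(),
                        fusion_strategy = "concat", fusion_weights = c(1, 1, 1)) {
  fit <- trainModel(ep, features, train_idx, model_cfg, train_cfg,
                    fusion_strategy, fusion_weights)
  f3 <- applyFusion(features$f3, fit$fusion)
  probs <- .forwardIndices(fit$model, ep, f3, features, test_idx)
  labs <- epochLabels(ep)[test_idx]
  pred <- max.col(probs) - 1L
  cm <- confusionCounts(labs, pred, model_cfg$n_classes)
  roc <- rocAuc(probs, labs)
  list(fit = fit, probs = probs, pred = pred, confusion = cm,
       accuracy = accuracyFromConfusion(cm), kappa = cohenKappa(cm),
       auc = roc$macro_auc, n_test = length(test_idx))
}

#' Cross-validated evaluation
#'
#' Runs [fitAndScore()] over a list of folds and aggregates per-fold
#' metrics into an evaluation report.
#'
#' @param ep,features data and features.
#' @param folds from [makeSubjectFolds()] or [makeLosoFolds()].
#' @param model_cfg,train_cfg,fusion_strategy model and training setup.
#'   Each fold derives its own child seed from \code{train_cfg$seed}.
#' @param verbose print per-fold progress.
#' @return list of class \code{eval_report}: \code{per_fold}
#'   data.frame, pooled \code{confusion}, aggregate \code{accuracy}
#'   (mean of fold accuracies), \code{accuracy_sd}, \code{kappa} (from
#'   the pooled confusion), \code{macro_auc} (mean over folds),
#'   \code{pooled} (labels/pred/probs across folds).
#' @export
crossValidate <- function(ep, features, folds,
                          model_cfg = modelConfig(n_classes = length(unique(epochLabels(ep)))),
                          train_cfg = trainConfig(),
                          fusion_strategy = "concat", verbose = FALSE) {
  K <- model_cfg$n_classes
  per <- data.frame()
  cmTot <- matrix(0, K, K)
  labsAll <- integer(0); predAll <- integer(0)
  probsAll <- matrix(numeric(0), ncol = K)
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    tc <- train_cfg
    tc$seed <- .childSeed(train_cfg$seed, f)
    res <- fitAndScore(ep, features, fold$train, fold$test, model_cfg, tc,
                       fusion_strategy)
    per <- rbind(per, data.frame(fold = f, subject = fold$subject,
                                 accuracy = res$accuracy,
                                 kappa = as.numeric(res$kappa),
                                 auc = res$auc, n_test = res$n_test))
    cmTot <- cmTot + res$confusion
    labsAll <- c(labsAll, epochLabels(ep)[fold$test])
    predAll <- c(predAll, res$pred)
    probsAll <- rbind(probsAll, res$probs)
    if (verbose)
      message(sprintf("fold %d/%d (%s): acc %.1f%%", f, length(folds),
                      fold$subject, res$accuracy))
  }
  structure(list(per_fold = per, confusion = cmTot,
                 accuracy = mean(per$accuracy),
                 accuracy_sd = stats::sd(per$accuracy),
                 kappa = cohenKappa(cmTot),
                 macro_auc = mean(per$auc, na.rm = TRUE),
                 pooled = list(labels = labsAll, pred = predAll,
                               probs = probsAll)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("cross-validated evaluation over %d folds\n", nrow(x$per_fold)))
  cat(sprintf("  accuracy %.2f%% (sd %.2f), kappa %.3f, macro AUC %.3f\n",
              x$accuracy, x$accuracy_sd, as.numeric(x$kappa), x$macro_auc))
  invisible(x)
}
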