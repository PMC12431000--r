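## Graph-theoretic connectivity features: per-pair local metrics,
## whole-head thresholded adjacency, global efficiency and the fused
## feature vector.

#' Feature-extraction configuration
#'
#' @param density_threshold correlation threshold inside the
#'   sliding-window connection density (default 0.3).
#' @param adjacency_threshold correlation threshold for the whole-head
#'   adjacency (default 0.3).
#' @param window_length_s sliding-window length L in seconds
#'   (default 1).
#' @param epsilon stabilizer in the reciprocal mean-difference feature
#'   (default 1e-6).
#' @param thresholds_signed if \code{TRUE} (default) the thresholds act
#'   on signed correlations, as defined; set \code{FALSE} to threshold
#'   \code{|rho|} instead (escape hatch for strongly anti-correlated
#'   HbO/HbR pairs).
#' @return a validated \code{feature_config} list.
#' @export
featureConfig <- function(density_threshold = 0.3, adjacency_threshold = 0.3,
                          window_length_s = 1, epsilon = 1e-6,
                          thresholds_signed = TRUE) {
  if (abs(density_threshold) >= 1 || abs(adjacency_threshold) >= 1)
    .stopf("thresholds must lie in (-1, 1)")
  if (!.isPositiveScalar(window_length_s)) .stopf("window_length_s must be > 0")
  if (!.isPositiveScalar(epsilon)) .stopf("epsilon must be > 0")
  structure(list(density_threshold = density_threshold,
                 adjacency_threshold = adjacency_threshold,
                 window_length_s = window_length_s, epsilon = epsilon,
                 thresholds_signed = isTRUE(thresholds_signed)),
            class = "feature_config")
}

#' Pearson correlation with degenerate-variance handling
#'
#' Product-moment correlation of two equal-length series. If either
#' series has zero variance the correlation is undefined; it is returned
#' as 0 with attribute \code{degenerate = TRUE} so that downstream
#' threshold counts never see \code{NaN}.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in \code{[-1, 1]}, possibly with a
#'   \code{degenerate} attribute.
#' @export
pearsonCorr <- function(x, y) {
  if (length(x) != length(y)) .stopf("series lengths differ (%d vs %d)", length(x), length(y))
  if (length(x) < 2L) .stopf("need at least 2 samples")
  xc <- x - mean(x); yc <- y - mean(y)
  vx <- sum(xc^2); vy <- sum(yc^2)
  if (vx == 0 || vy == 0) return(structure(0, degenerate = TRUE))
  sum(xc * yc) / sqrt(vx * vy)
}

#' Connection strength of a channel pair
#'
#' Normalized Pearson correlation \eqn{s = (\rho + 1)/2 \in [0, 1]} of
#' the HbO and HbR series of one optode.
#'
#' @param x,y the two series of the pair.
#' @return strength in \code{[0, 1]} (degenerate flag propagated).
#' @export
connectionStrength <- function(x, y) {
  rho <- pearsonCorr(x, y)
  structure((as.numeric(rho) + 1) / 2, degenerate = attr(rho, "degenerate"))
}

#' Sliding-window connection density
#'
#' Fraction of length-L windows (stride 1) in which the within-pair
#' correlation exceeds the significance threshold:
#' \deqn{Sd = \frac{1}{T-L+1} \sum_k 1[\rho_k > \theta].}
#'
#' @param x,y the two series of the pair.
#' @param cfg a [featureConfig()].
#' @return density in \code{[0, 1]}.
#' @export
connectionDensity <- function(x, y, cfg = featureConfig()) {
  Tn <- length(x)
  if (length(y) != Tn) .stopf("series lengths differ (%d vs %d)", Tn, length(y))
  L <- .densityWindowSamples(cfg, Tn)
  nW <- Tn - L + 1L
  hits <- 0L
  for (k in seq_len(nW)) {
    idx <- k:(k + L - 1L)
    rho <- as.numeric(pearsonCorr(x[idx], y[idx]))
    if (!cfg$thresholds_signed) rho <- abs(rho)
    if (rho > cfg$density_threshold) hits <- hits + 1L
  }
  hits / nW
}

## window length in samples for a series of length Tn; the config stores
## seconds, converted with the sampling rate when one is attached.
.densityWindowSamples <- function(cfg, Tn, rate = attr(cfg, "rate")) {
  L <- if (!is.null(rate)) as.integer(round(cfg$window_length_s * rate)) else Tn
  L <- min(L, Tn)
  if (L < 2L) .stopf("density window must span at least 2 samples (got %d)", L)
  L
}

#' Reciprocal of functional signal mean difference
#'
#' \deqn{RFSMD = 1 / (\mathrm{mean}_t |x(t) - y(t)| + \epsilon),} a
#' similarity-based proxy for information-transfer efficiency between
#' the two series of a pair. Bounded above by \code{1/epsilon}.
#'
#' @param x,y the two series of the pair.
#' @param cfg a [featureConfig()].
#' @return positive scalar.
#' @export
rfsmd <- function(x, y, cfg = featureConfig()) {
  if (length(x) != length(y)) .stopf("series lengths differ")
  1 / (mean(abs(x - y)) + cfg$epsilon)
}

#' Thresholded whole-head connectivity adjacency
#'
#' Binary symmetric adjacency over all C rows of an epoch (HbO and HbR
#' channels alike): an edge joins channels whose Pearson correlation
#' exceeds the global connection threshold.
#'
#' @param epoch \code{C x T} numeric matrix.
#' @param cfg a [featureConfig()].
#' @return \code{C x C} binary matrix, zero diagonal.
#' @export
buildAdjacency <- function(epoch, cfg = featureConfig()) {
  C <- nrow(epoch)
  if (C < 2L) .stopf("need at least 2 channels")
  sds <- apply(epoch, 1L, stats::sd)
  R <- matrix(0, C, C)
  ok <- sds > 0
  if (sum(ok) >= 2L)
    R[ok, ok] <- suppressWarnings(stats::cor(t(epoch[ok, , drop = FALSE])))
  if (!cfg$thresholds_signed) R <- abs(R)
  A <- (R > cfg$adjacency_threshold) * 1
  diag(A) <- 0
  A[is.na(A)] <- 0
  A
}

#' Global efficiency of a binary graph
#'
#' Mean inverse shortest-path length over all ordered node pairs,
#' \deqn{e = \frac{1}{C(C-1)} \sum_{c_1 \ne c_2} 1/d(c_1, c_2),} with
#' disconnected pairs contributing 0. Distances are unweighted
#' shortest-path lengths.
#'
#' @param A binary symmetric adjacency with zero diagonal.
#' @return efficiency in \code{[0, 1]}.
#' @export
globalEfficiency <- function(A) {
  C <- nrow(A)
  if (is.null(C) || C < 2L) .stopf("need at least 2 nodes")
  g <- igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected")
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (C * (C - 1))
}

#' All graph-derived features of one epoch
#'
#' Computes the per-pair local features (strength, density, RFSMD), the
#' thresholded adjacency with its global efficiency, and the fused
#' feature vector \code{f3 = [f1; f2; e]} where \code{f1} is the
#' column-stacked raw epoch and \code{f2} interleaves
#' \code{(s_i, Sd_i, RFSMD_i)} per pair.
#'
#' @param epoch \code{C x T} matrix with interleaved \code{(HbO, HbR)}
#'   rows per pair (see [interleavedRoles()]).
#' @param cfg a [featureConfig()].
#' @param roles optional channel-role table; defaults to interleaved.
#' @return list with elements \code{pair} (data.frame s, Sd, RFSMD per
#'   pair), \code{adjacency}, \code{efficiency}, \code{f1}, \code{f2},
#'   \code{f3}, \code{degenerate} (logical per pair).
#' @export
assembleFeatures <- function(epoch, cfg = featureConfig(), roles = NULL) {
  C <- nrow(epoch); Tn <- ncol(epoch)
  if (is.null(roles)) roles <- interleavedRoles(C / 2L)
  Cp <- C / 2L
  s <- Sd <- rf <- numeric(Cp); degen <- logical(Cp)
  for (i in seq_len(Cp)) {
    xo <- epoch[which(roles$pair == i & roles$species == "HbO"), ]
    xr <- epoch[which(roles$pair == i & roles$species == "HbR"), ]
    si <- connectionStrength(xo, xr)
    degen[i] <- isTRUE(attr(si, "degenerate"))
    s[i] <- as.numeric(si)
    Sd[i] <- connectionDensity(xo, xr, cfg)
    rf[i] <- rfsmd(xo, xr, cfg)
  }
  A <- buildAdjacency(epoch, cfg)
  e <- globalEfficiency(A)
  f1 <- as.vector(epoch)                 # column-wise stack of the C x T matrix
  f2 <- as.vector(rbind(s, Sd, rf))      # (s_1, Sd_1, RFSMD_1, s_2, ...)
  list(pair = data.frame(pair = seq_len(Cp), s = s, Sd = Sd, RFSMD = rf),
       adjacency = A, efficiency = e, f1 = f1, f2 = f2,
       f3 = c(f1, f2, e), degenerate = degen)
}

#' Graph features for every epoch of a set
#'
#' @param ep an \linkS4class{EpochSet}.
#' @param cfg a [featureConfig()]; the epoch sampling rate is attached
#'   so the density window length in seconds is honoured.
#' @return list with \code{pairFeatures} (\code{N x Cp x 3} array,
#'   features ordered s, Sd, RFSMD), \code{efficiency} (length N),
#'   \code{f3} (\code{N x D} matrix) and the \code{config} used.
#' @export
epochFeatures <- function(ep, cfg = featureConfig()) {
  stopifnot(is(ep, "EpochSet"))
  attr(cfg, "rate") <- samplingRate(ep)
  n <- nEpochs(ep); Cp <- nPairs(ep)
  d <- dim(ep@epochs)
  D <- d[2L] * d[3L] + 3L * Cp + 1L
  pf <- array(0, dim = c(n, Cp, 3L),
              dimnames = list(NULL, NULL, c("s", "Sd", "RFSMD")))
  eff <- numeric(n)
  f3 <- matrix(0, n, D)
  for (k in seq_len(n)) {
    feats <- assembleFeatures(ep@epochs[k, , ], cfg, ep@channelRoles)
    pf[k, , ] <- as.matrix(feats$pair[, c("s", "Sd", "RFSMD")])
    eff[k] <- feats$efficiency
    f3[k, ] <- feats$f3
  }
  list(pairFeatures = pf, efficiency = eff, f3 = f3, config = cfg)
}

#' Average functional-connectivity efficiency of an epoch set
#'
#' 100 x the mean global efficiency over epochs; the quantity swept by
#' the connectivity-threshold ablation.
#'
#' @param ep an \linkS4class{EpochSet}.
#' @param cfg a [featureConfig()].
#' @return percentage in \code{[0, 100]}.
#' @export
averageEfficiency <- function(ep, cfg = featureConfig()) {
  stopifnot(is(ep, "EpochSet"))
  if (nEpochs(ep) < 1L) .stopf("empty epoch set")
  e <- vapply(seq_len(nEpochs(ep)), function(k)
    globalEfficiency(buildAdjacency(ep@epochs[k, , ], cfg)), numeric(1))
  100 * mean(e)
}

#' Write per-pair feature tables
#'
#' @param ep an \linkS4class{EpochSet}.
#' @param features result of [epochFeatures()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (pair-feature CSV and per-epoch
#'   efficiency CSV).
#' @export
writeFeatureTables <- function(ep, features, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nEpochs(ep); Cp <- nPairs(ep)
  long <- data.frame(
    epoch_id = rep(seq_len(n), each = Cp),
    subject = rep(subjectIds(ep), each = Cp),
    label = rep(epochLabels(ep), each = Cp),
    pair_id = rep(seq_len(Cp), n),
    s = as.vector(t(features$pairFeatures[, , "s"])),
    Sd = as.vector(t(features$pairFeatures[, , "Sd"])),
    RFSMD = as.vector(t(features$pairFeatures[, , "RFSMD"])))
  p1 <- file.path(dir, "pair_features.csv")
  utils::write.csv(long, p1, row.names = FALSE)
  p2 <- file.path(dir, "global_efficiency.csv")
  utils::write.csv(data.frame(epoch_id = seq_len(n),
                              subject = subjectIds(ep),
                              label = epochLabels(ep),
                              efficiency = features$efficiency),
                   p2, row.names = FALSE)
  invisible(c(p1, p2))
}
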