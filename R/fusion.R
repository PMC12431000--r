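## Fusion strategies for the three blocks of the fused feature vector
## f3 = [f1 (raw epoch); f2 (pair features); e (efficiency)]: plain
## concatenation (default), per-dimension z-score or min-max scaling
## fitted on the training set, or fixed block weights.

#' Fit a fusion transform
#'
#' @param f3_train \code{n x D} training fused-feature matrix.
#' @param strategy \code{"concat"}, \code{"zscore_concat"},
#'   \code{"minmax_concat"} or \code{"fixed_weighted"}.
#' @param C,T_len,Cp data dimensions defining the block boundaries.
#' @param weights length-3 block weights for \code{"fixed_weighted"}
#'   (f1, f2, e); \code{c(1, 1, 1)} reproduces plain concatenation.
#' @return a \code{fusion_transform} (or \code{NULL} for plain
#'   concatenation).
#' @export
fitFusion <- function(f3_train,
                      strategy = c("concat", "zscore_concat",
                                   "minmax_concat", "fixed_weighted"),
                      C, T_len, Cp, weights = c(1, 1, 1)) {
  strategy <- match.arg(strategy)
  if (strategy == "concat") return(NULL)
  D <- C * T_len + 3L * Cp + 1L
  stopifnot(ncol(f3_train) == D)
  out <- list(strategy = strategy, D = D,
              blocks = list(f1 = seq_len(C * T_len),
                            f2 = C * T_len + seq_len(3L * Cp),
                            e = D))
  if (strategy == "zscore_concat") {
    out$center <- colMeans(f3_train)
    s <- apply(f3_train, 2L, stats::sd)
    out$scale <- ifelse(s > 0, s, 1)
  } else if (strategy == "minmax_concat") {
    lo <- apply(f3_train, 2L, min)
    hi <- apply(f3_train, 2L, max)
    out$lo <- lo
    out$range <- ifelse(hi > lo, hi - lo, 1)
  } else {
    stopifnot(length(weights) == 3L)
    out$weights <- weights
  }
  structure(out, class = "fusion_transform")
}

#' Apply a fusion transform
#'
#' @param f3 \code{n x D} fused-feature matrix.
#' @param fusion a [fitFusion()] result (\code{NULL} = identity).
#' @return transformed matrix of the same shape.
#' @export
applyFusion <- function(f3, fusion = NULL) {
  if (is.null(fusion)) return(f3)
  switch(fusion$strategy,
    zscore_concat = sweep(sweep(f3, 2L, fusion$center), 2L, fusion$scale, `/`),
    minmax_concat = sweep(sweep(f3, 2L, fusion$lo), 2L, fusion$range, `/`),
    fixed_weighted = {
      out <- f3
      out[, fusion$blocks$f1] <- out[, fusion$blocks$f1] * fusion$weights[1L]
      out[, fusion$blocks$f2] <- out[, fusion$blocks$f2] * fusion$weights[2L]
      out[, fusion$blocks$e] <- out[, fusion$blocks$e] * fusion$weights[3L]
      out
    })
}
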