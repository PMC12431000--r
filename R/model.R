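## The topology-enhanced temporal network. All tensors are plain R
## matrices; batches are stacked along rows. Weight matrices are stored
## as (out x in) and applied as X %*% t(W) + b. The forward pass caches
## every intermediate needed by the hand-written backward pass in
## backprop.R.

#' Model configuration
#'
#' @param d_model Transformer/projection feature dimension (default 64;
#'   must be divisible by \code{n_heads}).
#' @param n_heads self-attention heads (default 4).
#' @param n_encoder_layers encoder depth (default 1, a single standard
#'   Transformer layer).
#' @param ffn_dim encoder feed-forward width (default 128).
#' @param lstm_hidden LSTM hidden size h per direction (default 64).
#' @param mlp_hidden classifier hidden width m (default 128).
#' @param n_classes number of classes K.
#' @param dropout_temporal dropout after the fused-feature projection
#'   (default 0.1, training only).
#' @param dropout_mlp dropout in the intermediate MLP layer
#'   (default 0.2, training only).
#' @param alpha_mode how the graph-attention weights enter the LSTM gate
#'   input: \code{"scalar_per_step"} (default; the step's own weight
#'   \eqn{\alpha_i}) or \code{"full_vector"} (the whole \eqn{\alpha}).
#' @param hidden_readout Bi-LSTM readout: \code{"last"} (default;
#'   concatenated final hidden states) or \code{"mean"} (mean over
#'   steps).
#' @param use_graph include the graph-feature block of the fused vector
#'   (ablation switch; when \code{FALSE}, \code{f2} and \code{e} are
#'   zeroed and the attention falls back to uniform).
#' @param use_gam learnable graph attention (\code{FALSE} fixes
#'   \eqn{\alpha_i = 1/C_p}).
#' @param use_bilstm run the Bi-LSTM (\code{FALSE} feeds the mean-pooled
#'   pair sequence directly to the classifier).
#' @return a validated \code{model_config} list.
#' @export
modelConfig <- function(d_model = 64, n_heads = 4, n_encoder_layers = 1,
                        ffn_dim = 128, lstm_hidden = 64, mlp_hidden = 128,
                        n_classes = 2, dropout_temporal = 0.1,
                        dropout_mlp = 0.2,
                        alpha_mode = c("scalar_per_step", "full_vector"),
                        hidden_readout = c("last", "mean"),
                        use_graph = TRUE, use_gam = TRUE, use_bilstm = TRUE) {
  alpha_mode <- match.arg(alpha_mode)
  hidden_readout <- match.arg(hidden_readout)
  dims <- c(d_model, n_heads, n_encoder_layers, ffn_dim, lstm_hidden,
            mlp_hidden, n_classes)
  if (any(dims < 1) || any(dims != round(dims)))
    .stopf("all model dimensions must be positive integers")
  if (d_model %% n_heads != 0L) .stopf("d_model must be divisible by n_heads")
  structure(list(d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 n_encoder_layers = as.integer(n_encoder_layers),
                 ffn_dim = as.integer(ffn_dim),
                 lstm_hidden = as.integer(lstm_hidden),
                 mlp_hidden = as.integer(mlp_hidden),
                 n_classes = as.integer(n_classes),
                 dropout_temporal = dropout_temporal,
                 dropout_mlp = dropout_mlp, alpha_mode = alpha_mode,
                 hidden_readout = hidden_readout,
                 use_graph = isTRUE(use_graph), use_gam = isTRUE(use_gam),
                 use_bilstm = isTRUE(use_bilstm)),
            class = "model_config")
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.rowSoftmax <- function(x) {
  x <- x - x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x)
  e / rowSums(e)
}

## Xavier-uniform initialization for projections
.xavier <- function(nout, nin) {
  b <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nout * nin, -b, b), nout, nin)
}

## uniform fan-in initialization for LSTM gates (1/sqrt(h))
.gateInit <- function(nout, nin, h) {
  b <- 1 / sqrt(h)
  matrix(stats::runif(nout * nin, -b, b), nout, nin)
}

#' Sinusoidal positional encoding
#'
#' @param T_len sequence length.
#' @param d feature dimension.
#' @return \code{T_len x d} matrix.
#' @export
positionalEncoding <- function(T_len, d) {
  pos <- seq_len(T_len) - 1
  i <- seq_len(d) - 1
  angle <- outer(pos, 1 / 10000^((i %/% 2) * 2 / d))
  pe <- matrix(0, T_len, d)
  even <- which(i %% 2 == 0)
  pe[, even] <- sin(angle[, even, drop = FALSE])
  if (length(even) < d) {
    odd <- which(i %% 2 == 1)
    pe[, odd] <- cos(angle[, odd, drop = FALSE])
  }
  pe
}

## gate-input width for the LSTM
.lstmInDim <- function(cfg, Cp) {
  2L * cfg$d_model + cfg$lstm_hidden +
    if (cfg$alpha_mode == "scalar_per_step") 1L else Cp
}

#' Initialize model parameters
#'
#' Every learnable tensor of the network, shaped for the given data
#' dimensions. Projections use Xavier-uniform initialization, LSTM gate
#' blocks uniform fan-in; all draws come from the supplied seed.
#'
#' @param cfg a [modelConfig()].
#' @param Cp number of channel pairs.
#' @param T_len samples per epoch.
#' @param D fused-feature dimension (\code{2 Cp T_len + 3 Cp + 1}).
#' @param seed RNG seed.
#' @return object of class \code{topotemp_model}: \code{config},
#'   \code{dims} and the named parameter list \code{params}.
#' @export
initModel <- function(cfg, Cp, T_len, D = 2L * Cp * T_len + 3L * Cp + 1L,
                      seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  set.seed(seed)
  d <- cfg$d_model; Fd <- cfg$ffn_dim; h <- cfg$lstm_hidden
  m <- cfg$mlp_hidden; K <- cfg$n_classes
  inL <- .lstmInDim(cfg, Cp)
  clsIn <- D + if (cfg$use_bilstm) 2L * h else 2L * d
  enc <- lapply(seq_len(cfg$n_encoder_layers), function(l) list(
    Wq = .xavier(d, d), bq = numeric(d),
    Wk = .xavier(d, d), bk = numeric(d),
    Wv = .xavier(d, d), bv = numeric(d),
    Wo = .xavier(d, d), bo = numeric(d),
    ln1_g = rep(1, d), ln1_b = numeric(d),
    Wf1 = .xavier(Fd, d), bf1 = numeric(Fd),
    Wf2 = .xavier(d, Fd), bf2 = numeric(d),
    ln2_g = rep(1, d), ln2_b = numeric(d)))
  params <- list(
    Wp = .xavier(d, 2L), bp = numeric(d),
    enc = enc,
    Ww = .xavier(d, D), bw = numeric(d),
    Walpha = .xavier(1L, 3L),
    lstm_f = list(W = .gateInit(4L * h, inL, h), b = numeric(4L * h)),
    lstm_b = list(W = .gateInit(4L * h, inL, h), b = numeric(4L * h)),
    W1 = .xavier(m, clsIn), b1 = numeric(m),
    W2 = .xavier(K, m), b2 = numeric(K))
  structure(list(config = cfg, params = params,
                 dims = list(Cp = Cp, T_len = as.integer(T_len),
                             D = as.integer(D), seed = as.integer(seed))),
            class = "topotemp_model")
}

#' @export
print.topotemp_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(rapply(x$params, length, how = "unlist"), sum, numeric(1)))
  cat(sprintf(paste0("topology-enhanced temporal network: Cp=%d, T=%d, D=%d\n",
                     "  d_model=%d heads=%d ffn=%d lstm=%d mlp=%d classes=%d",
                     " (%d parameters)\n"),
              x$dims$Cp, x$dims$T_len, x$dims$D, cfg$d_model, cfg$n_heads,
              cfg$ffn_dim, cfg$lstm_hidden, cfg$mlp_hidden, cfg$n_classes,
              as.integer(np)))
  invisible(x)
}

## ------------------------------------------------------------------ ##
## forward-pass building blocks (each returns output + cache)

.layerNorm <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv                        # inv recycles down columns: per-row scale
  list(y = sweep(xhat, 2L, g, `*`) + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

## key-position gather indices: row (s, t) attends to rows (s, j)
.attnIndex <- function(nSeq, T_len) {
  base <- rep((seq_len(nSeq) - 1L) * T_len, each = T_len)
  lapply(seq_len(T_len), function(j) base + j)
}

## multi-head self-attention over nSeq contiguous blocks of T rows,
## vectorized across all sequences via gather indices
.selfAttention <- function(Z, layer, nSeq, T_len, H) {
  d <- ncol(Z); hd <- d %/% H
  N <- nrow(Z)
  Q <- tcrossprod(Z, layer$Wq) + rep(layer$bq, each = N)
  K <- tcrossprod(Z, layer$Wk) + rep(layer$bk, each = N)
  V <- tcrossprod(Z, layer$Wv) + rep(layer$bv, each = N)
  jdx <- .attnIndex(nSeq, T_len)
  O <- matrix(0, N, d)
  Acache <- vector("list", H)
  for (hh in seq_len(H)) {
    cols <- ((hh - 1L) * hd + 1L):(hh * hd)
    Qh <- Q[, cols, drop = FALSE]
    Kh <- K[, cols, drop = FALSE]
    Vh <- V[, cols, drop = FALSE]
    S <- matrix(0, N, T_len)
    for (j in seq_len(T_len))
      S[, j] <- rowSums(Qh * Kh[jdx[[j]], , drop = FALSE]) / sqrt(hd)
    A <- .rowSoftmax(S)
    Acache[[hh]] <- A
    Oh <- matrix(0, N, hd)
    for (j in seq_len(T_len))
      Oh <- Oh + A[, j] * Vh[jdx[[j]], , drop = FALSE]
    O[, cols] <- Oh
  }
  Oproj <- tcrossprod(O, layer$Wo) + rep(layer$bo, each = N)
  list(out = Oproj, Q = Q, K = K, V = V, O = O, A = Acache, jdx = jdx)
}

.encoderLayer <- function(Z, layer, nSeq, T_len, H) {
  att <- .selfAttention(Z, layer, nSeq, T_len, H)
  res1 <- Z + att$out
  ln1 <- .layerNorm(res1, layer$ln1_g, layer$ln1_b)
  Hpre <- tcrossprod(ln1$y, layer$Wf1) + rep(layer$bf1, each = nrow(Z))
  Hact <- pmax(Hpre, 0)
  ffn <- tcrossprod(Hact, layer$Wf2) + rep(layer$bf2, each = nrow(Z))
  res2 <- ln1$y + ffn
  ln2 <- .layerNorm(res2, layer$ln2_g, layer$ln2_b)
  list(out = ln2$y, att = att, Zin = Z, ln1 = ln1, ln2 = ln2,
       Hpre = Hpre, Hact = Hact, y1 = ln1$y)
}

## one LSTM direction over the pair sequence; E is a list of B x 2d
## matrices per step, alphaIn a list of the per-step alpha gate input
.lstmDirection <- function(E, alphaIn, W, b, h, order) {
  B <- nrow(E[[1L]])
  hp <- matrix(0, B, h); cp <- matrix(0, B, h)
  steps <- vector("list", length(order))
  hs <- vector("list", length(order))
  for (j in seq_along(order)) {
    i <- order[j]
    U <- cbind(hp, E[[i]], alphaIn[[i]])
    Zg <- tcrossprod(U, W) + rep(b, each = B)
    g <- .sigmoid(Zg[, seq_len(h), drop = FALSE])
    ii <- .sigmoid(Zg[, h + seq_len(h), drop = FALSE])
    cc <- tanh(Zg[, 2L * h + seq_len(h), drop = FALSE])
    o <- .sigmoid(Zg[, 3L * h + seq_len(h), drop = FALSE])
    cn <- g * cp + ii * cc
    tc <- tanh(cn)
    hn <- o * tc
    steps[[j]] <- list(U = U, g = g, i = ii, cc = cc, o = o,
                       c_prev = cp, c = cn, tc = tc)
    hs[[j]] <- hn
    hp <- hn; cp <- cn
  }
  list(h_last = hp, steps = steps, hs = hs)
}

#' Attention-modulated LSTM cell
#'
#' One gated update with the graph-attention weight appended to the
#' gate input \code{[h_prev, E_i, alpha_i]}: forget gate
#' \eqn{g = \sigma(W_g u + b_f)}, input gate
#' \eqn{i = \sigma(W_i u + b_i)}, candidate
#' \eqn{\tilde c = \tanh(W_c u + b_c)}, state
#' \eqn{c = g \odot c_{prev} + i \odot \tilde c}, output gate
#' \eqn{o = \sigma(W_o u + b_o)}, hidden \eqn{h = o \odot \tanh(c)}.
#'
#' @param h_prev,c_prev previous hidden / cell state (length h).
#' @param E_i fused pair representation at this step (length 2d).
#' @param alpha_i attention weight(s) entering the gate input.
#' @param W stacked gate weights \code{4h x (h + 2d + length(alpha_i))},
#'   rows ordered (forget, input, candidate, output).
#' @param b stacked gate biases \code{(b_f, b_i, b_c, b_o)}.
#' @return list with the new \code{h} and \code{c}.
#' @export
attentionLstmCell <- function(h_prev, c_prev, E_i, alpha_i, W, b) {
  if (!all(is.finite(c(h_prev, c_prev, E_i, alpha_i))))
    .stopf("non-finite LSTM input")
  h <- length(h_prev)
  u <- c(h_prev, E_i, alpha_i)
  z <- as.numeric(W %*% u) + b
  g <- .sigmoid(z[seq_len(h)])
  i <- .sigmoid(z[h + seq_len(h)])
  cc <- tanh(z[2 * h + seq_len(h)])
  o <- .sigmoid(z[3 * h + seq_len(h)])
  c_new <- g * c_prev + i * cc
  list(h = o * tanh(c_new), c = c_new)
}

#' Graph attention weights
#'
#' Softmax over channel pairs of a learned linear map of the local
#' connectivity features \code{(s, Sd, RFSMD)}.
#'
#' @param pairFeats \code{Cp x 3} matrix (or \code{B x Cp x 3} array)
#'   of per-pair features.
#' @param Walpha \code{1 x 3} weight matrix.
#' @return attention weights on the simplex, \code{Cp} vector (or
#'   \code{B x Cp} matrix).
#' @export
graphAttention <- function(pairFeats, Walpha) {
  if (length(dim(pairFeats)) == 3L) {
    B <- dim(pairFeats)[1L]; Cp <- dim(pairFeats)[2L]
    pf <- matrix(pairFeats, B * Cp, 3L)
    lg <- matrix(pf %*% t(Walpha), B, Cp)
    .rowSoftmax(lg)
  } else {
    lg <- as.numeric(as.matrix(pairFeats) %*% t(Walpha))
    as.numeric(.rowSoftmax(matrix(lg, 1L)))
  }
}

## assemble the (HbO, HbR) projection input matrix for a batch:
## rows ordered t fastest, then pair, then sample
.pairInputMatrix <- function(X, roles) {
  Cp <- nrow(roles) / 2L
  hboIdx <- vapply(seq_len(Cp), function(i)
    which(roles$pair == i & roles$species == "HbO"), integer(1))
  hbrIdx <- vapply(seq_len(Cp), function(i)
    which(roles$pair == i & roles$species == "HbR"), integer(1))
  hbo <- X[, hboIdx, , drop = FALSE]
  hbr <- X[, hbrIdx, , drop = FALSE]
  cbind(as.vector(aperm(hbo, c(3L, 2L, 1L))),
        as.vector(aperm(hbr, c(3L, 2L, 1L))))
}

#' Full forward pass
#'
#' Runs an epoch batch through input projection, positional encoding,
#' Transformer encoding, temporal pooling, fused-feature projection,
#' graph attention, the attention-modulated Bi-LSTM and the classifier
#' head. Deterministic in evaluation mode; dropout is active only with
#' \code{train = TRUE}.
#'
#' @param model a [initModel()] object.
#' @param batch list with \code{X} (\code{B x C x T} array), \code{f3}
#'   (\code{B x D}), \code{pf} (\code{B x Cp x 3}) and optionally
#'   \code{labels}.
#' @param roles channel-role table for the epochs.
#' @param train training mode (enables dropout; requires a seeded RNG).
#' @return list with \code{probs} (\code{B x K}), \code{alpha}
#'   (\code{B x Cp}) and the \code{cache} consumed by
#'   [modelBackward()].
#' @export
modelForward <- function(model, batch, roles = interleavedRoles(model$dims$Cp),
                         train = FALSE) {
  cfg <- model$config; p <- model$params
  Cp <- model$dims$Cp; T_len <- model$dims$T_len
  d <- cfg$d_model; h <- cfg$lstm_hidden
  B <- dim(batch$X)[1L]
  nSeq <- B * Cp
  f3 <- batch$f3
  if (!cfg$use_graph) {                  # zero the graph block (f2 and e)
    f3 <- f3
    f3[, (model$dims$D - 3L * Cp):model$dims$D] <- 0
  }

  M <- .pairInputMatrix(batch$X, roles)
  Z0 <- tcrossprod(M, p$Wp) + rep(p$bp, each = nrow(M))
  pe <- positionalEncoding(T_len, d)
  Z <- Z0 + pe[rep(seq_len(T_len), nSeq), , drop = FALSE]

  encCaches <- vector("list", length(p$enc))
  for (l in seq_along(p$enc)) {
    encCaches[[l]] <- .encoderLayer(Z, p$enc[[l]], nSeq, T_len, cfg$n_heads)
    Z <- encCaches[[l]]$out
  }
  grp <- rep(seq_len(nSeq), each = T_len)
  Fmat <- rowsum(Z, grp) / T_len
  dimnames(Fmat) <- NULL          # (B*Cp) x d, pair fastest in b blocks? see below

  fproj <- tcrossprod(f3, p$Ww) + rep(p$bw, each = B)
  dropT <- NULL
  if (train && cfg$dropout_temporal > 0) {
    dropT <- matrix(stats::rbinom(length(fproj), 1L, 1 - cfg$dropout_temporal) /
                      (1 - cfg$dropout_temporal), nrow(fproj), ncol(fproj))
    fproj <- fproj * dropT
  }

  ## E per step: rows of Fmat for pair i are at (b-1)*Cp + i
  E <- vector("list", Cp)
  for (i in seq_len(Cp)) {
    Fi <- Fmat[(seq_len(B) - 1L) * Cp + i, , drop = FALSE]
    E[[i]] <- cbind(Fi, fproj)
  }

  if (cfg$use_gam && cfg$use_graph) {
    alpha <- graphAttention(batch$pf, p$Walpha)
    if (B == 1L) alpha <- matrix(alpha, 1L)
  } else {
    alpha <- matrix(1 / Cp, B, Cp)
  }
  alphaIn <- vector("list", Cp)
  for (i in seq_len(Cp)) {
    alphaIn[[i]] <- if (cfg$alpha_mode == "scalar_per_step")
      alpha[, i, drop = FALSE] else alpha
  }

  lstmF <- lstmB <- NULL
  if (cfg$use_bilstm) {
    lstmF <- .lstmDirection(E, alphaIn, p$lstm_f$W, p$lstm_f$b, h, seq_len(Cp))
    lstmB <- .lstmDirection(E, alphaIn, p$lstm_b$W, p$lstm_b$b, h, rev(seq_len(Cp)))
    if (cfg$hidden_readout == "last") {
      hcat <- cbind(lstmF$h_last, lstmB$h_last)
    } else {
      hcat <- cbind(Reduce(`+`, lstmF$hs) / Cp, Reduce(`+`, lstmB$hs) / Cp)
    }
  } else {
    hcat <- Reduce(`+`, E) / Cp           # mean-pooled pair sequence
  }

  clsIn <- cbind(f3, hcat)
  z1 <- tcrossprod(clsIn, p$W1) + rep(p$b1, each = B)
  a1 <- pmax(z1, 0)
  dropM <- NULL
  if (train && cfg$dropout_mlp > 0) {
    dropM <- matrix(stats::rbinom(length(a1), 1L, 1 - cfg$dropout_mlp) /
                      (1 - cfg$dropout_mlp), nrow(a1), ncol(a1))
    a1 <- a1 * dropM
  }
  logits <- tcrossprod(a1, p$W2) + rep(p$b2, each = B)
  probs <- .rowSoftmax(logits)

  cache <- list(M = M, Z0pe = Z0, enc = encCaches, Fmat = Fmat, f3 = f3,
                fproj = fproj, dropT = dropT, E = E, alpha = alpha,
                alphaIn = alphaIn, pf = batch$pf, lstmF = lstmF,
                lstmB = lstmB, hcat = hcat, clsIn = clsIn, z1 = z1,
                a1 = a1, dropM = dropM, probs = probs, B = B,
                nSeq = nSeq, train = train)
  list(probs = probs, alpha = alpha, cache = cache)
}

#' Cross-entropy loss
#'
#' @param probs \code{B x K} class probabilities.
#' @param labels integer labels in \code{0..K-1}.
#' @return mean negative log-likelihood.
#' @export
crossEntropy <- function(probs, labels) {
  B <- nrow(probs)
  -mean(log(pmax(probs[cbind(seq_len(B), labels + 1L)], 1e-12)))
}

#' Predict class probabilities for an epoch set
#'
#' @param model a trained \code{topotemp_model}.
#' @param ep an \linkS4class{EpochSet}.
#' @param features matching [epochFeatures()] output (computed if
#'   missing).
#' @param fusion optional fusion transform from [fitFusion()].
#' @param batch_size evaluation batch size.
#' @return \code{N x K} probability matrix.
#' @export
predictModel <- function(model, ep, features = NULL, fusion = NULL,
                         batch_size = 64L) {
  if (is.null(features)) features <- epochFeatures(ep)
  f3 <- applyFusion(features$f3, fusion)
  n <- nEpochs(ep)
  K <- model$config$n_classes
  out <- matrix(0, n, K)
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(n, at + batch_size - 1L)
    batch <- list(X = ep@epochs[idx, , , drop = FALSE],
                  f3 = f3[idx, , drop = FALSE],
                  pf = features$pairFeatures[idx, , , drop = FALSE])
    out[idx, ] <- modelForward(model, batch, ep@channelRoles)$probs
  }
  out
}
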