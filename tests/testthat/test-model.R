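test_that("input projection and positional encoding behave linearly", {
  tb <- tinyModelBatch()
  m <- tb$model
  ## zero weights and bias: the projected sequence is exactly the
  ## positional encoding
  m$params$Wp <- m$params$Wp * 0
  m$params$bp <- m$params$bp * 0
  M <- topofnirs:::.pairInputMatrix(tb$batch$X, interleavedRoles(tb$Cp))
  Z0 <- tcrossprod(M, m$params$Wp)
  expect_equal(Z0, matrix(0, nrow(M), ncol(Z0)))

  ## selector row: first feature equals the HbO series
  Wp <- matrix(0, 8, 2); Wp[1, 1] <- 1
  Z <- tcrossprod(M, Wp)
  expect_equal(Z[, 1], M[, 1])

  ## random case against an explicit loop oracle
  set.seed(3)
  Wp2 <- matrix(rnorm(16), 8, 2); bp2 <- rnorm(8)
  Zfast <- tcrossprod(M, Wp2) + rep(bp2, each = nrow(M))
  for (r in sample(nrow(M), 5))
    expect_equal(Zfast[r, ], as.numeric(Wp2 %*% M[r, ] + bp2),
                 tolerance = 1e-12)

  pe <- positionalEncoding(10, 8)
  expect_equal(dim(pe), c(10, 8))
  expect_true(all(abs(pe) <= 1))
})

test_that("transformer encoding shares weights across pairs and normalizes attention", {
  tb <- tinyModelBatch(B = 2, Cp = 3, T_len = 6)
  ## duplicate one pair's series into another pair
  X <- tb$batch$X
  X[, 3:4, ] <- X[, 1:2, ]
  batch <- tb$batch; batch$X <- X
  fwd <- modelForward(tb$model, batch, interleavedRoles(3))
  expect_equal(dim(fwd$cache$Fmat), c(2 * 3, tb$model$config$d_model))
  ## pairs 1 and 2 of each sample encode identically (weight sharing)
  expect_equal(fwd$cache$Fmat[1, ], fwd$cache$Fmat[2, ], tolerance = 1e-10)
  expect_equal(fwd$cache$Fmat[4, ], fwd$cache$Fmat[5, ], tolerance = 1e-10)

  ## attention rows lie on the simplex
  for (A in fwd$cache$enc[[1]]$att$A) {
    expect_true(all(A >= 0))
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-9)
  }

  ## temporal pooling is the plain time average
  grp <- rep(seq_len(2 * 3), each = 6)
  Z1 <- fwd$cache$enc[[1]]$out
  expect_equal(fwd$cache$Fmat, rowsum(Z1, grp) / 6, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("graph attention is a softmax over pairs of a learned map", {
  ## identical features -> uniform weights
  pf <- matrix(0.4, 5, 3)
  expect_equal(graphAttention(pf, matrix(rnorm(3), 1)), rep(1 / 5, 5))
  ## single pair -> weight 1
  expect_equal(graphAttention(matrix(runif(3), 1), matrix(rnorm(3), 1)), 1)
  ## logit difference log(3) -> 1:3 odds
  Wa <- matrix(c(1, 0, 0), 1)
  pf2 <- rbind(c(0, 9, 9), c(log(3), 9, 9))
  expect_equal(graphAttention(pf2, Wa), c(0.25, 0.75))
  ## simplex for random inputs, batched
  set.seed(4)
  a <- graphAttention(array(rnorm(60), dim = c(4, 5, 3)), matrix(rnorm(3), 1))
  expect_equal(rowSums(a), rep(1, 4))
  expect_true(all(a > 0))
})

test_that("the attention-modulated LSTM cell matches its closed forms and oracle", {
  h <- 4; d2 <- 6
  W0 <- matrix(0, 4 * h, h + d2 + 1); b0 <- numeric(4 * h)
  ## zero parameters, zero state: everything collapses to zero
  r0 <- attentionLstmCell(numeric(h), numeric(h), rnorm(d2), 0.5, W0, b0)
  expect_equal(r0$h, numeric(h))
  expect_equal(r0$c, numeric(h))
  ## zero parameters, c_prev = 2: c = 1, h = 0.5 * tanh(1)
  r2 <- attentionLstmCell(numeric(h), rep(2, h), rnorm(d2), 0.5, W0, b0)
  expect_equal(r2$c, rep(1, h))
  expect_equal(r2$h, rep(0.5 * tanh(1), h), tolerance = 1e-12)

  set.seed(11)
  for (r in 1:50) {
    W <- matrix(rnorm(4 * h * (h + d2 + 1)), 4 * h)
    b <- rnorm(4 * h)
    hp <- rnorm(h); cp <- rnorm(h); E <- rnorm(d2); a <- runif(1)
    got <- attentionLstmCell(hp, cp, E, a, W, b)
    want <- lstmCellOracle(hp, cp, E, a, W, b)
    expect_equal(got$h, want$h, tolerance = 1e-6)
    expect_equal(got$c, want$c, tolerance = 1e-6)
  }
  expect_error(attentionLstmCell(c(NA, 1), c(0, 0), rnorm(d2), 1, W0[, 1:9], b0),
               "non-finite")
})

test_that("the bidirectional pass is direction-symmetric", {
  tb <- tinyModelBatch(B = 3, Cp = 4)
  m <- tb$model
  ## shared direction weights + single pair: both halves agree
  tb1 <- tinyModelBatch(B = 3, Cp = 1, seed = 9)
  m1 <- tb1$model
  m1$params$lstm_b <- m1$params$lstm_f
  fwd1 <- modelForward(m1, tb1$batch, interleavedRoles(1))
  h <- m1$config$lstm_hidden
  expect_equal(fwd1$cache$hcat[, 1:h], fwd1$cache$hcat[, h + 1:h],
               tolerance = 1e-12)

  ## reversing the pair order and swapping direction parameters swaps
  ## the forward/backward halves
  fwd <- modelForward(m, tb$batch, interleavedRoles(4))
  mRev <- m
  mRev$params$lstm_f <- m$params$lstm_b
  mRev$params$lstm_b <- m$params$lstm_f
  rev_idx <- 4:1
  chRev <- as.vector(rbind(2 * rev_idx - 1, 2 * rev_idx))
  batchRev <- tb$batch
  batchRev$X <- tb$batch$X[, chRev, , drop = FALSE]
  batchRev$pf <- tb$batch$pf[, rev_idx, , drop = FALSE]
  fwdRev <- modelForward(mRev, batchRev, interleavedRoles(4))
  h <- m$config$lstm_hidden
  expect_equal(fwdRev$cache$hcat[, 1:h], fwd$cache$hcat[, h + 1:h],
               tolerance = 1e-9)
  expect_equal(fwdRev$cache$hcat[, h + 1:h], fwd$cache$hcat[, 1:h],
               tolerance = 1e-9)
})

test_that("classification head produces calibrated simplex outputs", {
  tb <- tinyModelBatch()
  m <- tb$model
  ## zero output layer -> uniform class probabilities
  m$params$W2 <- m$params$W2 * 0
  m$params$b2 <- m$params$b2 * 0
  fwd <- modelForward(m, tb$batch)
  expect_equal(fwd$probs, matrix(1 / 3, 4, 3), ignore_attr = TRUE)

  fwd2 <- modelForward(tb$model, tb$batch)
  expect_equal(rowSums(fwd2$probs), rep(1, 4), tolerance = 1e-7)
  expect_true(all(fwd2$probs > 0))
  expect_true(is.finite(crossEntropy(fwd2$probs, tb$labels)))
})

test_that("forward is deterministic, batch-consistent and permutation-aware", {
  tb <- tinyModelBatch(B = 8, Cp = 3, T_len = 5)
  f1 <- modelForward(tb$model, tb$batch)
  f2 <- modelForward(tb$model, tb$batch)
  expect_identical(f1$probs, f2$probs)

  ## batch of 8 equals 8 single-sample passes
  for (b in 1:8) {
    single <- list(X = tb$batch$X[b, , , drop = FALSE],
                   f3 = tb$batch$f3[b, , drop = FALSE],
                   pf = tb$batch$pf[b, , , drop = FALSE])
    fs <- modelForward(tb$model, single)
    expect_equal(as.numeric(fs$probs), f1$probs[b, ], tolerance = 1e-5)
  }

  ## pre-LSTM stages are pair-equivariant; the full network is
  ## order-sensitive by design
  perm <- c(2, 3, 1)
  chPerm <- as.vector(rbind(2 * perm - 1, 2 * perm))
  bp <- tb$batch
  bp$X <- tb$batch$X[, chPerm, , drop = FALSE]
  bp$pf <- tb$batch$pf[, perm, , drop = FALSE]
  fp <- modelForward(tb$model, bp)
  ## alpha permutes with the pairs
  expect_equal(fp$alpha, f1$alpha[, perm], tolerance = 1e-10)
  ## pooled encodings permute with the pairs (rows are (b-1)*Cp + i)
  for (b in 1:2) for (i in 1:3)
    expect_equal(fp$cache$Fmat[(b - 1) * 3 + i, ],
                 f1$cache$Fmat[(b - 1) * 3 + perm[i], ], tolerance = 1e-9)
  ## but the classifier output differs for generic parameters
  expect_gt(max(abs(fp$probs - f1$probs)), 1e-6)
})

test_that("analytic gradients match finite differences across parameter groups", {
  tb <- tinyModelBatch()
  model <- tb$model; batch <- tb$batch; labels <- tb$labels
  fwd <- modelForward(model, batch)
  grads <- modelBackward(model, fwd$cache, labels)

  lossAt <- function(params) {
    m2 <- model; m2$params <- params
    crossEntropy(modelForward(m2, batch)$probs, labels)
  }
  leafPaths <- function(x, prefix = integer()) {
    if (is.list(x)) {
      out <- list()
      for (k in seq_along(x)) out <- c(out, leafPaths(x[[k]], c(prefix, k)))
      out
    } else list(prefix)
  }
  getL <- function(x, p) { for (k in p) x <- x[[k]]; x }
  setL <- function(x, p, v) {
    if (length(p) == 1) { x[[p]] <- v; return(x) }
    x[[p[1]]] <- setL(x[[p[1]]], p[-1], v); x
  }
  eps <- 1e-6
  set.seed(99)
  for (pth in leafPaths(model$params)) {
    w <- getL(model$params, pth)
    gw <- getL(grads, pth)
    for (j in sample(length(w), min(2, length(w)))) {
      wp <- w; wp[j] <- wp[j] + eps
      wm <- w; wm[j] <- wm[j] - eps
      num <- (lossAt(setL(model$params, pth, wp)) -
                lossAt(setL(model$params, pth, wm))) / (2 * eps)
      expect_equal(gw[j], num, tolerance = 1e-4,
                   label = paste("grad at", paste(pth, collapse = ".")))
    }
  }

  ## every parameter group receives gradient signal on a random batch;
  ## the key-projection bias is the one structural exception (attention
  ## softmax is invariant to constant key shifts)
  bkPath <- c(3L, 1L, 4L)                 # params$enc[[1]]$bk
  for (pth in leafPaths(model$params)) {
    g <- getL(grads, pth)
    if (identical(as.integer(pth), bkPath)) {
      expect_lt(max(abs(g)), 1e-12)       # bk: structurally zero
    } else {
      expect_gt(max(abs(g)), 0,
                label = paste("group", paste(pth, collapse = ".")))
    }
  }
})

test_that("gradients flow correctly in the reduced model variants", {
  for (cfgMod in list(modelConfig(d_model = 8, n_heads = 2, ffn_dim = 12,
                                  lstm_hidden = 5, mlp_hidden = 7,
                                  n_classes = 2, use_bilstm = FALSE),
                      modelConfig(d_model = 8, n_heads = 2, ffn_dim = 12,
                                  lstm_hidden = 5, mlp_hidden = 7,
                                  n_classes = 2, use_gam = FALSE),
                      modelConfig(d_model = 8, n_heads = 2, ffn_dim = 12,
                                  lstm_hidden = 5, mlp_hidden = 7,
                                  n_classes = 2,
                                  alpha_mode = "full_vector"),
                      modelConfig(d_model = 8, n_heads = 2, ffn_dim = 12,
                                  lstm_hidden = 5, mlp_hidden = 7,
                                  n_classes = 2,
                                  hidden_readout = "mean"))) {
    tb <- tinyModelBatch(B = 3, Cp = 3, T_len = 5, K = 2, cfg = cfgMod)
    fwd <- modelForward(tb$model, tb$batch)
    grads <- modelBackward(tb$model, fwd$cache, tb$labels)
    lossAt <- function(params) {
      m2 <- tb$model; m2$params <- params
      crossEntropy(modelForward(m2, tb$batch)$probs, tb$labels)
    }
    ## spot-check three scalars in distinct groups
    for (probe in list(c("W1", 5), c("Ww", 3), c("Wp", 2))) {
      p <- tb$model$params
      j <- as.integer(probe[2])
      eps <- 1e-6
      p1 <- p; p1[[probe[1]]][j] <- p1[[probe[1]]][j] + eps
      p2 <- p; p2[[probe[1]]][j] <- p2[[probe[1]]][j] - eps
      num <- (lossAt(p1) - lossAt(p2)) / (2 * eps)
      expect_equal(grads[[probe[1]]][j], num, tolerance = 1e-4)
    }
  }
})
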