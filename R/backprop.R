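## Hand-derived backpropagation through the full network. Mirrors
## model.R stage by stage in reverse; validated in the test suite
## against finite differences and a scalar-loop LSTM oracle.

.zeroLike <- function(p) {
  if (is.list(p)) lapply(p, .zeroLike)
  else if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
  else numeric(length(p))
}

## backward through a row-wise layer normalization
.layerNormBackward <- function(dy, lnCache, g) {
  xhat <- lnCache$xhat
  inv <- lnCache$inv
  dxhat <- sweep(dy, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  list(dx = inv * (dxhat - m1 - xhat * m2),
       dg = colSums(dy * xhat), db = colSums(dy))
}

## backward through one LSTM direction (steps stored by .lstmDirection)
.lstmDirectionBackward <- function(dir, W, h, order, dh_last, dh_steps,
                                   d2, alphaWidth) {
  B <- nrow(dir$h_last)
  nStep <- length(order)
  dW <- matrix(0, nrow(W), ncol(W))
  db <- numeric(nrow(W))
  dE <- vector("list", nStep)            # indexed by pair id later
  dAlpha <- vector("list", nStep)
  dh <- dh_last
  dc <- matrix(0, B, h)
  for (j in rev(seq_len(nStep))) {
    st <- dir$steps[[j]]
    if (!is.null(dh_steps)) dh <- dh + dh_steps[[j]]
    do <- dh * st$tc
    dzo <- do * st$o * (1 - st$o)
    dcn <- dc + dh * st$o * (1 - st$tc^2)
    dg <- dcn * st$c_prev
    dzg <- dg * st$g * (1 - st$g)
    di <- dcn * st$cc
    dzi <- di * st$i * (1 - st$i)
    dcc <- dcn * st$i
    dzc <- dcc * (1 - st$cc^2)
    dZg <- cbind(dzg, dzi, dzc, dzo)
    dW <- dW + crossprod(dZg, st$U)
    db <- db + colSums(dZg)
    dU <- dZg %*% W
    dh <- dU[, seq_len(h), drop = FALSE]
    dc <- dcn * st$g
    i <- order[j]
    dE[[i]] <- dU[, h + seq_len(d2), drop = FALSE]
    dAlpha[[i]] <- dU[, h + d2 + seq_len(alphaWidth), drop = FALSE]
  }
  list(dW = dW, db = db, dE = dE, dAlpha = dAlpha)
}

#' Backward pass
#'
#' Computes the gradient of the mean cross-entropy loss with respect to
#' every model parameter, reusing the cache of [modelForward()].
#'
#' @param model a \code{topotemp_model}.
#' @param cache the \code{cache} element returned by [modelForward()].
#' @param labels integer labels in \code{0..K-1} for the batch.
#' @return named gradient list shaped like \code{model$params}.
#' @export
modelBackward <- function(model, cache, labels) {
  cfg <- model$config; p <- model$params
  Cp <- model$dims$Cp; T_len <- model$dims$T_len
  d <- cfg$d_model; h <- cfg$lstm_hidden; H <- cfg$n_heads
  B <- cache$B; nSeq <- cache$nSeq
  D <- model$dims$D
  g <- .zeroLike(p)

  ## classifier head
  onehot <- matrix(0, B, cfg$n_classes)
  onehot[cbind(seq_len(B), labels + 1L)] <- 1
  dlogits <- (cache$probs - onehot) / B
  g$W2 <- crossprod(dlogits, cache$a1)
  g$b2 <- colSums(dlogits)
  da1 <- dlogits %*% p$W2
  if (!is.null(cache$dropM)) da1 <- da1 * cache$dropM
  dz1 <- da1 * (cache$z1 > 0)
  g$W1 <- crossprod(dz1, cache$clsIn)
  g$b1 <- colSums(dz1)
  dclsIn <- dz1 %*% p$W1
  dhcat <- dclsIn[, D + seq_len(ncol(cache$hcat)), drop = FALSE]

  dE <- replicate(Cp, matrix(0, B, 2L * d), simplify = FALSE)
  dalpha <- matrix(0, B, Cp)
  alphaWidth <- if (cfg$alpha_mode == "scalar_per_step") 1L else Cp

  if (cfg$use_bilstm) {
    if (cfg$hidden_readout == "last") {
      dhF <- dhcat[, seq_len(h), drop = FALSE]
      dhB <- dhcat[, h + seq_len(h), drop = FALSE]
      stepsF <- stepsB <- NULL
    } else {
      zero <- matrix(0, B, h)
      dhF <- dhB <- zero
      stepsF <- replicate(Cp, dhcat[, seq_len(h), drop = FALSE] / Cp,
                          simplify = FALSE)
      stepsB <- replicate(Cp, dhcat[, h + seq_len(h), drop = FALSE] / Cp,
                          simplify = FALSE)
    }
    bf <- .lstmDirectionBackward(cache$lstmF, p$lstm_f$W, h, seq_len(Cp),
                                 dhF, stepsF, 2L * d, alphaWidth)
    bb <- .lstmDirectionBackward(cache$lstmB, p$lstm_b$W, h, rev(seq_len(Cp)),
                                 dhB, stepsB, 2L * d, alphaWidth)
    g$lstm_f$W <- bf$dW; g$lstm_f$b <- bf$db
    g$lstm_b$W <- bb$dW; g$lstm_b$b <- bb$db
    for (i in seq_len(Cp)) {
      dE[[i]] <- bf$dE[[i]] + bb$dE[[i]]
      if (alphaWidth == 1L)
        dalpha[, i] <- dalpha[, i] + bf$dAlpha[[i]] + bb$dAlpha[[i]]
      else
        dalpha <- dalpha + bf$dAlpha[[i]] + bb$dAlpha[[i]]
    }
  } else {
    for (i in seq_len(Cp)) dE[[i]] <- dhcat / Cp
  }

  ## graph attention
  if (cfg$use_gam && cfg$use_graph) {
    alpha <- cache$alpha
    dlg <- alpha * (dalpha - rowSums(dalpha * alpha))
    pf <- matrix(cache$pf, B * Cp, 3L)
    g$Walpha <- matrix(colSums(pf * as.vector(dlg)), 1L)
  }

  ## split E into pooled-transformer and projected-fusion halves
  dFmat <- matrix(0, nSeq, d)
  dfproj <- matrix(0, B, d)
  for (i in seq_len(Cp)) {
    rows <- (seq_len(B) - 1L) * Cp + i
    dFmat[rows, ] <- dFmat[rows, ] + dE[[i]][, seq_len(d), drop = FALSE]
    dfproj <- dfproj + dE[[i]][, d + seq_len(d), drop = FALSE]
  }
  if (!is.null(cache$dropT)) dfproj <- dfproj * cache$dropT
  g$Ww <- crossprod(dfproj, cache$f3)
  g$bw <- colSums(dfproj)

  ## temporal pooling
  grp <- rep(seq_len(nSeq), each = T_len)
  dZ <- dFmat[grp, , drop = FALSE] / T_len

  ## encoder layers in reverse
  for (l in rev(seq_along(p$enc))) {
    lay <- p$enc[[l]]; ec <- cache$enc[[l]]
    ln2b <- .layerNormBackward(dZ, ec$ln2, lay$ln2_g)
    g$enc[[l]]$ln2_g <- ln2b$dg; g$enc[[l]]$ln2_b <- ln2b$db
    dres2 <- ln2b$dx
    dy1 <- dres2                                    # residual branch
    dffn <- dres2
    dHact <- dffn %*% lay$Wf2
    g$enc[[l]]$Wf2 <- crossprod(dffn, ec$Hact)
    g$enc[[l]]$bf2 <- colSums(dffn)
    dHpre <- dHact * (ec$Hpre > 0)
    g$enc[[l]]$Wf1 <- crossprod(dHpre, ec$y1)
    g$enc[[l]]$bf1 <- colSums(dHpre)
    dy1 <- dy1 + dHpre %*% lay$Wf1
    ln1b <- .layerNormBackward(dy1, ec$ln1, lay$ln1_g)
    g$enc[[l]]$ln1_g <- ln1b$dg; g$enc[[l]]$ln1_b <- ln1b$db
    dres1 <- ln1b$dx
    dZin <- dres1                                   # residual branch
    dattout <- dres1
    att <- ec$att
    dO <- dattout %*% lay$Wo
    g$enc[[l]]$Wo <- crossprod(dattout, att$O)
    g$enc[[l]]$bo <- colSums(dattout)
    hd <- d %/% H
    N <- nrow(dZ)
    jdx <- att$jdx
    grpSeq <- rep(seq_len(nSeq), each = T_len)
    dQ <- matrix(0, N, d)
    dK <- matrix(0, N, d)
    dV <- matrix(0, N, d)
    for (hh in seq_len(H)) {
      cols <- ((hh - 1L) * hd + 1L):(hh * hd)
      A <- att$A[[hh]]
      dOh <- dO[, cols, drop = FALSE]
      Qh <- att$Q[, cols, drop = FALSE]
      Kh <- att$K[, cols, drop = FALSE]
      Vh <- att$V[, cols, drop = FALSE]
      dA <- matrix(0, N, T_len)
      dVh <- matrix(0, N, hd)
      for (j in seq_len(T_len)) {
        dA[, j] <- rowSums(dOh * Vh[jdx[[j]], , drop = FALSE])
        rows_j <- (seq_len(nSeq) - 1L) * T_len + j
        dVh[rows_j, ] <- dVh[rows_j, , drop = FALSE] +
          rowsum(A[, j] * dOh, grpSeq)
      }
      dS <- A * (dA - rowSums(dA * A))
      dQh <- matrix(0, N, hd)
      dKh <- matrix(0, N, hd)
      for (j in seq_len(T_len)) {
        dQh <- dQh + dS[, j] * Kh[jdx[[j]], , drop = FALSE] / sqrt(hd)
        rows_j <- (seq_len(nSeq) - 1L) * T_len + j
        dKh[rows_j, ] <- dKh[rows_j, , drop = FALSE] +
          rowsum(dS[, j] * Qh, grpSeq) / sqrt(hd)
      }
      dQ[, cols] <- dQh; dK[, cols] <- dKh; dV[, cols] <- dVh
    }
    Zin <- ec$Zin
    g$enc[[l]]$Wq <- crossprod(dQ, Zin); g$enc[[l]]$bq <- colSums(dQ)
    g$enc[[l]]$Wk <- crossprod(dK, Zin); g$enc[[l]]$bk <- colSums(dK)
    g$enc[[l]]$Wv <- crossprod(dV, Zin); g$enc[[l]]$bv <- colSums(dV)
    dZin <- dZin + dQ %*% lay$Wq + dK %*% lay$Wk + dV %*% lay$Wv
    dZ <- dZin
  }

  ## input projection (positional encoding is constant)
  g$Wp <- crossprod(dZ, cache$M)
  g$bp <- colSums(dZ)
  g
}
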