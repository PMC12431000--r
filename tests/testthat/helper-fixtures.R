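## Shared fixture builders. Everything is generated in code; sizes are
## kept small so the default run stays fast.

## tiny annotated recording: nPairs pairs, trials of task_s seconds
tinyRecording <- function(nPairs = 2, rate = 10, n_trials = 2, task_s = 10,
                          rest_s = 5, labels = NULL, seed = 1) {
  set.seed(seed)
  taskSamp <- task_s * rate
  restSamp <- rest_s * rate
  nTime <- restSamp + n_trials * (taskSamp + restSamp)
  sig <- matrix(rnorm(2 * nPairs * nTime), 2 * nPairs, nTime)
  onsets <- restSamp + 1 + (seq_len(n_trials) - 1) * (taskSamp + restSamp)
  ann <- data.frame(onset = onsets, duration_s = task_s,
                    label = labels %||% rep_len(0:1, n_trials),
                    subject = "s1", stringsAsFactors = FALSE)
  HemodynamicRecording(sig, rate, interleavedRoles(nPairs), ann)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## tiny labeled epoch set with random content
tinyEpochSet <- function(n = 8, Cp = 3, T_len = 10, K = 2, rate = 10,
                         seed = 1) {
  set.seed(seed)
  EpochSet(array(rnorm(n * 2 * Cp * T_len), dim = c(n, 2 * Cp, T_len)),
           labels = rep_len(seq_len(K) - 1L, n),
           subjects = rep("s1", n), samplingRate = rate,
           epochLengthS = T_len / rate)
}

## small model + random batch for network tests
tinyModelBatch <- function(B = 4, Cp = 3, T_len = 5, K = 3, seed = 42,
                           cfg = modelConfig(d_model = 8, n_heads = 2,
                                             ffn_dim = 12, lstm_hidden = 5,
                                             mlp_hidden = 7, n_classes = K)) {
  set.seed(seed)
  C <- 2 * Cp
  D <- C * T_len + 3 * Cp + 1
  model <- initModel(cfg, Cp, T_len, D, seed = seed + 1)
  batch <- list(X = array(rnorm(B * C * T_len), dim = c(B, C, T_len)),
                f3 = matrix(rnorm(B * D), B, D),
                pf = array(runif(B * Cp * 3), dim = c(B, Cp, 3)))
  labels <- sample(seq_len(K) - 1L, B, replace = TRUE)
  list(model = model, batch = batch, labels = labels, D = D, Cp = Cp)
}

## Floyd-Warshall all-pairs shortest paths: the brute-force oracle
## against which the BFS-based efficiency is checked
fwEfficiency <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  d[A != 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

## adjacency matrix from an integer bit pattern over the upper triangle
bitsToAdjacency <- function(bits, n) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- bits
  A + t(A)
}

## scalar-loop oracle for one attention-modulated LSTM gate update
lstmCellOracle <- function(h_prev, c_prev, E_i, alpha_i, W, b) {
  u <- c(h_prev, E_i, alpha_i)
  h <- length(h_prev)
  z <- numeric(4 * h)
  for (r in seq_len(4 * h)) {
    acc <- 0
    for (k in seq_along(u)) acc <- acc + W[r, k] * u[k]
    z[r] <- acc + b[r]
  }
  sig <- function(x) 1 / (1 + exp(-x))
  g <- sig(z[1:h]); i <- sig(z[h + 1:h])
  cc <- tanh(z[2 * h + 1:h]); o <- sig(z[3 * h + 1:h])
  c_new <- g * c_prev + i * cc
  list(h = o * tanh(c_new), c = c_new)
}

## study-conditions dataset: classes differing only in coupling blocks
coupledBlocksData <- function(n_subjects = 2, n_trials_per_class = 5,
                              Cp = 10, seed = 11) {
  cfg <- presetSimConfig("coupled_blocks", n_subjects = n_subjects,
                         n_trials_per_class = n_trials_per_class,
                         Cp = Cp, seed = seed)
  ep <- simulatedEpochs(simulateDataset(cfg))
  list(ep = ep, features = epochFeatures(ep), config = cfg)
}
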