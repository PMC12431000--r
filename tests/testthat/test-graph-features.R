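test_that("Pearson correlation matches hand-evaluated cases and flags degeneracy", {
  expect_equal(as.numeric(pearsonCorr(c(1, 2, 3), c(1, 2, 3))), 1)
  expect_equal(as.numeric(pearsonCorr(c(1, 2, 3), c(3, 2, 1))), -1)
  ## cov-sum 4 over sqrt(5 * 5)
  expect_equal(as.numeric(pearsonCorr(c(1, 2, 3, 4), c(1, 3, 2, 4))), 0.8)
  expect_error(pearsonCorr(1:3, 1:4), "lengths differ")
  flat <- pearsonCorr(rep(1, 5), rnorm(5))
  expect_equal(as.numeric(flat), 0)
  expect_true(attr(flat, "degenerate"))
})

test_that("connection strength is the normalized correlation", {
  x <- rnorm(20)
  expect_equal(as.numeric(connectionStrength(x, x)), 1)
  expect_equal(as.numeric(connectionStrength(x, -x)), 0)
  expect_equal(as.numeric(connectionStrength(c(1, 2, 3, 4), c(1, 3, 2, 4))), 0.9)
})

test_that("connection density counts sliding windows above threshold", {
  cfg <- featureConfig()
  x <- rnorm(12)
  expect_equal(connectionDensity(x, 2 * x + 1, cfg), 1)
  expect_equal(connectionDensity(x, -x, cfg), 0)

  ## T=6, L=3 crafted case checked against an exhaustive window oracle
  cfg3 <- featureConfig(window_length_s = 3)
  attr(cfg3, "rate") <- 1                  # 1 Hz -> L = 3 samples
  x6 <- c(1, 2, 3, 4, 5, 6)
  y6 <- c(1, 2, 3, 3, 2, 1)
  oracle <- function(x, y, L, thr) {
    hits <- 0
    for (k in 1:(length(x) - L + 1)) {
      rho <- cor(x[k:(k + L - 1)], y[k:(k + L - 1)])
      if (!is.na(rho) && rho > thr) hits <- hits + 1
    }
    hits / (length(x) - L + 1)
  }
  expect_equal(oracle(x6, y6, 3, 0.3), 0.5)   # exactly 2 of 4 windows
  expect_equal(connectionDensity(x6, y6, cfg3), 0.5)

  ## random pairs agree with the oracle
  set.seed(21)
  for (r in 1:10) {
    x <- rnorm(15); y <- rnorm(15)
    cfgL <- featureConfig(window_length_s = 4)
    attr(cfgL, "rate") <- 1
    expect_equal(connectionDensity(x, y, cfgL), oracle(x, y, 4, 0.3))
  }

  ## with L = T the density is the full-series indicator
  set.seed(22)
  for (r in 1:10) {
    x <- rnorm(10); y <- rnorm(10)
    d <- connectionDensity(x, y, cfg)
    expect_true(d %in% c(0, 1))
    expect_equal(d, as.numeric(as.numeric(pearsonCorr(x, y)) > 0.3))
  }
})

test_that("reciprocal mean difference matches analytic values", {
  cfg <- featureConfig()
  x <- rnorm(10)
  expect_equal(rfsmd(x, x, cfg), 1e6)
  expect_equal(rfsmd(x, x + 1, cfg), 1 / (1 + 1e-6))
  expect_equal(rfsmd(c(1, 2), c(2, 4), cfg), 1 / (1.5 + 1e-6))
  expect_lte(rfsmd(rnorm(5), rnorm(5), cfg), 1 / cfg$epsilon)
})

test_that("adjacency thresholds signed correlations symmetrically", {
  cfg <- featureConfig()
  x <- rnorm(30)
  A1 <- buildAdjacency(rbind(x, 2 * x, x + 0), cfg)
  expect_equal(A1, matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))

  ## anti-correlated pair yields no edge under the signed threshold
  expect_equal(buildAdjacency(rbind(x, -x), cfg), matrix(0, 2, 2))
  ## ... but an edge when thresholding |rho|
  cfgAbs <- featureConfig(thresholds_signed = FALSE)
  expect_equal(buildAdjacency(rbind(x, -x), cfgAbs),
               matrix(c(0, 1, 1, 0), 2))

  ## crafted 3-channel case with exactly one edge, checked directly
  set.seed(5)
  a <- rnorm(40)
  b <- a + rnorm(40, sd = 0.5)             # correlated with a
  c3 <- rnorm(40)                          # independent
  stopifnot(cor(a, b) > 0.3, abs(cor(a, c3)) < 0.3, abs(cor(b, c3)) < 0.3)
  A <- buildAdjacency(rbind(a, b, c3), cfg)
  expect_equal(A, t(A))
  expect_equal(sum(A), 2)
  expect_equal(A[1, 2], 1)
})

test_that("global efficiency equals the brute-force shortest-path oracle", {
  ## analytic anchors
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(globalEfficiency(K4), 1)
  P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[2, 1] <- P3[2, 3] <- P3[3, 2] <- 1
  expect_equal(globalEfficiency(P3), 5 / 6)
  expect_equal(globalEfficiency(matrix(0, 4, 4)), 0)
  expect_error(globalEfficiency(matrix(0, 1, 1)), "2 nodes")

  ## exhaustive 4-node graphs and random 8-node graphs vs Floyd-Warshall
  for (bitsInt in 0:63) {
    bits <- as.integer(intToBits(bitsInt))[1:6]
    A <- bitsToAdjacency(bits, 4)
    expect_equal(globalEfficiency(A), fwEfficiency(A))
  }
  set.seed(8)
  for (r in 1:25) {
    n <- sample(5:8, 1)
    A <- bitsToAdjacency(rbinom(n * (n - 1) / 2, 1, 0.4), n)
    expect_equal(globalEfficiency(A), fwEfficiency(A))
  }
})

test_that("assembled features have the contracted layout and invariants", {
  cfg <- featureConfig()
  set.seed(12)
  epoch <- matrix(rnorm(4 * 10), 4, 10)
  f <- assembleFeatures(epoch, cfg)
  expect_length(f$f3, 4 * 10 + 3 * 2 + 1)
  expect_equal(f$f3[1:40], as.vector(epoch))
  expect_equal(f$f3[41:46],
               as.vector(rbind(f$pair$s, f$pair$Sd, f$pair$RFSMD)))
  expect_equal(f$f3[47], f$efficiency)
  expect_true(all(f$pair$s >= 0 & f$pair$s <= 1))
  expect_true(all(f$pair$Sd >= 0 & f$pair$Sd <= 1))
  expect_gte(f$efficiency, 0); expect_lte(f$efficiency, 1)

  ## zero epoch: degenerate pairs, empty graph, zero raw block
  f0 <- assembleFeatures(matrix(0, 4, 10), cfg)
  expect_true(all(f0$degenerate))
  expect_equal(f0$efficiency, 0)
  expect_equal(f0$f1, rep(0, 40))

  ## positive rescaling leaves correlation-based features unchanged,
  ## RFSMD scales inversely
  f2x <- assembleFeatures(3 * epoch, cfg)
  expect_equal(f2x$pair$s, f$pair$s)
  expect_equal(f2x$pair$Sd, f$pair$Sd)
  expect_equal(f2x$adjacency, f$adjacency)
  expect_equal(f2x$efficiency, f$efficiency)
  expect_equal(f2x$pair$RFSMD,
               1 / (3 * (1 / f$pair$RFSMD - cfg$epsilon) + cfg$epsilon))
})

test_that("average efficiency behaves as a mean and is monotone in the threshold", {
  ## two epochs engineered for known efficiencies
  ep1 <- matrix(rnorm(10), 1, 10)
  identE <- rbind(ep1, ep1 + 1e-9, ep1 - 1e-9, ep1 * 2)   # complete graph
  set.seed(2)
  x <- rnorm(10)
  mixedE <- rbind(x, x, rnorm(10), rnorm(10))
  arr <- array(0, dim = c(2, 4, 10))
  arr[1, , ] <- identE; arr[2, , ] <- identE
  epA <- EpochSet(arr, c(0L, 1L), samplingRate = 10, epochLengthS = 1)
  expect_equal(averageEfficiency(epA), 100)

  d <- coupledBlocksData(n_subjects = 1, n_trials_per_class = 2, Cp = 4,
                         seed = 33)
  ae <- vapply(seq(0.1, 0.5, by = 0.1), function(th)
    averageEfficiency(d$ep, featureConfig(adjacency_threshold = th)),
    numeric(1))
  expect_true(all(diff(ae) <= 1e-12))
})
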