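test_that("accuracy and kappa match hand-computed confusion matrices", {
  cm <- matrix(c(45, 5, 5, 45), 2, byrow = TRUE)
  expect_equal(accuracyFromConfusion(cm), 90)
  expect_equal(as.numeric(cohenKappa(cm)), 0.8)   # po 0.9, pe 0.5

  perfect <- diag(c(10, 20, 30))
  expect_equal(accuracyFromConfusion(perfect), 100)
  expect_equal(as.numeric(cohenKappa(perfect)), 1)

  single <- matrix(c(7, 0, 0, 0), 2)
  k <- cohenKappa(single)
  expect_equal(as.numeric(k), 0)
  expect_true(attr(k, "degenerate"))
  expect_error(accuracyFromConfusion(matrix(0, 2, 2)), "empty")

  ## independence of truth and prediction gives kappa near zero, and
  ## chance-level accuracy stays inside the 99% binomial band
  set.seed(14)
  truth <- sample(0:1, 200, replace = TRUE)
  pred <- sample(0:1, 200, replace = TRUE)
  cmR <- confusionCounts(truth, pred, 2)
  expect_lt(abs(as.numeric(cohenKappa(cmR))), 0.15)
  half_width <- 100 * qnorm(0.995) * sqrt(0.25 / 200)
  expect_lt(abs(accuracyFromConfusion(cmR) - 50), half_width)
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(15)
  for (r in 1:10) {
    K <- sample(2:4, 1)
    truth <- sample(0:(K - 1), 60, replace = TRUE)
    pred <- ifelse(runif(60) < 0.6, truth, sample(0:(K - 1), 60, TRUE))
    cm <- confusionCounts(truth, pred, K)
    expect_equal(as.numeric(cohenKappa(cm)),
                 e1071::classAgreement(cm)$kappa, tolerance = 1e-12)
  }
})

test_that("ROC/AUC equals the pair-counting Mann-Whitney oracle", {
  ## anchors
  expect_equal(rocCurve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(rocCurve(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)

  pairOracle <- function(scores, pos) {
    sp <- scores[pos]; sn <- scores[!pos]
    tot <- 0
    for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(sp) * length(sn))
  }
  set.seed(16)
  for (r in 1:25) {
    n <- sample(4:50, 1)
    pos <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(rocCurve(scores, pos)$auc, pairOracle(scores, pos))
  }
  expect_error(rocCurve(1:4, rep(TRUE, 4)), "positive and")

  skip_if_not_installed("pROC")
  set.seed(17)
  for (r in 1:5) {
    pos <- runif(30) > 0.4
    if (!any(pos) || all(pos)) next
    scores <- rnorm(30) + pos
    expect_equal(rocCurve(scores, pos)$auc,
                 as.numeric(pROC::auc(pROC::roc(pos, scores, quiet = TRUE))),
                 tolerance = 1e-12)
  }
})

test_that("one-vs-rest ROC skips degenerate classes with a flag", {
  set.seed(18)
  scores <- matrix(runif(30), 10, 3)
  labels <- c(rep(0L, 5), rep(1L, 5))   # class 2 absent
  r <- rocAuc(scores, labels)
  expect_true(isTRUE(r$per_class[[3]]$skipped))
  expect_true(is.na(r$auc[3]))
  expect_equal(r$macro_auc, mean(r$auc[1:2]))
})

test_that("group statistics flag true differences and only those", {
  d <- coupledBlocksData(n_subjects = 1, n_trials_per_class = 3, Cp = 4,
                         seed = 41)
  st <- featureGroupStats(d$ep, d$features)
  expect_true(all(c("pair", "feature", "p", "significant") %in%
                    names(st$tests)))
  expect_true(all(st$tests$p >= 0 & st$tests$p <= 1, na.rm = TRUE))
  ## strength separates the coupled blocks
  sRows <- st$tests[st$tests$feature == "s", ]
  expect_gt(sum(sRows$significant), 0)

  ## identical groups: exact tie, p = 1, nothing significant
  pf <- array(0.5, dim = c(12, 2, 3),
              dimnames = list(NULL, NULL, c("s", "Sd", "RFSMD")))
  epT <- tinyEpochSet(n = 12, Cp = 2)
  stT <- featureGroupStats(epT, list(pairFeatures = pf))
  expect_true(all(stT$tests$p == 1))
  expect_length(stT$significant_pairs, 0)
  expect_true(all(stT$tests$degenerate))

  ## Welch t on identical printed samples is exactly zero
  x <- c(1, 2, 3); y <- c(1, 2, 3)
  tt <- t.test(x, y)
  expect_equal(unname(tt$statistic), 0)

  ## shifted groups are detected with near-certain power
  set.seed(42)
  hits <- 0
  for (r in 1:100) {
    g1 <- rnorm(30); g2 <- rnorm(30) + 5
    hits <- hits + (t.test(g1, g2)$p.value < 0.05)
  }
  expect_gte(hits, 99)

  ## three classes route through one-way ANOVA
  d3 <- coupledBlocksData(n_subjects = 1, n_trials_per_class = 3, Cp = 6,
                          seed = 43)
  ## build a 3-class labeling by splitting one class
  ep3 <- d3$ep
  labs <- epochLabels(ep3)
  labs[which(labs == 1)[1:15]] <- 2L
  ep3@labels <- labs
  st3 <- featureGroupStats(ep3, d3$features)
  expect_true(all(is.finite(st3$tests$statistic) | st3$tests$degenerate))
})

test_that("fold construction is stratified, disjoint and subject-aware", {
  ep <- tinyEpochSet(n = 60, Cp = 2, K = 2)
  folds <- makeSubjectFolds(ep, 5, seed = 3)
  expect_length(folds, 5)
  tests <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:60)
  for (f in folds) {
    expect_length(f$test, 12)
    expect_length(intersect(f$train, f$test), 0)
    expect_equal(as.numeric(table(epochLabels(ep)[f$test])), c(6, 6))
  }
  expect_identical(makeSubjectFolds(ep, 5, seed = 3),
                   makeSubjectFolds(ep, 5, seed = 3))
  expect_error(makeSubjectFolds(tinyEpochSet(n = 6), 5), "< 5 folds")

  ## LOSO: one fold per subject, subject-disjoint
  ep2 <- tinyEpochSet(n = 40, Cp = 2)
  ep2@subjects <- rep(c("a", "b", "c", "d"), each = 10)
  loso <- makeLosoFolds(ep2)
  expect_length(loso, 4)
  for (f in loso) {
    expect_length(intersect(subjectIds(ep2)[f$train],
                            subjectIds(ep2)[f$test]), 0)
    expect_equal(unique(subjectIds(ep2)[f$test]), f$subject)
  }
  ep1 <- tinyEpochSet(n = 10, Cp = 2)
  expect_error(makeLosoFolds(ep1), "at least 2 subjects")
})
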