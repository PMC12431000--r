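## Group statistics on the per-pair connectivity features: which channel
## pairs differ between task classes, and by how much.

#' Per-pair feature group statistics
#'
#' For every channel pair and every local feature (strength s, density
#' Sd, RFSMD), compares the feature's distribution across task classes:
#' a two-sided Welch t test for two classes, a one-way ANOVA F test for
#' three or more. Group means, standard deviations and quartiles
#' accompany the test so the summary carries the content of the usual
#' violin/box plots.
#'
#' @param ep an \linkS4class{EpochSet} (provides the class labels).
#' @param features matching [epochFeatures()] output.
#' @param alpha significance level for the significant-pair set
#'   (default 0.05).
#' @param adjust multiplicity correction: \code{"none"} (default,
#'   per-pair testing) or \code{"BH"} (Benjamini-Hochberg).
#' @return list: \code{tests} data.frame (pair, feature, statistic,
#'   df, p, p_adj, significant, degenerate), \code{groups} data.frame of
#'   per-class summaries (mean, sd, quartiles), and
#'   \code{significant_pairs}, the pairs significant for at least one
#'   feature.
#' @export
featureGroupStats <- function(ep, features, alpha = 0.05,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  labs <- epochLabels(ep)
  classes <- sort(unique(labs))
  if (length(classes) < 2L) .stopf("need at least 2 classes")
  if (min(table(labs)) < 3L) .stopf("need at least 3 epochs per class")
  pf <- features$pairFeatures
  Cp <- dim(pf)[2L]
  featNames <- dimnames(pf)[[3L]]

  tests <- data.frame()
  groups <- data.frame()
  for (i in seq_len(Cp)) {
    for (f in featNames) {
      x <- pf[, i, f]
      byClass <- split(x, labs)
      for (k in names(byClass)) {
        q <- stats::quantile(byClass[[k]], c(0.25, 0.5, 0.75))
        groups <- rbind(groups, data.frame(
          pair = i, feature = f, class = as.integer(k),
          n = length(byClass[[k]]), mean = mean(byClass[[k]]),
          sd = stats::sd(byClass[[k]]),
          q25 = q[[1L]], median = q[[2L]], q75 = q[[3L]]))
      }
      degenerate <- all(vapply(byClass, function(v) stats::var(v) == 0,
                               logical(1)))
      if (degenerate) {
        ## exact ties within every group: identical groups are a perfect
        ## tie (p = 1); distinct constants separate with zero variance
        df <- NA_real_
        if (length(unique(x)) == 1L) { stat <- 0; p <- 1 }
        else { stat <- Inf; p <- 0 }
      } else if (length(classes) == 2L) {
        tt <- stats::t.test(byClass[[1L]], byClass[[2L]])
        stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
      } else {
        fit <- stats::aov(x ~ factor(labs))
        an <- summary(fit)[[1L]]
        stat <- an$`F value`[1L]; df <- an$Df[1L]; p <- an$`Pr(>F)`[1L]
      }
      tests <- rbind(tests, data.frame(pair = i, feature = f,
                                       statistic = stat, df = df, p = p,
                                       degenerate = degenerate))
    }
  }
  tests$p_adj <- if (adjust == "BH") stats::p.adjust(tests$p, "BH") else tests$p
  tests$significant <- tests$p_adj < alpha
  list(tests = tests, groups = groups,
       significant_pairs = sort(unique(tests$pair[tests$significant])))
}
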