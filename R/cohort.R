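# Cohort-level statistics: grade scoring across regional groups, paired
# Wilcoxon comparisons, Fisher's exact contingency tests, and
# Spearman/BH metric-pattern association reporting.

#' Mean grade score of a regional group within a tumour
#'
#' Transforms each region's growth pattern to its grade score and
#' averages over the regions belonging to the requested group (seeding,
#' non-seeding or metastasis).
#'
#' @param regions region metadata data.frame (growth_pattern,
#'   seeding_label).
#' @param group one of \code{"seeding"}, \code{"non_seeding"},
#'   \code{"metastasis"}.
#' @param scoreMap named numeric grade score map (see
#'   \code{\link{gradeScoreMap}}).
#' @return mean score, or \code{NA} with a warning for an empty group.
#' @export
meanGroupGrade <- function(regions, group = c("seeding", "non_seeding",
                                              "metastasis"),
                           scoreMap = gradeScoreMap("figure")) {
  group <- match.arg(group)
  sel <- regions[regions$seeding_label == group, , drop = FALSE]
  grades <- deriveGrade(sel$growth_pattern)
  grades <- grades[grades != "unknown"]
  if (!length(grades)) {
    warning("no regions with known grade in group '", group, "'")
    return(NA_real_)
  }
  mean(scoreMap[grades])
}

#' Paired comparison of per-tumour group grade means
#'
#' Two-sided Wilcoxon signed-rank test on paired per-tumour means (exact
#' when sample size permits and there are no ties; zero differences are
#' dropped per the classic convention).
#'
#' @param meansA,meansB numeric vectors of per-tumour means, paired by
#'   position; NA pairs are dropped.
#' @return list with \code{n} (pairs used) and \code{p}.
#' @export
pairedGradeComparison <- function(meansA, meansB) {
  ok <- !is.na(meansA) & !is.na(meansB)
  a <- meansA[ok]
  b <- meansB[ok]
  if (!length(a)) stop("no complete pairs")
  if (all(a == b)) {
    warning("all paired differences are zero")
    return(list(n = length(a), p = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                            alternative = "two.sided"))
  list(n = length(a), p = wt$p.value)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the probability method (summing hypergeometric
#' probabilities of all tables with fixed margins that are at most as
#' probable as the observed one). The odds ratio reported is the sample
#' odds ratio ad/bc (0 and Inf allowed), not the conditional MLE.
#'
#' @param a,b,c,d the four cell counts (row-wise), or \code{a} may be a
#'   2x2 matrix.
#' @return list with \code{odds_ratio} and \code{p}.
#' @examples
#' fisherExact(17, 4, 37, 33)  # p ~ 0.024
#' @export
fisherExact <- function(a, b = NULL, c = NULL, d = NULL) {
  tab <- if (is.matrix(a)) a else matrix(c(a, b, c, d), 2, byrow = TRUE)
  if (any(tab < 0) || all(tab == 0)) stop("invalid 2x2 table")
  p <- stats::fisher.test(tab)$p.value
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, p = p)
}

#' Associate heterogeneity metrics with growth-pattern proportions
#'
#' Spearman rank correlation of each tumour-level metric against each
#' growth pattern's area proportion, with Benjamini-Hochberg adjustment
#' across the whole tested family.
#'
#' @param metrics data.frame of tumour-level metrics (rows = tumours).
#' @param patternPct data.frame/matrix of pattern proportions (rows =
#'   the same tumours, columns = patterns).
#' @return data.frame with metric, pattern, rho, p, q.
#' @export
associateMetricsWithPatterns <- function(metrics, patternPct) {
  if (nrow(metrics) < 3) stop("need at least 3 tumours")
  mNames <- colnames(metrics)
  pNames <- colnames(patternPct)
  rows <- list()
  for (m in mNames) for (p in pNames) {
    x <- metrics[[m]]
    y <- patternPct[, p]
    if (stats::sd(x, na.rm = TRUE) == 0 || stats::sd(y, na.rm = TRUE) == 0) {
      rho <- NA_real_; pv <- NA_real_
    } else {
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
      rho <- unname(ct$estimate); pv <- ct$p.value
    }
    rows[[length(rows) + 1L]] <-
      data.frame(metric = m, pattern = p, rho = rho, p = pv)
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
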