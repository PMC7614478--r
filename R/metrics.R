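# Intra-tumour heterogeneity metrics: wGII, FLOH, % subclonal SCNA,
# TMB clonality, illusion-of-clonality burden, subclonal diversity and
# recent subclonal expansion. Genome-fraction metrics are computed over
# autosomes only; homozygously deleted segments are excluded.

.autosomalStates <- function(profile, ploidy, homdelFloor = 0.5) {
  st <- .stateGRanges(profile, ploidy, homdelFloor)
  st <- st[.isAutosome(seqnames(st))]
  st[!mcols(st)$homdel_excluded]
}

#' Weighted genome instability index (wGII)
#'
#' Per autosome, the fraction of covered base pairs whose copy-number
#' state is gain or loss relative to the region's ploidy; wGII is the
#' unweighted mean of these per-chromosome fractions over autosomes with
#' coverage, so every chromosome contributes equally regardless of size.
#'
#' @param profile segment \code{GRanges} with \code{cnA}, \code{cnB}.
#' @param ploidy region mean ploidy.
#' @param homdelFloor see \code{\link{classifySegmentState}}.
#' @return wGII in \[0, 1\].
#' @export
wGII <- function(profile, ploidy, homdelFloor = 0.5) {
  st <- .autosomalStates(profile, ploidy, homdelFloor)
  if (!length(st)) stop("no autosomal coverage")
  chroms <- as.character(seqnames(st))
  aberr <- mcols(st)$gain | mcols(st)$loss
  w <- width(st)
  per <- vapply(unique(chroms), function(ch) {
    i <- chroms == ch
    sum(w[i & aberr]) / sum(w[i])
  }, numeric(1))
  mean(per)
}

#' Fraction of the genome subject to LOH (FLOH)
#'
#' Total autosomal base pairs in LOH (minor allele copy number < 0.5,
#' not homozygously deleted) divided by total covered autosomal base
#' pairs.
#'
#' @inheritParams wGII
#' @return FLOH in \[0, 1\].
#' @export
fLOH <- function(profile, ploidy = 2, homdelFloor = 0.5) {
  st <- .autosomalStates(profile, ploidy, homdelFloor)
  if (!length(st)) stop("no autosomal coverage")
  sum(width(st)[mcols(st)$loh]) / sum(width(st))
}

#' Mean of a regional metric across a tumour's regions
#' @param values numeric vector of per-region values.
#' @return arithmetic mean.
#' @export
tumourMeanMetric <- function(values) {
  if (!length(values)) stop("no regional values")
  mean(values)
}

#' Percent of SCNA-affected genome that is subclonal
#'
#' Over the union of all regions' breakpoints (autosomes), a base is
#' subject to SCNA when any region carries a gain or loss there; it is
#' subclonal when the regions do not all share the same event (direction
#' only: gain vs loss vs neutral; a base uncovered in a region counts as
#' neutral there). Returns 100 x subclonal bases / SCNA bases.
#'
#' @param bundle a \code{\linkS4class{TumourBundle}}.
#' @param homdelFloor see \code{\link{classifySegmentState}}.
#' @return percentage in \[0, 100\]; \code{NA} with a warning for a
#'   single-region tumour or when no base is SCNA.
#' @export
pctSubclonalSCNA <- function(bundle, homdelFloor = 0.5) {
  reg <- regionTable(bundle)
  if (nrow(reg) < 2) {
    warning("subclonality undefined for a single region")
    return(NA_real_)
  }
  profs <- segmentProfiles(bundle)
  states <- lapply(seq_len(nrow(reg)), function(i) {
    st <- .autosomalStates(profs[[reg$region_id[i]]], reg$ploidy[i],
                           homdelFloor)
    mcols(st)$state <- ifelse(mcols(st)$gain, 1L,
                              ifelse(mcols(st)$loss, -1L, 0L))
    st
  })
  bins <- disjoin(unlist(GenomicRanges::GRangesList(
    lapply(states, granges))))
  if (!length(bins)) {
    warning("no SCNA-affected bases")
    return(NA_real_)
  }
  mat <- matrix(0L, length(bins), length(states))
  for (k in seq_along(states)) {
    ov <- findOverlaps(bins, states[[k]])
    mat[S4Vectors::queryHits(ov), k] <-
      mcols(states[[k]])$state[S4Vectors::subjectHits(ov)]
  }
  anyEvent <- rowSums(mat != 0L) > 0L
  clonal <- anyEvent & apply(mat, 1, function(x) length(unique(x)) == 1L)
  w <- width(bins)
  denom <- sum(w[anyEvent])
  if (denom == 0) {
    warning("no SCNA-affected bases")
    return(NA_real_)
  }
  100 * sum(w[anyEvent & !clonal]) / denom
}

#' Truncal and subclonal tumour mutational burden
#'
#' Mutations assigned to the root cluster of the clone tree are truncal;
#' all others are subclonal at the tumour level.
#'
#' @param tree a \code{\linkS4class{CloneTree}}.
#' @param catalog mutation catalog data.frame (columns mutation_id,
#'   cluster_id, per-region CCFs).
#' @return list with \code{truncal_tmb}, \code{subclonal_tmb},
#'   \code{pct_subclonal_tmb}.
#' @export
tmbClonality <- function(tree, catalog) {
  orphan <- setdiff(unique(catalog$cluster_id), clusterIDs(tree))
  if (length(orphan))
    stop("mutations assigned to unknown cluster(s): ",
         paste(orphan, collapse = ", "))
  root <- rootCluster(tree)
  truncal <- sum(catalog$cluster_id == root)
  subclonal <- sum(catalog$cluster_id != root)
  tot <- truncal + subclonal
  list(truncal_tmb = truncal, subclonal_tmb = subclonal,
       pct_subclonal_tmb = if (tot > 0) 100 * subclonal / tot else NA_real_)
}

#' Illusion-of-clonality mutation burden
#'
#' Counts mutations that are subclonal at the tumour level (non-root
#' cluster) yet regionally clonal (cluster CCF at or above
#' \code{regionalClonalCCF}) in at least one region — mutations that would
#' appear clonal under single-region sampling. If per-cluster upper CCF
#' confidence bounds are supplied, regionally clonal means upper bound
#' >= 1.
#'
#' @param tree a \code{CloneTree}.
#' @param catalog mutation catalog data.frame.
#' @param regionalClonalCCF point-estimate threshold (default 0.9).
#' @param ccfUpper optional clusters x regions matrix of CCF upper bounds.
#' @return integer count.
#' @export
illusionClonalityCount <- function(tree, catalog, regionalClonalCCF = 0.9,
                                   ccfUpper = NULL) {
  root <- rootCluster(tree)
  ccf <- if (is.null(ccfUpper)) ccfMatrix(tree) else ccfUpper
  thr <- if (is.null(ccfUpper)) regionalClonalCCF else 1
  regClonal <- apply(ccf >= thr, 1, any, na.rm = TRUE)
  eligible <- setdiff(clusterIDs(tree)[regClonal], root)
  sum(catalog$cluster_id %in% eligible)
}

#' Cancer-cell clone proportions in one region
#'
#' The proportion of a region's cancer cells belonging to clone c equals
#' CCF(c) minus the summed CCFs of c's children; small negative values
#' from CCF noise are clipped to zero and the vector renormalised over
#' clones with positive proportion.
#'
#' @param tree a \code{CloneTree}.
#' @param region region id (a column of the CCF matrix).
#' @return named numeric vector summing to 1.
#' @export
cloneProportions <- function(tree, region) {
  ccf <- ccfMatrix(tree)[, region]
  par <- parentVector(tree)
  prop <- ccf
  for (cl in clusterIDs(tree)) {
    kids <- clusterIDs(tree)[!is.na(par) & par == cl]
    prop[cl] <- ccf[cl] - sum(ccf[kids])
  }
  prop[prop < 0] <- 0
  if (sum(prop) <= 0) stop("all clone proportions are zero in ", region)
  prop / sum(prop)
}

#' Shannon diversity of clone proportions
#'
#' @param proportions numeric vector of clone proportions (summing to 1).
#' @return Shannon index in nats: \code{-sum(p * log(p))} over p > 0.
#' @examples
#' subclonalDiversity(c(0.5, 0.5))  # log(2)
#' @export
subclonalDiversity <- function(proportions) {
  p <- proportions[proportions > 0]
  -sum(p * log(p))
}

#' Minimum regional subclonal diversity of a tumour
#' @param tree a \code{CloneTree}.
#' @return minimum over regions of the Shannon diversity of that region's
#'   clone proportions.
#' @export
minSubclonalDiversity <- function(tree) {
  min(vapply(colnames(ccfMatrix(tree)), function(r)
    subclonalDiversity(cloneProportions(tree, r)), numeric(1)))
}

#' Recent subclonal expansion score
#'
#' The maximum, across regions, of the largest CCF attained by any leaf
#' (terminal) cluster of the clone tree — the size of the largest recent
#' subclonal expansion anywhere in the tumour. A root-only tree returns
#' the root's maximum regional CCF with a \code{degenerate} attribute.
#'
#' @param tree a \code{CloneTree}.
#' @return score in \[0, 1\].
#' @export
recentExpansionScore <- function(tree) {
  leaves <- leafClusters(tree)
  degenerate <- identical(leaves, rootCluster(tree))
  score <- max(ccfMatrix(tree)[leaves, , drop = FALSE])
  attr(score, "degenerate") <- degenerate
  score
}

#' Tumour-level heterogeneity metric panel
#'
#' Computes the full metric set for one tumour: mean regional wGII and
#' FLOH, percent subclonal SCNA, truncal/subclonal TMB with percentage,
#' illusion-of-clonality burden, minimum subclonal diversity and recent
#' subclonal expansion score.
#'
#' @param bundle a \code{TumourBundle}.
#' @param regionalClonalCCF threshold for the illusion metric.
#' @return one-row data.frame.
#' @export
tumourMetrics <- function(bundle, regionalClonalCCF = 0.9) {
  reg <- regionTable(bundle)
  profs <- segmentProfiles(bundle)
  wg <- vapply(seq_len(nrow(reg)), function(i)
    wGII(profs[[reg$region_id[i]]], reg$ploidy[i]), numeric(1))
  fl <- vapply(seq_len(nrow(reg)), function(i)
    fLOH(profs[[reg$region_id[i]]], reg$ploidy[i]), numeric(1))
  tr <- cloneTree(bundle)
  tmb <- tmbClonality(tr, mutationCatalog(bundle))
  data.frame(
    tumour_id = tumourID(bundle),
    wgii_mean = tumourMeanMetric(wg),
    floh_mean = tumourMeanMetric(fl),
    pct_subclonal_scna = suppressWarnings(pctSubclonalSCNA(bundle)),
    truncal_tmb = tmb$truncal_tmb,
    subclonal_tmb = tmb$subclonal_tmb,
    pct_subclonal_tmb = tmb$pct_subclonal_tmb,
    illusion_tmb = illusionClonalityCount(tr, mutationCatalog(bundle),
                                          regionalClonalCCF),
    min_subclonal_diversity = minSubclonalDiversity(tr),
    recent_expansion_score = as.numeric(recentExpansionScore(tr)))
}

#' Per-region heterogeneity metrics
#' @param bundle a \code{TumourBundle}.
#' @return data.frame with one row per region: wGII, FLOH, subclonal
#'   diversity.
#' @export
regionMetrics <- function(bundle) {
  reg <- regionTable(bundle)
  profs <- segmentProfiles(bundle)
  tr <- cloneTree(bundle)
  do.call(rbind, lapply(seq_len(nrow(reg)), function(i) {
    rid <- reg$region_id[i]
    data.frame(tumour_id = tumourID(bundle), region_id = rid,
               wgii = wGII(profs[[rid]], reg$ploidy[i]),
               floh = fLOH(profs[[rid]], reg$ploidy[i]),
               subclonal_diversity =
                 subclonalDiversity(cloneProportions(tr, rid)))
  }))
}
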