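# Ancestor-like / descendant-like regional pair inference from pairwise
# LOH trees, grade-transition classification, and Monte-Carlo permutation
# tests with empirical p = (r + 1) / (n + 1).

#' Regions eligible for ancestry inference
#'
#' Primary tumour regions with purity at or above \code{purityMin}
#' (regions with purity below 0.15 are removed by default because LOH
#' calling is unreliable at low purity); metastasis regions are excluded.
#'
#' @param regions region metadata data.frame.
#' @param purityMin minimum purity (default 0.15; the boundary value is
#'   kept).
#' @return subset of \code{regions}.
#' @export
eligibleRegions <- function(regions, purityMin = 0.15) {
  keep <- regions$purity >= purityMin &
    regions$seeding_label != "metastasis"
  if (!any(keep)) warning("no eligible regions remain")
  regions[keep, , drop = FALSE]
}

# arm-level LOH per region: arms where LOH bands cover >= armLohFraction
# of the arm's cytoband length
.armLevelLoh <- function(calls, armLohFraction = 0.75) {
  armKey <- paste0(calls$chrom, calls$arm)
  frac <- vapply(split(seq_len(nrow(calls)), armKey), function(i)
    sum(calls$width[i] * calls$loh[i]) / sum(calls$width[i]), numeric(1))
  names(frac)[frac >= armLohFraction]
}

#' Build a pairwise LOH tree for two regions
#'
#' Counts shared (trunk) and private (branch) LOH cytobands between two
#' regions. With phased calls a band is shared only when both regions
#' lost the same haplotype; mirrored LOH (opposite haplotypes) counts as
#' private to both. Arm-level LOH in a region means LOH over at least
#' \code{armLohFraction} of the arm's cytoband length; shared and private
#' arm-level LOH counts are derived the same way.
#'
#' @param callsA,callsB cytoband call data.frames from
#'   \code{\link{cytobandLohCalls}} over the same band set.
#' @param armLohFraction arm-level LOH threshold (default 0.75).
#' @param haplotypeAware require the same lost haplotype for sharing when
#'   phase is available (default TRUE).
#' @return list with \code{trunk}, \code{branch_a}, \code{branch_b},
#'   \code{shared_arm_loh}, \code{private_arm_loh_a},
#'   \code{private_arm_loh_b}.
#' @export
pairLohTree <- function(callsA, callsB, armLohFraction = 0.75,
                        haplotypeAware = TRUE) {
  if (nrow(callsA) != nrow(callsB) ||
      !all(callsA$band == callsB$band & callsA$chrom == callsB$chrom))
    stop("mismatched cytoband sets")
  a <- callsA$loh == 1L
  b <- callsB$loh == 1L
  both <- a & b
  if (haplotypeAware) {
    sameHap <- is.na(callsA$lost) | is.na(callsB$lost) |
      callsA$lost == callsB$lost
    shared <- both & sameHap
  } else shared <- both
  trunk <- sum(shared)
  branchA <- sum(a & !shared)
  branchB <- sum(b & !shared)
  armsA <- .armLevelLoh(callsA, armLohFraction)
  armsB <- .armLevelLoh(callsB, armLohFraction)
  list(trunk = trunk, branch_a = branchA, branch_b = branchB,
       shared_arm_loh = length(intersect(armsA, armsB)),
       private_arm_loh_a = length(setdiff(armsA, armsB)),
       private_arm_loh_b = length(setdiff(armsB, armsA)))
}

#' Classify a regional pair as ancestor-like / descendant-like
#'
#' An ancestor-like region has a private LOH branch shorter than X per
#' cent of the trunk; a descendant-like region has a private branch
#' longer than Y per cent of the trunk AND more than one arm-level
#' private LOH. A call is produced only when one region qualifies as
#' ancestor-like and the other as descendant-like. Pairs failing the
#' shared arm-level LOH gate or with zero trunk yield no call. The
#' arm-count requirement is dropped when \code{requireArmCount = FALSE}
#' (mutation-based trees).
#'
#' @param tree pair tree from \code{\link{pairLohTree}} (trunk/branch
#'   counts).
#' @param regionA,regionB region ids.
#' @param X ancestor cutoff, per cent of trunk (default 2).
#' @param Y descendant cutoff, per cent of trunk (default 10).
#' @param requireArmCount require > 1 arm-level private LOH for the
#'   descendant (default TRUE).
#' @param requireSharedArm require >= 1 shared arm-level LOH (default
#'   TRUE).
#' @return one-row data.frame (ancestor_region, descendant_region,
#'   trunk, branch lengths, X, Y) or NULL when no call.
#' @export
classifyPair <- function(tree, regionA, regionB, X = 2, Y = 10,
                         requireArmCount = TRUE, requireSharedArm = TRUE) {
  if (tree$trunk == 0) return(NULL)
  if (requireSharedArm && tree$shared_arm_loh < 1) return(NULL)
  pctA <- 100 * tree$branch_a / tree$trunk
  pctB <- 100 * tree$branch_b / tree$trunk
  ancA <- pctA < X
  ancB <- pctB < X
  descA <- pctA > Y && (!requireArmCount || tree$private_arm_loh_a > 1)
  descB <- pctB > Y && (!requireArmCount || tree$private_arm_loh_b > 1)
  aFirst <- ancA && descB
  bFirst <- ancB && descA
  if (aFirst == bFirst) return(NULL)  # neither, or both (impossible X<Y)
  anc <- if (aFirst) regionA else regionB
  desc <- if (aFirst) regionB else regionA
  data.frame(ancestor_region = anc, descendant_region = desc,
             trunk = tree$trunk,
             branch_ancestor = if (aFirst) tree$branch_a else tree$branch_b,
             branch_descendant = if (aFirst) tree$branch_b else tree$branch_a,
             X = X, Y = Y)
}

# dominant-mutation (CCF >= ccfMin) trunk/branch tree for a region pair
.pairMutationTree <- function(catalog, regionA, regionB, ccfMin = 0.95) {
  ca <- catalog[[regionA]]
  cb <- catalog[[regionB]]
  a <- !is.na(ca) & ca >= ccfMin
  b <- !is.na(cb) & cb >= ccfMin
  list(trunk = sum(a & b), branch_a = sum(a & !b), branch_b = sum(b & !a),
       shared_arm_loh = NA_integer_, private_arm_loh_a = NA_integer_,
       private_arm_loh_b = NA_integer_)
}

#' Infer ancestor-descendant-like regional pairs for a tumour
#'
#' LOH method: cytoband LOH calls per eligible region, pairwise LOH trees
#' gated on at least one shared arm-level LOH, then the X/Y
#' classification. Mutation method: the same X/Y rules on trunk/branch
#' counts of dominant mutations (regional CCF >= 0.95), without the
#' arm-count requirement. Combined: pairs called with the same
#' orientation by both methods.
#'
#' @param bundle a \code{\linkS4class{TumourBundle}}.
#' @param cytobands cytoband \code{GRanges}.
#' @param method \code{"loh"}, \code{"mutation"} or \code{"combined"}.
#' @param X,Y cutoffs in per cent of trunk (defaults 2 and 10).
#' @param purityMin eligibility threshold (default 0.15).
#' @param ccfMin dominant-mutation CCF threshold (default 0.95).
#' @param armLohFraction arm-level LOH threshold (default 0.75).
#' @param haplotypeAware see \code{\link{pairLohTree}}.
#' @return data.frame of calls (possibly zero rows) with tumour_id,
#'   ancestor_region, descendant_region, method and tree counts.
#' @export
inferPairs <- function(bundle, cytobands,
                       method = c("loh", "mutation", "combined"),
                       X = 2, Y = 10, purityMin = 0.15, ccfMin = 0.95,
                       armLohFraction = 0.75, haplotypeAware = TRUE) {
  method <- match.arg(method)
  empty <- data.frame(tumour_id = character(), ancestor_region = character(),
                      descendant_region = character(), trunk = integer(),
                      branch_ancestor = integer(),
                      branch_descendant = integer(), X = numeric(),
                      Y = numeric(), method = character())
  elig <- suppressWarnings(eligibleRegions(regionTable(bundle), purityMin))
  if (nrow(elig) < 2) return(empty)
  rids <- elig$region_id
  runMethod <- function(m) {
    if (m == "loh") {
      bt <- .bandTable(cytobands)
      calls <- lapply(rids, function(rid)
        cytobandLohCalls(segmentProfiles(bundle)[[rid]], bt))
      names(calls) <- rids
    }
    cat2 <- mutationCatalog(bundle)
    pairs <- utils::combn(rids, 2)
    res <- lapply(seq_len(ncol(pairs)), function(k) {
      ra <- pairs[1, k]; rb <- pairs[2, k]
      tr <- if (m == "loh")
        pairLohTree(calls[[ra]], calls[[rb]], armLohFraction,
                    haplotypeAware)
      else .pairMutationTree(cat2, ra, rb, ccfMin)
      classifyPair(tr, ra, rb, X, Y,
                   requireArmCount = (m == "loh"),
                   requireSharedArm = (m == "loh"))
    })
    res <- res[!vapply(res, is.null, TRUE)]
    if (!length(res)) return(empty)
    out <- do.call(rbind, res)
    out$tumour_id <- tumourID(bundle)
    out$method <- m
    out[, names(empty)]
  }
  if (method %in% c("loh", "mutation")) return(runMethod(method))
  lohCalls <- runMethod("loh")
  mutCalls <- runMethod("mutation")
  if (!nrow(lohCalls) || !nrow(mutCalls)) return(empty)
  key <- function(d) paste(d$ancestor_region, d$descendant_region)
  out <- lohCalls[key(lohCalls) %in% key(mutCalls), , drop = FALSE]
  if (nrow(out)) out$method <- "combined"
  out
}

#' Infer ancestor-descendant pairs across a cohort
#' @param cohort list with \code{bundles} and \code{cytobands}.
#' @param ... passed to \code{\link{inferPairs}}.
#' @return pooled call data.frame.
#' @export
cohortPairs <- function(cohort, ...) {
  do.call(rbind, lapply(cohort$bundles, function(b)
    inferPairs(b, cohort$cytobands, ...)))
}

#' Dominant-mutation burden (TMB CCF95) per called pair
#'
#' Counts mutations with regional CCF at or above \code{ccfMin} in the
#' ancestor and descendant regions of each call.
#'
#' @param calls call data.frame from \code{\link{inferPairs}} /
#'   \code{\link{cohortPairs}}.
#' @param catalogs named list (by tumour id) of mutation catalog
#'   data.frames.
#' @param ccfMin CCF threshold (default 0.95).
#' @return \code{calls} with added \code{ancestor_tmb95},
#'   \code{descendant_tmb95}.
#' @export
comparePairTMB <- function(calls, catalogs, ccfMin = 0.95) {
  cnt <- function(tid, rid) {
    cc <- catalogs[[tid]][[rid]]
    sum(!is.na(cc) & cc >= ccfMin)
  }
  calls$ancestor_tmb95 <- mapply(cnt, calls$tumour_id,
                                 calls$ancestor_region)
  calls$descendant_tmb95 <- mapply(cnt, calls$tumour_id,
                                   calls$descendant_region)
  calls
}

#' Grade transition direction of a called pair
#'
#' Compares the architectural grade of the descendant-like region with
#' its ancestor-like counterpart: higher grade is \code{"upward"}, lower
#' \code{"downward"}, equal \code{"same"}; \code{NA} when either grade is
#' unknown.
#'
#' @param calls call data.frame.
#' @param regions pooled region metadata with \code{tumour_id},
#'   \code{region_id}, \code{grade} columns (or a single tumour's
#'   region table plus \code{tumour_id} in calls).
#' @return \code{calls} with added \code{transition} column.
#' @export
gradeTransition <- function(calls, regions) {
  lvl <- setNames(seq_along(GRADE_LEVELS), GRADE_LEVELS)
  key <- paste(regions$tumour_id, regions$region_id)
  g <- setNames(regions$grade, key)
  ga <- g[paste(calls$tumour_id, calls$ancestor_region)]
  gd <- g[paste(calls$tumour_id, calls$descendant_region)]
  sa <- lvl[ga]
  sd <- lvl[gd]
  calls$transition <- ifelse(is.na(sa) | is.na(sd), NA_character_,
                             ifelse(sd > sa, "upward",
                                    ifelse(sd < sa, "downward", "same")))
  calls
}

.upwardCount <- function(calls, gradeOf) {
  lvl <- setNames(seq_along(GRADE_LEVELS), GRADE_LEVELS)
  sa <- lvl[gradeOf[paste(calls$tumour_id, calls$ancestor_region)]]
  sd <- lvl[gradeOf[paste(calls$tumour_id, calls$descendant_region)]]
  sum(!is.na(sa) & !is.na(sd) & sd > sa)
}

.tmbGreaterCount <- function(calls, tmbOf) {
  ta <- tmbOf[paste(calls$tumour_id, calls$ancestor_region)]
  td <- tmbOf[paste(calls$tumour_id, calls$descendant_region)]
  sum(!is.na(ta) & !is.na(td) & td > ta)
}

#' Monte-Carlo permutation test for descendant enrichment
#'
#' Tests whether upward grade transitions (or higher dominant-mutation
#' burden) are enriched in descendant-like regions. The observed count of
#' qualifying pairs is compared with counts obtained after randomising
#' the regional labels (growth patterns or TMB values) within each
#' tumour, among that tumour's eligible regions, keeping the pair
#' structure fixed. The empirical p-value is (r + 1) / (n + 1) where r is
#' the number of permutations whose statistic meets the exceedance rule:
#' by default strictly greater than the observed count (the rule the
#' empirical-p formula is stated with); the conservative
#' greater-or-equal convention, under which ties count toward r, is
#' available.
#'
#' @param calls call data.frame (needs tumour_id, ancestor_region,
#'   descendant_region).
#' @param regions pooled eligible-region metadata with \code{tumour_id},
#'   \code{region_id} and \code{grade} (for \code{upward_count}) or a
#'   \code{tmb95} column (for \code{tmb_greater_count}).
#' @param statistic \code{"upward_count"} or \code{"tmb_greater_count"}.
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed (required for reproducibility).
#' @param exceedance \code{"gt"} (strictly higher counts, default) or
#'   \code{"geq"} (ties count toward r; conservative).
#' @return list with \code{observed}, \code{n_perm}, \code{r},
#'   \code{empirical_p}, \code{seed}, \code{statistic}.
#' @export
permutationTest <- function(calls, regions,
                            statistic = c("upward_count",
                                          "tmb_greater_count"),
                            nPerm = 1000, seed = 1,
                            exceedance = c("gt", "geq")) {
  statistic <- match.arg(statistic)
  exceedance <- match.arg(exceedance)
  if (nPerm < 1) stop("nPerm must be >= 1")
  if (!nrow(calls)) stop("no calls to test")
  labCol <- if (statistic == "upward_count") "grade" else "tmb95"
  if (is.null(regions[[labCol]]))
    stop("regions must carry a '", labCol, "' column")
  statFun <- if (statistic == "upward_count") .upwardCount
             else .tmbGreaterCount
  tumours <- unique(calls$tumour_id)
  regions <- regions[regions$tumour_id %in% tumours, , drop = FALSE]
  labels <- setNames(regions[[labCol]],
                     paste(regions$tumour_id, regions$region_id))
  observed <- statFun(calls, labels)
  byTumour <- split(seq_len(nrow(regions)), regions$tumour_id)
  set.seed(seed)
  perms <- vapply(seq_len(nPerm), function(i) {
    shuffled <- labels
    for (idx in byTumour)
      shuffled[idx] <- labels[idx][sample.int(length(idx))]
    statFun(calls, shuffled)
  }, numeric(1))
  r <- if (exceedance == "geq") sum(perms >= observed)
       else sum(perms > observed)
  list(observed = observed, n_perm = nPerm, r = r,
       empirical_p = (r + 1) / (nPerm + 1), seed = seed,
       statistic = statistic)
}

#' Cutoff sensitivity grid for ancestry inference
#'
#' Re-runs pair inference and the upward-transition permutation test over
#' a grid of (X, Y) cutoffs. Combinations with X >= Y are skipped with a
#' warning; rows with zero calls carry p = NA.
#'
#' @param cohort list with \code{bundles} and \code{cytobands}.
#' @param XValues,YValues cutoff vectors (per cent of trunk).
#' @param nPerm permutations per cell.
#' @param seed RNG seed.
#' @param ... passed to \code{\link{inferPairs}}.
#' @return data.frame with X, Y, n_pairs, observed, empirical_p.
#' @export
sensitivityGrid <- function(cohort, XValues = c(1, 2, 5),
                            YValues = c(10, 20), nPerm = 1000, seed = 1,
                            ...) {
  regions <- do.call(rbind, lapply(cohort$bundles, function(b) {
    r <- suppressWarnings(eligibleRegions(regionTable(b)))
    if (!nrow(r)) return(NULL)
    cbind(tumour_id = tumourID(b), r)
  }))
  rows <- list()
  for (X in XValues) for (Y in YValues) {
    if (X >= Y) {
      warning("skipping X=", X, " >= Y=", Y)
      next
    }
    calls <- cohortPairs(cohort, X = X, Y = Y, ...)
    if (is.null(calls) || !nrow(calls)) {
      rows[[length(rows) + 1L]] <-
        data.frame(X = X, Y = Y, n_pairs = 0L, observed = NA_real_,
                   empirical_p = NA_real_)
      next
    }
    pt <- permutationTest(calls, regions, "upward_count", nPerm, seed)
    rows[[length(rows) + 1L]] <-
      data.frame(X = X, Y = Y, n_pairs = nrow(calls),
                 observed = pt$observed, empirical_p = pt$empirical_p)
  }
  do.call(rbind, rows)
}
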