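# Binary mutation / cytoband-LOH matrices, pairwise inter-region
# Euclidean distances, and the mixed-model comparison of same- vs
# different-pattern regional pairs.

# precomputed static view of a cytoband GRanges, reusable across many
# per-region calls
.bandTable <- function(cytobands) {
  chrom <- as.character(seqnames(cytobands))
  lev <- unique(chrom)
  offB <- (match(chrom, lev) - 1) * 1e9
  list(bandTable = TRUE, chrom = chrom, arm = mcols(cytobands)$arm,
       band = mcols(cytobands)$band, width = width(cytobands),
       bS = offB + start(cytobands), bE = offB + end(cytobands),
       lev = lev)
}

#' Cytoband-level LOH calls for one region
#'
#' Each cytoband is called by the copy-number state of the largest
#' genomic segment overlapping it: largest means greatest overlap length
#' within the band, ties broken by the leftmost segment. Cytobands with
#' no overlapping segment are called 0. The lost haplotype (A or B) is
#' recorded for phased sharing decisions downstream.
#'
#' @param profile segment \code{GRanges} with \code{cnA}, \code{cnB}.
#' @param cytobands cytoband \code{GRanges} (mcols \code{band},
#'   \code{arm}).
#' @param homdelFloor see \code{\link{classifySegmentState}}.
#' @return data.frame with one row per cytoband: \code{chrom},
#'   \code{arm}, \code{band}, \code{width}, \code{loh} (0/1) and
#'   \code{lost} (\code{"A"}, \code{"B"} or \code{NA}).
#' @export
cytobandLohCalls <- function(profile, cytobands, homdelFloor = 0.5) {
  bt <- if (is.list(cytobands) && !is.null(cytobands$bandTable))
    cytobands else .bandTable(cytobands)
  nB <- length(bt$chrom)
  out <- structure(
    list(chrom = bt$chrom, arm = bt$arm, band = bt$band,
         width = bt$width, loh = integer(nB),
         lost = rep(NA_character_, nB)),
    class = "data.frame", row.names = seq_len(nB))
  sChrom <- as.character(seqnames(profile))
  lev <- bt$lev
  # project onto one axis with large per-chromosome offsets, then sweep
  offS <- (match(sChrom, lev) - 1) * 1e9
  offS[is.na(offS)] <- -1e9           # segment chrom not in band set
  bS <- bt$bS; bE <- bt$bE
  sS <- offS + start(profile); sE <- offS + end(profile)
  o <- order(sS)
  sS <- sS[o]; sE <- sE[o]
  cnA <- mcols(profile)$cnA[o]; cnB <- mcols(profile)$cnB[o]
  isLohSeg <- pmin(cnA, cnB) < LOH_MINOR_CN & (cnA + cnB) >= homdelFloor
  jHi <- findInterval(bE, sS)              # last segment starting in band
  jLo <- findInterval(bS - 0.5, sE) + 1L   # first segment ending in band
  covered <- jHi >= jLo & jLo <= length(sS)
  best <- integer(nB)
  single <- covered & jHi == jLo
  best[single] <- jLo[single]
  for (i in which(covered & jHi > jLo)) {
    js <- jLo[i]:jHi[i]
    w <- pmin(sE[js], bE[i]) - pmax(sS[js], bS[i]) + 1
    best[i] <- js[which.max(w)]            # tie -> leftmost segment
  }
  hit <- which(covered)
  seg <- best[hit]
  lohHit <- isLohSeg[seg]
  out$loh[hit] <- as.integer(lohHit)
  out$lost[hit] <- ifelse(lohHit, ifelse(cnA[seg] <= cnB[seg], "A", "B"),
                          NA_character_)
  out
}

#' Binary feature matrix over regions
#'
#' Builds the features x regions 0/1 matrix used for genomic distances:
#' either mutation presence (CCF > 0) or cytoband-level LOH. Features
#' absent from every region are dropped.
#'
#' @param bundle a \code{\linkS4class{TumourBundle}}.
#' @param kind \code{"mutation"} or \code{"loh"}.
#' @param cytobands required for \code{kind = "loh"}.
#' @return integer matrix with feature rownames and region colnames;
#'   attribute \code{kind}.
#' @export
binaryFeatureMatrix <- function(bundle, kind = c("mutation", "loh"),
                                cytobands = NULL) {
  kind <- match.arg(kind)
  rids <- regionIDs(bundle)
  if (kind == "mutation") {
    m <- mutationCatalog(bundle)
    ccf <- as.matrix(m[, intersect(rids, names(m)), drop = FALSE])
    mat <- 1L * (!is.na(ccf) & ccf > 0)
    rownames(mat) <- m$mutation_id
  } else {
    if (is.null(cytobands)) stop("cytobands required for LOH matrix")
    bt <- .bandTable(cytobands)
    cols <- lapply(rids, function(rid)
      cytobandLohCalls(segmentProfiles(bundle)[[rid]], bt)$loh)
    mat <- do.call(cbind, cols)
    colnames(mat) <- rids
    rownames(mat) <- paste0(bt$chrom, bt$arm, ".", bt$band)
  }
  colnames(mat) <- rids
  mat <- mat[rowSums(mat) > 0, , drop = FALSE]
  attr(mat, "kind") <- kind
  mat
}

#' Pairwise Euclidean distances between regions
#'
#' For binary feature columns the Euclidean distance is the square root
#' of the number of discordant features.
#'
#' @param mat features x regions matrix (see
#'   \code{\link{binaryFeatureMatrix}}).
#' @param tumourID optional tumour id to attach.
#' @return data.frame of all unordered region pairs with columns
#'   \code{tumour_id}, \code{region_i}, \code{region_j},
#'   \code{distance}, \code{kind}.
#' @export
pairwiseEuclidean <- function(mat, tumourID = NA_character_) {
  rids <- colnames(mat)
  if (length(rids) < 2) {
    warning("fewer than 2 regions; no pairs")
    return(data.frame(tumour_id = character(), region_i = character(),
                      region_j = character(), distance = numeric(),
                      kind = character()))
  }
  pairs <- utils::combn(rids, 2)
  d <- apply(pairs, 2, function(p)
    sqrt(sum((mat[, p[1]] - mat[, p[2]])^2)))
  data.frame(tumour_id = tumourID, region_i = pairs[1, ],
             region_j = pairs[2, ], distance = d,
             kind = attr(mat, "kind") %||% NA_character_)
}

#' Label regional pairs as same- or different-pattern
#'
#' @param pairs data.frame from \code{\link{pairwiseEuclidean}}.
#' @param regions region metadata data.frame with \code{region_id} and
#'   \code{growth_pattern}.
#' @return \code{pairs} with added \code{pattern_relation}
#'   (\code{"same"}/\code{"different"}) plus purity columns when
#'   available; pairs involving an unknown pattern are dropped (count
#'   reported via message).
#' @export
labelPatternRelation <- function(pairs, regions) {
  pat <- setNames(tolower(regions$growth_pattern), regions$region_id)
  pi <- pat[pairs$region_i]
  pj <- pat[pairs$region_j]
  drop <- is.na(pi) | is.na(pj) | pi == "unknown" | pj == "unknown"
  if (any(drop))
    message(sum(drop), " pair(s) dropped for unknown growth pattern")
  out <- pairs[!drop, , drop = FALSE]
  out$pattern_relation <- ifelse(pi[!drop] == pj[!drop], "same", "different")
  if (!is.null(regions$purity)) {
    pur <- setNames(regions$purity, regions$region_id)
    out$purity_min_pair <- pmin(pur[out$region_i], pur[out$region_j])
  }
  out
}

#' Compare distances between same- and different-pattern pairs
#'
#' Fits a linear mixed-effects model (distance ~ pattern_relation with a
#' per-tumour random intercept) and reports the fixed-effect contrast
#' (different minus same) with its ANOVA p-value. By default the cohort
#' is restricted to tumours contributing both pair classes; an optional
#' purity filter drops pairs involving a low-purity region. A
#' single-tumour input falls back to ordinary least squares.
#'
#' @param pairs labelled pairs (see \code{\link{labelPatternRelation}}),
#'   possibly pooled over tumours.
#' @param minPurity drop pairs whose lower-purity region is below this
#'   (default 0: keep all; requires a \code{purity_min_pair} column).
#' @param restrictMixed keep only tumours with both same- and
#'   different-pattern pairs (default TRUE).
#' @return list with \code{effect} (different - same), \code{p},
#'   \code{n_same}, \code{n_different}, \code{n_tumours},
#'   \code{model} (\code{"lme"} or \code{"lm"}).
#' @export
comparePairDistances <- function(pairs, minPurity = 0,
                                 restrictMixed = TRUE) {
  df <- pairs
  if (minPurity > 0) {
    if (is.null(df$purity_min_pair))
      stop("purity filter requested but no purity_min_pair column")
    df <- df[df$purity_min_pair > minPurity, , drop = FALSE]
  }
  if (restrictMixed) {
    keep <- vapply(split(df$pattern_relation, df$tumour_id),
                   function(x) all(c("same", "different") %in% x), TRUE)
    df <- df[df$tumour_id %in% names(keep)[keep], , drop = FALSE]
  }
  if (!nrow(df) || length(unique(df$pattern_relation)) < 2)
    stop("degenerate design: need both same- and different-pattern pairs")
  df$pattern_relation <- factor(df$pattern_relation,
                                levels = c("same", "different"))
  nTum <- length(unique(df$tumour_id))
  if (stats::sd(df$distance) == 0) {
    # no variation at all: nothing to estimate
    return(list(effect = 0, p = 1,
                n_same = sum(df$pattern_relation == "same"),
                n_different = sum(df$pattern_relation == "different"),
                n_tumours = nTum, model = "degenerate"))
  }
  fit <- NULL
  if (nTum >= 2)
    fit <- tryCatch(
      nlme::lme(distance ~ pattern_relation, random = ~ 1 | tumour_id,
                data = df, method = "REML"),
      error = function(e) NULL)
  if (!is.null(fit)) {
    an <- stats::anova(fit)
    eff <- unname(nlme::fixef(fit)["pattern_relationdifferent"])
    p <- an["pattern_relation", "p-value"]
    model <- "lme"
  } else {
    fit <- stats::lm(distance ~ pattern_relation, data = df)
    eff <- unname(stats::coef(fit)["pattern_relationdifferent"])
    p <- stats::anova(fit)["pattern_relation", "Pr(>F)"]
    model <- "lm"
  }
  list(effect = eff, p = p,
       n_same = sum(df$pattern_relation == "same"),
       n_different = sum(df$pattern_relation == "different"),
       n_tumours = nTum, model = model)
}

#' All labelled inter-region distances for a cohort
#'
#' @param cohort list with \code{bundles} and \code{cytobands}.
#' @param kind \code{"loh"} or \code{"mutation"}.
#' @return pooled labelled pair data.frame.
#' @export
cohortPairDistances <- function(cohort, kind = c("loh", "mutation")) {
  kind <- match.arg(kind)
  out <- lapply(cohort$bundles, function(b) {
    mat <- binaryFeatureMatrix(b, kind, cohort$cytobands)
    if (ncol(mat) < 2) return(NULL)
    p <- suppressWarnings(pairwiseEuclidean(mat, tumourID(b)))
    if (!nrow(p)) return(NULL)
    labelPatternRelation(p, regionTable(b))
  })
  out <- out[!vapply(out, is.null, TRUE)]
  do.call(rbind, out)
}
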