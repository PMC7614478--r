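# SCNA state classification and clonality calling.
#
# Thresholds follow the ploidy-adjusted log2 convention: amplification at
# log2(4/2), gain at log2(2.5/2), loss at log2(1.5/2); LOH when the minor
# allele copy number is below 0.5; segments below the homozygous-deletion
# floor are excluded from state calling.

AMP_THRESHOLD <- log2(4 / 2)
GAIN_THRESHOLD <- log2(2.5 / 2)
LOSS_THRESHOLD <- log2(1.5 / 2)
LOH_MINOR_CN <- 0.5
AUTOSOMES <- as.character(1:22)

.isAutosome <- function(chrom) {
  sub("^chr", "", as.character(chrom)) %in% AUTOSOMES
}

#' Ploidy-adjusted log ratio
#'
#' @param totalCN total copy number (cnA + cnB), >= 0.
#' @param ploidy sample mean ploidy, > 0.
#' @return \code{log2(totalCN / ploidy)}; \code{-Inf} for zero copies.
#' @examples
#' ploidyAdjustedLogratio(4, 2)  # 1
#' @export
ploidyAdjustedLogratio <- function(totalCN, ploidy) {
  if (any(ploidy <= 0)) stop("ploidy must be > 0")
  if (any(totalCN < 0)) stop("total copy number must be >= 0")
  log2(totalCN / ploidy)
}

#' Classify allele-specific segment states
#'
#' Vectorised over segments. A segment is amplified when its
#' ploidy-adjusted log ratio reaches \code{log2(4/2)}, gained at
#' \code{log2(2.5/2)}, lost at \code{log2(1.5/2)} (thresholds inclusive);
#' LOH when \code{min(cnA, cnB) < 0.5} and the segment is not homozygously
#' deleted. Segments with total copy number below \code{homdelFloor} are
#' flagged \code{homdel_excluded} and carry no other state.
#'
#' @param cnA,cnB allele-specific copy numbers (>= 0).
#' @param ploidy sample mean ploidy (> 0).
#' @param homdelFloor total-CN floor below which a segment counts as a
#'   homozygous deletion (default 0.5).
#' @return data.frame with logical columns \code{amp}, \code{gain},
#'   \code{loss}, \code{loh}, \code{homdel_excluded} and numeric
#'   \code{logratio}.
#' @export
classifySegmentState <- function(cnA, cnB, ploidy, homdelFloor = 0.5) {
  if (any(cnA < 0) || any(cnB < 0)) stop("copy numbers must be >= 0")
  if (any(ploidy <= 0)) stop("ploidy must be > 0")
  total <- cnA + cnB
  lr <- log2(total / ploidy)
  homdel <- total < homdelFloor
  amp <- !homdel & lr >= AMP_THRESHOLD
  gain <- !homdel & lr >= GAIN_THRESHOLD
  loss <- !homdel & lr <= LOSS_THRESHOLD
  loh <- !homdel & pmin(cnA, cnB) < LOH_MINOR_CN
  data.frame(amp = amp, gain = gain, loss = loss, loh = loh,
             homdel_excluded = homdel, logratio = lr)
}

# annotate a segment GRanges with state flags for a given ploidy
.stateGRanges <- function(profile, ploidy, homdelFloor = 0.5) {
  st <- classifySegmentState(mcols(profile)$cnA, mcols(profile)$cnB,
                             ploidy, homdelFloor)
  mcols(profile) <- cbind(mcols(profile), st)
  profile
}

# GRanges of whole arms from a cytoband map, named "<chrom><arm>"
.armRanges <- function(cytobands) {
  key <- paste0(as.character(seqnames(cytobands)), mcols(cytobands)$arm)
  spl <- split(cytobands, key)
  gr <- unlist(GenomicRanges::GRangesList(lapply(spl, function(g)
    GRanges(seqnames(g)[1], IRanges(min(start(g)), max(end(g)))))))
  names(gr) <- names(spl)
  gr
}

#' Fraction of a chromosome arm altered by an event
#'
#' Base-pair length of the arm covered by segments carrying the event
#' (per \code{\link{classifySegmentState}}), divided by the arm length.
#' Bases not covered by any segment count as unaltered.
#'
#' @param profile segment \code{GRanges} with \code{cnA}, \code{cnB}.
#' @param arm arm name, e.g. \code{"5q"} (chromosome followed by p/q).
#' @param event one of \code{"gain"}, \code{"loss"}, \code{"loh"},
#'   \code{"amp"}.
#' @param ploidy region mean ploidy.
#' @param cytobands cytoband \code{GRanges} (mcols \code{band},
#'   \code{arm}).
#' @param homdelFloor see \code{\link{classifySegmentState}}.
#' @return fraction in \[0, 1\].
#' @export
armFractionAltered <- function(profile, arm, event, ploidy, cytobands,
                               homdelFloor = 0.5) {
  arms <- .armRanges(cytobands)
  if (!(arm %in% names(arms)))
    stop("unknown arm '", arm, "'")
  armGR <- arms[arm]
  st <- .stateGRanges(profile, ploidy, homdelFloor)
  hits <- st[mcols(st)[[event]] %in% TRUE]
  if (!length(hits)) return(0)
  ov <- findOverlaps(hits, armGR)
  if (!length(ov)) return(0)
  inter <- pintersect(hits[S4Vectors::queryHits(ov)],
                      armGR[S4Vectors::subjectHits(ov)])
  sum(width(reduce(granges(inter)))) / sum(width(armGR))
}

#' Detect mirrored subclonal allelic imbalance (MSAI)
#'
#' MSAI is present when two regions carry allelic imbalance over the same
#' genomic interval but on opposite parental haplotypes (region i has
#' cnA - cnB > delta where region j has cnB - cnA > delta). Requires
#' phased profiles with consistent A/B labels across regions.
#'
#' @param profiles named list of segment \code{GRanges} (>= 2 regions).
#' @param interval \code{GRanges} of length 1: the interval to test.
#' @param delta imbalance margin in copies (default 0.5).
#' @param minOverlap minimum fraction of the interval over which the
#'   opposite imbalance must hold (default 0.5).
#' @return list with \code{msai} (logical) and \code{pair} (character
#'   vector of the witnessing region pair, or NULL).
#' @export
detectMSAI <- function(profiles, interval, delta = 0.5, minOverlap = 0.5) {
  if (length(profiles) < 2) return(list(msai = FALSE, pair = NULL))
  for (p in profiles)
    if (is.null(mcols(p)$cnA) || is.null(mcols(p)$cnB))
      stop("unphased input: cnA/cnB required; use presence-only mode")
  need <- minOverlap * sum(width(interval))
  ids <- names(profiles)
  imbal <- lapply(profiles, function(p) {
    ov <- findOverlaps(p, interval)
    if (!length(ov)) return(GRanges())
    seg <- pintersect(p[S4Vectors::queryHits(ov)],
                      interval[S4Vectors::subjectHits(ov)])
    d <- mcols(p)$cnA[S4Vectors::queryHits(ov)] -
      mcols(p)$cnB[S4Vectors::queryHits(ov)]
    mcols(seg)$dir <- sign(d) * (abs(d) > delta)
    seg
  })
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      aPos <- reduce(granges(imbal[[i]][mcols(imbal[[i]])$dir == 1]))
      aNeg <- reduce(granges(imbal[[i]][mcols(imbal[[i]])$dir == -1]))
      bPos <- reduce(granges(imbal[[j]][mcols(imbal[[j]])$dir == 1]))
      bNeg <- reduce(granges(imbal[[j]][mcols(imbal[[j]])$dir == -1]))
      w1 <- sum(width(GenomicRanges::intersect(aPos, bNeg)))
      w2 <- sum(width(GenomicRanges::intersect(aNeg, bPos)))
      if (max(w1, w2) >= need)
        return(list(msai = TRUE, pair = c(ids[i], ids[j])))
    }
  }
  list(msai = FALSE, pair = NULL)
}

#' Call arm-level event clonality across regions
#'
#' Truncal when at least one region shows >= 98 per cent of the arm
#' altered and every remaining region shows >= 75 per cent, without
#' mirrored subclonal allelic imbalance over the arm; subclonal when some
#' region falls below 75 per cent or MSAI is detected; absent when no
#' region reaches 98 per cent. LOH arm events use the same thresholds on
#' the LOH fraction. Under \code{clonalityMode = "ubiquity"} an event is
#' truncal iff present (fraction >= \code{ubiquityMin}) in all regions.
#'
#' @param bundle a \code{\linkS4class{TumourBundle}}.
#' @param arm arm name, e.g. \code{"3q"}.
#' @param event \code{"gain"}, \code{"loss"} or \code{"loh"}.
#' @param cytobands cytoband \code{GRanges}.
#' @param highFrac,lowFrac the 0.98 / 0.75 thresholds.
#' @param clonalityMode \code{"threshold_rules"} (default) or
#'   \code{"ubiquity"}.
#' @param ubiquityMin presence threshold for ubiquity mode (default 0.5).
#' @param ... passed to \code{\link{detectMSAI}}.
#' @return list with \code{arm}, \code{event}, \code{clonality}
#'   (\code{"truncal"}, \code{"subclonal"} or \code{"absent"}),
#'   \code{msai}, and \code{fractions} (named per-region vector).
#' @export
callArmClonality <- function(bundle, arm, event, cytobands,
                             highFrac = 0.98, lowFrac = 0.75,
                             clonalityMode = c("threshold_rules", "ubiquity"),
                             ubiquityMin = 0.5, ...) {
  clonalityMode <- match.arg(clonalityMode)
  reg <- regionTable(bundle)
  profs <- segmentProfiles(bundle)
  frac <- vapply(reg$region_id, function(rid)
    armFractionAltered(profs[[rid]], arm, event,
                       reg$ploidy[reg$region_id == rid], cytobands),
    numeric(1))
  armGR <- .armRanges(cytobands)[arm]
  ms <- if (length(profs) >= 2) detectMSAI(profs, armGR, ...)
        else list(msai = FALSE, pair = NULL)
  if (clonalityMode == "ubiquity") {
    clon <- if (all(frac >= ubiquityMin)) "truncal"
            else if (any(frac >= ubiquityMin)) "subclonal" else "absent"
    if (clon == "truncal" && ms$msai) clon <- "subclonal"
    return(list(arm = arm, event = event, clonality = clon,
                msai = ms$msai, fractions = frac))
  }
  clon <- if (max(frac) < highFrac) "absent"
          else if (all(frac >= lowFrac) && !ms$msai) "truncal"
          else "subclonal"
  list(arm = arm, event = event, clonality = clon, msai = ms$msai,
       fractions = frac)
}

# length-weighted mean total CN of a profile over an interval; NA when the
# interval is uncovered
.meanIntervalCN <- function(profile, interval) {
  ov <- findOverlaps(profile, interval)
  if (!length(ov)) return(NA_real_)
  seg <- pintersect(profile[S4Vectors::queryHits(ov)],
                    interval[S4Vectors::subjectHits(ov)])
  cn <- mcols(profile)$cnA[S4Vectors::queryHits(ov)] +
    mcols(profile)$cnB[S4Vectors::queryHits(ov)]
  sum(cn * width(seg)) / sum(width(seg))
}

#' Call clonality of a gene/interval amplification
#'
#' An interval is amplified in a region when its length-weighted mean
#' copy number reaches twice the region ploidy (the log2(4/2)
#' amplification threshold). With at least one amplified region, the
#' amplification is truncal when every other region shows mean CN of at
#' least ploidy + 1 and no mirrored subclonal allelic imbalance overlaps
#' the interval; otherwise subclonal. \code{"none"} when no region is
#' amplified.
#'
#' @param bundle a \code{TumourBundle}.
#' @param interval \code{GRanges} of length 1.
#' @param ... passed to \code{\link{detectMSAI}}.
#' @return \code{"truncal"}, \code{"subclonal"} or \code{"none"}.
#' @export
callAmplificationClonality <- function(bundle, interval, ...) {
  reg <- regionTable(bundle)
  profs <- segmentProfiles(bundle)
  cn <- vapply(reg$region_id, function(rid)
    .meanIntervalCN(profs[[rid]], interval), numeric(1))
  uncovered <- is.na(cn)
  if (any(uncovered))
    warning("interval uncovered in region(s): ",
            paste(reg$region_id[uncovered], collapse = ", "),
            " (treated as not amplified)")
  amped <- !uncovered & cn >= 2 * reg$ploidy
  if (!any(amped)) return("none")
  gained <- !uncovered & cn >= reg$ploidy + 1
  ms <- if (length(profs) >= 2) detectMSAI(profs, interval, ...)
        else list(msai = FALSE)
  if (all(amped | gained) && !ms$msai) "truncal" else "subclonal"
}

#' Classify a focal interval gain across regions
#'
#' Computes the length-weighted mean ploidy-adjusted copy number of the
#' interval per region, log2 transformed. Truncal when all regions exceed
#' the threshold; subclonal when at least one but not all do; none
#' otherwise. The comparison is strict (>), matching the gain-call
#' convention for focal peak intervals.
#'
#' @param bundle a \code{TumourBundle}.
#' @param interval \code{GRanges} of length 1 (e.g. the 3q peak
#'   chr3:131091386-191871390).
#' @param threshold log2 threshold (default \code{log2(2.5/2)}).
#' @return \code{"truncal"}, \code{"subclonal"} or \code{"none"}.
#' @export
classifyFocalGain <- function(bundle, interval, threshold = GAIN_THRESHOLD) {
  reg <- regionTable(bundle)
  profs <- segmentProfiles(bundle)
  lr <- vapply(seq_len(nrow(reg)), function(i) {
    cn <- .meanIntervalCN(profs[[reg$region_id[i]]], interval)
    if (is.na(cn)) NA_real_ else log2(cn / reg$ploidy[i])
  }, numeric(1))
  if (any(is.na(lr))) {
    warning("interval uncovered in region(s): ",
            paste(reg$region_id[is.na(lr)], collapse = ", "),
            " (treated as not gained)")
    lr[is.na(lr)] <- -Inf
  }
  gained <- lr > threshold
  if (all(gained)) "truncal" else if (any(gained)) "subclonal" else "none"
}

#' Build a minimum-consistent single-sample profile
#'
#' Uniformly segments all regions over the union of their breakpoints and
#' takes, per resulting segment, the minimum ploidy-corrected total copy
#' number (total CN / ploidy x 2) across the regions covering it. This is
#' the single-sample profile construction used to feed recurrence analysis
#' of copy-number peaks.
#'
#' @param profiles named list of segment \code{GRanges}.
#' @param ploidies numeric vector of ploidies, in the same order (or named
#'   by region).
#' @return \code{GRanges} with metadata column \code{cn} (ploidy-corrected
#'   total copy number).
#' @export
buildMinConsistentProfile <- function(profiles, ploidies) {
  if (!length(profiles)) stop("empty profile set")
  if (!is.null(names(ploidies)) && !is.null(names(profiles)))
    ploidies <- ploidies[names(profiles)]
  corrected <- mapply(function(p, pl) {
    mcols(p)$cn <- (mcols(p)$cnA + mcols(p)$cnB) / pl * 2
    p
  }, profiles, ploidies, SIMPLIFY = FALSE)
  bins <- disjoin(unlist(GenomicRanges::GRangesList(
    lapply(corrected, granges))))
  vals <- matrix(NA_real_, length(bins), length(corrected))
  for (k in seq_along(corrected)) {
    ov <- findOverlaps(bins, corrected[[k]])
    vals[S4Vectors::queryHits(ov), k] <-
      mcols(corrected[[k]])$cn[S4Vectors::subjectHits(ov)]
  }
  cn <- apply(vals, 1, function(x) if (all(is.na(x))) NA_real_
              else min(x, na.rm = TRUE))
  keep <- !is.na(cn)
  out <- bins[keep]
  mcols(out)$cn <- cn[keep]
  sort(out)
}

#' Export a profile as a GISTIC-style seg table
#'
#' @param profile \code{GRanges} with a \code{cn} metadata column (see
#'   \code{\link{buildMinConsistentProfile}}).
#' @param sample sample identifier.
#' @return data.frame with columns sample, chrom, start, end, num_markers,
#'   log2ratio. \code{num_markers} is a synthetic stand-in (segment length
#'   / 1000, rounded) since marker counts are not carried by the profile.
#' @export
gisticSegTable <- function(profile, sample) {
  data.frame(sample = sample,
             chrom = as.character(seqnames(profile)),
             start = start(profile), end = end(profile),
             num_markers = round(width(profile) / 1000),
             log2ratio = log2(pmax(mcols(profile)$cn, 1e-6) / 2))
}
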