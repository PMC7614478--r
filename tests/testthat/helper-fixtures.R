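# Shared fixture builders. All fixtures are constructed in code; the
# toy genome has one or two chromosomes with kilobase-scale arms so
# per-base brute-force oracles stay cheap.

library(GenomicRanges)

# segment GRanges from parallel vectors
segGR <- function(chrom, start, end, cnA, cnB) {
  GRanges(chrom, IRanges(start, end), cnA = cnA, cnB = cnB)
}

# toy cytoband map: one chromosome, p arm 1-4000 (2 bands), q arm
# 4001-10000 (2 bands)
toyCytobands <- function() {
  GRanges("1", IRanges(c(1, 2001, 4001, 7001),
                       c(2000, 4000, 7000, 10000)),
          band = c("p1", "p2", "q1", "q2"),
          arm = c("p", "p", "q", "q"))
}

# minimal valid clone tree: root C1 (ccf 1) with child C2
toyTree <- function(tid = "T1", regions = c("R1", "R2"),
                    childCCF = c(0.4, 0.6)) {
  ccf <- rbind(C1 = rep(1, length(regions)), C2 = childCCF)
  colnames(ccf) <- regions
  CloneTree(tid, c(C1 = NA_character_, C2 = "C1"), ccf,
            c(C1 = 10L, C2 = 5L))
}

toyMutations <- function(tree) {
  ccf <- ccfMatrix(tree)
  n <- mutationCounts(tree)
  cl <- rep(rownames(ccf), n)
  df <- data.frame(mutation_id = paste0("M", seq_along(cl)),
                   cluster_id = cl)
  cbind(df, as.data.frame(ccf[cl, , drop = FALSE], row.names = NULL))
}

# a small fully consistent bundle over the toy genome
toyBundle <- function(tid = "T1") {
  tree <- toyTree(tid)
  regions <- data.frame(region_id = c("R1", "R2"),
                        purity = c(0.5, 0.6), ploidy = c(2, 2),
                        growth_pattern = c("acinar", "solid"),
                        seeding_label = c("non_seeding", "seeding"))
  segs <- list(
    R1 = segGR("1", c(1, 4001), c(4000, 10000), c(1, 1), c(1, 1)),
    R2 = segGR("1", c(1, 4001), c(4000, 10000), c(1, 2), c(1, 1)))
  TumourBundle(tid, regions, segs, tree, toyMutations(tree),
               list(pattern_pct = c(acinar = 50, solid = 50),
                    predominant = "acinar", stas = FALSE,
                    necrosis = FALSE, relapse = "none"))
}

# random segment profile over [1, len] on one chromosome: contiguous
# segments with integer-ish allele copies; used by per-base oracles
randomProfile <- function(len = 10000, nSeg = 6, chrom = "1") {
  cuts <- sort(sample(seq_len(len - 1), nSeg - 1))
  start <- c(1, cuts + 1)
  end <- c(cuts, len)
  cnA <- sample(0:3, nSeg, replace = TRUE)
  cnB <- sample(0:2, nSeg, replace = TRUE)
  segGR(chrom, start, end, cnA, cnB)
}

# per-base state oracle over a profile restricted to [1, len]
baseStates <- function(profile, ploidy, len) {
  state <- data.frame(gain = rep(FALSE, len), loss = FALSE, loh = FALSE,
                      covered = FALSE, homdel = FALSE)
  for (i in seq_along(profile)) {
    idx <- start(profile)[i]:end(profile)[i]
    st <- classifySegmentState(mcols(profile)$cnA[i],
                               mcols(profile)$cnB[i], ploidy)
    state$covered[idx] <- !st$homdel_excluded
    state$homdel[idx] <- st$homdel_excluded
    state$gain[idx] <- st$gain
    state$loss[idx] <- st$loss
    state$loh[idx] <- st$loh
  }
  state
}

eligibleTable <- function(cohort, purityMin = 0.15) {
  do.call(rbind, lapply(cohort$bundles, function(b) {
    r <- suppressWarnings(eligibleRegions(regionTable(b), purityMin))
    if (!nrow(r)) return(NULL)
    cbind(tumour_id = tumourID(b), r)
  }))
}
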